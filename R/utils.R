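# Internal helpers: classed errors, seed scoping, table checks.

abort_metarep <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "metarep_error"), ...)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state;
# a NULL seed uses (and advances) the current stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort_metarep("`seed` must be a single integer or NULL.",
                    "metarep_domain_error")
    }
    withr::with_seed(as.integer(seed), expr)
  }
}

check_positive_scalar <- function(x, name, integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 &&
    (!integer || x == trunc(x))
  if (!ok) {
    abort_metarep(
      sprintf("`%s` must be a single positive %s.", name,
              if (integer) "integer" else "number"),
      "metarep_domain_error")
  }
  invisible(x)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    abort_metarep("`level` must be a single number strictly between 0 and 1.",
                  "metarep_domain_error")
  }
  invisible(level)
}

# A counts table is a data frame with a `gene_id` character key column and
# one or more numeric sample columns of non-negative whole numbers.
check_counts_table <- function(counts, arg = "counts") {
  if (!is.data.frame(counts) || !"gene_id" %in% names(counts)) {
    abort_metarep(sprintf("`%s` must be a data frame with a `gene_id` column.",
                          arg), "metarep_schema_error")
  }
  samples <- setdiff(names(counts), "gene_id")
  if (length(samples) == 0L) {
    abort_metarep(sprintf("`%s` has no sample columns.", arg),
                  "metarep_schema_error")
  }
  if (anyDuplicated(counts$gene_id)) {
    abort_metarep(sprintf("`%s` has duplicated gene ids.", arg),
                  "metarep_schema_error")
  }
  for (s in samples) {
    v <- counts[[s]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != trunc(v))) {
      abort_metarep(
        sprintf("column `%s` of `%s` must hold non-negative integer counts.",
                s, arg),
        "metarep_schema_error")
    }
  }
  samples
}

sample_columns <- function(tbl, key = "gene_id") setdiff(names(tbl), key)
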
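# Rarefaction of mapped read counts and length-normalised relative abundance.

# One multivariate-hypergeometric draw: subsample `depth` reads without
# replacement from a vector of per-gene counts. Sequential conditional
# hypergeometric draws, O(n genes).
rmvhyper <- function(counts, depth) {
  n <- length(counts)
  out <- integer(n)
  remaining <- sum(counts)
  k <- depth
  for (i in seq_len(n)) {
    if (k == 0L) break
    ci <- counts[i]
    x <- rhyper(1L, ci, remaining - ci, k)
    out[i] <- x
    k <- k - x
    remaining <- remaining - ci
  }
  out
}

#' Downsize (rarefy) a count table to a fixed depth
#'
#' Subsamples reads without replacement (a multivariate hypergeometric draw)
#' so that every sample column sums to exactly `depth`, equalising sequencing
#' effort across samples. Samples already at `depth` pass through unchanged.
#'
#' @param counts Counts tibble: `gene_id` plus integer sample columns.
#' @param depth Target number of reads per sample. The conventional depth for
#'   gut-metagenome platform comparisons is 20 million uniquely mapped reads.
#' @param seed Integer seed making the draw reproducible, or `NULL`.
#' @param on_short What to do with samples whose total is below `depth`:
#'   `"error"` (default) or `"keep"` to pass them through undownsized, as one
#'   does for runs too shallow to rarefy.
#' @return A counts tibble of the same shape.
#' @export
downsample_counts <- function(counts, depth = 2e7, seed = NULL,
                              on_short = c("error", "keep")) {
  samples <- check_counts_table(counts)
  check_positive_scalar(depth, "depth", integer = TRUE)
  on_short <- match.arg(on_short)
  with_seed_or_current(seed, {
    for (s in samples) {
      total <- sum(counts[[s]])
      if (total < depth) {
        if (on_short == "error") {
          abort_metarep(
            sprintf("sample `%s` has %d reads, fewer than depth %d.",
                    s, total, as.integer(depth)),
            "metarep_depth_error")
        }
        next
      }
      if (total > depth) {
        counts[[s]] <- rmvhyper(as.integer(counts[[s]]), as.integer(depth))
      }
    }
    counts
  })
}

#' Length-normalised relative abundance
#'
#' For gene g with count c_g and length L_g, the relative abundance is
#' `(c_g / L_g) / sum_j(c_j / L_j)`, the standard gene-catalog normalisation:
#' dividing by length removes the advantage long genes have in recruiting
#' reads, and the profile is invariant to global rescaling of counts.
#'
#' @param counts Counts tibble: `gene_id` plus integer sample columns.
#' @param catalog Gene catalog tibble with `gene_id` and `length_bp`; must
#'   cover every gene in `counts`.
#' @return A tibble of the same shape as `counts` whose sample columns each
#'   sum to 1.
#' @export
relative_abundance <- function(counts, catalog) {
  samples <- check_counts_table(counts)
  stopifnot(is.data.frame(catalog),
            all(c("gene_id", "length_bp") %in% names(catalog)))
  len <- catalog$length_bp[match(counts$gene_id, catalog$gene_id)]
  if (anyNA(len)) {
    abort_metarep("`catalog` lacks lengths for some genes in `counts`.",
                  "metarep_schema_error")
  }
  if (any(len <= 0)) {
    abort_metarep("gene lengths must be positive.", "metarep_schema_error")
  }
  for (s in samples) {
    w <- counts[[s]] / len
    tot <- sum(w)
    if (tot <= 0) {
      abort_metarep(
        sprintf("sample `%s` has all-zero counts; profile undefined.", s),
        "metarep_domain_error")
    }
    counts[[s]] <- w / tot
  }
  counts
}
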
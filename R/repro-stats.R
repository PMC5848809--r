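# Highly-reproducible-gene selection and replicate reproducibility
# statistics: Spearman correlation, the ALC mean-difference statistic, and
# per-gene paired tests with Benjamini-Hochberg FDR control.

check_pairs <- function(pairs, samples) {
  if (!is.data.frame(pairs) ||
      !all(c("sample_a", "sample_b") %in% names(pairs)) || nrow(pairs) < 1L) {
    abort_metarep(
      "`pairs` must be a data frame with columns `sample_a`, `sample_b`.",
      "metarep_input_error")
  }
  missing <- setdiff(c(pairs$sample_a, pairs$sample_b), samples)
  if (length(missing)) {
    abort_metarep(sprintf("paired sample(s) not found in table: %s",
                          paste(missing, collapse = ", ")),
                  "metarep_input_error")
  }
  pairs
}

#' Select highly reproducible (HR) genes
#'
#' A gene qualifies in a replicate pair when it has at least `min_count`
#' mapped reads in *both* members; HR genes are those qualifying in at least
#' `min_pairs` of the pairs. For a single-pair analysis use `min_pairs = 1`.
#'
#' @param counts Counts tibble: `gene_id` plus integer sample columns.
#' @param pairs Data frame with columns `sample_a` and `sample_b`, one row per
#'   replicate pair.
#' @param min_count Read-count floor, default 10.
#' @param min_pairs Number of pairs a gene must qualify in; default
#'   `min(6, nrow(pairs))`, the conventional at-least-6-pairs rule capped at
#'   the number of pairs available.
#' @return A tibble `gene_id`, `n_pairs_detected`, restricted to HR genes.
#' @export
hr_genes <- function(counts, pairs, min_count = 10L, min_pairs = NULL) {
  samples <- check_counts_table(counts)
  pairs <- check_pairs(pairs, samples)
  check_positive_scalar(min_count, "min_count", integer = TRUE)
  if (is.null(min_pairs)) min_pairs <- min(6L, nrow(pairs))
  check_positive_scalar(min_pairs, "min_pairs", integer = TRUE)
  if (min_pairs > nrow(pairs)) {
    abort_metarep(sprintf("`min_pairs` (%d) exceeds the number of pairs (%d).",
                          as.integer(min_pairs), nrow(pairs)),
                  "metarep_input_error")
  }
  det <- rowSums(do.call(cbind, lapply(seq_len(nrow(pairs)), function(i) {
    counts[[pairs$sample_a[i]]] >= min_count &
      counts[[pairs$sample_b[i]]] >= min_count
  })))
  tibble(gene_id = counts$gene_id, n_pairs_detected = as.integer(det)) |>
    filter(.data$n_pairs_detected >= min_pairs)
}

#' Spearman correlation of two abundance profiles
#'
#' Rank correlation with average ranks for ties (equivalently, the Pearson
#' correlation of the rank vectors), over a common set of genes.
#'
#' @param profiles Tibble: `gene_id` plus numeric sample columns.
#' @param sample_a,sample_b Names of the two profile columns to correlate.
#' @param genes Optional character vector restricting to a gene subset
#'   (e.g. HR genes).
#' @return A one-row tibble: `rho`, `n`.
#' @export
spearman_cor <- function(profiles, sample_a, sample_b, genes = NULL) {
  stopifnot(is.data.frame(profiles), "gene_id" %in% names(profiles))
  if (!all(c(sample_a, sample_b) %in% names(profiles))) {
    abort_metarep("`sample_a`/`sample_b` must name columns of `profiles`.",
                  "metarep_input_error")
  }
  if (!is.null(genes)) {
    profiles <- profiles[profiles$gene_id %in% genes, , drop = FALSE]
  }
  a <- profiles[[sample_a]]
  b <- profiles[[sample_b]]
  if (length(a) < 3L) {
    abort_metarep("need at least 3 genes for a rank correlation.",
                  "metarep_domain_error")
  }
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) {
    abort_metarep("rank correlation undefined for a constant profile.",
                  "metarep_domain_error")
  }
  tibble(rho = cor(a, b, method = "spearman"), n = length(a))
}

#' ALC: mean absolute log2 abundance difference between two profiles
#'
#' For each gene, `d_g = |log2(a_g / b_g)|`; the ALC is the mean of `d_g`,
#' which equals the area left of the cumulative distribution curve of the
#' differences, and converts to a mean fold change as `2^ALC` (1 means the
#' profiles agree perfectly; a low ALC denotes high reproducibility).
#'
#' @inheritParams spearman_cor
#' @param genes Character vector of genes to compare (typically HR genes);
#'   every gene must have positive abundance in both profiles.
#' @return An object of class `alc_result` holding the per-gene differences;
#'   [glance()] gives `alc`, `fold_change`, `n_genes`.
#' @export
alc <- function(profiles, sample_a, sample_b, genes = NULL) {
  stopifnot(is.data.frame(profiles), "gene_id" %in% names(profiles))
  if (!is.null(genes)) {
    profiles <- profiles[profiles$gene_id %in% genes, , drop = FALSE]
  }
  a <- profiles[[sample_a]]
  b <- profiles[[sample_b]]
  if (length(a) == 0L) {
    abort_metarep("no genes to compare.", "metarep_domain_error")
  }
  if (any(a <= 0) || any(b <= 0)) {
    abort_metarep(
      "zero abundance among compared genes; restrict to HR genes first.",
      "metarep_domain_error")
  }
  d <- abs(log2(a / b))
  structure(list(alc = mean(d), fold_change = 2^mean(d),
                 n_genes = length(d), d = d,
                 samples = c(sample_a, sample_b)),
            class = "alc_result")
}

#' @exportS3Method generics::glance
glance.alc_result <- function(x, ...) {
  tibble(alc = x$alc, fold_change = x$fold_change, n_genes = x$n_genes)
}

#' @exportS3Method generics::tidy
tidy.alc_result <- function(x, ...) tibble(d = x$d)

#' @export
print.alc_result <- function(x, ...) {
  cat(sprintf("ALC over %d genes: %.4f (mean fold change %.3f)\n",
              x$n_genes, x$alc, x$fold_change))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`,
#' returned in the input order. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort_metarep("p-values must lie in [0, 1].", "metarep_domain_error")
  }
  p.adjust(pvals, method = "BH")
}

# Exact two-sided sign-test p for k successes of n (memoised over the few
# distinct (k, n) combinations that occur).
sign_test_p <- function(k, n) {
  key <- paste(k, n)
  u <- !duplicated(key)
  pu <- mapply(function(k1, n1) {
    if (n1 == 0L) return(1)
    stats::binom.test(k1, n1, p = 0.5)$p.value
  }, k[u], n[u])
  unname(pu[match(key, key[u])])
}

#' Per-gene paired tests between two replicate groups
#'
#' For each gene and each replicate pair, computes the log2 difference of
#' relative abundances (pairs where either member is zero are dropped for
#' that gene). Two paired tests are run per gene: a t test on the log2
#' differences (requiring at least 3 usable pairs) and an exact two-sided
#' sign test on the signs of the differences (zero differences dropped, the
#' standard exact-sign-test convention). Each test family is
#' Benjamini-Hochberg adjusted separately; a gene is significant when either
#' family's adjusted value falls below `alpha`.
#'
#' @param profiles Relative-abundance tibble: `gene_id` plus sample columns
#'   covering every sample named in `pairs`.
#' @param pairs Data frame with columns `sample_a`, `sample_b`.
#' @param genes Character vector of genes to test (typically from
#'   [hr_genes()] with the at-least-6-pairs rule).
#' @param alpha FDR level, default 0.05.
#' @return A tibble with one row per gene: `gene_id`, `n_pairs`,
#'   `mean_log2fc`, `p_t`, `p_sign`, `q_t`, `q_sign`, `significant`.
#' @export
paired_gene_tests <- function(profiles, pairs, genes, alpha = 0.05) {
  stopifnot(is.data.frame(profiles), "gene_id" %in% names(profiles))
  pairs <- check_pairs(pairs, names(profiles))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_metarep("`alpha` must lie strictly between 0 and 1.",
                  "metarep_domain_error")
  }
  profiles <- profiles[profiles$gene_id %in% genes, , drop = FALSE]
  if (nrow(profiles) == 0L) {
    abort_metarep("none of `genes` are present in `profiles`.",
                  "metarep_input_error")
  }
  A <- as.matrix(profiles[, pairs$sample_a, drop = FALSE])
  B <- as.matrix(profiles[, pairs$sample_b, drop = FALSE])
  D <- log2(A) - log2(B)
  D[A <= 0 | B <= 0] <- NA  # pair unusable for this gene

  n_pairs <- rowSums(!is.na(D))
  dbar <- rowMeans(D, na.rm = TRUE)
  dsd <- apply(D, 1L, stats::sd, na.rm = TRUE)

  # paired t on log2 differences; skipped (NA) below 3 usable pairs;
  # all-equal differences give t = 0 -> p = 1 via the sd == 0 branch.
  p_t <- rep(NA_real_, nrow(D))
  ok <- n_pairs >= 3L
  degen <- ok & (dsd == 0)
  p_t[degen & dbar == 0] <- 1
  p_t[degen & dbar != 0] <- 0
  use <- ok & !degen
  tstat <- dbar[use] / (dsd[use] / sqrt(n_pairs[use]))
  p_t[use] <- 2 * pt(-abs(tstat), df = n_pairs[use] - 1L)

  nonzero <- rowSums(D != 0, na.rm = TRUE)
  kpos <- rowSums(D > 0, na.rm = TRUE)
  p_sign <- sign_test_p(kpos, nonzero)

  q_t <- rep(NA_real_, length(p_t))
  q_t[!is.na(p_t)] <- bh_adjust(p_t[!is.na(p_t)])
  q_sign <- bh_adjust(p_sign)

  tibble(gene_id = profiles$gene_id,
         n_pairs = as.integer(n_pairs),
         mean_log2fc = dbar,
         p_t = p_t, p_sign = p_sign, q_t = q_t, q_sign = q_sign,
         significant = pmin(ifelse(is.na(q_t), Inf, q_t), q_sign) < alpha)
}
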
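# Read-count fluctuation intervals between equal-depth technical replicates.
#
# Given a gene's count k in replicate 1, which replicate-2 counts are
# consistent with pure counting noise? Three exchangeable-replicate nulls are
# offered; all intervals are two-sided equal-tail discrete quantile intervals
# with the CDF accumulated by direct pmf summation, ties resolved toward the
# wider (conservative) side.
#
# * "predictive" (default): replicate-2 count ~ NegBin(size = k, prob = 1/2),
#   the posterior predictive of an equal-depth Poisson replicate under a
#   scale-invariant prior. Its variance 2k owns up to the fact that BOTH
#   replicates are noisy, which is what makes the observed concordance of
#   twin replicates reach the nominal level.
# * "poisson": replicate-2 count ~ Poisson(k) - treats k as the true mean.
# * "binomial": replicate-2 count ~ Binomial(depth, k / depth), the exact
#   finite-depth thinning version of "poisson".

fluct_models <- c("predictive", "poisson", "binomial")

fluct_pmf <- function(k, model, depth) {
  switch(model,
    predictive = function(x) dnbinom(x, size = k, prob = 0.5),
    poisson    = function(x) dpois(x, k),
    binomial   = function(x) dbinom(x, size = depth, prob = k / depth))
}

# Equal-tail interval for one count. lo = max{j : P(X < j) <= alpha/2},
# hi = min{j : P(X <= j) >= 1 - alpha/2}.
fluct_interval_one <- function(k, level, model, depth) {
  if (k == 0L) return(c(0L, 0L))
  alpha <- (1 - level) / 2
  sdk <- sqrt(if (model == "predictive") 2 * k else k)
  kmax <- ceiling(k + 12 * sdk + 30)
  if (model == "binomial") kmax <- min(kmax, depth)
  cdf <- cumsum(fluct_pmf(k, model, depth)(0:kmax))
  lo <- sum(cdf <= alpha)                  # number of j-1 values passing
  hi <- which(cdf >= 1 - alpha)[1] - 1L
  c(lo, hi)
}

#' Concordance interval for a replicate read count
#'
#' For each replicate-1 count, the equal-tail `level` interval of replicate-2
#' counts consistent with equal-depth resampling noise. A count of 0 yields
#' the degenerate interval \[0, 0\].
#'
#' @param count1 Vector of non-negative integer replicate-1 counts.
#' @param level Interval level, default 0.99.
#' @param model Fluctuation null: `"predictive"` (default; negative-binomial
#'   with variance `2 * count1`, accounting for counting noise in both
#'   replicates), `"poisson"`, or `"binomial"`.
#' @param depth Sample depth, required for `model = "binomial"`.
#' @return A tibble with columns `count1`, `lo`, `hi`.
#' @examples
#' fluctuation_interval(10)  # a 10-read gene is expected to reappear
#' @export
fluctuation_interval <- function(count1, level = 0.99,
                                 model = c("predictive", "poisson",
                                           "binomial"),
                                 depth = NULL) {
  check_level(level)
  model <- match.arg(model)
  if (!is.numeric(count1) || anyNA(count1) || any(count1 < 0) ||
      any(count1 != trunc(count1))) {
    abort_metarep("`count1` must be non-negative integers.",
                  "metarep_domain_error")
  }
  if (model == "binomial") {
    check_positive_scalar(depth, "depth", integer = TRUE)
    if (any(count1 > depth)) {
      abort_metarep("`count1` cannot exceed `depth`.", "metarep_domain_error")
    }
  }
  u <- sort(unique(as.integer(count1)))
  iv <- vapply(u, fluct_interval_one, integer(2),
               level = level, model = model, depth = depth)
  idx <- match(as.integer(count1), u)
  tibble(count1 = as.integer(count1), lo = iv[1L, idx], hi = iv[2L, idx])
}

#' Smallest replicate-1 count guaranteeing detection in replicate 2
#'
#' Scans upward for the first count whose fluctuation interval has a lower
#' bound of at least 1 read: genes at or above this count are expected to
#' reappear in an equal-depth replicate at the given level.
#'
#' @inheritParams fluctuation_interval
#' @return A single integer count.
#' @export
detectability_threshold <- function(level = 0.99,
                                    model = c("predictive", "poisson",
                                              "binomial"),
                                    depth = NULL) {
  check_level(level)
  model <- match.arg(model)
  for (k in 1:10000) {
    if (fluct_interval_one(k, level, model, depth)[1] >= 1L) return(k)
  }
  abort_metarep("no detectability threshold found below 10000.",
                "metarep_domain_error")
}

#' Fraction of genes inside their fluctuation interval
#'
#' Evaluates, over genes with at least one replicate-1 read, whether the
#' replicate-2 count falls inside the replicate-1 count's concordance
#' interval, and summarises the fraction that do. This is the per-gene
#' concordance a platform comparison quotes ("x% of genes showed the expected
#' read count fluctuations").
#'
#' @param counts Counts tibble: `gene_id` plus integer sample columns.
#' @param rep1,rep2 Names of the two replicate columns in `counts`.
#' @inheritParams fluctuation_interval
#' @return An object of class `fluctuation_coverage`: the per-gene tibble
#'   (`gene_id`, `count1`, `count2`, `lo`, `hi`, `within`) with the summary
#'   available through [glance()] (`n_evaluated`, `n_within`,
#'   `fraction_within`, `level`, `model`).
#' @export
fluctuation_coverage <- function(counts, rep1, rep2, level = 0.99,
                                 model = c("predictive", "poisson",
                                           "binomial"),
                                 depth = NULL) {
  samples <- check_counts_table(counts)
  model <- match.arg(model)
  if (!all(c(rep1, rep2) %in% samples)) {
    abort_metarep("`rep1` and `rep2` must name sample columns of `counts`.",
                  "metarep_input_error")
  }
  if (model == "binomial" && is.null(depth)) depth <- sum(counts[[rep1]])
  keep <- counts[[rep1]] >= 1
  c1 <- as.integer(counts[[rep1]][keep])
  c2 <- as.integer(counts[[rep2]][keep])
  iv <- fluctuation_interval(c1, level = level, model = model, depth = depth)
  per_gene <- tibble(gene_id = counts$gene_id[keep],
                     count1 = c1, count2 = c2,
                     lo = iv$lo, hi = iv$hi,
                     within = c2 >= iv$lo & c2 <= iv$hi)
  structure(per_gene,
            class = c("fluctuation_coverage", class(per_gene)),
            level = level, model = model)
}

#' @exportS3Method generics::glance
glance.fluctuation_coverage <- function(x, ...) {
  tibble(n_evaluated = nrow(x),
         n_within = sum(x$within),
         fraction_within = mean(x$within),
         level = attr(x, "level"),
         model = attr(x, "model"))
}

#' @exportS3Method generics::tidy
tidy.fluctuation_coverage <- function(x, ...) as_tibble(x)

#' @export
print.fluctuation_coverage <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Fluctuation coverage (%s model, level %.2f): %d / %d genes within (%.2f%%)\n",
    g$model, g$level, g$n_within, g$n_evaluated, 100 * g$fraction_within))
  invisible(x)
}
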
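# Independent oracles and small builders used across the suite.

# Equal-tail discrete interval from R's distribution functions (pnbinom /
# ppois / pbinom), independent of the package's pmf-summation route.
oracle_interval <- function(k, level = 0.99, model = "predictive",
                            depth = NULL) {
  if (k == 0) return(c(0L, 0L))
  a <- (1 - level) / 2
  cdf <- switch(model,
    predictive = function(x) pnbinom(x, size = k, prob = 0.5),
    poisson    = function(x) ppois(x, k),
    binomial   = function(x) pbinom(x, size = depth, prob = k / depth))
  ks <- 0:ceiling(k + 15 * sqrt(2 * k) + 40)
  F <- cdf(ks)
  lo <- sum(F <= a)          # max{j : P(X < j) <= a}
  hi <- ks[which(F >= 1 - a)[1]]
  c(lo, hi)
}

# Brute-force OA trimming: explicit window scan with prod(), no logs.
oracle_trim <- function(q, threshold = 0.8, window = 10L, min_length = 30L) {
  acc <- 1 - 10^(-q / 10)
  n <- length(q)
  w <- min(window, n)
  cut <- n
  for (i in seq_len(n - w + 1L)) {
    if (prod(acc[i:(i + w - 1L)]) < threshold) {
      cut <- i - 1L
      break
    }
  }
  if (cut < min_length) {
    list(retained_length = 0L, whole_read_oa = NA_real_)
  } else {
    list(retained_length = cut, whole_read_oa = prod(acc[seq_len(cut)]))
  }
}

# Step-up FDR adjustment written out by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Iterative proportional fitting for the no-three-way 2x2x2 model.
oracle_ipf <- function(cube, iter = 200) {
  fit <- array(sum(cube) / 8, dim = c(2, 2, 2))
  margins <- list(c(1, 2), c(1, 3), c(2, 3))
  for (it in seq_len(iter)) {
    for (m in margins) {
      obs_m <- apply(cube, m, sum)
      fit_m <- apply(fit, m, sum)
      ratio <- obs_m / fit_m
      ratio[fit_m == 0] <- 0
      fit <- sweep(fit, m, ratio, "*")
    }
  }
  fit
}

# Area left of the empirical CDF of d, as the exact step-function integral
# of 1 - F.
oracle_area_left <- function(d) {
  xs <- sort(d)
  n <- length(xs)
  sum(diff(c(0, xs)) * (1 - (seq_len(n) - 1) / n))
}

# One-row-per-read tibble from a list of phred vectors (random ACGT bases).
make_reads <- function(phreds) {
  tibble::tibble(
    read_id = paste0("r", seq_along(phreds)),
    sequence = vapply(phreds, function(q)
      paste(sample(c("A", "C", "G", "T"), length(q), replace = TRUE),
            collapse = ""), character(1)),
    phred = lapply(phreds, as.integer))
}

# Tiny gene catalog with constant lengths (lengths cancel in ratio
# statistics) and uniform GC.
flat_catalog <- function(n_genes, length_bp = 1000L) {
  tibble::tibble(gene_id = sprintf("g%06d", seq_len(n_genes)),
                 length_bp = length_bp,
                 gc_fraction = stats::runif(n_genes, 0.25, 0.75))
}

# Twin technical replicates: one shared abundance vector, independent
# multinomial draws.
twin_replicates <- function(n_genes, depth, sigma = 2, seed = 1,
                            n_reps = 2) {
  catg <- flat_catalog(n_genes)
  prof <- simulate_abundances(catg, sigma = sigma, seed = seed)
  list(catalog = catg, profile = prof,
       counts = simulate_replicate_table(prof, depth = depth,
                                         n_reps = n_reps,
                                         seed = seed + 100L))
}
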
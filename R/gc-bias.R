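# GC-bias analyses: GC content, per-species robust regression of gene
# abundance on GC, and the log-linear likelihood-ratio test on the
# abundance x GC x platform contingency cube.

#' GC fraction of nucleotide sequences
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; ambiguous bases (N etc.)
#' are excluded from both numerator and denominator.
#'
#' @param seq Character vector of sequences over `{A, C, G, T, N}` (any case).
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (!is.character(seq) || length(seq) == 0L) {
    abort_metarep("`seq` must be a character vector of sequences.",
                  "metarep_domain_error")
  }
  x <- Biostrings::DNAStringSet(toupper(seq))
  af <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  unambig <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(unambig == 0)) {
    abort_metarep("sequence with no unambiguous A/C/G/T bases; GC undefined.",
                  "metarep_domain_error")
  }
  unname((af[, "G"] + af[, "C"]) / unambig)
}

#' Huber robust linear regression (one predictor)
#'
#' M-estimation by iteratively reweighted least squares with the Huber psi
#' (weights `min(1, k * s / |r|)`), residual scale `s` re-estimated each
#' iteration as the median absolute deviation times 1.4826. On data whose
#' scaled residuals all stay within `k`, the estimate coincides with ordinary
#' least squares; a single gross outlier, which would drag the OLS slope, is
#' down-weighted away.
#'
#' @param x,y Numeric vectors, at least 3 points, `x` not constant.
#' @param k Huber tuning constant, default 1.345 (95% Gaussian efficiency).
#' @param tol Convergence tolerance on the coefficient step, default 1e-8.
#' @param max_iter Iteration cap, default 50; hitting it flags
#'   `converged = FALSE` and returns the last iterate.
#' @return An object of class `huber_fit`: `slope`, `intercept`, `scale`,
#'   `n_iter`, `converged`, plus the data and weights for inspection.
#' @export
huber_fit <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 50L) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L || anyNA(x) || anyNA(y)) {
    abort_metarep("`x` and `y` must be equal-length numeric vectors, n >= 3.",
                  "metarep_domain_error")
  }
  if (length(unique(x)) == 1L) {
    abort_metarep("`x` is constant; the design is degenerate.",
                  "metarep_degenerate_error")
  }
  check_positive_scalar(k, "k")
  wls <- function(w) {
    sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    sxx <- sum(w * (x - mx)^2)
    b <- sum(w * (x - mx) * (y - my)) / sxx
    c(intercept = my - b * mx, slope = b)
  }
  beta <- wls(rep(1, length(x)))
  converged <- FALSE
  iter <- 0L
  scale <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - beta["intercept"] - beta["slope"] * x
    scale <- mad(r, center = 0)  # 1.4826 * median(|r|)
    if (scale < .Machine$double.eps^0.5 * (1 + mad(y))) {
      # (near-)exact fit: all points are inliers, OLS is the estimate
      converged <- TRUE
      break
    }
    w <- pmin(1, k * scale / abs(r))
    w[abs(r) < .Machine$double.eps] <- 1
    new_beta <- wls(w)
    step <- max(abs(new_beta - beta))
    beta <- new_beta
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(slope = unname(beta["slope"]),
                 intercept = unname(beta["intercept"]),
                 scale = scale, n_iter = iter, converged = converged,
                 x = x, y = y),
            class = "huber_fit")
}

#' @export
print.huber_fit <- function(x, ...) {
  cat(sprintf(
    "Huber fit: slope %.4f, intercept %.4f (scale %.4g, %d iterations%s)\n",
    x$slope, x$intercept, x$scale, x$n_iter,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.huber_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"), estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.huber_fit <- function(x, ...) {
  tibble(scale = x$scale, n_iter = x$n_iter, converged = x$converged,
         n = length(x$x))
}

#' Per-species robust regression of gene abundance on GC content
#'
#' Under the working assumption that genes from one species are roughly
#' evenly abundant regardless of their GC content, any systematic slope of
#' log10 gene abundance on GC within a species measures a sequencing-platform
#' GC bias. Fits [huber_fit()] of `log10(abundance)` on `gc_fraction` per
#' species (genes with positive abundance only; species with fewer than
#' `min_genes` usable genes are skipped with a warning) and reports the
#' per-species slopes; the median slope is the platform's bias summary.
#'
#' @param profile Abundance tibble: `gene_id` plus one abundance column.
#' @param catalog Gene catalog with `gene_id`, `gc_fraction`, `species`
#'   (genes without a species label are ignored).
#' @param sample Name of the abundance column; defaults to the single
#'   non-key column.
#' @param species Optional character vector restricting which species to fit
#'   (e.g. the top-20 most-affected species from [top_species()]).
#' @param min_genes Minimum usable genes per species, default 3.
#' @param ... Passed on to [huber_fit()].
#' @return A tibble of class `species_slopes`: `species`, `n_genes`, `slope`,
#'   `intercept`, `converged`; [glance()] gives `median_slope` and
#'   `n_species`.
#' @export
species_slopes <- function(profile, catalog, sample = NULL, species = NULL,
                           min_genes = 3L, ...) {
  stopifnot(is.data.frame(profile), "gene_id" %in% names(profile))
  if (is.null(sample)) {
    sample <- sample_columns(profile)
    if (length(sample) != 1L) {
      abort_metarep("`profile` has several abundance columns; give `sample`.",
                    "metarep_input_error")
    }
  }
  if (!all(c("gene_id", "gc_fraction", "species") %in% names(catalog))) {
    abort_metarep("`catalog` needs gene_id, gc_fraction and species columns.",
                  "metarep_schema_error")
  }
  dat <- tibble(gene_id = profile$gene_id, abundance = profile[[sample]]) |>
    inner_join(catalog[, c("gene_id", "gc_fraction", "species")],
               by = "gene_id") |>
    filter(!is.na(.data$species), .data$abundance > 0)
  if (!is.null(species)) dat <- dat[dat$species %in% species, , drop = FALSE]
  fits <- dat |>
    group_by(.data$species) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < min_genes || length(unique(g$gc_fraction)) == 1L) {
        return(NULL)
      }
      f <- huber_fit(g$gc_fraction, log10(g$abundance), ...)
      tibble(species = key$species, n_genes = nrow(g), slope = f$slope,
             intercept = f$intercept, converged = f$converged)
    })
  skipped <- sum(vapply(fits, is.null, logical(1)))
  if (skipped > 0L) {
    warning(sprintf("%d species skipped (fewer than %d usable genes).",
                    skipped, as.integer(min_genes)), call. = FALSE)
  }
  out <- bind_rows(fits)
  structure(out, class = c("species_slopes", class(out)))
}

#' @exportS3Method generics::glance
glance.species_slopes <- function(x, ...) {
  tibble(median_slope = median(x$slope), n_species = nrow(x))
}

#' Rank species by number of significantly different genes
#'
#' The species most affected by a platform difference are those contributing
#' the most significantly different genes; ties are broken alphabetically.
#'
#' @param tests Per-gene test results from [paired_gene_tests()].
#' @param catalog Gene catalog with `gene_id` and `species`.
#' @param n How many species to return, default 20.
#' @return Character vector of species names, most affected first.
#' @export
top_species <- function(tests, catalog, n = 20L) {
  tests |>
    filter(.data$significant) |>
    inner_join(catalog[, c("gene_id", "species")], by = "gene_id") |>
    filter(!is.na(.data$species)) |>
    count(.data$species, name = "n_signif") |>
    arrange(desc(.data$n_signif), .data$species) |>
    slice_head(n = n) |>
    pull(.data$species)
}

#' Build the abundance x GC x platform contingency cube
#'
#' Classifies every (species, platform) observation as high/low abundance and
#' high/low GC, using medians pooled over both platforms' observations
#' ("high" means strictly above the median), and tallies the 2 x 2 x 2 cube
#' of species counts. Species without a GC value are excluded with a warning.
#'
#' @param profile_a,profile_b Species abundance tibbles (`species` plus one
#'   abundance column, e.g. the platform mean over samples) for the two
#'   platforms.
#' @param species_gc Tibble with `species` and `gc_fraction`.
#' @param platforms Names for the two platform slabs.
#' @return A 2 x 2 x 2 `table`-like array with dimensions
#'   `abundance` (high/low), `gc` (high/low), `platform`.
#' @export
build_cube <- function(profile_a, profile_b, species_gc,
                       platforms = c("A", "B")) {
  one <- function(p) {
    stopifnot(is.data.frame(p), "species" %in% names(p))
    val <- sample_columns(p, key = "species")
    if (length(val) != 1L) {
      abort_metarep("species profiles must have exactly one abundance column.",
                    "metarep_input_error")
    }
    tibble(species = p$species, abundance = p[[val]])
  }
  a <- one(profile_a); b <- one(profile_b)
  obs <- bind_rows(mutate(a, platform = platforms[1]),
                   mutate(b, platform = platforms[2])) |>
    left_join(species_gc[, c("species", "gc_fraction")], by = "species")
  if (anyNA(obs$gc_fraction)) {
    warning(sprintf("%d observation(s) lack species GC and were excluded.",
                    sum(is.na(obs$gc_fraction))), call. = FALSE)
    obs <- obs[!is.na(obs$gc_fraction), , drop = FALSE]
  }
  if (nrow(obs) == 0L) {
    abort_metarep("no observations left to tabulate.", "metarep_input_error")
  }
  med_ab <- median(obs$abundance)
  med_gc <- median(obs$gc_fraction)
  lv <- c("high", "low")
  tab <- table(
    abundance = factor(ifelse(obs$abundance > med_ab, "high", "low"), lv),
    gc = factor(ifelse(obs$gc_fraction > med_gc, "high", "low"), lv),
    platform = factor(obs$platform, platforms))
  attr(tab, "medians") <- c(abundance = med_ab, gc = med_gc)
  tab
}

#' Log-linear likelihood-ratio test for a platform-dependent GC association
#'
#' Fits the hierarchical log-linear model with all three two-way margins but
#' no three-way interaction to the 2 x 2 x 2 cube (iterative proportional
#' fitting via `stats::loglin`), and tests it against the saturated model:
#' `G2 = 2 * sum(observed * log(observed / fitted))` over non-empty cells, on
#' 1 degree of freedom. A small p-value means the abundance-GC association
#' differs between the platforms.
#'
#' @param cube A 2 x 2 x 2 array from [build_cube()].
#' @param margin_tol Maximum allowed deviation of fitted from observed
#'   two-way margins; larger deviations flag non-convergence.
#' @return An object of class `loglin_lrt`: `g2`, `df` (= 1), `p_value`,
#'   `observed`, `fitted`, `converged`.
#' @export
loglinear_lrt <- function(cube, margin_tol = 1e-8) {
  if (length(dim(cube)) != 3L || !all(dim(cube) == 2L)) {
    abort_metarep("`cube` must be a 2 x 2 x 2 array.", "metarep_input_error")
  }
  if (any(cube < 0) || sum(cube) <= 0) {
    abort_metarep("`cube` must hold non-negative counts with positive total.",
                  "metarep_input_error")
  }
  margins <- list(c(1, 2), c(1, 3), c(2, 3))
  fit <- loglin(cube, margin = margins, fit = TRUE, eps = 1e-10,
                iter = 200L, print = FALSE)
  dev <- max(vapply(margins, function(m) {
    max(abs(apply(fit$fit, m, sum) - apply(cube, m, sum)))
  }, numeric(1)))
  converged <- dev <= margin_tol
  if (!converged) {
    warning(sprintf(
      "IPF did not reproduce the two-way margins (max deviation %.3g).", dev),
      call. = FALSE)
  }
  obs <- as.numeric(cube)
  fitv <- as.numeric(fit$fit)
  pos <- obs > 0
  g2 <- 2 * sum(obs[pos] * log(obs[pos] / fitv[pos]))
  g2 <- max(g2, 0)
  structure(list(g2 = g2, df = 1L,
                 p_value = pchisq(g2, df = 1L, lower.tail = FALSE),
                 observed = cube, fitted = fit$fit, converged = converged),
            class = "loglin_lrt")
}

#' @export
print.loglin_lrt <- function(x, ...) {
  cat(sprintf(
    "Log-linear LRT (no-three-way vs saturated): G2 = %.4f, df = %d, p = %.4g\n",
    x$g2, x$df, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.loglin_lrt <- function(x, ...) {
  tibble(g2 = x$g2, df = x$df, p_value = x$p_value, converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.loglin_lrt <- function(x, ...) {
  dn <- dimnames(x$observed)
  grid <- expand.grid(abundance = dn[[1]], gc = dn[[2]], platform = dn[[3]],
                      stringsAsFactors = FALSE)
  as_tibble(grid) |>
    mutate(observed = as.numeric(x$observed), fitted = as.numeric(x$fitted))
}
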
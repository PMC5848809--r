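test_that("GC content counts unambiguous bases case-insensitively", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GgNcA"), 3 / 4)  # G, g, c over 4 unambiguous
  expect_equal(gc_content(c("gc", "at")), c(1, 0))
  expect_error(gc_content("NNN"), class = "metarep_domain_error")
})

test_that("the Huber fit equals least squares on clean data", {
  x <- 1:20
  y <- 2 * x + 1
  f <- huber_fit(x, y)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_true(f$converged)

  # small residuals all inside the Huber corner: identical to OLS
  e <- rep(c(-1, 1), 10) * 0.3
  f2 <- huber_fit(x, y + e)
  ols <- stats::lm(I(y + e) ~ x)
  expect_equal(f2$slope, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(f2$intercept, unname(coef(ols)[1]), tolerance = 1e-8)

  # permutation invariance
  set.seed(101)
  o <- sample(20)
  f3 <- huber_fit(x[o], (y + e)[o])
  expect_equal(f3$slope, f2$slope, tolerance = 1e-12)

  expect_error(huber_fit(rep(1, 5), 1:5),
               class = "metarep_degenerate_error")
  expect_error(huber_fit(1:2, 1:2), class = "metarep_domain_error")
})

test_that("a gross outlier moves least squares but not the Huber fit", {
  set.seed(102)
  x <- seq(0, 1, length.out = 21)
  y <- 2 * x + 0.2 + rnorm(21, sd = 0.01)
  xo <- c(x, 0.95)
  yo <- c(y, -5)  # one wild point
  hub <- huber_fit(xo, yo)
  ols_slope <- unname(coef(stats::lm(yo ~ xo))[2])
  expect_lt(abs(hub$slope - 2), 0.05)
  expect_gt(abs(ols_slope - 2), 0.2)

  # independent cross-check against MASS's IRLS with matching settings
  skip_if_not_installed("MASS")
  rlm <- MASS::rlm(yo ~ xo, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 100)
  expect_lt(abs(hub$slope - unname(coef(rlm)[2])), 0.02)
})

test_that("per-species slopes recover an injected GC tilt", {
  catg <- simulate_catalog(n_genes = 6000, n_species = 30, seed = 111)
  prof <- simulate_abundances(catg, sigma = 2, seed = 112)
  tilted <- apply_platform_bias(prof, catg, beta = 1)

  sl0 <- species_slopes(prof, catg)
  sl1 <- species_slopes(tilted, catg)
  expect_true(all(c("species", "slope", "n_genes") %in% names(sl0)))
  # the tilt adds beta / ln(10) ~ 0.434 to every species' log10 slope
  expect_equal(glance(sl1)$median_slope - glance(sl0)$median_slope,
               1 / log(10), tolerance = 0.05)

  # a sparse species is skipped with a warning
  catg2 <- catg
  catg2$species[catg2$species == catg2$species[1]] <- NA
  catg2$species[1:2] <- "rare_sp"
  expect_warning(species_slopes(prof, catg2), "skipped")
})

test_that("the contingency cube classifies against pooled medians", {
  sp <- paste0("s", 1:4)
  gc <- tibble::tibble(species = sp, gc_fraction = c(0.3, 0.4, 0.6, 0.7))
  pa <- tibble::tibble(species = sp, ab = c(1, 2, 3, 4))

  # identical platforms: the two slabs agree and each sums to 4
  cube <- build_cube(pa, pa, gc)
  expect_identical(cube[, , 1], cube[, , 2])
  expect_identical(sum(cube[, , 1]), 4L)
  expect_identical(sum(cube), 8L)

  # swapping the abundances of the extreme species moves cube mass
  pb <- tibble::tibble(species = sp, ab = c(4, 2, 3, 1))
  cube2 <- build_cube(pa, pb, gc)
  expect_identical(sum(cube2), 8L)
  expect_false(identical(cube2[, , 1], cube2[, , 2]))

  # unknown GC drops the observation with a warning
  expect_warning(cube3 <- build_cube(pa, pb, gc[1:3, ]), "excluded")
  expect_identical(sum(cube3), 6L)
})

test_that("the log-linear LRT matches an IPF oracle", {
  # no interaction at all: fitted == observed, G2 = 0, p = 1
  flat <- array(5, dim = c(2, 2, 2))
  res <- loglinear_lrt(flat)
  expect_equal(res$g2, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1)
  expect_equal(res$fitted, flat, ignore_attr = TRUE, tolerance = 1e-10)

  # pure three-way interaction: strictly positive deviance
  cube <- array(c(4, 1, 1, 4, 1, 4, 4, 1), dim = c(2, 2, 2))
  res2 <- loglinear_lrt(cube)
  expect_gt(res2$g2, 0)
  expect_lt(res2$p_value, 1)
  want <- oracle_ipf(cube)
  expect_equal(res2$fitted, want, ignore_attr = TRUE, tolerance = 1e-6)
  g2_want <- 2 * sum(cube * log(cube / want))
  expect_equal(res2$g2, g2_want, tolerance = 1e-6)

  # random cubes: all three two-way margins reproduced to 1e-8
  set.seed(121)
  for (i in 1:10) {
    rc <- array(rpois(8, 20) + 1L, dim = c(2, 2, 2))
    fit <- loglinear_lrt(rc)
    expect_true(fit$converged)
    for (m in list(c(1, 2), c(1, 3), c(2, 3))) {
      expect_lt(max(abs(apply(fit$fitted, m, sum) - apply(rc, m, sum))),
                1e-8)
    }
    # relabelling hi/lo consistently in both slabs leaves G2 unchanged
    flipped <- rc[2:1, 2:1, ]
    expect_equal(loglinear_lrt(flipped)$g2, fit$g2, tolerance = 1e-8)
  }

  expect_error(loglinear_lrt(array(1, dim = c(3, 2, 2))),
               class = "metarep_input_error")
})

test_that("top_species ranks by flagged-gene count with name tie-break", {
  catg <- tibble::tibble(gene_id = paste0("g", 1:6),
                         species = c("b", "b", "a", "a", "c", NA))
  tests <- tibble::tibble(gene_id = paste0("g", 1:6),
                          significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(top_species(tests, catg, n = 2), c("a", "b"))
  tests$significant[1:2] <- FALSE
  expect_identical(top_species(tests, catg), c("a", "c"))
})
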
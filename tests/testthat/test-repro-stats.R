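pair_tbl <- function(n) {
  tibble::tibble(sample_a = paste0("a", seq_len(n)),
                 sample_b = paste0("b", seq_len(n)))
}

test_that("HR gene selection applies the both-members and min-pairs rules", {
  cts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        a1 = c(10L, 9L, 50L), b1 = c(10L, 100L, 50L))
  hr <- hr_genes(cts, pair_tbl(1), min_pairs = 1)
  expect_identical(sort(hr$gene_id), c("g1", "g3"))  # g2 fails one member

  # qualifying in 5 of 8 pairs is not enough under the >= 6 rule
  set.seed(91)
  cts8 <- tibble::tibble(gene_id = "g")
  for (i in 1:8) {
    cts8[[paste0("a", i)]] <- if (i <= 5) 20L else 3L
    cts8[[paste0("b", i)]] <- 20L
  }
  expect_identical(nrow(hr_genes(cts8, pair_tbl(8), min_pairs = 6)), 0L)
  expect_identical(hr_genes(cts8, pair_tbl(8), min_pairs = 5)$gene_id, "g")
  # the default caps the 6-pair rule at the pairs available
  expect_identical(hr_genes(cts8, pair_tbl(8))$n_pairs_detected, integer(0))

  expect_error(hr_genes(cts8, pair_tbl(8), min_pairs = 9),
               class = "metarep_input_error")
})

test_that("Spearman correlation matches the rank-difference formula", {
  prof <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         a = c(0.1, 0.3, 0.6), b = c(0.6, 0.1, 0.3))
  # ranks (1,2,3) vs (3,1,2): rho = 1 - 6*6/(3*8) = -0.5
  expect_equal(spearman_cor(prof, "a", "b")$rho, -0.5)

  set.seed(92)
  prof2 <- tibble::tibble(gene_id = paste0("g", 1:50),
                          a = runif(50))
  prof2$b <- prof2$a
  expect_equal(spearman_cor(prof2, "a", "b")$rho, 1)
  prof2$b <- exp(3 * prof2$a)  # any strictly monotone transform
  expect_equal(spearman_cor(prof2, "a", "b")$rho, 1)
  prof2$b <- max(prof2$a) - prof2$a  # rank reversal
  expect_equal(spearman_cor(prof2, "a", "b")$rho, -1)

  prof2$b <- 1
  expect_error(spearman_cor(prof2, "a", "b"),
               class = "metarep_domain_error")
})

test_that("ALC equals the mean |log2 ratio| and the area left of the CDF", {
  prof <- tibble::tibble(gene_id = c("g1", "g2"),
                         a = c(0.5, 0.5), b = c(0.25, 0.75))
  res <- alc(prof, "a", "b")
  expect_equal(res$alc, mean(c(1, log2(0.75 / 0.5))))
  expect_equal(res$alc, 0.7924813, tolerance = 1e-6)
  expect_equal(res$fold_change, 2^res$alc)

  # identical profiles: ALC 0, fold change 1
  same <- alc(prof, "a", "a")
  expect_equal(same$alc, 0)
  expect_equal(same$fold_change, 1)

  # symmetry in the two profiles
  expect_equal(alc(prof, "b", "a")$alc, res$alc)

  # mean == numeric area left of the empirical CDF, to 1e-9
  set.seed(93)
  prof3 <- tibble::tibble(gene_id = paste0("g", 1:400),
                          a = rlnorm(400), b = rlnorm(400))
  r3 <- alc(prof3, "a", "b")
  expect_equal(r3$alc, oracle_area_left(r3$d), tolerance = 1e-9)

  prof$b[1] <- 0
  expect_error(alc(prof, "a", "b"), class = "metarep_domain_error")
})

test_that("BH adjustment reproduces the step-up construction", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.007), 0.007)  # m = 1: unchanged

  set.seed(94)
  for (i in 1:20) {
    p <- runif(sample(3:60, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "metarep_domain_error")
})

test_that("paired tests are exact on closed-form cases", {
  # six pairs, every difference positive: sign-test p = 2 * (1/2)^6
  prof <- tibble::tibble(gene_id = c("g1", "g2", "g3"))
  for (i in 1:6) {
    prof[[paste0("a", i)]] <- c(0.5, 0.3, 0.2) + 0.02 * i
    prof[[paste0("b", i)]] <- c(0.4, 0.35, 0.25)
  }
  res <- paired_gene_tests(prof, pair_tbl(6), genes = prof$gene_id)
  expect_equal(res$p_sign[res$gene_id == "g1"], 2 * 0.5^6)

  # identical groups: every difference zero, nothing significant
  prof0 <- prof
  for (i in 1:6) prof0[[paste0("b", i)]] <- prof0[[paste0("a", i)]]
  res0 <- paired_gene_tests(prof0, pair_tbl(6), genes = prof0$gene_id)
  expect_equal(res0$p_t, rep(1, 3))
  expect_equal(res0$p_sign, rep(1, 3))
  expect_false(any(res0$significant))

  # fewer than 3 usable pairs: t test skipped, sign test still reported
  prof2 <- tibble::tibble(gene_id = "g", a1 = 0.6, b1 = 0.4,
                          a2 = 0.6, b2 = 0.4)
  res2 <- paired_gene_tests(prof2, pair_tbl(2), genes = "g")
  expect_true(is.na(res2$p_t))
  expect_equal(res2$p_sign, 0.5)
})

test_that("a known 2-fold shift is detected with FDR control", {
  # 2000 genes, 5% given a 2-fold shift in group B; 8 pairs at depth 2e5.
  powers <- c(); fprs <- c()
  for (s in 1:20) {
    catg <- tibble::tibble(gene_id = sprintf("g%04d", 1:2000),
                           length_bp = 500L)
    prof <- simulate_abundances(catg, sigma = 1.5, seed = 100 + s)
    shifted <- withr::with_seed(400 + s,
                                sample(catg$gene_id, 100))
    b <- prof$abundance * ifelse(prof$gene_id %in% shifted, 2, 1)
    profB <- tibble::tibble(gene_id = prof$gene_id, abundance = b / sum(b))
    ctsA <- simulate_replicate_table(prof, 2e5, 8, "a", seed = 200 + s)
    ctsB <- simulate_replicate_table(profB, 2e5, 8, "b", seed = 300 + s)
    cts <- dplyr::inner_join(ctsA, ctsB, by = "gene_id")
    hr <- hr_genes(cts, pair_tbl(8), min_pairs = 6)
    ra <- relative_abundance(cts, catg)
    tst <- paired_gene_tests(ra, pair_tbl(8), hr$gene_id, alpha = 0.05)
    is_shift <- tst$gene_id %in% shifted
    powers <- c(powers, mean(tst$significant[is_shift]))
    fprs <- c(fprs, mean(tst$significant[!is_shift]))
  }
  expect_gte(mean(powers), 0.8)
  expect_lte(mean(fprs), 0.05 * 1.5)
})

test_that("twin replicates produce essentially no significant genes", {
  tw <- local({set.seed(95); twin_replicates(20000, 3e5, seed = 95,
                                             n_reps = 16)})
  pairs <- tibble::tibble(sample_a = paste0("rep", 1:8),
                          sample_b = paste0("rep", 9:16))
  hr <- hr_genes(tw$counts, pairs, min_pairs = 6)
  ra <- relative_abundance(tw$counts, tw$catalog)
  tst <- paired_gene_tests(ra, pairs, hr$gene_id)
  expect_gt(nrow(tst), 500)
  expect_lte(mean(tst$significant), 0.002)
})
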
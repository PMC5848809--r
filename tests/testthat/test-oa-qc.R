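test_that("per-base accuracy and fragment OA follow the Phred definition", {
  expect_equal(base_accuracy(0), 0)
  expect_equal(base_accuracy(10), 0.9)
  expect_equal(base_accuracy(30), 0.999)
  expect_error(base_accuracy(-1), class = "metarep_domain_error")
  expect_true(all(diff(base_accuracy(0:60)) > 0))  # strictly increasing

  expect_equal(fragment_oa(c(0.9, 0.9)), 0.81)
  expect_equal(fragment_oa(rep(1, 5)), 1)
  expect_equal(fragment_oa(rep(base_accuracy(30), 10)), 0.999^10)
  expect_lte(fragment_oa(c(0.5, 0.99)), 0.5)
  expect_error(fragment_oa(numeric(0)), class = "metarep_domain_error")
})

test_that("trim_read matches a brute-force window scan", {
  params <- qc_params()

  # all-Q30 read: every window has OA 0.999^10 ~ 0.990, kept in full
  r <- trim_read(rep(30L, 100), params)
  expect_identical(r$retained_length, 100L)
  expect_identical(r$reason, "kept_full")
  expect_equal(r$whole_read_oa, 0.999^100, tolerance = 1e-12)

  # low-quality 3' block: trimmed before the first window touching it
  r <- trim_read(c(rep(30L, 90), rep(3L, 10)), params)
  expect_identical(r$reason, "trimmed")
  expect_lte(r$retained_length, 90L)
  expect_identical(r$retained_length,
                   oracle_trim(c(rep(30L, 90), rep(3L, 10)))$retained_length)

  # hopeless read: first window fails, prefix shorter than min_length
  r <- trim_read(rep(2L, 20), params)
  expect_identical(r$reason, "discarded_short")
  expect_identical(r$retained_length, 0L)

  # randomised agreement with the prod()-based oracle
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:120, 1)
    q <- sample(0:40, n, replace = TRUE)
    got <- trim_read(q, params)
    want <- oracle_trim(q)
    expect_identical(got$retained_length, as.integer(want$retained_length))
    if (want$retained_length > 0) {
      expect_equal(got$whole_read_oa, want$whole_read_oa, tolerance = 1e-12)
    }
  }
})

test_that("reads at uniform quality satisfy the closed-form keep rule", {
  for (q in c(2L, 10L, 16L, 17L, 20L, 30L, 40L)) {
    for (thr in c(0.5, 0.8, 0.95)) {
      r <- trim_read(rep(q, 50), qc_params(oa_threshold = thr))
      kept_full <- r$retained_length == 50L
      expect_identical(kept_full, base_accuracy(q)^10 >= thr)
    }
  }
  # reads shorter than the window are judged as one fragment of their length
  short <- trim_read(rep(17L, 5), qc_params(min_length = 3))
  expect_identical(short$retained_length,
                   if (base_accuracy(17)^5 >= 0.8) 5L else 0L)
})

test_that("retention is monotone in the OA threshold and preserves prefixes", {
  reads <- simulate_fastq(n_reads = 400, drop_rate = 0.3, seed = 31)
  prev_lens <- NULL
  prev_pct <- NULL
  for (thr in c(0.5, 0.7, 0.9, 0.97)) {
    res <- run_qc(reads, qc_params(oa_threshold = thr))
    lens <- rep(0L, nrow(reads))
    idx <- match(res$reads$read_id, reads$read_id)
    lens[idx] <- vapply(res$reads$phred, length, integer(1))
    if (!is.null(prev_lens)) {
      expect_true(all(lens <= prev_lens))
      expect_lte(res$report$pct_retained, prev_pct + 1e-12)
    }
    prev_lens <- lens
    prev_pct <- res$report$pct_retained
    # retained reads are prefixes of their inputs, bases untouched
    orig <- reads$sequence[idx]
    expect_true(all(substr(orig, 1, nchar(res$reads$sequence)) ==
                      res$reads$sequence))
    expect_true(all(mapply(function(a, b) identical(a[seq_along(b)], b),
                           reads$phred[idx], res$reads$phred)))
  }
})

test_that("the QC report aggregates retention, Q30 and OA correctly", {
  # perfect reads: everything kept at full length
  perfect <- make_reads(replicate(20, rep(40L, 80), simplify = FALSE))
  res <- run_qc(perfect)
  expect_equal(res$report$pct_retained, 100)
  expect_equal(res$report$mean_retained_length, 80)
  expect_equal(res$report$pct_q30, 100)
  expect_equal(res$report$mean_oa, base_accuracy(40)^80)

  # hopeless reads: nothing survives
  res0 <- run_qc(make_reads(replicate(5, rep(2L, 50), simplify = FALSE)))
  expect_identical(res0$report$n_retained, 0L)
  expect_equal(res0$report$pct_retained, 0)

  # streaming file interface agrees with the in-memory one
  reads <- simulate_fastq(n_reads = 700, drop_rate = 0.3, seed = 41)
  fq <- withr::local_tempfile(fileext = ".fq")
  hq <- withr::local_tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  rep_file <- run_qc_file(fq, hq, chunk_size = 150)
  rep_mem <- run_qc(reads)$report
  expect_equal(as.data.frame(rep_file), as.data.frame(rep_mem))
  expect_identical(read_fastq(hq)$phred, run_qc(reads)$reads$phred)
})

test_that("retention of simulated dropped reads matches the closed form", {
  # Linear decay 38 -> 33 never trips the 0.8 window on its own; a Q2
  # segment of 10 bases at uniform offset in 1..91 truncates the read to
  # offset - 10 bases, which survives min_length 30 iff offset >= 40.
  n <- 6000
  drop_rate <- 0.4
  reads <- simulate_fastq(n_reads = n, read_length = 100, q_start = 38,
                          q_end = 33, q_noise_sd = 1.5, drop_rate = drop_rate,
                          segment_length = 10, segment_q = 2, seed = 51)
  res <- run_qc(reads)
  expected_pct <- 100 * (1 - drop_rate * 39 / 91)
  expect_lt(abs(res$report$pct_retained - expected_pct), 2)
})
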
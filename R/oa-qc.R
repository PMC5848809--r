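# Overall-accuracy (OA) quality control.
#
# The OA of a read fragment is the probability that every base in it was
# called correctly: the product of the per-base accuracies 1 - 10^(-Q/10).
# A window of `window` bases slides 5'->3' in steps of one; the read is
# truncated immediately before the start of the first window whose OA falls
# below `oa_threshold`, which catches both the usual 3' quality decay and
# low-quality segments buried mid-read that plain tail trimming misses.
# Prefixes shorter than `min_length` are discarded outright.

#' Quality-control parameters for the OA filter
#'
#' @param oa_threshold Minimum fragment OA, in (0, 1). A fragment of `window`
#'   bases all at Q17 has OA ~0.82, so the default 0.8 tolerates ~Q17 stretches
#'   but cuts at genuine quality drops.
#' @param window Fragment length in bases for the sliding window. Reads
#'   shorter than `window` are evaluated as one fragment of their own length.
#' @param min_length Shortest retained prefix, in bases; shorter survivors are
#'   discarded.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(oa_threshold = 0.8, window = 10L, min_length = 30L) {
  if (!is.numeric(oa_threshold) || length(oa_threshold) != 1L ||
      oa_threshold <= 0 || oa_threshold >= 1) {
    abort_metarep("`oa_threshold` must lie strictly between 0 and 1.",
                  "metarep_domain_error")
  }
  check_positive_scalar(window, "window", integer = TRUE)
  check_positive_scalar(min_length, "min_length", integer = TRUE)
  structure(list(oa_threshold = oa_threshold, window = as.integer(window),
                 min_length = as.integer(min_length)),
            class = "qc_params")
}

#' Per-base accuracy from a Phred score
#'
#' `base_accuracy(q)` is `1 - 10^(-q/10)`: 0 at Q0, 0.9 at Q10, 0.999 at Q30.
#'
#' @param q Vector of non-negative Phred scores.
#' @return Accuracies in `[0, 1)`.
#' @export
base_accuracy <- function(q) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0)) {
    abort_metarep("Phred scores must be non-negative numbers.",
                  "metarep_domain_error")
  }
  1 - 10^(-q / 10)
}

#' Overall accuracy of a read fragment
#'
#' The probability that all bases in the fragment are correct: the product of
#' the per-base accuracies. Always at most the worst single base.
#'
#' @param accuracies Non-empty vector of per-base accuracies in `[0, 1]`.
#' @return A single number in `[0, 1]`.
#' @export
fragment_oa <- function(accuracies) {
  if (!is.numeric(accuracies) || length(accuracies) == 0L ||
      anyNA(accuracies) || any(accuracies < 0 | accuracies > 1)) {
    abort_metarep("`accuracies` must be a non-empty vector in [0, 1].",
                  "metarep_domain_error")
  }
  prod(accuracies)
}

# Retained prefix length for one phred vector; log-space so that windows
# containing Q0 bases (accuracy 0) compare as -Inf.
trim_length_one <- function(q, log_threshold, window) {
  n <- length(q)
  la <- log1p(-10^(-q / 10))  # log per-base accuracy
  w <- min(window, n)
  cs <- cumsum(la)
  win <- cs[w:n] - c(0, cs)[seq_len(n - w + 1L)]
  fail <- which(win < log_threshold)
  if (length(fail)) fail[1] - 1L else n
}

#' Trim a single read by the OA rule
#'
#' @param phred Integer vector of per-base Phred scores (5' to 3').
#' @param params A [qc_params()] object.
#' @return A list: `retained_length` (0 if discarded), `reason` (one of
#'   `"kept_full"`, `"trimmed"`, `"discarded_short"`), and `whole_read_oa`
#'   (product of per-base accuracies over the retained prefix; `NA` if
#'   discarded).
#' @export
trim_read <- function(phred, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (length(phred) == 0L) {
    abort_metarep("cannot trim an empty read.", "metarep_domain_error")
  }
  len <- trim_length_one(phred, log(params$oa_threshold), params$window)
  if (len < params$min_length) {
    return(list(retained_length = 0L, reason = "discarded_short",
                whole_read_oa = NA_real_))
  }
  keep <- seq_len(len)
  list(retained_length = len,
       reason = if (len == length(phred)) "kept_full" else "trimmed",
       whole_read_oa = exp(sum(log1p(-10^(-phred[keep] / 10)))))
}

qc_report_row <- function(n_raw, retained_len, q30_bases, retained_bases,
                          oa_sum) {
  n_ret <- length(retained_len)
  tibble(
    n_raw = n_raw,
    n_retained = n_ret,
    pct_retained = if (n_raw > 0) 100 * n_ret / n_raw else NA_real_,
    pct_q30 = if (retained_bases > 0) 100 * q30_bases / retained_bases
              else NA_real_,
    mean_retained_length = if (n_ret > 0) mean(retained_len) else NA_real_,
    mean_oa = if (n_ret > 0) oa_sum / n_ret else NA_real_
  )
}

#' Run OA quality control over a set of reads
#'
#' Applies [trim_read()] to every read and aggregates a report. Retained reads
#' are prefixes of their inputs; no base is ever altered.
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param params A [qc_params()] object.
#' @return A list of class `qc_result`: `reads`, the retained (possibly
#'   trimmed) read tibble with a `reason` column, and `report`, a one-row
#'   tibble with `n_raw`, `n_retained`, `pct_retained`, `pct_q30` (percentage
#'   of retained bases at Phred >= 30), `mean_retained_length`, and `mean_oa`
#'   (mean whole-read OA of retained reads).
#' @seealso [run_qc_file()] for a streaming, file-to-file version.
#' @export
run_qc <- function(reads, params = qc_params()) {
  stopifnot(is.data.frame(reads), "phred" %in% names(reads))
  log_thr <- log(params$oa_threshold)
  lens <- vapply(reads$phred, trim_length_one, integer(1),
                 log_threshold = log_thr, window = params$window)
  keep <- lens >= params$min_length
  out <- reads[keep, , drop = FALSE]
  klen <- lens[keep]
  out$sequence <- substring(out$sequence, 1L, klen)
  out$phred <- Map(function(q, l) q[seq_len(l)], out$phred, klen)
  out$reason <- ifelse(klen == vapply(reads$phred[keep], length, integer(1)),
                       "kept_full", "trimmed")
  oa <- vapply(out$phred, function(q) exp(sum(log1p(-10^(-q / 10)))),
               numeric(1))
  allq <- unlist(out$phred, use.names = FALSE)
  structure(
    list(reads = as_tibble(out),
         report = qc_report_row(nrow(reads), klen, sum(allq >= 30),
                                length(allq), sum(oa))),
    class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "OA quality control: %d / %d reads retained (%.2f%%), mean length %.1f bp,\n%.2f%% bases >= Q30, mean whole-read OA %.3f\n",
    r$n_retained, r$n_raw, r$pct_retained, r$mean_retained_length,
    r$pct_q30, r$mean_oa))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.qc_result <- function(x, ...) x$report

#' Stream OA quality control from FASTQ to FASTQ
#'
#' Constant-memory version of [run_qc()]: reads `input` in chunks, writes
#' retained reads to `output` (if not `NULL`), and returns the aggregated
#' report.
#'
#' @param input Path to the raw FASTQ file.
#' @param output Path for the high-quality FASTQ, or `NULL` to skip writing.
#' @param params A [qc_params()] object.
#' @param encoding Quality offset of both input and output, 33 or 64.
#' @param chunk_size Reads per chunk.
#' @return The one-row QC report tibble.
#' @export
run_qc_file <- function(input, output = NULL, params = qc_params(),
                        encoding = 33, chunk_size = 10000L) {
  state <- new.env(parent = emptyenv())
  state$n_raw <- 0L; state$lens <- list(); state$q30 <- 0
  state$bases <- 0; state$oa <- 0; state$first <- TRUE
  fastq_apply(input, function(chunk) {
    res <- run_qc(chunk, params)
    state$n_raw <- state$n_raw + nrow(chunk)
    state$lens[[length(state$lens) + 1L]] <-
      vapply(res$reads$phred, length, integer(1))
    allq <- unlist(res$reads$phred, use.names = FALSE)
    state$q30 <- state$q30 + sum(allq >= 30)
    state$bases <- state$bases + length(allq)
    state$oa <- state$oa + sum(vapply(res$reads$phred, function(q)
      exp(sum(log1p(-10^(-q / 10)))), numeric(1)))
    if (!is.null(output)) {
      write_fastq(res$reads[c("read_id", "sequence", "phred")], output,
                  encoding = encoding, append = !state$first)
      state$first <- FALSE
    }
    NULL
  }, encoding = encoding, chunk_size = chunk_size)
  qc_report_row(state$n_raw, unlist(state$lens), state$q30, state$bases,
                state$oa)
}
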
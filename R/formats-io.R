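# FASTQ and TSV input/output.
#
# Reads are represented as a tibble with columns `read_id` (header text after
# the leading "@"), `sequence`, and `phred` (list column of integer vectors,
# one score per base). Only the modern 4-line FASTQ dialect is supported, with
# a bare "+" separator; quality offsets 33 (Sanger) and 64 (old Illumina) are
# both handled, and scores outside [0, 60] are rejected as a probable
# offset mix-up.

PHRED_MAX <- 60L

check_encoding <- function(encoding) {
  if (!is.numeric(encoding) || length(encoding) != 1L ||
      !encoding %in% c(33, 64)) {
    abort_metarep("`encoding` must be 33 or 64.", "metarep_encoding_error")
  }
  as.integer(encoding)
}

parse_fastq_chunk <- function(lines, offset, line0) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    abort_metarep(
      sprintf("truncated FASTQ record starting at line %d.",
              line0 + (n %/% 4L) * 4L + 1L),
      "metarep_parse_error")
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort_metarep(sprintf("expected '@' header at line %d.",
                          line0 + (bad[1] - 1L) * 4L + 1L),
                  "metarep_parse_error")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort_metarep(sprintf("expected '+' separator at line %d.",
                          line0 + (bad[1] - 1L) * 4L + 3L),
                  "metarep_parse_error")
  }
  bad <- which(nchar(seqs) != nchar(qual) | nchar(seqs) == 0L)
  if (length(bad)) {
    abort_metarep(
      sprintf("sequence and quality lengths differ (or are zero) at line %d.",
              line0 + (bad[1] - 1L) * 4L + 2L),
      "metarep_parse_error")
  }

  phred <- lapply(qual, function(s) utf8ToInt(s) - offset)
  rng <- range(unlist(phred, use.names = FALSE))
  if (rng[1] < 0L) {
    abort_metarep(
      sprintf(paste0("negative Phred score after subtracting offset %d; ",
                     "is the file really Phred+%d?"), offset, offset),
      "metarep_encoding_error")
  }
  if (rng[2] > PHRED_MAX) {
    abort_metarep(
      sprintf(paste0("Phred score %d exceeds %d; this usually means a ",
                     "Phred+64 file read with offset 33."),
              rng[2], PHRED_MAX),
      "metarep_encoding_error")
  }
  tibble(read_id = substring(hdr, 2L), sequence = seqs, phred = phred)
}

#' Stream a FASTQ file through a callback, chunk by chunk
#'
#' Reads `chunk_size` records at a time (constant memory in the file size),
#' parses them into the package's read tibble, and hands each chunk to `f`.
#' Plain and gzip-compressed files are both accepted.
#'
#' @param path Path to a 4-line-record FASTQ file (optionally gzipped).
#' @param f Function of one argument, called on each chunk tibble; its return
#'   values are collected into a list.
#' @param encoding Quality offset, 33 (Sanger) or 64 (old Illumina).
#' @param chunk_size Number of reads per chunk.
#' @return Invisibly, the list of values returned by `f`.
#' @seealso [read_fastq()] which materialises the whole file.
#' @export
fastq_apply <- function(path, f, encoding = 33, chunk_size = 10000L) {
  offset <- check_encoding(encoding)
  check_positive_scalar(chunk_size, "chunk_size", integer = TRUE)
  if (!file.exists(path)) {
    abort_metarep(sprintf("FASTQ file not found: %s", path),
                  "metarep_parse_error")
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  out <- list()
  line0 <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    chunk <- parse_fastq_chunk(lines, offset, line0)
    out[[length(out) + 1L]] <- f(chunk)
    line0 <- line0 + length(lines)
  }
  invisible(out)
}

#' Read a FASTQ file into a read tibble
#'
#' @inheritParams fastq_apply
#' @return A tibble with columns `read_id`, `sequence`, and `phred`
#'   (list column of integer per-base quality scores).
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)$phred[[1]]  # 'I' is Phred 40 at offset 33
#' @export
read_fastq <- function(path, encoding = 33, chunk_size = 10000L) {
  chunks <- fastq_apply(path, identity, encoding = encoding,
                        chunk_size = chunk_size)
  if (length(chunks) == 0L) {
    return(tibble(read_id = character(), sequence = character(),
                  phred = list()))
  }
  bind_rows(chunks)
}

#' Write a read tibble as FASTQ
#'
#' Round-trips with [read_fastq()]: writing then reading (or the reverse, for
#' files in this 4-line dialect) reproduces the input exactly.
#'
#' @param reads Tibble with `read_id`, `sequence`, `phred` columns.
#' @param path Output path.
#' @param encoding Quality offset, 33 or 64.
#' @param append Append to an existing file instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, encoding = 33, append = FALSE) {
  offset <- check_encoding(encoding)
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "phred") %in% names(reads)))
  qual <- vapply(reads$phred, function(q) {
    code <- q + offset
    if (length(code) && (min(code) < 33L || max(code) > 126L)) {
      abort_metarep(
        sprintf("Phred + offset %d falls outside printable ASCII [33, 126].",
                offset),
        "metarep_encoding_error")
    }
    if (length(code) == 0L) "" else intToUtf8(code)
  }, character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  if (nrow(reads) == 0L) lines <- character()
  con <- file(path, open = if (append) "at" else "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---- TSV tables -------------------------------------------------------------

table_schemas <- list(
  gene_catalog    = list(key = "gene_id",
                         required = c("gene_id", "length_bp", "gc_fraction")),
  counts          = list(key = "gene_id", required = "gene_id"),
  species_profile = list(key = "species", required = "species"),
  species_gc      = list(key = "species",
                         required = c("species", "gc_fraction"))
)

validate_schema <- function(tbl, schema) {
  sc <- table_schemas[[schema]]
  missing <- setdiff(sc$required, names(tbl))
  if (length(missing)) {
    abort_metarep(sprintf("schema '%s': missing column(s) %s.", schema,
                          paste0("`", missing, "`", collapse = ", ")),
                  "metarep_schema_error")
  }
  if (anyDuplicated(tbl[[sc$key]])) {
    abort_metarep(sprintf("schema '%s': duplicated `%s` values.", schema,
                          sc$key),
                  "metarep_schema_error")
  }
  if ("gc_fraction" %in% names(tbl)) {
    v <- tbl$gc_fraction
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad)) {
      abort_metarep(
        sprintf("schema '%s': gc_fraction outside [0, 1] at row %d.",
                schema, bad[1]),
        "metarep_schema_error")
    }
  }
  if ("length_bp" %in% names(tbl)) {
    v <- tbl$length_bp
    bad <- which(!is.finite(v) | v < 1 | v != trunc(v))
    if (length(bad)) {
      abort_metarep(
        sprintf("schema '%s': length_bp must be a positive integer (row %d).",
                schema, bad[1]),
        "metarep_schema_error")
    }
  }
  value_cols <- setdiff(names(tbl), c(sc$key, "species", "length_bp",
                                      "gc_fraction"))
  if (schema %in% c("counts", "species_profile")) {
    if (length(value_cols) == 0L) {
      abort_metarep(sprintf("schema '%s': no sample columns found.", schema),
                    "metarep_schema_error")
    }
    for (s in value_cols) {
      v <- tbl[[s]]
      if (!is.numeric(v)) {
        abort_metarep(
          sprintf("schema '%s': column `%s` is not numeric.", schema, s),
          "metarep_schema_error")
      }
      bad <- which(!is.finite(v) | v < 0 |
                     (schema == "counts" & v != trunc(v)))
      if (length(bad)) {
        abort_metarep(
          sprintf("schema '%s': invalid value in column `%s` at row %d.",
                  schema, s, bad[1]),
          "metarep_schema_error")
      }
    }
  }
  tbl
}

#' Read a typed tab-separated table
#'
#' Reads one of the pipeline's tabular inputs and validates it against its
#' schema: `gene_catalog` (gene_id, length_bp, gc_fraction, optional species),
#' `counts` (gene_id plus integer sample columns), `species_profile`
#' (species plus numeric sample columns, MetaPhlAn-style), or `species_gc`
#' (species, gc_fraction). Violations raise a schema error naming the first
#' offending row.
#'
#' @param path Path to a TSV file with a header row.
#' @param schema One of `"gene_catalog"`, `"counts"`, `"species_profile"`,
#'   `"species_gc"`.
#' @return A validated tibble.
#' @export
read_typed_table <- function(path, schema = c("gene_catalog", "counts",
                                        "species_profile", "species_gc")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort_metarep(sprintf("table not found: %s", path), "metarep_parse_error")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_schema(tbl, schema)
}

#' Write a table as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_typed_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Build a gene catalog from a FASTA file
#'
#' Computes per-gene length and GC fraction (via [gc_content()]) from gene
#' sequences; species labels, which a FASTA cannot carry reliably, are left
#' absent.
#'
#' @param path Path to a (optionally gzipped) FASTA file of gene sequences.
#' @return A gene-catalog tibble: `gene_id`, `length_bp`, `gc_fraction`.
#' @export
catalog_from_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  tibble(gene_id = ids,
         length_bp = Biostrings::width(seqs),
         gc_fraction = gc_content(as.character(seqs)))
}
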
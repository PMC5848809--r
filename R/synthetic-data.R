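# Synthetic data with the statistical structure the pipeline assumes:
# gene catalogs with bimodal GC, log-normal community abundances, paired
# multinomial replicate counts, an exponential GC tilt standing in for a
# platform bias, and FASTQ reads with 3' quality decay plus random
# low-quality segments. Every generator is a pure function of its
# parameters and seed.

# Fisher log-series sampler: P(N = n) = -theta^n / (n * log(1 - theta)).
rlogseries <- function(n, theta = 0.99) {
  kmax <- 1e5
  pmf <- theta^(seq_len(kmax)) / seq_len(kmax)
  sample.int(kmax, n, replace = TRUE, prob = pmf)
}

#' Simulate a gene catalog
#'
#' Genes are assigned to species with log-series species sizes (a few large
#' species, a long tail of small ones, the usual community shape); GC
#' fractions are drawn from a two-component normal mixture truncated to
#' `[0, 1]`, giving the bimodal GC density characteristic of large gut gene
#' catalogs; lengths are log-normal with a floor.
#'
#' @param n_genes,n_species Catalog size.
#' @param gc_means,gc_sds,gc_weight Mixture components: means, standard
#'   deviations, and the weight of the first component.
#' @param length_meanlog,length_sdlog Log-normal gene length parameters
#'   (defaults give a median near 750 bp).
#' @param min_length Length floor in bp.
#' @param log_series_theta Shape of the species-size log-series.
#' @param seed Integer seed, or `NULL`.
#' @return A gene-catalog tibble: `gene_id`, `length_bp`, `gc_fraction`,
#'   `species`.
#' @export
simulate_catalog <- function(n_genes = 100000L, n_species = 100L,
                             gc_means = c(0.40, 0.60),
                             gc_sds = c(0.05, 0.06), gc_weight = 0.6,
                             length_meanlog = log(750), length_sdlog = 0.45,
                             min_length = 100L, log_series_theta = 0.99,
                             seed = NULL) {
  check_positive_scalar(n_genes, "n_genes", integer = TRUE)
  check_positive_scalar(n_species, "n_species", integer = TRUE)
  if (n_species > n_genes) {
    abort_metarep("`n_species` cannot exceed `n_genes`.",
                  "metarep_domain_error")
  }
  if (gc_weight < 0 || gc_weight > 1 ||
      length(gc_means) != 2L || length(gc_sds) != 2L || any(gc_sds <= 0)) {
    abort_metarep("degenerate GC mixture specification.",
                  "metarep_domain_error")
  }
  with_seed_or_current(seed, {
    sizes <- rlogseries(n_species, log_series_theta)
    species <- paste0("sp", formatC(seq_len(n_species), width = 3,
                                    flag = "0"))
    assigned <- sample(species, n_genes, replace = TRUE,
                       prob = sizes / sum(sizes))
    comp <- runif(n_genes) < gc_weight
    gc <- rnorm(n_genes,
                mean = ifelse(comp, gc_means[1], gc_means[2]),
                sd = ifelse(comp, gc_sds[1], gc_sds[2]))
    gc <- pmin(1, pmax(0, gc))
    len <- pmax(as.integer(min_length),
                as.integer(round(rlnorm(n_genes, length_meanlog,
                                        length_sdlog))))
    tibble(gene_id = paste0("gene", formatC(seq_len(n_genes),
                                            width = nchar(n_genes),
                                            flag = "0")),
           length_bp = len, gc_fraction = gc, species = assigned)
  })
}

#' Simulate a community abundance profile
#'
#' Independent log-normal masses per gene, normalised to sum to 1. The
#' abundance is independent of GC content by construction, so this is the
#' null community for the GC-bias analyses. The default `sigma = 2` gives
#' the heavy right tail of gut metagenomes, where most genes carry few reads
#' at any realistic depth.
#'
#' @param catalog Gene catalog tibble (only `gene_id` is used).
#' @param sigma Log-normal sigma of the gene masses; 0 gives a uniform
#'   profile.
#' @param seed Integer seed, or `NULL`.
#' @return An abundance tibble: `gene_id`, `abundance` (sums to 1).
#' @export
simulate_abundances <- function(catalog, sigma = 2, seed = NULL) {
  stopifnot(is.data.frame(catalog), "gene_id" %in% names(catalog))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    abort_metarep("`sigma` must be a single non-negative number.",
                  "metarep_domain_error")
  }
  with_seed_or_current(seed, {
    mass <- rlnorm(nrow(catalog), meanlog = 0, sdlog = sigma)
    tibble(gene_id = catalog$gene_id, abundance = mass / sum(mass))
  })
}

#' Tilt an abundance profile in GC content (platform bias)
#'
#' Re-weights each gene's abundance by `exp(beta * (gc - pivot))` and
#' renormalises: the simplest monotone GC enrichment, emulating a platform
#' that over-recruits reads from GC-rich (`beta > 0`) or AT-rich
#' (`beta < 0`) genes. `beta = 0` is the identity.
#'
#' @param profile Abundance tibble: `gene_id`, `abundance`.
#' @param catalog Gene catalog with `gene_id` and `gc_fraction`.
#' @param beta Tilt strength (per unit GC fraction).
#' @param pivot GC value left unweighted, default 0.5.
#' @return An abundance tibble of the same shape.
#' @export
apply_platform_bias <- function(profile, catalog, beta, pivot = 0.5) {
  stopifnot(is.data.frame(profile),
            all(c("gene_id", "abundance") %in% names(profile)))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    abort_metarep("`beta` must be a single finite number.",
                  "metarep_domain_error")
  }
  gc <- catalog$gc_fraction[match(profile$gene_id, catalog$gene_id)]
  if (anyNA(gc)) {
    abort_metarep("`catalog` lacks GC for some genes in `profile`.",
                  "metarep_schema_error")
  }
  w <- profile$abundance * exp(beta * (gc - pivot))
  tibble(gene_id = profile$gene_id, abundance = w / sum(w))
}

#' Simulate replicate read counts from an abundance profile
#'
#' One multinomial draw of `depth` reads over the genes; independent draws
#' (different seeds) model technical replicates of the same library.
#'
#' @param profile Abundance tibble: `gene_id`, `abundance`.
#' @param depth Reads per replicate.
#' @param seed Integer seed, or `NULL`.
#' @return A counts tibble: `gene_id`, `count`.
#' @export
simulate_replicate_counts <- function(profile, depth = 1000000L,
                                      seed = NULL) {
  stopifnot(is.data.frame(profile),
            all(c("gene_id", "abundance") %in% names(profile)))
  check_positive_scalar(depth, "depth", integer = TRUE)
  with_seed_or_current(seed, {
    tibble(gene_id = profile$gene_id,
           count = as.integer(rmultinom(1L, as.integer(depth),
                                        profile$abundance)[, 1]))
  })
}

#' Simulate a table of replicate counts
#'
#' Convenience wrapper drawing `n_reps` independent multinomial replicates
#' from one profile into a single counts tibble.
#'
#' @inheritParams simulate_replicate_counts
#' @param n_reps Number of replicate columns.
#' @param prefix Sample-name prefix; columns are `<prefix>1 ... <prefix>n`.
#' @return A counts tibble: `gene_id` plus `n_reps` count columns.
#' @export
simulate_replicate_table <- function(profile, depth = 1000000L, n_reps = 2L,
                                     prefix = "rep", seed = NULL) {
  check_positive_scalar(n_reps, "n_reps", integer = TRUE)
  with_seed_or_current(seed, {
    draws <- rmultinom(n_reps, as.integer(depth), profile$abundance)
    cols <- lapply(seq_len(n_reps), function(i) as.integer(draws[, i]))
    names(cols) <- paste0(prefix, seq_len(n_reps))
    as_tibble(c(list(gene_id = profile$gene_id), cols))
  })
}

#' Simulate FASTQ reads with realistic quality structure
#'
#' Per-base quality follows a linear decay from `q_start` at the 5' end to
#' `q_end` at the 3' end plus Gaussian jitter, clamped to `[0, 45]` —
#' the gradual 3' quality decline of short-read sequencers. With probability
#' `drop_rate` a read additionally carries one contiguous low-quality
#' segment (`segment_length` bases at `segment_q`) at a uniformly random
#' offset — the random mid-read quality drop the OA filter is designed to
#' catch. Bases are uniform over ACGT.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (single-end short-read scale).
#' @param q_start,q_end Mean Phred at the first and last base.
#' @param q_noise_sd Per-base Gaussian jitter, default 2.
#' @param drop_rate Per-read probability of one low-quality segment.
#' @param segment_length,segment_q Segment geometry and quality.
#' @param seed Integer seed, or `NULL`.
#' @return A read tibble (`read_id`, `sequence`, `phred`) as from
#'   [read_fastq()].
#' @export
simulate_fastq <- function(n_reads = 1000L, read_length = 100L,
                           q_start = 38, q_end = 30, q_noise_sd = 2,
                           drop_rate = 0.05, segment_length = 10L,
                           segment_q = 2L, seed = NULL) {
  check_positive_scalar(n_reads, "n_reads", integer = TRUE)
  check_positive_scalar(read_length, "read_length", integer = TRUE)
  if (drop_rate < 0 || drop_rate > 1) {
    abort_metarep("`drop_rate` must lie in [0, 1].", "metarep_domain_error")
  }
  seg <- min(as.integer(segment_length), as.integer(read_length))
  with_seed_or_current(seed, {
    baseline <- q_start + (q_end - q_start) *
      (seq_len(read_length) - 1) / max(1L, read_length - 1L)
    q <- matrix(rnorm(n_reads * read_length,
                      mean = rep(baseline, each = n_reads),
                      sd = q_noise_sd),
                nrow = n_reads)
    q <- pmin(pmax(round(q), 0L), 45L)  # matrix first: pmin/pmax keep dims
    dropped <- runif(n_reads) < drop_rate
    offsets <- sample.int(read_length - seg + 1L, n_reads, replace = TRUE)
    for (i in which(dropped)) {
      q[i, offsets[i]:(offsets[i] + seg - 1L)] <- as.integer(segment_q)
    }
    bases <- matrix(sample(c("A", "C", "G", "T"), n_reads * read_length,
                           replace = TRUE), nrow = n_reads)
    tibble(
      read_id = paste0("read", formatC(seq_len(n_reads),
                                       width = nchar(n_reads), flag = "0")),
      sequence = apply(bases, 1L, paste0, collapse = ""),
      phred = lapply(seq_len(n_reads), function(i) as.integer(q[i, ])))
  })
}
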
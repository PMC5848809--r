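Package: metarep
Title: Reproducibility and GC-Bias Statistics for Metagenomic Sequencing Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and concordance statistics for shotgun metagenomic
    sequencing experiments with technical replicates, within or across
    sequencing platforms. Implements an overall-accuracy (OA) read quality
    control that trims reads at the first low-accuracy sliding fragment;
    rarefaction of uniquely-mapped gene counts and length-normalised relative
    abundance; concordance intervals for replicate read-count fluctuations with
    coverage summaries; highly-reproducible-gene selection, Spearman profile
    correlation, the ALC mean-difference statistic, and per-gene paired t and
    sign tests with Benjamini-Hochberg adjustment; GC-bias quantification via
    per-species robust (Huber) regression of gene abundance on GC content and a
    log-linear likelihood-ratio test on an abundance-by-GC-by-platform
    contingency cube; and a synthetic-data generator (gene catalogs, multinomial
    replicate counts, GC-tilted platforms, FASTQ reads) so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
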
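# ggplot2 displays for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.fluctuation_coverage <- function(object, ...) {
  g <- glance(object)
  band <- distinct(as_tibble(object[c("count1", "lo", "hi")])) |>
    arrange(.data$count1)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$count1, y = .data$count2)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$count1, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, fill = "red", alpha = 0.15) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(
      x = "reads in replicate 1", y = "reads in replicate 2",
      title = sprintf("%.2f%% of genes within the %d%% concordance band",
                      100 * g$fraction_within, round(100 * g$level)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.alc_result <- function(object, ...) {
  d <- sort(object$d)
  df <- tibble(d = d, F = seq_along(d) / length(d))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$F)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$alc, linetype = 2) +
    ggplot2::labs(
      x = "|log2 abundance difference|", y = "cumulative proportion of genes",
      title = sprintf("ALC = %.3f (mean fold change %.3f)",
                      object$alc, object$fold_change))
}

#' @exportS3Method ggplot2::autoplot
autoplot.huber_fit <- function(object, ...) {
  ggplot2::ggplot(tibble(x = object$x, y = object$y),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(title = sprintf("Huber fit: slope %.3f", object$slope))
}

#' @exportS3Method ggplot2::autoplot
autoplot.species_slopes <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::geom_vline(xintercept = median(object$slope), colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "per-species slope of log10 abundance on GC",
                  y = "species",
                  title = sprintf("median slope %.3f over %d species",
                                  median(object$slope), nrow(object)))
}

#' Compare GC densities of gene sets
#'
#' Overlays the GC-content densities of named gene sets against a catalog —
#' e.g. all genes, HR genes, and the genes flagged as significantly
#' different between platforms, whose GC density goes bimodal when a
#' platform GC bias is present.
#'
#' @param catalog Gene catalog with `gene_id` and `gc_fraction`.
#' @param gene_sets Named list of character vectors of gene ids.
#' @return A ggplot object.
#' @export
plot_gc_density <- function(catalog, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  df <- bind_rows(lapply(names(gene_sets), function(nm) {
    tibble(set = nm,
           gc = catalog$gc_fraction[catalog$gene_id %in% gene_sets[[nm]]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gc, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "GC fraction", y = "density", colour = NULL)
}

#' Mean Phred score by read position
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @return A ggplot object.
#' @export
plot_read_quality <- function(reads) {
  lens <- vapply(reads$phred, length, integer(1))
  df <- tibble(position = unlist(lapply(lens, seq_len)),
               phred = unlist(reads$phred)) |>
    group_by(.data$position) |>
    summarise(mean_phred = mean(.data$phred), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_phred)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "read position (bp)", y = "mean Phred score")
}
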
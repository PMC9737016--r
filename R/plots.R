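#' Plot ROH segments along chromosomes
#'
#' One horizontal track per individual per chromosome, segments drawn to
#' genomic scale.
#'
#' @param object a tibble from [detect_roh()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot roh_segments
#' @export
autoplot.roh_segments <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start_pos / 1e6, xend = .data$end_pos / 1e6,
      y = .data$individual, yend = .data$individual
    ), linewidth = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Runs of homozygosity")
}

#' Plot per-SNP ROH incidence with the island threshold
#'
#' @param object a tibble from [snp_incidence()].
#' @param threshold island incidence threshold to draw (default 0.30).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot incidence_track
#' @export
autoplot.incidence_track <- function(object, threshold = 0.30, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pos / 1e6, .data$incidence)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "fraction of individuals in ROH")
}

#' Bar chart of the ROH length-class distribution
#'
#' @param summary a tibble from [length_class_summary()].
#' @return a ggplot object.
#' @export
plot_length_classes <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    factor(.data$class, .data$class), .data$n
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")),
                       vjust = -0.3) +
    ggplot2::labs(x = "ROH length class", y = "count")
}

#' Heatmap of the genomic relationship matrix
#'
#' @param object an object from [relatedness_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot roh_grm
#' @export
autoplot.roh_grm <- function(object, ...) {
  df <- tidyr::expand_grid(
    id1 = object$individuals, id2 = object$individuals
  )
  df$relatedness <- as.vector(t(object$A))
  ggplot2::ggplot(df, ggplot2::aes(.data$id1, .data$id2,
                                   fill = .data$relatedness)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
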
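#' Plot a LOD scan
#'
#' LOD curve per chromosome with the permutation threshold (when set) as a
#' dashed line.
#'
#' @param object a `qtl_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.qtl_scan <- function(object, ...) {
  df <- object$result
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(object$threshold),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Synteny dot plot of alignment blocks
#'
#' @param blocks alignment block tibble.
#' @return a ggplot with reference position against query position, one
#'   segment per block, minus-strand blocks in red.
#' @export
plot_blocks <- function(blocks) {
  ggplot2::ggplot(blocks) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$ref_start, xend = .data$ref_end,
      y = if_else(.data$strand == "+", .data$qry_start, .data$qry_end),
      yend = if_else(.data$strand == "+", .data$qry_end, .data$qry_start),
      colour = .data$strand)) +
    ggplot2::scale_colour_manual(values = c("+" = "#2c7fb8", "-" = "#de2d26")) +
    ggplot2::facet_grid(.data$qry_chrom ~ .data$ref_chrom, scales = "free") +
    ggplot2::labs(x = "reference (bp)", y = "query (bp)") +
    ggplot2::theme_minimal()
}

#' Plot a windowed track
#'
#' @param track tibble from [window_track()] or [gc_track()].
#' @param value name of the value column (default autodetected:
#'   `occupancy` or `gc`).
#' @return a ggplot.
#' @export
plot_track <- function(track, value = NULL) {
  value <- value %||% intersect(c("occupancy", "gc"), names(track))[1]
  ggplot2::ggplot(track, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data[[value]])) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (bp)", y = value) +
    ggplot2::theme_minimal()
}
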
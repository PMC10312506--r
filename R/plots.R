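# ggplot2 helpers for tracks, heatmaps and window identities

#' @importFrom ggplot2 ggplot aes geom_line geom_tile geom_rect geom_step
#'   geom_point labs scale_fill_viridis_c theme_minimal autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a windowed numeric track
#'
#' @param track Tibble with `start`, `end` and one numeric value column.
#' @param value Name of the value column (default: first numeric column
#'   other than `start`/`end`).
#' @param highlight Optional interval tibble (`start`, `end`) drawn as
#'   shaded rectangles (e.g. CDRs or planted dips).
#' @return A ggplot object.
#' @export
plot_track <- function(track, value = NULL, highlight = NULL) {
  if (is.null(value)) {
    value <- setdiff(names(track)[vapply(track, is.numeric, logical(1))],
                     c("start", "end", "pos"))[1]
  }
  xcol <- if ("start" %in% names(track)) "start" else "pos"
  p <- ggplot(track, aes(x = .data[[xcol]] / 1e3, y = .data[[value]]))
  if (!is.null(highlight) && nrow(highlight) > 0) {
    p <- p + geom_rect(data = highlight,
                       aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "orange", alpha = 0.25)
  }
  p + geom_step() +
    labs(x = "position (kbp)", y = value) +
    theme_minimal()
}

#' Plot a self-identity heatmap
#'
#' @param object An `identity_heatmap`.
#' @param ... Unused.
#' @return A ggplot object (tile heatmap of pairwise window identity).
#' @export
autoplot.identity_heatmap <- function(object, ...) {
  nw <- nrow(object$matrix)
  df <- tidyr::expand_grid(i = seq_len(nw), j = seq_len(nw)) %>%
    mutate(identity = object$matrix[cbind(.data$i, .data$j)],
           x = object$windows$start[.data$i] / 1e3,
           y = object$windows$start[.data$j] / 1e3)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$identity)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(min(df$identity), 1)) +
    labs(x = "position (kbp)", y = "position (kbp)",
         fill = "identity", title = paste0("window = ",
                                           object$window_bp, " bp (",
                                           object$method, ")")) +
    theme_minimal()
}

#' Plot windowed identity along the reference
#'
#' @param windows Window tibble from the identity functions.
#' @param region_bed Optional region classes (`start`, `end`, `class`) shown
#'   as coloured rectangles.
#' @return A ggplot object.
#' @export
plot_window_identity <- function(windows, region_bed = NULL) {
  p <- ggplot(windows, aes(x = (.data$start + .data$end) / 2e3,
                           y = .data$mean_identity))
  if (!is.null(region_bed) && nrow(region_bed) > 0) {
    p <- p + geom_rect(data = region_bed,
                       aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                           ymin = -Inf, ymax = Inf, fill = .data$class),
                       inherit.aes = FALSE, alpha = 0.15)
  }
  p + geom_point() + geom_line() +
    labs(x = "position (kbp)", y = "mean identity") +
    theme_minimal()
}

#' Plot a calibrated tree with node ages
#'
#' @param x A `calibrated_tree`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, `x`.
#' @export
plot.calibrated_tree <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  if (!is.null(x$support)) {
    ape::nodelabels(text = round(x$support),
                    frame = "none", adj = c(1.2, -0.3), cex = 0.7)
  }
  invisible(x)
}
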
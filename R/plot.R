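#' Plot a lineage forest as a ggplot cladogram
#'
#' A quick-look ggplot2 rendering of the same layout used for SVG export:
#' time runs downwards, branches split at divisions and converge at
#' fusions, deaths are red crosses, field exits blue double bars. For
#' publication-quality vector output use [write_cladogram_svg()].
#'
#' @param object A `lineage_forest`.
#' @param timeline A [timeline()] (optional).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lineage_forest
#' @export
autoplot.lineage_forest <- function(object, timeline = NULL, ...) {
  layout <- cladogram_layout(object, timeline)
  seg <- layout$segments
  jn <- layout$junctions
  mk <- layout$markers
  gl <- layout$gridlines
  tl <- layout$timeline

  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(data = gl, ggplot2::aes(yintercept = .data$frame),
                        colour = "grey80", linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$lane, xend = .data$lane,
                   y = .data$frame0, yend = .data$frame1),
      linewidth = 0.6)
  if (nrow(jn)) {
    jn$lane0 <- (jn$x0 - layout$style$margin_left) / layout$style$lane_width
    jn$lane1 <- (jn$x1 - layout$style$margin_left) / layout$style$lane_width
    p <- p + ggplot2::geom_segment(
      data = jn,
      ggplot2::aes(x = .data$lane0, xend = .data$lane1,
                   y = .data$frame, yend = .data$frame),
      linewidth = 0.6)
  }
  deaths <- mk[!is.na(mk$type) & mk$type == "death", , drop = FALSE]
  if (nrow(deaths)) {
    deaths$frame <- (deaths$y - layout$style$margin_top) / layout$style$px_per_frame
    deaths$lane <- (deaths$x - layout$style$margin_left) / layout$style$lane_width
    p <- p + ggplot2::geom_point(
      data = deaths, ggplot2::aes(x = .data$lane, y = .data$frame),
      shape = 4, colour = "red", size = 3, stroke = 1)
  }
  outs <- mk[!is.na(mk$type) & mk$type == "out", , drop = FALSE]
  if (nrow(outs)) {
    outs$frame <- (outs$y - layout$style$margin_top) / layout$style$px_per_frame
    outs$lane <- (outs$x - layout$style$margin_left) / layout$style$lane_width
    p <- p + ggplot2::geom_point(
      data = outs, ggplot2::aes(x = .data$lane, y = .data$frame),
      shape = "=", colour = "blue", size = 4)
  }
  roots <- seg[seg$name %in% forest_roots(object), , drop = FALSE]
  if (nrow(roots)) {
    p <- p + ggplot2::geom_text(
      data = roots, ggplot2::aes(x = .data$lane, y = .data$frame0, label = .data$name),
      vjust = -0.8, size = 3)
  }
  p +
    ggplot2::scale_y_reverse(name = "frame",
                             breaks = gl$frame,
                             sec.axis = ggplot2::dup_axis(
                               name = "hours",
                               labels = function(b) frames_to_hours(tl, b))) +
    ggplot2::scale_x_continuous(name = NULL, breaks = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
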
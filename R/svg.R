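fmt_px <- function(x) sub("\\.0+$", "", sprintf("%.2f", x))

svg_line <- function(x1, y1, x2, y2, stroke, width, dash = NULL) {
  d <- if (!is.null(dash)) sprintf(' stroke-dasharray="%s"', dash) else ""
  sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
          fmt_px(x1), fmt_px(y1), fmt_px(x2), fmt_px(y2), stroke, fmt_px(width), d)
}

svg_text <- function(x, y, text, size, family, anchor = "middle", fill = "black") {
  sprintf('<text x="%s" y="%s" font-size="%s" font-family="%s" text-anchor="%s" fill="%s">%s</text>',
          fmt_px(x), fmt_px(y), fmt_px(size), family, anchor, fill,
          xml_escape(text))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

highlight_shape_svg <- function(shape, colour, x, y, r) {
  switch(shape,
    circle = sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                     fmt_px(x), fmt_px(y), fmt_px(r), colour),
    square = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                     fmt_px(x - r), fmt_px(y - r), fmt_px(2 * r), fmt_px(2 * r), colour),
    triangle = sprintf('<polygon points="%s,%s %s,%s %s,%s" fill="%s"/>',
                       fmt_px(x), fmt_px(y - r), fmt_px(x - r), fmt_px(y + r),
                       fmt_px(x + r), fmt_px(y + r), colour),
    star = {
      ang <- pi / 2 + 2 * pi * (0:9) / 10
      rad <- rep(c(r, 0.45 * r), 5)
      pts <- paste(fmt_px(x + rad * cos(ang)), fmt_px(y - rad * sin(ang)),
                   sep = ",", collapse = " ")
      sprintf('<polygon points="%s" fill="%s"/>', pts, colour)
    })
}

#' Render a cladogram layout as standalone SVG
#'
#' Emits SVG 1.1 text using the cladogram vocabulary: black vertical
#' lifespan strokes that split at divisions and converge at fusions, a red
#' cross at each death, a double parallel blue bar at each field exit, day
#' gridlines with frame numbers along the left axis, cell names above their
#' branches and the frame number printed below each event. Rendering is
#' deterministic: identical forest and style give byte-identical SVG.
#'
#' @param layout A `cladogram_layout` from [cladogram_layout()].
#' @return A single string of SVG markup.
#' @export
render_svg <- function(layout) {
  stopifnot(inherits(layout, "cladogram_layout"))
  st <- layout$style
  w <- layout$canvas$width; h <- layout$canvas$height
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_px(w), fmt_px(h), fmt_px(w), fmt_px(h)),
    sprintf('<rect width="%s" height="%s" fill="white"/>', fmt_px(w), fmt_px(h)))

  gl <- layout$gridlines
  out <- c(out, '<g class="days">')
  for (i in seq_len(nrow(gl))) {
    out <- c(out,
      svg_line(st$margin_left - 40, gl$y[i], w - st$margin_right, gl$y[i],
               "#bbbbbb", 0.7, dash = "4 3"),
      svg_text(st$margin_left - 44, gl$y[i] + 4, sprintf("%d", gl$frame[i]),
               st$font_size - 2, st$font_family, anchor = "end", fill = "#555555"))
    if (i < nrow(gl)) {
      ymid <- (gl$y[i] + gl$y[i + 1]) / 2
      out <- c(out, svg_text(st$margin_left - 64, ymid + 4,
                             sprintf("day %d", gl$day[i]),
                             st$font_size, st$font_family, anchor = "end"))
    }
  }
  out <- c(out, '</g>')

  seg <- layout$segments
  out <- c(out, '<g class="lineage">')
  for (i in seq_len(nrow(seg))) {
    out <- c(out, svg_line(seg$x[i], seg$y0[i], seg$x[i], seg$y1[i],
                           st$stroke, st$stroke_width))
  }
  jn <- layout$junctions
  if (nrow(jn)) {
    for (i in seq_len(nrow(jn))) {
      if (jn$type[i] == "division") {
        out <- c(out, svg_line(jn$x0[i], jn$y[i], jn$x1[i], jn$y[i],
                               st$stroke, st$stroke_width))
      } else {
        out <- c(out, svg_line(jn$x0[i], jn$y[i], jn$x1[i], jn$y[i],
                               st$stroke, st$stroke_width * 0.8))
      }
    }
  }
  out <- c(out, '</g>')

  mk <- layout$markers
  r <- st$marker_size
  deaths <- mk[!is.na(mk$type) & mk$type == "death", , drop = FALSE]
  out <- c(out, '<g class="deaths">')
  for (i in seq_len(nrow(deaths))) {
    x <- deaths$x[i]; y <- deaths$y[i]
    out <- c(out, sprintf('<g class="death-cross">%s%s</g>',
      svg_line(x - r, y - r, x + r, y + r, st$death_colour, st$stroke_width),
      svg_line(x - r, y + r, x + r, y - r, st$death_colour, st$stroke_width)))
  }
  out <- c(out, '</g>')

  outs <- mk[!is.na(mk$type) & mk$type == "out", , drop = FALSE]
  out <- c(out, '<g class="outs">')
  for (i in seq_len(nrow(outs))) {
    x <- outs$x[i]; y <- outs$y[i]
    out <- c(out, sprintf('<g class="out-bars">%s%s</g>',
      svg_line(x - r, y - 2.2, x + r, y - 2.2, st$out_colour, st$stroke_width),
      svg_line(x - r, y + 2.2, x + r, y + 2.2, st$out_colour, st$stroke_width)))
  }
  out <- c(out, '</g>')

  hls <- mk[!is.na(mk$type) & mk$type == "highlight", , drop = FALSE]
  if (nrow(hls)) {
    out <- c(out, '<g class="highlights">')
    for (i in seq_len(nrow(hls))) {
      out <- c(out, highlight_shape_svg(hls$shape[i], hls$colour[i],
                                        hls$x[i] + r + 7, st$margin_top - 13, r))
    }
    out <- c(out, '</g>')
  }

  lb <- layout$labels
  out <- c(out, '<g class="labels">')
  for (i in seq_len(nrow(lb))) {
    if (lb$type[i] == "name") {
      out <- c(out, svg_text(lb$x[i], lb$y[i], lb$text[i],
                             st$font_size, st$font_family))
    } else {
      out <- c(out, svg_text(lb$x[i], lb$y[i], lb$text[i],
                             st$font_size - 2, st$font_family,
                             anchor = "start", fill = "#333333"))
    }
  }
  out <- c(out, '</g>', '</svg>')
  paste(out, collapse = "\n")
}

#' Write a cladogram SVG for a forest
#'
#' Convenience wrapper: lays out the forest and writes the rendered SVG.
#'
#' @param forest A `lineage_forest` (or a ready `cladogram_layout`).
#' @param path Output file path.
#' @param timeline,style Passed to [cladogram_layout()].
#' @return `path`, invisibly.
#' @export
write_cladogram_svg <- function(forest, path, timeline = NULL,
                                style = cladogram_style()) {
  layout <- if (inherits(forest, "cladogram_layout")) forest
            else cladogram_layout(forest, timeline, style)
  writeLines(render_svg(layout), path, useBytes = TRUE)
  invisible(path)
}
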
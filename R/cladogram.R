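#' Cladogram style settings
#'
#' Geometry and colours for SVG rendering. The lineage vocabulary itself is
#' fixed (black strokes, a red cross for death, a double parallel blue bar
#' for a field exit); everything geometric is adjustable.
#'
#' @param lane_width Horizontal pixels between adjacent lanes.
#' @param px_per_frame Vertical pixels per frame.
#' @param margin_left,margin_top,margin_right,margin_bottom Canvas margins
#'   in pixels (left margin hosts the day axis, top margin the cell names).
#' @param stroke Lineage stroke colour.
#' @param stroke_width Lineage stroke width in pixels.
#' @param death_colour Colour of the death cross.
#' @param out_colour Colour of the exit double bar.
#' @param marker_size Half-size in pixels of death/exit/highlight marks.
#' @param font_size Label font size in pixels.
#' @param font_family Label font family.
#' @return A `cladogram_style` list.
#' @export
cladogram_style <- function(lane_width = 42,
                            px_per_frame = 1.4,
                            margin_left = 86,
                            margin_top = 46,
                            margin_right = 30,
                            margin_bottom = 24,
                            stroke = "black",
                            stroke_width = 1.6,
                            death_colour = "red",
                            out_colour = "blue",
                            marker_size = 5,
                            font_size = 11,
                            font_family = "Helvetica, Arial, sans-serif") {
  structure(list(
    lane_width = lane_width, px_per_frame = px_per_frame,
    margin_left = margin_left, margin_top = margin_top,
    margin_right = margin_right, margin_bottom = margin_bottom,
    stroke = stroke, stroke_width = stroke_width,
    death_colour = death_colour, out_colour = out_colour,
    marker_size = marker_size, font_size = font_size,
    font_family = font_family), class = "cladogram_style")
}

# Lane assignment. Division edges form trees: leaves (cells that never
# divide, including fused inputs) take consecutive integer lanes within
# each root block and every mother sits at the midpoint of her daughters'
# span. Fusion products are then placed at the midpoint of their inputs'
# lanes; a product's own division subtree is laid out around that centre in
# a narrow band. Finally any residual lane collision between two cells
# alive over overlapping frames is resolved by a small deterministic nudge.
assign_lanes <- function(forest) {
  n <- nrow(forest)
  lane <- rep(NA_real_, n)
  ord <- seq_len(n); names(ord) <- forest$name
  is_prod <- forest$birth_mode == "FROM_FUSION"
  next_leaf <- 0

  place_tree <- function(i) {
    kids <- forest$children[[i]]
    if (forest$fate[i] == "DIVIDED" && length(kids)) {
      ki <- unname(ord[kids])
      for (k in ki) place_tree(k)
      lane[i] <<- mean(lane[ki])
    } else {
      lane[i] <<- next_leaf
      next_leaf <<- next_leaf + 1
    }
  }
  for (r in which(forest$birth_mode == "INITIAL")) {
    place_tree(r)
    next_leaf <- next_leaf + 1  # gap between root blocks
  }

  # fusion products in creation order: inputs are already placed
  place_band <- function(i, centre, width) {
    kids <- forest$children[[i]]
    if (forest$fate[i] == "DIVIDED" && length(kids)) {
      ki <- unname(ord[kids])
      m <- length(ki)
      for (j in seq_along(ki)) {
        place_band(ki[j], centre + width * ((j - 1) / max(1, m - 1) - 0.5),
                   width / m)
      }
      lane[i] <<- mean(lane[ki])
    } else {
      lane[i] <<- centre
    }
  }
  for (i in which(is_prod)) {
    pin <- unname(ord[forest$parents[[i]]])
    place_band(i, mean(lane[pin]), 0.8)
  }

  # collision nudge: equal lanes with overlapping lifespans
  fin <- forest_final_frame(forest)
  b <- forest$birth_frame
  f <- ifelse(is.na(forest$fate_frame), fin, forest$fate_frame)
  for (i in seq_len(n)) {
    repeat {
      clash <- which(abs(lane - lane[i]) < 1e-9 & seq_len(n) < i &
                       b < f[i] & b[i] < f)
      if (!length(clash)) break
      lane[i] <- lane[i] + 0.37
    }
  }
  lane
}

#' Lay out a lineage forest for cladogram rendering
#'
#' Computes pixel positions on a canvas with time running top to bottom
#' (frame 0 at the top): one vertical segment per cell, horizontal
#' junctions where a mother splits into daughters, converging connectors
#' where cells fuse, day gridlines at the left, cell names and per-event
#' frame labels.
#'
#' @param forest A `lineage_forest`.
#' @param timeline A [timeline()] (defaults to 10-minute frames covering
#'   the forest).
#' @param style A [cladogram_style()].
#' @return A `cladogram_layout` list with tibbles `segments`, `junctions`,
#'   `markers`, `gridlines`, `labels`, plus `lanes` and `canvas`.
#' @export
cladogram_layout <- function(forest, timeline = NULL, style = cladogram_style()) {
  stopifnot(inherits(forest, "lineage_forest"))
  if (is.null(timeline)) {
    timeline <- default_timeline(max(forest_final_frame(forest), 1L))
  }
  lane <- assign_lanes(forest)
  x_of <- function(l) style$margin_left + l * style$lane_width
  y_of <- function(fr) style$margin_top + fr * style$px_per_frame
  fin <- timeline$total_frames
  f_end <- ifelse(is.na(forest$fate_frame), fin, forest$fate_frame)

  segments <- tibble(
    name = forest$name, lane = lane,
    frame0 = forest$birth_frame, frame1 = as.integer(f_end),
    x = x_of(lane), y0 = y_of(forest$birth_frame), y1 = y_of(f_end))

  junction_proto <- tibble(type = character(), cell = character(),
                           frame = integer(), x0 = double(), x1 = double(),
                           xc = double(), y = double())
  marker_proto <- tibble(type = character(), name = character(),
                         x = double(), y = double(),
                         shape = character(), colour = character())
  div_idx <- which(forest$fate == "DIVIDED")
  junctions <- dplyr::bind_rows(
    junction_proto,
    purrr::map_dfr(div_idx, function(i) {
      ki <- match(forest$children[[i]], forest$name)
      tibble(type = "division", cell = forest$name[i],
             frame = forest$fate_frame[i],
             x0 = min(x_of(lane[ki])), x1 = max(x_of(lane[ki])),
             xc = x_of(lane[i]), y = y_of(forest$fate_frame[i]))
    }),
    purrr::map_dfr(which(forest$birth_mode == "FROM_FUSION"), function(i) {
      pin <- match(forest$parents[[i]], forest$name)
      tibble(type = "fusion", cell = forest$name[i],
             frame = forest$birth_frame[i],
             x0 = x_of(lane[pin]), x1 = x_of(lane[i]),
             xc = x_of(lane[i]), y = y_of(forest$birth_frame[i]))
    }))

  markers <- dplyr::bind_rows(
    marker_proto,
    purrr::map_dfr(which(forest$fate == "DEATH"), function(i) {
      tibble(type = "death", name = forest$name[i],
             x = x_of(lane[i]), y = y_of(forest$fate_frame[i]),
             shape = NA_character_, colour = NA_character_)
    }),
    purrr::map_dfr(which(forest$fate == "OUT"), function(i) {
      tibble(type = "out", name = forest$name[i],
             x = x_of(lane[i]), y = y_of(forest$fate_frame[i]),
             shape = NA_character_, colour = NA_character_)
    }),
    purrr::map_dfr(which(!is.na(forest$marker)), function(i) {
      parts <- strsplit(forest$marker[i], ":", fixed = TRUE)[[1]]
      tibble(type = "highlight", name = forest$name[i],
             x = x_of(lane[i]), y = y_of(forest$birth_frame[i]),
             shape = parts[[1]], colour = parts[[2]])
    }))

  day_frames <- seq(0L, fin, by = timeline$frames_per_day)
  gridlines <- tibble(
    frame = day_frames,
    day = pmin(day_frames %/% timeline$frames_per_day + 1L, timeline$n_days),
    y = y_of(day_frames))

  name_labels <- tibble(
    type = "name", text = forest$name,
    x = x_of(lane),
    y = ifelse(forest$birth_mode == "INITIAL",
               style$margin_top - 10, y_of(forest$birth_frame) - 4))
  frame_events <- dplyr::bind_rows(
    tibble(frame = forest$fate_frame[forest$fate %in% c("DIVIDED", "DEATH", "OUT")],
           x = x_of(lane[forest$fate %in% c("DIVIDED", "DEATH", "OUT")])),
    tibble(frame = forest$birth_frame[forest$birth_mode == "FROM_FUSION"],
           x = x_of(lane[forest$birth_mode == "FROM_FUSION"])))
  frame_labels <- tibble(
    type = "frame", text = as.character(frame_events$frame),
    x = frame_events$x + 5, y = y_of(frame_events$frame) + style$font_size + 2)

  width <- max(x_of(max(c(lane, 0))), style$margin_left) + style$margin_right
  height <- y_of(fin) + style$margin_bottom
  structure(list(
    lanes = stats::setNames(lane, forest$name),
    segments = segments, junctions = junctions, markers = markers,
    gridlines = gridlines,
    labels = dplyr::bind_rows(name_labels, frame_labels),
    canvas = list(width = width, height = height),
    timeline = timeline, style = style), class = "cladogram_layout")
}

#' @export
print.cladogram_layout <- function(x, ...) {
  cat(sprintf("<cladogram_layout> %d segment(s), %d junction(s), %d marker(s), canvas %.0fx%.0f px\n",
              nrow(x$segments), nrow(x$junctions), nrow(x$markers),
              x$canvas$width, x$canvas$height))
  invisible(x)
}
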
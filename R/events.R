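#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Canonical event vocabulary. `exit` is accepted as an alias for `out`
# (the field-exit keyword is a dialect choice; see the methods vignette).
EVENT_KINDS <- c("begin", "div", "death", "fusion", "out", "end")
MARKER_SHAPES <- c("circle", "square", "triangle", "star")

parse_error <- function(msg, line = NULL) {
  prefix <- if (!is.null(line)) sprintf("line %d: ", line) else ""
  abort(paste0(prefix, msg),
        class = c("cladotrace_parse_error", "cladotrace_error"),
        line = line)
}

semantic_error <- function(msg, line = NULL) {
  prefix <- if (!is.null(line)) sprintf("line %d: ", line) else ""
  abort(paste0(prefix, msg),
        class = c("cladotrace_semantic_error", "cladotrace_error"),
        line = line)
}

new_cell_events <- function(df, source_lines, final_frame) {
  df <- as_tibble(df)
  structure(df,
            source_lines = source_lines,
            final_frame = final_frame,
            class = c("cell_events", class(df)))
}

#' Parse a cell-event annotation file
#'
#' Reads the plain-text annotation format used to record cell fates in a
#' time-lapse movie: one event per line, `<frame> <keyword> <cell names...>`,
#' where `frame` is a non-negative image index and `keyword` is one of
#' `begin`, `div`, `death`, `fusion`, `out` (alias `exit`) or `end`
#' (case-insensitive). A `begin` line may carry a trailing highlight marker
#' `@<shape>:<colour>` (shapes: circle, square, triangle, star). Blank lines
#' and lines starting with `#` are ignored.
#'
#' Arity rules: `begin`, `death`, `out` and `end` name exactly one cell;
#' `div` names the mother followed by two or more daughters; `fusion` names
#' two or more input cells followed by the fusion product (last name).
#'
#' @param text Character scalar (raw file contents) or character vector of
#'   lines.
#' @return A `cell_events` tibble with columns `line` (input line number),
#'   `frame`, `kind`, `cells` (list of cell names) and `marker`
#'   (`"shape:colour"` or `NA`), stably sorted by frame; attributes
#'   `source_lines` and `final_frame`.
#' @seealso [read_events()], [build_forest()], [write_events()]
#' @examples
#' parse_events("0 begin C1\n112 div C1 C1.1 C1.2")
#' @export
parse_events <- function(text) {
  if (length(text) == 1L && (grepl("\n", text) || !nzchar(text))) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(text)
  }
  n_src <- length(lines)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))

  rows <- lapply(keep, function(i) parse_event_line(lines[[i]], i))
  df <- tibble(
    line   = vapply(rows, `[[`, integer(1), "line"),
    frame  = vapply(rows, `[[`, integer(1), "frame"),
    kind   = vapply(rows, `[[`, character(1), "kind"),
    cells  = purrr::map(rows, "cells"),
    marker = vapply(rows, `[[`, character(1), "marker")
  )
  # stable sort: same-frame events keep input order
  df <- df[order(df$frame), , drop = FALSE]
  final_frame <- if (nrow(df)) max(df$frame) else 0L
  new_cell_events(df, source_lines = n_src, final_frame = final_frame)
}

parse_event_line <- function(line, lineno) {
  tokens <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(tokens) < 3L) {
    parse_error("expected '<frame> <keyword> <cell...>', got too few fields", lineno)
  }
  if (!grepl("^[0-9]+$", tokens[[1]])) {
    parse_error(sprintf("malformed frame index '%s' (must be a non-negative integer)",
                        tokens[[1]]), lineno)
  }
  frame <- suppressWarnings(as.integer(tokens[[1]]))
  if (is.na(frame)) parse_error(sprintf("frame index '%s' out of range", tokens[[1]]), lineno)

  kind <- tolower(tokens[[2]])
  if (kind == "exit") kind <- "out"
  if (!kind %in% EVENT_KINDS) {
    parse_error(sprintf("unknown event keyword '%s'", tokens[[2]]), lineno)
  }

  rest <- tokens[-(1:2)]
  marker <- NA_character_
  is_marker <- grepl("^@", rest)
  if (any(is_marker)) {
    if (sum(is_marker) > 1L || !is_marker[length(rest)]) {
      parse_error("a highlight marker '@shape:colour' may only appear once, at end of line", lineno)
    }
    if (kind != "begin") {
      parse_error("highlight markers are only allowed on 'begin' lines", lineno)
    }
    marker <- parse_marker(rest[length(rest)], lineno)
    rest <- rest[-length(rest)]
  }
  if (!length(rest)) parse_error("no cell names given", lineno)

  n <- length(rest)
  switch(kind,
    begin = , death = , out = , end = {
      if (n != 1L) {
        parse_error(sprintf("'%s' takes exactly one cell name, got %d", kind, n), lineno)
      }
    },
    div = {
      if (n < 3L) {
        parse_error(sprintf(
          "'div' takes a mother followed by at least 2 daughters, got %d name(s)", n), lineno)
      }
    },
    fusion = {
      if (n < 3L) {
        parse_error(sprintf(
          "'fusion' takes at least 2 inputs followed by the product, got %d name(s)", n), lineno)
      }
    }
  )
  list(line = lineno, frame = frame, kind = kind, cells = rest, marker = marker)
}

parse_marker <- function(token, lineno) {
  body <- sub("^@", "", token)
  parts <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[[1]]) || !nzchar(parts[[2]])) {
    parse_error(sprintf("malformed marker '%s' (expected '@shape:colour')", token), lineno)
  }
  shape <- tolower(parts[[1]])
  if (!shape %in% MARKER_SHAPES) {
    parse_error(sprintf("unknown marker shape '%s' (use %s)", parts[[1]],
                        paste(MARKER_SHAPES, collapse = ", ")), lineno)
  }
  paste0(shape, ":", parts[[2]])
}

#' Read a cell-event annotation file from disk
#'
#' @param path Path to a UTF-8 event file.
#' @inherit parse_events return
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: '%s'", path),
          class = c("cladotrace_io_error", "cladotrace_error"))
  }
  parse_events(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Serialise a lineage forest back to the event-file format
#'
#' Produces a canonical event file such that parsing and rebuilding yields a
#' forest identical to the input (round-trip identity). Synthetic `end`
#' events added by `auto_end` are written out explicitly.
#'
#' @param forest A `lineage_forest` (see [build_forest()]).
#' @return A single string of event lines (empty string for an empty forest).
#' @export
format_events <- function(forest) {
  stopifnot(inherits(forest, "lineage_forest"))
  if (!nrow(forest)) return("")
  ord <- seq_len(nrow(forest))
  names(ord) <- forest$name

  open_rows <- purrr::pmap(
    list(forest$name, forest$birth_frame, forest$birth_mode,
         forest$parents, forest$marker, ord),
    function(name, bf, mode, parents, marker, o) {
      if (mode == "INITIAL") {
        mk <- if (!is.na(marker)) paste0(" @", marker) else ""
        list(frame = bf, seq = o, text = sprintf("%d begin %s%s", bf, name, mk))
      } else if (mode == "FROM_FUSION") {
        list(frame = bf, seq = o,
             text = sprintf("%d fusion %s %s", bf, paste(parents, collapse = " "), name))
      } else NULL  # FROM_DIVISION cells are opened by the mother's div line
    }
  )
  div_rows <- purrr::pmap(
    list(forest$name, forest$fate, forest$fate_frame, forest$children),
    function(name, fate, ff, children) {
      if (fate == "DIVIDED") {
        list(frame = ff, seq = min(ord[children]),
             text = sprintf("%d div %s %s", ff, name, paste(children, collapse = " ")))
      } else NULL
    }
  )
  close_rows <- purrr::pmap(
    list(forest$name, forest$fate, forest$fate_frame, ord),
    function(name, fate, ff, o) {
      kw <- switch(fate, DEATH = "death", OUT = "out", END = "end", NULL)
      if (!is.null(kw)) {
        # closure events sort after all openings at the same frame
        list(frame = ff, seq = nrow(forest) + o,
             text = sprintf("%d %s %s", ff, kw, name))
      } else NULL
    }
  )
  rows <- purrr::compact(c(open_rows, div_rows, close_rows))
  frames <- vapply(rows, `[[`, numeric(1), "frame")
  seqs <- vapply(rows, `[[`, numeric(1), "seq")
  texts <- vapply(rows, `[[`, character(1), "text")
  paste(texts[order(frames, seqs)], collapse = "\n")
}

#' @rdname format_events
#' @param path Output file path.
#' @return `write_events()` returns `path` invisibly.
#' @export
write_events <- function(forest, path) {
  writeLines(format_events(forest), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.cell_events <- function(x, ...) {
  cat(sprintf("<cell_events> %d event(s), final frame %d\n",
              nrow(x), attr(x, "final_frame")))
  NextMethod()
}
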
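new_lineage_forest <- function(df, final_frame) {
  df <- as_tibble(df)
  structure(df,
            final_frame = as.integer(final_frame),
            class = c("lineage_forest", class(df)))
}

#' Build a validated lineage forest from an event log
#'
#' Replays the sorted events and turns every named cell into exactly one
#' track: `begin` opens a root, `div` closes the mother (fate `DIVIDED`) and
#' opens her daughters at the same frame, `fusion` closes its inputs (fate
#' `FUSED`) and opens the product, and `death`/`out`/`end` close a cell.
#' A cell may be opened and closed at the same frame only if the opening
#' line precedes the closing line in the file.
#'
#' The result is a forest of trees rooted at the initial cells; fusion
#' events may join trees into a directed acyclic graph.
#'
#' @param events A `cell_events` tibble from [parse_events()] or
#'   [read_events()].
#' @param auto_end If `TRUE` (default), any cell still open after the last
#'   event is closed with a synthetic `end` at the final frame (the usual
#'   convention: survivors are only annotated when something happens to
#'   them). If `FALSE`, an unterminated cell is a validation error.
#' @return A `lineage_forest` tibble with one row per cell: `name`,
#'   `birth_frame`, `birth_mode` (`INITIAL`, `FROM_DIVISION`,
#'   `FROM_FUSION`), `parents` (list), `fate` (`DIVIDED`, `FUSED`, `DEATH`,
#'   `OUT`, `END`), `fate_frame`, `children` (list), `marker`. Rows are in
#'   creation order, so parents always precede their children. Attribute
#'   `final_frame` carries the log's last frame.
#' @examples
#' ev <- parse_events(c("0 begin C1", "112 div C1 C1.1 C1.2"))
#' build_forest(ev)
#' @export
build_forest <- function(events, auto_end = TRUE) {
  stopifnot(inherits(events, "cell_events"))
  final_frame <- attr(events, "final_frame")

  n_guess <- max(8L, sum(lengths(events$cells)))
  name <- character(n_guess); birth_frame <- integer(n_guess)
  birth_mode <- character(n_guess); fate <- character(n_guess)
  fate_frame <- integer(n_guess); marker <- character(n_guess)
  parents <- vector("list", n_guess); children <- vector("list", n_guess)
  idx <- new.env(parent = emptyenv())
  n <- 0L

  grow <- function(k) {
    length(name) <<- k; length(birth_frame) <<- k; length(birth_mode) <<- k
    length(fate) <<- k; length(fate_frame) <<- k; length(marker) <<- k
    length(parents) <<- k; length(children) <<- k
  }
  open_cell <- function(nm, frame, mode, par, mk, lineno) {
    if (!is.null(idx[[nm]])) {
      semantic_error(sprintf(
        "cell name '%s' reused; names must be unique for each video", nm), lineno)
    }
    n <<- n + 1L
    if (n > length(name)) grow(2L * length(name))
    idx[[nm]] <- n
    name[n] <<- nm; birth_frame[n] <<- frame; birth_mode[n] <<- mode
    fate[n] <<- "OPEN"; fate_frame[n] <<- NA_integer_
    parents[[n]] <<- par; children[[n]] <<- character(0)
    marker[n] <<- mk %||% NA_character_
  }
  require_open <- function(nm, frame, lineno) {
    i <- idx[[nm]]
    if (is.null(i)) {
      semantic_error(sprintf(
        "event refers to cell '%s' which was never created (no earlier 'begin', 'div' or 'fusion')",
        nm), lineno)
    }
    if (fate[i] != "OPEN") {
      semantic_error(sprintf(
        "event at frame %d on cell '%s', but it was already closed (%s at frame %d)",
        frame, nm, tolower(fate[i]), fate_frame[i]), lineno)
    }
    if (frame < birth_frame[i]) {
      semantic_error(sprintf(
        "event at frame %d precedes cell '%s' birth at frame %d",
        frame, nm, birth_frame[i]), lineno)
    }
    i
  }
  close_cell <- function(i, frame, what, kids = character(0)) {
    fate[i] <<- what; fate_frame[i] <<- frame; children[[i]] <<- kids
  }

  for (r in seq_len(nrow(events))) {
    frame <- events$frame[[r]]; kind <- events$kind[[r]]
    cells <- events$cells[[r]]; lineno <- events$line[[r]]
    switch(kind,
      begin = open_cell(cells[[1]], frame, "INITIAL", character(0),
                        events$marker[[r]], lineno),
      div = {
        i <- require_open(cells[[1]], frame, lineno)
        daughters <- cells[-1]
        close_cell(i, frame, "DIVIDED", daughters)
        for (d in daughters) {
          open_cell(d, frame, "FROM_DIVISION", cells[[1]], NA_character_, lineno)
        }
      },
      fusion = {
        inputs <- cells[-length(cells)]
        product <- cells[[length(cells)]]
        ii <- vapply(inputs, require_open, integer(1), frame = frame, lineno = lineno)
        for (i in ii) close_cell(i, frame, "FUSED", product)
        open_cell(product, frame, "FROM_FUSION", inputs, NA_character_, lineno)
      },
      death = close_cell(require_open(cells[[1]], frame, lineno), frame, "DEATH"),
      out   = close_cell(require_open(cells[[1]], frame, lineno), frame, "OUT"),
      end   = close_cell(require_open(cells[[1]], frame, lineno), frame, "END")
    )
  }

  keep <- seq_len(n)
  still_open <- keep[fate[keep] == "OPEN"]
  if (length(still_open)) {
    if (auto_end) {
      for (i in still_open) close_cell(i, final_frame, "END")
    } else {
      semantic_error(sprintf(
        "cell(s) still open at end of log with auto_end disabled: %s",
        paste(name[still_open], collapse = ", ")))
    }
  }

  new_lineage_forest(
    tibble(name = name[keep], birth_frame = birth_frame[keep],
           birth_mode = birth_mode[keep], parents = parents[keep],
           fate = fate[keep], fate_frame = fate_frame[keep],
           children = children[keep], marker = marker[keep]),
    final_frame = final_frame)
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest> %d cell(s), %d root(s), final frame %d\n",
              nrow(x), sum(x$birth_mode == "INITIAL"), attr(x, "final_frame")))
  NextMethod()
}

forest_final_frame <- function(forest) attr(forest, "final_frame")

#' Root cells of a lineage forest
#'
#' @param forest A `lineage_forest`.
#' @return Character vector of root (maternal) cell names, in file order.
#' @export
forest_roots <- function(forest) forest$name[forest$birth_mode == "INITIAL"]

# index of each cell's parents; rows are in creation order so parents
# always precede children
parent_indices <- function(forest) {
  ord <- seq_len(nrow(forest))
  names(ord) <- forest$name
  purrr::map(forest$parents, ~ unname(ord[.x]))
}

#' Does a cell have a division anywhere in its ancestry?
#'
#' Used to classify deaths as mitotic (preceded by a division in the dying
#' cell's observed lineage) or non-mitotic. A cell qualifies if it was
#' itself born from a division, or if any ancestor reached through parent
#' links was; a fusion product inherits the OR over its fusion inputs.
#'
#' @param forest A `lineage_forest`.
#' @param cell A single cell name, or `NULL` (default) for all cells.
#' @param scope `"ancestry"` (default) walks the full parent chain;
#'   `"immediate"` only asks whether the cell itself was born from a
#'   division (a stricter reading of "death following mitosis").
#' @return Named logical vector (all cells) or a single logical.
#' @export
has_division_ancestry <- function(forest, cell = NULL,
                                  scope = c("ancestry", "immediate")) {
  scope <- match.arg(scope)
  direct <- forest$birth_mode == "FROM_DIVISION"
  if (scope == "immediate") {
    anc <- direct
  } else {
    pidx <- parent_indices(forest)
    anc <- logical(nrow(forest))
    for (i in seq_len(nrow(forest))) {
      anc[i] <- direct[i] || any(anc[pidx[[i]]])
    }
  }
  names(anc) <- forest$name
  if (is.null(cell)) return(anc)
  if (!cell %in% forest$name) {
    abort(sprintf("unknown cell '%s'", cell), class = "cladotrace_error")
  }
  unname(anc[cell])
}

# For every cell, the set of roots whose lineage contains it. With
# sibling-only fusions each cell has exactly one root; a fusion across
# lineages gives the product the union of its inputs' roots.
cell_roots <- function(forest) {
  pidx <- parent_indices(forest)
  roots <- vector("list", nrow(forest))
  for (i in seq_len(nrow(forest))) {
    if (forest$birth_mode[i] == "INITIAL") {
      roots[[i]] <- forest$name[i]
    } else {
      roots[[i]] <- unique(unlist(roots[pidx[[i]]]))
    }
  }
  names(roots) <- forest$name
  roots
}

forests_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (!identical(forest_final_frame(a), forest_final_frame(b))) return(FALSE)
  oa <- order(a$name); ob <- order(b$name)
  cols_ok <- all(
    identical(a$name[oa], b$name[ob]),
    identical(a$birth_frame[oa], b$birth_frame[ob]),
    identical(a$birth_mode[oa], b$birth_mode[ob]),
    identical(a$fate[oa], b$fate[ob]),
    identical(a$fate_frame[oa], b$fate_frame[ob]),
    identical(a$marker[oa], b$marker[ob])
  )
  if (!cols_ok) return(FALSE)
  all(purrr::map2_lgl(a$parents[oa], b$parents[ob], ~ identical(sort(.x), sort(.y)))) &&
    all(purrr::map2_lgl(a$children[oa], b$children[ob], ~ identical(sort(.x), sort(.y))))
}
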
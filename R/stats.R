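# population SD (n denominator): comparisons between conditions use the
# spread of the observed cells, not an inference to a larger population
pop_sd <- function(x) {
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Basic cell tallies
#'
#' `count_initial()` counts the cells followed from the start of the movie
#' (`begin` events, i.e. roots); `count_final()` counts the cells that were
#' still present when observation stopped (`end` fate, mother or daughter
#' alike); `count_fusions()` counts fusion events, each event once whatever
#' its input arity; `count_out()` counts cells that left the field of view.
#'
#' @param forest A `lineage_forest`.
#' @return A single integer.
#' @export
count_initial <- function(forest) sum(forest$birth_mode == "INITIAL")

#' @rdname count_initial
#' @export
count_final <- function(forest) sum(forest$fate == "END")

#' @rdname count_initial
#' @export
count_fusions <- function(forest) sum(forest$birth_mode == "FROM_FUSION")

#' @rdname count_initial
#' @export
count_out <- function(forest) sum(forest$fate == "OUT")

#' Mitosis counts by quality
#'
#' Tallies all divisions and splits them into dichotomic (exactly two
#' daughters, a normal mitosis) and non-dichotomic (more than two).
#'
#' @param forest A `lineage_forest`.
#' @return One-row tibble with columns `total`, `dichotomic`,
#'   `non_dichotomic` (`total == dichotomic + non_dichotomic`).
#' @export
count_mitoses <- function(forest) {
  div <- forest$fate == "DIVIDED"
  nond <- div & lengths(forest$children) > 2L
  tibble(total = sum(div),
         dichotomic = sum(div) - sum(nond),
         non_dichotomic = sum(nond))
}

#' Abnormal mitosis count
#'
#' A division is abnormal when it is non-dichotomic, or when it is later
#' followed by a fusion that re-merges at least two of its direct
#' daughters. A division that is both (e.g. a split into four whose
#' daughters then coalesce) is counted exactly once. Fusions between
#' unrelated cells contribute to the fusion count but make no division
#' abnormal.
#'
#' @param forest A `lineage_forest`.
#' @return A single integer, at most `count_mitoses(forest)$total`.
#' @export
count_abnormal_mitoses <- function(forest) {
  div_idx <- which(forest$fate == "DIVIDED")
  if (!length(div_idx)) return(0L)
  fusion_inputs <- forest$parents[forest$birth_mode == "FROM_FUSION"]
  abnormal <- vapply(div_idx, function(i) {
    kids <- forest$children[[i]]
    length(kids) > 2L ||
      any(vapply(fusion_inputs, function(ins) sum(ins %in% kids) >= 2L, logical(1)))
  }, logical(1))
  sum(abnormal)
}

#' Death counts by mitotic history
#'
#' Total deaths, split by whether the dying cell had a division anywhere in
#' its observed lineage ([has_division_ancestry()]): mitotic death versus
#' non-mitotic death.
#'
#' @param forest A `lineage_forest`.
#' @param scope Passed to [has_division_ancestry()].
#' @return One-row tibble with columns `total`, `mitotic`, `non_mitotic`.
#' @export
count_deaths <- function(forest, scope = c("ancestry", "immediate")) {
  dead <- forest$fate == "DEATH"
  anc <- has_division_ancestry(forest, scope = match.arg(scope))
  tibble(total = sum(dead),
         mitotic = sum(dead & anc),
         non_mitotic = sum(dead & !anc))
}

#' Inter-mitosis intervals
#'
#' Time between two successive divisions in a cell line: for every division
#' whose mother was herself born from a division, the interval is the
#' mother's lifespan in frames (her division frame minus her birth frame).
#' Chains bridged by a fusion (daughter fuses, the product divides) are not
#' counted as successive mitoses.
#'
#' @param forest A `lineage_forest`.
#' @return List with `intervals` (integer frames, possibly empty), `mean`
#'   and `sd` (population SD), both `NA` when no interval exists.
#' @export
inter_mitosis_intervals <- function(forest) {
  sel <- forest$fate == "DIVIDED" & forest$birth_mode == "FROM_DIVISION"
  iv <- forest$fate_frame[sel] - forest$birth_frame[sel]
  list(intervals = as.integer(iv),
       mean = if (length(iv)) mean(iv) else NA_real_,
       sd = pop_sd(iv))
}

#' Time from the start of observation to the first division
#'
#' For each root whose lineage contains at least one division, the frame of
#' the earliest division in that lineage minus the root's begin frame.
#' Roots that never divide have no "first division" and are excluded; their
#' number is reported alongside.
#'
#' @param forest A `lineage_forest`.
#' @return List with `times` (named integer frames per qualifying root),
#'   `mean`, `sd` (population), and `n_excluded` (roots with no division).
#' @export
time_to_first_division <- function(forest) {
  roots <- forest_roots(forest)
  croots <- cell_roots(forest)
  div_idx <- which(forest$fate == "DIVIDED")
  times <- purrr::map_int(roots, function(r) {
    in_lineage <- div_idx[purrr::map_lgl(croots[div_idx], ~ r %in% .x)]
    if (!length(in_lineage)) return(NA_integer_)
    min(forest$fate_frame[in_lineage]) -
      forest$birth_frame[forest$name == r]
  })
  names(times) <- roots
  ok <- !is.na(times)
  list(times = times[ok],
       mean = if (any(ok)) mean(times[ok]) else NA_real_,
       sd = pop_sd(times[ok]),
       n_excluded = sum(!ok))
}

#' Division probability
#'
#' The ratio of cells reaching the end of the movie to cells present at its
#' start (`final / initial`), 0 when the forest has no roots. The
#' alternative denominator `"initial_minus_out"` subtracts the number of
#' field exits from the initial count, one reading of "excluding cells that
#' went out of the field"; it returns `NA` when that denominator is not
#' positive.
#'
#' @param forest A `lineage_forest`.
#' @param denominator `"initial"` (default) or `"initial_minus_out"`.
#' @return A fraction (may exceed 1 in proliferating populations).
#' @export
division_probability <- function(forest,
                                 denominator = c("initial", "initial_minus_out")) {
  denominator <- match.arg(denominator)
  ini <- count_initial(forest)
  if (ini == 0L) return(0)
  den <- switch(denominator,
                initial = ini,
                initial_minus_out = ini - count_out(forest))
  if (den <= 0L) return(NA_real_)
  count_final(forest) / den
}

# cells present at the start of frame f: born at or before f and closed
# strictly after it
alive_at_frame <- function(forest, f) {
  sum(forest$birth_frame <= f &
        (is.na(forest$fate_frame) | forest$fate_frame > f))
}

#' Per-day event counts and ratios
#'
#' Bins divisions, deaths, fusions and field exits into experiment days
#' ([day_of_frame()]) and reports, for each day, the raw counts plus ratios
#' against the number of cells alive at the day's first frame.
#'
#' @param forest A `lineage_forest`.
#' @param timeline A [timeline()]; its `total_frames` must cover the
#'   forest's final frame.
#' @return Tibble with columns `day`, `divisions`, `deaths`, `fusions`,
#'   `outs`, `alive_at_start`, `div_ratio`, `death_ratio`, `fusion_ratio`,
#'   `out_ratio`. Column sums of the counts equal the forest totals.
#' @export
per_day_table <- function(forest, timeline) {
  stopifnot(inherits(timeline, "timeline"))
  if (forest_final_frame(forest) > timeline$total_frames) {
    abort(sprintf(
      "forest final frame %d exceeds timeline total_frames %d",
      forest_final_frame(forest), timeline$total_frames),
      class = "cladotrace_error")
  }
  days <- seq_len(timeline$n_days)
  bin <- function(frames) {
    if (!length(frames)) return(integer(length(days)))
    tabulate(day_of_frame(timeline, frames), nbins = length(days))
  }
  out <- tibble(
    day = days,
    divisions = bin(forest$fate_frame[forest$fate == "DIVIDED"]),
    deaths = bin(forest$fate_frame[forest$fate == "DEATH"]),
    fusions = bin(forest$birth_frame[forest$birth_mode == "FROM_FUSION"]),
    outs = bin(forest$fate_frame[forest$fate == "OUT"]),
    alive_at_start = vapply(
      (days - 1L) * timeline$frames_per_day,
      function(f) alive_at_frame(forest, f), numeric(1))
  )
  ratio <- function(x) ifelse(out$alive_at_start > 0, x / out$alive_at_start, NA_real_)
  out %>%
    mutate(div_ratio = ratio(.data$divisions),
           death_ratio = ratio(.data$deaths),
           fusion_ratio = ratio(.data$fusions),
           out_ratio = ratio(.data$outs))
}

#' Division count per maternal cell
#'
#' For every root, the number of division events among the root itself and
#' all its descendants — the per-cell event counter used to spot cells that
#' stand out from the population (the rows `0 1 2 ... 7` of a per-condition
#' division histogram are built from this table).
#'
#' @param forest A `lineage_forest`.
#' @return Tibble with columns `root`, `divisions`, `marker` (the root's
#'   highlight marker or `NA`), one row per root in file order.
#' @export
per_cell_division_counts <- function(forest) {
  roots <- forest_roots(forest)
  croots <- cell_roots(forest)
  div_idx <- which(forest$fate == "DIVIDED")
  counts <- purrr::map_int(roots, function(r) {
    sum(purrr::map_lgl(croots[div_idx], ~ r %in% .x))
  })
  tibble(root = roots,
         divisions = counts,
         marker = forest$marker[match(roots, forest$name)])
}

#' Full statistics report for a lineage forest
#'
#' Aggregates every counting and interval statistic into one object:
#' initial/final cell numbers, mitosis counts by quality, fusion and
#' abnormal-mitosis counts, deaths by mitotic history, field exits,
#' inter-mitosis intervals, time to first division, division probability,
#' the per-day table and the per-cell division counter.
#'
#' @param forest A `lineage_forest`.
#' @param timeline A [timeline()]; defaults to 10-minute frames with
#'   `total_frames` taken from the forest.
#' @param scope Mitotic-death classification, see [count_deaths()].
#' @return A `lineage_stats` object. Use [tidy()] for the long
#'   parameter/value summary table, [glance()] for a one-row overview, and
#'   [write_stats_csv()] to export `summary.csv`, `per_day.csv` and
#'   `per_cell.csv`.
#' @examples
#' ev <- parse_events(c("0 begin C1", "112 div C1 C1.1 C1.2"))
#' compute_report(build_forest(ev))
#' @export
compute_report <- function(forest, timeline = NULL,
                           scope = c("ancestry", "immediate")) {
  scope <- match.arg(scope)
  if (is.null(timeline)) {
    timeline <- default_timeline(max(forest_final_frame(forest), 1L))
  }
  mit <- count_mitoses(forest)
  dth <- count_deaths(forest, scope = scope)
  structure(list(
    initial_cell_count = count_initial(forest),
    final_cell_count = count_final(forest),
    mitosis_count = mit$total,
    dichotomic_mitosis_count = mit$dichotomic,
    non_dichotomic_mitosis_count = mit$non_dichotomic,
    fusion_count = count_fusions(forest),
    abnormal_mitosis_count = count_abnormal_mitoses(forest),
    death_count = dth$total,
    mitotic_death_count = dth$mitotic,
    non_mitotic_death_count = dth$non_mitotic,
    out_count = count_out(forest),
    inter_mitosis = inter_mitosis_intervals(forest),
    time_to_first_division = time_to_first_division(forest),
    division_probability = division_probability(forest),
    per_day = per_day_table(forest, timeline),
    per_cell = per_cell_division_counts(forest),
    timeline = timeline
  ), class = "lineage_stats")
}

stats_summary_tbl <- function(x) {
  tl <- x$timeline
  tibble(
    parameter = c(
      "initial_cell_count", "final_cell_count",
      "mitosis_count", "dichotomic_mitosis_count", "non_dichotomic_mitosis_count",
      "fusion_count", "abnormal_mitosis_count",
      "death_count", "mitotic_death_count", "non_mitotic_death_count",
      "out_count",
      "inter_mitosis_mean_frames", "inter_mitosis_sd_frames",
      "inter_mitosis_mean_hours",
      "time_to_first_division_mean_frames", "time_to_first_division_sd_frames",
      "time_to_first_division_mean_hours",
      "roots_without_division",
      "division_probability"),
    value = c(
      x$initial_cell_count, x$final_cell_count,
      x$mitosis_count, x$dichotomic_mitosis_count, x$non_dichotomic_mitosis_count,
      x$fusion_count, x$abnormal_mitosis_count,
      x$death_count, x$mitotic_death_count, x$non_mitotic_death_count,
      x$out_count,
      x$inter_mitosis$mean, x$inter_mitosis$sd,
      if (is.na(x$inter_mitosis$mean)) NA_real_
      else frames_to_hours(tl, x$inter_mitosis$mean),
      x$time_to_first_division$mean, x$time_to_first_division$sd,
      if (is.na(x$time_to_first_division$mean)) NA_real_
      else frames_to_hours(tl, x$time_to_first_division$mean),
      x$time_to_first_division$n_excluded,
      x$division_probability)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a lineage statistics report
#'
#' @param x A `lineage_stats` object from [compute_report()].
#' @param ... Unused.
#' @return `tidy()`: a long tibble `parameter`/`value` (the same table
#'   written to `summary.csv`). `glance()`: a one-row tibble of the scalar
#'   counts and means.
#' @method tidy lineage_stats
#' @export
tidy.lineage_stats <- function(x, ...) stats_summary_tbl(x)

#' @rdname tidy.lineage_stats
#' @method glance lineage_stats
#' @export
glance.lineage_stats <- function(x, ...) {
  s <- stats_summary_tbl(x)
  tidyr::pivot_wider(s, names_from = "parameter", values_from = "value")
}

#' @export
print.lineage_stats <- function(x, ...) {
  cat("<lineage_stats>\n")
  s <- stats_summary_tbl(x)
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-36s %s\n", s$parameter[i], format(s$value[i], digits = 6)))
  }
  cat(sprintf("  per-day table: %d day(s); per-cell table: %d root(s)\n",
              nrow(x$per_day), nrow(x$per_cell)))
  invisible(x)
}

#' Write a statistics report as CSV files
#'
#' Writes three files into `dir`: `summary.csv` (`parameter,value`),
#' `per_day.csv` and `per_cell.csv`. Comma-separated, UTF-8, `.` decimal
#' separator, header row, missing values spelled `NA` — readable by any
#' spreadsheet program.
#'
#' @param report A `lineage_stats` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_stats_csv <- function(report, dir) {
  stopifnot(inherits(report, "lineage_stats"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(summary = file.path(dir, "summary.csv"),
             per_day = file.path(dir, "per_day.csv"),
             per_cell = file.path(dir, "per_cell.csv"))
  readr::write_csv(stats_summary_tbl(report), paths[["summary"]], na = "NA")
  readr::write_csv(report$per_day, paths[["per_day"]], na = "NA")
  readr::write_csv(report$per_cell, paths[["per_cell"]], na = "NA")
  invisible(paths)
}
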
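#' Configuration for the lineage simulator
#'
#' Per-frame rates of a seeded stochastic branching process whose output
#' stands in for a manually annotated movie. Defaults emulate the scale of
#' a typical monotherapy video-microscopy run: 50 tracked cells, 432 frames
#' (10-minute intervals over 3 days), roughly one division per cell per day
#' (`(1 + 0.0048)^144 ~ 2`), occasional multi-daughter divisions, sibling
#' fusions, deaths and field exits.
#'
#' @param n_initial Number of cells present at frame 0.
#' @param n_frames Number of frames simulated (events occur at frames
#'   `1..n_frames`; survivors end at `n_frames`).
#' @param p_div Per-cell per-frame division probability.
#' @param p_multi Probability that a division is non-dichotomic (3–6
#'   daughters, uniform).
#' @param p_death Per-cell per-frame death probability.
#' @param p_out Per-cell per-frame field-exit probability.
#' @param p_sibling_fusion Per-frame probability that a surviving pair of
#'   sibling daughters fuses.
#' @param frames_per_day Frames per experiment day (for ground-truth
#'   per-day tables).
#' @param frame_interval_min Minutes per frame.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_initial = 50L, n_frames = 432L,
                       p_div = 0.0048, p_multi = 0.05,
                       p_death = 0.001, p_out = 0.0005,
                       p_sibling_fusion = 0.002,
                       frames_per_day = 144L,
                       frame_interval_min = 10,
                       seed = 1L) {
  probs <- c(p_div = p_div, p_multi = p_multi, p_death = p_death,
             p_out = p_out, p_sibling_fusion = p_sibling_fusion)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all rates must be probabilities in [0, 1]", class = "cladotrace_error")
  }
  if (p_div + p_death + p_out > 1) {
    abort("p_div + p_death + p_out must not exceed 1 per frame",
          class = "cladotrace_error")
  }
  if (n_initial < 0L || n_frames < 1L) {
    abort("need n_initial >= 0 and n_frames >= 1", class = "cladotrace_error")
  }
  structure(list(n_initial = as.integer(n_initial),
                 n_frames = as.integer(n_frames),
                 p_div = p_div, p_multi = p_multi, p_death = p_death,
                 p_out = p_out, p_sibling_fusion = p_sibling_fusion,
                 frames_per_day = as.integer(frames_per_day),
                 frame_interval_min = frame_interval_min,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an annotated movie with known ground truth
#'
#' Runs the branching process frame by frame. Each alive cell
#' independently draws death, field exit and division; when several fates
#' are drawn in the same frame the precedence is death > exit > division
#' (one fate per cell per frame). Daughters of one division form a sibling
#' group; from the following frame on, each surviving pair in a group may
#' fuse. Fusion products do not rejoin the sibling group. Survivors receive
#' an `end` event at the last frame.
#'
#' Every emitted event also increments an independent ground-truth tally,
#' so the returned `truth` can serve as an exact oracle for the statistics
#' computed from the event log.
#'
#' @param config A [sim_config()].
#' @return A `lineage_sim` list with `events` (a `cell_events` tibble, as
#'   from [parse_events()]), `truth` (a `lineage_truth` list mirroring the
#'   fields of [compute_report()]) and `config`.
#' @examples
#' sim <- simulate_lineage(sim_config(n_initial = 5, n_frames = 144, seed = 7))
#' compute_report(build_forest(sim$events))
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n0 <- config$n_initial; TT <- config$n_frames
  fpd <- config$frames_per_day
  nd <- max(1L, as.integer(ceiling(TT / fpd)))
  day_of <- function(t) min(t %/% fpd + 1L, nd)

  cap <- max(16L, 4L * n0)
  nm <- character(cap); bf <- integer(cap); mode <- character(cap)
  anc <- logical(cap); root <- character(cap); grp <- rep(NA_integer_, cap)
  counter <- integer(cap); alive <- logical(cap)
  n <- 0L
  grow <- function() {
    k <- 2L * length(nm)
    length(nm) <<- k; length(bf) <<- k; length(mode) <<- k
    length(anc) <<- k; length(root) <<- k
    grp <<- c(grp, rep(NA_integer_, k - length(grp)))
    length(counter) <<- k; length(alive) <<- k
  }
  new_cell <- function(name, frame, m, a, r, g) {
    n <<- n + 1L
    if (n > length(nm)) grow()
    nm[n] <<- name; bf[n] <<- frame; mode[n] <<- m
    anc[n] <<- a; root[n] <<- r; grp[n] <<- g
    counter[n] <<- 0L; alive[n] <<- TRUE
    n
  }

  ev_frame <- integer(0); ev_kind <- character(0); ev_cells <- list()
  push_event <- function(frame, kind, cells) {
    ev_frame[[length(ev_frame) + 1L]] <<- frame
    ev_kind[[length(ev_kind) + 1L]] <<- kind
    ev_cells[[length(ev_cells) + 1L]] <<- cells
  }

  groups <- list()  # each: list(members = int idx, abnormal = lgl)

  tr <- list(mitosis = 0L, dich = 0L, nondich = 0L, fusion = 0L,
             abnormal = 0L, death = 0L, mitotic_death = 0L,
             nonmitotic_death = 0L, out = 0L)
  intervals <- integer(0)
  first_div <- stats::setNames(rep(NA_integer_, n0), paste0("C", seq_len(n0)))
  per_root_div <- stats::setNames(integer(n0), paste0("C", seq_len(n0)))
  day_div <- integer(nd); day_death <- integer(nd)
  day_fus <- integer(nd); day_out <- integer(nd)
  alive_at_start <- rep(NA_real_, nd)
  alive_at_start[1] <- n0

  for (i in seq_len(n0)) {
    new_cell(paste0("C", i), 0L, "INITIAL", FALSE, paste0("C", i), NA_integer_)
    push_event(0L, "begin", paste0("C", i))
  }

  drop_from_group <- function(i) {
    g <- grp[i]
    if (!is.na(g)) {
      groups[[g]]$members <<- setdiff(groups[[g]]$members, i)
      grp[i] <<- NA_integer_
    }
  }

  for (t in seq_len(TT)) {
    ai <- which(alive[seq_len(n)])
    if (length(ai)) {
      dies <- stats::runif(length(ai)) < config$p_death
      exits <- !dies & stats::runif(length(ai)) < config$p_out
      divs <- !dies & !exits & stats::runif(length(ai)) < config$p_div
      d <- day_of(t)

      for (i in ai[dies]) {
        alive[i] <- FALSE; drop_from_group(i)
        push_event(t, "death", nm[i])
        tr$death <- tr$death + 1L
        if (anc[i]) tr$mitotic_death <- tr$mitotic_death + 1L
        else tr$nonmitotic_death <- tr$nonmitotic_death + 1L
        day_death[d] <- day_death[d] + 1L
      }
      for (i in ai[exits]) {
        alive[i] <- FALSE; drop_from_group(i)
        push_event(t, "out", nm[i])
        tr$out <- tr$out + 1L
        day_out[d] <- day_out[d] + 1L
      }
      g0 <- length(groups)  # fusions only in groups that predate this frame
      for (i in ai[divs]) {
        k <- 2L
        if (config$p_multi > 0 && stats::runif(1) < config$p_multi) {
          k <- sample(3:6, 1L)
        }
        daughters <- paste0(nm[i], ".", counter[i] + seq_len(k))
        counter[i] <- counter[i] + k
        alive[i] <- FALSE; drop_from_group(i)
        gid <- length(groups) + 1L
        groups[[gid]] <- list(mother = i, members = integer(0),
                              abnormal = k > 2L)
        for (dn in daughters) {
          j <- new_cell(dn, t, "FROM_DIVISION", TRUE, root[i], gid)
          groups[[gid]]$members <- c(groups[[gid]]$members, j)
        }
        push_event(t, "div", c(nm[i], daughters))
        tr$mitosis <- tr$mitosis + 1L
        if (k > 2L) { tr$nondich <- tr$nondich + 1L; tr$abnormal <- tr$abnormal + 1L }
        else tr$dich <- tr$dich + 1L
        if (mode[i] == "FROM_DIVISION") {
          intervals <- c(intervals, t - bf[i])
        }
        if (is.na(first_div[[root[i]]])) first_div[[root[i]]] <- t
        per_root_div[[root[i]]] <- per_root_div[[root[i]]] + 1L
        day_div[d] <- day_div[d] + 1L
      }
      if (config$p_sibling_fusion > 0 && g0 > 0L) {
        for (g in seq_len(g0)) {
          mem <- groups[[g]]$members
          mem <- mem[alive[mem]]
          if (length(mem) < 2L) next
          m <- length(mem)
          fused <- logical(m)
          for (a in seq_len(m - 1L)) {
            for (b in seq((a + 1L), m)) {
              if (fused[a] || fused[b]) next
              if (stats::runif(1) < config$p_sibling_fusion) {
                ia <- mem[a]; ib <- mem[b]
                fused[a] <- TRUE; fused[b] <- TRUE
                alive[ia] <- FALSE; alive[ib] <- FALSE
                drop_from_group(ia); drop_from_group(ib)
                mi <- groups[[g]]$mother
                counter[mi] <- counter[mi] + 1L
                pname <- paste0(nm[mi], ".", counter[mi])
                new_cell(pname, t, "FROM_FUSION", anc[ia] || anc[ib],
                         root[ia], NA_integer_)
                push_event(t, "fusion", c(nm[ia], nm[ib], pname))
                tr$fusion <- tr$fusion + 1L
                day_fus[d] <- day_fus[d] + 1L
                if (!groups[[g]]$abnormal) {
                  groups[[g]]$abnormal <- TRUE
                  tr$abnormal <- tr$abnormal + 1L
                }
              }
            }
          }
        }
      }
    }
    if (t %% fpd == 0L && t < TT) {
      d_next <- t %/% fpd + 1L
      if (d_next <= nd) alive_at_start[d_next] <- sum(alive[seq_len(n)])
    }
  }

  survivors <- which(alive[seq_len(n)])
  for (i in survivors) push_event(TT, "end", nm[i])
  final <- length(survivors)
  alive_at_start[is.na(alive_at_start)] <- 0

  events <- new_cell_events(
    tibble(line = seq_along(ev_frame),
           frame = ev_frame, kind = ev_kind, cells = ev_cells,
           marker = NA_character_),
    source_lines = length(ev_frame),
    final_frame = if (length(ev_frame)) max(ev_frame) else 0L)

  ratio <- function(x) ifelse(alive_at_start > 0, x / alive_at_start, NA_real_)
  ttfd <- first_div[!is.na(first_div)]
  truth <- structure(list(
    initial_cell_count = n0,
    final_cell_count = final,
    mitosis_count = tr$mitosis,
    dichotomic_mitosis_count = tr$dich,
    non_dichotomic_mitosis_count = tr$nondich,
    fusion_count = tr$fusion,
    abnormal_mitosis_count = tr$abnormal,
    death_count = tr$death,
    mitotic_death_count = tr$mitotic_death,
    non_mitotic_death_count = tr$nonmitotic_death,
    out_count = tr$out,
    inter_mitosis = list(intervals = intervals,
                         mean = if (length(intervals)) mean(intervals) else NA_real_,
                         sd = pop_sd(intervals)),
    time_to_first_division = list(
      times = ttfd,
      mean = if (length(ttfd)) mean(as.integer(ttfd)) else NA_real_,
      sd = pop_sd(as.integer(ttfd)),
      n_excluded = sum(is.na(first_div))),
    division_probability = if (n0 > 0L) final / n0 else 0,
    per_day = tibble(day = seq_len(nd),
                     divisions = day_div, deaths = day_death,
                     fusions = day_fus, outs = day_out,
                     alive_at_start = alive_at_start,
                     div_ratio = ratio(day_div),
                     death_ratio = ratio(day_death),
                     fusion_ratio = ratio(day_fus),
                     out_ratio = ratio(day_out)),
    per_cell = tibble(root = names(per_root_div),
                      divisions = unname(per_root_div),
                      marker = NA_character_)
  ), class = "lineage_truth")

  structure(list(events = events, truth = truth, config = config),
            class = "lineage_sim")
}

#' @export
print.lineage_sim <- function(x, ...) {
  cat(sprintf(
    "<lineage_sim> seed %d: %d initial cell(s), %d frame(s), %d event(s)\n",
    x$config$seed, x$config$n_initial, x$config$n_frames, nrow(x$events)))
  invisible(x)
}

#' Expected division count of the pure-birth process
#'
#' Closed form for the dichotomic pure-birth limit (no death, no exit, no
#' fusion, no multi-daughter divisions): the expected population grows by a
#' factor `1 + p_div` per frame, so the expected total number of divisions
#' over `n_frames` frames is `n_initial * ((1 + p_div)^n_frames - 1)`. Used
#' to bound Monte-Carlo means of [simulate_lineage()].
#'
#' @param config A [sim_config()] with `p_death`, `p_out`,
#'   `p_sibling_fusion` and `p_multi` all zero.
#' @return Expected number of divisions (a non-negative number).
#' @export
expected_divisions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$p_death != 0 || config$p_out != 0 ||
      config$p_sibling_fusion != 0 || config$p_multi != 0) {
    abort("closed form only valid for the dichotomic pure-birth limit (zero death/out/fusion/multi rates)",
          class = "cladotrace_error")
  }
  config$n_initial * ((1 + config$p_div)^config$n_frames - 1)
}
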
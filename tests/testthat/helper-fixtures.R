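# shared fixtures: the two bundled worked examples plus randomised
# simulator configurations used by property-style tests

demo_path <- function(which = c("three", "six")) {
  which <- match.arg(which)
  system.file("extdata",
              sprintf("demo_%s_cells.txt", which),
              package = "cladotrace", mustWork = TRUE)
}

three_cell_forest <- function() build_forest(read_events(demo_path("three")))
six_cell_forest <- function() build_forest(read_events(demo_path("six")))

# a small randomised configuration; rates drawn from the seed so a batch of
# configs covers quiet, proliferative and death-heavy regimes
random_sim_config <- function(seed) {
  set.seed(seed + 900000L)
  sim_config(
    n_initial = sample(2:8, 1),
    n_frames = sample(c(96L, 144L, 216L), 1),
    p_div = runif(1, 0, 0.012),
    p_multi = runif(1, 0, 0.4),
    p_death = runif(1, 0, 0.004),
    p_out = runif(1, 0, 0.002),
    p_sibling_fusion = runif(1, 0, 0.02),
    frames_per_day = sample(c(48L, 72L, 144L), 1),
    seed = seed)
}

sim_timeline <- function(config) {
  timeline(frame_interval_min = config$frame_interval_min,
           frames_per_day = config$frames_per_day,
           total_frames = config$n_frames)
}

report_scalar_fields <- c(
  "initial_cell_count", "final_cell_count", "mitosis_count",
  "dichotomic_mitosis_count", "non_dichotomic_mitosis_count",
  "fusion_count", "abnormal_mitosis_count", "death_count",
  "mitotic_death_count", "non_mitotic_death_count", "out_count",
  "division_probability")

# TRUE when a report computed from the simulated events matches the
# simulator's own ground-truth tallies field for field
report_matches_truth <- function(report, truth) {
  for (k in report_scalar_fields) {
    if (!isTRUE(all.equal(as.numeric(report[[k]]), as.numeric(truth[[k]])))) {
      return(paste0("mismatch in ", k))
    }
  }
  if (!identical(sort(report$inter_mitosis$intervals),
                 sort(as.integer(truth$inter_mitosis$intervals)))) {
    return("mismatch in inter_mitosis intervals")
  }
  ttfd_r <- sort(unname(report$time_to_first_division$times))
  ttfd_t <- sort(unname(as.integer(truth$time_to_first_division$times)))
  if (!identical(ttfd_r, ttfd_t)) return("mismatch in time_to_first_division")
  if (report$time_to_first_division$n_excluded !=
      truth$time_to_first_division$n_excluded) {
    return("mismatch in excluded-root count")
  }
  if (!isTRUE(all.equal(as.data.frame(report$per_day),
                        as.data.frame(truth$per_day)))) {
    return("mismatch in per-day table")
  }
  if (!isTRUE(all.equal(as.data.frame(report$per_cell),
                        as.data.frame(truth$per_cell)))) {
    return("mismatch in per-cell table")
  }
  TRUE
}

# conservation identities every report must satisfy
expect_report_conservation <- function(report) {
  expect_identical(report$mitosis_count,
                   report$dichotomic_mitosis_count +
                     report$non_dichotomic_mitosis_count)
  expect_identical(report$death_count,
                   report$mitotic_death_count + report$non_mitotic_death_count)
  expect_lte(report$abnormal_mitosis_count, report$mitosis_count)
  expect_identical(sum(report$per_day$divisions), report$mitosis_count)
  expect_identical(sum(report$per_day$deaths), report$death_count)
  expect_identical(sum(report$per_day$fusions), report$fusion_count)
  expect_identical(sum(report$per_day$outs), report$out_count)
}
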
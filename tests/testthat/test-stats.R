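test_that("counting statistics reproduce the three-cell worked example", {
  f <- three_cell_forest()
  expect_equal(count_initial(f), 3L)
  expect_equal(count_final(f), 1L)  # only C3 reaches the end
  mit <- count_mitoses(f)
  expect_equal(c(mit$total, mit$dichotomic, mit$non_dichotomic), c(1L, 0L, 1L))
  expect_equal(count_fusions(f), 1L)
  # the division in three also has fused daughters; counted once
  expect_equal(count_abnormal_mitoses(f), 1L)
  dth <- count_deaths(f)
  expect_equal(c(dth$total, dth$mitotic, dth$non_mitotic), c(2L, 1L, 1L))
  expect_equal(count_out(f), 1L)
  expect_equal(division_probability(f), 1 / 3)
  ttfd <- time_to_first_division(f)
  expect_equal(unname(ttfd$times), 112L)
  expect_equal(ttfd$mean, 112)
  expect_equal(ttfd$n_excluded, 2L)
  expect_equal(inter_mitosis_intervals(f)$intervals, integer(0))
  expect_true(is.na(inter_mitosis_intervals(f)$mean))
})

test_that("the six-cell scenario counts divisions by quality", {
  f <- six_cell_forest()
  mit <- count_mitoses(f)
  expect_equal(c(mit$total, mit$dichotomic, mit$non_dichotomic), c(3L, 1L, 2L))
  div_sizes <- lengths(f$children[f$fate == "DIVIDED"])
  expect_setequal(div_sizes[div_sizes > 2], c(4L, 6L))
  expect_equal(count_fusions(f), 1L)  # the six-way coalescence is one event
  dth <- count_deaths(f)
  expect_equal(dth$total, 1L)
  expect_equal(dth$non_mitotic, 1L)   # C3 never divided
  expect_equal(count_out(f), 1L)
  expect_equal(count_final(f), 8L)
})

test_that("empty and degenerate forests give zero counts", {
  f <- build_forest(parse_events(""))
  expect_equal(count_initial(f), 0L)
  expect_equal(count_mitoses(f)$total, 0L)
  expect_equal(division_probability(f), 0)
  r <- compute_report(f)
  expect_equal(r$mitosis_count, 0L)
  expect_true(all(r$per_day$divisions == 0))
  one <- build_forest(parse_events("0 begin A"))
  expect_equal(count_final(one), 1L)
  expect_equal(division_probability(one), 1)
  expect_equal(count_deaths(build_forest(parse_events(c("0 begin A", "9 death A"))))$non_mitotic, 1L)
})

test_that("abnormal mitoses deduplicate daughter fusions correctly", {
  # dichotomic division whose daughters fuse afterwards: abnormal
  f1 <- build_forest(parse_events(c("0 begin A", "10 div A A.1 A.2",
                                    "50 fusion A.1 A.2 A.3")))
  expect_equal(count_abnormal_mitoses(f1), 1L)
  # dichotomic division, no fusion: normal
  f2 <- build_forest(parse_events(c("0 begin A", "10 div A A.1 A.2")))
  expect_equal(count_abnormal_mitoses(f2), 0L)
  # fusion of unrelated cells qualifies no division
  f3 <- build_forest(parse_events(c("0 begin A", "0 begin B", "10 div A A.1 A.2",
                                    "50 fusion A.1 B AB")))
  expect_equal(count_fusions(f3), 1L)
  expect_equal(count_abnormal_mitoses(f3), 0L)
  # division in four followed by a daughter fusion: still one abnormal event
  f4 <- build_forest(parse_events(c("0 begin A", "10 div A A.1 A.2 A.3 A.4",
                                    "50 fusion A.1 A.2 A.5")))
  expect_equal(count_abnormal_mitoses(f4), 1L)
})

test_that("inter-mitosis intervals measure mother lifespans between divisions", {
  f <- build_forest(parse_events(c(
    "0 begin A", "100 div A A.1 A.2", "250 div A.1 A.1.1 A.1.2")))
  im <- inter_mitosis_intervals(f)
  expect_equal(im$intervals, 150L)
  expect_equal(im$mean, 150)
  expect_equal(frames_to_hours(timeline(), im$mean), 25)
  # chains bridged by a fusion are not successive mitoses
  fb <- build_forest(parse_events(c(
    "0 begin A", "100 div A A.1 A.2", "150 fusion A.1 A.2 A.3",
    "300 div A.3 A.3.1 A.3.2")))
  expect_equal(inter_mitosis_intervals(fb)$intervals, integer(0))
})

test_that("division probability supports the alternative denominator", {
  f <- build_forest(parse_events(c("0 begin A", "0 begin B", "0 begin C",
                                   "50 out C")))
  expect_equal(division_probability(f), 2 / 3)
  expect_equal(division_probability(f, denominator = "initial_minus_out"), 1)
  all_out <- build_forest(parse_events(c("0 begin A", "5 out A")))
  expect_true(is.na(division_probability(all_out, denominator = "initial_minus_out")))
})

test_that("the per-day table bins the worked example onto its three days", {
  f <- three_cell_forest()
  pd <- per_day_table(f, timeline())
  expect_equal(pd$divisions, c(1L, 0L, 0L))
  expect_equal(pd$deaths, c(0L, 1L, 1L))
  expect_equal(pd$outs, c(0L, 1L, 0L))
  expect_equal(pd$fusions, c(0L, 0L, 1L))
  # 3 roots at frame 0; 5 alive at frame 144 (C1, C3 + three daughters);
  # 3 alive at frame 288 (C3, C2.1, C2.3)
  expect_equal(pd$alive_at_start, c(3, 5, 3))
  expect_equal(pd$div_ratio, c(1 / 3, 0, 0))
  expect_error(per_day_table(f, timeline(total_frames = 200)),
               class = "cladotrace_error")
})

test_that("per-day sums equal the totals on simulated forests", {
  for (seed in 31:40) {
    cfg <- random_sim_config(seed)
    f <- build_forest(simulate_lineage(cfg)$events)
    r <- compute_report(f, sim_timeline(cfg))
    expect_report_conservation(r)
  }
})

test_that("per-cell division counts tally each root's lineage", {
  f <- three_cell_forest()
  pc <- per_cell_division_counts(f)
  expect_equal(pc$root, c("C1", "C2", "C3"))
  expect_equal(pc$divisions, c(0L, 1L, 0L))
  deep <- build_forest(parse_events(c(
    "0 begin A", "10 div A A.1 A.2",
    "60 div A.1 A.1.1 A.1.2", "80 div A.2 A.2.1 A.2.2")))
  expect_equal(per_cell_division_counts(deep)$divisions, 3L)
})

test_that("adding events never decreases the corresponding count", {
  base <- c("0 begin A", "0 begin B", "20 div A A.1 A.2")
  f0 <- build_forest(parse_events(base))
  f_div <- build_forest(parse_events(c(base, "60 div A.1 X Y")))
  f_death <- build_forest(parse_events(c(base, "60 death B")))
  expect_gt(count_mitoses(f_div)$total, count_mitoses(f0)$total)
  expect_gt(count_deaths(f_death)$total, count_deaths(f0)$total)
})

test_that("frame-based statistics ignore the frame interval; hours scale with it", {
  f <- three_cell_forest()
  r10 <- compute_report(f, timeline(frame_interval_min = 10, frames_per_day = 144,
                                    total_frames = 432))
  r20 <- compute_report(f, timeline(frame_interval_min = 20, frames_per_day = 144,
                                    total_frames = 432))
  expect_identical(r10$mitosis_count, r20$mitosis_count)
  expect_identical(r10$time_to_first_division$mean, r20$time_to_first_division$mean)
  s10 <- tidy(r10); s20 <- tidy(r20)
  h10 <- s10$value[s10$parameter == "time_to_first_division_mean_hours"]
  h20 <- s20$value[s20$parameter == "time_to_first_division_mean_hours"]
  expect_equal(h20, 2 * h10)
})

test_that("tidy/glance expose the summary and CSV export round-trips", {
  f <- three_cell_forest()
  r <- compute_report(f)
  s <- tidy(r)
  expect_equal(s$value[s$parameter == "initial_cell_count"], 3)
  g <- glance(r)
  expect_equal(nrow(g), 1L)
  expect_equal(g$division_probability, 1 / 3)

  dir <- withr::local_tempdir()
  paths <- write_stats_csv(r, dir)
  expect_true(all(file.exists(paths)))
  s2 <- readr::read_csv(paths[["summary"]], show_col_types = FALSE)
  expect_equal(s2$value, s$value)
  pd2 <- readr::read_csv(paths[["per_day"]], show_col_types = FALSE)
  expect_equal(as.data.frame(pd2)$divisions, r$per_day$divisions)
  pc2 <- readr::read_csv(paths[["per_cell"]], show_col_types = FALSE)
  expect_equal(pc2$root, r$per_cell$root)
})
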
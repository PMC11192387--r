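test_that("an untouched cell is a straight line spanning the whole movie", {
  f <- build_forest(parse_events(c("0 begin A", "432 end A")))
  lay <- cladogram_layout(f, timeline())
  expect_equal(nrow(lay$segments), 1L)
  expect_equal(lay$segments$frame0, 0L)
  expect_equal(lay$segments$frame1, 432L)
  expect_equal(nrow(lay$junctions), 0L)
})

test_that("the worked example splits into three lanes and re-merges", {
  f <- three_cell_forest()
  lay <- cladogram_layout(f, timeline())
  st <- lay$style
  y_of <- function(fr) st$margin_top + fr * st$px_per_frame
  # C2's segment ends at the division y; a division junction spans the
  # three daughter lanes there
  seg <- lay$segments
  expect_equal(seg$y1[seg$name == "C2"], y_of(112))
  dj <- lay$junctions[lay$junctions$type == "division", ]
  expect_equal(nrow(dj), 1L)
  expect_equal(dj$y, y_of(112))
  daughter_lanes <- lay$lanes[c("C2.1", "C2.2", "C2.3")]
  expect_equal(length(unique(daughter_lanes)), 3L)
  expect_equal(unname(lay$lanes[["C2"]]), mean(daughter_lanes))
  # fusion junction at y(380), product lane at the midpoint of its inputs
  fj <- lay$junctions[lay$junctions$type == "fusion", ]
  expect_equal(unique(fj$y), y_of(380))
  expect_equal(unname(lay$lanes[["C2.4"]]),
               mean(lay$lanes[c("C2.1", "C2.3")]))
})

test_that("roots occupy disjoint lane groups", {
  f <- build_forest(parse_events(c(
    "0 begin A", "0 begin B",
    "10 div A A.1 A.2", "20 div B B.1 B.2", "432 end A.1")))
  lay <- cladogram_layout(f, timeline())
  a_lanes <- lay$lanes[c("A", "A.1", "A.2")]
  b_lanes <- lay$lanes[c("B", "B.1", "B.2")]
  expect_lt(max(a_lanes), min(b_lanes))
})

test_that("no two temporally overlapping cells share a lane", {
  for (seed in c(2, 13, 44)) {
    f <- build_forest(simulate_lineage(random_sim_config(seed))$events)
    lay <- cladogram_layout(f)
    fin <- attr(f, "final_frame")
    b <- f$birth_frame
    e <- ifelse(is.na(f$fate_frame), fin, f$fate_frame)
    lane <- unname(lay$lanes[f$name])
    n <- nrow(f)
    for (i in seq_len(n)) {
      clash <- abs(lane - lane[i]) < 1e-9 & seq_len(n) != i & b < e[i] & b[i] < e
      expect_false(any(clash), label = sprintf("lane clash, seed %d", seed))
    }
  }
})

test_that("SVG marker counts equal the death and exit statistics", {
  f <- three_cell_forest()
  svg <- render_svg(cladogram_layout(f, timeline()))
  n_cross <- lengths(regmatches(svg, gregexpr('class="death-cross"', svg)))
  n_bars <- lengths(regmatches(svg, gregexpr('class="out-bars"', svg)))
  expect_equal(n_cross, count_deaths(f)$total)
  expect_equal(n_bars, count_out(f))
  # the frame number is printed below each event
  expect_match(svg, ">112<")
  expect_match(svg, ">410<")
})

test_that("identical forest and style give byte-identical SVG", {
  f <- six_cell_forest()
  s1 <- render_svg(cladogram_layout(f, timeline()))
  s2 <- render_svg(cladogram_layout(f, timeline()))
  expect_identical(s1, s2)
})

test_that("an empty forest still renders a valid axis-only SVG", {
  f <- build_forest(parse_events(""))
  svg <- render_svg(cladogram_layout(f, timeline()))
  expect_silent(xml2::read_xml(svg))
  expect_match(svg, 'class="days"')
})

test_that("highlight markers render with their shape and colour", {
  f <- build_forest(parse_events(c("0 begin A @triangle:orange", "432 end A")))
  svg <- render_svg(cladogram_layout(f, timeline()))
  expect_match(svg, '<polygon points="[^"]+" fill="orange"/>')
})

test_that("simulated forests render well-formed SVG contained in the viewBox", {
  for (seed in 101:130) {
    cfg <- random_sim_config(seed)
    lay <- cladogram_layout(build_forest(simulate_lineage(cfg)$events),
                            sim_timeline(cfg))
    svg <- render_svg(lay)
    doc <- xml2::read_xml(svg)
    expect_equal(xml2::xml_name(doc), "svg")
    w <- lay$canvas$width; h <- lay$canvas$height
    for (ln in xml2::xml_find_all(doc, ".//*[local-name()='line']")) {
      xs <- as.numeric(c(xml2::xml_attr(ln, "x1"), xml2::xml_attr(ln, "x2")))
      ys <- as.numeric(c(xml2::xml_attr(ln, "y1"), xml2::xml_attr(ln, "y2")))
      expect_true(all(xs >= -1e-6 & xs <= w + 1e-6),
                  label = sprintf("x in viewBox, seed %d", seed))
      expect_true(all(ys >= -1e-6 & ys <= h + 1e-6),
                  label = sprintf("y in viewBox, seed %d", seed))
    }
  }
})

test_that("autoplot returns a ggplot cladogram", {
  p <- ggplot2::autoplot(three_cell_forest(), timeline())
  expect_s3_class(p, "ggplot")
  expect_silent(ggplot2::ggplot_build(p))
})
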
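test_that("the worked example builds a forest of 7 tracks and 3 roots", {
  f <- three_cell_forest()
  expect_s3_class(f, "lineage_forest")
  expect_equal(nrow(f), 7L)
  expect_setequal(f$name, c("C1", "C2", "C3", "C2.1", "C2.2", "C2.3", "C2.4"))
  expect_equal(forest_roots(f), c("C1", "C2", "C3"))
  expect_equal(attr(f, "final_frame"), 432L)
  expect_equal(f$fate[f$name == "C2"], "DIVIDED")
  expect_equal(f$children[f$name == "C2"][[1]], c("C2.1", "C2.2", "C2.3"))
  expect_equal(f$parents[f$name == "C2.4"][[1]], c("C2.1", "C2.3"))
  expect_equal(f$fate[f$name == "C2.1"], "FUSED")
  # parent/child links are mutually consistent
  for (i in seq_len(nrow(f))) {
    for (p in f$parents[[i]]) {
      expect_true(f$name[i] %in% f$children[f$name == p][[1]])
    }
  }
})

test_that("auto_end closes untouched cells at the final frame", {
  ev <- parse_events(c("0 begin A", "50 death B", "0 begin B"))
  f <- build_forest(ev)
  expect_equal(f$fate[f$name == "A"], "END")
  expect_equal(f$fate_frame[f$name == "A"], 50L)
  expect_error(build_forest(parse_events("0 begin A"), auto_end = FALSE),
               class = "cladotrace_semantic_error", regexp = "still open")
})

test_that("semantic violations are rejected", {
  expect_error(build_forest(parse_events("10 death X")),
               class = "cladotrace_semantic_error", regexp = "never created")
  expect_error(build_forest(parse_events(c("0 begin A", "0 begin A"))),
               class = "cladotrace_semantic_error", regexp = "unique")
  expect_error(build_forest(parse_events(c("0 begin A", "5 death A", "9 out A"))),
               class = "cladotrace_semantic_error", regexp = "already closed")
  # closure line preceding the birth line at the same frame
  expect_error(build_forest(parse_events(c("0 begin A", "5 death A.1",
                                           "5 div A A.1 A.2"))),
               class = "cladotrace_semantic_error")
  # fusion involving an already-dead cell
  expect_error(build_forest(parse_events(c("0 begin A", "0 begin B",
                                           "5 death A", "9 fusion A B AB"))),
               class = "cladotrace_semantic_error", regexp = "already closed")
})

test_that("same-frame birth then closure is legal when ordered correctly", {
  f <- build_forest(parse_events(c("0 begin A", "5 div A A.1 A.2",
                                   "5 death A.1")))
  expect_equal(f$fate[f$name == "A.1"], "DEATH")
  expect_equal(f$fate_frame[f$name == "A.1"], 5L)
})

test_that("creation order never places a child before its parents", {
  for (seed in c(3, 11, 27)) {
    f <- build_forest(simulate_lineage(random_sim_config(seed))$events)
    pos <- seq_len(nrow(f)); names(pos) <- f$name
    for (i in seq_len(nrow(f))) {
      for (p in f$parents[[i]]) expect_lt(pos[[p]], i)
      expect_true(all(f$fate_frame[i] >= f$birth_frame[i]))
    }
  }
})

test_that("division ancestry walks parent links through fusions", {
  f <- three_cell_forest()
  expect_true(has_division_ancestry(f, "C2.4"))   # fusion of two daughters
  expect_false(has_division_ancestry(f, "C1"))    # root, no divisions
  expect_true(has_division_ancestry(f, "C2.1"))   # direct daughter
  expect_false(has_division_ancestry(f, "C2"))    # mother herself not born of one
  expect_error(has_division_ancestry(f, "nope"), regexp = "unknown cell")
  # strict reading: only the cell's own birth counts
  expect_false(has_division_ancestry(f, "C2.4", scope = "immediate"))
})

test_that("division ancestry is monotone along descent", {
  for (seed in c(5, 21)) {
    f <- build_forest(simulate_lineage(random_sim_config(seed))$events)
    anc <- has_division_ancestry(f)
    for (i in seq_len(nrow(f))) {
      if (anc[[f$name[i]]]) {
        for (k in f$children[[i]]) expect_true(anc[[k]])
      }
    }
  }
})

test_that("fusion across unrelated lineages joins trees into a DAG", {
  f <- build_forest(parse_events(c(
    "0 begin A", "0 begin B",
    "10 div A A.1 A.2",
    "40 fusion A.1 B AB",
    "90 div AB AB.1 AB.2")))
  expect_equal(sort(cladotrace:::cell_roots(f)[["AB"]]), c("A", "B"))
  expect_true(has_division_ancestry(f, "AB"))
  # the downstream division is attributed to both roots
  pc <- per_cell_division_counts(f)
  expect_equal(pc$divisions[pc$root == "A"], 2L)
  expect_equal(pc$divisions[pc$root == "B"], 1L)
})
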
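---
title: "Lineage statistics and cladograms from annotated time-lapse movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage statistics and cladograms from annotated time-lapse movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladotrace)
```

## The problem

Time-lapse video-microscopy follows individual cells through a movie of a
few hundred frames. For cancer cells under treatment the interesting
behaviours — divisions into more than two daughters, the coalescence of
daughter cells back into one, death with or without a preceding mitosis,
cells drifting out of the camera field — are exactly the ones automated
trackers handle worst, so the movies are annotated by hand: the
experimenter names each cell and writes one line per event. `cladotrace`
takes that file and produces (i) a validated lineage forest, (ii) the
single-cell statistics used to compare treatment conditions and (iii) a
cladogram drawing of the whole movie.

## The event model

Six event kinds describe everything the format can express. `begin` opens
a root cell at its first observed frame; `div` closes the mother and opens
two or more daughters at the division frame; `fusion` closes two or more
input cells and opens the named product; `death`, `out` and `end` close a
cell (death, field exit, end of observation). Replaying the events in
frame order yields one *track* per cell: birth frame and mode, terminal
fate and frame, parent and child links. Divisions make the forest a
collection of trees; fusions may join branches, so in general the forest
is a directed acyclic graph.

Validation is strict: every name must be opened before it is used and may
be used for only one cell per movie; events on closed cells, frames before
a cell's birth, and fusions involving an already-closed cell are errors
with line-numbered diagnostics. A cell may be opened and closed at the
same frame only if the opening line comes first. Cells left open at the
last frame are closed by a synthetic `end` there (`auto_end = TRUE`, the
usual annotation convention — survivors carry no explicit event); with
`auto_end = FALSE` they are a validation error instead.

Two details of the grammar are dialect choices rather than fixed
conventions of the format family: the field-exit keyword (we write `out`
and accept `exit`) and the highlight-marker syntax `@shape:colour` on
`begin` lines. Both are documented so files remain self-describing.

## Statistics: definitions and edge cases

Counting statistics follow directly from the tracks: initial cells are
roots, final cells are `end` fates, mitoses are `DIVIDED` fates split by
daughter count (dichotomic = 2, non-dichotomic > 2), fusions are counted
one per event regardless of arity (a six-input coalescence is one fusion).

**Abnormal mitosis** is a division that is non-dichotomic *or* followed by
a fusion re-merging at least two of its direct daughters; a division
qualifying on both grounds is counted once. We require ≥2 of the fusion's
inputs to be daughters of the division: a daughter fusing with an
unrelated cell does not make her mother's division abnormal, though it
does count as a fusion.

**Mitotic death** is a death preceded by a division in the dying cell's
lineage. We interpret "preceded" through the whole ancestry: a cell is
mitotic-death-eligible if it was born from a division or if any ancestor
was, with a fusion product inheriting the OR over its inputs. A stricter
reading — only the cell's own birth counts — is available via
`scope = "immediate"` in `count_deaths()` and `has_division_ancestry()`.

**Inter-mitosis intervals** are the lifespans of mothers that were
themselves born from a division (her division frame minus her birth
frame). Chains bridged by a fusion (daughters fuse, the product divides)
are *not* counted as successive mitoses: the product is a different cell
with mixed ancestry. **Time to first division** is computed per root, over
roots whose lineage divides at least once; non-dividing roots are excluded
from the mean and their count reported, rather than contributing zeros
that would bias condition comparisons. Means are accompanied by population
standard deviations (denominator *n*): the tracked cells are the entire
observed population, not a sample used for inference. Empty sequences
yield `NA`, never 0.

**Division probability** is the final over the initial cell number. The
idea of additionally excluding cells that died or left the field is
ambiguous (excluded from what, exactly?), so the plain ratio is the
default and a literal alternative denominator, initial minus the number of
field exits, is available via `denominator = "initial_minus_out"`
(returning `NA` when non-positive). We do not claim either reading is
canonical.

**Per-day tables** bin event frames into half-open day windows
`[k·fpd, (k+1)·fpd)` of `fpd` frames each, with the terminal frame clamped
into the last day so end-of-movie events stay countable. The ratio
denominator — nowhere standardised — is the number of cells alive at the
day's first frame, where "alive at frame f" means born at or before f and
closed strictly after f. Count columns always sum to the movie totals.

**Per-cell division counts** attribute every division to the root(s) whose
lineage contains it. With sibling-only fusions each cell has exactly one
root; if a fusion joins unrelated lineages, the downstream divisions are
attributed to *each* contributing root, so the per-root column can then
sum to more than the global mitosis count. This is the only statistic
affected by that rare case.

## Timeline

`timeline()` holds the frame interval in minutes (default 10), frames per
day (derived as `round(24·60/interval)` when not given; 144 at the
default) and the movie length (default 432 frames, i.e. 72 h). All
interval statistics are computed in frames and converted to hours only for
reporting, so they are invariant to the interval setting while hour-valued
outputs scale linearly with it.

## Cladogram layout and rendering

Time runs top to bottom (`y = margin + frame × px_per_frame`); each cell
is a vertical segment in its own horizontal lane. Lane assignment is the
classic tidy-tree layout applied to the division trees: leaves take
consecutive integer lanes within each root's block (roots in file order,
one empty lane between blocks) and every mother sits at the midpoint of
her daughters' span. Fusion products are placed at the midpoint of their
inputs' lanes — a stated convention, since no standard exists for ordering
fusion products among siblings — and a product's own division subtree is
laid out in a narrow band around that centre. Because a midpoint can
collide with a still-alive intermediate sibling, a final pass nudges any
cell whose lane equals that of a temporally overlapping earlier cell by a
fixed fraction of a lane; the pass is deterministic, so identical input
and style always give byte-identical SVG.

The SVG vocabulary: black strokes for lifespans, a horizontal junction at
each division, straight connectors from each fusion input to the product
lane at the fusion frame, a red cross at each death, a double parallel
blue bar at each field exit, dashed day gridlines with frame numbers on
the left axis, cell names above their branches and the event frame number
printed below each event. Event labels use fixed offsets with no collision
resolution; dense movies tolerate some overlap, which matches how these
figures are usually read (zooming into the vector image). `autoplot()`
provides a ggplot2 quick look with the same geometry.

## The simulator and what tests can conclude

`simulate_lineage()` runs a seeded per-frame branching process: each alive
cell independently draws death, field exit and division (precedence
death > exit > division, one fate per cell per frame); a division has 2
daughters, or 3–6 (uniform) with probability `p_multi`; daughters of one
division form a sibling group in which, from the next frame on, each
surviving pair may fuse with probability `p_sibling_fusion` per frame
(fusion products do not rejoin the group); survivors get `end` at the last
frame. Every event also increments an independent ground-truth tally, so
the simulator doubles as an exact oracle for the statistics pipeline. In
the dichotomic pure-birth limit the expected total division count has the
closed form `n·((1+p)^T − 1)`, which the Monte-Carlo mean must match
within sampling error.

Default rates mirror the scale of a typical experiment: 50 tracked cells,
432 frames, and a division rate of 0.0048 per cell per frame, chosen so an
untreated cell divides about once per day (`(1+0.0048)^144 ≈ 2`); death,
exit, multi-daughter and fusion rates are small. These are test knobs
calibrated to magnitude, not fitted biological parameters. The simulator
emulates the event *repertoire* of real annotations, not their biology: no
cell-cycle refractory period, no correlated fates between siblings, no
treatment dynamics. Passing the oracle suite therefore shows the
counting/interval machinery is exact on well-formed logs of realistic
shape — it says nothing about annotation errors, which the parser's
validation layer addresses separately.

The test suite and the acceptance script use batches of small simulations
(2–8 roots, 96–216 frames, randomised rates, fixed seeds; 1000 forests in
the oracle suite, 500 and 200 runs respectively in the pure-birth checks)
— sizes chosen to cover quiet, proliferative and death-heavy regimes while
keeping the whole suite quick to run.

## Numerical and design notes

- Frames are integers throughout; no floating-point time arithmetic enters
  any count.
- Events at the same frame keep input order (stable sort), which is what
  makes "born and closed at the same frame" well-defined.
- The serialiser writes, within a frame, opening events before
  closure-only events, in cell-creation order; this canonical order
  guarantees write → parse → build is the identity on forests (the
  round-trip property tested across simulated forests).
- The RNG state of the caller is saved and restored around
  `simulate_lineage()`; all randomness flows from `sim_config(seed =)`.
- CSV output uses comma separation, `.` decimals, a header row and `NA`
  for missing values; SVG output is SVG 1.1 with a white background and a
  `viewBox` that contains every drawn line.

## Known limitations

- The format carries no spatial or morphological information, so none is
  modelled.
- Statistical comparison between conditions (ANOVA and post-hoc tests on
  the per-condition tallies) is out of scope; the CSV tables are designed
  to feed external tools.
- Label collisions in very dense cladograms are tolerated, not resolved.
- Fusions between cells of unrelated lineages are accepted and handled,
  but the per-root division counter then intentionally double-attributes
  shared descendants (see above).
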
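# cladotrace

Single-cell fate analysis for manually annotated time-lapse
video-microscopy. Automated trackers still struggle with the complex
behaviours of cancer cells — divisions into more than two daughters, cell
fusions, deaths that follow a mitosis — so these movies are often annotated
by hand, one event per line in a plain-text file. `cladotrace` turns such an
annotation file into a validated cell lineage forest, computes the standard
single-cell statistics, and draws the lineage as a cladogram in SVG.

## The annotation format

One event per line: `<frame> <keyword> <cell names...>`.

```
0 begin C1          # cell C1 is present at the start of the movie
112 div C2 C2.1 C2.2 C2.3    # C2 divides into three daughters at frame 112
287 out C2.2        # C2.2 leaves the camera field
380 fusion C2.1 C2.3 C2.4    # two daughters fuse; the product is C2.4
410 death C2.4      # the fusion product dies
432 end C3          # C3 is still alive when observation stops
```

Keywords are case-insensitive (`exit` is accepted for `out`); `#` lines and
blank lines are ignored; a `begin` line may carry a highlight marker
`@<shape>:<colour>` (circle, square, triangle, star) to flag a cell of
interest on the cladogram. Cells still open at the last frame are closed by
a synthetic `end` unless `auto_end = FALSE`.

## The statistics

From the lineage forest the package computes, per movie:

- initial and final cell numbers (`begin` and `end` events);
- mitosis count, split into dichotomic (2 daughters) and non-dichotomic
  (>2 daughters);
- fusion count (one per fusion event, whatever its arity);
- abnormal mitosis count: a division that is non-dichotomic **or** followed
  by the coalescence of ≥2 of its daughters, counted once per division;
- deaths, split into mitotic (a division somewhere in the dying cell's
  lineage) and non-mitotic;
- inter-mitosis intervals (lifespans of mothers that were themselves born
  from a division) and time from the start of the movie to each root's
  first division, with means and population SDs;
- division probability = final / initial cell number;
- per-day event counts and ratios against the cells alive at each day's
  first frame;
- a per-root division counter for single-cell heterogeneity analysis.

## Worked example

```r
library(cladotrace)
path <- system.file("extdata", "demo_three_cells.txt", package = "cladotrace")
forest <- build_forest(read_events(path))
forest
#> <lineage_forest> 7 cell(s), 3 root(s), final frame 432
report <- compute_report(forest, timeline(frame_interval_min = 10))
report
#> <lineage_stats>
#>   initial_cell_count                   3
#>   final_cell_count                     1
#>   mitosis_count                        1
#>   dichotomic_mitosis_count             0
#>   non_dichotomic_mitosis_count         1
#>   fusion_count                         1
#>   abnormal_mitosis_count               1
#>   death_count                          2
#>   mitotic_death_count                  1
#>   non_mitotic_death_count              1
#>   out_count                            1
#>   ...
#>   time_to_first_division_mean_frames   112
#>   division_probability                 0.333333
```

Three cells are followed over 432 frames (10 minutes per frame, 72 hours).
One divides into three at frame 112 — a non-dichotomic, hence abnormal,
mitosis; two of the daughters later fuse, and the fusion product dies (a
mitotic death, since a division precedes it in its lineage). One root dies
without ever dividing (non-mitotic), one survives to the end, so the
division probability — final over initial cell number — is 1/3.

```r
write_cladogram_svg(forest, "lineage.svg")   # red cross = death,
                                             # blue double bar = field exit
write_stats_csv(report, "stats/")            # summary / per_day / per_cell
tidy(report)                                 # the summary as a tibble
ggplot2::autoplot(forest)                    # quick-look ggplot cladogram
```

Or from a shell, via the installed script:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","cladotrace",package="cladotrace"))') \
  analyze demo_three_cells.txt --svg out.svg --csv-dir stats
```

A seeded branching-process simulator (`simulate_lineage()`,
`sim_config()`) generates event files with known ground-truth tallies for
testing; `simulate_to_file()` / the `simulate` subcommand write the event
file plus a ground-truth sidecar CSV.

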
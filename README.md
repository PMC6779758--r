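# sproutquant

Quantitative analysis of endothelial cell behaviour in angiogenesis assays:

* **Motility statistics** from tracked cell or sprout-tip positions —
  average displacement `d(τ) = ⟨‖x_i(t+τ) − x_i(t)‖⟩_{i,t}` over all cells
  and time points, and the time-dependent average speed
  `v(t) = ⟨‖x_i(t+τ₀) − x_i(t)‖/τ₀⟩_i` with a one-hour lag, each with SEM
  and exact pooling across independent experiments.
* **A modified Sholl analysis of multicellular sprout arbors**: brightfield
  z-stacks of gel-embedded spheroid aggregates are segmented by local
  intensity variance (in-focus structure is textured, out-of-focus is
  smooth), reconstructed into a voxel volume using the optics' depth of
  field, and intersected with concentric cylinders (radii 20–560 µm, step
  20 µm). Each connected patch on a rolled-out cylinder surface is one
  sprout traversal; the radius of maximal traversal count separates the
  branching zone from the sprout elongation zone, and per-group sprout
  length distributions are normalized to the control count at that boundary.
* **Vessel morphometry** of quasi-2D tissue (e.g. fetal chorion fields of
  865 µm × 650 µm): density as the foreground area fraction, total
  centerline length from a topological skeleton, mean width from the
  distance transform sampled along the skeleton.
* **Gelatin degradation**: fraction of a fluorescent substrate digested
  (dark) by matrix metalloproteinase activity.

Every estimator ships with a synthetic-data generator that produces inputs
with exact ground truth (persistent random walks, rendered tube arbors with
bookkept cylinder crossings, vessel networks and gelatin substrates of
programmed density/area), so the whole pipeline is validated end to end.

## Worked example

```r
library(sproutquant)

## --- motility: simulate 30 cells for 24 h at 10-min sampling -------------
sim <- generate_tracks(n_cells = 30, duration_h = 24, dt_h = 1/6,
                       speed_mean_um_h = 11, seed = 8)
speed <- mean_speed_timeseries(sim$tracks, tau0_hours = 1)
head(round(speed, 3))
#>   t_hours   mean   sem  n
#> 1   0.000 10.768 0.033 30
#> 2   0.167 10.760 0.038 30
#> 3   0.333 10.772 0.036 30
```

The programmed path speed was 11 µm/h; the measured 1-h chord speed is
≈10.77 µm/h — the ~2% deficit is the expected chord shortening of a
persistent random walk, not an estimator error (straight-line motion
returns the programmed speed exactly).

```r
mean_displacement(sim$tracks, lags_hours = c(1/6, 1, 2, 5))
#>   lag_hours   mean   sem    n
#> 1     0.167  1.833 0.000 4320
#> 2     1.000 10.786 0.003 4170
#> 3     2.000 21.173 0.012 3990
#> 4     5.000 50.265 0.066 3450
```

`d(τ)` grows nearly linearly (≈11 µm/h × τ) because the persistence time
(8 h) exceeds these lags. `n` counts all (cell, time) pairs.

```r
## --- sprout arbor: simulate, then analyze end to end ---------------------
arb <- generate_arbor(n_sprouts = 12, seed = 8)   # 14-slice z-stack
res <- analyze_arbor(arb$stack, window = 7)
res$profile[res$profile$radius_um %in% seq(100, 200, 20), ]
#>    radius_um count in_aggregate
#> 5        100    12        FALSE
#> 6        120    12        FALSE
#> 7        140    13        FALSE
#> 8        160    15        FALSE
#> 9        180    16        FALSE
#> 10       200    18        FALSE
attr(res$profile, "boundary_radius_um")
#> [1] 200
```

The 12 primary sprouts are recovered at the aggregate surface; counts rise
to 18 through the branching zone and the branching/elongation boundary is
placed at 200 µm, one radial step inside the generator's 210 µm zone edge
(the detected aggregate radius was 94.8 µm for a 90 µm phantom).

File-based runs (`run_motility()`, `run_arbor()`, `run_vessels()`,
`run_gelatin()`, `run_simulate()`) read track CSVs / multi-page TIFFs with a
JSON sidecar config and write CSV/JSON outputs plus a resolved-config
provenance block. A thin CLI over these functions is installed at
`system.file("exec", "sproutquant.R", package = "sproutquant")`.

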
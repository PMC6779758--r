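test_that("track generator is deterministic and hits degenerate limits", {
  a <- generate_tracks(n_cells = 10, duration_h = 6, seed = 5)
  b <- generate_tracks(n_cells = 10, duration_h = 6, seed = 5)
  expect_identical(a$tracks, b$tracks)
  c <- generate_tracks(n_cells = 10, duration_h = 6, seed = 6)
  expect_false(identical(a$tracks$x_um, c$tracks$x_um))

  # infinite persistence: ballistic, measured speed exactly the programmed one
  g <- generate_tracks(n_cells = 5, duration_h = 8, dt_h = 1 / 6,
                       speed_mean_um_h = 11, persistence_time_h = Inf, seed = 2)
  sc <- mean_speed_timeseries(g$tracks, 1)
  expect_equal(sc$mean, rep(11, nrow(sc)), tolerance = 1e-12)

  expect_error(generate_tracks(n_cells = 0), "positive")
  expect_error(generate_tracks(persistence_time_h = -1), "positive")
})

test_that("programmed migration speed is recovered from simulated walks", {
  g <- generate_tracks(n_cells = 100, duration_h = 24, dt_h = 1 / 6,
                       speed_mean_um_h = 11, seed = 42)
  sc <- mean_speed_timeseries(g$tracks, 1)
  overall <- mean(sc$mean)
  expect_lt(abs(overall - 11) / 11, 0.05)
})

test_that("arbor generator bookkeeping matches its construction", {
  # no sprouts: stack segments to an empty volume
  g0 <- generate_arbor(n_sprouts = 0, seed = 1)
  expect_true(all(g0$ground_truth$per_radius$count == 0))

  # eight branch-free sprouts spanning the full zone: count 8 throughout
  g8 <- generate_arbor(n_sprouts = 8, branch_probability = 0, seed = 13)
  segs <- g8$ground_truth$segments
  expect_equal(nrow(segs), 8L)
  pr <- g8$ground_truth$per_radius
  inner <- pr$radius_um > 90 & pr$radius_um <= min(segs$e) - 10
  expect_true(all(pr$count[inner] == 8))

  # determinism of the rendered stack
  ga <- generate_arbor(n_sprouts = 5, seed = 17)
  gb <- generate_arbor(n_sprouts = 5, seed = 17)
  expect_identical(ga$stack$slices, gb$stack$slices)

  # branches only inside the branching zone
  gbk <- generate_arbor(n_sprouts = 10, branch_probability = 0.3, seed = 19)
  br <- gbk$ground_truth$segments
  expect_true(all(br$s[br$parent > 0] < 210))
  expect_error(generate_arbor(aggregate_radius_um = 300,
                              branching_zone_outer_um = 200), "aggregate")
})

test_that("thinning an arbor removes the programmed sprout fraction at every radius", {
  ctrl <- generate_arbor(n_sprouts = 15, seed = 23)
  thin <- thin_arbor(ctrl, fraction = 0.4, seed = 24)
  pc <- ctrl$ground_truth$per_radius
  pt <- thin$ground_truth$per_radius
  # where counts are substantial, the per-radius ratio is 0.6 up to the
  # per-stratum rounding of the deletion draw (+/- a couple of sprouts)
  keepable <- pc$count >= 10 & !pc$in_aggregate
  ratio <- pt$count[keepable] / pc$count[keepable]
  expect_lt(max(abs(ratio - 0.6)), 0.15)
  expect_identical(thin_arbor(ctrl, 0.4, seed = 24)$stack$slices,
                   thin$stack$slices)
})

test_that("field generators close the loop with their estimators", {
  blank <- generate_vessel_field(density = 0, seed = 1)
  expect_equal(sum(blank$mask), 0)

  v <- generate_vessel_field(density = 0.75, seed = 5)
  mask <- vessel_mask(v$image, 1)
  expect_lt(abs(vessel_stats(mask, 1)$density - 0.75), 0.02)

  g <- generate_gelatin_field(0.10, seed = 6)
  expect_lt(abs(digested_area_fraction(g$image, 1) - 0.10), 0.005)

  expect_error(generate_vessel_field(density = 1.5), "density")
  expect_identical(generate_gelatin_field(0.05, seed = 3)$image,
                   generate_gelatin_field(0.05, seed = 3)$image)
})
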
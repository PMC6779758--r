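test_that("stationary and ballistic tracks give the closed-form curves", {
  ts0 <- track_set(stationary_df())
  d0 <- mean_displacement(ts0, c(0.5, 1, 2))
  expect_equal(d0$mean, rep(0, 3))
  s0 <- mean_speed_timeseries(ts0, 1)
  expect_equal(s0$mean, rep(0, nrow(s0)))

  v <- 25
  tsb <- track_set(ballistic_df(v_um_h = v))
  lags <- c(1 / 6, 0.5, 1, 2, 5)
  db <- mean_displacement(tsb, lags)
  expect_equal(db$mean, v * lags, tolerance = 1e-12)
  sb <- mean_speed_timeseries(tsb, 1)
  expect_equal(sb$mean, rep(v, nrow(sb)), tolerance = 1e-12)
  expect_true(all(sb$n == 3))

  # single cell moving on a straight line at 24 um/h: d(1 h) = 24 um
  one <- data.frame(track_id = "c", t_hours = seq(0, 3, 1 / 6),
                    x_um = 24 * seq(0, 3, 1 / 6), y_um = 0)
  expect_equal(mean_displacement(track_set(one), 1)$mean, 24)
})

test_that("estimators equal the brute-force pair enumeration on random walks", {
  lags <- c(1 / 6, 0.5, 1, 2, 5)
  for (seed in c(11, 12, 13)) {
    g <- generate_tracks(n_cells = 6, duration_h = 6, dt_h = 1 / 6,
                         speed_mean_um_h = 15, persistence_time_h = 0.3,
                         seed = seed)
    df <- as.data.frame(g$tracks)
    got <- mean_displacement(g$tracks, lags)
    for (i in seq_along(lags)) {
      o <- oracle_displacement(df, lags[i], 1 / 6)
      expect_equal(got$mean[i], o$mean, tolerance = 1e-9)
      expect_equal(got$sem[i], o$sem, tolerance = 1e-9)
      expect_equal(got$n[i], o$n)
    }
    gs <- mean_speed_timeseries(g$tracks, 1)
    os <- oracle_speed(df, 1)
    expect_equal(gs$t_hours, os$t_hours)
    expect_equal(gs$mean, os$mean, tolerance = 1e-9)
  }
})

test_that("estimators handle missing observations by pair-wise exclusion", {
  g <- generate_tracks(n_cells = 5, duration_h = 5, dt_h = 0.5,
                       persistence_time_h = 1, seed = 4)
  df <- as.data.frame(g$tracks)
  # punch holes and drop one track's tail
  holes <- df[-c(3, 17, 30, 44), ]
  holes <- holes[!(holes$track_id == "cell002" & holes$t_hours > 3), ]
  ts <- track_set(holes, dt_hours = 0.5)
  got <- mean_displacement(ts, c(0.5, 2))
  for (i in 1:2) {
    o <- oracle_displacement(holes, c(0.5, 2)[i], 0.5)
    expect_equal(got$mean[i], o$mean, tolerance = 1e-9)
    expect_equal(got$n[i], o$n)
  }
  # deleting a whole track only removes that track's pairs
  kept <- holes[holes$track_id != "cell004", ]
  got2 <- mean_displacement(track_set(kept, dt_hours = 0.5), c(0.5, 2))
  o2 <- oracle_displacement(kept, 0.5, 0.5)
  expect_equal(got2$mean[1], o2$mean, tolerance = 1e-9)
})

test_that("displacement obeys diffusive scaling and subadditivity", {
  # uncorrelated random walk: log-log slope of d(tau) near 1/2
  g <- generate_tracks(n_cells = 100, duration_h = 24, dt_h = 1 / 6,
                       speed_mean_um_h = 12, persistence_time_h = 0.01,
                       seed = 7)
  lags <- c(0.5, 1, 2, 4)
  d <- mean_displacement(g$tracks, lags)
  expect_true(all(d$n >= 1e4))
  slope <- coef(lm(log(d$mean) ~ log(d$lag_hours)))[2]
  expect_gt(slope, 0.45)
  expect_lt(slope, 0.55)

  # triangle inequality on means: d(t1 + t2) <= d(t1) + d(t2)
  g2 <- generate_tracks(n_cells = 20, duration_h = 12, dt_h = 1 / 6,
                        persistence_time_h = 2, seed = 8)
  dd <- mean_displacement(g2$tracks, c(1, 2, 3))
  expect_lte(dd$mean[3], dd$mean[1] + dd$mean[2] + 1e-9)
})

test_that("invalid lags, empty input and over-long tau0 raise errors", {
  ts <- track_set(ballistic_df())
  expect_error(mean_displacement(ts, 0.25), "0.25")
  expect_error(mean_speed_timeseries(ts, 100), "span")
  expect_error(track_set(data.frame(track_id = character(0),
                                    t_hours = numeric(0), x_um = numeric(0),
                                    y_um = numeric(0))), "no tracks")
  expect_error(track_set(data.frame(track_id = "a", t_hours = c(0, 1, 2.5),
                                    x_um = 0, y_um = 0)), "uniform")
  expect_warning(mean_displacement(ts, c(1, 6)), "6")
})

test_that("pooling merges populations rather than averaging means", {
  ts <- track_set(ballistic_df(n_cells = 4, v_um_h = 10))
  c1 <- mean_displacement(ts, c(0.5, 1))
  # a curve pooled with itself: same mean, SEM scaled by 1/sqrt(2)
  p <- pool_curves(list(c1, c1))
  expect_equal(p$mean, c1$mean)
  expect_equal(p$sem, c1$sem / sqrt(2), tolerance = 1e-12)
  expect_equal(p$n, 2L * c1$n)

  # disjoint single-value curves with equal n pool to the midpoint
  a <- structure(data.frame(lag_hours = 1, mean = 10, sem = 0, n = 5L),
                 class = c("lag_curve", "data.frame"))
  b <- structure(data.frame(lag_hours = 1, mean = 20, sem = 0, n = 5L),
                 class = c("lag_curve", "data.frame"))
  expect_equal(pool_curves(list(a, b))$mean, 15)

  # pooling replicates equals one pass over the concatenated track sets
  gs <- lapply(c(21, 22, 23), function(s) {
    generate_tracks(n_cells = 8, duration_h = 6, dt_h = 1 / 6,
                    persistence_time_h = 1, seed = s)$tracks
  })
  lags <- c(0.5, 1, 2)
  pooled <- pool_curves(lapply(gs, mean_displacement, lags_hours = lags))
  single <- mean_displacement(combine_tracks(gs), lags)
  expect_equal(pooled$mean, single$mean, tolerance = 1e-9)
  expect_equal(pooled$sem, single$sem, tolerance = 1e-9)
  expect_equal(pooled$n, single$n)
  # speed curves pool the same way
  sp <- pool_curves(lapply(gs, mean_speed_timeseries))
  ss <- mean_speed_timeseries(combine_tracks(gs))
  expect_equal(sp$mean, ss$mean, tolerance = 1e-9)

  # mismatched grids are refused with the offending points named
  shifted <- mean_displacement(gs[[1]], c(0.5, 1, 2.5))
  expect_error(pool_curves(list(pooled, shifted)), "2.5")
})
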
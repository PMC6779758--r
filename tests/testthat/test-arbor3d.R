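geom_px <- 2  # phantom pixel size (um)

phantom_volume <- function(segs, n_px = 601) {
  arbor_volume_from_segments(segs, center_um = c(x = (n_px - 1), y = (n_px - 1)),
                             n_px = n_px, pixel_size_um = geom_px)
}
phantom_center <- c(x = 600, y = 600)

test_that("voxel reconstruction follows the stated conventions", {
  st <- image_stack(replicate(3, matrix(0.5, 40, 40), simplify = FALSE),
                    pixel_size_um = 2)
  expect_warning(vol <- reconstruct_volume(st, window = 5), "flat|empty")
  expect_equal(sum(vol$mask), 0)

  # one foreground pixel in one slice -> one voxel at (x, y, k*dz)
  masks <- replicate(3, matrix(FALSE, 10, 10), simplify = FALSE)
  masks[[2]][4, 7] <- TRUE
  vol <- binary_volume(masks, pixel_size_um = 2, dz_um = 20, depth_of_field_um = 10)
  occ <- which(vol$mask, arr.ind = TRUE)
  expect_equal(nrow(occ), 1L)
  expect_equal(unname(occ[1, ]), c(4L, 7L, 2L))

  # rendered arbor: centerline sample points land inside occupied footprints
  g <- generate_arbor(n_sprouts = 6, branch_probability = 0, seed = 21)
  vol <- reconstruct_volume(g$stack, window = 7)
  segs <- g$ground_truth$segments
  ctr <- g$ground_truth$center_um
  hit <- 0; tot <- 0
  for (j in seq_len(nrow(segs))) {
    rho <- seq(segs$s[j] + 7, segs$e[j] - 7, by = 10)
    z <- segs$z0[j] + segs$slope[j] * (rho - segs$s[j])
    k <- pmin(pmax(round(z / 20) + 1, 1), dim(vol$mask)[3])
    row <- round((ctr["y"] + rho * sin(segs$phi[j])) / 2) + 1
    col <- round((ctr["x"] + rho * cos(segs$phi[j])) / 2) + 1
    hit <- hit + sum(vol$mask[cbind(row, col, k)])
    tot <- tot + length(rho)
  }
  expect_gte(hit / tot, 0.95)
})

test_that("cylinder sampling uses the 20-560 um default grid and finds crossings", {
  segs <- radial_segments(1, phi0 = 0.7)
  vol <- phantom_volume(segs)
  maps <- cylinder_traversals(vol, phantom_center)
  expect_length(maps, 28)
  expect_equal(vapply(maps, function(m) m$radius_um, numeric(1)),
               seq(20, 560, by = 20))
  # a single radial tube crosses each cylinder in its span exactly once
  counts <- vapply(maps, count_sprouts, integer(1))
  span <- seq(20, 560, 20) > 90 & seq(20, 560, 20) < 450
  expect_true(all(counts[span] == 1))
  expect_true(all(counts[seq(20, 560, 20) > 450] == 0))
  # the marked patch sits at the tube azimuth
  m <- maps[[10]]  # r = 200
  idx <- which(m$surface, arr.ind = TRUE)
  ang <- (idx[, 1] - 1) / nrow(m$surface) * 2 * pi
  expect_lt(min(abs(mean(ang) - 0.7)), 2 * m$arc_step_um / 200)

  expect_error(cylinder_traversals(vol, c(x = -50, y = 0)), "outside")
  expect_warning(cylinder_traversals(vol, c(x = 20, y = 600), radii_um = 560),
                 "truncated")
})

test_that("particle counting respects wrap-around, gaps and min size", {
  expect_equal(count_sprouts(matrix(FALSE, 60, 10)), 0L)

  s <- matrix(FALSE, 60, 10)
  s[5:9, 3:7] <- TRUE          # 25 px patch
  s[30:34, 3:7] <- TRUE        # second patch
  expect_equal(count_sprouts(s, min_patch_px = 9), 2L)

  # patch split across the theta = 0 seam counts once
  s2 <- matrix(FALSE, 60, 10)
  s2[c(58:60, 1:3), 4:5] <- TRUE
  expect_equal(count_sprouts(s2), 1L)

  # a one-column axial gap is bridged; a two-column gap is not
  s3 <- matrix(FALSE, 60, 10)
  s3[10:14, 3] <- TRUE; s3[10:14, 5] <- TRUE
  expect_equal(count_sprouts(s3), 1L)
  s4 <- matrix(FALSE, 60, 10)
  s4[10:14, 3] <- TRUE; s4[10:14, 6] <- TRUE
  expect_equal(count_sprouts(s4), 2L)

  # speckle below min_patch_px is ignored
  s5 <- matrix(FALSE, 60, 10)
  s5[20, 4] <- TRUE; s5[40:44, 7:8] <- TRUE
  expect_equal(count_sprouts(s5, min_patch_px = 4), 1L)
})

test_that("N radial tubes are conserved across radii, rotation and arc step", {
  for (n in c(3, 17, 30)) {
    segs <- radial_segments(n, s = 90, e = 450, z0 = 120)
    vol <- phantom_volume(segs)
    radii <- seq(100, 440, by = 20)
    counts <- vapply(cylinder_traversals(vol, phantom_center, radii),
                     count_sprouts, integer(1))
    expect_true(all(counts == n), label = sprintf("n=%d conserved", n))
    # halving the arc step changes no count
    counts_half <- vapply(cylinder_traversals(vol, phantom_center, radii,
                                              arc_step_um = 1),
                          count_sprouts, integer(1))
    expect_equal(counts_half, counts)
  }
  # rotating the arbor about the axis changes no per-radius count
  segs <- radial_segments(9)
  base <- vapply(cylinder_traversals(phantom_volume(segs), phantom_center,
                                     seq(100, 440, 20)), count_sprouts, integer(1))
  rot <- segs; rot$phi <- (rot$phi + 1.2345) %% (2 * pi)
  rcounts <- vapply(cylinder_traversals(phantom_volume(rot), phantom_center,
                                        seq(100, 440, 20)), count_sprouts, integer(1))
  expect_equal(rcounts, base)
  # beyond the boundary of a non-branching arbor counts never increase
  segs2 <- radial_segments(12, e = 450)
  segs2$e <- seq(250, 470, length.out = 12) %/% 20 * 20 + 10
  counts2 <- vapply(cylinder_traversals(phantom_volume(segs2), phantom_center,
                                        seq(100, 560, 20)), count_sprouts, integer(1))
  expect_true(all(diff(counts2) <= 0))
})

test_that("profile boundary detection applies the smallest-arg-max tie rule", {
  # strictly decreasing counts: boundary at the first non-aggregate radius
  p <- arbor_profile(c(9, 7, 5, 3), radii_um = c(20, 40, 60, 80),
                     aggregate_radius_um = 10)
  expect_equal(attr(p, "boundary_radius_um"), 20)

  # tie broken toward the smaller radius
  p2 <- arbor_profile(c(3, 7, 7, 5), radii_um = c(20, 40, 60, 80),
                      aggregate_radius_um = 10)
  expect_equal(attr(p2, "boundary_radius_um"), 40)

  # aggregate-interior radii are flagged and excluded from the zone logic
  p3 <- arbor_profile(c(12, 4, 3, 2), radii_um = c(20, 40, 60, 80),
                      aggregate_radius_um = 25)
  expect_true(p3$in_aggregate[1])
  expect_equal(attr(p3, "boundary_radius_um"), 40)

  expect_error(arbor_profile(c(0, 0, 0), radii_um = c(20, 40, 60),
                             aggregate_radius_um = 10), "no sprouts")
})

test_that("length distribution normalizes to control and hits ratio/zero cases", {
  mkprof <- function(counts, boundary_at = 2) {
    p <- arbor_profile(counts, radii_um = seq(20, by = 20,
                                              length.out = length(counts)),
                       aggregate_radius_um = 0)
    p
  }
  ctrl <- list(mkprof(c(40, 100, 80, 60, 20, 0)), mkprof(c(60, 120, 100, 60, 40, 0)))
  # control curve equals 1 at its own boundary by construction
  ld <- length_distribution(ctrl, ctrl)
  expect_equal(ld$control$mean_norm[1], 1.0)
  expect_equal(ld$normalization, 110)
  # a group with 40% fewer sprouts at every radius sits at 0.6x control
  low <- list(mkprof(c(24, 60, 48, 36, 12, 0)), mkprof(c(36, 72, 60, 36, 24, 0)))
  ld2 <- length_distribution(low, ctrl)
  expect_equal(ld2$group$mean_norm, 0.6 * ld2$control$mean_norm, tolerance = 1e-9)
  # beyond every sprout's extent the normalized value is zero
  expect_equal(tail(ld2$group$mean_norm, 1), 0)
  # mismatched radii grids are refused
  short <- list(mkprof(c(4, 10, 8, 6, 2)))
  expect_error(length_distribution(short, ctrl), "grids")
})

test_that("tip speed curve recovers programmed schedules", {
  # tips advancing radially at 5 um/h
  t <- 0:24
  tips <- do.call(rbind, lapply(1:6, function(i) {
    ang <- i
    data.frame(track_id = paste0("tip", i), t_hours = t,
               x_um = (90 + 5 * t) * cos(ang), y_um = (90 + 5 * t) * sin(ang))
  }))
  sc <- tip_speed_curve(track_set(tips))
  expect_equal(sc$mean, rep(5, nrow(sc)), tolerance = 1e-12)

  # stalled tips
  sc0 <- tip_speed_curve(track_set(stationary_df(duration_h = 24, dt_h = 1)))
  expect_equal(sc0$mean, rep(0, nrow(sc0)))

  # programmed slow-down 6 -> 3 um/h over 24 h recovered within 5%
  sched <- function(t) 6 - 3 * t / 24
  g <- generate_tracks(n_cells = 30, duration_h = 24, dt_h = 1,
                       persistence_time_h = Inf, speed_schedule = sched,
                       speed_sd_um_h = 0.15, seed = 31)
  sc2 <- tip_speed_curve(g$tracks)
  # chord speed over [t, t+1] matches the window-averaged schedule
  expected <- vapply(sc2$t_hours, function(t) (sched(t) + sched(t + 1)) / 2,
                     numeric(1))
  expect_true(all(abs(sc2$mean - expected) / expected < 0.05))
})
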
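# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's vectorized code paths: plain
# double loops over data frames.

# naive mean displacement at one lag: loop over every (track, time) pair
oracle_displacement <- function(df, lag_h, dt_h) {
  vals <- c()
  for (id in unique(df$track_id)) {
    d <- df[df$track_id == id, ]
    for (i in seq_len(nrow(d))) {
      j <- which(abs(d$t_hours - (d$t_hours[i] + lag_h)) < 1e-9)
      if (length(j) == 1) {
        vals <- c(vals, sqrt((d$x_um[j] - d$x_um[i])^2 + (d$y_um[j] - d$y_um[i])^2))
      }
    }
  }
  list(mean = mean(vals), n = length(vals),
       sem = sqrt(max(mean(vals^2) - mean(vals)^2, 0)) / sqrt(length(vals)))
}

# naive per-timepoint mean speed with lag tau0
oracle_speed <- function(df, tau0_h) {
  out <- list()
  for (t in sort(unique(df$t_hours))) {
    vals <- c()
    for (id in unique(df$track_id)) {
      d <- df[df$track_id == id, ]
      i <- which(abs(d$t_hours - t) < 1e-9)
      j <- which(abs(d$t_hours - (t + tau0_h)) < 1e-9)
      if (length(i) == 1 && length(j) == 1) {
        vals <- c(vals, sqrt((d$x_um[j] - d$x_um[i])^2 +
                             (d$y_um[j] - d$y_um[i])^2) / tau0_h)
      }
    }
    if (length(vals) > 0) out[[length(out) + 1]] <- data.frame(t_hours = t, mean = mean(vals))
  }
  do.call(rbind, out)
}

# straight-line mover fixture
ballistic_df <- function(n_cells = 3, v_um_h = 25, duration_h = 5, dt_h = 1 / 6) {
  t <- seq(0, duration_h, by = dt_h)
  do.call(rbind, lapply(seq_len(n_cells), function(i) {
    ang <- 2 * pi * i / n_cells
    data.frame(track_id = paste0("c", i), t_hours = t,
               x_um = 10 * i + v_um_h * t * cos(ang),
               y_um = 5 * i + v_um_h * t * sin(ang))
  }))
}

stationary_df <- function(n_cells = 4, duration_h = 3, dt_h = 0.5) {
  t <- seq(0, duration_h, by = dt_h)
  do.call(rbind, lapply(seq_len(n_cells), function(i) {
    data.frame(track_id = paste0("c", i), t_hours = t,
               x_um = 7 * i, y_um = 3 * i)
  }))
}

# textured disk on a smooth ramp: segmentation phantom with known mask
textured_disk_slice <- function(n = 300, radius_px = 100, seed = 1) {
  withr::with_seed(seed, {
    ramp <- matrix(rep(seq(0.4, 0.6, length.out = n), each = n), n, n)
    img <- ramp + matrix(rnorm(n * n, 0, 0.01), n, n)
    ctr <- (n + 1) / 2
    d2 <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
                function(r, c) r^2 + c^2)
    mask <- d2 <= radius_px^2
    img[mask] <- 0.5 + runif(sum(mask), -0.3, 0.3)
    list(slice = pmin(pmax(img, 0), 1), mask = mask)
  })
}

# axis-aligned bar phantom in an 865 x 650 um field at 1 um/px
bar_mask <- function(width_um = 10, length_um = 400, pixel_size_um = 1,
                     field_um = c(865, 650)) {
  nc <- round(field_um[1] / pixel_size_um)
  nr <- round(field_um[2] / pixel_size_um)
  m <- matrix(FALSE, nr, nc)
  r0 <- round(nr / 2)
  w <- round(width_um / pixel_size_um)
  l <- round(length_um / pixel_size_um)
  c0 <- round((nc - l) / 2)
  m[r0:(r0 + w - 1), c0:(c0 + l - 1)] <- TRUE
  m
}

# minimal radial-tube segment table for phantom volumes
radial_segments <- function(n, s = 90, e = 450, z0 = 120, slope = 0,
                            phi0 = 0.1) {
  data.frame(phi = phi0 + 2 * pi * (seq_len(n) - 1) / n,
             s = s, e = e, z0 = z0, slope = slope, parent = 0L)
}
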
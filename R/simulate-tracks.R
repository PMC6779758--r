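#' Simulate persistent-random-walk cell trajectories
#'
#' The generator emulates time-lapse tracking data: each cell performs a 2D
#' persistent random walk whose heading diffuses so that the directional
#' autocorrelation decays as exp(-t / persistence_time), while the per-step
#' path speed follows the programmed mean (optionally time-varying through
#' `speed_schedule`, optionally noisy through `speed_sd`). With
#' `persistence_time = Inf` the walk degenerates to straight-line (ballistic)
#' motion at exactly the programmed speed.
#'
#' @param n_cells number of cells.
#' @param duration_h recording span (h).
#' @param dt_h sampling interval (h); 10 min = 1/6 h for motility recordings,
#'   1 h for sprout-tip tracks.
#' @param speed_mean_um_h mean path speed (um/h).
#' @param persistence_time_h directional persistence time (h); default 8 h,
#'   reflecting the strongly persistent day-scale motion of endothelial cells.
#' @param speed_sd_um_h per-step speed standard deviation (um/h), default 0.
#' @param speed_schedule optional function of time (h) returning the mean
#'   speed at that time, overriding `speed_mean_um_h`.
#' @param field_um side of the square seeding field (um).
#' @param seed integer RNG seed; identical seeds give identical tracks.
#' @return List with `tracks` (a [track_set()]) and `ground_truth` (the
#'   configuration plus the per-step programmed speeds).
#' @export
generate_tracks <- function(n_cells = 50, duration_h = 24, dt_h = 1 / 6,
                            speed_mean_um_h = 11, persistence_time_h = 8,
                            speed_sd_um_h = 0, speed_schedule = NULL,
                            field_um = 500, seed = 1) {
  if (n_cells <= 0 || duration_h <= 0 || dt_h <= 0 || speed_mean_um_h < 0 ||
      persistence_time_h <= 0 || speed_sd_um_h < 0) {
    stop("all track simulation parameters must be positive")
  }
  n_steps <- round(duration_h / dt_h)
  if (abs(n_steps * dt_h - duration_h) > 1e-9) stop("dt_h must divide duration_h")
  withr::with_seed(seed, {
    t_grid <- (0:n_steps) * dt_h
    sched <- if (is.null(speed_schedule)) {
      rep(speed_mean_um_h, n_steps)
    } else {
      vapply(t_grid[-length(t_grid)], speed_schedule, numeric(1))
    }
    sigma_th <- if (is.finite(persistence_time_h)) {
      sqrt(2 * dt_h / persistence_time_h)
    } else 0
    parts <- lapply(seq_len(n_cells), function(i) {
      x <- numeric(n_steps + 1)
      y <- numeric(n_steps + 1)
      x[1] <- stats::runif(1, 0, field_um)
      y[1] <- stats::runif(1, 0, field_um)
      theta <- stats::runif(1, 0, 2 * pi)
      dth <- if (sigma_th > 0) stats::rnorm(n_steps, 0, sigma_th) else numeric(n_steps)
      sp <- sched
      if (speed_sd_um_h > 0) sp <- pmax(sp + stats::rnorm(n_steps, 0, speed_sd_um_h), 0)
      th <- theta + cumsum(c(0, dth))[seq_len(n_steps)]
      x[-1] <- x[1] + cumsum(sp * dt_h * cos(th))
      y[-1] <- y[1] + cumsum(sp * dt_h * sin(th))
      data.frame(track_id = sprintf("cell%03d", i), t_hours = t_grid,
                 x_um = x, y_um = y)
    })
    tracks <- track_set(do.call(rbind, parts), dt_hours = dt_h)
    list(tracks = tracks,
         ground_truth = list(speed_mean_um_h = speed_mean_um_h,
                             speed_schedule_um_h = sched,
                             t_steps_h = t_grid[-length(t_grid)],
                             persistence_time_h = persistence_time_h,
                             n_cells = n_cells, dt_h = dt_h,
                             duration_h = duration_h, seed = seed))
  })
}
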
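#' Average cell displacement versus time lag
#'
#' For each requested lag tau, computes the mean over all cells i and time
#' points t of the displacement magnitude |x_i(t + tau) - x_i(t)|, using every
#' (cell, time) pair for which both endpoints were observed (overlapping
#' windows). Pairs with a missing endpoint are skipped, never imputed. The
#' reported SEM is computed over the same pair population, from the population
#' variance; displacement pairs sharing a track are correlated, so this SEM is
#' an optimistic error estimate (see the methods vignette).
#'
#' @param tracks a [track_set()].
#' @param lags_hours numeric vector of lags in hours; each must be a positive
#'   multiple of the sampling interval.
#' @param rms if `TRUE`, report the root-mean-square displacement
#'   sqrt(mean |dx|^2) instead of the mean magnitude.
#' @return A data frame of class `lag_curve` with columns `lag_hours`, `mean`
#'   (um), `sem` (um), `n` (number of pairs). Lags with zero valid pairs are
#'   dropped with a warning.
#' @export
mean_displacement <- function(tracks, lags_hours, rms = FALSE) {
  stopifnot(inherits(tracks, "track_set"))
  if (nrow(tracks) == 0) stop("no tracks")
  m <- .track_matrices(tracks)
  steps <- lags_hours / m$dt
  bad <- abs(steps - round(steps)) > 1e-6 | lags_hours <= 0
  if (any(bad)) {
    stop("lag(s) not a positive multiple of dt = ", m$dt, " h: ",
         paste(format(lags_hours[bad]), collapse = ", "))
  }
  steps <- as.integer(round(steps))
  nt <- nrow(m$x)
  rows <- lapply(seq_along(steps), function(j) {
    k <- steps[j]
    if (k >= nt) return(NULL)
    i1 <- seq_len(nt - k)
    dx <- m$x[i1 + k, , drop = FALSE] - m$x[i1, , drop = FALSE]
    dy <- m$y[i1 + k, , drop = FALSE] - m$y[i1, , drop = FALSE]
    d <- sqrt(dx^2 + dy^2)
    d <- d[is.finite(d)]
    if (length(d) == 0) return(NULL)
    v <- if (rms) d^2 else d
    mu <- mean(v)
    data.frame(lag_hours = lags_hours[j],
               mean = if (rms) sqrt(mu) else mu,
               sem = .sem_pop(v),
               n = length(d))
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) {
    warning("lag(s) with no valid pairs dropped: ",
            paste(format(lags_hours[empty]), collapse = ", "))
  }
  if (all(empty)) stop("no valid displacement pairs for any requested lag")
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- NULL
  class(out) <- c("lag_curve", "data.frame")
  out
}

#' Time-dependent average cell speed
#'
#' At each time t, averages |x_i(t + tau0) - x_i(t)| / tau0 over the cells
#' observed at both endpoints (a chord speed over the lag window, the
#' convention used for published speed curves). Time points with no eligible
#' cell are absent from the curve.
#'
#' @param tracks a [track_set()].
#' @param tau0_hours lag in hours (default 1 h); must be a positive multiple
#'   of the sampling interval and not exceed the recording span.
#' @return A data frame of class `speed_curve` with columns `t_hours`, `mean`
#'   (um/h), `sem` (um/h), `n` (number of cells).
#' @export
mean_speed_timeseries <- function(tracks, tau0_hours = 1) {
  stopifnot(inherits(tracks, "track_set"))
  if (nrow(tracks) == 0) stop("no tracks")
  m <- .track_matrices(tracks)
  k <- tau0_hours / m$dt
  if (abs(k - round(k)) > 1e-6 || tau0_hours <= 0) {
    stop("tau0 = ", tau0_hours, " h is not a positive multiple of dt = ", m$dt, " h")
  }
  k <- as.integer(round(k))
  nt <- nrow(m$x)
  if (k >= nt) stop("tau0 = ", tau0_hours, " h exceeds the recording span")
  i1 <- seq_len(nt - k)
  dx <- m$x[i1 + k, , drop = FALSE] - m$x[i1, , drop = FALSE]
  dy <- m$y[i1 + k, , drop = FALSE] - m$y[i1, , drop = FALSE]
  sp <- sqrt(dx^2 + dy^2) / tau0_hours
  rows <- lapply(i1, function(i) {
    v <- sp[i, ]
    v <- v[is.finite(v)]
    if (length(v) == 0) return(NULL)
    data.frame(t_hours = m$grid[i], mean = mean(v), sem = .sem_pop(v),
               n = length(v))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no time point has an eligible cell")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("speed_curve", "data.frame")
  out
}

# population-variance SEM: sd_pop / sqrt(n)
.sem_pop <- function(v) {
  n <- length(v)
  sqrt(max(mean(v^2) - mean(v)^2, 0) / n)
}

#' Pool displacement or speed curves from independent experiments
#'
#' Merges the underlying pair/cell populations before averaging: the result is
#' the pooled mean and pooled SEM one would obtain from a single pass over the
#' concatenated data, not a mean of per-experiment means. All curves must be
#' on identical lag/time grids.
#'
#' @param curves list of `lag_curve` or `speed_curve` objects (all same type).
#' @return A pooled curve of the same class.
#' @export
pool_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  cls <- class(curves[[1]])[1]
  if (!cls %in% c("lag_curve", "speed_curve")) {
    stop("curves must be lag_curve or speed_curve objects")
  }
  gridcol <- if (cls == "lag_curve") "lag_hours" else "t_hours"
  g0 <- curves[[1]][[gridcol]]
  for (cu in curves[-1]) {
    if (!identical(class(cu)[1], cls)) stop("cannot pool curves of different types")
    g <- cu[[gridcol]]
    if (length(g) != length(g0) || any(abs(g - g0) > 1e-9)) {
      off <- if (length(g) != length(g0)) {
        union(setdiff(format(g), format(g0)), setdiff(format(g0), format(g)))
      } else {
        bad <- abs(g - g0) > 1e-9
        paste(format(g0[bad]), "vs", format(g[bad]))
      }
      stop("curve grids differ at: ", paste(off, collapse = ", "))
    }
  }
  # pooled moments from (mean, sem, n): population variance = sem^2 * n
  n_tot <- Reduce(`+`, lapply(curves, function(cu) cu$n))
  s1 <- Reduce(`+`, lapply(curves, function(cu) cu$n * cu$mean))
  s2 <- Reduce(`+`, lapply(curves, function(cu) cu$n * (cu$sem^2 * cu$n + cu$mean^2)))
  mu <- s1 / n_tot
  var_pop <- pmax(s2 / n_tot - mu^2, 0)
  out <- data.frame(g = g0, mean = mu, sem = sqrt(var_pop / n_tot), n = n_tot)
  names(out)[1] <- gridcol
  class(out) <- c(cls, "data.frame")
  out
}
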
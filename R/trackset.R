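#' Construct a track set
#'
#' A `track_set` holds per-cell (or per-sprout-tip) position time series on a
#' shared, uniformly spaced time grid. Positions are in micrometers, times in
#' hours. A cell need not be observed at every time point: entries that are
#' simply absent from the table (cell lost, or entering the field late) are
#' treated as missing and excluded pair-wise from all statistics.
#'
#' @param data data frame with columns `track_id`, `t_hours`, `x_um`, `y_um`
#'   (a `frame` column, if present, is ignored for computation).
#' @param dt_hours sampling interval in hours; if `NULL`, inferred from the
#'   time grid.
#' @param tol absolute tolerance (hours) for grid uniformity.
#' @return A data frame of class `track_set` with attributes `dt_hours` and
#'   `time_grid` (the full common grid in hours).
#' @export
track_set <- function(data, dt_hours = NULL, tol = 1e-9) {
  required <- c("track_id", "t_hours", "x_um", "y_um")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("track table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(data) == 0) stop("no tracks")
  if (!all(is.finite(data$x_um)) || !all(is.finite(data$y_um))) {
    stop("all present positions must be finite")
  }
  times <- sort(unique(data$t_hours))
  if (length(times) < 2) {
    if (is.null(dt_hours)) stop("cannot infer dt_hours from a single time point")
  } else {
    dts <- diff(times)
    dt_est <- min(dts)
    if (any(abs(dts / dt_est - round(dts / dt_est)) * dt_est > tol)) {
      stop("time points are not on a uniform grid")
    }
    if (is.null(dt_hours)) dt_hours <- dt_est
  }
  if (dt_hours <= 0) stop("dt_hours must be positive")
  # snap observed times onto the full grid and check consistency
  k <- (data$t_hours - times[1]) / dt_hours
  if (any(abs(k - round(k)) * dt_hours > tol)) {
    stop("observed times do not lie on the dt_hours grid")
  }
  grid <- times[1] + dt_hours * seq(0, round((max(times) - times[1]) / dt_hours))
  if (anyDuplicated(data[, c("track_id", "t_hours")])) {
    stop("duplicated (track_id, t_hours) observation")
  }
  out <- data.frame(track_id = data$track_id,
                    t_hours = data$t_hours,
                    x_um = data$x_um,
                    y_um = data$y_um,
                    stringsAsFactors = FALSE)
  out <- out[order(out$track_id, out$t_hours), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dt_hours") <- dt_hours
  attr(out, "time_grid") <- grid
  class(out) <- c("track_set", "data.frame")
  out
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d observations, dt = %g h, span %g h\n",
              length(unique(x$track_id)), nrow(x), attr(x, "dt_hours"),
              diff(range(attr(x, "time_grid")))))
  invisible(x)
}

# Internal: lay a track_set out as [time x track] matrices of x and y,
# with NA where an observation is absent.
.track_matrices <- function(tracks) {
  grid <- attr(tracks, "time_grid")
  dt <- attr(tracks, "dt_hours")
  ids <- unique(tracks$track_id)
  ti <- round((tracks$t_hours - grid[1]) / dt) + 1L
  ci <- match(tracks$track_id, ids)
  X <- matrix(NA_real_, nrow = length(grid), ncol = length(ids))
  Y <- X
  X[cbind(ti, ci)] <- tracks$x_um
  Y[cbind(ti, ci)] <- tracks$y_um
  list(x = X, y = Y, grid = grid, dt = dt, ids = ids)
}

#' Combine several track sets into one
#'
#' Tracks are re-labelled to stay unique across sets. All sets must share the
#' same sampling interval; time grids are merged.
#'
#' @param ... `track_set` objects.
#' @return A single `track_set`.
#' @export
combine_tracks <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "track_set")) {
    sets <- sets[[1]]
  }
  dts <- vapply(sets, function(s) attr(s, "dt_hours"), numeric(1))
  if (max(dts) - min(dts) > 1e-9) stop("track sets have different dt_hours")
  parts <- lapply(seq_along(sets), function(i) {
    d <- as.data.frame(sets[[i]])
    d$track_id <- paste0("set", i, ":", d$track_id)
    d
  })
  track_set(do.call(rbind, parts), dt_hours = dts[1])
}
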
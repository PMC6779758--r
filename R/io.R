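#' Read a track table from CSV
#'
#' Expected columns: `track_id,frame,t_hours,x_um,y_um` (comma separated,
#' '.' decimal, UTF-8, header mandatory; `frame` is carried but not used).
#'
#' @param path CSV file.
#' @param dt_hours optional sampling interval; inferred when `NULL`.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, dt_hours = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "t_hours", "x_um", "y_um")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("track CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  track_set(d, dt_hours = dt_hours)
}

#' Write a track table to CSV
#'
#' @param tracks a [track_set()].
#' @param path output CSV file.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  dt <- attr(tracks, "dt_hours")
  grid0 <- attr(tracks, "time_grid")[1]
  d <- data.frame(track_id = tracks$track_id,
                  frame = as.integer(round((tracks$t_hours - grid0) / dt)),
                  t_hours = tracks$t_hours,
                  x_um = tracks$x_um, y_um = tracks$y_um)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a displacement or speed curve to CSV
#'
#' Columns: the lag/time grid, `mean`, `sem`, `n`.
#' @param curve a `lag_curve` or `speed_curve`.
#' @param path output CSV file.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Physical calibration comes from the arguments (typically a sidecar JSON
#' config); TIFF resolution tags, when present and inconsistent with
#' `pixel_size_um`, raise a warning.
#'
#' @param path TIFF file.
#' @param pixel_size_um,dz_um,depth_of_field_um geometry in um.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um, dz_um = 20, depth_of_field_um = 10) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path, " (",
                                             conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of RGB pages
    info <- attr(p, "info")
    if (!is.null(info) && !is.null(info$x.resolution) && info$x.resolution > 0) {
      res_um <- 1 / info$x.resolution * 1e4  # TIFF res is per cm by default
      if (is.finite(res_um) && abs(res_um - pixel_size_um) / pixel_size_um > 0.05) {
        warning("TIFF resolution tag (", signif(res_um, 3),
                " um/px) disagrees with configured pixel size (",
                pixel_size_um, " um/px)")
      }
    }
    unclass(p)
  })
  image_stack(slices, pixel_size_um, dz_um, depth_of_field_um)
}

#' Write an image stack (or list of matrices) as a multi-page TIFF
#'
#' @param stack an [image_stack()] or list of numeric matrices in \code{[0,1]}.
#' @param path output TIFF file.
#' @export
write_stack <- function(stack, path) {
  slices <- if (inherits(stack, "image_stack")) stack$slices else stack
  tiff::writeTIFF(lapply(slices, function(s) pmin(pmax(s, 0), 1)), path,
                  bits.per.sample = 16)
  invisible(path)
}

# resolved-config provenance block written next to every run's outputs
.write_resolved_config <- function(config, out_dir, name = "resolved_config.json") {
  config$version <- as.character(utils::packageVersion("sproutquant"))
  payload <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                              digits = NA, null = "null")
  config$config_sha1 <- substr(digest_string(payload), 1, 12)
  jsonlite::write_json(config, file.path(out_dir, name), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(config)
}

# small polynomial rolling hash (hex) so runs can be matched to their configs
#' @keywords internal
digest_string <- function(x) {
  bytes <- utf8ToInt(x)
  h1 <- 5381; h2 <- 52711
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 2147483647
    h2 <- (h2 * 31 + b) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' Run the motility analysis on a track CSV
#'
#' Computes the displacement-versus-lag curve and the hourly-lag speed curve
#' and writes `displacement.csv`, `speed.csv` and the resolved configuration
#' into `out_dir`.
#'
#' @param tracks_csv input track CSV (see [read_tracks()]).
#' @param out_dir output directory (created if needed).
#' @param lags_hours displacement lags (h); default 10 min to 5 h.
#' @param tau0_hours speed lag (h), default 1.
#' @param dt_hours optional sampling interval override.
#' @return Invisible list with both curves.
#' @export
run_motility <- function(tracks_csv, out_dir, lags_hours = NULL, tau0_hours = 1,
                         dt_hours = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tracks <- read_tracks(tracks_csv, dt_hours = dt_hours)
  dt <- attr(tracks, "dt_hours")
  if (is.null(lags_hours)) {
    lags_hours <- seq(dt, min(5, diff(range(attr(tracks, "time_grid")))), by = dt)
  }
  disp <- mean_displacement(tracks, lags_hours)
  speed <- mean_speed_timeseries(tracks, tau0_hours)
  write_curve(disp, file.path(out_dir, "displacement.csv"))
  write_curve(speed, file.path(out_dir, "speed.csv"))
  .write_resolved_config(list(subcommand = "motility", tracks = tracks_csv,
                              dt_hours = dt, lags_hours = lags_hours,
                              tau0_hours = tau0_hours), out_dir)
  invisible(list(displacement = disp, speed = speed))
}

#' Run the sprout-arbor analysis on a z-stack TIFF
#'
#' @param stack_tiff multi-page TIFF of the arbor.
#' @param config list (or path to JSON) with `pixel_size_um`, `dz_um`,
#'   `depth_of_field_um`, and optional `center_px`, `aggregate_radius_um`,
#'   `radii_um` (`list(start, stop, step)`), `window_px`, `threshold`,
#'   `min_patch_px`.
#' @param out_dir output directory; receives `counts.csv`, `profile.json`,
#'   rolled-out cylinder surfaces as `surfaces.tif`, and the resolved config.
#' @return Invisible result of [analyze_arbor()].
#' @export
run_arbor <- function(stack_tiff, config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(list(dz_um = 20, depth_of_field_um = 10,
                                center_px = "auto", aggregate_radius_um = "auto",
                                radii_um = list(start = 20, stop = 560, step = 20),
                                window_px = 15, threshold = "auto",
                                min_patch_px = 4, min_size_px = 9), config)
  if (is.null(cfg$pixel_size_um)) stop("config must provide pixel_size_um")
  stack <- read_stack(stack_tiff, cfg$pixel_size_um, cfg$dz_um, cfg$depth_of_field_um)
  center <- if (identical(cfg$center_px, "auto")) "auto" else {
    c(x = cfg$center_px[1] * cfg$pixel_size_um, y = cfg$center_px[2] * cfg$pixel_size_um)
  }
  radii <- seq(cfg$radii_um$start, cfg$radii_um$stop, by = cfg$radii_um$step)
  res <- analyze_arbor(stack, center_um = center,
                       aggregate_radius_um = cfg$aggregate_radius_um,
                       radii_um = radii, window = cfg$window_px,
                       threshold = cfg$threshold, min_size_px = cfg$min_size_px,
                       min_patch_px = cfg$min_patch_px)
  utils::write.csv(data.frame(radius_um = res$profile$radius_um,
                              count = res$profile$count),
                   file.path(out_dir, "counts.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(boundary_radius_um = attr(res$profile, "boundary_radius_um"),
                            aggregate_radius_um = res$aggregate$radius_um,
                            center_um = as.list(res$aggregate$center_um)),
                       file.path(out_dir, "profile.json"), auto_unbox = TRUE,
                       digits = NA)
  # audit figure: rolled-out surfaces side by side, padded to the largest
  surfs <- lapply(res$maps, function(m) m$surface * 1)
  maxth <- max(vapply(surfs, nrow, integer(1)))
  panel <- do.call(cbind, lapply(surfs, function(s) {
    rbind(s, matrix(0, maxth - nrow(s), ncol(s)))
  }))
  write_stack(list(panel), file.path(out_dir, "surfaces.tif"))
  .write_resolved_config(c(list(subcommand = "arbor", stack = stack_tiff), cfg),
                         out_dir)
  invisible(res)
}

#' Compare sprout-length distributions of two groups of arbor analyses
#'
#' @param group_profiles,control_profiles lists of `arbor_profile` objects
#'   (e.g. from [analyze_arbor()] runs).
#' @param out_dir output directory; receives `length_distribution.csv`.
#' @return Invisible [length_distribution()] result.
#' @export
run_arbor_compare <- function(group_profiles, control_profiles, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ld <- length_distribution(group_profiles, control_profiles)
  both <- rbind(cbind(group = "group", ld$group),
                cbind(group = "control", ld$control))
  utils::write.csv(both, file.path(out_dir, "length_distribution.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(ld)
}

#' Run vessel morphometry on a fluorescence field image
#'
#' @param image_tiff single-page TIFF of a CD34-labelled field.
#' @param config list or JSON path with `pixel_size_um` and optional
#'   `threshold`, `min_object_um2`.
#' @param out_dir output directory; receives `vessel_stats.csv`.
#' @return Invisible `vessel_stats`.
#' @export
run_vessels <- function(image_tiff, config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(list(threshold = "auto", min_object_um2 = 50), config)
  img <- .read_single_tiff(image_tiff)
  mask <- vessel_mask(img, cfg$pixel_size_um, cfg$threshold, cfg$min_object_um2)
  st <- vessel_stats(mask, cfg$pixel_size_um)
  utils::write.csv(data.frame(field_id = basename(image_tiff),
                              density = st$density,
                              mean_width_um = st$mean_width_um,
                              total_length_um = st$total_length_um,
                              n_segments = st$n_segments),
                   file.path(out_dir, "vessel_stats.csv"), row.names = FALSE,
                   quote = FALSE)
  .write_resolved_config(c(list(subcommand = "vessels", image = image_tiff), cfg),
                         out_dir)
  invisible(st)
}

#' Run gelatin-digestion quantification on a fluorescence image
#'
#' @param image_tiff single-page TIFF of the gelatin substrate.
#' @param config list or JSON path with `pixel_size_um` and optional
#'   `threshold`, `min_object_um2`.
#' @param out_dir output directory; receives `digested.csv`.
#' @return Invisible digested fraction.
#' @export
run_gelatin <- function(image_tiff, config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(list(threshold = "auto", min_object_um2 = 20), config)
  img <- .read_single_tiff(image_tiff)
  frac <- digested_area_fraction(img, cfg$pixel_size_um, cfg$threshold,
                                 cfg$min_object_um2)
  utils::write.csv(data.frame(field_id = basename(image_tiff),
                              digested_fraction = frac),
                   file.path(out_dir, "digested.csv"), row.names = FALSE,
                   quote = FALSE)
  .write_resolved_config(c(list(subcommand = "gelatin", image = image_tiff), cfg),
                         out_dir)
  invisible(frac)
}

.read_single_tiff <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3) p <- p[, , 1]
  unclass(p)
}

#' Generate a synthetic dataset and write it with its ground truth
#'
#' Dispatches to the synthetic-data generators and serializes the dataset
#' (CSV for tracks, TIFF for images) with a `ground_truth.json` beside it.
#' All randomness flows from `seed`; identical seed and config give
#' byte-identical outputs.
#'
#' @param what one of `"tracks"`, `"arbor"`, `"vessels"`, `"gelatin"`.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param config named list of generator arguments (see [generate_tracks()],
#'   [generate_arbor()], [generate_vessel_field()], [generate_gelatin_field()]).
#' @return Invisible generator result.
#' @export
run_simulate <- function(what = c("tracks", "arbor", "vessels", "gelatin"),
                         out_dir, seed = 1, config = list()) {
  what <- match.arg(what)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt_path <- file.path(out_dir, "ground_truth.json")
  res <- switch(what,
    tracks = {
      r <- do.call(generate_tracks, c(config, list(seed = seed)))
      write_tracks(r$tracks, file.path(out_dir, "tracks.csv"))
      jsonlite::write_json(r$ground_truth, gt_path, auto_unbox = TRUE, digits = NA)
      r
    },
    arbor = {
      r <- do.call(generate_arbor, c(config, list(seed = seed)))
      write_stack(r$stack, file.path(out_dir, "stack.tif"))
      gt <- r$ground_truth
      gt$angles <- NULL
      jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
      r
    },
    vessels = {
      r <- do.call(generate_vessel_field, c(config, list(seed = seed)))
      write_stack(list(r$image), file.path(out_dir, "field.tif"))
      jsonlite::write_json(r$ground_truth, gt_path, auto_unbox = TRUE, digits = NA)
      r
    },
    gelatin = {
      r <- do.call(generate_gelatin_field, c(config, list(seed = seed)))
      write_stack(list(r$image), file.path(out_dir, "substrate.tif"))
      jsonlite::write_json(r$ground_truth, gt_path, auto_unbox = TRUE, digits = NA)
      r
    })
  .write_resolved_config(c(list(subcommand = "simulate", what = what,
                                seed = seed), config), out_dir)
  invisible(res)
}
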
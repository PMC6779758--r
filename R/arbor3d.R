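#' Construct an image stack
#'
#' An ordered series of 2D brightfield slices with physical calibration. Slice
#' `k` (0-based) sits at z = k * dz; structures within +/- depth_of_field / 2
#' of a slice's plane appear in focus. With dz = 20 um and ~10 um depth of
#' field (the acquisition used for sprout arbors) the sampling is gapped: half
#' of the axial extent is never in focus in any slice.
#'
#' @param slices list of numeric matrices, all the same shape.
#' @param pixel_size_um lateral pixel size (um/px).
#' @param dz_um slice spacing (um).
#' @param depth_of_field_um in-focus axial extent per slice (um).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, pixel_size_um, dz_um = 20, depth_of_field_um = 10) {
  stopifnot(is.list(slices), length(slices) >= 1)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all slices must have the same shape")
  }
  if (pixel_size_um <= 0 || dz_um <= 0 || depth_of_field_um <= 0) {
    stop("pixel_size_um, dz_um and depth_of_field_um must be positive")
  }
  structure(list(slices = slices, pixel_size_um = pixel_size_um,
                 dz_um = dz_um, depth_of_field_um = depth_of_field_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<image_stack> %d slices of %dx%d px, %g um/px, dz = %g um, dof = %g um\n",
              length(x$slices), d[1], d[2], x$pixel_size_um, x$dz_um,
              x$depth_of_field_um))
  invisible(x)
}

#' Reconstruct a binary voxel volume from a segmented z-stack
#'
#' Each slice is segmented by local intensity variance ([segment_slice()]);
#' every foreground pixel of slice k becomes one occupied voxel centred at
#' z = k * dz with axial extent equal to the depth of field and lateral extent
#' equal to the pixel size. Voxels are NOT stretched across the inter-slice
#' gap; downstream traversal counting merges patches across one-slice gaps
#' instead (see [count_sprouts()]).
#'
#' @param stack an [image_stack()].
#' @param window,threshold,min_size_px passed to [segment_slice()].
#' @return An object of class `binary_volume`: logical array `mask`
#'   (row, col, slice) plus the stack geometry.
#' @export
reconstruct_volume <- function(stack, window = 15, threshold = "auto",
                               min_size_px = 9) {
  stopifnot(inherits(stack, "image_stack"))
  if (identical(threshold, "auto")) {
    # one threshold for the whole stack: the optics are shared, and slices
    # with no in-focus structure carry no bimodality of their own
    vmaps <- lapply(stack$slices, local_variance_map, window = window)
    threshold <- exp(.otsu_values(log(unlist(vmaps) + 1e-12))) - 1e-12
    masks <- lapply(vmaps, function(v) .remove_small(v > threshold, min_size_px))
    if (!any(vapply(masks, any, logical(1)))) {
      warning("no in-focus structure detected; volume is empty")
    }
  } else {
    masks <- lapply(stack$slices, segment_slice, window = window,
                    threshold = threshold, min_size_px = min_size_px)
  }
  binary_volume(masks, stack$pixel_size_um, stack$dz_um, stack$depth_of_field_um)
}

# Otsu's between-class-variance threshold on a numeric vector
.otsu_values <- function(v, n_bins = 512) {
  rng <- range(v)
  if (diff(rng) < 1e-12) return(rng[2])
  h <- tabulate(pmin(as.integer((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  mt <- m1[n_bins]
  bcv <- (mt * w1 - m1)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Construct a binary volume from per-slice masks
#'
#' @param masks list of logical matrices (one per slice) or a 3D logical array.
#' @param pixel_size_um,dz_um,depth_of_field_um geometry in um.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(masks, pixel_size_um, dz_um = 20, depth_of_field_um = 10) {
  if (is.list(masks)) {
    arr <- array(FALSE, c(dim(masks[[1]]), length(masks)))
    for (k in seq_along(masks)) arr[, , k] <- masks[[k]]
  } else arr <- masks
  structure(list(mask = arr, pixel_size_um = pixel_size_um, dz_um = dz_um,
                 depth_of_field_um = depth_of_field_um),
            class = "binary_volume")
}

#' Locate the aggregate (spheroid body) in a reconstructed volume
#'
#' The aggregate appears as the largest connected in-focus component of the
#' middle slice. Its centre is taken at the maximum of the Euclidean distance
#' transform of that component and its radius as that maximal distance (the
#' largest inscribed circle), which is robust against sprouts attached to the
#' aggregate outline.
#'
#' @param volume a `binary_volume`.
#' @return List with `center_um` (x, y), `radius_um`, and `middle_slice`.
#' @export
detect_aggregate <- function(volume) {
  stopifnot(inherits(volume, "binary_volume"))
  k <- ceiling(dim(volume$mask)[3] / 2)
  m <- volume$mask[, , k]
  if (!any(m)) stop("no foreground in the middle slice; cannot locate aggregate")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  big <- which.max(tabulate(lab[lab > 0]))
  comp <- lab == big
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(comp * 1)))
  idx <- arrayInd(which.max(dm), dim(dm))
  px <- volume$pixel_size_um
  list(center_um = c(x = (idx[2] - 1) * px, y = (idx[1] - 1) * px),
       radius_um = max(dm) * px,
       middle_slice = k)
}

#' Sample concentric cylinder surfaces through a binary volume
#'
#' For each radius r, the cylinder x = center + (r cos(theta), r sin(theta))
#' (axis perpendicular to the slice plane) is sampled at arc increments of
#' `arc_step_um` over all z levels; a surface point is marked iff it falls
#' inside an occupied voxel. The rolled-out surface is a binary matrix with
#' the angular coordinate along rows (wrapping) and the slice index along
#' columns — the flattened-cylinder representation in which sprout traversals
#' appear as connected patches.
#'
#' @param volume a `binary_volume`.
#' @param center_um aggregate centre (x, y) in um.
#' @param radii_um increasing radii in um; default 20, 40, ..., 560.
#' @param arc_step_um angular sampling step in um of arc; default one pixel.
#' @return List of `cylinder_map` objects (`radius_um`, `surface`,
#'   `arc_step_um`, `truncated`).
#' @export
cylinder_traversals <- function(volume, center_um,
                                radii_um = seq(20, 560, by = 20),
                                arc_step_um = NULL) {
  stopifnot(inherits(volume, "binary_volume"))
  if (any(diff(radii_um) <= 0) || any(radii_um <= 0)) {
    stop("radii must be positive and increasing")
  }
  px <- volume$pixel_size_um
  if (is.null(arc_step_um)) arc_step_um <- px
  dims <- dim(volume$mask)
  nz <- dims[3]
  cx <- center_um[1]; cy <- center_um[2]
  if (cx < 0 || cy < 0 || cx > (dims[2] - 1) * px || cy > (dims[1] - 1) * px) {
    stop("center is outside the volume footprint")
  }
  any_trunc <- FALSE
  maps <- lapply(radii_um, function(r) {
    ntheta <- max(8L, as.integer(round(2 * pi * r / arc_step_um)))
    theta <- (seq_len(ntheta) - 1) * 2 * pi / ntheta
    col <- round((cx + r * cos(theta)) / px) + 1L
    row <- round((cy + r * sin(theta)) / px) + 1L
    inside <- row >= 1 & row <= dims[1] & col >= 1 & col <= dims[2]
    truncated <- !all(inside)
    if (truncated) any_trunc <<- TRUE
    surf <- matrix(FALSE, ntheta, nz)
    if (any(inside)) {
      ri <- row[inside]; ci <- col[inside]
      flat <- volume$mask
      dim(flat) <- c(dims[1] * dims[2], nz)
      surf[inside, ] <- flat[(ci - 1L) * dims[1] + ri, , drop = FALSE]
    }
    structure(list(radius_um = r, surface = surf,
                   arc_step_um = 2 * pi * r / ntheta, truncated = truncated),
              class = "cylinder_map")
  })
  if (any_trunc) warning("some cylinder radii extend beyond the volume footprint; surfaces truncated")
  maps
}

#' Count individual sprouts on a rolled-out cylinder surface
#'
#' Connected-component ("particle") counting on the flattened surface with
#' 8-connectivity; the angular axis wraps, so a patch split across the
#' theta = 0 seam is counted once. Because the axial sampling is gapped
#' (dz > depth of field), patches separated by exactly one empty slice column
#' are merged (`merge_z_gap = 1`) so that one sprout crossing between two
#' sampled planes is not counted twice. Components smaller than
#' `min_patch_px` are discarded as speckle.
#'
#' @param cmap a `cylinder_map` (or plain logical matrix, theta x z).
#' @param min_patch_px minimum patch area in surface samples; default 4.
#' @param merge_z_gap number of empty z columns tolerated inside one patch.
#' @return Integer sprout count.
#' @export
count_sprouts <- function(cmap, min_patch_px = 4, merge_z_gap = 1) {
  surf <- if (inherits(cmap, "cylinder_map")) cmap$surface else cmap
  stopifnot(is.matrix(surf), min_patch_px >= 1)
  fg <- which(surf)
  if (length(fg) == 0) return(0L)
  nth <- nrow(surf); nz <- ncol(surf)
  th <- (fg - 1L) %% nth          # 0-based angular index
  zz <- (fg - 1L) %/% nth         # 0-based slice index
  key <- th + nth * zz
  id <- seq_along(fg)
  lookup <- integer(nth * nz)
  lookup[key + 1L] <- id
  dz_off <- c(-(1L + merge_z_gap):(1L + merge_z_gap))
  edges_from <- integer(0); edges_to <- integer(0)
  for (dth in -1:1) {
    for (dzv in dz_off) {
      if (dth == 0 && dzv == 0) next
      nt <- (th + dth) %% nth
      nzv <- zz + dzv
      ok <- nzv >= 0 & nzv < nz
      if (!any(ok)) next
      nk <- nt[ok] + nth * nzv[ok]
      nb <- lookup[nk + 1L]
      hit <- nb > 0L
      edges_from <- c(edges_from, id[ok][hit])
      edges_to <- c(edges_to, nb[hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges_from) > 0) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  comp <- igraph::components(g)
  sizes <- comp$csize
  sum(sizes >= min_patch_px)
}

#' Radial sprout-traversal profile and zone boundary
#'
#' Assembles per-radius traversal counts into an arbor profile and locates the
#' boundary between the branching zone (dense, ramified growth near the
#' aggregate surface) and the elongation zone (radially extending sprouts):
#' the smallest radius outside the aggregate at which the traversal count is
#' maximal. Radii at or inside the aggregate radius are flagged as aggregate
#' interior and excluded from the zone logic.
#'
#' @param counts integer traversal counts, one per radius.
#' @param radii_um increasing radii (um).
#' @param aggregate_radius_um radius of the initial aggregate (um).
#' @return Data frame of class `arbor_profile` with columns `radius_um`,
#'   `count`, `in_aggregate`, and attributes `boundary_radius_um` and
#'   `aggregate_radius_um`.
#' @export
arbor_profile <- function(counts, radii_um = seq(20, 560, by = 20),
                          aggregate_radius_um = 0) {
  stopifnot(length(counts) == length(radii_um), aggregate_radius_um >= 0)
  if (any(diff(radii_um) <= 0)) stop("radii must be increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  in_agg <- radii_um <= aggregate_radius_um
  outside <- counts[!in_agg]
  if (length(outside) == 0 || all(outside == 0)) stop("no sprouts detected")
  boundary <- radii_um[!in_agg][which.max(outside)]  # smallest arg-max
  out <- data.frame(radius_um = radii_um, count = as.integer(round(counts)),
                    in_aggregate = in_agg)
  attr(out, "boundary_radius_um") <- boundary
  attr(out, "aggregate_radius_um") <- aggregate_radius_um
  class(out) <- c("arbor_profile", "data.frame")
  out
}

#' Full arbor analysis of one z-stack
#'
#' Convenience wrapper: segment, reconstruct, locate the aggregate, sample
#' cylinders, count sprouts per radius, and build the [arbor_profile()].
#'
#' @param stack an [image_stack()].
#' @param center_um aggregate centre (x, y um) or `"auto"`.
#' @param aggregate_radius_um aggregate radius (um) or `"auto"`.
#' @param radii_um analysis radii (um).
#' @param window,threshold,min_size_px segmentation parameters.
#' @param arc_step_um,min_patch_px cylinder sampling / particle parameters.
#' @return List with `profile`, `maps`, `volume`, `aggregate`.
#' @export
analyze_arbor <- function(stack, center_um = "auto", aggregate_radius_um = "auto",
                          radii_um = seq(20, 560, by = 20), window = 15,
                          threshold = "auto", min_size_px = 9,
                          arc_step_um = NULL, min_patch_px = 4) {
  vol <- reconstruct_volume(stack, window = window, threshold = threshold,
                            min_size_px = min_size_px)
  agg <- NULL
  if (identical(center_um, "auto") || identical(aggregate_radius_um, "auto")) {
    agg <- detect_aggregate(vol)
  }
  if (identical(center_um, "auto")) center_um <- agg$center_um
  if (identical(aggregate_radius_um, "auto")) aggregate_radius_um <- agg$radius_um
  maps <- cylinder_traversals(vol, center_um, radii_um, arc_step_um)
  counts <- vapply(maps, count_sprouts, integer(1), min_patch_px = min_patch_px)
  counts[radii_um <= aggregate_radius_um] <- 0L
  prof <- arbor_profile(counts, radii_um, aggregate_radius_um)
  list(profile = prof, maps = maps, volume = vol,
       aggregate = list(center_um = center_um,
                        radius_um = aggregate_radius_um))
}

#' Normalized sprout-length distribution of groups of aggregates
#'
#' For each aggregate the traversal counts are restricted to the sprout
#' elongation zone (radii at or beyond its own zone boundary) and re-expressed
#' against sprout length beyond the boundary. Group means are normalized by
#' the control group's average sprout count at its boundary (length 0), so the
#' control curve equals 1 at length 0 by construction. SEM stripes are over
#' aggregates.
#'
#' @param profiles list of `arbor_profile` for the test group.
#' @param control_profiles list of `arbor_profile` for the control group.
#' @return List with `group`, `control` (data frames `length_um`, `mean_norm`,
#'   `sem_norm`, `n`) and `normalization` (control mean count at boundary).
#' @export
length_distribution <- function(profiles, control_profiles) {
  stopifnot(length(control_profiles) >= 1, length(profiles) >= 1)
  grids <- lapply(c(profiles, control_profiles), function(p) p$radius_um)
  g0 <- grids[[1]]
  if (!all(vapply(grids, function(g) length(g) == length(g0) &&
                  all(abs(g - g0) < 1e-9), logical(1)))) {
    stop("profiles are not on identical radii grids")
  }
  step <- diff(g0)[1]
  counts_beyond <- function(p, len) {
    # traversal count at radius boundary + len; 0 beyond the measured grid
    b <- attr(p, "boundary_radius_um")
    r <- b + len
    i <- match(TRUE, abs(p$radius_um - r) < 1e-6)
    if (is.na(i)) 0 else p$count[i]
  }
  max_len <- max(g0) - min(vapply(c(profiles, control_profiles),
                                  attr, numeric(1), "boundary_radius_um"))
  lens <- seq(0, max_len, by = step)
  norm_const <- mean(vapply(control_profiles, counts_beyond, numeric(1), len = 0))
  if (norm_const <= 0) stop("zero normalization constant (control has no sprouts at its boundary)")
  curve <- function(group) {
    rows <- lapply(lens, function(len) {
      v <- vapply(group, counts_beyond, numeric(1), len = len) / norm_const
      data.frame(length_um = len, mean_norm = mean(v), sem_norm = .sem_pop(v),
                 n = length(v))
    })
    do.call(rbind, rows)
  }
  list(group = curve(profiles), control = curve(control_profiles),
       normalization = norm_const)
}

#' Average sprout-tip speed curve
#'
#' Sprout tips are tracked hourly; this delegates to
#' [mean_speed_timeseries()] with a one hour lag.
#'
#' @param tip_tracks a [track_set()] of sprout tip positions.
#' @param tau0_hours lag, default 1 h.
#' @return A `speed_curve`.
#' @export
tip_speed_curve <- function(tip_tracks, tau0_hours = 1) {
  mean_speed_timeseries(tip_tracks, tau0_hours = tau0_hours)
}
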
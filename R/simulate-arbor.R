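#' Simulate a sprouting aggregate rendered as a brightfield z-stack
#'
#' Generates a stylized three-dimensional sprout arbor with exact ground
#' truth: straight tubes radiate outward from a central spheroid aggregate,
#' new tubes ("branches") appear only inside the branching zone, and the whole
#' geometry is rendered as a gapped brightfield z-stack in which structures
#' inside a slice's depth-of-field window carry high-variance texture while
#' out-of-focus structures cast smooth defocused shading. The rendering
#' exercises the focus-variance segmentation; it is not an optics simulation.
#'
#' Radial extents and branch spawn radii are quantized to midpoints of the
#' 20 um analysis grid so that a tube either fully crosses an analysis
#' cylinder or stays clear of it, making the per-radius ground-truth crossing
#' count exact. Tubes are placed by rejection sampling with a minimum
#' angular-arc / axial clearance so that distinct sprouts remain resolvable as
#' separate patches on every cylinder surface, emulating the sparse arbors the
#' method is designed for. The number of branches spawned per radial shell is
#' the configured per-segment rate with stochastic rounding, so expected
#' counts scale exactly with the configured sprout numbers across groups.
#'
#' @param n_sprouts number of primary sprouts leaving the aggregate.
#' @param aggregate_radius_um radius of the central aggregate (um).
#' @param branching_zone_outer_um outer edge of the branching zone (um);
#'   branches appear only inside this radius.
#' @param max_radius_um maximal sprout extent (um).
#' @param branch_probability per-segment probability of spawning a branch in
#'   each 20 um radial shell of the branching zone.
#' @param tube_width_um sprout (tube) diameter in um.
#' @param pixel_size_um,dz_um,depth_of_field_um,n_slices stack geometry.
#' @param analysis_radii_um radii at which ground-truth crossings are
#'   bookkept; default 20, 40, ..., 560.
#' @param seed integer RNG seed.
#' @param keep_masks if `TRUE`, the exact in-focus footprint masks are
#'   returned in `ground_truth$focus_masks`.
#' @return List with `stack` (an [image_stack()]) and `ground_truth`:
#'   `segments` (one row per tube: azimuth, radial span, axial course),
#'   `per_radius` (`radius_um`, `count`, `in_aggregate`), `angles` (crossing
#'   azimuths per radius), `boundary_radius_um` (smallest radius of maximal
#'   count outside the aggregate), `center_um`, `aggregate_radius_um`.
#' @export
generate_arbor <- function(n_sprouts = 15, aggregate_radius_um = 90,
                           branching_zone_outer_um = 210, max_radius_um = 520,
                           branch_probability = 0.12, tube_width_um = 14,
                           pixel_size_um = 2, dz_um = 20, depth_of_field_um = 10,
                           n_slices = 14,
                           analysis_radii_um = seq(20, 560, by = 20),
                           seed = 1, keep_masks = FALSE) {
  if (!(aggregate_radius_um < branching_zone_outer_um &&
        branching_zone_outer_um < max_radius_um)) {
    stop("need aggregate_radius_um < branching_zone_outer_um < max_radius_um")
  }
  if (tube_width_um <= 0) stop("tube_width_um must be positive")
  if (n_sprouts < 0) stop("n_sprouts must be >= 0")
  geom <- list(pixel_size_um = pixel_size_um, dz_um = dz_um,
               depth_of_field_um = depth_of_field_um, n_slices = n_slices,
               tube_width_um = tube_width_um)
  half_um <- max(analysis_radii_um) + 40
  n_px <- 2L * as.integer(ceiling(half_um / pixel_size_um)) + 1L
  center_um <- c(x = (n_px - 1) / 2 * pixel_size_um,
                 y = (n_px - 1) / 2 * pixel_size_um)
  z_top <- (n_slices - 1) * dz_um
  z_band <- c(25, z_top - 25)             # keep tubes off the stack faces
  z_agg <- z_top / 2
  step <- 20
  mids <- function(lo, hi) {              # 20 um grid midpoints in (lo, hi)
    m <- seq(step / 2, max_radius_um + step, by = step)
    m[m > lo & m < hi]
  }
  withr::with_seed(seed, {
    segs <- data.frame(phi = numeric(0), s = numeric(0), e = numeric(0),
                       z0 = numeric(0), slope = numeric(0), parent = integer(0))
    ext_choices <- mids(branching_zone_outer_um + 40, max_radius_um + 1e-9)
    draw_slope <- function(z0, e, s) {
      # clamp so the tube stays inside the axial band
      lim <- 0.08
      span <- e - s
      lo <- max(-lim, (z_band[1] - z0) / span)
      hi <- min(lim, (z_band[2] - z0) / span)
      if (lo > hi) 0 else stats::runif(1, lo, hi)
    }
    arc_min <- tube_width_um + 20          # resolvability clearance (um of arc)
    # tubes that overlap in azimuth must sit >= 4 slice columns apart so the
    # gap-tolerant patch merging never bridges two distinct sprouts
    z_min_sep <- 4 * dz_um
    conflicts <- function(cand) {
      if (nrow(segs) == 0) return(FALSE)
      for (j in seq_len(nrow(segs))) {
        lo <- max(cand$s, segs$s[j]); hi <- min(cand$e, segs$e[j])
        if (lo >= hi) next
        rr <- seq(lo + 5, hi, by = 10)
        dphi <- abs(cand$phi - segs$phi[j]) %% (2 * pi)
        dphi <- min(dphi, 2 * pi - dphi)
        zc <- cand$z0 + cand$slope * (rr - cand$s)
        zj <- segs$z0[j] + segs$slope[j] * (rr - segs$s[j])
        if (any(rr * dphi < arc_min & abs(zc - zj) < z_min_sep)) return(TRUE)
      }
      FALSE
    }
    place <- function(make_candidate, tries = 40) {
      for (i in seq_len(tries)) {
        cand <- make_candidate()
        if (!conflicts(cand)) return(cand)
      }
      NULL
    }
    # primary sprouts leave the aggregate surface
    for (i in seq_len(n_sprouts)) {
      cand <- place(function() {
        z0 <- stats::runif(1, max(z_band[1], z_agg - aggregate_radius_um * 0.8),
                           min(z_band[2], z_agg + aggregate_radius_um * 0.8))
        e <- sample(ext_choices, 1)
        list(phi = stats::runif(1, 0, 2 * pi), s = aggregate_radius_um, e = e,
             z0 = z0, slope = draw_slope(z0, e, aggregate_radius_um))
      })
      if (!is.null(cand)) {
        segs <- rbind(segs, data.frame(phi = cand$phi, s = cand$s, e = cand$e,
                                       z0 = cand$z0, slope = cand$slope,
                                       parent = 0L))
      }
    }
    # branching: per 20 um shell of the branching zone, each live segment
    # branches at rate branch_probability (stochastically rounded count)
    for (rho in mids(aggregate_radius_um + step / 2, branching_zone_outer_um - step / 2 + 1e-9)) {
      alive <- which(segs$s < rho & segs$e > rho)
      if (length(alive) == 0) next
      m <- branch_probability * length(alive)
      n_new <- floor(m) + stats::rbinom(1, 1, m - floor(m))
      for (b in seq_len(n_new)) {
        par <- sample(alive, 1)
        cand <- place(function() {
          off <- sample(c(-1, 1), 1) * stats::runif(1, 15, 40) * pi / 180
          zp <- segs$z0[par] + segs$slope[par] * (rho - segs$s[par])
          z0 <- min(max(zp + stats::runif(1, -15, 15), z_band[1]), z_band[2])
          e <- sample(ext_choices, 1)
          list(phi = (segs$phi[par] + off) %% (2 * pi), s = rho, e = e,
               z0 = z0, slope = draw_slope(z0, e, rho))
        }, tries = 30)
        if (!is.null(cand)) {
          segs <- rbind(segs, data.frame(phi = cand$phi, s = cand$s, e = cand$e,
                                         z0 = cand$z0, slope = cand$slope,
                                         parent = par))
        }
      }
    }
    .assemble_arbor(segs, geom, n_px, center_um, z_agg, aggregate_radius_um,
                    branching_zone_outer_um, analysis_radii_um, n_sprouts,
                    seed, keep_masks)
  })
}

# build ground truth and rendered stack from a finished segment table;
# must be called inside an RNG scope (rendering draws noise)
.assemble_arbor <- function(segs, geom, n_px, center_um, z_agg,
                            aggregate_radius_um, branching_zone_outer_um,
                            analysis_radii_um, n_sprouts, seed, keep_masks) {
  in_agg <- analysis_radii_um <= aggregate_radius_um
  angles <- lapply(analysis_radii_um, function(r) {
    if (r <= aggregate_radius_um) return(numeric(0))
    sort(segs$phi[segs$s < r & segs$e > r])
  })
  counts <- vapply(angles, length, integer(1))
  boundary <- if (any(counts[!in_agg] > 0)) {
    analysis_radii_um[!in_agg][which.max(counts[!in_agg])]
  } else NA_real_
  masks <- .render_focus_masks(segs, geom, n_px, center_um, z_agg,
                               aggregate_radius_um)
  slices <- .render_arbor_slices(segs, geom, n_px, center_um, z_agg,
                                 aggregate_radius_um, masks)
  gt <- list(segments = segs,
             per_radius = data.frame(radius_um = analysis_radii_um,
                                     count = counts, in_aggregate = in_agg),
             angles = angles,
             boundary_radius_um = boundary,
             center_um = center_um,
             aggregate_radius_um = aggregate_radius_um,
             branching_zone_outer_um = branching_zone_outer_um,
             n_sprouts = n_sprouts, seed = seed,
             geom = geom, n_px = n_px, z_agg = z_agg,
             analysis_radii_um = analysis_radii_um)
  if (keep_masks) gt$focus_masks <- masks
  list(stack = image_stack(slices, geom$pixel_size_um, geom$dz_um,
                           geom$depth_of_field_um),
       ground_truth = gt)
}

#' Derive a sprout-thinned copy of a simulated arbor
#'
#' Deletes a fixed fraction of tubes from an existing simulated arbor,
#' stratified by origin (primary sprouts, and branches per spawn shell) with
#' stochastic rounding of the per-stratum deletion count, and re-renders the
#' stack. Because thinning operates on the matched geometry, the thinned
#' arbor carries the programmed fraction fewer sprouts at every radius —
#' emulating a perturbation that reduces sprout numbers without altering
#' individual sprout morphology.
#'
#' @param arbor result of [generate_arbor()].
#' @param fraction fraction of tubes to delete, in \code{[0, 1)}.
#' @param seed RNG seed for the deletion draw and re-rendering.
#' @param keep_masks as in [generate_arbor()].
#' @return Same structure as [generate_arbor()].
#' @export
thin_arbor <- function(arbor, fraction = 0.4, seed = 1, keep_masks = FALSE) {
  stopifnot(fraction >= 0, fraction < 1)
  gt <- arbor$ground_truth
  segs <- gt$segments
  withr::with_seed(seed, {
    keep <- rep(TRUE, nrow(segs))
    for (sv in unique(segs$s)) {
      idx <- which(segs$s == sv)
      m <- fraction * length(idx)
      ndel <- floor(m) + stats::rbinom(1, 1, m - floor(m))
      if (ndel > 0) keep[sample(idx, min(ndel, length(idx)))] <- FALSE
    }
    .assemble_arbor(segs[keep, , drop = FALSE], gt$geom, gt$n_px,
                    gt$center_um, gt$z_agg, gt$aggregate_radius_um,
                    gt$branching_zone_outer_um, gt$analysis_radii_um,
                    sum(keep & segs$s == min(segs$s)), seed, keep_masks)
  })
}

#' Ideal (noise-free) arbor volume from a tube segment table
#'
#' Builds the exact in-focus occupancy volume of a set of radial tube
#' segments, bypassing rendering and segmentation — useful for validating the
#' cylinder-sampling and particle-counting stages in isolation.
#'
#' @param segments data frame with columns `phi` (rad), `s`, `e` (radial span,
#'   um), `z0`, `slope` (axial course).
#' @param center_um (x, y) of the arbor axis in um.
#' @param n_px image side in pixels.
#' @param pixel_size_um,dz_um,depth_of_field_um,n_slices,tube_width_um geometry.
#' @return A `binary_volume`.
#' @export
arbor_volume_from_segments <- function(segments, center_um, n_px,
                                       pixel_size_um = 2, dz_um = 20,
                                       depth_of_field_um = 10, n_slices = 14,
                                       tube_width_um = 14) {
  geom <- list(pixel_size_um = pixel_size_um, dz_um = dz_um,
               depth_of_field_um = depth_of_field_um, n_slices = n_slices,
               tube_width_um = tube_width_um)
  masks <- .render_focus_masks(segments, geom, n_px, center_um,
                               z_agg = NA, aggregate_radius_um = 0)
  binary_volume(masks, pixel_size_um, dz_um, depth_of_field_um)
}

# disk-painting offset cache
.disk_offsets <- local({
  cache <- list()
  function(rad_px) {
    key <- as.character(rad_px)
    if (is.null(cache[[key]])) {
      d <- expand.grid(dr = -rad_px:rad_px, dc = -rad_px:rad_px)
      d <- d[d$dr^2 + d$dc^2 <= rad_px^2, ]
      cache[[key]] <<- d
    }
    cache[[key]]
  }
})

.paint_disks <- function(mask, rows, cols, rads_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_along(rows)) {
    off <- .disk_offsets(rads_px[i])
    r <- rows[i] + off$dr
    c <- cols[i] + off$dc
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    mask[cbind(r[ok], c[ok])] <- TRUE
  }
  mask
}

# exact in-focus footprints of tubes (+ aggregate sphere) per slice
.render_focus_masks <- function(segs, geom, n_px, center_um, z_agg,
                                aggregate_radius_um) {
  px <- geom$pixel_size_um
  half_w <- geom$tube_width_um / 2
  dof2 <- geom$depth_of_field_um / 2
  lapply(seq_len(geom$n_slices), function(k) {
    zk <- (k - 1) * geom$dz_um
    mask <- matrix(FALSE, n_px, n_px)
    if (aggregate_radius_um > 0 && is.finite(z_agg)) {
      gap <- max(0, abs(z_agg - zk) - dof2)
      if (gap < aggregate_radius_um) {
        rad <- sqrt(aggregate_radius_um^2 - gap^2)
        mask <- .paint_disks(mask, round(center_um["y"] / px) + 1L,
                             round(center_um["x"] / px) + 1L,
                             as.integer(round(rad / px)))
      }
    }
    if (nrow(segs) > 0) {
      for (j in seq_len(nrow(segs))) {
        # capsule trimmed by half a width so the painted object spans
        # exactly (s, e) radially, caps included
        if (segs$e[j] - segs$s[j] < geom$tube_width_um) next
        rho <- seq(segs$s[j] + half_w, segs$e[j] - half_w, by = 1.5)
        z <- segs$z0[j] + segs$slope[j] * (rho - segs$s[j])
        gap <- pmax(0, abs(z - zk) - dof2)
        vis <- gap < half_w
        if (!any(vis)) next
        rad_um <- sqrt(half_w^2 - gap[vis]^2)
        x <- center_um["x"] + rho[vis] * cos(segs$phi[j])
        y <- center_um["y"] + rho[vis] * sin(segs$phi[j])
        mask <- .paint_disks(mask, round(y / px) + 1L, round(x / px) + 1L,
                             pmax(1L, as.integer(round(rad_um / px))))
      }
    }
    mask
  })
}

# brightfield-style rendering: smooth background + defocused shading +
# high-variance texture on the in-focus footprints
.render_arbor_slices <- function(segs, geom, n_px, center_um, z_agg,
                                 aggregate_radius_um, focus_masks) {
  px <- geom$pixel_size_um
  half_w <- geom$tube_width_um / 2
  dof2 <- geom$depth_of_field_um / 2
  grad <- matrix(rep(seq(-0.04, 0.04, length.out = n_px), each = n_px),
                 n_px, n_px)
  lapply(seq_len(geom$n_slices), function(k) {
    zk <- (k - 1) * geom$dz_um
    img <- 0.55 + grad + matrix(stats::rnorm(n_px * n_px, 0, 0.01), n_px, n_px)
    shadow <- matrix(FALSE, n_px, n_px)
    if (aggregate_radius_um > 0 && is.finite(z_agg)) {
      gap <- max(0, abs(z_agg - zk) - dof2)
      if (gap >= aggregate_radius_um && gap < aggregate_radius_um + 60) {
        shadow <- .paint_disks(shadow, round(center_um["y"] / px) + 1L,
                               round(center_um["x"] / px) + 1L,
                               as.integer(round(aggregate_radius_um * 0.9 / px)))
      }
    }
    if (nrow(segs) > 0) {
      for (j in seq_len(nrow(segs))) {
        rho <- seq(segs$s[j], segs$e[j], by = 4)
        z <- segs$z0[j] + segs$slope[j] * (rho - segs$s[j])
        gap <- pmax(0, abs(z - zk) - dof2)
        oo <- gap >= half_w & gap < 30
        if (!any(oo)) next
        x <- center_um["x"] + rho[oo] * cos(segs$phi[j])
        y <- center_um["y"] + rho[oo] * sin(segs$phi[j])
        shadow <- .paint_disks(shadow, round(y / px) + 1L, round(x / px) + 1L,
                               as.integer(round((half_w + 0.5 * gap[oo]) / px)))
      }
    }
    if (any(shadow)) {
      # defocused structures must stay genuinely smooth: wide blur, shallow
      # depth, so their edges carry less local variance than the background
      sh <- EBImage::imageData(EBImage::gblur(EBImage::Image(shadow * 1), sigma = 6))
      img <- img - 0.10 * sh
    }
    fm <- focus_masks[[k]]
    nfg <- sum(fm)
    if (nfg > 0) img[fm] <- 0.5 + stats::runif(nfg, -0.28, 0.28)
    pmin(pmax(img, 0), 1)
  })
}
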
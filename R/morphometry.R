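#' Segment a fluorescence image of a vessel network
#'
#' Bright (labelled) vessels on a dark background: intensity threshold
#' (Otsu's between-class-variance criterion when `"auto"`), removal of small
#' foreground objects, and filling of small enclosed background holes.
#' Large enclosed background regions are genuine avascular gaps and are left
#' open; only speckle-sized holes are filled.
#'
#' @param image numeric intensity matrix.
#' @param pixel_size_um um per pixel.
#' @param threshold intensity threshold or `"auto"`.
#' @param min_object_um2 foreground objects smaller than this are removed.
#' @param max_hole_um2 enclosed background holes up to this area are filled.
#' @return Logical mask. An empty mask triggers a warning, not an error.
#' @export
vessel_mask <- function(image, pixel_size_um, threshold = "auto",
                        min_object_um2 = 50, max_hole_um2 = 50) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  if (identical(threshold, "auto")) threshold <- .otsu_threshold(image)
  mask <- image > threshold
  if (!any(mask)) {
    warning("empty vessel mask")
    return(mask)
  }
  apx <- pixel_size_um^2
  mask <- .remove_small(mask, ceiling(min_object_um2 / apx))
  .fill_small_holes(mask, ceiling(max_hole_um2 / apx))
}

.otsu_threshold <- function(image) {
  rng <- range(image)
  if (diff(rng) < 1e-12) return(rng[2])  # flat image: nothing above threshold
  u <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(u), range = c(0, 1))
  th * diff(rng) + rng[1]
}

# fill enclosed background components below max_hole pixels
.fill_small_holes <- function(mask, max_hole) {
  if (max_hole < 1) return(mask)
  bg <- !mask
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bg * 1)))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes <= max_hole), border_labels)
  if (length(fill) > 0) mask[matrix(lab %in% fill, nrow(lab), ncol(lab))] <- TRUE
  mask
}

#' Vessel morphometry of a binary mask
#'
#' Density is the foreground fraction (projected vessel area over total
#' area). Length and width come from the topological skeleton (Zhang-Suen
#' thinning) and the Euclidean distance transform:
#' total centerline length sums lateral steps as `pixel_size_um` and diagonal
#' steps as `pixel_size_um * sqrt(2)`, with short spurs pruned and each free
#' vessel end extended by its local radius (the medial axis retreats by one
#' radius at blunt ends); mean width is twice the mean distance-transform
#' value along the skeleton, excluding points near junctions and endpoints
#' where the distance transform is inflated or deflated.
#'
#' @param mask logical matrix.
#' @param pixel_size_um um per pixel.
#' @return List of class `vessel_stats`: `density`, `mean_width_um`
#'   (NA for an empty mask), `total_length_um`, `n_segments` (connected
#'   vessel components).
#' @export
vessel_stats <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size_um > 0)
  density <- mean(mask)
  if (!any(mask)) {
    return(structure(list(density = 0, mean_width_um = NA_real_,
                          total_length_um = 0, n_segments = 0L),
                     class = "vessel_stats"))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n_segments <- max(lab)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  skel <- skeletonize(mask)
  skel <- .prune_spurs(skel, dm)
  geom <- .skeleton_geometry(skel, dm)
  structure(list(
    density = density,
    mean_width_um = 2 * geom$mean_radius_px * pixel_size_um,
    total_length_um = (geom$length_px + geom$end_correction_px) * pixel_size_um,
    n_segments = as.integer(n_segments)
  ), class = "vessel_stats")
}

#' @export
print.vessel_stats <- function(x, ...) {
  cat(sprintf("<vessel_stats> density %.3f, width %.1f um, length %.0f um, %d segments\n",
              x$density, x$mean_width_um, x$total_length_um, x$n_segments))
  invisible(x)
}

#' Topological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels that do not break connectivity until the
#' mask is one pixel thin. Implemented here because no installed package
#' provides 2D thinning.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask
  m[] <- as.logical(m)
  # pad with background so neighbour shifts are simple
  nr <- nrow(m); nc <- ncol(m)
  M <- matrix(FALSE, nr + 2, nc + 2)
  M[2:(nr + 1), 2:(nc + 1)] <- m
  sh <- function(A, dr, dc) {
    A[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P2 <- sh(M, -1, 0); P3 <- sh(M, -1, 1); P4 <- sh(M, 0, 1)
      P5 <- sh(M, 1, 1);  P6 <- sh(M, 1, 0);  P7 <- sh(M, 1, -1)
      P8 <- sh(M, 0, -1); P9 <- sh(M, -1, -1)
      P1 <- M[2:(nr + 1), 2:(nc + 1)]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- matrix(0L, nr, nc)
      for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
      if (phase == 1) {
        c3 <- !(P2 & P4 & P6); c4 <- !(P4 & P6 & P8)
      } else {
        c3 <- !(P2 & P4 & P8); c4 <- !(P2 & P6 & P8)
      }
      del <- P1 & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) {
        changed <- TRUE
        sub <- M[2:(nr + 1), 2:(nc + 1)]
        sub[del] <- FALSE
        M[2:(nr + 1), 2:(nc + 1)] <- sub
      }
    }
    if (!changed) break
  }
  M[2:(nr + 1), 2:(nc + 1)]
}

# ---- skeleton graph helpers ---------------------------------------------

# neighbour degree map of a skeleton (8-connectivity)
.skel_degree <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  M <- matrix(0L, nr + 2, nc + 2)
  M[2:(nr + 1), 2:(nc + 1)] <- skel
  deg <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    deg <- deg + M[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
  }
  deg * skel
}

# remove terminal branches shorter than 1.5x the local radius at their
# junction; repeated twice to catch spurs revealed by the first pass
.prune_spurs <- function(skel, dm, factor = 1.5, passes = 2) {
  for (pass in seq_len(passes)) {
    deg <- .skel_degree(skel)
    ends <- which(skel & deg == 1)
    if (length(ends) == 0) return(skel)
    nr <- nrow(skel)
    nbr_off <- c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
    removed_any <- FALSE
    for (e in ends) {
      if (!skel[e]) next
      path <- e
      prev <- -1L
      cur <- e
      repeat {
        nbrs <- cur + nbr_off
        nbrs <- nbrs[nbrs >= 1 & nbrs <= length(skel)]
        # guard against wrap across matrix columns
        cr <- (cur - 1) %% nr
        nbrs <- nbrs[abs(((nbrs - 1) %% nr) - cr) <= 1]
        nbrs <- nbrs[skel[nbrs] & nbrs != prev & !(nbrs %in% path)]
        if (length(nbrs) != 1) break       # junction, end, or ambiguity
        nxt <- nbrs
        if (deg[nxt] >= 3) {               # reached a junction
          blen <- length(path)
          if (blen < factor * dm[nxt]) {
            skel[path] <- FALSE
            removed_any <- TRUE
          }
          break
        }
        path <- c(path, nxt)
        prev <- cur
        cur <- nxt
        if (length(path) > 10000) break
      }
    }
    if (!removed_any) break
  }
  skel
}

# centerline length (px units), endpoint radius correction, and mean radius
# along the skeleton away from junctions/endpoints
.skeleton_geometry <- function(skel, dm) {
  idx <- which(skel)
  if (length(idx) == 0) {
    return(list(length_px = 0, end_correction_px = 0, mean_radius_px = NA_real_))
  }
  nr <- nrow(skel); nc <- ncol(skel)
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  at <- function(dr, dc) {
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    hit <- logical(length(idx))
    hit[ok] <- skel[cbind(r2[ok], c2[ok])]
    hit
  }
  # lateral edges counted once (east, south)
  n_lat <- sum(at(0, 1)) + sum(at(1, 0))
  # diagonal edges (SE, SW), skipped when a lateral 2-step path exists
  se <- at(1, 1) & !(at(0, 1) | at(1, 0))
  sw <- at(1, -1) & !(at(0, -1) | at(1, 0))
  n_diag <- sum(se) + sum(sw)
  length_px <- n_lat + sqrt(2) * n_diag
  deg <- .skel_degree(skel)
  ends <- which(skel & deg <= 1)
  end_correction <- sum(dm[ends])
  # width sampling: exclude points within (local radius + 1) of any special
  # point (endpoint or junction), where the distance transform is biased
  special <- which(skel & (deg != 2))
  keep <- rep(TRUE, length(idx))
  if (length(special) > 0) {
    sr <- (special - 1) %% nr + 1
    sc <- (special - 1) %/% nr + 1
    for (i in seq_along(special)) {
      rad <- dm[special[i]] + 1
      d2 <- (rr - sr[i])^2 + (cc - sc[i])^2
      keep[d2 <= rad^2] <- FALSE
    }
  }
  radii <- dm[idx[keep]]
  mean_radius <- if (length(radii) > 0) mean(radii) else mean(dm[idx])
  list(length_px = length_px, end_correction_px = end_correction,
       mean_radius_px = mean_radius)
}

#' Fraction of gelatin substrate digested
#'
#' Proteolytic cleavage of a fluorescent gelatin substrate appears as a
#' localized loss of fluorescence: digested regions are dark. The digested
#' fraction is the share of pixels below the threshold, after removal of
#' speckle-sized dark objects.
#'
#' @param image numeric intensity matrix.
#' @param pixel_size_um um per pixel.
#' @param threshold intensity threshold or `"auto"` (Otsu).
#' @param min_object_um2 dark objects smaller than this are ignored.
#' @return Fraction in \code{[0, 1]}.
#' @export
digested_area_fraction <- function(image, pixel_size_um, threshold = "auto",
                                   min_object_um2 = 20) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  if (identical(threshold, "auto")) threshold <- .otsu_threshold(image)
  dark <- image < threshold
  if (!any(dark)) return(0)
  dark <- .remove_small(dark, ceiling(min_object_um2 / pixel_size_um^2))
  mean(dark)
}
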
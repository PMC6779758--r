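#' Simulate a chorion-like vessel network field
#'
#' Paints randomly oriented thick segments ("vessel" bars of programmed width)
#' onto a field until the programmed density (projected vessel area fraction)
#' is reached, then renders a fluorescence-like image: bright vessels on a dim
#' background, slight optical blur, additive noise. The exact painted mask and
#' its achieved density are the ground truth.
#'
#' @param density target vessel area fraction in (0, 1].
#' @param field_um field size (width, height) in um; default the 865 x 650 um
#'   microscopic field.
#' @param pixel_size_um um per pixel.
#' @param width_range_um vessel width range (um).
#' @param length_range_um vessel segment length range (um).
#' @param seed RNG seed.
#' @return List with `image` (matrix), `mask` (logical ground-truth mask) and
#'   `ground_truth` (`density`, the achieved fraction).
#' @export
generate_vessel_field <- function(density = 0.75, field_um = c(865, 650),
                                  pixel_size_um = 1,
                                  width_range_um = c(8, 30),
                                  length_range_um = c(80, 300), seed = 1) {
  if (density < 0 || density > 1) stop("target density must be in [0, 1]")
  nc <- round(field_um[1] / pixel_size_um)
  nr <- round(field_um[2] / pixel_size_um)
  withr::with_seed(seed, {
    mask <- matrix(FALSE, nr, nc)
    while (mean(mask) < density) {
      x0 <- stats::runif(1, 0, nc); y0 <- stats::runif(1, 0, nr)
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, length_range_um[1], length_range_um[2]) / pixel_size_um
      hw <- stats::runif(1, width_range_um[1], width_range_um[2]) / 2 / pixel_size_um
      mask <- mask | .thick_segment_mask(nr, nc, x0, y0, ang, len, hw)
    }
    img <- 0.2 + 0.6 * mask
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = 0.8))
    img <- img + matrix(stats::rnorm(nr * nc, 0, 0.03), nr, nc)
    list(image = pmin(pmax(img, 0), 1), mask = mask,
         ground_truth = list(density = mean(mask), seed = seed,
                             pixel_size_um = pixel_size_um))
  })
}

# pixels within hw of the segment (x0,y0)->(x0+len*cos, y0+len*sin), px units
.thick_segment_mask <- function(nr, nc, x0, y0, ang, len, hw) {
  dx <- cos(ang); dy <- sin(ang)
  x1 <- x0 + len * dx; y1 <- y0 + len * dy
  pad <- ceiling(hw) + 1
  cmin <- max(1, floor(min(x0, x1)) - pad); cmax <- min(nc, ceiling(max(x0, x1)) + pad)
  rmin <- max(1, floor(min(y0, y1)) - pad); rmax <- min(nr, ceiling(max(y0, y1)) + pad)
  if (cmin > cmax || rmin > rmax) return(matrix(FALSE, nr, nc))
  cs <- cmin:cmax; rs <- rmin:rmax
  X <- matrix(rep(cs, each = length(rs)), length(rs))
  Y <- matrix(rep(rs, length(cs)), length(rs))
  t <- ((X - x0) * dx + (Y - y0) * dy)
  t <- pmin(pmax(t, 0), len)
  d2 <- (X - (x0 + t * dx))^2 + (Y - (y0 + t * dy))^2
  m <- matrix(FALSE, nr, nc)
  m[rs, cs] <- d2 <= hw^2
  m
}

#' Simulate a gelatin degradation substrate image
#'
#' A uniformly bright fluorescent substrate with dark circular digested
#' patches of programmed total area fraction. Patches are placed without
#' overlap; the last patch radius is chosen to hit the target area exactly
#' (in continuous coordinates), so the ground-truth fraction is the target up
#' to pixel discretization.
#'
#' @param digested_fraction target fraction of the field area digested.
#' @param field_um field size (width, height) in um.
#' @param pixel_size_um um per pixel.
#' @param patch_radius_range_um radii of digested patches (um).
#' @param seed RNG seed.
#' @return List with `image`, `mask` (digested ground truth) and
#'   `ground_truth` (`digested_fraction` of the discretized mask).
#' @export
generate_gelatin_field <- function(digested_fraction = 0.10,
                                   field_um = c(865, 650), pixel_size_um = 1,
                                   patch_radius_range_um = c(12, 35), seed = 1) {
  if (digested_fraction < 0 || digested_fraction > 0.8) {
    stop("digested_fraction must be in [0, 0.8]")
  }
  nc <- round(field_um[1] / pixel_size_um)
  nr <- round(field_um[2] / pixel_size_um)
  area_target <- digested_fraction * nr * nc
  withr::with_seed(seed, {
    mask <- matrix(FALSE, nr, nc)
    placed <- matrix(numeric(0), ncol = 3)  # (row, col, rad) in px
    remaining <- area_target
    guard <- 0
    while (remaining > 1 && guard < 10000) {
      guard <- guard + 1
      rad <- stats::runif(1, patch_radius_range_um[1], patch_radius_range_um[2]) /
        pixel_size_um
      if (pi * rad^2 > remaining) rad <- sqrt(remaining / pi)
      r0 <- stats::runif(1, rad + 2, nr - rad - 2)
      c0 <- stats::runif(1, rad + 2, nc - rad - 2)
      if (nrow(placed) > 0) {
        d <- sqrt((placed[, 1] - r0)^2 + (placed[, 2] - c0)^2)
        if (any(d < placed[, 3] + rad + 3)) next
      }
      mask <- .paint_disks(mask, round(r0), round(c0), as.integer(round(rad)))
      placed <- rbind(placed, c(r0, c0, rad))
      remaining <- area_target - sum(mask)
    }
    img <- 0.8 - 0.6 * mask
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = 0.7))
    img <- img + matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    list(image = pmin(pmax(img, 0), 1), mask = mask,
         ground_truth = list(digested_fraction = mean(mask), seed = seed,
                             pixel_size_um = pixel_size_um))
  })
}
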
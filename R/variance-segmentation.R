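#' Local intensity variance map
#'
#' Per-pixel population variance of intensities in a square window, the focus
#' measure used to separate in-focus (textured, high-variance) from
#' out-of-focus (smooth, low-variance) structures in brightfield slices.
#' Borders are handled by reflection (symmetric padding, edge pixel
#' duplicated). Computed exactly with summed-area tables.
#'
#' @param slice numeric matrix of intensities.
#' @param window odd window side length in pixels, >= 3.
#' @return Matrix of the same shape; non-negative everywhere.
#' @export
local_variance_map <- function(slice, window = 15) {
  stopifnot(is.matrix(slice))
  if (!all(is.finite(slice))) stop("slice contains non-finite values")
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  p <- (window - 1L) / 2L
  padded <- .reflect_pad(slice, p)
  s1 <- .box_sum(padded, window)
  s2 <- .box_sum(padded^2, window)
  v <- s2 / window^2 - (s1 / window^2)^2
  v[v < 0] <- 0
  v
}

.reflect_pad <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  if (p >= nr || p >= nc) stop("window too large for slice")
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  m[ri, ci, drop = FALSE]
}

# sum over window x window boxes of a padded matrix; returns matrix of the
# unpadded shape, one box sum per original pixel (summed-area table)
.box_sum <- function(padded, window) {
  cs <- apply(padded, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  I <- matrix(0, nrow(padded) + 1, ncol(padded) + 1)
  I[-1, -1] <- cs
  nr <- nrow(padded) - window + 1
  nc <- ncol(padded) - window + 1
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  I[r1 + window, c1 + window, drop = FALSE] -
    I[r1, c1 + window, drop = FALSE] -
    I[r1 + window, c1, drop = FALSE] +
    I[r1, c1, drop = FALSE]
}

#' Segment one slice by local intensity variance
#'
#' Thresholds the local-variance map and removes small connected components.
#' With `threshold = "auto"` the threshold is chosen by Otsu's between-class
#' variance criterion applied to the log-variance map, which is close to
#' bimodal when both smooth background and textured in-focus structure are
#' present.
#'
#' @param slice numeric matrix.
#' @param window odd variance window (px), default 15.
#' @param threshold numeric variance threshold, or `"auto"`.
#' @param min_size_px connected components (8-connectivity) smaller than this
#'   are removed. Default 9.
#' @return Logical matrix (foreground = in focus). An all-background result is
#'   returned with a warning, not an error.
#' @export
segment_slice <- function(slice, window = 15, threshold = "auto", min_size_px = 9) {
  v <- local_variance_map(slice, window)
  if (identical(threshold, "auto")) {
    lv <- log(v + 1e-12)
    rng <- range(lv)
    if (diff(rng) < 1e-6) {
      warning("variance map is flat; returning empty mask")
      return(matrix(FALSE, nrow(slice), ncol(slice)))
    }
    u <- (lv - rng[1]) / diff(rng)
    th_u <- EBImage::otsu(EBImage::Image(u), range = c(0, 1))
    threshold <- exp(th_u * diff(rng) + rng[1]) - 1e-12
  }
  mask <- v > threshold
  if (!any(mask)) {
    warning("empty mask after variance thresholding")
    return(mask)
  }
  .remove_small(mask, min_size_px)
}

# drop 8-connected foreground components below min_size pixels
.remove_small <- function(mask, min_size) {
  if (min_size <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
}
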
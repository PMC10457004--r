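#' Label connected pixel components
#'
#' Breadth-first labeling of TRUE pixels of a logical matrix under 8- (or
#' 4-) connectivity.
#'
#' @param bin logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(bin, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  nextlab <- 0L
  todo <- which(bin)
  for (start in todo) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- (p - 1L) %% nr + 1L
      c0 <- (p - 1L) %/% nr + 1L
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[bin[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Extract candidate regions of interest from a reconstructed image
#'
#' Thresholds the image at |value| >= threshold x Amax (boundary inclusive;
#' default 62.5% of Amax) and groups the surviving pixels into connected
#' components. An all-zero image (Amax = 0) yields no candidates.
#'
#' @param image an [EITImage-class].
#' @param threshold fraction of Amax; default 0.625.
#' @param connectivity component connectivity, 8 (default) or 4.
#' @return a list of integer matrices (n_pixels x 2, columns row/col), one
#'   per candidate component.
#' @export
extractCandidateROIs <- function(image, threshold = 0.625,
                                 connectivity = 8L) {
  a <- amax(image)
  if (a <= 0) return(list())
  v <- imageValues(image)
  bin <- !is.na(v) & abs(v) >= threshold * a - 1e-12 * a
  lab <- labelComponents(bin, connectivity)
  n <- max(lab)
  lapply(seq_len(n), function(k) which(lab == k, arr.ind = TRUE))
}

## in-mask pixels 8-adjacent to an out-of-mask pixel (or the image edge)
maskBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      out <- out | !pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
    }
  }
  out & mask
}

## image-side of pixel columns: "left"/"right"/"axis"
pixelSide <- function(col, grid) {
  if (grid %% 2L == 0L) {
    ifelse(col <= grid %/% 2L, "left", "right")
  } else {
    mid <- (grid + 1L) %/% 2L
    ifelse(col == mid, "axis", ifelse(col < mid, "left", "right"))
  }
}

## barycenter of a pixel set in the GAI coordinate frame, pixel units:
## origin at the intersection of the vertical symmetry axis and the lowest
## point of the circle; returns c(dist to Y axis, height above the bottom)
gaiBarycenter <- function(pixels, grid) {
  x <- (pixels[, 2L] - 0.5) * 2 / grid - 1   # unit coords
  y <- 1 - (pixels[, 1L] - 0.5) * 2 / grid
  c(dist_y_axis = mean(abs(x)) * grid / 2,
    height = mean(y + 1) * grid / 2)
}

#' Filter candidate components down to effective ROIs
#'
#' Excludes, in order: components touching the imaging boundary (any pixel
#' 8-adjacent to an out-of-mask pixel), components crossed by the vertical
#' symmetry axis (pixels on both image sides; on odd grids the center column
#' itself counts as crossing), and small targets whose pixel count is below
#' \code{min_area_frac} (default 0.85%) of the in-mask pixel count.
#' Survivors are labeled with their image side, area, barycenter in the
#' GAI coordinate frame (pixel units) and mean absolute value.
#'
#' @param components output of [extractCandidateROIs()].
#' @param image the [EITImage-class] they came from.
#' @param min_area_frac small-target threshold as a fraction of the domain
#'   pixel count; default 0.0085.
#' @return a list of ROI records: each a list with \code{pixels} (n x 2
#'   matrix), \code{side} ("left"/"right", image coordinates),
#'   \code{area_px}, \code{barycenter} (dist_y_axis, height) and
#'   \code{mean_abs_value}.
#' @export
filterEffectiveROIs <- function(components, image, min_area_frac = 0.0085) {
  mask <- imageMask(image)
  v <- imageValues(image)
  g <- nrow(mask)
  rim <- maskBoundary(mask)
  domain_px <- sum(mask)
  out <- list()
  for (px in components) {
    if (any(rim[px])) next                       # boundary contact
    sides <- pixelSide(px[, 2L], g)
    us <- unique(sides)
    if ("axis" %in% us || length(us) > 1L) next  # crossed by the axis
    if (nrow(px) / domain_px < min_area_frac) next  # small target
    out[[length(out) + 1L]] <- list(
      pixels = px,
      side = us,
      area_px = nrow(px),
      barycenter = gaiBarycenter(px, g),
      mean_abs_value = mean(abs(v[px])))
  }
  out
}

## mirror a pixel set across the vertical axis (even grids: exact)
mirrorPixels <- function(pixels, grid) {
  cbind(pixels[, 1L], grid + 1L - pixels[, 2L], deparse.level = 0L)
}

#' Per-side area-ratio and signal-intensity features
#'
#' AR_ROI of a side is the total pixel count of that side's effective ROIs
#' divided by the in-mask pixel count (0 when the side has none). MVRRC (the
#' side's signal intensity) is the mean absolute value over the single
#' effective ROI on that side containing the side's maximum-|value|
#' effective-ROI pixel; when the side has no effective ROI, the footprint of
#' the opposite side's maximum-value ROI is mirrored across the axis and the
#' mean |value| inside the mirrored outline is used instead
#' (\code{mirrored_fallback = TRUE}); when neither side has an effective
#' ROI, the intensity is 0.
#'
#' @param image an [EITImage-class].
#' @param effective_rois output of [filterEffectiveROIs()].
#' @param side "left" or "right" (image coordinates).
#' @return a list with \code{ar_roi} (fraction in \[0, 1\]), \code{mvrrc},
#'   \code{mirrored_fallback} and \code{n_effective_rois} (on that side).
#' @export
sideFeatures <- function(image, effective_rois, side) {
  stopifnot(side %in% c("left", "right"))
  v <- imageValues(image)
  g <- nrow(v)
  domain_px <- sum(imageMask(image))
  mine <- Filter(function(r) r$side == side, effective_rois)
  other <- Filter(function(r) r$side != side, effective_rois)
  ar <- sum(vapply(mine, function(r) r$area_px, 1)) / domain_px

  maxRoi <- function(rois) {
    peaks <- vapply(rois, function(r) max(abs(v[r$pixels])), 1)
    rois[[which.max(peaks)]]
  }
  if (length(mine)) {
    mvrrc <- maxRoi(mine)$mean_abs_value
    fallback <- FALSE
  } else if (length(other)) {
    foot <- mirrorPixels(maxRoi(other)$pixels, g)
    vals <- v[foot]
    if (all(is.na(vals)))
      stop("mirrored ROI footprint lies entirely outside the mask")
    mvrrc <- mean(abs(vals), na.rm = TRUE)
    fallback <- TRUE
  } else {
    mvrrc <- 0
    fallback <- FALSE
  }
  list(ar_roi = ar, mvrrc = mvrrc, mirrored_fallback = fallback,
       n_effective_rois = length(mine))
}
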
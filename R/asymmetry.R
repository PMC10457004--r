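## one GAI term: 2|a-b|/(a+b), with the degenerate a=b=0 case counted as
## perfectly symmetric (0)
gaiTerm <- function(a, b) {
  if (a + b <= 0) return(0)
  2 * abs(a - b) / (a + b)
}

#' Geometric asymmetry index (GAI) of the effective ROIs
#'
#' For one effective ROI per side, with barycenter coordinates in the frame
#' whose origin is the intersection of the vertical symmetry axis and the
#' lower arc of the imaging circle (Lx/Rx = height above the bottom =
#' distance to the X-axis; Ly/Ry = horizontal distance to the Y-axis):
#'
#' GAI = 0.5 * ( 2|Lx - Rx| / (Lx + Rx) + 2|Ly - Ry| / (Ly + Ry) ) * 100%.
#'
#' When several ROIs lie on a side, the index is the mean of the pairwise
#' GAI over every cross-side pair. When exactly one side has ROIs the
#' configuration is "not symmetrical" (NS). When neither side has an ROI the
#' index is undefined (NA, excluded from statistics).
#'
#' @param left_rois,right_rois lists of ROI records (see
#'   [filterEffectiveROIs()]) for the image-left and image-right sides.
#' @return a list with \code{value} (percent in \[0, 200\], or NA) and
#'   \code{ns} (logical).
#' @export
gai <- function(left_rois, right_rois) {
  nl <- length(left_rois); nr <- length(right_rois)
  if (nl == 0L && nr == 0L) return(list(value = NA_real_, ns = FALSE))
  if (nl == 0L || nr == 0L) return(list(value = NA_real_, ns = TRUE))
  vals <- numeric(0)
  for (L in left_rois) {
    for (R in right_rois) {
      bl <- L$barycenter; br <- R$barycenter
      if (any(bl < 0) || any(br < 0))
        stop("barycenter distances must be non-negative")
      vals <- c(vals, 0.5 * (gaiTerm(bl[["height"]], br[["height"]]) +
                             gaiTerm(bl[["dist_y_axis"]], br[["dist_y_axis"]])) * 100)
    }
  }
  list(value = mean(vals), ns = FALSE)
}

#' Intensity asymmetry index (IAI) of the effective ROIs
#'
#' For each effective ROI (either side), I_ROI is its mean absolute
#' reconstructed resistivity change and I_contralateral the mean absolute
#' value over its mirror-reflected footprint (raw pixel values, no
#' thresholding). Per ROI,
#'
#' IAI = 2 * |I_ROI - I_contralateral| / (I_ROI + I_contralateral) * 100%,
#'
#' and the reported index is the mean over all effective ROIs. NA when there
#' are none.
#'
#' @param image an [EITImage-class].
#' @param effective_rois output of [filterEffectiveROIs()].
#' @return percent in \[0, 200\], or NA.
#' @export
iai <- function(image, effective_rois) {
  if (!length(effective_rois)) return(NA_real_)
  v <- imageValues(image)
  g <- nrow(v)
  vals <- vapply(effective_rois, function(r) {
    i_roi <- r$mean_abs_value
    mirror <- mirrorPixels(r$pixels, g)
    mv <- v[mirror]
    if (all(is.na(mv)))
      stop("mirrored ROI footprint lies entirely outside the mask")
    i_con <- mean(abs(mv), na.rm = TRUE)
    gaiTerm(i_roi, i_con) * 100
  }, 1)
  mean(vals)
}

#' Map an anatomical side to its image side (and back)
#'
#' The image-left columns correspond to the subject's anatomical right (the
#' radiological convention), so the maps are the same in both directions.
#'
#' @param side "left" or "right".
#' @return the opposite label.
#' @export
oppositeSide <- function(side) {
  c(left = "right", right = "left")[[side]]
}

#' Positive-event flags for one patient record at one frequency
#'
#' A positive event occurs when the affected side's area ratio (or signal
#' intensity) on the image is smaller than the healthy side's; ties count as
#' negative. Sides here are anatomical: the affected anatomical side is
#' found on the opposite image side.
#'
#' @param record a list or one-row data.frame with fields
#'   \code{affected_side} ("left"/"right", anatomical), \code{ar_left},
#'   \code{ar_right}, \code{si_left}, \code{si_right} (image-side features).
#' @return a list with logicals \code{positive_ar} and \code{positive_si}.
#' @export
positiveEvents <- function(record) {
  side <- record$affected_side
  if (is.null(side) || !side %in% c("left", "right"))
    stop("positiveEvents requires a patient record with a unilateral affected side")
  aff_img <- oppositeSide(side)           # anatomical -> image side
  hea_img <- oppositeSide(aff_img)
  pick <- function(prefix, s) record[[paste0(prefix, s)]]
  list(positive_ar = pick("ar_", aff_img) < pick("ar_", hea_img),
       positive_si = pick("si_", aff_img) < pick("si_", hea_img))
}

#' Positive rates across a patient cohort and the key frequency range
#'
#' Per-frequency positive rate = positives / patients, separately for the
#' area-ratio and signal-intensity events. The key frequency range is the
#' maximal contiguous band of frequencies at which both rates exceed 50%.
#'
#' @param events data.frame with columns \code{frequency_hz},
#'   \code{positive_ar}, \code{positive_si} (one row per patient per
#'   frequency).
#' @return a list with \code{rates} (data.frame: frequency_hz, rate_ar,
#'   rate_si) and \code{key_range_hz} (numeric(2) band edges, or numeric(0)
#'   when empty).
#' @export
positiveRates <- function(events) {
  if (!nrow(events)) stop("no patient records")
  fr <- sort(unique(events$frequency_hz))
  rate <- function(flag, f) {
    x <- events[events$frequency_hz == f, flag]
    mean(x)
  }
  rates <- data.frame(
    frequency_hz = fr,
    rate_ar = vapply(fr, function(f) rate("positive_ar", f), 1),
    rate_si = vapply(fr, function(f) rate("positive_si", f), 1))
  both <- rates$rate_ar > 0.5 & rates$rate_si > 0.5
  key <- numeric(0)
  if (any(both)) {
    runs <- rle(both)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok <- which(runs$values)
    best <- ok[which.max(runs$lengths[ok])]
    key <- c(fr[starts[best]], fr[ends[best]])
  }
  list(rates = rates, key_range_hz = key)
}
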
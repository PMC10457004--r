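#' Default 16-electrode multifrequency acquisition protocol
#'
#' Builds the opposite-excitation / adjacent-measurement protocol: drive
#' pairs (k, (k+8) mod 16) for k = 0..15 (each diametral pair driven twice,
#' once per polarity), and for each drive the 12 adjacent electrode pairs not
#' containing a driven electrode, listed clockwise starting just after the
#' first driven electrode. For drive (5, 13) this yields the channels
#' 6-7, 7-8, 8-9, 9-10, 10-11, 11-12, 14-15, 15-0, 0-1, 1-2, 2-3, 3-4.
#'
#' @param frequencies_hz acquisition frequencies in Hz; default the nine
#'   frequencies 21, 30, 40, 50, 60, 70, 80, 90 and 100 kHz.
#' @param background_hz background (reference) frequency for frequency
#'   differencing; default 21 kHz.
#' @param drive_current_rms RMS drive current in ampere; default 176 uA.
#' @param n_drives number of drives acquired per frame; default 16 (all
#'   opposite pairs in both polarities), 8 gives one polarity each.
#' @return an [EITProtocol-class].
#' @examples
#' p <- defaultProtocol()
#' measurementPairs(p)[[6]]  # drive (5,13)
#' @export
defaultProtocol <- function(frequencies_hz = c(21, 30, 40, 50, 60, 70, 80, 90, 100) * 1e3,
                            background_hz = 21e3,
                            drive_current_rms = 176e-6,
                            n_drives = 16L) {
  stopifnot(n_drives %in% c(8L, 16L))
  ks <- seq_len(n_drives) - 1L
  dp <- cbind(ks, (ks + 8L) %% 16L)
  dimnames(dp) <- NULL
  mp <- lapply(ks, adjacentMeasurementPairs)
  new("EITProtocol",
      n_electrodes = 16L,
      drive_pairs = dp,
      measurement_pairs = mp,
      frequencies_hz = as.numeric(frequencies_hz),
      background_hz = as.numeric(background_hz),
      drive_current_rms = as.numeric(drive_current_rms))
}

#' Adjacent measurement pairs for one opposite drive
#'
#' The 12 adjacent electrode pairs (i, i+1 mod 16) that exclude both driven
#' electrodes for the opposite drive (k, k+8): i runs over
#' k+1..k+6 and k+9..k+14 (mod 16), matching the published channel order.
#'
#' @param k 0-based index of the first driven electrode.
#' @return integer matrix (12 x 2) of 0-based electrode indices.
#' @export
adjacentMeasurementPairs <- function(k) {
  k <- as.integer(k)
  i <- (k + c(1:6, 9:14)) %% 16L
  cbind(i, (i + 1L) %% 16L, deparse.level = 0L)
}

#' Map a channel to its mirrored channel under left-right reflection
#'
#' Reflection of the imaging domain about the vertical axis maps electrode e
#' to (16 - e) mod 16. A drive (k, k+8) maps to drive ((16 - k) mod 16, ...)
#' and an adjacent measurement pair (i, i+1) maps to the reversed pair
#' (-i-1, -i), so the mirrored voltage carries the opposite sign. Used to
#' test and quantify left-right symmetry of noise-free frames.
#'
#' @param protocol an [EITProtocol-class].
#' @return a data.frame with one row per channel (drive-major order) and
#'   columns \code{drive}, \code{meas}, \code{mirror_drive},
#'   \code{mirror_meas} (1-based indices) and \code{sign} (+1/-1).
#' @export
mirrorChannelMap <- function(protocol) {
  dp <- drivePairs(protocol)
  mps <- measurementPairs(protocol)
  ndr <- nrow(dp)
  key <- function(a, b) paste(a, b)
  ## lookup: drive first-electrode -> drive row
  drow <- match((16L - dp[, 1L]) %% 16L, dp[, 1L])
  out <- vector("list", ndr)
  for (d in seq_len(ndr)) {
    mp <- mps[[d]]
    md <- drow[d]
    if (is.na(md))
      stop("protocol is not closed under mirroring (need 16 drives)")
    mmp <- mps[[md]]
    ## mirrored pair of (i, j): (16-i, 16-j); appears in mmp reversed
    mi <- (16L - mp[, 1L]) %% 16L
    mj <- (16L - mp[, 2L]) %% 16L
    idx_fwd <- match(key(mi, mj), key(mmp[, 1L], mmp[, 2L]))
    idx_rev <- match(key(mj, mi), key(mmp[, 1L], mmp[, 2L]))
    sign <- ifelse(is.na(idx_fwd), -1, 1)
    idx <- ifelse(is.na(idx_fwd), idx_rev, idx_fwd)
    if (anyNA(idx))
      stop("mirrored measurement pair not present in protocol")
    out[[d]] <- data.frame(drive = d, meas = seq_len(nrow(mp)),
                           mirror_drive = md, mirror_meas = idx,
                           sign = sign)
  }
  do.call(rbind, out)
}
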
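#' Amplification factors from a calibration-standard acquisition
#'
#' The ratio of the theoretical boundary data of the calibration standard to
#' its measured boundary data, per frequency and per channel:
#' A[f, c] = theoretical[f, c] / measured[f, c]. Multiplying acquired frames
#' by A removes the acquisition chain's frequency response and per-channel
#' gain error.
#'
#' @param theoretical,measured_pcb [EITFrameSet-class] pairs of the standard
#'   under the same protocol.
#' @param per_frequency when TRUE, average |A| over channels within each
#'   frequency and return a per-frequency factor replicated across channels
#'   (the coarser reading of a per-frequency calibration); default FALSE
#'   (full per-channel factors).
#' @return a [CalibrationFactors-class].
#' @export
amplificationFactors <- function(theoretical, measured_pcb,
                                 per_frequency = FALSE) {
  vt <- voltages(theoretical)
  vm <- voltages(measured_pcb)
  if (!identical(dim(vt), dim(vm)))
    stop("theoretical and measured frame sets have different shapes")
  tiny <- 1e-12 * max(abs(vt))
  bad <- which(abs(vm) <= tiny, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "near-zero measured standard channel (frequency %d, drive %d, channel %d)",
      bad[1L, 1L], bad[1L, 2L], bad[1L, 3L]))
  A <- vt / vm
  if (per_frequency) {
    for (i in seq_len(dim(A)[1L]))
      A[i, , ] <- mean(abs(A[i, , ]))
  }
  new("CalibrationFactors", factors = A,
      frequencies_hz = frequencies(theoretical))
}

#' Apply calibration factors to a frame set
#'
#' Elementwise product of the acquired voltages with the amplification
#' factors. Calibrating the standard's own measured frames returns its
#' theoretical frames exactly.
#'
#' @param frames an [EITFrameSet-class].
#' @param A a [CalibrationFactors-class] with matching shape.
#' @return an [EITFrameSet-class].
#' @export
applyCalibration <- function(frames, A) {
  v <- voltages(frames)
  fa <- calibrationArray(A)
  if (!identical(dim(v), dim(fa)))
    stop("frame set and calibration factors have different shapes")
  new("EITFrameSet", voltages = v * fa, protocol = frames@protocol,
      provenance = c(frames@provenance, list(calibrated = TRUE)))
}
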
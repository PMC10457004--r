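#' @import methods
#' @importFrom stats approx rnorm runif sd wilcox.test quantile median
#' @importFrom utils read.csv write.csv
NULL

#' EITProtocol: acquisition protocol for 16-electrode multifrequency EIT
#'
#' Describes the opposite-excitation / adjacent-measurement acquisition
#' scheme: which electrode pairs carry the drive current, which adjacent
#' electrode pairs are measured for each drive, the acquisition frequencies
#' and the background (reference) frequency used for frequency differencing.
#' Electrode indices are 0-based, electrode 0 at the anterior (top of the
#' image), indices increasing clockwise in image orientation.
#'
#' @slot n_electrodes integer, number of scalp electrodes (16).
#' @slot drive_pairs integer matrix (n_drives x 2), 0-based electrode indices
#'   of each opposite drive pair.
#' @slot measurement_pairs list of integer matrices (12 x 2) of 0-based
#'   adjacent measurement pairs, one matrix per drive; no driven electrode
#'   appears in its drive's measurement pairs.
#' @slot frequencies_hz numeric, ordered acquisition frequencies (Hz).
#' @slot background_hz numeric, the background frequency (must be a member of
#'   \code{frequencies_hz}).
#' @slot drive_current_rms numeric, RMS drive current in ampere.
#' @exportClass EITProtocol
setClass("EITProtocol",
  representation(
    n_electrodes = "integer",
    drive_pairs = "matrix",
    measurement_pairs = "list",
    frequencies_hz = "numeric",
    background_hz = "numeric",
    drive_current_rms = "numeric"
  )
)

setValidity("EITProtocol", function(object) {
  msg <- character()
  ne <- object@n_electrodes
  if (length(ne) != 1L || ne != 16L)
    msg <- c(msg, "n_electrodes must be 16")
  dp <- object@drive_pairs
  if (ncol(dp) != 2L)
    msg <- c(msg, "drive_pairs must have two columns")
  if (any(dp < 0L) || any(dp >= ne))
    msg <- c(msg, "drive pair indices must be in 0..15")
  if (!all((dp[, 1L] + 8L) %% 16L == dp[, 2L]))
    msg <- c(msg, "drive pairs must be opposite pairs (k, (k+8) mod 16)")
  if (length(object@measurement_pairs) != nrow(dp))
    msg <- c(msg, "one measurement-pair matrix required per drive")
  for (d in seq_along(object@measurement_pairs)) {
    mp <- object@measurement_pairs[[d]]
    if (nrow(mp) != 12L) {
      msg <- c(msg, sprintf("drive %d must have exactly 12 measurement pairs", d))
      next
    }
    if (any(mp %in% dp[d, ]))
      msg <- c(msg, sprintf("drive %d has a measurement pair containing a driven electrode", d))
  }
  if (!any(abs(object@frequencies_hz - object@background_hz) < 1e-9))
    msg <- c(msg, "background_hz must be a member of frequencies_hz")
  if (is.unsorted(object@frequencies_hz, strictly = TRUE))
    msg <- c(msg, "frequencies_hz must be strictly increasing")
  if (object@drive_current_rms <= 0)
    msg <- c(msg, "drive_current_rms must be positive")
  if (length(msg)) msg else TRUE
})

#' EITMesh: triangular finite-element mesh of the unit disk
#'
#' A conforming triangulation of the circular imaging domain (unit radius,
#' dimensionless) with 16 equally spaced boundary electrode arcs. Electrode 0
#' is centered at the top (anterior); electrode indices increase clockwise in
#' image orientation (x to the image right, y up).
#'
#' @slot nodes numeric matrix (n_nodes x 2) of node coordinates.
#' @slot triangles integer matrix (n_elements x 3) of 1-based node indices.
#' @slot electrodes list of 16 integer vectors of boundary node indices, one
#'   per electrode.
#' @slot areas numeric, element areas (all positive).
#' @slot gradx,grady numeric matrices (n_elements x 3): x/y components of the
#'   P1 basis-function gradients on each element (cached for assembly).
#' @exportClass EITMesh
setClass("EITMesh",
  representation(
    nodes = "matrix",
    triangles = "matrix",
    electrodes = "list",
    areas = "numeric",
    gradx = "matrix",
    grady = "matrix"
  )
)

setValidity("EITMesh", function(object) {
  msg <- character()
  r <- sqrt(rowSums(object@nodes^2))
  if (any(r > 1 + 1e-9))
    msg <- c(msg, "all nodes must lie inside the unit disk")
  if (any(object@areas <= 0))
    msg <- c(msg, "all element areas must be positive")
  if (length(object@electrodes) != 16L)
    msg <- c(msg, "mesh must carry 16 electrode node sets")
  if (any(vapply(object@electrodes, length, 1L) == 0L))
    msg <- c(msg, "every electrode node set must be non-empty")
  if (length(msg)) msg else TRUE
})

#' ConductivityField: element-wise conductivity on a mesh
#'
#' @slot values numeric, conductivity (S/m) per mesh element; strictly
#'   positive and finite.
#' @exportClass ConductivityField
setClass("ConductivityField", representation(values = "numeric"))

setValidity("ConductivityField", function(object) {
  v <- object@values
  if (!all(is.finite(v)) || any(v <= 0))
    "conductivities must be strictly positive and finite"
  else TRUE
})

#' EITFrameSet: multifrequency boundary-voltage frames
#'
#' Boundary voltages indexed frequency x drive x measurement channel, as
#' produced by one acquisition (one frequency cycle) or by the forward
#' simulator.
#'
#' @slot voltages numeric array (n_frequencies x n_drives x 12), volt.
#' @slot protocol the [EITProtocol-class] the frames were acquired under.
#' @slot provenance list; generator configuration, seed, free-form notes.
#' @exportClass EITFrameSet
setClass("EITFrameSet",
  representation(voltages = "array", protocol = "EITProtocol",
                 provenance = "list")
)

setValidity("EITFrameSet", function(object) {
  d <- dim(object@voltages)
  p <- object@protocol
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "voltages must be a 3D array (frequency x drive x channel)")
  else {
    if (d[1L] != length(p@frequencies_hz))
      msg <- c(msg, "first dimension must match protocol frequencies")
    if (d[2L] != nrow(p@drive_pairs))
      msg <- c(msg, "second dimension must match protocol drives")
    if (d[3L] != 12L)
      msg <- c(msg, "third dimension must be 12 measurement channels")
  }
  if (!all(is.finite(object@voltages)))
    msg <- c(msg, "all voltages must be finite")
  if (length(msg)) msg else TRUE
})

#' CalibrationFactors: per-frequency, per-channel amplification factors
#'
#' The ratio of theoretical transfer impedances of the calibration standard
#' to its measured boundary data; multiplying acquired frames by these
#' factors calibrates the frequency response of the acquisition chain.
#'
#' @slot factors numeric array (n_frequencies x n_drives x 12), dimensionless.
#' @slot frequencies_hz numeric, frequencies the factors apply to.
#' @exportClass CalibrationFactors
setClass("CalibrationFactors",
  representation(factors = "array", frequencies_hz = "numeric")
)

setValidity("CalibrationFactors", function(object) {
  if (!all(is.finite(object@factors)) || any(object@factors <= 0))
    "calibration factors must be finite and positive"
  else TRUE
})

#' EITImage: reconstructed frequency-difference image
#'
#' A square pixel grid of reconstructed resistivity-change values on a
#' circular mask. Positive values denote a resistivity increase, negative a
#' decrease. Row 1 is anterior (forehead); the image-left columns correspond
#' to the subject's anatomical right.
#'
#' @slot values numeric matrix (grid x grid); NA outside the mask.
#' @slot mask logical matrix (grid x grid), TRUE for in-domain pixels.
#' @slot amax numeric, maximum absolute value over the mask.
#' @slot foreground_hz,background_hz numeric, the two frequencies differenced.
#' @exportClass EITImage
setClass("EITImage",
  representation(values = "matrix", mask = "matrix", amax = "numeric",
                 foreground_hz = "numeric", background_hz = "numeric")
)

setValidity("EITImage", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must have identical dimensions")
  if (any(!is.na(object@values[!object@mask])))
    msg <- c(msg, "values outside the mask must be NA")
  inmask <- object@values[object@mask]
  amax <- if (length(inmask)) max(abs(inmask)) else 0
  if (!isTRUE(all.equal(object@amax, amax, tolerance = 1e-12)))
    msg <- c(msg, "amax must equal max |value| over the mask")
  if (object@amax < 0) msg <- c(msg, "amax must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PCBNetwork: resistor-network calibration standard
#'
#' A resistive network standing in for the calibration printed circuit board:
#' by default 16 electrode nodes joined to a central hub by 16 spoke
#' resistors and to each other by 16 ring resistors (32 precision resistors
#' of 499 ohm). Its transfer impedances are frequency independent, which is
#' what makes it usable as a frequency-response standard.
#'
#' @slot nodes character, node names.
#' @slot edges data.frame with columns \code{from}, \code{to} (node names)
#'   and \code{resistance_ohm}.
#' @slot electrode_nodes character(16), node name attached to each electrode.
#' @exportClass PCBNetwork
setClass("PCBNetwork",
  representation(nodes = "character", edges = "data.frame",
                 electrode_nodes = "character")
)

setValidity("PCBNetwork", function(object) {
  msg <- character()
  if (!all(c(object@edges$from, object@edges$to) %in% object@nodes))
    msg <- c(msg, "edge endpoints must be listed nodes")
  if (any(object@edges$resistance_ohm <= 0))
    msg <- c(msg, "resistances must be positive")
  if (length(object@electrode_nodes) != 16L)
    msg <- c(msg, "16 electrode nodes are required")
  if (!all(object@electrode_nodes %in% object@nodes))
    msg <- c(msg, "electrode nodes must be listed nodes")
  ## connectivity: union-find over edges
  parent <- seq_along(object@nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(object@edges))) {
    i <- find(match(object@edges$from[k], object@nodes))
    j <- find(match(object@edges$to[k], object@nodes))
    if (i != j) parent[i] <- j
  }
  roots <- vapply(seq_along(object@nodes), find, 1L)
  if (length(unique(roots)) != 1L)
    msg <- c(msg, "network must be connected")
  if (length(msg)) msg else TRUE
})
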
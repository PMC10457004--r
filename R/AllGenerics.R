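## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' @rdname EITProtocol-class
#' @param object an object.
#' @export
setGeneric("nElectrodes", function(object) standardGeneric("nElectrodes"))

#' @rdname EITProtocol-class
#' @export
setGeneric("drivePairs", function(object) standardGeneric("drivePairs"))

#' @rdname EITProtocol-class
#' @export
setGeneric("measurementPairs", function(object) standardGeneric("measurementPairs"))

#' @rdname EITProtocol-class
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname EITProtocol-class
#' @export
setGeneric("backgroundHz", function(object) standardGeneric("backgroundHz"))

#' @rdname EITProtocol-class
#' @export
setGeneric("driveCurrent", function(object) standardGeneric("driveCurrent"))

#' @rdname EITFrameSet-class
#' @param object an object.
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))

#' @rdname EITMesh-class
#' @param object an object.
#' @export
setGeneric("meshNodes", function(object) standardGeneric("meshNodes"))

#' @rdname EITMesh-class
#' @export
setGeneric("meshTriangles", function(object) standardGeneric("meshTriangles"))

#' @rdname EITMesh-class
#' @export
setGeneric("electrodeNodes", function(object) standardGeneric("electrodeNodes"))

#' @rdname EITMesh-class
#' @export
setGeneric("elementAreas", function(object) standardGeneric("elementAreas"))

#' @rdname EITMesh-class
#' @export
setGeneric("nElements", function(object) standardGeneric("nElements"))

#' @rdname ConductivityField-class
#' @param object an object.
#' @export
setGeneric("fieldValues", function(object) standardGeneric("fieldValues"))

#' @rdname EITImage-class
#' @param object an object.
#' @export
setGeneric("imageValues", function(object) standardGeneric("imageValues"))

#' @rdname EITImage-class
#' @export
setGeneric("imageMask", function(object) standardGeneric("imageMask"))

#' @rdname EITImage-class
#' @export
setGeneric("amax", function(object) standardGeneric("amax"))

#' @rdname CalibrationFactors-class
#' @param object an object.
#' @export
setGeneric("calibrationArray", function(object) standardGeneric("calibrationArray"))

setMethod("nElectrodes", "EITProtocol", function(object) object@n_electrodes)
setMethod("drivePairs", "EITProtocol", function(object) object@drive_pairs)
setMethod("measurementPairs", "EITProtocol", function(object) object@measurement_pairs)
setMethod("frequencies", "EITProtocol", function(object) object@frequencies_hz)
setMethod("frequencies", "EITFrameSet", function(object) object@protocol@frequencies_hz)
setMethod("backgroundHz", "EITProtocol", function(object) object@background_hz)
setMethod("driveCurrent", "EITProtocol", function(object) object@drive_current_rms)
setMethod("voltages", "EITFrameSet", function(object) object@voltages)
setMethod("meshNodes", "EITMesh", function(object) object@nodes)
setMethod("meshTriangles", "EITMesh", function(object) object@triangles)
setMethod("electrodeNodes", "EITMesh", function(object) object@electrodes)
setMethod("elementAreas", "EITMesh", function(object) object@areas)
setMethod("nElements", "EITMesh", function(object) nrow(object@triangles))
setMethod("fieldValues", "ConductivityField", function(object) object@values)
setMethod("imageValues", "EITImage", function(object) object@values)
setMethod("imageMask", "EITImage", function(object) object@mask)
setMethod("amax", "EITImage", function(object) object@amax)
setMethod("calibrationArray", "CalibrationFactors", function(object) object@factors)

setMethod("show", "EITProtocol", function(object) {
  cat("EITProtocol:", object@n_electrodes, "electrodes,",
      nrow(object@drive_pairs), "opposite drives x 12 adjacent channels\n")
  cat("  frequencies:", paste0(object@frequencies_hz / 1e3, collapse = ", "),
      "kHz (background", object@background_hz / 1e3, "kHz)\n")
  cat("  drive current:", object@drive_current_rms * 1e6, "uA RMS\n")
})

setMethod("show", "EITMesh", function(object) {
  cat("EITMesh: unit disk,", nrow(object@nodes), "nodes,",
      nrow(object@triangles), "triangles, 16 electrode arcs\n")
  cat(sprintf("  total area %.4f (disk area %.4f)\n",
              sum(object@areas), pi))
})

setMethod("show", "EITFrameSet", function(object) {
  d <- dim(object@voltages)
  cat("EITFrameSet:", d[1L], "frequencies x", d[2L], "drives x", d[3L],
      "channels\n")
  cat(sprintf("  voltage RMS %.3e V\n", sqrt(mean(object@voltages^2))))
})

setMethod("show", "EITImage", function(object) {
  cat("EITImage:", nrow(object@values), "x", ncol(object@values),
      "grid,", sum(object@mask), "in-mask pixels\n")
  cat(sprintf("  %g kHz - %g kHz, Amax = %.4g\n",
              object@foreground_hz / 1e3, object@background_hz / 1e3,
              object@amax))
})

setMethod("show", "CalibrationFactors", function(object) {
  cat("CalibrationFactors:", paste(dim(object@factors), collapse = " x "),
      "(frequency x drive x channel)\n")
})

setMethod("show", "PCBNetwork", function(object) {
  cat("PCBNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "resistors\n")
})
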
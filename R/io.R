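#' @importFrom jsonlite write_json read_json
NULL

#' Write / read a frame set as a flat CSV
#'
#' Columns: frequency_hz, drive_index (1-based), measurement_index
#' (1-based), voltage_v.
#'
#' @param frames an [EITFrameSet-class].
#' @param path output path.
#' @return \code{writeFrameSetCSV}: the path, invisibly.
#' @export
writeFrameSetCSV <- function(frames, path) {
  v <- voltages(frames)
  fr <- frequencies(frames)
  d <- dim(v)
  df <- data.frame(
    frequency_hz = rep(fr, times = d[2L] * d[3L]),
    drive_index = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    measurement_index = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    voltage_v = as.vector(v))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrameSetCSV
#' @param protocol the [EITProtocol-class] the frames were acquired under.
#' @return \code{readFrameSetCSV}: an [EITFrameSet-class].
#' @export
readFrameSetCSV <- function(path, protocol) {
  df <- read.csv(path)
  fr <- frequencies(protocol)
  ndr <- nrow(drivePairs(protocol))
  v <- array(NA_real_, c(length(fr), ndr, 12L))
  fi <- match(df$frequency_hz, fr)
  if (anyNA(fi)) stop("frame CSV contains frequencies not in the protocol")
  v[cbind(fi, df$drive_index, df$measurement_index)] <- df$voltage_v
  if (anyNA(v)) stop("frame CSV does not cover the full protocol")
  new("EITFrameSet", voltages = v, protocol = protocol,
      provenance = list(kind = "csv", path = path))
}

#' Serialize a mesh to (and from) a JSON file
#'
#' Plain structure: node coordinates, 1-based triangle indices, electrode
#' node sets.
#'
#' @param mesh an [EITMesh-class].
#' @param path file path.
#' @return \code{writeMeshJSON}: the path, invisibly.
#' @export
writeMeshJSON <- function(mesh, path) {
  write_json(list(nodes = meshNodes(mesh),
                  triangles = meshTriangles(mesh),
                  electrodes = electrodeNodes(mesh)),
             path, digits = NA)
  invisible(path)
}

#' @rdname writeMeshJSON
#' @return \code{readMeshJSON}: an [EITMesh-class].
#' @export
readMeshJSON <- function(path) {
  x <- read_json(path, simplifyVector = TRUE)
  nodes <- as.matrix(x$nodes)
  tris <- matrix(as.integer(as.matrix(x$triangles)), ncol = 3L)
  geo <- triangleGeometry(nodes, tris)
  new("EITMesh", nodes = nodes, triangles = tris,
      electrodes = lapply(x$electrodes, as.integer),
      areas = geo$areas, gradx = geo$gradx, grady = geo$grady)
}

#' Write calibration factors as CSV
#'
#' Columns: frequency_hz, drive_index, measurement_index, factor.
#'
#' @param A a [CalibrationFactors-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCalibrationCSV <- function(A, path) {
  fa <- calibrationArray(A)
  d <- dim(fa)
  df <- data.frame(
    frequency_hz = rep(A@frequencies_hz, times = d[2L] * d[3L]),
    drive_index = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    measurement_index = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    factor = as.vector(fa))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to a directory
#'
#' One frames CSV per subject plus a JSON manifest (subject ids, groups,
#' affected sides, seeds) and the calibration-standard frames.
#'
#' @param cohort an \code{EITCohort} from [generateCohort()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(cohort$frames))
    writeFrameSetCSV(cohort$frames[[s]],
                     file.path(dir, paste0(cohort$meta$subject_id[s], ".csv")))
  writeFrameSetCSV(cohort$pcb$theoretical, file.path(dir, "pcb_theoretical.csv"))
  writeFrameSetCSV(cohort$pcb$measured, file.path(dir, "pcb_measured.csv"))
  write_json(list(seed = cohort$seed, subjects = cohort$meta),
             file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write a reconstructed image as CSV (masked pixels) plus metadata JSON
#'
#' @param image an [EITImage-class].
#' @param path_csv path of the pixel CSV (columns row, col, value).
#' @param path_json optional metadata path (frequencies, Amax, grid size).
#' @return the CSV path, invisibly.
#' @export
writeImageCSV <- function(image, path_csv, path_json = NULL) {
  m <- imageMask(image)
  idx <- which(m, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1L], col = idx[, 2L],
                   value = imageValues(image)[idx])
  write.csv(df, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    write_json(list(foreground_hz = image@foreground_hz,
                    background_hz = image@background_hz,
                    amax = amax(image), grid_size = nrow(m)),
               path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_csv)
}
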
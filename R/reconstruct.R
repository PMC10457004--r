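#' Reconstruction configuration
#'
#' @param lambda_rel Tikhonov regularization weight, expressed relative to
#'   the mean diagonal of the normal matrix J'J (dimensionless, > 0);
#'   default 1e-2. The relative scaling keeps the effective damping
#'   mesh-size invariant.
#' @param grid_size pixels per image side (>= 32); default 64.
#' @param weighted_difference use the weighted frequency difference
#'   v(f) - alpha v(f0) with alpha = <v(f), v(f0)> / <v(f0), v(f0)>;
#'   default TRUE. The weighting projects out the spatially uniform
#'   background-dispersion component, which would otherwise dominate every
#'   image as a domain-filling (hence boundary-touching, hence excluded)
#'   reconstructed target; FALSE gives the simple difference v(f) - v(f0).
#' @param damping "identity" for standard Tikhonov regularization
#'   (lambda I), or "diagonal" for the Levenberg-Marquardt-style variant
#'   lambda diag(J'J).
#' @return a list of class \code{ReconstructionConfig}.
#' @export
reconstructionConfig <- function(lambda_rel = 1e-2, grid_size = 64L,
                                 weighted_difference = TRUE,
                                 damping = c("identity", "diagonal")) {
  stopifnot(lambda_rel > 0, grid_size >= 32L)
  structure(list(lambda_rel = lambda_rel, grid_size = as.integer(grid_size),
                 weighted_difference = weighted_difference,
                 damping = match.arg(damping)),
            class = "ReconstructionConfig")
}

#' Frequency-difference vectors of a frame set
#'
#' One difference vector per foreground frequency: Delta v = v(f) - v(f0)
#' with f0 the background frequency (all other frequencies are foreground;
#' under the default 9-frequency protocol with 21 kHz background this yields
#' 8 difference vectors). In weighted mode Delta v = v(f) - alpha v(f0) with
#' alpha the projection coefficient of v(f) on v(f0).
#'
#' @param frames an [EITFrameSet-class].
#' @param background_hz background frequency; default the protocol's.
#' @param weighted logical; default FALSE.
#' @return a named list (names = foreground frequency in Hz) of numeric
#'   vectors of length n_drives x 12, drive-major channel order.
#' @export
fdDifference <- function(frames, background_hz = NULL, weighted = FALSE) {
  fr <- frequencies(frames)
  if (is.null(background_hz)) background_hz <- frames@protocol@background_hz
  i0 <- which(abs(fr - background_hz) < 1e-9)
  if (length(i0) != 1L)
    stop("background frequency ", background_hz, " Hz not present in frames")
  v <- voltages(frames)
  flat <- function(i) as.vector(t(v[i, , ]))  # drive-major channel order
  v0 <- flat(i0)
  out <- list()
  for (i in seq_along(fr)) {
    if (i == i0) next
    vi <- flat(i)
    alpha <- if (weighted) sum(vi * v0) / sum(v0 * v0) else 1
    out[[as.character(fr[i])]] <- vi - alpha * v0
  }
  out
}

#' Precomputed frequency-difference reconstructor
#'
#' Factorizes the damped normal equations (J'J + lambda D) once and caches
#' the pixel-to-element map, so that many difference vectors can be
#' reconstructed cheaply (e.g. 8 foreground frequencies x all subjects of a
#' cohort).
#'
#' @param J Jacobian matrix from [computeJacobian()].
#' @param mesh the [EITMesh-class] the Jacobian was built on.
#' @param cfg a [reconstructionConfig()].
#' @return a list of class \code{FDReconstructor}.
#' @export
fdReconstructor <- function(J, mesh, cfg = reconstructionConfig()) {
  JtJ <- crossprod(J)
  dg <- diag(JtJ)
  D <- if (cfg$damping == "diagonal") diag(dg) else diag(mean(dg), ncol(J))
  ch <- chol(JtJ + cfg$lambda_rel * D)
  structure(list(J = J, chol = ch, mesh = mesh, cfg = cfg,
                 pixel_map = pixelElementMap(mesh, cfg$grid_size)),
            class = "FDReconstructor")
}

#' Reconstruct a frequency-difference image
#'
#' Damped least squares with standard Tikhonov regularization: solves
#' (J'J + lambda D) x = J' Delta v for the element-wise conductivity change,
#' negates it to the resistivity-change sign convention (positive pixel =
#' resistivity increase) and rasterizes element values onto the square pixel
#' grid (pixel value = value of the element containing the pixel center;
#' pixels outside the meshed disk are masked). Amax is the maximum absolute
#' value over the mask. The solve is linear in Delta v.
#'
#' @param delta_v numeric difference vector (length = rows of J), or an
#'   element of [fdDifference()] output.
#' @param reconstructor an [fdReconstructor()]; alternatively pass \code{J},
#'   \code{mesh} and \code{cfg} to build one on the fly.
#' @param J,mesh,cfg used only when \code{reconstructor} is NULL.
#' @param foreground_hz,background_hz frequencies recorded in the image
#'   metadata.
#' @return an [EITImage-class].
#' @export
reconstructImage <- function(delta_v, reconstructor = NULL, J = NULL,
                             mesh = NULL, cfg = reconstructionConfig(),
                             foreground_hz = NA_real_,
                             background_hz = NA_real_) {
  if (is.null(reconstructor)) {
    if (is.null(J) || is.null(mesh))
      stop("provide either a reconstructor or J and mesh")
    reconstructor <- fdReconstructor(J, mesh, cfg)
  }
  rec <- reconstructor
  if (length(delta_v) != nrow(rec$J))
    stop("difference vector length ", length(delta_v),
         " does not match Jacobian rows ", nrow(rec$J))
  x <- backsolve(rec$chol, forwardsolve(t(rec$chol), crossprod(rec$J, delta_v)))
  elem_vals <- -as.vector(x)  # conductivity change -> resistivity change sign
  g <- rec$cfg$grid_size
  vals <- matrix(NA_real_, g, g)
  mask <- rec$pixel_map > 0L
  vals[mask] <- elem_vals[rec$pixel_map[mask]]
  inm <- vals[mask]
  new("EITImage", values = vals, mask = mask,
      amax = if (length(inm)) max(abs(inm)) else 0,
      foreground_hz = as.numeric(foreground_hz),
      background_hz = as.numeric(background_hz))
}

#' Map pixel centers to containing mesh elements
#'
#' Pixel (row, col) covers the square cell of a grid x grid raster of the
#' bounding box [-1,1]^2; row 1 is the top (anterior), columns increase to
#' the image right. The map holds the 1-based element index containing each
#' pixel center, or 0 for pixels outside the meshed domain.
#'
#' @param mesh an [EITMesh-class].
#' @param grid_size pixels per side.
#' @return integer matrix (grid_size x grid_size).
#' @export
pixelElementMap <- function(mesh, grid_size) {
  g <- as.integer(grid_size)
  cs <- (seq_len(g) - 0.5) * 2 / g - 1
  px <- rep(cs, each = g)          # column-major: x varies with column
  py <- rep(rev(cs), times = g)    # row 1 = top
  map <- integer(g * g)
  cand <- which(px^2 + py^2 <= 1)
  tr <- mesh@triangles
  nd <- mesh@nodes
  remaining <- cand
  for (e in seq_len(nrow(tr))) {
    if (!length(remaining)) break
    x1 <- nd[tr[e, 1L], 1L]; y1 <- nd[tr[e, 1L], 2L]
    x2 <- nd[tr[e, 2L], 1L]; y2 <- nd[tr[e, 2L], 2L]
    x3 <- nd[tr[e, 3L], 1L]; y3 <- nd[tr[e, 3L], 2L]
    d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    l1 <- ((y2 - y3) * (px[remaining] - x3) + (x3 - x2) * (py[remaining] - y3)) / d
    l2 <- ((y3 - y1) * (px[remaining] - x3) + (x1 - x3) * (py[remaining] - y3)) / d
    l3 <- 1 - l1 - l2
    tol <- -1e-12
    hit <- l1 >= tol & l2 >= tol & l3 >= tol
    map[remaining[hit]] <- e
    remaining <- remaining[!hit]
  }
  matrix(map, g, g)
}

#' Render a reconstructed image with the diverging color convention
#'
#' Red encodes a resistivity decrease (negative values), green a negligible
#' change, blue a resistivity increase; out-of-mask pixels are white. The
#' five color-scale tick labels are +Amax, +0.5Amax, 0.000, -0.5Amax and
#' -Amax. Deterministic for fixed input.
#'
#' @param image an [EITImage-class].
#' @param file optional path; when given, the raster is written as a PNG.
#' @return (invisibly) a list with \code{raster} (grid x grid x 3 RGB array
#'   in \[0,1\]) and \code{labels} (character(5), top tick first).
#' @export
renderImage <- function(image, file = NULL) {
  v <- imageValues(image)
  m <- imageMask(image)
  a <- amax(image)
  t <- if (a > 0) v / a else v * 0
  g <- nrow(v)
  R <- G <- B <- matrix(1, g, g)
  neg <- m & !is.na(t) & t < 0
  pos <- m & !is.na(t) & t >= 0
  R[neg] <- -t[neg];     G[neg] <- 1 + t[neg]; B[neg] <- 0
  R[pos] <- 0;           G[pos] <- 1 - t[pos]; B[pos] <- t[pos]
  raster <- array(c(R, G, B), c(g, g, 3L))
  fmt <- function(x) if (x == 0) "0.000" else sprintf("%+.3f", x)
  labels <- vapply(c(a, a / 2, 0, -a / 2, -a), fmt, "")
  if (!is.null(file)) png::writePNG(raster, target = file)
  invisible(list(raster = raster, labels = labels))
}
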
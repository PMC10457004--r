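#' TissueSpectrum: frequency-dependent tissue conductivity
#'
#' Anchor conductivities at anchor frequencies; values between anchors are
#' interpolated linearly on the log-frequency axis. Conductivity is
#' non-decreasing with frequency (beta dispersion), and over the 21-100 kHz
#' band the default spectra obey the literature ordering of the relative
#' impedance change: white matter > ischemic tissue > gray matter >
#' hemorrhage.
#'
#' @slot tissue_id one of "white_matter", "gray_matter", "blood_hemorrhage",
#'   "ischemic", "background_brain".
#' @slot anchor_frequencies_hz ordered anchor frequencies (Hz).
#' @slot anchor_conductivities conductivities (S/m) at the anchors.
#' @exportClass TissueSpectrum
setClass("TissueSpectrum",
  representation(tissue_id = "character",
                 anchor_frequencies_hz = "numeric",
                 anchor_conductivities = "numeric"))

setValidity("TissueSpectrum", function(object) {
  msg <- character()
  if (length(object@anchor_frequencies_hz) != length(object@anchor_conductivities))
    msg <- c(msg, "one conductivity required per anchor frequency")
  if (is.unsorted(object@anchor_frequencies_hz, strictly = TRUE))
    msg <- c(msg, "anchor frequencies must be strictly increasing")
  if (any(object@anchor_conductivities <= 0))
    msg <- c(msg, "conductivities must be positive")
  if (is.unsorted(object@anchor_conductivities))
    msg <- c(msg, "conductivity must be non-decreasing with frequency")
  if (length(msg)) msg else TRUE
})

#' Default tissue conductivity spectra
#'
#' Literature-inspired generator defaults (two anchors, 21 and 100 kHz).
#' The relative conductivity increase over the band is 20% for white matter,
#' 15% for ischemic tissue, 12% for unstructured background brain, 10% for
#' gray matter and 3% for hemorrhagic blood, satisfying the dispersion
#' ordering white matter > ischemic > gray matter > hemorrhage. Hemorrhage
#' is much more conductive than brain parenchyma in absolute terms.
#'
#' @return a named list of [TissueSpectrum-class] objects.
#' @export
defaultTissueSpectra <- function() {
  mk <- function(id, s21, rel) {
    new("TissueSpectrum", tissue_id = id,
        anchor_frequencies_hz = c(21e3, 100e3),
        anchor_conductivities = c(s21, s21 * (1 + rel)))
  }
  list(
    white_matter     = mk("white_matter",     0.07, 0.20),
    ischemic         = mk("ischemic",         0.08, 0.15),
    background_brain = mk("background_brain", 0.10, 0.12),
    gray_matter      = mk("gray_matter",      0.10, 0.10),
    blood_hemorrhage = mk("blood_hemorrhage", 0.70, 0.03)
  )
}

#' Conductivity of a tissue at a frequency
#'
#' Linear interpolation of the anchor conductivities on the log-frequency
#' axis; errors outside the anchored range.
#'
#' @param spectrum a [TissueSpectrum-class].
#' @param f_hz frequency (Hz), scalar or vector, within the anchor range.
#' @return conductivity (S/m), same length as \code{f_hz}.
#' @export
tissueConductivity <- function(spectrum, f_hz) {
  fa <- spectrum@anchor_frequencies_hz
  if (any(f_hz < fa[1L] - 1e-9) || any(f_hz > fa[length(fa)] + 1e-9))
    stop("frequency outside the anchored range [",
         fa[1L], ", ", fa[length(fa)], "] Hz")
  approx(log(fa), spectrum@anchor_conductivities, xout = log(f_hz),
         rule = 2)$y
}

#' Relative conductivity change of a tissue over a band
#'
#' @param spectrum a [TissueSpectrum-class].
#' @param f_lo,f_hi band edges (Hz); defaults 21 and 100 kHz.
#' @return dimensionless fractional change (sigma(f_hi)-sigma(f_lo))/sigma(f_lo).
#' @export
dispersionChange <- function(spectrum, f_lo = 21e3, f_hi = 100e3) {
  s <- tissueConductivity(spectrum, c(f_lo, f_hi))
  (s[2L] - s[1L]) / s[1L]
}

#' Head phantom configuration
#'
#' Describes one synthetic head: a homogeneous background tissue, an
#' optional pair of mirrored posterior disk inclusions (emulating the two
#' approximately left-right symmetric stronger-resistivity features observed
#' in healthy images), an optional unilateral lesion, and the acquisition
#' noise model. All geometry is dimensionless (fractions of the domain
#' radius). A phantom without a lesion is a healthy phantom and is exactly
#' mirror-symmetric about the vertical axis.
#'
#' @param background_tissue tissue id of the background.
#' @param posterior_pair NULL, or a list with \code{angle_deg} (offset of
#'   each disk from the posterior axis, degrees), \code{r} (center radius
#'   fraction), \code{radius} (disk radius fraction, in (0, 0.5]) and
#'   \code{tissue}.
#' @param lesion NULL (healthy), or a list with \code{side} ("left"/"right",
#'   the subject's anatomical side; anatomical left renders on the image
#'   right), \code{angle_deg} (polar angle from anterior, 0-180), \code{r}
#'   (center radius fraction), \code{radius} (disk radius fraction, in
#'   [0, 0.5]) and \code{tissue}.
#' @param noise_relative_sd additive measurement-noise SD as a fraction of
#'   the frame RMS voltage; default 2e-4 (74 dB SNR, in the range reported
#'   for multifrequency EIT systems after frequency-cycle averaging; at this
#'   level the healthy posterior features remain detectable in every
#'   subject, matching the healthy-group baseline the generator emulates).
#' @param channel_gain_sd SD of the multiplicative per-channel gain error
#'   (constant across frequency); default 0.01.
#' @param seed integer RNG seed for the acquisition noise.
#' @param spectra named list of [TissueSpectrum-class] objects.
#' @return a validated list of class \code{HeadPhantomConfig}.
#' @export
headPhantomConfig <- function(background_tissue = "background_brain",
                              posterior_pair = list(angle_deg = 40, r = 0.55,
                                                    radius = 0.16,
                                                    tissue = "white_matter"),
                              lesion = NULL,
                              noise_relative_sd = 2e-4,
                              channel_gain_sd = 0.01,
                              seed = 1L,
                              spectra = defaultTissueSpectra()) {
  cfg <- list(background_tissue = background_tissue,
              posterior_pair = posterior_pair, lesion = lesion,
              noise_relative_sd = noise_relative_sd,
              channel_gain_sd = channel_gain_sd,
              seed = as.integer(seed), spectra = spectra)
  class(cfg) <- "HeadPhantomConfig"
  validateHeadPhantomConfig(cfg)
  cfg
}

validateHeadPhantomConfig <- function(cfg) {
  stopifnot(cfg$background_tissue %in% names(cfg$spectra),
            cfg$noise_relative_sd >= 0, cfg$channel_gain_sd >= 0)
  checkDisk <- function(r, radius, what) {
    if (radius < 0 || radius > 0.5)
      stop(what, ": radius fraction must be in [0, 0.5]")
    if (r + radius > 1 + 1e-9)
      stop(what, ": inclusion extends outside the imaging domain")
  }
  if (!is.null(cfg$posterior_pair)) {
    with(cfg$posterior_pair, checkDisk(r, radius, "posterior_pair"))
    stopifnot(cfg$posterior_pair$tissue %in% names(cfg$spectra))
  }
  if (!is.null(cfg$lesion)) {
    stopifnot(cfg$lesion$side %in% c("left", "right"),
              cfg$lesion$tissue %in% names(cfg$spectra))
    with(cfg$lesion, checkDisk(r, radius, "lesion"))
  }
  invisible(cfg)
}

## disk-inclusion centers in image coordinates (x right, y up)
posteriorCenters <- function(pp) {
  b <- pp$angle_deg * pi / 180
  rbind(c(pp$r * sin(b), -pp$r * cos(b)),
        c(-pp$r * sin(b), -pp$r * cos(b)))
}

lesionCenter <- function(lesion) {
  a <- lesion$angle_deg * pi / 180
  s <- if (lesion$side == "left") 1 else -1  # anatomical left -> image right
  c(s * lesion$r * sin(a), lesion$r * cos(a))
}

#' Realize a head phantom as a conductivity field at one frequency
#'
#' Element conductivity is the background tissue's value at \code{f_hz},
#' overridden inside the posterior inclusion disks and the lesion disk
#' (evaluated at element centroids). A zero-radius lesion degenerates to the
#' healthy phantom.
#'
#' @param cfg a [headPhantomConfig()].
#' @param mesh an [EITMesh-class].
#' @param f_hz frequency (Hz).
#' @return a [ConductivityField-class].
#' @export
buildHeadPhantom <- function(cfg, mesh, f_hz) {
  validateHeadPhantomConfig(cfg)
  ctr <- elementCentroids(mesh)
  sig <- rep(tissueConductivity(cfg$spectra[[cfg$background_tissue]], f_hz),
             nElements(mesh))
  paint <- function(sig, center, radius, tissue) {
    if (radius <= 0) return(sig)
    inside <- (ctr[, 1L] - center[1L])^2 + (ctr[, 2L] - center[2L])^2 <= radius^2
    sig[inside] <- tissueConductivity(cfg$spectra[[tissue]], f_hz)
    sig
  }
  if (!is.null(cfg$posterior_pair)) {
    cc <- posteriorCenters(cfg$posterior_pair)
    sig <- paint(sig, cc[1L, ], cfg$posterior_pair$radius, cfg$posterior_pair$tissue)
    sig <- paint(sig, cc[2L, ], cfg$posterior_pair$radius, cfg$posterior_pair$tissue)
  }
  if (!is.null(cfg$lesion))
    sig <- paint(sig, lesionCenter(cfg$lesion), cfg$lesion$radius,
                 cfg$lesion$tissue)
  new("ConductivityField", values = sig)
}

## evaluate expr with a temporary RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate one multifrequency acquisition of a head phantom
#'
#' For every protocol frequency the phantom is forward-solved and measured,
#' then a multiplicative per-channel gain error g_c ~ Normal(1,
#' channel_gain_sd) (constant across frequency, emulating a fixed
#' acquisition-chain imperfection) and additive Gaussian noise with SD =
#' noise_relative_sd x RMS(frame at that frequency) are applied. Fully
#' deterministic for a fixed config seed.
#'
#' @param cfg a [headPhantomConfig()]; its \code{seed} drives the noise.
#' @param mesh an [EITMesh-class].
#' @param protocol an [EITProtocol-class].
#' @param gains optional numeric matrix (n_drives x 12) of fixed per-channel
#'   gains (e.g. a device-level gain shared across subjects and with the
#'   calibration standard); when NULL, gains are drawn from the config seed.
#' @return an [EITFrameSet-class].
#' @export
simulateAcquisition <- function(cfg, mesh, protocol, gains = NULL) {
  validateHeadPhantomConfig(cfg)
  fr <- frequencies(protocol)
  ndr <- nrow(drivePairs(protocol))
  clean <- array(0, c(length(fr), ndr, 12L))
  for (i in seq_along(fr)) {
    sig <- buildHeadPhantom(cfg, mesh, fr[i])
    clean[i, , ] <- forwardFrame(mesh, sig, protocol)
  }
  withSeed(cfg$seed, {
    if (is.null(gains))
      gains <- matrix(rnorm(ndr * 12L, 1, cfg$channel_gain_sd), ndr, 12L)
    noisy <- clean
    for (i in seq_along(fr)) {
      frame <- clean[i, , ] * gains
      rms <- sqrt(mean(clean[i, , ]^2))
      noisy[i, , ] <- frame +
        matrix(rnorm(ndr * 12L, 0, cfg$noise_relative_sd * rms), ndr, 12L)
    }
    new("EITFrameSet", voltages = noisy, protocol = protocol,
        provenance = list(kind = "head_phantom", seed = cfg$seed,
                          noise_relative_sd = cfg$noise_relative_sd,
                          channel_gain_sd = cfg$channel_gain_sd,
                          lesion = cfg$lesion))
  })
}

#' Default resistor-network calibration standard
#'
#' Sixteen electrode nodes joined to a central hub by 16 spoke resistors and
#' around the perimeter by 16 ring resistors, all 499 ohm (32 precision
#' resistors in total). A pure star would produce zero adjacent-pair
#' voltages under opposite drive; the ring resistors give every adjacent
#' measurement channel a nonzero, frequency-independent theoretical value.
#'
#' @param r_ohm resistance of every resistor; default 499.
#' @return a [PCBNetwork-class].
#' @export
pcbNetwork <- function(r_ohm = 499) {
  en <- paste0("E", 0:15)
  edges <- rbind(
    data.frame(from = en, to = "HUB", resistance_ohm = r_ohm),
    data.frame(from = en, to = en[c(2:16, 1L)], resistance_ohm = r_ohm)
  )
  new("PCBNetwork", nodes = c(en, "HUB"), edges = edges,
      electrode_nodes = en)
}

#' Node potentials of the calibration network under each protocol drive
#'
#' Nodal analysis: solves G v = i for the resistive network with the
#' protocol's drive current injected/extracted at the driven electrode
#' nodes; potentials are grounded to zero mean over the electrode nodes.
#'
#' @param network a [PCBNetwork-class].
#' @param protocol an [EITProtocol-class].
#' @return numeric matrix (n_nodes x n_drives), rownames = node names.
#' @export
pcbPotentials <- function(network, protocol) {
  nn <- network@nodes
  n <- length(nn)
  i <- match(network@edges$from, nn)
  j <- match(network@edges$to, nn)
  g <- 1 / network@edges$resistance_ohm
  G <- sparseMatrix(i = c(i, j, i, j), j = c(j, i, i, j),
                    x = c(-g, -g, g, g), dims = c(n, n))
  dp <- drivePairs(protocol)
  I0 <- driveCurrent(protocol)
  e <- match(network@electrode_nodes, nn)
  B <- matrix(0, n, nrow(dp))
  for (d in seq_len(nrow(dp))) {
    B[e[dp[d, 1L] + 1L], d] <- I0
    B[e[dp[d, 2L] + 1L], d] <- -I0
  }
  free <- 2:n
  V <- matrix(0, n, ncol(B))
  V[free, ] <- as.matrix(solve(forceSymmetricCsparse(G[free, free]),
                               B[free, , drop = FALSE]))
  V <- sweep(V, 2L, colMeans(V[e, , drop = FALSE]))
  rownames(V) <- nn
  V
}

#' Simulate a calibration-standard acquisition
#'
#' Computes the theoretical boundary frames of the resistor network
#' (identical at every frequency, the network being purely resistive) and a
#' measured version distorted by per-channel gains.
#'
#' @param network a [PCBNetwork-class].
#' @param protocol an [EITProtocol-class].
#' @param gains per-channel gain factors: scalar, or matrix (n_drives x 12);
#'   default 1 (ideal acquisition).
#' @return list with elements \code{theoretical} and \code{measured}, both
#'   [EITFrameSet-class].
#' @export
simulatePCB <- function(network, protocol, gains = 1) {
  V <- pcbPotentials(network, protocol)
  dp <- drivePairs(protocol)
  mps <- measurementPairs(protocol)
  e <- match(network@electrode_nodes, network@nodes)
  frame <- matrix(0, nrow(dp), 12L)
  for (d in seq_len(nrow(dp))) {
    mp <- mps[[d]]
    frame[d, ] <- V[e[mp[, 1L] + 1L], d] - V[e[mp[, 2L] + 1L], d]
  }
  nf <- length(frequencies(protocol))
  theo <- array(rep(frame, each = nf), c(nf, nrow(dp), 12L))
  if (length(gains) == 1L) gains <- matrix(gains, nrow(dp), 12L)
  meas <- array(0, dim(theo))
  for (i in seq_len(nf)) meas[i, , ] <- theo[i, , ] * gains
  list(
    theoretical = new("EITFrameSet", voltages = theo, protocol = protocol,
                      provenance = list(kind = "pcb_theoretical")),
    measured = new("EITFrameSet", voltages = meas, protocol = protocol,
                   provenance = list(kind = "pcb_measured"))
  )
}

#' Generate a synthetic cohort of multifrequency acquisitions
#'
#' Emulates the study design: \code{n_healthy} symmetric phantoms with
#' per-subject mirrored jitter of the posterior inclusion pair, and
#' \code{n_patients} phantoms with one unilateral lesion of randomized side,
#' position and size. A single device-level per-channel gain vector is drawn
#' once and shared by every subject and by the calibration-standard
#' acquisition, so the calibration factors estimated from the standard apply
#' to the whole cohort. Reproducible for a fixed seed.
#'
#' @param n_healthy,n_patients group sizes (>= 1); study defaults 16 and 8.
#' @param mesh an [EITMesh-class].
#' @param protocol an [EITProtocol-class].
#' @param base_cfg template [headPhantomConfig()]; its noise and posterior
#'   settings apply to every subject.
#' @param seed integer master seed.
#' @param lesion_tissue tissue id of patient lesions; default
#'   "blood_hemorrhage".
#' @param lesion_r range of lesion center radius fraction.
#' @param lesion_radius range of lesion disk radius fraction.
#' @param lesion_angle_deg range of lesion polar angle (degrees from
#'   anterior).
#' @return a list of class \code{EITCohort}: \code{frames} (list of
#'   [EITFrameSet-class]), \code{meta} (data.frame: subject_id, group,
#'   affected_side (anatomical), seed), \code{pcb} (theoretical + measured
#'   standard frames), \code{gains}, \code{seed}.
#' @export
generateCohort <- function(n_healthy, n_patients, mesh, protocol,
                           base_cfg = headPhantomConfig(),
                           seed = 1L,
                           lesion_tissue = "blood_hemorrhage",
                           lesion_r = c(0.35, 0.6),
                           lesion_radius = c(0.12, 0.2),
                           lesion_angle_deg = c(40, 140)) {
  stopifnot(n_healthy >= 1L, n_patients >= 1L)
  n <- n_healthy + n_patients
  withSeed(seed, {
    ndr <- nrow(drivePairs(protocol))
    gains <- matrix(rnorm(ndr * 12L, 1, base_cfg$channel_gain_sd), ndr, 12L)
    subject_seeds <- sample.int(2^31 - 2, n)
    jit <- function(x, a) x + runif(1, -a, a)
    cfgs <- vector("list", n)
    sides <- rep(NA_character_, n)
    for (s in seq_len(n)) {
      pp <- base_cfg$posterior_pair
      if (!is.null(pp)) {
        pp$angle_deg <- jit(pp$angle_deg, 5)
        pp$r <- jit(pp$r, 0.05)
        pp$radius <- min(jit(pp$radius, 0.03), 0.5)
      }
      lesion <- NULL
      if (s > n_healthy) {
        sides[s] <- sample(c("left", "right"), 1L)
        lesion <- list(side = sides[s],
                       angle_deg = runif(1, lesion_angle_deg[1L], lesion_angle_deg[2L]),
                       r = runif(1, lesion_r[1L], lesion_r[2L]),
                       radius = runif(1, lesion_radius[1L], lesion_radius[2L]),
                       tissue = lesion_tissue)
        # keep the lesion inside the domain
        lesion$r <- min(lesion$r, 1 - lesion$radius - 1e-6)
      }
      cfgs[[s]] <- headPhantomConfig(
        background_tissue = base_cfg$background_tissue,
        posterior_pair = pp, lesion = lesion,
        noise_relative_sd = base_cfg$noise_relative_sd,
        channel_gain_sd = base_cfg$channel_gain_sd,
        seed = subject_seeds[s], spectra = base_cfg$spectra)
    }
    frames <- lapply(cfgs, simulateAcquisition, mesh = mesh,
                     protocol = protocol, gains = gains)
    meta <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      group = rep(c("healthy", "patient"), c(n_healthy, n_patients)),
      affected_side = ifelse(is.na(sides), "none", sides),
      seed = subject_seeds,
      stringsAsFactors = FALSE)
    cohort <- list(frames = frames, meta = meta,
                   pcb = simulatePCB(pcbNetwork(), protocol, gains),
                   gains = gains, seed = seed, configs = cfgs)
    class(cohort) <- "EITCohort"
    cohort
  })
}
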
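#' Process one subject's frames into images, features and asymmetry indices
#'
#' Runs the per-subject analysis chain: (optional) calibration, frequency
#' differencing against the background frame, damped-least-squares
#' reconstruction of each foreground frequency, effective-ROI extraction,
#' per-side area-ratio/signal-intensity features, and the GAI and IAI
#' asymmetry indices.
#'
#' @param frames an [EITFrameSet-class].
#' @param reconstructor an [fdReconstructor()] built for the acquisition
#'   mesh and protocol.
#' @param A optional [CalibrationFactors-class] applied before imaging.
#' @param roi_threshold ROI threshold as a fraction of Amax; default 0.625.
#' @param min_area_frac small-target exclusion threshold; default 0.0085.
#' @param weighted weighted frequency differencing; default NULL (use the
#'   reconstructor's configuration).
#' @return a list with \code{images} (named list of [EITImage-class], one
#'   per foreground frequency), \code{features} (data.frame, one row per
#'   frequency: image-side features \code{ar_left}, \code{ar_right},
#'   \code{si_left}, \code{si_right}, fallback flags, ROI counts) and
#'   \code{asymmetry} (data.frame: frequency_hz, gai_percent, is_ns,
#'   iai_percent).
#' @export
processSubject <- function(frames, reconstructor, A = NULL,
                           roi_threshold = 0.625, min_area_frac = 0.0085,
                           weighted = NULL) {
  if (is.null(weighted)) weighted <- reconstructor$cfg$weighted_difference
  if (!is.null(A)) frames <- applyCalibration(frames, A)
  dv <- fdDifference(frames, weighted = weighted)
  f0 <- frames@protocol@background_hz
  feats <- asym <- list()
  images <- list()
  for (fname in names(dv)) {
    f <- as.numeric(fname)
    img <- reconstructImage(dv[[fname]], reconstructor,
                            foreground_hz = f, background_hz = f0)
    images[[fname]] <- img
    rois <- filterEffectiveROIs(
      extractCandidateROIs(img, threshold = roi_threshold), img,
      min_area_frac = min_area_frac)
    sl <- sideFeatures(img, rois, "left")
    sr <- sideFeatures(img, rois, "right")
    g <- gai(Filter(function(r) r$side == "left", rois),
             Filter(function(r) r$side == "right", rois))
    feats[[fname]] <- data.frame(
      frequency_hz = f,
      ar_left = sl$ar_roi, ar_right = sr$ar_roi,
      si_left = sl$mvrrc, si_right = sr$mvrrc,
      fallback_left = sl$mirrored_fallback,
      fallback_right = sr$mirrored_fallback,
      n_rois_left = sl$n_effective_rois,
      n_rois_right = sr$n_effective_rois)
    asym[[fname]] <- data.frame(
      frequency_hz = f,
      gai_percent = g$value, is_ns = g$ns,
      iai_percent = iai(img, rois))
  }
  list(images = images,
       features = do.call(rbind, feats),
       asymmetry = do.call(rbind, asym))
}

#' Process a synthetic cohort end to end
#'
#' Estimates calibration factors from the cohort's calibration-standard
#' acquisition, builds the reconstruction operator once (Jacobian linearized
#' at the homogeneous background conductivity at the background frequency),
#' and runs [processSubject()] on every subject.
#'
#' @param cohort an \code{EITCohort} from [generateCohort()].
#' @param mesh,protocol the mesh and protocol the cohort was generated with.
#' @param cfg a [reconstructionConfig()].
#' @param calibrate apply the standard-based calibration; default TRUE.
#' @param base_cfg the phantom config that defines the background tissue
#'   (for the Jacobian linearization point); default [headPhantomConfig()].
#' @param ... passed on to [processSubject()].
#' @return a list with \code{features} and \code{asymmetry} (data.frames
#'   over all subjects, joined with the cohort metadata), \code{meta}, and
#'   \code{reconstructor}.
#' @export
processCohort <- function(cohort, mesh, protocol,
                          cfg = reconstructionConfig(), calibrate = TRUE,
                          base_cfg = headPhantomConfig(), ...) {
  A <- if (calibrate)
    amplificationFactors(cohort$pcb$theoretical, cohort$pcb$measured)
  else NULL
  sigma0 <- rep(
    tissueConductivity(base_cfg$spectra[[base_cfg$background_tissue]],
                       backgroundHz(protocol)),
    nElements(mesh))
  J <- computeJacobian(mesh, new("ConductivityField", values = sigma0),
                       protocol)
  rec <- fdReconstructor(J, mesh, cfg)
  feats <- asym <- list()
  for (s in seq_along(cohort$frames)) {
    res <- processSubject(cohort$frames[[s]], rec, A = A, ...)
    id <- cohort$meta$subject_id[s]
    res$features <- cbind(subject_id = id,
                          group = cohort$meta$group[s],
                          affected_side = cohort$meta$affected_side[s],
                          res$features)
    res$asymmetry <- cbind(subject_id = id,
                           group = cohort$meta$group[s],
                           res$asymmetry)
    feats[[s]] <- res$features
    asym[[s]] <- res$asymmetry
  }
  list(features = do.call(rbind, feats),
       asymmetry = do.call(rbind, asym),
       meta = cohort$meta, reconstructor = rec)
}

#' Group comparison report
#'
#' Reproduces the study's statistical structure on a processed cohort, per
#' foreground frequency: rank-sum comparisons of the left vs right features
#' of healthy subjects, of the affected vs healthy (anatomical) side
#' features of patients, and of the healthy vs patient GAI and IAI; plus
#' box-and-whisker summaries and the positive-rate curves with the key
#' frequency range. "Not symmetrical" (NS) GAI records enter the group
#' comparison at the formula supremum (200%) by default; set
#' \code{ns_value = NA} to exclude them instead. No multiple-testing
#' correction is applied across frequencies.
#'
#' @param features,asymmetry data.frames from [processCohort()].
#' @param alternative sidedness of the healthy-vs-patient index tests;
#'   default "two.sided".
#' @param ns_value numeric value substituted for NS GAI records (default
#'   200), or NA to drop them.
#' @return a list with \code{healthy_lr} (per-frequency p-values, left vs
#'   right AR and SI in healthy subjects), \code{patient_sides} (affected vs
#'   healthy side), \code{index_tests} (healthy vs patient GAI/IAI),
#'   \code{positive} (rates and key range), and \code{boxplots}.
#' @export
groupComparisonReport <- function(features, asymmetry,
                                  alternative = "two.sided",
                                  ns_value = 200) {
  stopifnot(nrow(features) > 0L, nrow(asymmetry) > 0L)
  if (!any(features$group == "healthy") || !any(features$group == "patient"))
    stop("report requires both a healthy and a patient group")
  fr <- sort(unique(features$frequency_hz))
  hl <- features[features$group == "healthy", ]
  pt <- features[features$group == "patient", ]

  healthy_lr <- do.call(rbind, lapply(fr, function(f) {
    s <- hl[hl$frequency_hz == f, ]
    data.frame(frequency_hz = f,
               p_ar = rankSumTest(s$ar_left, s$ar_right)$p_value,
               p_si = rankSumTest(s$si_left, s$si_right)$p_value)
  }))

  ## patient features keyed to anatomical sides
  aff_img <- vapply(pt$affected_side, oppositeSide, "")
  pt$ar_affected <- ifelse(aff_img == "left", pt$ar_left, pt$ar_right)
  pt$ar_healthy <- ifelse(aff_img == "left", pt$ar_right, pt$ar_left)
  pt$si_affected <- ifelse(aff_img == "left", pt$si_left, pt$si_right)
  pt$si_healthy <- ifelse(aff_img == "left", pt$si_right, pt$si_left)

  patient_sides <- do.call(rbind, lapply(fr, function(f) {
    s <- pt[pt$frequency_hz == f, ]
    data.frame(frequency_hz = f,
               p_ar = rankSumTest(s$ar_affected, s$ar_healthy)$p_value,
               p_si = rankSumTest(s$si_affected, s$si_healthy)$p_value)
  }))

  a <- asymmetry
  a$gai_num <- ifelse(a$is_ns, ns_value, a$gai_percent)
  index_tests <- do.call(rbind, lapply(fr, function(f) {
    sh <- a[a$group == "healthy" & a$frequency_hz == f, ]
    sp <- a[a$group == "patient" & a$frequency_hz == f, ]
    tst <- function(col) {
      x <- sh[[col]]; y <- sp[[col]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) return(NA_real_)
      rankSumTest(x, y, alternative = alternative)$p_value
    }
    data.frame(frequency_hz = f,
               p_gai = tst("gai_num"),
               p_iai = tst("iai_percent"),
               gai_median_healthy = median(sh$gai_num, na.rm = TRUE),
               gai_median_patient = median(sp$gai_num, na.rm = TRUE),
               iai_median_healthy = median(sh$iai_percent, na.rm = TRUE),
               iai_median_patient = median(sp$iai_percent, na.rm = TRUE))
  }))

  events <- do.call(rbind, lapply(seq_len(nrow(pt)), function(i) {
    ev <- positiveEvents(list(affected_side = pt$affected_side[i],
                              ar_left = pt$ar_left[i], ar_right = pt$ar_right[i],
                              si_left = pt$si_left[i], si_right = pt$si_right[i]))
    data.frame(subject_id = pt$subject_id[i],
               frequency_hz = pt$frequency_hz[i],
               positive_ar = ev$positive_ar, positive_si = ev$positive_si)
  }))
  positive <- positiveRates(events)
  positive$events <- events

  boxes <- list()
  for (f in fr) {
    boxes[[as.character(f)]] <- list(
      gai_healthy = boxplotStats(a$gai_num[a$group == "healthy" & a$frequency_hz == f]),
      gai_patient = boxplotStats(a$gai_num[a$group == "patient" & a$frequency_hz == f]),
      iai_healthy = boxplotStats(a$iai_percent[a$group == "healthy" & a$frequency_hz == f]),
      iai_patient = boxplotStats(a$iai_percent[a$group == "patient" & a$frequency_hz == f]))
  }

  list(healthy_lr = healthy_lr, patient_sides = patient_sides,
       index_tests = index_tests, positive = positive, boxplots = boxes)
}
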
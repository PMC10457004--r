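# mfeitsym

Multifrequency electrical-impedance-tomography (MFEIT) brain-asymmetry
analysis: a simulation and analysis pipeline for detecting intracranial
abnormalities from the left–right symmetry of frequency-difference EIT
images of the head.

## The problem and who this is for

MFEIT (frequency-difference EIT) drives a small alternating current
(176 µA RMS) through 16 scalp electrodes at several frequencies
(21–100 kHz) and reconstructs the change in the head's internal resistivity
distribution between a background frequency (21 kHz) and each higher
foreground frequency. Brain tissue conductivity rises with frequency
(β-dispersion) at tissue-specific rates — white matter > ischemic tissue >
gray matter > hemorrhage over this band — so a unilateral lesion breaks the
left–right symmetry of the image sequence without requiring any pre-onset
baseline. This package is for researchers studying that screening idea in
silico: it provides the forward physics, a synthetic cohort generator,
calibration, reconstruction, image-feature extraction and the group
statistics as one tested, reproducible chain.

## The statistics at the core

Effective regions of interest (ROIs) are 8-connected components of pixels
with |value| ≥ 62.5% of Amax (the image's maximum absolute resistivity
change), after excluding components that touch the imaging boundary, that
cross the vertical symmetry axis, or that cover < 0.85% of the imaging
domain. Per image the pipeline computes, for each side, the ROI area ratio
(AR_ROI) and mean absolute reconstructed resistivity change (MVRRC/SI), and
two asymmetry indices (barycenter distances measured from the origin at the
bottom of the imaging circle):

    GAI = 0.5 * ( 2|Lx - Rx| / (Lx + Rx) + 2|Ly - Ry| / (Ly + Ry) ) * 100%
    IAI = 2 * |I_ROI - I_contralateral| / (I_ROI + I_contralateral) * 100%

GAI is "NS" (not symmetrical) when only one side carries a ROI; multi-ROI
images average over cross-side pairs (GAI) or over ROIs (IAI). A patient
record is a *positive event* at a frequency when the affected side's
AR_ROI (or SI) is lower than the healthy side's; the *key frequency range*
is the contiguous band where both positive rates exceed 50%. Healthy and
patient cohorts are compared per frequency with Wilcoxon rank-sum tests.

## Worked example

```r
library(mfeitsym)

protocol <- defaultProtocol()            # 16 electrodes, 9 frequencies, 21 kHz background
mesh     <- buildMesh(1024)              # deterministic mirror-symmetric FE mesh
cohort   <- generateCohort(16, 8, mesh, protocol, seed = 1)   # 16 healthy + 8 patients
processed <- processCohort(cohort, mesh, protocol)            # calibrate, reconstruct, features
report <- groupComparisonReport(processed$features, processed$asymmetry,
                                alternative = "less")         # healthy < patient (one-sided)
round(report$index_tests[, c("frequency_hz", "p_gai", "p_iai",
                             "gai_median_healthy", "gai_median_patient")], 4)
```

```
  frequency_hz  p_gai  p_iai gai_median_healthy gai_median_patient
1        3e+04 0.7288 0.6713            67.4978           116.9121
2        4e+04 0.0972 0.0210            26.3832           118.1598
3        5e+04 0.0142 0.0003            12.6302           115.7288
4        6e+04 0.0100 0.0008            10.2949           115.8644
5        7e+04 0.0239 0.0025             5.9733            28.8371
6        8e+04 0.0032 0.0015             8.9353            28.2611
7        9e+04 0.0118 0.0004             3.4920            32.2256
8        1e+05 0.0159 0.0018             6.8006            30.7951
```

The geometric asymmetry index of the lesioned group is significantly higher
than the healthy group's at 6 of 8 foreground frequencies (the intensity
index at 7 of 8), while the healthy medians fall toward ~5–13% at mid-band
frequencies — symmetric images, as built. The positive-event analysis:

```r
report$positive$rates
report$positive$key_range_hz
```

```
  frequency_hz rate_ar rate_si
1        3e+04   0.625   0.625
2        4e+04   0.625   0.625
3        5e+04   0.625   0.625
4        6e+04   0.625   0.625
5        7e+04   0.500   0.625
6        8e+04   0.625   0.750
7        9e+04   0.750   0.750
8        1e+05   0.625   0.750
[1] 30000 60000
```

Both positive rates exceed 50% on the contiguous 30–60 kHz band, which the
pipeline reports as the key frequency range for this cohort. Demographics of
the shipped patient table:

```r
cohortDemographics(patientInfoTable())
#>   group n n_male n_female age_mean   age_sd
#> 1   all 8      7        1       59 10.46081
```

See `vignette("mfeitsym-methods")` for the forward model, the generator's
tissue spectra and noise model, and every numerical design decision.

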
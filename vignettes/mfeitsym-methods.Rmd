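---
title: "Multifrequency EIT brain-asymmetry analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifrequency EIT brain-asymmetry analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfeitsym)
```

## The problem

Multifrequency electrical impedance tomography (MFEIT, also called
frequency-difference EIT) drives a small alternating current through scalp
electrodes at several frequencies and images the change of the internal
resistivity distribution between a low background frequency and each higher
foreground frequency. Because the dielectric dispersion of brain tissue
differs from that of lesions (hemorrhage in particular disperses far less
over 21–100 kHz), a single frequency sweep can reveal an intracranial
abnormality without any pre-onset baseline measurement. Healthy brains are
approximately left–right symmetric in their dispersion, and most lesions are
unilateral, so the *left–right symmetry* of the frequency-difference images
is the natural screening statistic. This package implements the entire chain
in silico: forward simulation, calibration, reconstruction, region-of-interest
(ROI) extraction, two asymmetry indices, positive-event rates, and
nonparametric group comparisons between a healthy and a diseased cohort.

## Forward model

The head section is a unit disk carrying 16 equally spaced boundary
electrodes, electrode 0 at the anterior, indices increasing clockwise in
image orientation. Current (176 µA RMS by default) is driven through
diametrically opposite pairs (k, k+8 mod 16), and for each drive the 12
adjacent non-driven electrode pairs are measured, giving 16 × 12 = 192
channels per frame. The quasi-static conduction equation
∇·(σ∇u) = 0 is discretized with linear (P1) finite elements; electrodes are
modeled as boundary-node arcs (gap model: no contact-impedance layer, which
the analysis never relies on), current split uniformly over an arc's nodes,
and the electrode potential read as the arc's mean. Using the same averaging
vector for injection and read-out makes the discrete model exactly
reciprocal, which the tests verify to 1e-8 and better.

The mesh is a deterministic triangulation by concentric rings (ring k of R
carries 16k nodes), built as a right half-disk plus its exact reflection, so
the triangulation is *exactly* mirror-symmetric about the vertical axis.
This matters: a left–right asymmetric mesh imprints a systematic asymmetry
onto every simulated subject, which would bias the very statistic the
package studies. The price is that 22.5° rotational symmetry holds only to
discretization accuracy (a few percent on a 1024-element mesh), which the
tests treat accordingly.

The sensitivity (Jacobian) of each channel to each element's conductivity is
computed by the adjoint-field method, J[m, e] = −area_e · ∇w_m · ∇u_d, and
is verified against central finite differences to better than 1%.

Amplitude-only solves are performed at each frequency (conductivity
dispersion only, no reactive component): the analysis concerns resistivity-
change magnitudes, for which the real-valued conduction model suffices.

## Synthetic data generator

The generator defines the study conditions; its defaults were fixed from
dispersion physics and are not tuning knobs.

* **Tissue spectra.** Conductivity anchors at 21 and 100 kHz with log-
  frequency linear interpolation; conductivity is non-decreasing in
  frequency (β-dispersion). Defaults (S/m at 21 kHz, relative rise over the
  band): white matter 0.07 (+20%), ischemic tissue 0.08 (+15%), unstructured
  background brain 0.10 (+12%), gray matter 0.10 (+10%), hemorrhagic blood
  0.70 (+3%). The ordering of the relative change (white matter > ischemic >
  gray matter > hemorrhage) follows the published tissue-dispersion
  literature; the absolute values are literature-inspired generator
  defaults, not ground truth.
* **Healthy phantom.** Homogeneous background plus two mirrored posterior
  white-matter disks (centers 0.55 R from the origin, ±40° off the posterior
  axis, radius 0.16 R). These emulate the pair of approximately symmetric
  stronger-resistivity features consistently seen in posterior regions of
  healthy frequency-difference head images (anatomically attributed to the
  posterior temporal lobe's maximal width/thickness, a 3D effect this 2D
  phantom represents by a dispersion contrast). Per-subject jitter (±5° in
  angle, ±0.05 in center radius, ±0.03 in disk radius) is applied to the
  *pair as a mirrored unit*, so healthy phantoms stay exactly symmetric.
* **Patient phantom.** The healthy geometry plus one unilateral hemorrhagic
  disk with randomized side, polar position (radius fraction 0.35–0.60,
  angle 40–140° from anterior) and size (radius 0.12–0.20 R).
* **Noise model.** A multiplicative per-channel gain g_c ~ N(1, 0.01),
  constant across frequency (a fixed acquisition-chain imperfection — this
  is exactly what frequency differencing and PCB calibration can remove),
  plus additive Gaussian noise with SD equal to 2·10⁻⁴ of the frame RMS
  (74 dB SNR, within the range reported for multifrequency EIT hardware
  after frequency-cycle averaging). At this level the posterior features
  remain detectable in every healthy subject, matching the healthy baseline
  the generator emulates; one cycle is simulated (averaging is a
  configuration question left to the acquisition model, not the analysis).
* **Calibration standard.** The resistor-network phantom is 16 electrode
  nodes joined to a hub by 16 spokes and around the rim by 16 ring
  resistors, all 499 Ω (32 precision resistors). A pure star would null
  every adjacent-measurement voltage under opposite drive; the ring gives
  every channel a nonzero frequency-independent theoretical value, which is
  what a frequency-response standard needs. The topology is configurable
  and documented as an approximation of the real board.
* The cohort generator draws one device gain matrix per cohort, shared by
  all subjects and by the standard's acquisition, so calibration factors
  estimated from the standard genuinely apply to the subjects.

## Calibration

Amplification factors A[f, c] = theoretical[f, c] / measured[f, c] are
computed per frequency *and per channel* (the coarser per-frequency mean is
available as an option). Applying A to the standard's own measured frames
restores the theoretical frames exactly, and applying it to subject frames
removes the per-channel gain error; a dedicated test confirms that
calibration strictly reduces the mirror-symmetry residual of healthy frames.

## Reconstruction

Damped least squares with standard Tikhonov regularization:
(JᵀJ + λ·mean(diag(JᵀJ))·I) x = Jᵀ Δv, with λ = 10⁻² by default. Expressing
λ relative to the normal matrix's mean diagonal keeps the damping mesh-size
invariant; the diag(JᵀJ) (Levenberg–Marquardt) variant is available. The
conductivity-change solution is negated to the resistivity-change sign
convention (positive = resistivity increase) and rasterized onto a 64 × 64
grid by element-at-pixel-center lookup. Row 1 is anterior; image-left
corresponds to the subject's anatomical right (radiological convention).
Amax is the maximum absolute masked pixel value; rendering uses the
diverging red (resistivity decrease) / green (≈0) / blue (increase) map with
tick labels +Amax, +0.5Amax, 0.000, −0.5Amax, −Amax.

**Frequency differencing is weighted by default.** The package reconstructs
Δv = v(f) − α·v(f₀) with α = ⟨v(f), v(f₀)⟩/⟨v(f₀), v(f₀)⟩ rather than the
simple difference. The reason is structural: a dispersive *background* —
every brain tissue's conductivity rises with frequency — makes the simple
difference proportional to v(f₀) plus contrast terms. That uniform
component reconstructs as a domain-filling blob that saturates the
62.5%·Amax ROI band, touches the imaging boundary, and is therefore always
excluded, leaving no effective ROI in any image. The α-projection removes
exactly that component and leaves the spatial *deviations* from uniform
dispersion, which are the diagnostically meaningful structures. The simple
difference remains available (`weighted_difference = FALSE`).

## ROI extraction and features

Candidate ROIs are 8-connected components of pixels with |value| ≥
0.625·Amax (threshold inclusive; 4-connectivity available). Effective ROIs
survive three exclusions, applied in this order:

1. boundary contact — any pixel 8-adjacent to an out-of-mask pixel;
2. axis crossing — pixels on both sides of the vertical symmetry axis (on
   even grids the axis is the boundary between the two center columns, so
   side assignment is total; on odd grids the center column itself counts
   as crossing);
3. small target — area below 0.85% of the in-mask pixel count. The
   source definition ties the 0.85% to axis-cut halves, but since all
   axis-crossing components are already excluded by rule 2, the per-ROI
   reading is the only self-consistent one and is what is implemented.

Per side, the area ratio AR_ROI is the side's total effective-ROI pixel
count over the in-mask pixel count (0 when the side is empty). The signal
intensity (MVRRC) is the mean |value| over the side's ROI that contains the
side's peak |value|; an empty side borrows the *mirrored footprint* of the
opposite side's peak ROI and averages raw |values| inside it
(`mirrored_fallback`), and 0 when neither side has a ROI.

## Asymmetry indices

With the coordinate origin at the intersection of the vertical axis and the
circle's lowest point, and (Lx, Ly)/(Rx, Ry) the left/right ROI barycenter
distances to the X and Y axes (units cancel):

GAI = 0.5·(2|Lx−Rx|/(Lx+Rx) + 2|Ly−Ry|/(Ly+Ry))·100%.

One ROI per side applies the formula directly; multiple ROIs average the
formula over all cross-side pairs; exactly one populated side is "not
symmetrical" (NS); no ROIs at all is undefined (NA, excluded from
statistics). Degenerate denominators (both distances zero) contribute 0 —
symmetric-in-nothing. For the intensity index, each effective ROI is
compared with its mirror-reflected footprint (raw pixels, no threshold):

IAI = 2·|I_ROI − I_contra|/(I_ROI + I_contra)·100%,

averaged over all effective ROIs. Both indices live in [0, 200], are 0 under
perfect mirror symmetry, and are invariant to left–right flips and to
positive rescaling of the image — all verified as property tests.

For group statistics NS records enter at the formula supremum 200% (maximal
asymmetry) with the NS flag preserved; an exclude-NS mode is available. The
supremum encoding was chosen because an NS image is the extreme of the
asymmetry the index measures, and dropping such records would censor
precisely the most pathological images.

## Positive events and statistics

For a patient record, the event is positive when the affected side's AR_ROI
(or signal intensity) is *smaller* than the healthy side's; ties are
negative. Anatomical sides are mapped to image sides through the
radiological convention. The per-frequency positive rate is positives over
patients, and the key frequency range is the maximal contiguous band where
both the AR and SI rates exceed 50%.

Group comparisons use the Wilcoxon rank-sum test (exact enumeration for
pooled samples ≤ 12 without ties, otherwise the normal approximation with
midranks, tie correction and continuity correction — the test suite checks
exact agreement with full permutation enumeration for all tie-free shapes up
to n₁+n₂ = 10). Left-vs-right healthy comparisons use the unpaired rank-sum
test even though sides are paired within subject — fidelity to the source
methodology over statistical optimality; a signed-rank alternative would be
a one-line change. Two-sided tests are the default; the healthy-vs-patient
index comparison supports the one-sided "patients higher" alternative, which
is the directional hypothesis the indices were designed for. No
multiple-testing correction is applied across the 8 frequencies, again for
methodological fidelity.

## Problem sizes and numerical choices

The default analysis mesh has 1024 elements (577 nodes); reconstruction and
feature extraction run on a 64 × 64 grid. Forward-model accuracy tests use a
16384-element reference mesh, against which the 4096-element solution's
boundary voltages agree to ~0.5%. The full default cohort (16 healthy + 8
patients, 9 frequencies, 192 channels) generates and processes in well under
a minute on one core. Ties in the ring-merge triangulation are broken
deterministically; all stochastic operations are seed-deterministic, and the
cohort generator derives per-subject seeds from the master seed.

## What passing tests do and do not show

The generator emulates a circular 2D section with piecewise-constant
dispersion, mirrored posterior features, disk lesions, gain errors constant
in frequency and white additive noise. It does not model skull/scalp
layering, electrode misplacement, contact impedance, anatomically realistic
geometry, 3D current spreading, or physiological drift. Cohort-level
results (healthy left-right null, patient-vs-healthy index separation, a
mid-band key frequency range) therefore demonstrate that the *pipeline*
reproduces the qualitative study structure under its stated assumptions —
they are not evidence about real patients. With 16 independent null
hypothesis tests per cohort, some seeds will produce a healthy left-right
p-value below 0.05 by chance alone; that is expected behavior of the null,
not a pipeline defect.

## A worked example

```{r example, eval = FALSE}
protocol <- defaultProtocol()
mesh <- buildMesh(1024)
cohort <- generateCohort(16, 8, mesh, protocol, seed = 1)
processed <- processCohort(cohort, mesh, protocol)
report <- groupComparisonReport(processed$features, processed$asymmetry,
                                alternative = "less")
report$index_tests[, c("frequency_hz", "p_gai", "p_iai")]
report$positive$key_range_hz
```
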
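---
title: "Super-resolution ULM of testicular microvasculature: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolution ULM of testicular microvasculature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ulmvasc)
```

## What this package computes

Ultrasound localization microscopy (ULM) builds vascular maps below the
acoustic diffraction limit by localizing individual intravenous contrast
microbubbles in a contrast-enhanced ultrasound (CEUS) sequence, linking the
localizations into tracks, and accumulating thousands of tracks into
super-resolution (SR) rasters. `ulmvasc` implements that chain for
testicular microcirculation — paired B-mode/CEUS acquisitions at 114 Hz —
together with the downstream quantification used to compare non-obstructive
(NOA) and obstructive (OA) azoospermia: five vascular parameters (mean flow
velocity, tortuosity, diameter, box-counting fractal number, vessel
density), cohort-averaged histograms, a 12-sector regional breakdown around
the testicular hilum, a normalized Bernoulli pressure map, and a clinical
statistics layer (Lambert volume, group t-tests, Pearson matrix with
assumption checks, ROC/Youden, and the FSH + mean-diameter logistic
diagnostic model).

No patient imaging is distributed with the package. A synthetic module —
vascular phantoms with analytically known geometry, a microbubble transit
simulator with full ground truth, and an NOA/OA cohort simulator — stands in
for the acquisition, so every stage is testable end to end.

## The processing model, stage by stage

**SVD clutter handling.** The B-mode sequence is reshaped into a Casorati
matrix (pixels x frames) and reconstructed from its leading singular
components. Slow tissue structure concentrates in the top components while
transiting bubbles spread across the tail, so truncation removes bubble
clutter before motion estimation. The automatic rank keeps 99.9% of squared
singular-value energy: the static tissue pattern alone typically holds over
99% of the energy, and a 95% rule would select rank 1 and flatten exactly
the tissue-motion components that registration needs. `keep_rank` can be
set explicitly.

**Two-stage motion estimation.** Stage 1 estimates a global per-frame
translation against the middle frame (chosen to halve the largest
displacement that must be interpolated) by phase correlation: Hann
windowing, regularized spectral whitening (`|R| + 0.01 max|R|`), a
half-Nyquist low-pass, and a locally upsampled DFT evaluation of the
correlation surface. The regularization matters: fully whitened phase
correlation amplifies the incoherent high frequencies created by resampling
non-periodic fields and misses the 0.1 px target. Estimated translations
are then smoothed over a 9-frame Gaussian window — physiological motion
(breathing at ~0.3 Hz, probe drift) is slow against a 114 Hz frame rate, so
smoothing suppresses per-frame estimation jitter without biasing the
motion. Stage 2 refines residual local motion with per-block windowed phase
correlation on the globally aligned frame (16 px blocks, displacements
beyond the +-3 px search radius distrusted and zeroed), bilinearly
upsampled to a dense field. The inverse transform is applied to the CEUS
frames with bilinear interpolation and zero fill.

**Localization.** Per frame, the temporal-median background is subtracted
(static speckle otherwise imprints a ~0.4 px position bias that dwarfs
everything else), candidate pixels are regional maxima above mean + 4 SD,
and each is refined to an intensity-weighted centroid in an 11 px window
(window about four PSF sigmas wide; smaller windows pixel-lock).
Detections closer than half a window merge (brighter wins); detections
whose nearest neighbor lies between the merge radius and `isolation_px`
are dropped *pairwise*, because partially overlapping point-spread
functions bias both centroids — the classical sparse-bubble selection of
ULM. On isolated rendered blobs the detector is accurate to ~0.06 px;
inside the partial-overlap ring errors approach 1 px, which is why the
ring is discarded rather than kept.

**Tracking.** Frame-to-frame matching minimizes summed Euclidean distance
by an exact Hungarian assignment, gated at `v_max / frame_rate`. The gate
default is 15 mm/s — five times the ~3 mm/s testicular scale. A much wider
gate measurably splices tracks onto neighboring bubbles whenever a
detection drops out for a frame, creating fictitious 40-50 mm/s segments.
Tracks shorter than three frames are discarded. Track coordinates are then
smoothed with a [1/4, 1/2, 1/4] kernel: merged detections of
near-coincident bubble pairs alternate at exactly half the frame rate, and
this kernel nulls that Nyquist component while leaving sub-pixel-per-frame
physical motion essentially untouched. Per-segment velocity is displacement
times frame rate, computed after smoothing.

**SR mapping.** Tracks are rasterized segment by segment (Bresenham) onto a
4x upsampled grid; a pixel is counted once per track traversal (the
junction pixel shared by consecutive segments is de-duplicated — naive
per-segment counting doubles every interior count). The count raster is
blurred with a discrete Gaussian whose SD equals the localization
uncertainty expressed in SR pixels (default 1 SR px = 0.25 acquisition
pixel, matching the measured centroid precision; the same discrete kernel
later sets the binarization threshold, so blur and threshold can never
disagree). Velocity maps take the vector mean of segment velocities per
pixel; the direction map encodes the axial sign (positive toward the
transducer) as a signed magnitude, with the full angle kept as an
attribute. The MIP is the per-pixel temporal maximum of the
median-subtracted CEUS stack. The pressure map applies the simplified
Bernoulli relation — dynamic pressure proportional to speed squared — and
max-normalizes, so the dropped proportionality constant cancels exactly:
`p = v^2 / max(v^2)`, with isobars at `k / (n + 1)`, `k = 1..n`.
Max-scaling is one of several defensible normalizations; it is the one
implemented, and the invariance to uniform velocity rescaling is tested.

**Quantification.** The vessel mask thresholds the density at half the peak
amplitude a *single* unit-mass line traversal attains after the blur
(referencing one traversal rather than the global density peak keeps faint
single-pass vessels detectable next to multi-pass trunks). Centerlines come
from Zhang-Suen thinning; the diameter at each skeleton pixel is twice the
Euclidean distance to the nearest background pixel. Tortuosity is per-track
path length over chord (zero-chord tracks excluded and tallied). The
fractal number is box counting on log N vs log(1/s): local slopes between
adjacent scales are averaged over the longest run of at least three
consecutive slopes with pairwise spread at most 0.2 ("almost constant"
made operational); the log-log axes are used rather than a literal semi-log
reading, which would not produce a dimension. Vessel density is the mask
fraction of the ROI. Velocity statistics use strictly non-zero magnitude
pixels. Cohort histograms normalize within patient first and then average
the fractions, so each patient contributes equally (bins: velocity 0.5 mm/s
on [0, 10]; tortuosity 0.25 on [1, 6]; diameter 20 um on [0, 400]).

**Sectors.** The 12 x 30-degree frame starts at the testicular long-axis
direction and proceeds counterclockwise in physical coordinates (x right,
y up); image rows grow downward, so the raster handedness is flipped
internally. Sector k is the half-open wedge [(k-1) 30, k 30) degrees: a
boundary point belongs to the higher sector. Tracks are assigned to sectors
by the midpoint of their bounding box; sectors too small to support three
box-counting scales report `NA` fractal numbers.

**Clinical statistics.** Testicular volume is length x height x width x
0.71 (Lambert). Group comparisons use the pooled-variance t-test by default
(Welch behind a flag). The Pearson layer reports pairwise-complete r and
two-sided p with per-variable Shapiro-Wilk and (across groups) Levene
checks. ROC analysis sweeps the observed scores, computes the trapezoid AUC
(identical to the Mann-Whitney U statistic over n1 n0 — a tested identity),
a DeLong 95% CI, and the Youden-optimal cutoff with ties broken toward
higher specificity. The diagnostic model is a maximum-likelihood logistic
regression with OA coded 1, Wald CIs, odds ratios as exact exponentials of
the coefficients, McFadden pseudo-R2, and VIFs from auxiliary linear
regressions; perfect separation raises an error naming the covariate. No
multiple-testing adjustment is applied anywhere, matching the reporting
convention of the clinical analysis this package follows. The
classification report works from a fitted model and records, or directly
from a 2x2 observed-by-predicted table, at a probability cutoff of 0.5.

## What the simulator emulates — and what it does not

The transit simulator seeds bubbles at each vessel inlet as a Poisson
process (`mb_rate_hz` per segment; the in-plane concentration is a free
calibration choice — 2-3 bubbles/s keeps a handful of bubbles concurrently
in the field, the dilute regime ULM requires), advects them by plug flow
along the centerline at a fixed lateral offset drawn uniformly across the
lumen, and adds a small reflected lateral random walk (3 um/frame) for
shear-induced dispersion — without it, trajectories are perfectly parallel
lines and the density band develops persistent lateral gaps no real vessel
shows. Bubbles render as isotropic Gaussian blobs (PSF sigma 0.25 mm
default; 0.15 mm for the high-frequency recovery experiments) on smoothed
Rayleigh speckle at a configurable contrast (20 dB default), with identical
sinusoidal tissue motion on both channels (1 px, 3.5 s period by default)
and a fainter bubble imprint on B-mode as the clutter the SVD stage must
remove.

Not emulated: nonlinear bubble acoustics, RF-domain speckle physics,
depth-dependent PSF, out-of-plane motion, elastic (non-rigid) tissue
deformation beyond the optional local field, and bubble disruption. Passing
tests therefore demonstrate the correctness of the *processing chain* under
a controlled, truth-known acquisition model — not clinical performance on
patient data.

The cohort simulator draws the five vascular parameters from truncated
normals at the published NOA/OA group means and SDs (density in [0, 1],
fractal in [1, 2], tortuosity >= 1). The clinical covariates are not
tabulated group-wise in the source analysis, so their distributions are
plausible choices consistent with the reported directions and cutoffs:
FSH 18 (8) vs 4.5 (1.8) IU/L, LH 8 (3.5) vs 4 (1.5) IU/L, T 3.5 (1.5) vs
4.2 (1.5), age 28 (5) vs 32 (5) years, volume 8 (3) vs 13 (4) mL for NOA
vs OA. An optional Gaussian copula imposes a correlation structure; testis
dimensions are derived with fixed aspect ratios so the Lambert formula
reproduces the drawn volume exactly.

## The recovery experiment

`run_recovery_case()` fixes the conditions used to validate end-to-end
parameter recovery: straight, sinusoidal and bifurcating phantoms with
0.3 mm vessel radius and 3 mm/s plug flow in a 6 x 4 mm field, imaged for
30 s at 114 Hz with 0.1 mm pixels, a 0.15 mm PSF (a 12-14 MHz scrotal
linear array), 2.2 bubbles/s per segment, 1 px tissue motion, and the
default pipeline with a 7 px detection window (about four PSF sigmas at
this frequency). Those sizes put the vessel diameter at 24 SR pixels and
yield roughly 30-50 usable tracks per vessel cross-section — enough for
the half-peak mask (with its closing step) to fill the lumen while staying
below the multi-pass widening that very dense accumulation produces under
the single-traversal threshold. The sinusoid is gentle (amplitude 0.15 mm,
wavelength 4.5 mm) for a physical reason: a bubble at lateral offset `u`
from a centerline of curvature `kappa` genuinely moves at
`v (1 +- u kappa)`, so tight bends make the plug speed an ill-defined
velocity target; the chosen geometry keeps `u kappa` below 0.09. The
diameter tolerance is max(1 SR px, 10%) and the velocity tolerance 5%, at
fixed seeds.

```{r recovery, eval = FALSE}
run_recovery_case("straight", seed = 101)
```

## Numerical choices and degenerate inputs

- Sub-pixel registration refines on an upsampled DFT grid (factor 50,
  +-1.5 px) — about 0.02 px resolution; all-zero frames fall back to
  identity motion with a warning.
- The density blur uses an explicit separable kernel truncated at 4 SD and
  renormalized; mass over an interior line is conserved to well under
  0.5%.
- Bresenham rasterization rounds segment endpoints to the SR grid; a
  traversal increments each pixel once.
- Box sizes default to descending powers of two; any strictly descending
  sequence is accepted (the Sierpinski-carpet check uses powers of three,
  the carpet's natural scales). Fewer than three scales is an error; if no
  slope run is stable the mean of all slopes is used with a warning.
- Zero-chord tracks, empty skeletons, all-zero velocity rasters and empty
  patient histograms are excluded-and-tallied or reported `NA` rather than
  propagating NaN; an all-zero velocity field is an error for the pressure
  map ("no flow signal").
- All simulation randomness flows through a single integer seed
  (`withr::with_seed`), making every pipeline product bit-reproducible.

## Known limitations

- The half-peak binarization measures apparent width: with very dense
  multi-pass accumulation the mask widens by a few blur sigmas beyond the
  true lumen; with too few tracks it fragments. The recovery conditions
  document the regime in which the published rule is accurate.
- Velocities are first-order frame differences; speeds far above the gate
  or below ~0.5 px/s of apparent motion are outside the validated range.
- The sector fractal number is undefined (NA) for wedges smaller than
  three box-counting scales.
- DeLong CIs assume independent subjects; the pseudo-R2 is McFadden's.
- The two-stage registration is a translation + coarse-local scheme; it is
  not a reproduction of any specific published registration algorithm, and
  purely elastic deformation beyond the block scale is out of scope.
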
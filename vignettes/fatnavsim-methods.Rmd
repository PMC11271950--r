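---
title: "Simulating motion-degraded fat-navigator tracking and its image-quality consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating motion-degraded fat-navigator tracking and its image-quality consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Navigator-based retrospective motion correction for brain MRI estimates the
head pose from rapid 3D fat-selective volumes (FatNavs) interleaved with the
host acquisition. To cost almost no scan time, FatNavs are undersampled
aggressively (R = 16 as 4x4 in the two phase-encode directions) and
reconstructed with GRAPPA, whose weights are calibrated from a fully sampled
ACS block acquired **once** at the start of the scan. If the head later moves
far from the calibration position, the calibration no longer matches the
data, the navigator fills with parallel-imaging artifacts, and the rigid
registration that produces the motion estimate becomes biased. `fatnavsim`
simulates this chain on synthetic data and carries the resulting *residual*
motion through to the quality of the corrected T1-weighted image.

All real-data stages of the original experimental design (scanner
acquisition, human observers) are replaced by explicit generative models, so
every quantity in the pipeline is computable and testable.

# Pipeline and models

## Synthetic head and coils

The phantom is analytic: an ellipsoidal brain (default semiaxes 60/72/64 mm)
with WM core, GM ring and CSF rim, and - after a skull gap (10 mm) - a bright
subcutaneous fat shell (9 mm thick). The fat shell is the navigator
contrast; the brain interior is the T1-weighted target; their supports are
disjoint by construction. Edges carry a one-voxel linear ramp so that
k-space energy decays realistically instead of ringing from hard voxel
edges. An anatomical atlas would look prettier but adds nothing to the
mechanism under study, and an analytic shape gives an exact voxel-membership
oracle for the tests.

Coil sensitivities are smooth complex fields: Gaussian magnitude profiles
centered on a ring of channels around the head (alternating slightly above
and below the axial midplane so the z-direction is also encoded) with a
linear phase along each coil's direction. Eight channels are enough for
R = 2x2 work; the navigator experiment at R = 4x4 uses 16. A real 64-channel
array brings nothing extra to the degradation mechanism and would slow every
test several-fold.

Noise, when requested, is complex Gaussian added in k-space; under the
unitary centered FFT this is equivalent to image-space noise but keeps the
contract simpler (one noise site).

## k-space conventions

DC sits at 0-based index `floor(N/2)` on every axis; transforms are unitary.
Undersampling keeps every `accel`-th line phased so the DC line is always
sampled (the sampling phase is a convention; the mechanism does not depend
on it). ACS windowing uses a Tukey window (taper fraction 0.5) on the
phase-encode axes - the readout is fully sampled, so windowing it would only
discard signal; a flag allows 3D windowing. A Hamming window is applied to
the ACS block in k-space before zero-filling: apodizing the *spectrum* is
what suppresses ringing in the low-resolution calibration images, and the
subsequent coil/RSS ratio is invariant to any *image*-domain window, which
would therefore be a no-op.

## Coil-map estimation

Maps are estimated as the ratio of each coil's low-resolution image to the
root-sum-of-squares over coils, then smoothed by a penalized least-squares
smoother solved in the DCT basis (a discrete smoothing spline with a
Laplacian-squared penalty); the smoothing parameter is chosen by generalized
cross-validation. Real and imaginary parts are smoothed (a magnitude/phase
variant is available behind a flag); outside the support (RSS below 5% of
its maximum, where the ratio is dominated by noise) the smoother
extrapolates. The 5% threshold is a guard against division blow-up in the
signal-poor interior; results are insensitive to it over 2-10%.

## GRAPPA

"Kernel size 2x2" is interpreted as 2x2 *source blocks* in the undersampled
(y, z) plane; 3 readout taps are added along x (the readout extent is a free
choice and 3 is the common default in practice). For each missing-offset
class within the R-cell the weights solve a Tikhonov-regularized least
squares over all sliding fits inside the ACS; the regularizer is scaled to
the mean diagonal of the normal matrix (relative lambda 1e-4) because
unregularized fits are ill-conditioned at desk-scale coil counts.
Reconstruction passes acquired samples through bit-identically, synthesizes
every missing sample with circular boundary handling (consistent with
FFT-periodic data), and can re-insert an embedded ACS block verbatim.

The central mechanism - reconstruction error growing with the distance
between the current pose and the calibration pose - needs no bit-level
equivalence with any scanner implementation, and none is claimed.

## Rigid motion and registration

Poses are (tx, ty, tz / rx, ry, rz) in mm and degrees, rotations about the
volume center, applied rx -> ry -> rz in a right-handed frame. Resampling
uses Catmull-Rom cubic interpolation by default (trilinear available for
speed), implemented in a small C++ routine; out-of-field voxels are zero.

Registration minimizes the sum of squared differences over the 6 parameters
by Gauss-Newton, coarse-to-fine with Gaussian smoothing at FWHM 16, 8, then
4 mm. The 16 mm level is needed for the capture range demanded by the motion
grid (40 mm translations combined with 20 degree rotations); with only the
finer levels the optimizer can start outside the basin of attraction. Each
step passes a backtracking line search (step halved until the SSD decreases,
otherwise the level stops): on severely corrupted navigators the SSD
landscape has flat, runaway directions, and monotone descent is what keeps
the estimate physical without constraining good solutions. Convergence is
declared when every parameter update falls below 1e-3 (mm or deg), with at
most 64 iterations per level. SSD is appropriate because both volumes share
modality and contrast.

On uncorrupted transformed phantoms the registration recovers applied poses
to well under 0.1 mm / 0.1 deg - this zero-error baseline is what makes the
residuals attributable to the GRAPPA corruption.

## Motion grid, residual table, interpolation

The grid is the full factorial of rotations {0, 5, 10, 15, 20} deg (125
sets) paired index-to-index (lexicographic order) with the factorial of
translations {0..40} mm; negative-z translations (100 sets, movement toward
the feet being the one direction a head coil permits) are paired cyclically,
for 225 corruption runs per dataset. Residuals (applied minus estimated) are
averaged across datasets. Rotational residuals live on the (rx, ry, rz)
magnitude grid, translational ones on the (tx, ty, tz) grid with signed z;
queries interpolate trilinearly, re-apply the query's signs on the symmetric
axes, and clamp to the hull with a warning. Registrations that error out are
logged and excluded from the average.

## Motion traces and metrics

Traces are fractal noise: octave k contributes `weight^k` times a natural
cubic spline through `2^k + 1` uniform random controls; the sum is demeaned.
"Smooth" motion uses 3 octaves, "rough" 8 - the regimes are named after
their visual character (slow drift vs rapid jumps); the octave counts are
this package's calibration of that distinction, since no quantitative
definition exists. Rotation and translation channel groups are rescaled
exactly to their target RMS (per-channel RMS averaged over the three
channels of the group - the reading chosen for an ambiguous convention; any
fixed reading only relabels the RMS axis). The default set sweeps 24 RMS
levels up to 20 deg / 40 mm, four independent draws per level (different
k-space timing of the same magnitude), giving 96 traces per kind, 192 per
dataset, 576 over three datasets. The rotation and translation ladders are
paired by a seeded permutation rather than proportionally: with the two
magnitudes locked together the RMS regression's two regressors would be
exactly collinear and the model unidentifiable.

Framewise displacement is the sum of absolute parameter increments with
rotations converted to arc length on a 50 mm sphere; RMS compresses a trace
to one magnitude, FD to one "activity" value - rough traces carry much more
FD than smooth ones at matched RMS, which is why both metrics are kept.

## Target corruption and gradient entropy

The T1-weighted volume is corrupted shot-wise: the partition-encode axis is
split into contiguous near-equal blocks (one per readout train), each
shot's lines are taken from the FFT of the volume at that shot's pose, and
the composite k-space is inverted. This is exact for piecewise-constant
pose per shot. The with-correction arm uses the interpolated residual
trace; the no-correction arm uses the full trace.

Gradient entropy uses in-plane Prewitt gradients (x and y only, per axial
slice; the slice-select direction is deliberately excluded), edge-replicated
boundaries, the gradient-magnitude volume max-normalized and quantized to
256 bins, and base-2 Shannon entropy over the whole volume (a single-slice
flag exists). Entropy of the whole volume was chosen over a single slice
because shot-wise artifacts spread along the partition direction.

## Observers and statistics

Simulated observers share three latent cutpoints on the metric axis
(calibrated to the quartiles of the observed metric distribution) and draw
independent logistic noise; the score is 4 minus the number of cutpoints
below the noisy metric. This latent-variable model is a modelling choice -
nothing is known about real observers' internal criteria - but it produces
ordinal data with tunable agreement, which is all the statistical layer
needs.

Agreement uses Krippendorff's alpha with the ordinal metric (coincidence
matrix formulation, missing ratings allowed). Category probabilities come
from baseline-category multinomial logistic regression (matching the
convention of the classical routine this replaces; an ordinal cumulative
model is a flag away), with category intercepts at the crossings of
adjacent-category curves found by bisection. The RMS model is ordinary
least squares with a free intercept - the printed form of the model fixes
the intercept at 1, which would be unit-dependent and is read here as a
typesetting artifact - with and without the rotation x translation
interaction; BIC (`n log(RSS/n) + k log n`) selects between them, with an
exact-fit guard (both RSS at floating-noise level selects the smaller
model). Boundaries invert the selected model at each category intercept
with the other regressor at zero; negative solutions clip to zero and are
flagged unreachable. FD models are linear OLS and `a + b log(X - c)`
(natural log) via Levenberg-Marquardt with `c` bounded below `min(FD)` and
`b > 0` enforced by bounded restarts; the log boundary inverts as
`c + exp((Y - a)/b)`.

# Numerical choices and degenerate inputs

* Exactness guards: zero poses and zero traces return inputs unchanged;
  constant volumes have entropy 0; zero-variance rating tables raise an
  error rather than returning a meaningless alpha.
* The BIC exact-fit guard (RSS below 1e-12 of the total sum of squares)
  prevents log-of-machine-noise artifacts on noiseless data.
* Grid shapes divisible by the acceleration factors keep the circular
  GRAPPA boundary consistent with the sampling lattice (48 and 96 work for
  2x2 and 4x4).
* Complete separation in the multinomial fit is detected by coefficient
  blow-up and refitted with a small ridge penalty, flagged in the result.

# Problem sizes

The defaults used by the test-suite and the acceptance script are desk
scale, chosen so the full chain runs on one core in minutes: navigator
48^3 at 4 mm (as acquired), target 64-96^3 at 2-3 mm instead of 192^3 at
1 mm, 16 coils instead of 64, a 3x3x5 sub-grid of the motion grid for the
tracking table, 24 traces of 16 shots for the corruption arms. The full
study conditions (225-point grid, 192^3 target, 96 + 96 traces per dataset,
three datasets) are what `default_experiment_config("full")` encodes; the
mechanism is identical, only sampling density changes.

# What the synthetic data does and does not show

The generator reproduces the *structure* of the real experiment: fat/water
contrast separation, smooth coil fields, fixed-calibration GRAPPA, shot-wise
corruption, ordinal scoring coupled to image quality. It does not model MR
signal evolution (T1 recovery along the readout train, fat chemical shift,
excitation profiles), receive-field asymmetries of a real array, scanner
reconstruction details, or human perceptual criteria. Passing tests
therefore demonstrate the degradation mechanism and the correctness of the
analysis machinery - not the numerical boundary values that a specific
scanner, cohort and pair of observers would produce. Quantities that depend
on the unavailable in-vivo data (printed boundary values, in-vivo R^2,
observer alphas) are reproduced in *kind* (direction, ordering, model
preference), not in value.
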
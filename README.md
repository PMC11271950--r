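# fatnavsim

Simulation toolkit for studying how large head motion degrades highly
accelerated 3D fat-navigator (FatNav) volumes reconstructed with GRAPPA, how
that degradation biases navigator-derived motion estimates, and what that
residual motion does to the quality of a 3D T1-weighted brain volume.

## Who this is for

3D FatNavs are rapid fat-selective gradient-echo volumes interleaved with a
host sequence (e.g. MPRAGE) and used for retrospective rigid motion
correction. They are typically accelerated at R = 16 (4x4) and reconstructed
with GRAPPA from auto-calibration (ACS) data acquired **once** at the start
of the scan. When the head moves far from the calibration position, the
GRAPPA reconstruction degrades, the navigator volume fills with parallel
imaging artifacts, and the motion estimate derived from it becomes biased.
This package lets MR physicists quantify that chain end to end on synthetic
data: no scanner, no subject, fully reproducible.

## The model in brief

1. **Synthetic head**: an analytic ellipsoidal brain (CSF/GM/WM) plus a
   bright subcutaneous fat shell; smooth complex coil sensitivities on a
   ring of channels.
2. **Navigator corruption** (fixed-calibration pipeline): rigid transform
   `T(p)` (6 parameters: mm, deg) -> multiply by coil maps -> centered FFT
   -> Cartesian undersampling (R = accel_y x accel_z) -> GRAPPA synthesis
   with weights calibrated at the *unmoved* pose -> root-sum-of-squares.
3. **Tracking accuracy**: for a 225-entry grid of applied poses
   (rotations 0..20 deg by 5; translations 0..40 mm by 10, z also negative),
   register the corrupted navigator to the reference and tabulate the
   residual `r = p_applied - p_estimated`; interpolate `r` linearly for any
   query motion.
4. **Image quality**: shot-wise k-space splicing corrupts the T1-weighted
   target with either the full motion trace (no correction) or the
   interpolated residual trace (FatNav correction). Quality is scored by
   gradient entropy `GE = -sum p_i log2 p_i` over the Prewitt
   gradient-magnitude histogram, plus simulated ordinal observers (4 = no
   visible artifacts .. 1 = severe).
5. **Statistics**: Krippendorff's alpha between observers; multinomial
   logistic regression of score on GE with category intercepts at curve
   crossings; the RMS model `Y = b0 + a*X1 + b*X2 + c*X1*X2` (X1 = RMS
   rotation, X2 = RMS translation, BIC model selection) inverted to motion
   boundaries per quality category; and framewise-displacement models
   `Y = a + b*X` and `Y = a + b*log(X - c)` on the 50 mm-sphere FD metric.

## Worked example

```r
library(fatnavsim)

spec <- phantom_spec()                      # 48^3 navigator grid at 4 mm, 8 coils
ph   <- make_head_phantom(spec, "nav")
maps <- make_coil_maps(spec, "nav")
ksp  <- simulate_multicoil_kspace(ph$fat, maps)

sch <- sampling_scheme(2, 2, c(20, 32), dim(ph$fat))
w   <- calibrate_grappa(extract_acs(ksp, c(20, 32)), sch)

# navigator reconstructed after the head moved 20 mm / 10 deg, with the
# GRAPPA weights still calibrated at the original position ...
pose <- rigid_pose(tx = 20, rx = 10)
bad  <- corrupt_fatnav(ph$fat, maps, pose, w, sch)
# ... versus the same moved navigator without undersampling
sch1  <- sampling_scheme(1, 1, c(20, 32), dim(ph$fat))
w1    <- calibrate_grappa(extract_acs(ksp, c(20, 32)), sch1)
clean <- corrupt_fatnav(ph$fat, maps, pose, w1, sch1)
nrmse(bad, clean)          # parallel-imaging artifact level
#> [1] 0.1499671

ref <- corrupt_fatnav(ph$fat, maps, rigid_pose(), w, sch)
est <- register_rigid(bad, ref, c(4, 4, 4))
round(as.numeric(est), 2)  # estimated (tx ty tz rx ry rz)
#> [1] 19.88  0.00  0.00  8.79  0.03 -0.02
```

The mismatched calibration leaves a 15% artifact level in the navigator,
and the motion estimate derived from it is biased: the applied 10 degree
rotation comes back as 8.79 degrees (a 1.2 degree residual) while the
translation survives almost intact. Across the full motion grid this
residual grows with pose magnitude - exactly what the tracking-accuracy
table captures. `run_experiment()` chains every stage
(phantoms -> tracking table -> fractal-noise traces -> both corruption arms
-> gradient entropy/FD -> observers -> boundary report) and writes NIfTI,
CSV, YAML and JSON outputs to a run directory.

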
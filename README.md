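# lgeDixon

Simultaneous quantification of left atrial (LA) wall fibrosis and
epicardial adipose tissue (EAT) from 3D late gadolinium enhanced dual-echo
Dixon MRI (LGE-Dixon).

Atrial fibrosis and the epicardial fat that abuts the LA wall are both
risk factors for atrial fibrillation, and LGE-Dixon imaging captures the
two in a single, intrinsically co-registered acquisition: the water image
carries the LGE contrast used for scar, the fat image delineates the EAT.
This package re-implements that analysis chain end to end for researchers
who want a reproducible, testable version of it — including the vendor
water–fat separation step — driven by a digital LA phantom in place of
patient data.

## What it computes

**Two-point Dixon separation.** Each echo is modelled per voxel as
`S(TE) = A(T1, TI) · (W + F·e^{i·2π·f_fat·TE}) · e^{i·2π·ψ·TE}` with
`A = 1 − 2e^{−TI/T1}` the inversion-recovery weighting, `f_fat` the
single-peak fat chemical shift (−3.4 ppm ≈ −217 Hz at 1.5 T) and `ψ` the
B0 field map in Hz. `estimateFieldMap()` resolves the per-voxel water/fat
phasor ambiguity by magnitude-guided region growing (each voxel takes the
candidate closest to its resolved neighbourhood); `separateWaterFat()`
then demodulates `ψ` and solves the 2×2 complex linear system for the
water and fat magnitudes at arbitrary echo times.

**Fibrosis quantification.** The LA wall mask is the intramural tracing
minus mitral valve, pulmonary-vein antra, appendage and blood pool
(`deriveWallMask()`). The patient-specific scar threshold is the midpoint
of the mean blood-pool and mean mitral-valve signal on the water image,
`thr = SI_blood + (SI_MV − SI_blood)/2`, and the fibrosis percentage is
`100 · #{wall voxels with SI > thr} / #{wall voxels}`.

**EAT volumetry.** `eatVolume()` counts the EAT segmentation voxels and
converts by the voxel volume (1.25 × 1.25 × 2.5 mm³ = 3.90625 mm³ by
default), optionally indexed to body surface area (Mosteller by default,
Du Bois available).

**Agreement statistics.** `iccA1()` implements ICC(A,1) — two-way model,
absolute agreement, single measurement — with its F-based 95% confidence
interval; `blandAltman()` / `loaFromSummary()` give the bias, SD of
differences and 95% limits of agreement `bias ± 1.96·SD`.

**Digital phantom.** `generatePhantom()` builds a seeded analytic LA
scene (blood pool, wall shell, scar patches, EAT cap, exclusion
structures, smooth B0 field) and `simulateEchoes()` applies the forward
signal model with complex Gaussian noise, so every stage above is
testable against known ground truth.

## Worked example

```r
library(lgeDixon)

acq  <- AcquisitionParams()              # TR/TE1/TE2 = 7.1/2.2/4.8 ms, 1.5 T
spec <- PhantomSpec(scarFraction = 0.30, noiseSigma = 0.02, seed = 3L)
gt   <- generatePhantom(spec)
ech  <- simulateEchoes(gt, acq)

fm  <- estimateFieldMap(ech$echo1, ech$echo2, acq)
wf  <- separateWaterFat(ech$echo1, ech$echo2, fm, acq)

quantifyFibrosis(waterImage(wf), structureMasks(gt), quiet = TRUE)
#> FibrosisResult: 2251 / 7503 wall voxels above threshold 0.38422 -> 30.00%
#>   (blood SI 0.3089, MV SI 0.45954; voxel_fraction)

eatVolume(structureMasks(gt), heightM = 1.75, weightKg = 75)
#> EatResult: 3356 voxels = 13.11 mL (BSA 1.909 m^2 [mosteller] -> 6.866 mL/m^2)
```

The threshold (0.384) is the midpoint between the blood-pool mean (0.309)
and the brighter mitral-valve mean (0.460) on the water image; the 30.00%
fibrosis matches the phantom's designed scar fraction, and the 13.1 mL
EAT cap was sized to a typical cohort mean. `runPipeline()` automates the
same chain over a seed × noise grid from a JSON config, including a
perturbed-mask second reader for repeatability analysis, and
`inst/cli/lgedixon.R` exposes `simulate`, `separate`, `quantify`, `agree`
and `pipeline` subcommands for shell use.

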
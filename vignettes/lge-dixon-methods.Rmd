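---
title: "Methods: simultaneous LA fibrosis and epicardial fat quantification from LGE-Dixon MRI"
author: "lgeDixon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LGE-Dixon fibrosis and EAT quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgeDixon)
```

## Scope and rationale

Left atrial (LA) wall fibrosis and the epicardial adipose tissue (EAT)
adjacent to the wall are both implicated in atrial fibrillation, and a
dual-echo inversion-recovery spoiled gradient echo acquisition with Dixon
water–fat separation captures both in one scan: the water image carries
the late-gadolinium-enhancement (LGE) contrast for scar classification,
the fat image the EAT for volumetry. On clinical systems the water–fat
separation is a proprietary scanner step. This package re-implements the
whole chain — forward signal simulation, two-point separation with field
mapping, mask-based quantification and the agreement statistics used to
judge repeatability — so that every stage is open, seeded and testable.
Because patient volumes cannot be redistributed, a digital LA phantom
serves as the data source; it is first-class, tested code, not a fixture.

## The forward signal model

Each voxel contains water and fat proton densities $W, F \ge 0$ and a
longitudinal relaxation time $T_1$. At echo time $TE$ the complex signal
is

$$ S(TE) = A(T_1, TI)\,\bigl(W + F e^{i 2\pi f_{fat} TE}\bigr)\,
   e^{i 2\pi \psi TE} + \varepsilon, $$

with

* $A(T_1, TI) = 1 - 2e^{-TI/T_1}$, the idealized inversion-recovery
  weighting. $A$ vanishes at $TI = T_1 \ln 2$; with the default
  $TI = 340$ ms (the top of the 220–340 ms protocol range) tissue with a
  post-contrast $T_1$ of 500 ms is near-nulled ($|A| \approx 0.013$)
  while gadolinium-retaining scar ($T_1 \approx 250$ ms) and fat
  ($T_1 = 280$ ms, unaffected by contrast) remain bright. Exact nulling
  of $T_1 = 500$ ms would require $TI \approx 347$ ms, just outside the
  protocol range; the residual is part of what the pipeline must
  tolerate. Readout-train effects on contrast are ignored — the model is
  a stand-in for, not a claim of fidelity to, the vendor sequence.
* $f_{fat}$, a single-peak fat resonance at $-3.4$ ppm
  ($\approx -217$ Hz at 1.5 T), derived from the field strength at run
  time. Real fat spectra are multi-peak, but the vendor model is
  unspecified and a single peak keeps the two-point inverse well posed.
* $\psi$, a spatially smooth $B_0$ off-resonance field in Hz,
* $\varepsilon$, i.i.d. complex Gaussian noise per voxel and echo, with
  channel SD expressed as a fraction of the noiseless blood-pool signal
  magnitude so that noise levels are interpretable across scenes;
  magnitude images are therefore Rician.

Default acquisition parameters are the protocol settings
TR/TE1/TE2 = 7.1/2.2/4.8 ms, flip 20°, 1.5 T.

## The digital phantom

`generatePhantom()` realizes an analytic scene on a regular grid (default
$96 \times 96 \times 48$ voxels of $1.25 \times 1.25 \times 2.5$ mm³, so
whole-scene computations run in seconds): a spherical blood pool (28 mm)
inside a wall shell (3 mm — at least one in-plane voxel, enforced), an
EAT polar cap immediately outside the wall (thickness 3.5 mm, solid-angle
coverage 0.28, sized so the default cap is ≈13 mL, a typical cohort
mean), a mitral-valve disc at the inferior pole (25° angular radius), two
pulmonary-vein antra and an appendage stub cut into the shell. Exclusion
structures are confined to the shell so that all masks remain mutually
disjoint after wall subtraction. Scar patches are grown around seeded
random directions by angular distance until `round(fraction × wall
voxels)` voxels are taken, so the realized fraction is within one voxel
of the request (well inside the ±2-percentage-point contract). Field-map
models: `constant`, `linear-gradient` (spanning ±amplitude across x) and
`smooth-bump` (Gaussian, width a quarter of the grid extent); default
smooth-bump, 40 Hz.

Tissue defaults (water density, fat density, $T_1$/ms): blood pool
(1, 0, 320), healthy wall (1, 0, 500), scar (1, 0, 250), mitral valve
(1, 0, 260), EAT (0.1, 1, 280) — the small EAT water fraction exercises
separation on mixed voxels.

What the phantom does **not** emulate: realistic anatomy, cardiac or
respiratory motion, undersampled reconstruction, coil sensitivities,
multi-peak fat, partial-volume voxels at tissue borders (labels are
crisp). Passing tests therefore demonstrate correctness of the
algorithms under the stated signal model, not clinical performance on
patient data.

## Two-point water–fat separation

With the field map known, demodulating $e^{-i2\pi\psi TE_n}$ leaves the
linear system $s_n = W + F c_n$, $c_n = e^{i\theta_n}$,
$\theta_n = 2\pi f_{fat} TE_n$, which `separateWaterFat()` solves exactly
per voxel: $F = (s_2 - s_1)/(c_2 - c_1)$, $W = s_1 - F c_1$, returning
magnitudes. The general flexible-TE inversion is used because the
protocol TEs are near- but not exactly out/in-phase at 1.5 T; no phase
constants are hard-coded. A configuration in which the fat phasors at
the two echoes coincide within `singularAngle` (default 0.1 rad) is
rejected before any voxel work. Voxels where water and fat tie within
tolerance are flagged in the swap mask and reported as water-dominant — a
deterministic tie-break. In-phase and out-of-phase images are derived as
$W+F$ and $|W-F|$.

### Field-map estimation

The per-voxel two-point problem has a binary ambiguity: the dual-echo
magnitudes $|s_1|, |s_2|$ determine the amplitude pair
$\{W^2, F^2\}$ (via $W^2 + F^2$ and $WF$ from the known fat phase
projections) but not which root is water; each assignment, combined with
the echo phase ratio $s_2/s_1$, implies one off-resonance candidate
$\psi$ per voxel, defined modulo the aliasing period
$1/\Delta TE \approx 385$ Hz. `estimateFieldMap()` resolves the ambiguity
spatially, on the assumption that the true field is smooth while the
wrong-assignment candidate is displaced by roughly $f_{fat}$: voxels are
visited in decreasing magnitude order (a priority-queue region growing
implemented in C++, with index-ordered tie-breaks so results are fully
deterministic), each taking the candidate — over both assignments and
±1 aliasing period — closest to the mean of its already-resolved
6-neighbours. The seed is the highest-magnitude voxel and prefers the
candidate nearest 0 Hz, which identifies the correct branch whenever the
true field at the seed is below about half the fat shift. Voxels with
mean echo magnitude below `magThreshold` (default 5%) of the maximum
carry no reliable phase; they inherit the neighbourhood value, smoothly
extrapolating the map across signal voids (air, nulled tissue).
Estimation accuracy is therefore asserted over foreground voxels (those
above the magnitude floor). All-zero input has no seed and errors.

### The swap-rate diagnostic

For simulated data, `swapRate()` reports the fraction of foreground
voxels whose recovered dominant species contradicts the ground-truth
density dominance. Foreground requires unequal true densities *and* a
noiseless signal of at least 10% of the blood-pool reference: near-nulled
healthy wall sits at ≈3% of blood signal, below any realistic noise
floor, and including such voxels would turn the diagnostic into a coin
flip on noise rather than a measure of water–fat assignment. Ties count
as water, so wholesale exchange of the outputs scores 1.

## Fibrosis and EAT quantification

The wall mask is the LA intramural tracing minus mitral valve, exclusion
structures and blood pool, with per-structure removal counts logged; an
empty result errors. The scar threshold is the midpoint
$SI_{blood} + (SI_{MV} - SI_{blood})/2$ of the blood-pool and
mitral-valve means on the water image (never the in-phase image);
inverted contrast ($SI_{MV} < SI_{blood}$) warns but still returns the
midpoint. Classification uses a strict inequality — ties are
non-fibrotic — and the fibrosis burden is reported as a voxel-count
fraction (`definition: voxel_fraction`), not a surface measure: no
meshing is performed, and the voxel formulation is the one that is
exactly testable against labelled ground truth. Both the threshold rule
and the counting are invariant under axis permutations with matching
spacing permutation.

EAT volume counts every voxel of the EAT segmentation — the segmentation
itself is the quantity of interest, so no additional fat-signal
threshold is applied by default; an optional fat-fraction gate
(`fat/(water+fat) >` cut-off) is available. Interatrial septal fat is
simply part of the mask. Volume is `voxels × voxel volume / 1000` mL,
exactly. BSA indexing defaults to Mosteller
($\sqrt{h_{cm} w_{kg}/3600}$) with Du Bois
($0.007184\,h_{cm}^{0.725} w_{kg}^{0.425}$) selectable; the formula name
travels with the result because the choice is not standardized.

## Agreement statistics

`iccA1()` implements ICC(A,1): from the two-way mean squares for
subjects ($MS_R$), raters ($MS_C$) and residual ($MS_E$),

$$ ICC(A,1) = \frac{MS_R - MS_E}
   {MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}, $$

with the two-sided 95% CI from the F-distribution construction
(McGraw–Wong) using the Satterthwaite degrees of freedom; when the
residual variance vanishes but a rater offset remains, the limit
$\nu = k - 1$ of those degrees of freedom is used, and a fully degenerate
(perfect-agreement) table pins the interval at 1. Constant tables and
$n < 2$ or $k < 2$ error. The estimator is checked in the test suite
against an independent route (mean squares from `stats::aov`) to 1e-10,
and its sampling behaviour (bias of the point estimate, CI coverage) by
Monte-Carlo against a variance-components generator with population ICC
0.90 — split $\sigma^2_{subject}/\sigma^2_{rater}/\sigma^2_{error} =
0.90/0.01/0.09$, a small rater variance as appropriate for a
repeatability design; the split was fixed a priori. `blandAltman()` uses
the $n-1$ SD denominator and the 1.96 multiplier for the 95% limits of
agreement; both conventions are stated in the output rather than
configurable, since the downstream consistency checks depend on them.

## Pipeline and repeatability harness

`runPipeline()` executes phantom → echoes → field map → separation →
quantification for every (seed, noise) cell of a JSON-configured grid,
validating the configuration against a closed schema first (unknown keys
anywhere are rejected before compute) and logging seed, threshold,
means, formula choices and output hashes per cell; a failing cell is
recorded and the rest continue. The second-reader emulation re-quantifies
the same reconstruction with perturbed masks: a seeded one-voxel
translation plus a random 3% voxel drop of the traced structures (wall,
EAT, exclusions), leaving the signal-reference masks in place. This is a
deliberately crude reader model — it produces a systematic component
(translation against a fixed blood pool thins the derived wall) as well
as random disagreement, which is what the agreement statistics are meant
to detect; it does not claim to reproduce human tracing statistics.
Because agreement requires between-subject variance, the repeatability
experiment in `scripts/acceptance.R` uses a heterogeneous cohort of 10
phantoms with scar fractions 0.05–0.50 and EAT coverages 0.15–0.45.

## Problem sizes and determinism

The test suite exercises full-size ($96 \times 96 \times 48$) scenes for
the separation and recovery checks and $32 \times 32 \times 16$ scenes
for property-style loops, chosen so the whole suite completes in well
under a minute of compute per module. Every stochastic step — scar
placement, noise, rater simulation, mask perturbation — flows from an
explicit integer seed through a state-restoring RNG wrapper, and the
NIfTI export is byte-deterministic, so identical specifications
reproduce identical files.

## Known limitations

* Two echoes only: no $R_2^*$ estimation, no multi-peak fat, no
  three-echo joint estimation; accuracy claims are relative to this
  package's own forward model, never to scanner output.
* The region-growing unwrapper assumes a smooth field within roughly
  half an aliasing period across the object; pathological fields
  (discontinuities, amplitudes near $1/2\Delta TE$) can still swap
  regions — the swap mask and swap-rate diagnostic exist to surface
  this.
* The phantom's crisp labels make threshold recovery easier than in
  patients, where partial volume and surface definitions blur the scar
  boundary; recovery tolerances in the tests reflect the phantom, not
  clinical variability.
* Manual segmentation itself is out of scope: masks are inputs
  (phantom-provided here), and the reader-perturbation harness only
  caricatures human variability.
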
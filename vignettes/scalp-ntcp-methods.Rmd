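---
title: "Scalp-shell dosimetry and skin NTCP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalp-shell dosimetry and skin NTCP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalpdose)
```

# The problem

When tumor-treating-field (TTField) transducer arrays — four adhesive
patches, each carrying a 3×3 grid of ceramic disk electrodes — remain on the
scalp during cranial radiotherapy, the electrodes act as unintended bolus:
they pull the dose buildup toward the skin and raise the superficial dose.
The clinical mitigation is to re-fix the arrays every few days at a slightly
different position, smearing the buildup over a larger area. `scalpdose`
implements the dosimetric and radiobiological machinery needed to quantify
that effect: scalp-shell construction, DVH reduction, hot-spot area metrics,
the Lyman–Kutcher–Burman skin NTCP chain, a five-scenario electrode
positioning engine, and the statistical comparison of scenarios on a
patient cohort.

# Scalp shells

Skin toxicity is assessed in two concentric layers of the body contour: the
superficial layer 0–2 mm below the surface and the next layer at 2–4 mm
depth. `build_shells()` derives them from a binary body mask by Euclidean
depth banding: a voxel belongs to the band (inner, outer] if its centre lies
deeper than `inner` and at most `outer` millimetres below the body surface.
This equals the Boolean shell construction used by planning systems (body
minus body eroded by `outer`, intersected with body eroded by `inner`) with
erosion defined by physical distance, so anisotropic grids behave correctly.

Two numerical choices matter here:

* **Hole filling.** Body contours contain internal air cavities; depth is
  measured to the outer surface only, so the mask is flood-filled first.
* **Subvoxel surface localisation.** The naive distance to the nearest
  outside voxel centre is biased by up to half a voxel, and the bias depends
  on surface orientation — enough to distort a 2 mm shell on a 1 mm grid by
  >10% in volume. Instead, the surface is sampled where the 0.5 level of
  the local (3×3×3 box-mean) mask coverage crosses each lattice line; these
  crossing points are exact for planar interfaces and nearly unbiased on
  curved anatomy. Each voxel near the surface gets its exact distance to
  the nearest crossing point (a bucketed ring search in compiled code);
  voxels deeper than the refinement band (default 8 mm) fall back to the
  centre-to-centre transform. On a digitised sphere of radius 50 mm at
  1 mm voxels this reproduces the analytic 0–2 and 2–4 mm shell volumes
  within about 1% and 3% respectively; the package tests assert 5%. At
  2 mm voxels a 2 mm shell is a single voxel layer and its volume carries
  an inherent quantisation error of order 15% — the shells are still
  consistent between scenarios, which is what the scenario comparison
  needs, but absolute volumes at that resolution should not be
  over-interpreted.

# DVH reduction and hot-spot metrics

`cumulative_dvh()` bins structure voxels at 0.05 Gy resolution by default —
below the rounding precision of clinically reported doses — and returns the
volume at or above each bin edge. `dose_at_hottest_area()` implements the
D<sub>x cm²</sub> metrics: the published convention reports hot-spot *areas*
on a 2-mm layer, and the only consistent reading is an area-to-volume
conversion through the layer thickness (25 cm² × 0.2 cm = 5 cm³); the DVH
is then inverted at that volume with linear interpolation between edges.
Interpolation error is below one bin width. `isodose_area()` is the inverse
summary (area of the layer at or above a threshold, V40-style) and also
returns the voxel mask for visualisation.

# Radiobiology: gEUD, effective volume, Lyman NTCP

The skin is modelled as a reference organ of 100 cm² of skin, taken through
the 2-mm layer convention as a 20 cm³ reference volume. Three reductions,
all over differential DVH bins with bin-centre doses (second-order accurate
for the power mean):

* **Luxton gEUD** — the isotoxic uniform dose to the whole reference organ:
  $gEUD = \left(\sum_i \tfrac{v_i}{V_{ref}} D_i^{1/n}\right)^n$. Partial
  volumes are taken relative to the *reference* volume, so the part of the
  organ outside the structure contributes zero dose. With the skin volume
  exponent $n = 0.1$, $1/n = 10$ and $D^{10}$ overflows double precision
  for ordinary dose values once multiplied across bins, so the power mean
  is evaluated in log space.
* **Kutcher–Burman effective volume** —
  $v_{eff} = \sum_i \tfrac{v_i}{V_{ref}} (D_i/D_{max})^{1/n}$, the
  isoeffective fraction of the organ uniformly irradiated at the maximum
  dose. The identity $gEUD = D_{max}\, v_{eff}^{\,n}$ links the two routes;
  the package keeps both and its tests assert they give the same NTCP to
  within $10^{-6}$.
* **Lyman probit NTCP** — $NTCP = \Phi\!\big((D - TD_{50})/(m\,TD_{50})\big)$
  evaluated at the gEUD.

The default parameters are the Burman fit of the Emami skin tolerance data
for the necrosis/ulceration endpoint: $TD_{50} = 70$ Gy for the 100 cm²
reference organ and relative slope $m = 0.12$, with $n = 0.10$. Only the
tolerance dose and reference organ are printed in the source tables; the
$(n, m)$ pair is validated by reproducing all 35 published NTCP values from
the corresponding published gEUDs to within 0.0002 in probability — a check
the test suite and `reproduce_tables()` both run.

**Fractionation.** Accumulated physical dose enters the model unchanged;
this is what reproduces the published tables, including the
hypofractionated arm, so no linear-quadratic conversion is applied by
default. An explicit `eqd2()` transform is available for users who want an
EQD2-based sensitivity analysis.

# Scenario engine

Five positioning conditions are compared: (1) no electrodes, (2) varying
observed positions, (3) a virtually fixed position nearest the average
placement, (4) 2/5 of fractions as scenario 1 plus 3/5 as scenario 3, and
(5) 2/5 as scenario 1 plus 3/5 as scenario 2. Mixes are implemented as
deterministic 0.4/0.6 convex dose combinations of the accumulated component
courses rather than a random draw of fraction indices: for identical
per-fraction plans the two constructions coincide, and the deterministic
form is reproducible. Accumulation (`accumulate()`) demands exact grid
congruence — shape, spacing and origin — and refuses to resample silently.
`renormalization_factor()` restores the course prescription when only
imaged fractions enter the accumulation; it uses the course's own
prescription (60 or 40.05 Gy) since the intent of the renormalisation is
prescription restoration for every patient.

# The synthetic cohort generator

No clinical dose grids ship with the package; `generate_cohort()` produces
study conditions the pipeline and statistics can run on end to end.

* **Phantom.** A spherical head (radius 80 mm, 2 mm isotropic voxels) with
  a spherical PTV at a per-patient size and depth. The base dose is the
  prescription (60 Gy) inside the PTV with an exponential falloff
  (length 30 mm) outside it — a deliberately smooth stand-in for a
  noncoplanar IMRT distribution. Patient heterogeneity is driven by the
  two covariates the cohort tables report: PTV radius uniform on
  25–45 mm and PTV-to-surface gap uniform on 2–18 mm, spanning shell
  gEUDs from the sub-0.01% NTCP regime to the ~1% regime.
* **Electrodes.** Four 3×3 arrays (20 mm disks at 22 mm pitch) on the
  anterior/posterior/left/right surface. Their dosimetric effect is
  parametric, not transport-based: a multiplicative buildup gain of 0.085
  under each disk footprint and a 0.03 halo gain under the rest of the
  patch, decaying linearly with depth to zero at 4 mm. The 0.085 ceiling
  encodes the reported behaviour that the superficial dose increase under
  moving arrays stays below 8.5% outside the hottest 1 cm².
* **Placement variation.** Per-array tangent-plane offsets drawn from a
  zero-mean bivariate normal with SDs of 1.1 cm (major axis) and 0.7 cm
  (minor axis), matching the principal-component variation reported for
  fixation-to-fixation array migration; 20 fixation periods per course by
  default. The implied 95% confidence-ellipse half-axes are
  $\sqrt{5.991}\,\sigma \approx$ 2.7 and 1.7 cm; the reported half-axes
  (2.7, 1.8 cm) are mildly inconsistent with the reported SDs, and the
  sampler follows the SDs.
* **Scenario construction.** Because the per-fraction enhancement is
  multiplicative on a common base dose, the varying-position course equals
  the base scaled by the placement-averaged gain field — computed exactly
  rather than by summing per-fraction grids. Scenario 3 snaps to the
  sampled placement nearest the mean offset.

What the generator does *not* emulate: beam-direction effects and exit
dose, backscatter, anatomy changes between fractions, electrode contouring
noise, and the skin-recovery dynamics of array-off periods. Passing tests
on synthetic cohorts therefore demonstrate the correctness of the
*machinery* (geometry, reductions, statistics), not claims about any real
patient population.

**Parameter recovery.** For validating the statistical layer, the generator
accepts a ground-truth scenario-3 effect: the gains are rescaled per
patient (root solve on the gain multiplier) so that the fixed-electrode
NTCP at the *nominal* placement is exactly ×5 the electrode-free NTCP; the
snap to the nearest sampled placement then perturbs the realised effect.
Across 20 replicate 7-patient cohorts the 95% CI of the estimated factor is
required to cover the truth in at least 17 — the suite runs exactly this.

# Statistics

NTCP across patients spans orders of magnitude and is incompatible with
normality; its logarithm is approximately normal (the package reports
Lilliefors-corrected Kolmogorov–Smirnov P bands — `<0.01`, `0.01–0.15`,
`>0.15` — for both). The analysis model is therefore a two-way additive
fixed-effects fit of ln NTCP on patient and scenario, and scenario
comparisons are multiplicative factors $\exp(\alpha_a - \alpha_b)$. In a
balanced design this equals the geometric mean of per-patient NTCP ratios —
an identity the tests assert exactly. Confidence intervals use the residual
mean square with $(P-1)(S-1)$ degrees of freedom from a single fit over all
five scenarios (the natural default; the source analysis does not state its
per-contrast scenario set). Natural logarithms are used throughout; the
base cancels in the factors. NTCP values below $10^{-12}$ are floored with
a warning before logging, since deep-target synthetic patients can
underflow.

`spearman_rank()` wraps the rank correlation with average ranks for ties
(duplicated printed values occur in the hot-spot dose tables);
`ks_normality()` wraps `nortest::lillie.test()`. Both exist to fix the
package-level conventions; the tests validate them against brute-force
oracles rather than trusting the wrappers.

# Reproduction of the published cohort tables

The five per-patient, per-scenario summary tables of the PriCoTTF phase
I/II dosimetric study (hot-spot doses, gEUD of both shells, NTCP) are
shipped as plain CSV fixtures and loaded by `trial_cohort()`.
`reproduce_tables()` recomputes from them everything the statistical layer
derives: each NTCP cell from its gEUD through the Lyman model (flagged at
0.0002 absolute probability), the scenario factors with CIs, the
scenario-1 NTCP summary, the gEUD/NTCP rank correlation, and the gEUD
depth gradients. Quantities that require the clinical dose grids — the
patient-specific hot-spot doses themselves, the published P-values, the
0.76 rank correlation between D25cm² and NTCP, and the D25cm² ANOVA
differences — are covered by ordering and sign checks only, on both the
published tables and synthetic cohorts. Recomputing the scenario-5 factor
from the rounded printed NTCPs gives ≈1.95 against the published 1.88
(computed on unrounded data), so that factor is checked qualitatively
(greater than 1, smaller than the scenario-2 factor).

# Problem sizes and determinism

The test suite runs phantoms at 2 mm voxels (about 90³ voxels), 1 mm
sphere fixtures for the analytic shell checks, cohorts of 4–7 patients
with 8–20 fixation periods, 20 replicate cohorts for the recovery study,
and 500 simulated tables for CI coverage — sizes chosen so a full run
completes in a few minutes on one core while every assertion still probes
the property it names at meaningful scale. All randomness flows through
explicit integer seeds: `generate_cohort()` and `run_pipeline()` refuse to
run without one, and rerunning a pipeline with its stored configuration
reproduces its output CSVs byte for byte (each output carries a
configuration hash).

# Known limitations

* The electrode effect is a calibrated parametric gain, not radiation
  transport; absolute synthetic NTCPs are illustrative.
* Masks are the only structure representation (no polygon contours), and
  grids must match exactly — there is deliberately no resampling.
* DICOM-RT import is not provided; dose grids enter via NIfTI
  (`read_dose_nifti()`) or in-memory arrays.
* The Lyman/Kutcher–Burman chain is the only NTCP model; no logistic or
  relative-seriality variants, and no parameter sets for organs other than
  skin are bundled.
* At 2 mm voxels, single-voxel-thick shells carry ~15% volume quantisation
  error (see above).
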
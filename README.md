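# scalpdose

Scalp-shell dosimetry and skin NTCP for cranial radiotherapy delivered
through tumor-treating-field (TTField) transducer arrays.

When the four electrode arrays of TTField therapy stay fixed on the scalp
during radiotherapy, the ceramic disks act as bolus and raise the
superficial skin dose; varying the array position from fixation to fixation
smears the buildup and mitigates the skin toxicity risk. `scalpdose` is an
R package for quantifying that effect, for medical physicists and
radiation oncologists working with 3-D dose grids:

* **Scalp shells** — 0–2 mm and 2–4 mm depth bands of a body mask, built by
  a subvoxel-accurate Euclidean distance transform (`build_shells()`).
* **DVH reduction** — cumulative dose–volume histograms and hot-spot
  metrics: the minimum dose in the hottest 0.05 cm² and 25 cm² of a skin
  layer, and isodose areas (`cumulative_dvh()`, `dose_at_hottest_area()`,
  `isodose_area()`).
* **Radiobiology** — the Luxton generalized equivalent uniform dose
  (power mean with exponent 1/n), the Kutcher–Burman effective volume, and
  the Lyman probit NTCP for skin necrosis,
  NTCP = Φ((gEUD − TD₅₀)/(m·TD₅₀)), with the Burman skin parameterization
  (TD₅₀ = 70 Gy for 100 cm² of skin, m = 0.12, n = 0.10) as default
  (`geud()`, `kutcher_burman_veff()`, `lyman_ntcp()`).
* **Scenario engine** — per-fraction dose accumulation, prescription
  renormalization, and the five electrode-positioning scenarios (none /
  varying / fixed nearest-average / 2:3 mixes) as voxelwise convex dose
  combinations (`accumulate()`, `build_scenario()`).
* **Synthetic cohorts** — head phantoms with plan-like dose falloff,
  parametric electrode dose enhancement, and fixation-to-fixation
  placement variation with principal-axis SDs of 1.1/0.7 cm
  (`generate_cohort()`).
* **Statistics** — two-way ANOVA on log NTCP with multiplicative scenario
  factors and CIs, Spearman rank correlations, Lilliefors normality bands,
  broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods
  (`log_ntcp_anova()`, `scenario_factor()`).

The package also ships the published per-patient dosimetric summary tables
of the PriCoTTF phase I/II trial cohort (seven patients × five scenarios)
as plain CSV fixtures, and a workflow that recomputes the derived results
from them.

## Worked example

Reproduce the published cohort analysis from the packaged tables:

```r
library(scalpdose)

lkb_params()
#> <lkb_params> TD50 = 70 Gy, m = 0.12, n = 0.1, reference organ 100 cm^2 x 2 mm

reproduce_tables()
#> <table_reproduction> NTCP cells: 35/35 within 2.0e-04
#> scenario factors:
#> # A tibble: 3 × 6
#>   scenario_a scenario_b factor conf_lo conf_hi  p_value
#>        <dbl>      <dbl>  <dbl>   <dbl>   <dbl>    <dbl>
#> 1          3          1   5.49    4.15    7.26 5.02e-12
#> 2          2          1   3.53    2.67    4.67 2.02e- 9
#> 3          5          1   1.95    1.48    2.58 4.97e- 5
#> scenario 1 NTCP: min 0.0005%, median 0.1109%, max 1.4744%
#> Spearman gEUD vs NTCP: 1.00
#> mean gEUD depth gradient, scenarios 1-3: 3.21 Gy/mm
```

Reading the output: every one of the 35 published NTCP values is recovered
from its published superficial-layer gEUD through the Lyman model to within
0.0002 in probability — the functional relation behind their perfect rank
correlation. Fixing the arrays at the average position multiplies the skin
NTCP by ≈5.5 relative to irradiation without electrodes; letting the
position vary reduces that to ≈3.5; additionally irradiating without
arrays on the two array-change days per week reduces it to ≈1.9. Without
electrodes, the seven patients span NTCPs from 0.0005% to 1.47% (median
0.11%), and the gEUD rises by ≈3.2 Gy per mm from the 0–2 mm to the 2–4 mm
layer.

The same machinery runs end to end on synthetic data:

```r
cfg <- run_config(seed = 42, n_patients = 7)
res <- run_pipeline(cfg)
res$factors            # scenario factors with CIs on the synthetic cohort
autoplot(res$cohort)   # log-NTCP per patient across scenarios
```

And on your own grids:

```r
dose <- read_dose_nifti("course_dose.nii.gz")
body <- structure_mask(dose$values > 0, dose$spacing, name = "body")
sh   <- build_shells(body)                 # 0-2 and 2-4 mm scalp layers
dvh  <- cumulative_dvh(dose, sh$shell_0_2)
dose_at_hottest_area(dvh, area_cm2 = 25)   # D25cm2 of the superficial layer
lyman_ntcp(geud(dvh))                      # skin NTCP
```

## Package layout

* `R/` — grids and masks, shells, DVH, LKB radiobiology, scenario engine,
  phantom/cohort generator, statistics, table reproduction, pipeline.
* `src/` — Rcpp distance transform (subvoxel surface depth, hole filling,
  connectivity).
* `inst/extdata/` — published cohort tables as CSV.
* `vignettes/scalp-ntcp-methods.Rmd` — models, assumptions, numerical
  choices, and limitations.
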
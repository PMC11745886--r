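# tendonsfa

Quantitative analysis of longitudinal B-mode ultrasound images of the
Achilles tendon, for researchers studying tendon morphology in
neurological and musculoskeletal populations (e.g. paretic vs. control
limbs after stroke).

The package implements:

* **Spatial frequency analysis (SFA)** of the speckle pattern: every
  32 × 32-pixel kernel (≈ 2.0 mm) inside an analyst-drawn ROI is
  demeaned, zero-padded to 128 × 128, 2D-FFT'd, and high-pass filtered by
  a radial Butterworth with its −3 dB point at 1.0 cycles/mm. The **peak
  spatial frequency radius** `PSFR = sqrt(f_ax² + f_lat²)` at the
  filtered-magnitude maximum is averaged over all kernels. Higher PSFR
  indicates more regular collagen fascicle banding; lower PSFR indicates
  collagen disarray.
* **Tendon thickness** as the perpendicular distance between traced
  superficial and deep borders, at the image center column (mid-tendon
  sites) or at the tendon–calcaneus intersection (insertion site).
* **Reliability statistics**: ICC(3,1) = (BMS − EMS)/(BMS + (k−1)·EMS)
  with SEM = SD·√(1 − ICC) and the poor/fair/good/excellent categories.
* **Group statistics**: Shapiro-Wilk gate, one-way ANOVA across limbs
  from raw data or from published (mean, sd, n) summaries, η² effect
  sizes with noncentral-F confidence intervals, Bonferroni post hoc
  tests, and exact noncentral-t sample-size calculations.
* **A synthetic speckle phantom generator** with known band spacing
  (ground-truth PSFR = 1/period), organization jitter, border geometry
  and cohort structure, used to validate the whole chain end to end.

## Worked example

Generate a small synthetic cohort (4 stroke subjects with paretic and
non-paretic limbs, 4 controls, three sites each) and run the full
pipeline:

```r
library(tendonsfa)

coh <- generate_cohort(4, 4, seed = 7, dir = "demo")
cfg <- pipeline_config(workdir = "demo", manifest = coh$manifest,
                       sfa = sfa_config(stride_px = 4L), seed = 7)
out <- run_pipeline(cfg)
head(out$results[, c("subject_id", "limb", "site", "n_kernels",
                     "roi_psfr", "thickness_mm")], 4)
#>   subject_id        limb      site n_kernels roi_psfr thickness_mm
#> 1        S01     paretic  above4cm       384 1.905619     5.016226
#> 2        S01     paretic  above2cm       352 1.712378     4.901139
#> 3        S01     paretic insertion       154 1.446561     4.844218
#> 4        S01 non_paretic  above4cm       384 1.881356     4.984796
```

Each row is one image: `roi_psfr` is the mean PSFR (cycles/mm) over the
`n_kernels` analysed kernels, and `thickness_mm` the border separation at
that site. The report (`demo/report.md`) summarises the cohort as a
three-sites × three-limbs grid; with this seed the insertion-site PSFR
contrast — the designed effect — is the significant PSFR row:

```
| Measure | Site | Control | Non-paretic | Paretic | eta^2 | p |
|---|---|---|---|---|---|---|
| PSFR (mm^-1) | insertion | 1.99 (0.05) | 1.83 (0.20) | 1.61 (0.21) | 0.53 | 0.034 * |
```

Published group summaries can be analysed directly, without raw data:

```r
res <- anova_from_summary(list(
  group_summary("control",     1.94, 0.32, 19),
  group_summary("non_paretic", 1.78, 0.26, 15),
  group_summary("paretic",     1.70, 0.21, 15)))
round(res$eta_squared, 2)
#> [1] 0.13
```

A thin command-line wrapper (`exec/tendonsfa`) exposes the same steps as
`simulate`, `sfa`, `thickness`, `reliability`, `stats`, `report` and
`demo` subcommands.

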
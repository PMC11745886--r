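---
title: "Methods: spatial frequency analysis of tendon ultrasound speckle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial frequency analysis of tendon ultrasound speckle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonsfa)
```

## The measurement problem

Healthy tendon is a strongly anisotropic tissue: collagen fiber bundles run
in quasi-parallel fascicles whose echogenic interfaces produce a banded,
quasi-periodic speckle texture on longitudinal B-mode ultrasound.
Degeneration and abnormal loading disrupt this arrangement, and the speckle
texture loses its periodic structure. Spatial frequency analysis (SFA)
quantifies this: the 2D spectrum of a small speckle patch concentrates
energy at the spatial frequency of the fascicle banding, so the radial
position of the dominant spectral component — the peak spatial frequency
radius (PSFR, cycles/mm) — indexes collagen organization. Higher PSFR means
finer, more regular banding (better organization); lower PSFR means
coarser, more disordered texture (collagen disarray). Because the peak is
searched over the full 2D frequency plane, the measure is less sensitive to
probe angulation than an axial-only spectrum.

This package implements the full analysis chain for studies of Achilles
tendon morphology — PSFR, tendon thickness from traced borders, intra-rater
reliability statistics, and the group-comparison statistics used to compare
paretic, non-paretic and control limbs — together with a synthetic phantom
generator that provides ground truth the real data cannot.

## The SFA procedure

For each image, the analyst supplies a region of interest (ROI) polygon
covering the visible tendon and peritenon, away from the curved distal and
proximal image boundaries. The analysis then:

1. tiles the ROI with all 32 × 32-pixel kernels (≈ 2.0 mm at the default
   0.0625 mm/px calibration) whose four corners lie inside the polygon,
   on a configurable stride (default 1, i.e. every possible kernel);
2. subtracts each kernel's mean, zero-pads it to 128 × 128 samples (a
   frequency bin of 1/(128 × 0.0625) = 0.125 cycles/mm), and applies the
   2D FFT;
3. multiplies the magnitude spectrum by a radial Butterworth high-pass
   `H(r) = sqrt(v/(1+v))`, `v = (r/r0)^(4k)`, with the −3 dB point at
   `r0 = 1.0` cycles/mm and order `k = 2`, attenuating low-frequency
   artifacts (overall gain, shallow gradients);
4. takes PSFR = `sqrt(f_ax^2 + f_lat^2)` at the argmax of the filtered
   magnitude over the half-plane `f_ax ≥ 0` (the other half is redundant
   by conjugate symmetry), excluding the DC bin;
5. averages PSFR over all kernels with a valid peak.

```{r filter}
butterworth_highpass(c(0.5, 1.0, 2.0))
```

### Numerical choices

* **Filter family and order.** Only the −3 dB point of the high-pass is
  part of the published protocol; the family and order are not. We use a
  radial Butterworth of order 2 — maximally flat, with the cutoff gain
  `2^(-1/2)` exact by construction — and expose the order in
  `sfa_config()` so sensitivity can be tested.
* **No taper window.** Demeaning removes the DC term and its leakage
  skirt, which is the dominant leakage problem for a 32-sample window;
  zero-padding supplies the frequency sampling. A window would widen the
  fascicle peak by a factor ≈ 2 at this kernel size.
* **Grid-valued peaks, no interpolation.** PSFR is reported on the padded
  frequency grid (0.125 cycles/mm steps); zero-padding is the resolution
  mechanism. Sub-bin interpolation would manufacture precision the 2-mm
  kernel does not support.
* **Ties and degenerate kernels.** Exact magnitude ties resolve to the
  smaller radius, then the smaller angle from the axial axis — a
  deterministic, conservative rule. A kernel whose filtered maximum is
  below `1e-9` of its energy (e.g. a constant patch) is flagged no-peak
  and excluded from the ROI mean; the count is reported.
* **Full containment.** Kernels must lie entirely inside the ROI polygon;
  partially overlapping kernels would mix tendon with peritenon or
  anechoic regions.

## Thickness from traced borders

Tendon thickness is the perpendicular distance between the superficial and
deep border traces: at the mid-tendon sites (2 cm and 4 cm above the
insertion) measured at the image's center column, at the insertion measured
at the column where the deep border meets the calcaneal trace. The normal
is taken to the *superficial* border (the protocol does not say which
border defines perpendicularity; the superficial border is typically the
flatter trace), with the tangent estimated by a central difference over
±5 columns to smooth trace pixelation, and sub-pixel intersections by
linear interpolation along the polylines. The measurement is invariant to
rigid rotation and translation of the traces (verified to 1e-6 mm), and
recovers parallel-border separations within one pixel at tilts up to 20°.
If the border traces cross the calcaneal trace more than once, the
shallowest crossing is used; a near-miss within 1 px is accepted as the
closest-approach point.

## The synthetic phantom

Real tendon images for this population carry no ground truth: the true
collagen organization behind a given PSFR is unknown. The generator
therefore emulates the *image formation*, not the biology:

* **Scatterers.** Diffuse background scatterers (unit-mean exponential
  amplitudes, default 60/mm²) plus hyperechoic band scatterers at axial
  positions `z_k = z0 + k·p + ε_k`, `ε_k ~ N(0, jitter_sd_mm)`, with
  optional sinusoidal lateral undulation. The band period `p` sets the
  expected PSFR = `1/p`; the default 0.5 mm puts the peak at 2.0
  cycles/mm, inside the 1.55–2.2 cycles/mm range reported for healthy
  through degenerated Achilles tendons.
* **Organization knob.** Nothing quantitative is published about how much
  positional disorder corresponds to a given PSFR drop, so disorganization
  is modelled with a single scalar: per-band axial displacement with SD
  `jitter_sd_mm` plus per-column phase noise with SD `jitter_sd_mm/2`.
  This mapping is validated only by monotonicity — mean ROI PSFR decreases
  strictly over jitter levels {0, 0.05, 0.1, 0.2, 0.4} mm — never by
  magnitude.
* **Imaging.** The field is convolved with a separable PSF
  (`σ_ax = 0.15` mm, `σ_lat = 0.3` mm, carrier 3.0 cycles/mm — chosen so
  0.4–0.65 mm bands stay resolvable at 0.0625 mm/px), envelope-detected by
  the magnitude of the per-column analytic signal, and log-compressed over
  60 dB to 8 bits. This is an image-domain model: SFA operates on the
  displayed B-mode texture, so full RF/beamforming simulation would add
  cost without adding controllable structure.
* **Geometry.** Borders are laid down `thickness_mm` apart; at the
  insertion site a bright calcaneal line crosses the deep border once at
  the wedge angle, and the ROI stops short of the wedge. The annotations
  record exactly the laid-down geometry, so thickness recovery is tested
  against construction.
* **Cohorts.** `generate_cohort()` reproduces the study design — stroke
  subjects contribute paretic and non-paretic limbs, controls the right
  limb only, three sites each — with per-limb PSFR and thickness drawn
  from `default_effect_spec()`, whose values are representative group
  summaries for control, non-paretic and paretic limbs. The dispersion
  column of the published thickness summaries is used as the
  between-subject SD as printed. One master seed drives parameter draws
  and per-image child seeds, so cohorts are bit-reproducible.

What the phantom does *not* emulate: attenuation and time-gain
compensation, refraction and anisotropy artifacts at curved interfaces,
probe pressure, out-of-plane motion, and any real mapping from histology
to jitter. Passing phantom tests therefore shows the *pipeline* recovers
known structure under controlled degradation — not that PSFR measures
collagen histology.

## Reliability statistics

Test-retest tables (subjects × sessions) are summarised by ICC(3,1) — the
two-way mixed-effects, single-measures, consistency form,
`(BMS − EMS)/(BMS + (k−1)·EMS)`. The published protocol names only "ICC";
for intra-rater repeatability with a fixed rater, ICC(3,1) is the standard
fit, and the reported ranges cannot disambiguate the form, so the form is
an explicit argument for future extension. SEM = SD·√(1 − ICC) with the SD
taken over all cells. Categories: poor < 0.4, fair 0.4–0.7 (both
endpoints included, matching the quoted inclusive range), good (0.7, 0.9],
excellent > 0.9.

## Group statistics

* **Normality gate.** Shapiro-Wilk per group; the parametric path is
  licensed when all p > 0.05.
* **One-way ANOVA** across the three limbs, from raw data or from
  published `(mean, sd, n)` summaries
  (`SSB = Σ nᵢ(meanᵢ − grand)²`, `SSW = Σ (nᵢ−1)sdᵢ²`). The two paths
  agree to 1e-8 when the raw data's own summaries are fed back. The
  published results table is reconstructed as a *between-subjects*
  analysis: its degrees of freedom (2, 46) and effect sizes match the
  between-subjects computation from the printed summaries, even though
  the table footnote mentions repeated measures. Summary-based F values
  inherit the rounding of the printed inputs (about ±0.15 at these
  magnitudes); eta-squared is far less sensitive and reproduces to 2
  decimals.
* **Effect sizes.** eta² = SSB/SST with a 95% CI from inverting the
  noncentral-F CDF in the noncentrality parameter and mapping
  `λ → λ/(λ + df1 + df2 + 1)`; the lower bound clips at 0. Simulated
  coverage over mixed null/non-null designs is 93–97% (the null side
  covers at 97.5% because of the clip).
* **Post hoc.** All pairwise t-tests with the pooled within-group variance
  from the full ANOVA (Fisher-protected form; the protocol does not state
  the variant) and Bonferroni multiplier `m = g(g−1)/2 = 3`.
* **Sample size.** Exact noncentral-t power for the two-sample t-test
  (`df = 2n−2`, ncp `d·√(n/2)`), searched upward from n = 2. The two
  published design calculations are mutually inconsistent under a single
  tail convention: d = 2.1 → 5/group matches a two-tailed test, while
  d = 1.0 → 14/group matches a one-tailed test (two-tailed gives 17).
  Both are exposed through the `tails` argument and reproduced under the
  convention each number implies; no claim is made about which convention
  the original calculations used.

```{r power}
sample_size_two_sample_t(2.1, tails = "two")$n_total
sample_size_two_sample_t(1.0, tails = "one")$n_total
```

## Problem sizes used in the test suite

Validation runs use phantoms of 128 × 160 px (8 × 10 mm), which hold
300–3000 kernels per ROI depending on site and stride. Stride 1 is the
default for analysis; the jitter-monotonicity sweep (5 levels × 20 seeds)
uses stride 2, and ranking/invariance sweeps stride 8 — per-kernel PSFR is
unchanged by stride, which only subsamples the kernel grid, so these
choices trade kernel count against replicate count where replicates carry
the information. Cohort-level statistical properties (power of the
designed contrast, effect-size recovery at 50 subjects/group × 200
replicates) run on the generator's distributional layer
(`draw_cohort_params()`) rather than on rendered pixels; pixel-level
recovery is validated separately on rendered phantoms.

## Known limitations

* PSFR is grid-valued; differences smaller than 0.125 cycles/mm are not
  resolvable at the default padding.
* The jitter knob is a modeling convenience; only its sign of effect is
  validated.
* The pipeline assumes isotropic pixels; anisotropic calibration is not
  supported.
* Borders and ROI are inputs (manual tracing), as in the underlying
  protocol; no segmentation is attempted.
* The paired structure of paretic/non-paretic limbs is ignored by the
  one-way ANOVA, matching the published analysis; a mixed model would be
  more efficient but is out of scope.
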
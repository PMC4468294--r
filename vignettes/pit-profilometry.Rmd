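---
title: "Resorption pit analysis from stylus profilometry: models and methods"
author: "pitscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resorption pit analysis from stylus profilometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitscan)
```

## The measurement model

A stylus profilometer dragged across a resorbed bone disc yields a 1-D
height profile $h(x)$, $x$ in µm along the scan, $h$ in µm relative to
the instrument zero. The default scan geometry mirrors a Dektak 150 in
hills-and-valleys mode: 1000 µm scan length at 0.056 µm per sample
(17,858 samples) with a 65.5 µm vertical range. An osteoclast erosion
appears as a compact excursion *below* the level of the unresorbed
surface; all pit quantities are measured from that level, never from
the instrument zero.

Each pit is characterised by:

* **width** at the surface — distance between the two baseline
  crossings;
* **maximum depth** — largest drop below the baseline within the pit;
* **FWHM** — width of the pit at half of its maximum depth;
* **erosion area** — integral of the drop over the pit (µm²), the
  "area of resorption under the surface";
* **dent count / shape class** — a dent starts and finishes at the
  unresorbed-surface level; pits are *unidented*, *bidented* or
  *multidented* (3+ dents). Multidented pits are the morphological
  signature of continuous resorption, so the shape distribution is the
  endpoint that separates aggressively resorbing cultures from normal
  ones.

## Baseline estimation

The unresorbed level is unknown per trace and must be estimated in the
presence of the pits themselves. Two observations shape the estimator:

1. erosion is strictly one-sided (downward), so the unresorbed surface
   is the *upper* cluster of the height distribution and everything
   above the level is pure measurement noise;
2. on heavily resorbed discs the sub-surface fraction of the scan can
   reach ~50%, where symmetric robust location estimates (median ± MAD
   windows) visibly break down — we measured a level bias of −0.13 µm
   and an eight-fold inflated noise estimate with a symmetric fit on
   synthetic heavy-erosion traces, enough to shatter compound pits into
   unidented fragments.

The estimator therefore works one-sidedly. Start at the 0.875 height
quantile (inside the surface cluster whenever it holds ≥ 12.5% of
samples). Iterate (4 times): estimate the roughness from the *positive*
residuals only, $\hat\sigma = 1.4826\,\mathrm{med}(r_i\,|\,r_i>0)$ (the
half-normal consistency constant; pits cannot contaminate this side);
classify samples with $r_i \ge -3\hat\sigma$ as unresorbed; refit the
level as their median, or as an ordinary linear trend when its slope is
significant at 0.05 (discs are mounted nearly flat, but a small tilt is
common). If fewer than 25% of samples classify as unresorbed the trace
is reported as "no reliable baseline" — a scan that landed on a fully
eroded field — and the pipeline skips it with a logged reason.

On clean traces the estimator is comfortably within the $3\sigma/\sqrt n$
envelope of the true level (tested), and on heavy-erosion synthetics it
recovers the level to well under one noise standard deviation.

## Segmentation, dent counting, metrics

Topological decisions (where pits are, how many dents) are made on a
centred moving-average smoothed profile (window 1.0 µm ≈ 18 samples,
configurable); geometric quantities (depth, FWHM, area) are always
measured on the raw trace, so smoothing cannot bias them.

* **Seeding.** Candidate pits are where the smoothed profile drops below
  $\mathrm{level} - \max(3\sigma,\ \texttt{min\_depth}/2)$.
* **Extension.** Each candidate is extended outward on the *raw* trace
  to the nearest crossing of $\mathrm{level} - 2\sigma$, with the
  crossing position linearly interpolated between samples. Extending on
  the smoothed trace would push boundaries outward by about half the
  smoothing window; the raw crossing keeps the boundary within one
  sample of the true edge on noiseless shapes.
* **Distinctness.** A return above the $2\sigma$ gate shorter than
  `min_width` (default 1 µm) does not split a pit — single-sample noise
  dips at an internal ridge are not pit boundaries — while a full
  return for at least `min_width` does.
* **Filters.** Extents with maximum raw drop below `min_depth`
  (default 0.5 µm) or width below `min_width` are discarded.
* **Dent counting.** Within a pit of depth $d$, the ridge tolerance is
  $\max(2\sigma,\ 0.10\,d)$. The dent count is the number of maximal
  runs of the smoothed profile deeper than the tolerance that also
  reach the seeding gate — equivalently one plus the number of internal
  ridges rising to within the tolerance of the baseline, but robust to
  shallow shoulders near pit edges. A brute-force local-maximum scan
  confirms the equivalence on noiseless piecewise-linear profiles.
* **Metrics.** Depth takes the leftmost position on ties. FWHM is the
  distance between the outermost interpolated crossings of the
  half-depth contour — one value per pit, also for compound pits (the
  per-dent alternative would yield several values per pit where the
  study design expects one). Area is the trapezoid-rule integral of the
  drop, with the boundary slivers closed at the gate level. On analytic
  shapes the implementation reproduces the closed forms exactly:
  triangle FWHM $=w/2$, area $=wd/2$; Gaussian FWHM
  $=2\sigma_g\sqrt{2\ln 2}$, area $=d\,\sigma_g\sqrt{2\pi}$.

Tunable parameters, all in µm unless noted: `min_depth` (0.5),
`min_width` (1.0), `smooth_window` (1.0), `ridge_fraction` (0.10,
dimensionless), significance level `alpha` (0.05).

## Cohort aggregation and statistics

Pits are pooled across both discs and all scans of a subject ×
condition before medians are taken ("ten scans per subject" is read as
ten in total, five per disc; both are configurable). Per shape class
the median width, depth and FWHM are reported — empty classes give
missing values, never zeros — together with the shape percentages
(summing to 100) and the median erosion area. The default "median
erosion area" is the per-subject median of individual pit areas; the
alternative reading (median over scans of the total eroded area per
scan) is available via `area_mode = "per_scan_total"`.

Group and condition effects are tested exactly as in the study design:
Kruskal-Wallis across the three groups per condition, pairwise
Mann-Whitney between groups per condition, and Mann-Whitney between
conditions within each group, per endpoint, at α = 0.05 with no
multiple-testing adjustment (the original analysis applied none; the
per-row p-values are all reported, so any correction can be applied
downstream). The condition effect on the shape distribution is tested
per class on subject-level percentages (Mann-Whitney); a pooled
chi-square over pit counts is available via `shape_test =
"pooled_chisq"`. Cross-subject quartiles use inclusive linear
interpolation (R's default type 7). Mann-Whitney reports
$U = \min(U_1, U_2)$ with an exact two-sided p when $n_1+n_2 \le 12$
and there are no ties, else a normal approximation with tie and
continuity correction; these match full enumeration on all small
samples in the test suite.

## The synthetic cohort

No traces are deposited with profilometry studies of this kind, so the
package validates itself by parameter recovery on a generator that
emulates the study conditions:

* **Design.** 10 Charcot, 8 diabetic and 9 control subjects; two
  culture conditions (M-CSF + RANKL, and the same plus anti-TNF-α);
  10 scans per subject over 2 discs; one planar mask per subject ×
  condition.
* **Pits.** Pit count per scan is Poisson with density 7.5 pits/mm, so
  ten 1 mm scans average ~75 pits per subject-condition, matching the
  study's throughput. Each pit draws its dent count from the cell's
  mixture (3+ resolved uniformly over {3, 4}); each dent is a
  raised-cosine bump (compact support; area exactly
  $d\,w/2$) with log-normal depth and width. Dents are combined by
  pointwise maximum with spacing solved in closed form so each internal
  ridge rises to exactly `ridge_relief` × the shallower neighbour's
  depth below the baseline (default 0.05 — safely below the 0.10
  detection tolerance and safely above the 2σ noise gate). Pits are
  placed uniformly with ≥ 5 µm gaps by rejection.
* **Calibration.** The Charcot dent-count mixtures are set to the
  reported shape distributions — (0.36, 0.24, 0.40) under
  M-CSF + RANKL and (0.53, 0.22, 0.25) under anti-TNF — and diabetic
  and control cells share the latter mixture in both conditions, since
  the treatment has no effect outside the Charcot group. Depth and
  width scales are package defaults chosen to make Charcot RANKL pits
  visibly deeper and wider (depth median 3.5 µm, per-dent width median
  25 µm) than all other cells (2.0–2.2 µm, 18 µm); the literature
  reports these contrasts qualitatively here, so the scales are stated
  defaults, not anchored values. Planar medians are 20% (Charcot
  RANKL), 14% (Charcot anti-TNF; the 30% reduction), 8% elsewhere.
  Stylus noise defaults to σ = 0.02 µm, the nanometre-class roughness
  of a stylus profilometer on polished bone.
* **Subject variability.** Per subject × condition, all scale
  parameters and the mixture receive independent multiplicative
  log-normal jitter (sd 0.15, mixtures renormalised — this jitter is
  median-preserving to within 0.1 percentage point, verified by
  simulation). Jitter is independent between conditions; the study's
  tests are all unpaired, so a shared within-subject effect would not
  change any of them.
* **Determinism.** Every trace and mask gets its own seed derived from
  the master seed and its design indices by polynomial hashing
  (`derive_seed`), so identical configurations are byte-identical and
  any subject or scan can be regenerated in isolation.
* **Masks.** Planar masks rasterise axis-aligned random ellipses
  (log-normal semi-axes) onto a 512² grid until the target fraction is
  reached; the realised fraction overshoots the target by about 0.2
  percentage points (half an ellipse), which cancels in the
  between-condition ratio. Targets ≥ 80% are rejected as non-physical.

What the generator does *not* emulate: stylus-tip convolution (2.5 µm
radius), spatially correlated roughness, disc curvature beyond a linear
tilt, partially scanned pits at disc edges beyond scan-margin handling,
and any mechanistic link between osteoclast biology and pit shape. A
passing recovery suite therefore demonstrates that the *analysis* is
correct and well-calibrated under the stated measurement model — not
that the model captures every artefact of real Dektak data.

## Recovery results computed by the test-suite and acceptance script

With the default presets, the full pipeline (simulate → detect →
summarise) recovers the generating cell medians: the cross-subject
median shape percentages land within 5 percentage points of the
calibrated mixtures (seed family 1–5; per-seed medians scatter with
sd ≈ 2.7 points around the mixture, and the generator is
median-unbiased), detection finds ≥ 95% of generated pits with ≥ 90%
dent-count agreement (in practice ~100% at default noise), the planar
reduction averages ~30% over 20 seeds, and the Charcot-only
significance pattern (condition effect on unidented % and multidented
% significant in Charcot, not in diabetic or control) holds in ≥ 80%
of 20 master seeds. These are computed, not quoted: see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Crossing positions are linearly interpolated between samples; depth
  ties resolve to the leftmost position; FWHM crossings are clamped to
  the pit extent, which enforces FWHM ≤ width.
* Non-uniform position grids are accepted and integrated natively
  (trapezoid on the native grid); no resampling is ever performed.
* A constant trace has σ = 0 and the gates collapse to exact level
  crossings; an all-eroded trace raises the baseline error; an empty
  pit list yields an empty tibble, and summaries with zero pits report
  missing medians.
* Pit extents of fewer than 4 samples are rejected as degenerate.
* All randomness flows through explicit seeds; R's default Mersenne
  Twister is used throughout.

## Problem sizes used in the checks

The recovery tests run the design at full scale (27 subjects × 2
conditions × 10 scans of 17,858 samples — 540 traces per seed) for the
yield and significance-pattern checks, the Charcot subset (200 traces)
for the shape-distribution checks over seeds 1–5, and 20 seeds of
mask-only cohorts for the planar effect; unit and property tests use
analytic fixtures of a few thousand samples. A full cohort simulates
and analyses in well under a minute on one CPU.

## Known limitations

* FWHM is reported per pit, not per dent; for strongly asymmetric
  multidented pits the single FWHM mixes dent scales (flagged in the
  interface, configurable in a future revision).
* The baseline model is constant-or-linear; curved disc surfaces would
  need a spline baseline, which the one-sided scheme would support but
  is not implemented.
* Stylus-tip deconvolution is out of scope: widths of very narrow pits
  (≲ 5 µm) are physically broadened by the 2.5 µm tip radius in real
  data, and the generator does not model this.
* The chi-square option for shape distributions pools pits across
  subjects and ignores within-subject clustering; the default
  per-class Mann-Whitney on subject percentages is the safer test.
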
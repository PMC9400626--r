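---
title: "Quantifying serial dependence with DoG bias kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying serial dependence with DoG bias kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(serialbias)
```

## The design and its data

The package analyzes paired-trial experiments on visual working memory for
orientation. Each trial pair consists of an **ABC-retrocuing trial** — two
oriented samples (items A and B) at distinct locations, a retro-cue marking
one of them as the only item that might be tested (the uncued one becomes
the *irrelevant memory item*, IMI), then a third sample (item C), then a
probe of either the cued item or item C — followed by a linked **1-item
delayed-recall trial**. The key manipulation is where item C appears: at
the IMI's former location (*overlap*) or at a fresh location
(*no-overlap*). The scientific question is how each item of the ABC trial
biases recall on the linked 1-item trial, and whether the IMI's influence
reverses sign between conditions.

Orientations live on a 180°-periodic circle, so all differences are wrapped
into the half-open interval \([-90°, 90°)\) by `wrap_angle_180()`; the
boundary +90 maps to −90, a single fixed convention. With
`x = wrap(inducer − target)` and `y` the signed report error, an attractive
bias gives `y` the same sign as `x` near zero (a target of 90° after a 120°
inducer tends to be reported around 92°, i.e. `x = +30`, `y = +2`).

## Preprocessing

Three stages, applied to the merged all-subjects dataset in this order:

1. **Derivation** of the signed relative angles (`x_cued`, `x_imi`, `x_C`,
   and the within-trial `x_imi_vs_C`) and of the signed 1-item report error.
2. **Trial exclusion**: trials whose error deviates from the mean error by
   strictly more than 2 sample standard deviations are dropped. The default
   uses the *signed* error pooled over the merged dataset; a
   `metric = "absolute"` flag is provided because either reading is
   defensible, and the choice moves the excluded set only slightly under
   roughly symmetric error distributions.
3. **Residualization**: the mean signed error of the included rows is
   subtracted, so the residual errors average exactly zero. Demeaning is
   pooled (not per subject or condition) to match the merged-dataset
   analysis; per-condition demeaning would absorb part of any
   condition-specific bias into the offset.

An optional subject-level screen (`screen_subjects()`) removes subjects
whose mean absolute error is more than 2 SDs above the group mean, as a
single pass.

## The DoG bias kernel and its fit

The tuning of the bias with relative angle is modeled as a derivative of a
Gaussian,
\[
\hat y(x) = x\,a\,w\,c\,e^{-(wx)^2}, \qquad c = \sqrt 2 / e^{-0.5},
\]
with \(x\) in radians. The constant \(c\) normalizes the curve so its
extremum, at \(x = 1/(w\sqrt 2)\), has height exactly \(a\) (degrees).
Width \(w\) is bounded to \((0, 8]\) inverse radians — at the upper bound
the kernel is tuned to differences of only a few degrees, and fits pinned
at \(w = 8\) should be read as "narrower than the design can resolve".
Amplitude is bounded to \(\pm 30°\), far beyond any plausible bias.

`fit_dog()` minimizes the residual sum of squares over this box. Because
the model is linear in \(a\) for fixed \(w\), the amplitude is profiled out
exactly (\(\hat a(w) = \sum g y / \sum g^2\), clamped to its bounds, with
\(g\) the unit-amplitude kernel), leaving a one-dimensional problem in
\(w\). That problem is solved by scanning a dense geometric grid (251
points over \([0.1, 8]\)) and refining the best grid point with bounded 1-D
optimization. The procedure is deterministic, recovers noiseless
parameters to better than \(10^{-6}\), and — crucially for resampling —
reduces each refit to a handful of vector operations: for a fixed dataset
the grid-stage sums for *all* permutations or bootstrap resamples are
single matrix products. SSE ties (e.g. `y` identically zero) are broken
toward the smallest \(|a|\), then the smallest \(w\).

Effect size is reported as the **signed peak-to-peak distance**: max minus
min of the fitted curve over \([-\pi/2, \pi/2)\), signed by bias direction
(`peak_to_peak()`). It equals \(2a\) whenever the peak lies inside the
domain, i.e. for all \(w \gtrsim 0.45\); the public function evaluates a
1001-point grid augmented with the analytic peak locations, so grid
resolution never degrades the value.

## Resampling inference

- `permutation_test_serial_bias()` shuffles the x labels against the fixed
  responses, refits, and compares the observed peak-to-peak against the
  null distribution. The p-value is the plain proportion (no +1 smoothing)
  of null values at least as extreme; with `n_perm = 100` its resolution is
  exactly 0.01, which the power analysis relies on. "Extreme" is two-sided
  on \(|p2p|\) by default — small observed effects then correctly yield
  p-values near 1 — with one-sided alternatives behind a flag, since
  directional hypotheses (attraction vs. repulsion) are natural here.
- `permutation_test_condition_difference()` relabels the condition
  assignment of the pooled data points, preserving group sizes, and builds
  the null of `p2p(A) − p2p(B)`.
- `bootstrap_p2p_ci()` resamples rows with replacement and reports the
  percentile interval (2.5th/97.5th percentiles at level 0.95) of the
  bootstrap peak-to-peak distribution.

All three accept a seed and are bit-reproducible given one; resamples are
processed in chunks of 250 to bound memory at large n.

## Direct, indirect, and null models

Whether the IMI biases the next trial directly or through item C is cast
as model comparison on the same residual errors:

- **direct**: one DoG of the IMI's angle relative to the 1-item sample
  (2 parameters);
- **indirect**: stage 1 shifts item C's stored orientation by a DoG of the
  IMI's angle relative to item C (\(C' = C + \mathrm{DoG}(x_{imi}; a_1,
  w_1)\)); stage 2 predicts the error from \(C'\)'s angle relative to the
  sample (4 parameters). The stage-1 kernel argument is the IMI-vs-C
  angle throughout — the kernel that shifts \(C'\) is evaluated at that
  angle both inside the exponent and outside it;
- **null**: \(\hat y = 0\) (0 parameters).

`fit_indirect()` optimizes all four parameters jointly (one objective, not
a sequential two-step): a deterministic 3×3 multi-start bounded search over
\((a_1, w_1)\) with stage 2 profiled out as an inner DoG fit, followed by a
joint four-parameter polish. Noiseless parameter recovery is better than
\(10^{-3}\) on all four parameters. Identifiability is genuinely weak when
\(a_1\) is small — stage 1 then barely moves \(C'\) and \(w_1\) is nearly
unconstrained — which is why model comparison, not the raw stage-1
estimates, carries the inferential weight.

`aicc()` ranks the models: \(n\ln(SSE/n) + 2k + 2k(k+1)/(n-k-1)\), with
\(k\) counting only mean-function parameters (0/2/4). Counting the error
variance too (`count_sigma = TRUE`) shifts every model's AICc by a nearly
constant amount and rarely changes the ranking; the default keeps the
deltas directly comparable across the three models. On pure-noise data the
null model wins on average, but single datasets can tie within a fraction
of an AICc unit, so selection-recovery checks are majority-over-replicates.

## Power analysis

`estimate_power()` implements bootstrap power analysis for the permutation
test: draw `n_points` rows with replacement from the source data (or from
a generator closure), run the permutation test with `n_perm` shuffles,
repeat `n_datasets` times, and report the proportion of p-values strictly
below `alpha`. Resampling is of derived (x, y) data points, not of
subjects, matching the pooled analysis. Retrospective power uses the
source size; prospective power simply asks for a larger `n_points`.
Defaults (100 datasets × 100 permutations) trade Monte-Carlo precision
(±0.05 or so on the power) against runtime.

## The synthetic experiment generator

`simulation_config()` + `simulate_experiment()` emulate the full design:
6 blocks of 20 trial pairs per subject (3 blocks per condition, condition
order alternating across subjects), orientations drawn uniformly with
replacement from the integers 0–179, items A and B at distinct uniform
locations among 6, item C at the IMI's location under *overlap* and at one
of the four fresh locations under *no-overlap*, uniform retro-cue and
probe coin flips. At 96 subjects this yields exactly 11,520 trial pairs.

The response model: each report equals the true (or stored) orientation
plus the sum of the active bias kernels plus Gaussian noise, wrapped back
to \([0, 180)\). Kernels are specified per role × condition with known
amplitude, width and sign. Roles `cued`, `imi` and `C` act on the 1-item
report at the wrapped inducer-minus-sample angle and compose additively —
the simplest structure consistent with one-kernel-at-a-time analyses. The
`imi_on_C` role biases item C's *stored* orientation within the ABC trial;
that shift propagates both to the ABC report of item C and, when a `C`
kernel is active, to the next-trial recall — exactly the indirect-influence
generative model, and it reduces to the plain additive rule when absent.

Default noise: SD 10° on the 1-item report and 12° on the ABC report
(the three-item task is harder), placing mean absolute errors in the
6–12° range typical of online orientation-recall data; `subject_sd`
optionally spreads both SDs across subjects by a common Gaussian offset
truncated at zero. Demonstration kernels use \(|a| \approx 0.5–1.3°\)
(peak-to-peak 1–2.5°), the magnitude range such experiments report.

What the generator does **not** emulate: von Mises (circular) noise —
errors are Gaussian on the wrapped scale, defensible because observed
error SDs are far from the wrap boundary; guessing/lapse trials and swap
errors; per-subject kernel variation (kernels are population-level);
stimulus timing and display geometry, which never enter the analysis.
Passing recovery tests on these simulations therefore validates the
estimation machinery, not the psychological model of real data.

## Numerical and design choices

- Wrap convention: half-open \([-90°, 90°)\), +90 → −90, used everywhere.
- x is radians internally, degrees at API boundaries (converted once);
  printed widths \(w \approx 2\)–\(8\) are only physically sensible on the
  radian scale.
- Exclusion precedes demeaning; both pooled over the merged dataset.
- Peak-to-peak on a 1001-point grid plus analytic peak candidates.
- Permutation p-values are plain proportions; 0 is a possible value.
- Degenerate inputs fail loudly with classed conditions
  (`sb_insufficient_data`, `sb_invalid_params`, `sb_format_error`, ...)
  rather than returning NAs.
- Test problem sizes: unit tests run at hundreds-to-thousands of trials;
  calibration checks use 200 null datasets of n = 1000 with 200
  permutations; end-to-end recovery uses full 96-subject simulations over
  10 seeds. These sizes put Monte-Carlo error comfortably inside the
  asserted tolerances while keeping the suite fast.

## Known limitations

- The indirect model's stage-1 parameters are weakly identified for small
  \(a_1\); interpret them only alongside the AICc comparison.
- Percentile bootstrap CIs can undercover slightly for strongly skewed
  p2p distributions at small n; at the design's n ≈ 5,500 per condition
  this is negligible.
- The permutation test assumes exchangeability of (x, y) pairings within
  the analyzed cell; subject-level dependence is ignored by design (the
  analysis pools trials), so cells dominated by a few subjects would need
  a hierarchical extension.
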
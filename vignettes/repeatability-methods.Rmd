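---
title: "Measuring the repeatability of repeated retinal trait measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the repeatability of repeated retinal trait measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrep)
```

## The problem

Retinal traits computed automatically from color fundus photographs —
the vessel fractal dimension (FD) being the canonical example — are
candidate biomarkers for systemic vascular health. Using such a trait
for *individual* risk prediction requires that repeated measurements of
the same eye agree far better than measurements of different eyes do.
This package quantifies that requirement for any trait measured
repeatedly per eye, at two levels:

* **population level** — correlations between paired repeat
  measurements across eyes, and an intraclass correlation coefficient
  (ICC) from a between-/within-eye variance decomposition;
* **individual level** — a per-eye relative-noise statistic
  $\lambda$, which is what a clinician reading a single patient's
  value actually cares about.

Throughout, the *eye* (subject + laterality) is the analysis unit: the
estimators average the repeated images of one eye and compare eyes,
carrying `subject_id` for reporting only. Whether the two eyes of one
subject may be treated as independent is a design question the data
cannot settle; all counts are reported per eye so the reader can judge.

## The model and the estimators

Write $y_{ij}$ for the $j$-th measurement of eye $i$, $\sigma_b$ for
the SD of the eyes' true trait values and $\sigma_w$ for the
measurement-error SD. The ICC is

$$\mathrm{ICC} = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2},$$

the fraction of observed variation attributable to real between-eye
differences; 1 means noise-free measurement. `variance_decomposition()`
estimates $\sigma_b$ by the sample SD of the per-eye means, and
$\sigma_w$ by the pooled within-eye sample SD (the square root of the
df-weighted average of per-eye variances — the standard one-way
layout). Two conventions are deliberate and fixed:

* all SDs use the $n-1$ (sample) denominator;
* eyes with a single usable image contribute their value to
  $\sigma_b$ but nothing to $\sigma_w$ — using all data for the
  between-eye spread without fabricating a within-eye variance.

Note the estimator's small upward bias in $\sigma_b$: the SD of per-eye
means includes a $\sigma_w^2/n_i$ share of noise, so at 10 images per
eye a true ICC of 0.80 is estimated near 0.804. The validation suite
takes this into account rather than "correcting" the estimator, which
would depart from the simple per-eye-mean definition.

Which population supplies $\sigma_b$ is a design choice, not a fact of
the data. A narrow cohort (young, healthy) understates the trait
variation of any population one would actually screen, deflating the
ICC. `variance_decomposition()` therefore also reports an **adjusted
ICC** in which a `reference_sd_between` — typically
`combined_reference_sd()` over all available cohorts — replaces the
cohort's own $\sigma_b$. It replaces it in *both* numerator and
denominator: that is the only substitution consistent with the ICC
formula above.

### Paired correlations and random-pair resampling

With exactly two measurements per eye, Pearson and Spearman
correlations of the pairs are the familiar summaries (Spearman being
Pearson on average ranks, hence monotone-invariant and
outlier-robust). With more than two images per eye there is no
canonical pair, so `first_last_pairing()` makes the objective-but-
arbitrary choice of first and last image, and
`random_pair_resampling()` removes the arbitrariness: each of 20,000
replicates draws one random pair of distinct images per eye, and the
median correlation with the empirical 2.5–97.5% percentile interval is
reported. Numerical details that matter:

* sampled pairs are distinct (without replacement within the eye) and
  ordered by acquisition time before being placed in the two columns —
  the cross-eye correlation is *not* invariant to per-eye column
  swaps, and time-ordering makes the 2-images-per-eye case collapse
  exactly onto the first/last pairing;
* percentiles use linear interpolation (type 7);
* such resampling intervals can have inaccurate coverage for Pearson
  correlation, and should be read as descriptive;
* the resampling rows carry no p-value: they summarize a distribution,
  not a test.

### The individual-level statistic $\lambda$

$$\lambda = 100\% \times \frac{\text{within-eye SD}}{\text{between-eyes reference SD}}$$

expresses one eye's measurement scatter in units of how much eyes
differ — the natural yardstick for "could this noise move the patient
across the population distribution?". Because the SD squares
deviations, one gross error dominates $\lambda$; that is intended, as
a single bad image is exactly the failure mode of interest. The
reference SD defaults to the combined-cohort value for the same reason
as the adjusted ICC. Conventions: sample SD within eye (consistent
with the ICC estimation); eyes with fewer than two usable images are
*ineligible*, never assigned $\lambda = 0$ (zero would understate
their noise); quartile summaries use type-7 interpolation. With pooled
quantities the two levels connect algebraically:
$\mathrm{ICC} = 1/(1 + (\sigma_w/\sigma_b)^2)$, an identity the test
suite checks to $10^{-12}$.

### Robustness to image quality

Each image carries a quality score `quality_pbad` ∈ [0,1], the
probability that the image is bad. Three analyses probe how much of
the measurement noise is carried by poor-quality images:

* `exclusion_sweep()` recomputes the $\lambda$ distribution after
  excluding the worst 0–50% of images (a range covering and slightly
  exceeding exclusion levels typical of the oculomics literature).
  Exclusion is cohort-global by `pbad` rank — matching "exclude a
  share of images", not a per-eye quota — with ties broken by
  `image_id`, and `ceiling(f·N)` images removed so any nonzero
  fraction removes at least one. The reference SD is *not*
  re-estimated inside the sweep, so rows stay comparable; eyes
  falling below the two-image floor drop out of a row and are counted.
* `lambda_quality_correlation()` relates $\lambda$ to the *worst*
  (maximum) `pbad` per eye — worst, not mean, because one bad image
  suffices to inflate the SD. It is computed on the probability scale
  and on the log-odds scale `logit(pbad)`; a bounded probability can
  be a poor linear predictor while the underlying raw quality logit is
  not. The logit is monotone, so Spearman must agree between scales —
  asserted at run time to $10^{-9}$. `logit()` clips to
  $[10^{-6}, 1-10^{-6}]$ since only calibrated probabilities, not raw
  model logits, are available to this package.
* `apply_quality_threshold()` implements the recommended practical
  gate: discard only truly bad images (`pbad > 0.8`) rather than a
  fixed share.

### Interchangeability of two methods

`interchangeability()` asks whether two tools measuring the same trait
can stand in for one another: images at `pbad ≥ 0.8` are excluded,
each method is averaged per eye (averaging reduces noise), and the
per-eye mean vectors are compared by Pearson/Spearman plus a
Bland–Altman summary (mean difference and limits of agreement
$\bar d \pm 1.96\,\mathrm{SD}(d)$).

## The synthetic cohort generator

Real repeated-imaging cohorts of this kind are small and rarely
shareable, so the estimators are validated against
`generate_cohort()`, whose data-generating process mirrors the
structure the analysis assumes — and whose ground truth is known:

* eye truth: $t_i \sim N(\mu, \sigma_b^2)$, shared (as a standardized
  effect) across methods;
* image quality: $p_{ij} \sim \mathrm{Beta}(\alpha, \beta)$;
* noise: $\mathrm{SD}_{ij} = \sigma_{w,0}\,(1 + s\cdot\max(0,
  \mathrm{logit}\,p_{ij}))$ — a common noise floor for good images
  (`pbad < 0.5`), growing linearly in the quality logit beyond it,
  the functional form suggested by the observation that quality logits
  are the better linear predictor of $\lambda$;
* contamination: images with $p_{ij} > 0.8$ are, with probability
  `outlier_prob`, hit by an additional $N(0, (k\sigma_b)^2)$ gross
  error — an *additive* error rather than scaled noise, matching the
  empirical pattern where one or two badly illuminated images dominate
  an eye's SD; flags are shared across methods (bad illumination is an
  image property), magnitudes are not;
* drift: for longitudinal designs, the truth takes a
  $N(0,\sigma_d^2)$ random-walk step per *visit* (distinct
  acquisition date), so same-day repeats share the drifted truth.

The two presets fix the emulated study conditions. `caledonia-like`:
26 subjects, 39 eyes, 5–15 images per eye over 1–2 visits, no drift,
mostly good quality (Beta(1, 2.5); ~1.8% of images above 0.8),
$\sigma_b$ = 0.00733 (DART) / 0.02421 (AutoMorph). `grape-like`: 106
subjects, 196 eyes, exactly 2 images per eye (392), visit intervals of
months–years with drift, heavier bad-quality tail (Beta(1, 1.6)),
$\sigma_b$ = 0.03653 / 0.08926. Values not fixed by the emulated
designs were chosen once on realism grounds: noise floors set so the
median $\lambda$ lands near the observed few-percent (DART) and
~10–15% (AutoMorph) range; `noise_logit_slope = 3` so that an image at
`pbad = 0.8` is about five times noisier than a good one;
caledonia-like `outlier_scale = 10` because observed worst-case
$\lambda$ of ~80% against a combined reference SD five times the
cohort's own $\sigma_b$ implies gross errors of order ten times
$\sigma_b$ (grape-like keeps 3, its $\sigma_b$ being five times
larger).

What the generator does **not** emulate — and hence what passing tests
do not show about real data: structural disagreement between methods
(both presets give the two methods perfectly rank-correlated truths,
so simulated interchangeability is optimistic); non-Gaussian trait
distributions; quality that correlates with the trait itself (e.g.
media opacity in older eyes with genuinely lower FD); serial
correlation of noise within a visit; and any exact reproduction of the
original studies' reported statistics, which live on non-shareable
data.

## Validation problem sizes

The suite validates recovery at sizes chosen to make Monte-Carlo error
small relative to the tolerance being asserted: $\lambda$ recovery on
1,000 eyes × 10 images (median in [4.5, 5.5]% for a true 5% ratio —
the sample-SD chi bias at 9 df puts the expected median near 4.8%);
ICC recovery within ±0.02 on 500 eyes × 10 images; resampling
stability across seeds at 20,000 replicates; the outlier-collapse
property over 20 generator seeds of the contaminated preset; and the
logit-superiority property over 20 seeds of a 200-eye × 8-image
logit-linear cohort — 200 eyes, rather than the 39-eye preset, because
the Pearson sampling error at 39 eyes (≈0.1) would mask the ≈0.03
advantage the property asserts.

## Known limitations

* The ICC implemented is the single-rater, absolute-scale
  variance-ratio form appropriate for deterministic automatic methods;
  inter-rater ICC variants and mixed-model (REML) estimators are out
  of scope.
* No repeatability coefficient ($1.96\sqrt2\,\sigma_w$) or
  within-subject CV variants.
* The percentile interval of the resampling procedure is descriptive;
  for Pearson its coverage is not guaranteed.
* Quality scores are taken as given; nothing here estimates image
  quality.

## A short worked example

```{r example, eval = FALSE}
set.seed(1)
cal <- generate_cohort(cohort_preset("caledonia-like", seed = 1))
gra <- generate_cohort(cohort_preset("grape-like", seed = 2))
report <- run_full_analysis(list(cal$cohort, gra$cohort), seed = 1)

report$reference_sd                      # combined between-eye SDs
report$population[["caledonia-like.DART"]]$variance
subset(report$lambda_summary, method == "DART")
subset(report$sweep, cohort == "caledonia-like" & method == "DART",
       c(exclusion_fraction, lambda_median, lambda_max))
```
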
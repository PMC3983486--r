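---
title: "Modeling and scoring social feedback updating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and scoring social feedback updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformity)
```

This vignette is the package's own account of the science it implements: the
scoring model and its assumptions, the generative model behind the synthetic
cohort, the calibration of its defaults, and the design decisions taken where
the design was genuinely open.

## The paradigm and the scoring model

A participant rates 80 trait adjectives (40 positive, 40 negative) for two
targets — themselves and another person — on a 1–8 Likert scale, receives a
peer feedback rating per trait, and later re-rates every trait. A final
memory test asks them to recollect each feedback value. The feedback task is
organised in four runs of 20 adjectives (10 per valence), each adjective
appearing once per target within its run, self and other trials randomly
intermixed.

### The feedback grid

Feedback is presented as the mean of three integer ratings on the 1–8 scale,
displayed to one decimal. The admissible values are therefore thirds of
integers: 1.0, 1.3, 1.7, 2.0, 2.3, 2.7, …, 7.7, 8.0 (22 values,
`feedback_grid()`). Three properties of this grid matter:

* it contains every integer rating, so the feedback can match a
  participant's own rating exactly — zero-discrepancy trials genuinely
  occur and are excluded from scoring because they belong to neither
  desirability condition;
* it is exactly closed under reverse coding: `9 − g` is on the grid for
  every grid value `g` (the displayed rounding residuals of `k/3` and
  `(27−k)/3` are mirror images);
* consecutive displayed steps alternate between 0.3 and 0.4, which is why
  the grid is loosely described as "steps of 0.3".

Recollections are snapped to this grid (nearest value, ties upward), since
the memory test accepts answers in the same one-decimal format.

### Scoring

All ratings and feedback values of negative traits are reverse-coded
(`9 − x`) onto a common desirability scale. Per trial, the feedback
discrepancy is `|feedback − first|`; feedback strictly above the first
rating is desirable, strictly below undesirable. Trials missing the first or
second rating are excluded from update scoring; trials missing only the
second rating are retained for memory scoring when a recollection exists
(the response-time exclusion concerns the updating measure, and a
recollection of a feedback value the participant saw is meaningful
regardless of the re-rating). Missing recollections are simply excluded from
memory means, not scored as maximal error.

Per participant and (target × desirability) cell:

```
relative mean update      = mean(update) / mean(discrepancy)
relative absolute mean update = ± relative mean update
```

with the sign flipped for the undesirable cell. Two points deserve emphasis
because they are easy to get wrong:

* **Ratio of means, not mean of per-trial ratios.** Dividing trial-level
  updates by trial-level discrepancies and averaging gives a different (and
  noisier) estimator; a constructed test case verifies the two differ.
* **"Absolute" is a condition-level sign flip, not `|x|` per participant.**
  Flipping the undesirable cell's sign makes "positive = moved toward the
  feedback" uniform across conditions while keeping the estimator linear in
  the data: a participant who moves *away* from undesirable feedback gets a
  negative score. Taking `|x|` per participant instead would bound every
  score below by the folded-normal mean of its own sampling noise —
  with cell-score noise around 0.15–0.2 that floor alone is ≈ 0.12–0.16,
  which would make the low undesirable-cell means (~0.1) unreachable
  and would bias parameter recovery upward at α = 0. The signed ratio is
  also emitted (`relative_mean_update`) for one-sample tests against zero.

`score_trials(..., by_valence = TRUE)` splits cells further by trait valence
for the five-factor analysis; the same aggregator runs with one more
grouping key.

## The inference layer

The condition scores feed a split-plot ANOVA
(`split_plot_anova()`): every within-subject effect is reduced to a
per-participant contrast score (all within factors have two levels, so each
effect is a single-df contrast and no sphericity machinery is needed) and
tested in a between-subjects linear model against its own
subject-by-effect error stratum; pure between effects are tested on the
per-participant cell means. Sums of squares are Type III with sum-to-zero
contrasts, because the between groups (27/24/28/25) are unbalanced and the
tested hypotheses should be the unweighted-marginal ones. Partial η² is
`SS_effect / (SS_effect + SS_error)` with each effect's own error stratum.
With four between cells and 104 participants the between-subject error df is
100; a 27/28 two-group comparison gives 53. Participants missing any within
cell are dropped listwise — a deliberate, documented choice (retaining
partial data would require mixed models, which the reference analysis style
does not use).

Correlational machinery: Pearson correlations carry Fisher-z confidence
intervals `tanh(atanh(r) ± z/√(n−3))`; independent correlations are compared
with Fisher's z-test; dependent correlations sharing a variable with
Williams' t (df = n − 3) — of the two classical variants (Hotelling's 1940
statistic and Williams' 1959 modification) we implement Williams, the
variant with correct type-I behavior at moderate n, and verify its df rule
and calibration by simulation. Hierarchical regression steps are tested with
the nested-model F-change. All p-values are two-sided and come from exact
F/t/normal distributions; permutation and simulation checks appear only in
the test suite as oracles. Degenerate inputs are defined rather than left to
propagate: zero-variance one-sample tests report t = 0 or ±∞, an
identically-zero contrast stratum reports F = 0, constant inputs to a
correlation raise an error.

## The generative model

The synthetic cohort (`simulate_cohort_trials()`) exists to validate the
pipeline and to power design analyses, so it is the *minimal* generative
model whose sufficient statistic under the scoring chain is exactly the
relative mean update:

* **First ratings** (recoded scale): `round(N(μ_target, 1.3))` clamped to
  1..8, with personal means `μ` drawn around 5.6 (self) and 5.4 (other) with
  SD 0.55 — a positivity bias toward the self in initial ratings.
* **Feedback engine**: with probability 0.04 the feedback equals the first
  rating (a deliberate zero-discrepancy trial); otherwise a magnitude of
  1–12 grid steps (≈ 0.3–4.0 rating points) is drawn uniformly, signed
  toward the desirable direction with probability 0.5, and clamped to the
  scale. The engine's distribution is a modeling choice — the paradigm
  specifies only that discrepancies are manipulated by a random number
  generator — and the defaults were chosen once so that *realized* mean
  absolute discrepancies land near 1.8–2.1 and total zero-discrepancy
  exclusions (deliberate draws plus discrepancies collapsed by clamping at
  the top of the scale, about 2.8 per 80 trials on their own) land near 5–6
  per 80, matching the reference task statistics. Clamping also implies
  that at a recoded first rating of 8 no desirable feedback is possible.
* **Updating**: `second = round(first + α·(feedback − first) + ε)` clamped
  to 1..8, ε ~ N(0, 1.6). The update fraction α is per participant and per
  (target × desirability) cell, assembled on the logit scale:
  cell base + culture offset + 0.27·(interdependence − 3.57) + shared
  participant effect (SD 0.22) + cell-specific participant effect (SD 1.1),
  then mapped through the inverse logit, which keeps every α in [0, 1]. The
  shared effect is a stable conformity trait; it is deliberately small
  relative to the cell-specific effect because observed condition scores
  correlate only modestly across cells.
* **Recollection**: feedback + N(0, 2.3) for self, N(0, 2.65) for other,
  snapped to the grid — own feedback is remembered more accurately.
* **Missingness**: each response (first, second, recollection)
  independently missing with probability 0.02, giving ~3 update-excluded
  trials per 80.
* **Covariates**: truncated normals per group with the reference means/SDs
  (interdependence higher in Chinese groups and in Beijing, independence and
  self-esteem higher in German groups); self-esteem is generated with a 0.32
  correlation to independence and none to interdependence, so the
  dependent-correlation comparison has a real signal to find.

Likert rounding is applied *before* clamping; rounding with a noise SD ≥ 0.5
acts as dither and keeps cell means essentially unbiased, which is why the
parameter-recovery experiment (`recover_alpha()`) recovers α ∈ {0, 0.25,
0.5, 0.75, 1} within ±0.05 at 100 participants × 80 trials/target with noise
SD 0.5. At noise SD near zero and fractional α, rounding attenuates updates
(e.g. α = 0.25 moves most ratings by less than half a point, which rounds
away); recovery guarantees therefore assume noise SD ≥ 0.5.

### Calibration of the defaults

The default parameters were calibrated once, by moment-matching simulated
cohorts to the reference group statistics (cell means and SDs of relative
updates, realized discrepancies, memory errors, first-rating means, exclusion
counts, and the interdependence–updating correlation ≈ 0.25), and then
frozen. Because participant heterogeneity on the logit scale shifts cell
means toward 0.5, the latent cell bases (0.465/0.03 self, 0.475/0.055 other)
sit away from the realized cell means (~0.37 desirable / ~0.10
undesirable).

One tension is worth recording: the reference pattern shows a large cultural
difference in the desirable cells (~0.095), almost none in the undesirable
cells, and an overall difference of ~0.05, while a single culture shift on
the logit scale moves all four cells together in proportion to α(1−α). The
chosen offset (±0.16) lands between the values implied by the
desirable-cell gap and by the overall gap, yielding a culture effect size at
the upper end of the reference range (partial η² ≈ 0.04–0.07). The culture
effect is low-powered by construction — that is a property of the reference
design, not a defect of the simulator — so single simulated cohorts will
sometimes miss it at α = 0.05, while the desirability (positivity-bias)
effect is overwhelming in essentially every cohort.

### What the generator does not emulate

Trait-specific semantics (every adjective is exchangeable within its
valence), sequential or run-order effects, response-time structure, the
social interaction itself, and any neural quantities. Real cohorts also
contain participants whose updating is systematically opposite to feedback;
the generator produces negative cell scores only through noise. Passing
tests therefore show that the pipeline is correct and well-calibrated, not
that the generative model is a complete account of behavior.

## Numerical choices and problem sizes

* Grid arithmetic runs on integer grid indices (k = 3..24, value =
  `round(k/3, 1)`), so zero discrepancies and reverse coding are exact;
  snapping breaks ties upward.
* Scores are serialized at six decimals, feedback at one decimal; manifests
  record MD5 hashes of the data files, so identical config + seed give
  byte-identical artifacts.
* All randomness flows through a single seed per entry point
  (`withr::local_seed`); no function touches the global RNG state without
  restoring it.
* The test suite sizes its simulations to be statistically decisive while
  staying quick: grid-membership and engine-distribution checks use 10⁴–10⁵
  draws, oracle equivalence uses 50 random trial tables, parameter recovery
  uses 100 participants × 160 trials per α, the calibrated-cohort check uses
  200 seeded replicates of the full 104-participant design, and the CI
  coverage / type-I calibration checks use 2,000 simulated samples each.

## Known limitations

* The split-plot ANOVA supports only two-level within factors (single-df
  contrasts). That covers the paradigm's designs; higher-level within
  factors would need sphericity handling and are refused explicitly.
* Listwise deletion of participants with undefined cells diverges from
  analyses that retain partial data; with the default missingness (~2% per
  response) empty cells are extremely rare.
* The agent model is first-order: no trait memory across the two rating
  phases beyond the first rating itself, no anchoring on the feedback at
  recollection beyond Gaussian noise.
* `fisher_z_independent()` and `hotelling_williams_t()` operate on
  correlation values, not raw data, mirroring how such tests are usually
  reported; they do not handle missing-data patterns themselves.
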
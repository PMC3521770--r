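---
title: "Screening, cut-off optimization and validation of OR-rule autoantibody panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, cut-off optimization and validation of OR-rule autoantibody panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seropanel)
```

## The problem

Tumour-associated antigens (TAAs) can elicit autoantibody (AAb) responses
detectable in serum by ELISA years before clinical diagnosis. Because any
single antigen is seropositive in only a few percent of cancers, clinical
tests combine several antigens into an **OR-rule panel**: a sample is
panel-positive when its optical density (OD) exceeds a per-antigen
cut-off for at least one antigen. Extending an existing panel with new
antigens then poses a chain of statistical questions:

* which of many candidate antigens discriminate cancers from matched
  controls at all (screening);
* where to place each antigen's positivity cut-off so that the *panel*,
  not each antigen in isolation, performs best (joint optimization);
* how much a candidate adds beyond the antigens already in the panel
  (additive positivity);
* whether performance survives on an independent cohort with the
  cut-offs frozen (validation);
* and what the resulting sensitivity/specificity mean for a screening
  population at a given prevalence (PPV).

`seropanel` implements this chain end to end, plus a synthetic-cohort
generator so every stage can be exercised and tested without patient
data.

## Screening with the two-sample K-S distance

For each antigen and coating concentration the package computes the
Kolmogorov–Smirnov distance

$$D \;=\; \sup_x \bigl|\hat F_{\text{cancer}}(x) - \hat F_{\text{control}}(x)\bigr|,$$

the supremum over pooled observed ODs of the gap between the two
right-continuous empirical CDFs. `ks_statistic()` evaluates both ECDFs at
the pooled unique points, which handles ties exactly and makes the
supremum computation finite and exact; the unit tests verify it against
independent brute-force enumeration on a thousand random instances.

$D$ is used as a **discrimination score, not a test**: no p-value is
attached and no multiple-testing correction is applied, because the
guard against selection noise is the downstream independent-cohort
validation, not a significance threshold. Triage is two-staged and
inclusive ($D \ge$ threshold): a permissive first pass (default 0.13 at
either of the 2-point assay's 100/50 nM concentrations) followed by a
stricter confirmation (default 0.2 at 160/50 nM on the titration assay).
Whether the permissive stage was meant strictly or inclusively is not
decidable from the verbal descriptions such rules come with; the
inclusive rule is simpler and ties at a threshold have probability zero
for continuous ODs.

A caveat worth knowing: $D$ is most sensitive to differences in the
middle of the distributions, while panel positivity lives in the upper
tail. An antigen can carry a respectable $D$ yet contribute almost no
additive positives — which is exactly why the pipeline follows the
screen with cut-off-based additivity analysis rather than ranking leads
by $D$ alone.

## Cut-off optimization

### Candidate grids

For one antigen, only thresholds between consecutive observed ODs change
the confusion table, so the search space is finite: `candidate_grid()`
returns the midpoints between consecutive sorted unique pooled ODs plus
one point below the minimum and one above the maximum (offset by half the
smallest gap, or 0.5 for a single unique value). Positivity is strict,
`OD > cutoff`, and grid points never coincide with data, so the grid
realizes every achievable (sens, spec) pair exactly once — verified in
the tests against a dense brute-force sweep over real thresholds.

### Objectives

The verbal design criterion — "the maximum number of cancers positive and
controls negative" — is implemented in two interpretations:

* `youden_sum` (default for the optimizers): maximize
  $w_s \cdot \text{sens} + w_p \cdot \text{spec}$, which with equal
  cohort sizes and unit weights is exactly maximizing TP + TN;
* `sens_at_spec_floor`: maximize sensitivity subject to
  $\text{spec} \ge$ floor, scored internally as the scalar
  $\text{sens} - 1000 \cdot \max(0, \text{floor} - \text{spec})$ so that
  every search method (including exhaustive enumeration) can compare
  configurations on one axis and any feasible point dominates every
  infeasible one.

Among tied optima the **largest** cut-off is returned, biasing toward
specificity: in a screening application with prevalence of a few percent,
false positives are the costly error.

### Joint panel-level search

For a panel, the OR rule couples the cut-offs: raising one antigen's
cut-off matters only for samples no other antigen catches.
`optimize_joint()` offers:

* **exhaustive** enumeration of the grid product (global optimum; guarded
  by an evaluation budget);
* **coordinate** ascent: cyclic single-antigen sweeps holding the others
  fixed, starting from the independently optimized single-antigen
  cut-offs, until a full sweep changes nothing. Each sweep is exact (the
  per-antigen profile is evaluated on the full grid via sorted-vector
  counting), the objective is non-decreasing, and termination is finite
  because the objective takes finitely many values;
* **restart** (default): the warm-started coordinate run plus `n_restarts`
  (default 25) coordinate runs from seeded random grid initializations,
  best kept.

Two numerical choices deserve explanation. First, coordinate steps accept
only **strictly** improving moves; the largest-cutoff tie-break applies
within an improving step. Accepting score-neutral moves toward larger
cut-offs looks harmless but lets a cut-off drift above seropositive
samples that other panel antigens happen to cover *in the training
cohort* — training-neutral, but it silently destroys validation
sensitivity. Second, the per-antigen working concentration is the one
with the larger screening $D$ (ties fall back to the highest
concentration), a pragmatic rule for deciding which titration point feeds
positivity calling.

On 200 random 3-antigen instances with coarse grids, the restart search
attains the exhaustive optimum in all cases in the package's acceptance
tests (the required rate is 95%), and by construction can never exceed
it.

### What empirical maximization can and cannot recover

Exact empirical maximization of sens + spec carries an intrinsic
optimism: per antigen, the top of the pooled background order statistics
is a cancer with probability about one half and can then be captured at
zero training false-positive cost, so training sensitivity exceeds the
generative seropositive rate by up to roughly one sample per panel
antigen (≤ panel size / n cancers). Under the specificity floor the
distortion is capped by the floor itself, and the **validated**
sensitivity — the quantity this workflow actually reports — is an
unbiased estimate of the generative panel sensitivity
$1 - \prod_a (1 - \pi_a)$. The parameter-recovery acceptance test
checks exactly this over 100 replicate cohort pairs at 165/165 with
twelve antigens, and bounds the training-side optimism by the analytic
limit above. With the unconstrained Youden sum at weak signal strengths,
by contrast, cut-offs migrate into the body of the background
distribution, validated specificity erodes badly, and "sensitivity" no
longer estimates the seropositive rate — which is why the end-to-end
pipeline defaults to the floor objective (floor 0.99, the
high-specificity regime screening panels are tuned to) while the
optimizer API keeps the Youden sum as its neutral default.

## Panel arithmetic

`panel_performance()` reports the OR-rule confusion table; the empty
panel is defined as sens 0 / spec 1 (nobody called positive) so the base
row of a combination scan is well defined. `additive_analysis()`
decomposes a lead's positives into those already found by the base panel
and the additive remainder; the integer identity

$$\text{tp}(\text{base} \cup \{\ell\}) \;=\; \text{tp}(\text{base}) +
  \#\{\text{additive positive cancers of } \ell\}$$

holds exactly on every dataset and is asserted property-style in the
tests, together with the OR-rule monotonicity laws (growing a panel at
fixed cut-offs can only raise sensitivity and lower specificity).
`validate_external()` is deliberately the same code path as
`panel_performance()` — validation is pure application of frozen
cut-offs, never a re-fit. `ppv()` applies Bayes' rule and reports
"1 in N" with N = 1/PPV rounded half away from zero; at 2.4% prevalence
the operating points 38%/86% and 49%/93% give 1 in 16 and 1 in 7
respectively, reproduced to the integer in the acceptance tests.

Fractions are kept raw in all machine-readable output and rounded only
at reporting (one decimal for table-style percentages, whole percents in
summaries).

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes:

* **Mixture signal.** Controls, and non-seropositive cancers, draw their
  baseline OD from a common lognormal background (default
  meanlog = log 0.1, sdlog = 0.25); each cancer is seropositive for each
  antigen with probability $\pi_a$ and then draws from an elevated
  lognormal (default meanlog = log 1.8, sdlog = 0.35). Lognormality is an
  assumption — immunoassay ODs are conventionally modelled on the log
  scale and positivity is guaranteed — not an estimated fact; nothing in
  the source material fixes the distributional family.
* **Titration.** Baselines are parameterized at the highest (reference)
  coating concentration and scaled to the others by a saturable binding
  curve $c/(c + K)$ normalized to the reference, capped at the
  plate-reader ceiling `od_max` (default 3.5; half-maximal concentration
  default 40 nM).
* **Replicates.** Each (sample, antigen, concentration) cell is measured
  in duplicate with multiplicative Gaussian noise of CV 0.1, truncated at
  zero and capped at `od_max`.
* **Matching.** Cohorts are 1:1 matched with pair-level age, gender and
  smoking covariates. These are plumbing metadata: matching shapes the
  study design, not the statistics computed here, and the covariates
  never enter any calculation.
* **Correlation.** Seropositivity is independent across antigens by
  default. Because OR-rule arithmetic is sensitive to cross-antigen
  correlation, an optional per-sample "responder" latent factor
  (`responder_rho`) multiplies each cancer's seropositivity by
  $(1 \pm \rho)$ according to a Bernoulli(1/2) latent flag, preserving
  the marginal $\pi_a$ while inducing positive correlation.

Generation is a pure function of the seed: identical parameters give
bit-identical tables. Default study conditions are a 165/165 discovery
cohort and a 100/100 optimization cohort; the default antigen set
couples a seven-antigen base panel (combined generative sensitivity
$1 - \prod(1-\pi_a) \approx 30\%$) with eight candidate leads at
cancer seropositivities of 1–15% and six null candidates, matching the
magnitudes published for this kind of panel (base panel alone around
24–36% sensitivity, leads contributing single-digit additive gains).

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: plate/batch/day effects and calibration
drift (real designs assay matched pairs on the same day for this
reason); distribution-middle shifts between cancers and controls (in
real data these inflate K-S scores beyond the seropositive fraction, so
the synthetic pipeline confirms fewer leads at the 0.2 threshold than a
real screen would); non-lognormal tails; and any dependence between
seropositivity and matching covariates. Batch effects can be probed
manually by shifting the background parameters between training and
validation cohorts, which visibly degrades transferred performance.

## Problem sizes used in the checks

The acceptance suite runs the K-S oracle comparison on 1,000 random
instances (n ≤ 50), the optimizer-vs-exhaustive comparison on 200
3-antigen instances with ≤ 9-point grids, and the parameter-recovery
experiment on 100 replicate cohort pairs at 165/165 with 12 antigens
measured at two concentrations in duplicate. The end-to-end demo uses
the full default conditions (21 antigens, 5-point titration).

## Known limitations

* The exact objective and search procedure behind commercially deployed
  cut-off optimizations are not public; both objectives offered here are
  labelled interpretations of the verbal criterion, and the random-restart
  search claims no equivalence to any proprietary Monte-Carlo scheme.
* Calibration to reference units is out of scope; the pipeline operates
  on OD throughout, matching how uncalibrated lead antigens are run.
* Confidence intervals for cohort estimates are not produced for real
  single-cohort data; the replicate-pair machinery in the tests covers
  synthetic data only.
* Missing-data handling is exclusion-with-logging at the panel level
  (a sample missing any panel cell is excluded from that panel's
  counts); no imputation is attempted.
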
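---
title: "Deriving pre-operative transfusion risk scores by resampled best-subset selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving pre-operative transfusion risk scores by resampled best-subset selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcscore)
```

## The problem

Invasive spine surgery (open fusion, corpectomy) can require red-blood-cell
(RBC) transfusion, and in settings where RBC packages must be assigned to an
individual patient ahead of surgery, over-assignment directly reduces the
blood bank's available stock. A pre-operative risk score lets clinicians
assign packages only to patients likely to need them. `rbcscore` implements
the full derivation pipeline for such a score from a patient-level cohort:
exhaustive best-subset logistic model selection under repeated stratified
resampling, nested-resampling internal validation, and conversion of the
final model into an integer point system with a score-to-probability
look-up table.

The cohort schema fixes 18 candidate pre-operative predictors — patient
characteristics (sex, age, height, weight, ASA class, anticoagulant
premedication, number of prior spine surgeries), laboratory measures (Hb,
Quick, INR, PTT, thrombocytes) and surgical planning variables (fracture,
tumor, surgery type, incision, vertebral body replacement, number of
operated stages) — plus the binary outcome: transfusion of one or more RBC
packages during surgery or the post-operative course. Stages is ordinal
with the five observed levels 0, 1, 2, 3 and >3 (the published descriptive
and scoring tables use all five, including 0); thrombocyte counts are
stored in whatever unit the source system records, since the variable only
ever enters models as a candidate predictor, never in unit-dependent
formulas.

## Model selection by repeated stratified resampling

The outcome is modelled by logistic regression,
$\operatorname{logit} P(Y = 1 \mid x) = \beta_0 + x^\top \beta$. To keep
roughly ten events per covariate at a cohort size of a few hundred, the
candidate set $M$ contains every subset of at most $k_{\max} = 4$ of the 18
predictors, including the intercept-only null model:
$|M| = \sum_{k=0}^{4} \binom{18}{k} = 4048$ (`enumerate_models()`).

Selection (`run_selection()`) proceeds in three steps:

1. Draw $J$ (default 100) random divisions of the cohort into a training
   part holding 80% of each outcome class and a test part holding the rest
   (`make_split_plan()`; per-class training counts are
   `round(0.8 * n_class)`, using R's round-half-to-even).
2. Fit every model $m \in M$ to every training part and compute the test-set
   AUC, $\mathrm{AUC}_{jm}$ (`evaluate_models()`). The AUC is the
   Mann–Whitney estimator: the fraction of (event, non-event) pairs in which
   the event scores higher, tied pairs counted 1/2.
3. Select the model maximizing $\frac{1}{J}\sum_j \mathrm{AUC}_{jm}$
   (`select_best()`), and report that mean with its min and max.

Missing values are handled by complete-case analysis *per model*: for each
candidate model, both partitions of each split drop only the records missing
one of that model's own predictors. A `complete_case = "global"` option
filters once on the whole pool instead, for sensitivity analyses.

Pairs that cannot be evaluated — a filtered partition that is empty or
single-class, too few usable training rows, a fit failure — are flagged with
a closed set of reasons and excluded from that model's mean rather than
imputed; a model with more than half of its entries flagged is disqualified
from selection and reported. Exact ties on the mean AUC go to the smaller
model, then to enumeration order (by size, then lexicographic), and the tie
is recorded.

## Nested internal validation

The selected mean AUC is optimistic: it is a maximum over 4048 models of a
noisy criterion. `nested_validate()` estimates the performance of the
*selection procedure itself*: the cohort is divided $K$ times (default 100)
into a stratified 80% derivation cohort $D^{(k)}$ and its held-out 20%
complement; the entire selection algorithm — its own $J$ inner splits, all
models, mean-AUC maximization — runs inside $D^{(k)}$; the winning model is
refit on all of $D^{(k)}$ and its AUC on the held-out complement gives
$\mathrm{AUC}^{(k)}$. The mean [min, max] over $k$ summarizes the honest
out-of-sample discrimination.

A design note: describing this procedure one can also report, for each outer
iteration, the selected model's mean AUC over the *inner* validation parts.
That quantity is the maximized selection criterion itself, so it inherits
the selection optimism that nesting exists to remove; under a pure-noise
cohort it sits systematically above 0.5, whereas the held-out estimate is
centred on 0.5. The held-out evaluation is therefore the default
(`outer_eval = "holdout"`), with the inner means always stored and
`outer_eval = "inner_mean"` available for comparison. Each outer iteration
derives its inner split seed deterministically from the master seed and the
iteration index, so the whole procedure is reproducible from one integer.

## From coefficients to an integer point system

`derive_points()` converts the final fit into a Sullivan-style point system.
First, `reorient_to_lowest_risk()` re-expresses each categorical term
against its lowest-risk category (absorbing the shift into the intercept, so
predictions are unchanged); every category then carries a nonnegative
coefficient and the lowest-risk group scores 0 points. A constant $B$ — the
log-odds worth one point — is set to the coefficient of a designated binary
term; here the vertebral-body-replacement coefficient, so that implanting a
vertebral body replacement contributes exactly one point. Each category of a
categorical term scores $\operatorname{round}(\beta_c / B)$ points.

A continuous predictor is first banded. Hemoglobin uses the four clinically
meaningful bands $<8$, $[8;12)$, $[12;16]$ and $>16$ g/dL (`hb_band_spec()`),
each represented by a value $W$; a band scores
$\operatorname{round}(\beta_{\mathrm{Hb}} (W - W_{\mathrm{ref}}) / B)$
against the reference band (the lowest-risk one — for a negative slope, the
highest band). The representative values are the band midpoints 10 and 14
for the interior bands and 7.5 for $<8$ (the midpoint of the band edge and
the lowest plausibly observed Hb of 7.0), with $W_{\mathrm{ref}} = 16$, the
boundary of the reference band. This is the simple convention that
reproduces the published points (7, 5, 2, 0) from the published per-g/dL
coefficient; both the bands and the representatives are configurable through
`band_spec()`. Rounding of points is nearest-integer, ties away from zero.

With the published coefficient estimates and $B = 0.841$:

```{r points}
fit <- structure(list(
  intercept = NA_real_,
  coefficients = c(
    surgery_type_thoracic = 0.267, surgery_type_lumbar = 1.099,
    surgery_type_combination = 1.783, vbr_yes = 0.841,
    stages_1 = 0.593, stages_2 = 1.805, stages_3 = 2.260,
    stages_gt3 = 2.122, hb = -0.665),
  converged = TRUE, stabilized = FALSE, n_used = 251),
  class = "logistic_fit")
system <- derive_points(fit, b_source = "vbr", bands = list(hb_band_spec()),
                        model = c("surgery_type", "vbr", "stages", "hb"))
system
```

The look-up table follows the same construction
(`build_lookup()`): a patient with total score $P$ has estimated probability
$\operatorname{expit}(\beta_0 + o + B \cdot P)$, where the base offset $o$
is the linear-predictor contribution of the zero-point reference values
(zero for reoriented categorical terms;
$\beta_{\mathrm{Hb}} W_{\mathrm{ref}}$ for banded Hb). Consecutive scores
thus differ by exactly $B$ on the logit scale and the table is strictly
increasing. The published system's look-up table is shipped verbatim
(`published_score_fixture()`) because its fitted intercept was never
published; systems derived from data carry their own intercept and build
their own table.

```{r worked-example}
fx <- published_score_fixture()
score_patient(list(surgery_type = "lumbar", vbr = TRUE, stages = "0",
                   hb = 9.1), fx$system, fx$lookup)
```

## The synthetic cohort generator

No public patient-level data accompany the published score, so the package
includes a generator (`generate_cohort()`) whose defaults
(`default_synthetic_config()`) emulate the published cohort's descriptive
tables:

* categorical variables drawn with the tables' overall relative frequencies
  (e.g. surgery type 71/32/105/44 out of 252 for
  cervical/thoracic/lumbar/combination; ASA probabilities renormalized over
  the non-missing records);
* continuous variables drawn as truncated normals with the tables' overall
  mean/SD and observed [min, max] as truncation bounds (Hb: mean 12.7, SD
  2.32, bounds [7.0, 19.1]); truncation is by rejection sampling, so the
  bounds carry no probability atoms;
* per-field missingness applied completely at random at the tables' missing
  fractions (e.g. 1/252 for vertebral body replacement);
* outcomes drawn from a ground-truth logistic model on surgery type,
  vertebral body replacement, stages and Hb with the published coefficient
  magnitudes, *before* missingness is applied. The intercept is calibrated
  by one-dimensional root-finding (`calibrate_intercept()`) on a fixed-seed
  Monte-Carlo sample of linear predictors so that the mean event probability
  equals 0.242, the published event rate (61/252); the solved value is
  about 4.76 (it is positive because the strongly negative Hb term centres
  the linear predictor far below zero).

Covariates are drawn independently: the real cohort's correlation structure
was never published, and the generator does not guess it. Consequently,
passing tests on synthetic data demonstrate the correctness of the
algorithms and the internal consistency of the pipeline — not that the
published coefficient values would be recovered from correlated clinical
data, nor anything about transportability to real patients. The generator
likewise does not emulate the within-patient correlation of repeated
surgeries (the published analysis treats repeat surgeries as separate
records with a prior-surgery count covariate, and so does the schema), nor
any informative missingness.

## Numerical choices

* **Fitting.** `fit_logistic()` maximizes the likelihood by IRLS with
  step-halving (the deviance never increases across iterations);
  convergence at maximum absolute score $< 10^{-8}$ or relative deviance
  change $< 10^{-10}$. On detected separation or non-convergence — easy to
  provoke in 80% subsamples of a few hundred records — the model is refit
  with a small ridge penalty ($\lambda = 10^{-4}$ on non-intercept terms)
  and flagged `stabilized`, so every (model, split) pair still yields a
  usable AUC instead of being discarded.
* **Degenerate columns.** A category absent from a training part gives a
  constant dummy column; it is dropped for that fit and treated as
  coefficient 0 at prediction time.
* **AUC ties.** Tied score pairs count 1/2 (midrank convention), computed
  from ranks in $O(n \log n)$.
* **Reproducibility.** Every stochastic entry point takes an explicit seed
  and restores the caller's RNG state; nested runs derive per-iteration
  seeds deterministically from the master seed.

## Problem sizes used by the test suite

The full published configuration ($J = K = 100$, 4048 models) is the
package default. The test suite exercises the same code paths at reduced
sizes chosen to keep the full derivation loops tractable while leaving the
statistical questions answerable: selection recovery uses cohorts of
$n = 800$ with a pool of 8 predictors (the 4 true ones plus 4 noise
covariates), $J = 25$ and 20 seeded repetitions; null-behaviour checks use
pure-noise cohorts of $n = 400$, a 5-predictor pool with $k_{\max} = 2$,
$K = 8$ outer and $J = 10$ inner splits over 5 seeds; parameter-recovery
and calibration checks use single cohorts of $n = 20000$.

## Known limitations

* The look-up probability at score $P$ evaluates the fitted model at the
  bands' representative values, while a real score stratum mixes patients
  across a band and across covariate patterns rounding to the same total.
  On large synthetic cohorts generated from the *continuous* ground truth,
  mid-range strata therefore show observed event rates up to roughly 0.1
  below the look-up values — inherent discretization optimism of any
  integer point system, not an implementation artefact. When outcomes are
  generated from the score system itself the strata calibrate to within
  binomial noise, which is the property the test suite asserts;
  `score_distribution()` reports both observed and estimated probabilities
  so users can judge the discretization cost on their own data.
* Synthetic covariate independence (above) limits what synthetic
  experiments can say about correlated predictors such as Hb/Quick/INR.
* The selection algorithm is exhaustive by design; with pools much beyond
  20 predictors or $k_{\max} > 4$ the model count grows combinatorially and
  a screening step would be needed.
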
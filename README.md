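# rbcscore

Derivation and internal validation of pre-operative red-blood-cell (RBC)
transfusion risk scores for invasive spine surgery, for biostatisticians and
clinical-research teams building easy-to-use bedside point systems from
retrospective cohorts.

Where RBC packages must be cross-matched and assigned to an individual
patient before surgery, over-assignment removes scarce products from the
blood bank. A pre-operative score that stratifies transfusion risk lets
assignment follow predicted need. `rbcscore` implements the complete
derivation pipeline:

* **Cohort handling** — a fixed 18-predictor schema (patient
  characteristics, coagulation labs, surgical planning variables) plus the
  binary transfusion outcome; CSV I/O, descriptive baseline tables, and
  per-model complete-case filtering.
* **Exhaustive best-subset selection** — all
  $\sum_{k=0}^{4}\binom{18}{k} = 4048$ logistic models
  $\operatorname{logit} P(Y{=}1\mid x) = \beta_0 + x^\top\beta$ of at most
  4 predictors, each fitted on $J = 100$ stratified 80/20 resamples; the
  selected model maximizes the mean test-set AUC (Mann–Whitney estimator,
  ties counted 1/2).
* **Nested resampling validation** — the whole selection procedure re-run
  inside $K = 100$ stratified 80% derivation cohorts, each winner refit and
  evaluated on its held-out 20%, yielding an optimism-corrected
  mean [min, max] AUC.
* **Sullivan point system** — coefficients converted to integer risk points
  via a constant $B$ (log-odds per point, set to the
  vertebral-body-replacement coefficient), banded hemoglobin, and a strictly
  increasing score→probability look-up table
  ($\operatorname{logit}$ increments of exactly $B$ per point).
* **Synthetic cohorts** — a generator emulating the published cohort's
  marginal distributions, missingness and ~24.2% event rate with a known
  ground-truth model, so the entire pipeline is testable without patient
  data.

## Worked example

Score the two reference patients with the published point system
(`published_score_fixture()` ships the printed points and look-up table):

```r
library(rbcscore)
fx <- published_score_fixture()

# patient 1: lumbar surgery, vertebral body replacement, 0 stages, Hb 9.1
score_patient(list(surgery_type = "lumbar", vbr = TRUE, stages = "0",
                   hb = 9.1), fx$system, fx$lookup)
#> $total
#> [1] 7
#> $probability
#> [1] 0.3113
#> $per_term
#> surgery_type          vbr       stages           hb
#>            1            1            0            5
```

A total of 7 points (1 for lumbar surgery, 1 for the vertebral body
replacement, 0 for stages, 5 for a hemoglobin in [8;12) g/dL) maps to an
estimated transfusion probability of 31.13%.

Derive a score system from data end-to-end on a synthetic cohort:

```r
coh <- read_cohort(system.file("extdata", "synthetic_cohort.csv",
                               package = "rbcscore"))
res <- run_selection(coh, k_max = 4, J = 100, seed = 1)  # ~10 min: 4048 models x 100 splits
res$selection
#> <selection_result> best model: hb + incision + stages + surgery_type
#>   mean AUC 0.815 [0.625, 0.976] over 100 valid splits

final <- complete_cases(coh, res$selection$best_model)
enc   <- encode_design(final, res$selection$best_model)
fit   <- fit_logistic(enc$X, enc$y)
sys   <- derive_points(fit, b_source = "incision", bands = list(hb_band_spec()),
                       model = res$selection$best_model)
sys
#> <score_system> B = 0.8922, max score 11
#>  hb: <8=6, [8;12)=4, [12;16]=1, >16=0
#>  incision: dorsal=1, ventral=0
#>  stages: 0=0, 1=0, 2=2, 3=2, gt3=2
#>  surgery_type: cervical=0, thoracic=2, lumbar=2, combination=2
lookup <- build_lookup(sys)
head(score_distribution(final, sys, lookup))
#> <score_distribution> 252 scored, 0 dropped (incomplete)
#>  score  n rel_frequency observed_rate estimated_probability
#>      0  1      0.003968        0.0000              0.001925
#>      1  5      0.019841        0.0000              0.004685
#>      2 21      0.083333        0.0000              0.011358
#>      3 22      0.087302        0.0000              0.027273
#>      4 60      0.238095        0.1000              0.064045
#>      5 23      0.091270        0.1739              0.143102
```

Points to read off this run: at n = 252 the selection lands on a close
neighbour of the generator's true model (`incision` displaces `vbr`, whose
29/252 prevalence makes its coefficient hard to pin down at this sample
size) — exactly the selection variability that `nested_validate()` is there
to quantify. The constant B must anchor on a *binary* term of the selected
model, so this run uses the incision coefficient (0.8922 log-odds per
point); the published system anchors on vertebral body replacement. Each
point multiplies the transfusion odds by `exp(B)` ≈ 2.44, and the
estimated probabilities climb from 0.2% at score 0 to 97% at the maximal
score 11, tracking the observed per-stratum rates.

(`synthetic_cohort.csv` is a synthetic 252-record cohort generated by
`default_synthetic_config(n = 252, seed = 2030)`; it contains no real
patient data.)

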
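# In-code fixtures shared across test files.

# One fully observed record with low-risk defaults; override fields as needed.
toy_record <- function(...) {
  rec <- list(
    sex = "male", age = 60, height = 175, weight = 80, asa = "2",
    anticoagulant = FALSE, prior_surgeries = "0", hb = 13.5, quick = 100,
    inr = 1.0, ptt = 25, thrombocytes = 250, fracture = FALSE, tumor = FALSE,
    surgery_type = "cervical", incision = "dorsal", vbr = FALSE,
    stages = "0", transfused = FALSE
  )
  overrides <- list(...)
  rec[names(overrides)] <- overrides
  rec
}

# Deterministic small cohort: alternating outcome, mild variation in the
# fields used by tests.
toy_cohort <- function(n = 10, name = "toy") {
  rows <- lapply(seq_len(n), function(i) {
    toy_record(
      age = 40 + i, hb = 10 + (i %% 6), quick = 90 + i,
      sex = if (i %% 2 == 0) "female" else "male",
      surgery_type = c("cervical", "thoracic", "lumbar", "combination")[1 + (i %% 4)],
      stages = c("0", "1", "2", "3", "gt3")[1 + (i %% 5)],
      vbr = i %% 3 == 0,
      transfused = i %% 2 == 0
    )
  })
  cohort(do.call(rbind, lapply(rows, as.data.frame)), name = name)
}

# Independent O(n^2) pair-counting AUC oracle (ties count 1/2).
auc_pair_oracle <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# The printed point-system coefficients as a logistic_fit-shaped object
# (no intercept was ever published alongside them).
printed_coefficient_fit <- function(intercept = NA_real_) {
  structure(list(
    intercept = intercept,
    coefficients = c(
      surgery_type_thoracic = 0.267, surgery_type_lumbar = 1.099,
      surgery_type_combination = 1.783, vbr_yes = 0.841,
      stages_1 = 0.593, stages_2 = 1.805, stages_3 = 2.260,
      stages_gt3 = 2.122, hb = -0.665),
    se = NULL, converged = TRUE, stabilized = FALSE, n_used = 251,
    deviance = NA_real_, deviance_trace = NA_real_,
    terms = c("surgery_type_thoracic", "surgery_type_lumbar",
              "surgery_type_combination", "vbr_yes", "stages_1", "stages_2",
              "stages_3", "stages_gt3", "hb")
  ), class = "logistic_fit")
}

score_model <- c("surgery_type", "vbr", "stages", "hb")

# Pure-noise synthetic configuration: outcome independent of every covariate
# at the study's ~24.2% event rate.
null_signal_config <- function(n, seed) {
  cfg <- default_synthetic_config(n = n, seed = seed)
  cfg$true_model$coefficients <- list(
    surgery_type = c(thoracic = 0, lumbar = 0, combination = 0),
    vbr = c(yes = 0), stages = c("1" = 0, "2" = 0, "3" = 0, gt3 = 0),
    hb = 0)
  cfg$true_model$intercept <- stats::qlogis(61 / 252)
  cfg
}
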
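test_that("hemoglobin banding assigns boundary values to the printed bands", {
  spec <- hb_band_spec()
  expect_equal(spec$labels, c("<8", "[8;12)", "[12;16]", ">16"))
  values <- c(7.0, 7.999, 8, 9.1, 11.7, 12, 14, 16, 16.001, 19)
  expect_equal(assign_band(spec, values),
               c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L))
  expect_true(is.na(assign_band(spec, NA_real_)))
})

test_that("the printed coefficients reproduce the printed risk points exactly", {
  sys <- derive_points(printed_coefficient_fit(), b_source = "vbr",
                       bands = list(hb_band_spec()), model = score_model)
  expect_equal(sys$B, 0.841)
  expect_equal(sys$points$surgery_type,
               c(cervical = 0L, thoracic = 0L, lumbar = 1L, combination = 2L))
  expect_equal(sys$points$vbr, c(no = 0L, yes = 1L))
  expect_equal(sys$points$stages,
               c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, gt3 = 3L))
  expect_equal(unname(sys$points$hb), c(7L, 5L, 2L, 0L))
  expect_equal(sys$max_score, 13L)
})

test_that("reorientation moves the zero point to the lowest-risk category without changing predictions", {
  # printed-style coefficients are already anchored at the lowest-risk
  # references: reorientation is the identity
  as_is <- reorient_to_lowest_risk(printed_coefficient_fit(intercept = -2),
                                   score_model)
  expect_equal(as_is$intercept, -2)
  expect_equal(unname(as_is$terms$surgery_type), c(0, 0.267, 1.099, 1.783))

  # a fit whose schema reference is NOT the lowest-risk category: thoracic
  # carries a negative coefficient, so it becomes the new zero point
  shifted <- printed_coefficient_fit(intercept = -2)
  shifted$coefficients[c("surgery_type_thoracic", "surgery_type_lumbar",
                         "surgery_type_combination")] <- c(-0.5, 0.5, 1.0)
  re <- reorient_to_lowest_risk(shifted, score_model)
  expect_equal(unname(re$terms$surgery_type[order(names(re$terms$surgery_type))]),
               unname(c(cervical = 0.5, combination = 1.5, lumbar = 1.0,
                        thoracic = 0)[sort(c("cervical", "combination",
                                             "lumbar", "thoracic"))]))
  expect_equal(min(re$terms$surgery_type), 0)
  expect_equal(re$intercept, -2.5)

  # the reparameterized linear predictor is identical for every pattern
  raw_lp <- function(fit, surgery, vbr, stages, hb) {
    dummies <- c(surgery_type_thoracic = surgery == "thoracic",
                 surgery_type_lumbar = surgery == "lumbar",
                 surgery_type_combination = surgery == "combination",
                 vbr_yes = vbr,
                 stages_1 = stages == "1", stages_2 = stages == "2",
                 stages_3 = stages == "3", stages_gt3 = stages == "gt3")
    fit$intercept + sum(fit$coefficients[names(dummies)] * dummies) +
      fit$coefficients[["hb"]] * hb
  }
  re_lp <- function(fit, surgery, vbr, stages, hb) {
    fit$intercept + fit$terms$surgery_type[[surgery]] +
      fit$terms$vbr[[if (vbr) "yes" else "no"]] +
      fit$terms$stages[[stages]] + fit$terms$hb * hb
  }
  for (surgery in c("cervical", "thoracic", "lumbar", "combination")) {
    for (stage in c("0", "2", "gt3")) {
      expect_equal(re_lp(re, surgery, TRUE, stage, 11),
                   raw_lp(shifted, surgery, TRUE, stage, 11))
    }
  }
})

test_that("derive_points enforces its contract", {
  fit <- printed_coefficient_fit()
  expect_error(derive_points(fit, "vbr", bands = list(), model = score_model),
               "band spec")
  expect_error(derive_points(fit, "stages", bands = list(hb_band_spec()),
                             model = score_model), "binary")
  expect_error(derive_points(fit, "vbr", bands = list(hb_band_spec())),
               "model")
  # a reference band that is not lowest-risk is rejected
  bad_bands <- band_spec("hb", breaks = c(8, 12, 16),
                         representatives = c(7.5, 10, 14, 16),
                         reference_band = 1L,
                         break_in_lower = c(FALSE, FALSE, TRUE))
  expect_error(derive_points(fit, "vbr", bands = list(bad_bands),
                             model = score_model), "lowest-risk")
})

test_that("worked examples score 7 and 10 points with the published probabilities", {
  fx <- published_score_fixture()
  p1 <- score_patient(list(surgery_type = "lumbar", vbr = TRUE,
                           stages = "0", hb = 9.1),
                      fx$system, fx$lookup)
  expect_equal(p1$total, 7L)
  expect_equal(unname(p1$per_term), c(1L, 1L, 0L, 5L))
  expect_equal(p1$probability, 0.3113)

  p2 <- score_patient(list(surgery_type = "combination", vbr = FALSE,
                           stages = "gt3", hb = 11.7),
                      fx$system, fx$lookup)
  expect_equal(p2$total, 10L)
  expect_equal(unname(p2$per_term), c(2L, 0L, 3L, 5L))
  expect_equal(p2$probability, 0.8491)

  # an all-reference patient scores zero
  p0 <- score_patient(list(surgery_type = "cervical", vbr = FALSE,
                           stages = "0", hb = 17),
                      fx$system, fx$lookup)
  expect_equal(p0$total, 0L)
  expect_equal(p0$probability, 0.0013)
})

test_that("patient scoring is order-invariant and reports missing terms", {
  fx <- published_score_fixture()
  rec <- list(hb = 9.1, stages = "0", vbr = TRUE, surgery_type = "lumbar")
  p <- score_patient(rec, fx$system, fx$lookup)
  expect_equal(p$total, 7L)
  expect_equal(sum(p$per_term), p$total)
  expect_error(
    score_patient(list(surgery_type = "lumbar", vbr = NA, stages = "0"),
                  fx$system),
    "vbr.*hb|hb.*vbr")
})

test_that("the published look-up table has the printed endpoints and plausible increments", {
  fx <- published_score_fixture()
  expect_equal(fx$lookup$score, 0:13)
  expect_equal(fx$lookup$probability[1], 0.0013)
  expect_equal(fx$lookup$probability[14], 0.9859)
  expect_true(all(diff(fx$lookup$probability) > 0))
  # per-point logit increments consistent with B = 0.841 under the 2-decimal
  # rounding of the printed percentages
  incr <- diff(qlogis(fx$lookup$probability))
  expect_true(all(incr > 0.80 & incr < 0.88))
  # max score equals the sum of the per-term maxima: 2 + 1 + 3 + 7
  expect_equal(fx$system$max_score,
               sum(vapply(fx$system$points, max, integer(1))))
  expect_equal(fx$system$max_score, 13L)
})

test_that("a fitted system's look-up table is the Sullivan construction", {
  cfg <- default_synthetic_config(n = 4000, seed = 31)
  coh <- complete_cases(generate_cohort(cfg), score_model)
  enc <- encode_design(coh, score_model)
  fit <- fit_logistic(enc$X, enc$y)
  sys <- derive_points(fit, "vbr", bands = list(hb_band_spec()),
                       model = score_model)
  lookup <- build_lookup(sys)
  expect_equal(lookup$score, 0:sys$max_score)
  expect_true(all(diff(lookup$probability) > 0))
  # consecutive scores differ by exactly B on the logit scale
  expect_equal(diff(qlogis(lookup$probability)),
               rep(sys$B, sys$max_score), tolerance = 1e-12)
  # a fixture system without a fitted intercept cannot build a table
  expect_error(build_lookup(published_score_fixture()$system), "intercept")
})

test_that("score systems serialize to JSON", {
  fx <- published_score_fixture()
  parsed <- jsonlite::fromJSON(score_system_to_json(fx$system, fx$lookup))
  expect_equal(parsed$B, 0.841)
  expect_equal(parsed$max_score, 13)
  expect_equal(parsed$points$surgery_type$combination, 2)
  expect_equal(parsed$lookup$probability[8], 0.3113)
})
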
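make_study_sized_cohort <- function(seed = 8) {
  cfg <- default_synthetic_config(n = 600, seed = seed)
  coh <- generate_cohort(cfg)
  # trim to exactly 61 events / 191 non-events, the published class sizes
  ev <- which(coh$transfused)[1:61]
  nev <- which(!coh$transfused)[1:191]
  rbcscore:::subset_cohort(coh, sort(c(ev, nev)))
}

test_that("stratified splits preserve the event ratio and partition the cohort", {
  coh <- make_study_sized_cohort()
  plan <- make_split_plan(coh, J = 10, train_fraction = 0.8, seed = 1)
  for (sp in plan$splits) {
    expect_equal(sum(coh$transfused[sp$train]), 49)   # round(0.8 * 61)
    expect_equal(sum(!coh$transfused[sp$train]), 153) # round(0.8 * 191)
    expect_equal(sort(c(sp$train, sp$test)), seq_len(252))
    expect_length(intersect(sp$train, sp$test), 0)
  }
})

test_that("split plans are reproducible and respect tiny balanced cohorts", {
  coh <- make_study_sized_cohort()
  p1 <- make_split_plan(coh, J = 1, seed = 7)
  p2 <- make_split_plan(coh, J = 1, seed = 7)
  expect_identical(p1$splits, p2$splits)

  four <- cohort(do.call(rbind, lapply(1:4, function(i) {
    as.data.frame(toy_record(transfused = i <= 2, age = 40 + i))
  })))
  plan <- make_split_plan(four, J = 5, train_fraction = 0.5, seed = 2)
  for (sp in plan$splits) {
    expect_equal(sum(four$transfused[sp$train]), 1)
    expect_equal(sum(four$transfused[sp$test]), 1)
    expect_length(sp$train, 2)
  }
  # a class too small to appear in both partitions
  expect_error(make_split_plan(four, J = 1, train_fraction = 0.9, seed = 1),
               "too small")
})

test_that("the null model scores AUC 0.5 on every split", {
  coh <- toy_cohort(20)
  space <- enumerate_models(c("hb", "age"), 0)
  plan <- make_split_plan(coh, J = 4, seed = 3)
  mat <- evaluate_models(coh, space, plan)
  expect_equal(unname(mat$auc[, 1]), rep(0.5, 4))
})

test_that("a perfectly separating predictor attains AUC 1 on every split", {
  rows <- lapply(1:40, function(i) {
    as.data.frame(toy_record(hb = if (i %% 2 == 0) 9 - i / 40 else 14 + i / 40,
                             transfused = i %% 2 == 0))
  })
  coh <- cohort(do.call(rbind, rows))
  space <- enumerate_models("hb", 1)
  plan <- make_split_plan(coh, J = 5, seed = 4)
  mat <- evaluate_models(coh, space, plan)
  expect_equal(unname(mat$auc[, 2]), rep(1, 5))
})

test_that("evaluate_models matches an independent glm-based reimplementation", {
  coh <- toy_cohort(20)
  coh$quick[c(3, 11)] <- NA  # exercise per-model complete-case filtering
  space <- enumerate_models(c("hb", "quick", "sex"), 1)  # 4 models
  plan <- make_split_plan(coh, J = 3, seed = 5)
  mat <- evaluate_models(coh, space, plan)

  df <- as.data.frame(coh)
  df$y <- as.integer(coh$transfused)
  for (mi in seq_along(space$models)) {
    model <- space$models[[mi]]
    for (j in seq_len(plan$J)) {
      tr <- plan$splits[[j]]$train
      te <- plan$splits[[j]]$test
      if (length(model) > 0) {
        ok <- stats::complete.cases(df[, model, drop = FALSE])
        tr <- tr[ok[tr]]; te <- te[ok[te]]
      }
      if (length(unique(df$y[tr])) < 2 || length(unique(df$y[te])) < 2) {
        expect_true(!is.na(mat$reason[j, mi]))
        next
      }
      form <- if (length(model) == 0) y ~ 1
              else stats::reformulate(model, "y")
      ref_fit <- suppressWarnings(glm(form, binomial(), df[tr, ]))
      scores <- predict(ref_fit, df[te, ], type = "response")
      expect_equal(mat$auc[j, mi], auc_pair_oracle(scores, df$y[te]),
                   tolerance = 1e-8)
    }
  }
})

test_that("selection maximizes the mean AUC with documented tie-breaking", {
  space <- enumerate_models(c("hb", "age"), 2)  # (null), age, hb, age+hb
  fake <- structure(list(
    auc = cbind(c(0.5, 0.5), c(0.9, 0.9), c(0.95, 0.80), c(0.6, 0.6)),
    reason = matrix(NA_character_, 2, 4),
    labels = model_labels(space)), class = "auc_matrix")
  sel <- select_best(fake, space)
  expect_equal(sel$best_model, "age")  # mean 0.90 beats 0.875
  expect_equal(sel$mean_auc, 0.9)

  # exact tie between a 1- and a 2-predictor model: smaller model wins
  fake$auc[, 3] <- fake$auc[, 2]
  fake$auc[, 4] <- fake$auc[, 2]
  sel <- select_best(fake, space)
  expect_length(sel$best_model, 1)
  expect_equal(length(sel$ties), 3)

  # heavily flagged models are disqualified
  fake2 <- fake
  fake2$auc[, 2] <- c(0.99, NA)
  fake2$reason[2, 2] <- "single_class_test"
  sel2 <- select_best(fake2, space, max_flagged_frac = 0.4)
  expect_true(2 %in% sel2$disqualified)
  expect_false(identical(sel2$best_index, 2L))
})

test_that("selection is invariant to model enumeration order up to tie-break", {
  coh <- toy_cohort(24)
  space <- enumerate_models(c("hb", "age", "sex"), 2)
  plan <- make_split_plan(coh, J = 4, seed = 6)
  mat <- evaluate_models(coh, space, plan)
  sel <- select_best(mat, space)

  perm <- rev(seq_along(space$models))
  space_p <- space
  space_p$models <- space$models[perm]
  mat_p <- mat
  mat_p$auc <- mat$auc[, perm, drop = FALSE]
  mat_p$reason <- mat$reason[, perm, drop = FALSE]
  mat_p$labels <- mat$labels[perm]
  sel_p <- select_best(mat_p, space_p)
  expect_setequal(sel_p$best_model, sel$best_model)
})

test_that("flagged entries carry reasons from the documented closed set", {
  coh <- toy_cohort(14)
  coh$quick[1:9] <- NA  # makes some partitions unusable for the quick model
  space <- enumerate_models(c("quick"), 1)
  plan <- make_split_plan(coh, J = 6, seed = 9)
  mat <- evaluate_models(coh, space, plan)
  reasons <- mat$reason[!is.na(mat$reason)]
  expect_true(all(reasons %in% rbcscore:::flag_reasons()))
  expect_true(all(mat$auc[!is.na(mat$auc)] >= 0 & mat$auc[!is.na(mat$auc)] <= 1))
})

test_that("the full pipeline is reproducible given the seed", {
  cfg <- default_synthetic_config(n = 200, seed = 14)
  coh <- generate_cohort(cfg)
  r1 <- run_selection(coh, c("hb", "stages", "age"), k_max = 2, J = 5, seed = 10)
  r2 <- run_selection(coh, c("hb", "stages", "age"), k_max = 2, J = 5, seed = 10)
  expect_identical(r1$auc_matrix$auc, r2$auc_matrix$auc)
  expect_identical(r1$selection$best_model, r2$selection$best_model)
})

test_that("nested validation has the Fig-2 structure and is reproducible", {
  cfg <- default_synthetic_config(n = 300, seed = 15)
  coh <- generate_cohort(cfg)
  nv <- nested_validate(coh, c("hb", "stages"), k_max = 1, K = 3, J = 4,
                        seed = 20)
  expect_length(nv$auc_k, 3)
  expect_equal(nv$mean_auc, mean(nv$auc_k))
  expect_equal(nv$min_auc, min(nv$auc_k))
  expect_equal(nv$max_auc, max(nv$auc_k))
  expect_true(all(nv$auc_k >= 0 & nv$auc_k <= 1))
  nv2 <- nested_validate(coh, c("hb", "stages"), k_max = 1, K = 3, J = 4,
                         seed = 20)
  expect_identical(nv$auc_k, nv2$auc_k)
  # K = 1 reduces to one selection run on an 80% derivation sample
  nv1 <- nested_validate(coh, c("hb", "stages"), k_max = 1, K = 1, J = 4,
                         seed = 21)
  expect_length(nv1$auc_k, 1)
  expect_length(nv1$selected_models, 1)
})
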
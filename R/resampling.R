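subset_cohort <- function(x, idx) {
  out <- x[idx, , drop = FALSE]
  attr(out, "cohort_name") <- attr(x, "cohort_name")
  class(out) <- c("cohort", "data.frame")
  out
}

#' Stratified repeated train/test split plan
#'
#' Draws `J` independent random divisions of the cohort into a training part
#' (a `train_fraction` share) and a test part (the remainder), stratified by
#' the event/non-event outcome: within each outcome class,
#' `round(train_fraction * n_class)` records (round-half-to-even) go to
#' training. Every training cohort therefore carries the same event/non-event
#' counts, within one patient of the cohort's event fraction.
#'
#' @param x A `cohort` with both outcome classes.
#' @param J Number of splits.
#' @param train_fraction Training share in (0, 1); 0.8 gives the usual
#'   80/20 division.
#' @param seed Integer seed; the plan is reproducible given the seed.
#' @return A `split_plan`: list with `splits` (each a list of integer
#'   `train` and `test` row indices), `J`, `train_fraction`, `seed`, and
#'   `strata` (per-class training counts).
#' @export
make_split_plan <- function(x, J = 100L, train_fraction = 0.8, seed = 1L) {
  validate_cohort(x)
  stopifnot(J >= 1, train_fraction > 0, train_fraction < 1)
  idx_event <- which(x$transfused)
  idx_none <- which(!x$transfused)
  n_tr_event <- round(train_fraction * length(idx_event))
  n_tr_none <- round(train_fraction * length(idx_none))
  if (n_tr_event < 1 || n_tr_event >= length(idx_event) ||
      n_tr_none < 1 || n_tr_none >= length(idx_none)) {
    stop("an outcome class is too small to appear in both partitions")
  }
  splits <- with_local_seed(seed, {
    lapply(seq_len(J), function(j) {
      tr <- c(sample(idx_event, n_tr_event), sample(idx_none, n_tr_none))
      tr <- sort(tr)
      list(train = tr, test = setdiff(seq_len(nrow(x)), tr))
    })
  })
  structure(list(splits = splits, J = as.integer(J),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 strata = c(train_events = n_tr_event,
                            train_nonevents = n_tr_none)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> J = %d, train fraction %.2f (%d events + %d non-events per training cohort), seed %d\n",
              x$J, x$train_fraction, x$strata[["train_events"]],
              x$strata[["train_nonevents"]], x$seed))
  invisible(x)
}

# Design columns for a model without dropping degenerate columns (those are
# handled per training subset inside evaluate_models).
build_design_full <- function(x, model) {
  schema <- cohort_schema()
  n <- nrow(x)
  cols <- list()
  for (pred in model) {
    v <- x[[pred]]
    sc <- schema[[pred]]
    if (sc$type == "numeric") {
      cols[[pred]] <- as.numeric(v)
    } else if (sc$type == "logical") {
      cols[[paste0(pred, "_yes")]] <- as.numeric(v)
    } else {
      for (lev in sc$levels[-1]) {
        cols[[paste0(pred, "_", lev)]] <- as.numeric(v == lev)
      }
    }
  }
  if (length(cols) == 0) matrix(numeric(0), nrow = n, ncol = 0)
  else do.call(cbind, cols)
}

flag_reasons <- function() {
  c("empty_partition", "single_class_train", "single_class_test",
    "too_few_rows", "fit_error")
}

#' Evaluate every candidate model on every split
#'
#' For each (split, model) pair: both partitions are complete-case filtered
#' on the model's own predictors, the model is fitted on the filtered
#' training part, the filtered test part is scored, and the test-set AUC is
#' recorded. Pairs that cannot be evaluated (an empty or single-class
#' filtered partition, too few usable training rows, a fit error) are flagged
#' with a reason rather than silently zeroed. Dummy columns constant within a
#' training part are dropped for that fit and treated as coefficient 0 at
#' prediction.
#'
#' @param x A `cohort`.
#' @param space A `model_space`.
#' @param plan A `split_plan` on `x`.
#' @return An `auc_matrix`: list with `auc` (J x M numeric matrix, `NA` where
#'   flagged), `reason` (J x M character matrix, `NA` where evaluated), and
#'   `labels` (model labels).
#' @export
evaluate_models <- function(x, space, plan) {
  stopifnot(inherits(x, "cohort"), inherits(space, "model_space"),
            inherits(plan, "split_plan"))
  J <- plan$J
  M <- length(space$models)
  auc_mat <- matrix(NA_real_, J, M)
  reason_mat <- matrix(NA_character_, J, M)
  df <- as.data.frame(x)
  y_all <- as.integer(x$transfused)
  for (mi in seq_len(M)) {
    model <- space$models[[mi]]
    ok_rows <- if (length(model) == 0) rep(TRUE, nrow(x))
               else stats::complete.cases(df[, model, drop = FALSE])
    pos <- cumsum(ok_rows)  # row index -> position within complete subset
    Xfull <- build_design_full(subset_cohort(x, which(ok_rows)), model)
    for (j in seq_len(J)) {
      tr <- plan$splits[[j]]$train
      te <- plan$splits[[j]]$test
      tr <- tr[ok_rows[tr]]
      te <- te[ok_rows[te]]
      if (length(tr) == 0 || length(te) == 0) {
        reason_mat[j, mi] <- "empty_partition"; next
      }
      ytr <- y_all[tr]; yte <- y_all[te]
      if (length(unique(ytr)) < 2) { reason_mat[j, mi] <- "single_class_train"; next }
      if (length(unique(yte)) < 2) { reason_mat[j, mi] <- "single_class_test"; next }
      Xtr <- Xfull[pos[tr], , drop = FALSE]
      if (ncol(Xtr) > 0) {
        keep <- apply(Xtr, 2, function(col) any(col != col[1]))
        Xtr <- Xtr[, keep, drop = FALSE]
      }
      if (length(ytr) < ncol(Xtr) + 1) { reason_mat[j, mi] <- "too_few_rows"; next }
      fit <- tryCatch(fit_logistic(Xtr, ytr), error = function(e) NULL)
      if (is.null(fit)) { reason_mat[j, mi] <- "fit_error"; next }
      scores <- predict_prob(fit, Xfull[pos[te], , drop = FALSE])
      auc_mat[j, mi] <- auc(scores, yte)
    }
  }
  structure(list(auc = auc_mat, reason = reason_mat,
                 labels = model_labels(space)),
            class = "auc_matrix")
}

#' @export
print.auc_matrix <- function(x, ...) {
  cat(sprintf("<auc_matrix> %d splits x %d models, %d flagged entries\n",
              nrow(x$auc), ncol(x$auc), sum(!is.na(x$reason))))
  invisible(x)
}

#' Write the AUC matrix to CSV
#'
#' @param x An `auc_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_auc_matrix <- function(x, path) {
  stopifnot(inherits(x, "auc_matrix"))
  out <- as.data.frame(x$auc)
  names(out) <- x$labels
  utils::write.csv(cbind(split = seq_len(nrow(out)), out), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Select the best-performing model by mean test AUC
#'
#' The selected model maximizes the arithmetic mean AUC over its valid
#' (unflagged) entries. Models with more than `max_flagged_frac` of their
#' entries flagged are disqualified and reported. Exact ties on the mean are
#' broken in favour of fewer predictors, then enumeration order; ties are
#' recorded in the result.
#'
#' @param aucmat An `auc_matrix`.
#' @param space The `model_space` the matrix was computed on.
#' @param max_flagged_frac Disqualification threshold for flagged entries.
#' @return A `selection_result`: `best_model` (predictor names),
#'   `best_index`, `mean_auc`, `min_auc`, `max_auc`, `per_split_aucs`,
#'   `model_means`, `ties` (indices sharing the maximal mean), and
#'   `disqualified` (model indices).
#' @export
select_best <- function(aucmat, space, max_flagged_frac = 0.5) {
  stopifnot(inherits(aucmat, "auc_matrix"), inherits(space, "model_space"))
  M <- ncol(aucmat$auc)
  stopifnot(M == length(space$models))
  n_valid <- colSums(!is.na(aucmat$auc))
  flag_frac <- 1 - n_valid / nrow(aucmat$auc)
  disqualified <- which(flag_frac > max_flagged_frac)
  means <- colMeans(aucmat$auc, na.rm = TRUE)
  means[n_valid == 0] <- NA_real_
  means[disqualified] <- NA_real_
  if (all(is.na(means))) stop("no model has enough valid AUC entries")
  best_mean <- max(means, na.rm = TRUE)
  ties <- which(!is.na(means) & abs(means - best_mean) < 1e-15)
  if (length(ties) > 1) {
    sizes <- vapply(space$models[ties], length, integer(1))
    ties_ordered <- ties[order(sizes, ties)]
  } else {
    ties_ordered <- ties
  }
  best <- ties_ordered[1]
  vals <- aucmat$auc[, best]
  vals <- vals[!is.na(vals)]
  structure(list(
    best_model = space$models[[best]],
    best_index = best,
    mean_auc = mean(vals),
    min_auc = min(vals),
    max_auc = max(vals),
    per_split_aucs = aucmat$auc[, best],
    model_means = means,
    ties = ties_ordered,
    disqualified = disqualified
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  label <- if (length(x$best_model) == 0) "(null)" else paste(x$best_model, collapse = " + ")
  cat(sprintf("<selection_result> best model: %s\n  mean AUC %.3f [%.3f, %.3f] over %d valid splits\n",
              label, x$mean_auc, x$min_auc, x$max_auc,
              sum(!is.na(x$per_split_aucs))))
  if (length(x$ties) > 1) cat("  tie among", length(x$ties), "models (broken by size, then order)\n")
  invisible(x)
}

#' Run the full model selection on a cohort
#'
#' Convenience pipeline: enumerate the model space, draw the stratified split
#' plan, evaluate all models on all splits, and select the best by mean test
#' AUC.
#'
#' @param x A `cohort`.
#' @param predictor_pool Candidate predictors.
#' @param k_max Maximum model size.
#' @param J Number of stratified splits.
#' @param train_fraction Training share.
#' @param seed Integer seed.
#' @param complete_case `"per_model"` (default) filters each split's
#'   partitions on each model's own predictors; `"global"` filters the cohort
#'   once on the full predictor pool before splitting.
#' @return List with `selection`, `auc_matrix`, `plan`, `space`, and the
#'   (possibly filtered) `cohort`.
#' @export
run_selection <- function(x, predictor_pool = predictor_names(), k_max = 4L,
                          J = 100L, train_fraction = 0.8, seed = 1L,
                          complete_case = c("per_model", "global")) {
  complete_case <- match.arg(complete_case)
  if (complete_case == "global") x <- complete_cases(x, predictor_pool)
  space <- enumerate_models(predictor_pool, k_max)
  plan <- make_split_plan(x, J, train_fraction, seed)
  aucmat <- evaluate_models(x, space, plan)
  sel <- select_best(aucmat, space)
  list(selection = sel, auc_matrix = aucmat, plan = plan, space = space,
       cohort = x)
}

#' Nested resampling validation of the selection procedure
#'
#' Estimates the out-of-sample performance of the whole selection algorithm,
#' guarding against selection optimism. The cohort is divided `K` times into
#' a stratified 80% derivation cohort and its 20% held-out complement. The
#' complete selection procedure (its own `J` inner stratified splits,
#' all-models evaluation, mean-AUC maximization) runs entirely within each
#' derivation cohort; the selected model is then refit on the full derivation
#' cohort and its AUC is measured on the held-out complement, giving AUC(k).
#' The distribution of AUC(k) is summarized as mean \[min, max\].
#'
#' `outer_eval = "inner_mean"` instead reports, as AUC(k), the selected
#' model's mean AUC over the inner validation cohorts of the derivation
#' cohort (no held-out evaluation); this reproduces a literal reading of the
#' selection summary but carries the selection optimism, and the held-out
#' variant is the default. The inner means are stored in either case.
#'
#' @param x A `cohort`.
#' @param predictor_pool Candidate predictors.
#' @param k_max Maximum model size.
#' @param K Number of outer derivation cohorts.
#' @param J Number of inner splits within each derivation cohort.
#' @param train_fraction Training share used at both levels.
#' @param seed Master seed; each outer iteration derives its own inner seed
#'   deterministically from it.
#' @param outer_eval `"holdout"` (default) or `"inner_mean"`, see above.
#' @param complete_case Passed to the inner selection runs.
#' @return A `nested_validation`: `auc_k`, `mean_auc`, `min_auc`, `max_auc`,
#'   `selected_models` (per-k predictor sets), `inner_mean_auc` (per-k inner
#'   selection means), and the call parameters.
#' @export
nested_validate <- function(x, predictor_pool = predictor_names(), k_max = 4L,
                            K = 100L, J = 100L, train_fraction = 0.8,
                            seed = 1L, outer_eval = c("holdout", "inner_mean"),
                            complete_case = c("per_model", "global")) {
  outer_eval <- match.arg(outer_eval)
  complete_case <- match.arg(complete_case)
  validate_cohort(x)
  outer_plan <- make_split_plan(x, K, train_fraction, seed)
  space <- enumerate_models(predictor_pool, k_max)
  auc_k <- numeric(K)
  inner_means <- numeric(K)
  selected <- vector("list", K)
  for (k in seq_len(K)) {
    res <- tryCatch({
      deriv_idx <- outer_plan$splits[[k]]$train
      hold_idx <- outer_plan$splits[[k]]$test
      deriv <- subset_cohort(x, deriv_idx)
      inner_seed <- derive_seed(seed, k)
      inner_plan <- make_split_plan(deriv, J, train_fraction, inner_seed)
      if (complete_case == "global") {
        # filter within the derivation cohort, consistent with run_selection
        deriv <- complete_cases(deriv, predictor_pool)
        inner_plan <- make_split_plan(deriv, J, train_fraction, inner_seed)
      }
      aucmat <- evaluate_models(deriv, space, inner_plan)
      sel <- select_best(aucmat, space)
      auc_out <- if (outer_eval == "inner_mean") {
        sel$mean_auc
      } else {
        model <- sel$best_model
        deriv_cc <- complete_cases(deriv, model)
        hold <- subset_cohort(x, hold_idx)
        hold_ok <- if (length(model) == 0) rep(TRUE, nrow(hold))
                   else stats::complete.cases(as.data.frame(hold)[, model, drop = FALSE])
        hold <- subset_cohort(hold, which(hold_ok))
        if (length(unique(hold$transfused)) < 2) {
          stop("held-out cohort has a single outcome class")
        }
        Xtr <- build_design_full(deriv_cc, model)
        if (ncol(Xtr) > 0) {
          keep <- apply(Xtr, 2, function(col) any(col != col[1]))
          Xtr <- Xtr[, keep, drop = FALSE]
        }
        fit <- fit_logistic(Xtr, as.integer(deriv_cc$transfused))
        Xte <- build_design_full(hold, model)
        auc(predict_prob(fit, Xte), as.integer(hold$transfused))
      }
      list(auc = auc_out, inner = sel$mean_auc, model = sel$best_model)
    }, error = function(e) {
      stop(sprintf("outer iteration k = %d: %s", k, conditionMessage(e)),
           call. = FALSE)
    })
    auc_k[k] <- res$auc
    inner_means[k] <- res$inner
    selected[[k]] <- res$model
  }
  structure(list(auc_k = auc_k, mean_auc = mean(auc_k), min_auc = min(auc_k),
                 max_auc = max(auc_k), selected_models = selected,
                 inner_mean_auc = inner_means,
                 K = as.integer(K), J = as.integer(J),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 outer_eval = outer_eval),
            class = "nested_validation")
}

#' @export
print.nested_validation <- function(x, ...) {
  cat(sprintf("<nested_validation> K = %d outer, J = %d inner (%s)\n  AUC(k): mean %.3f [%.3f, %.3f]\n",
              x$K, x$J, x$outer_eval, x$mean_auc, x$min_auc, x$max_auc))
  invisible(x)
}
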
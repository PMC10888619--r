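#' Encode a design matrix with fixed reference levels
#'
#' Builds the 0/1 design matrix for a candidate model on a cohort that has
#' already been complete-case filtered for the model's predictors. Continuous
#' predictors contribute an identity column; categorical predictors
#' contribute one dummy column per non-reference level, the reference being
#' the first schema level (cervical surgery, 0 stages, no vertebral body
#' replacement, dorsal incision, ASA 1, 0 prior surgeries, male sex, and
#' "no" for the binaries). Column order is deterministic: predictors in model
#' order, levels in schema order.
#'
#' A categorical level absent from the cohort yields a constant zero dummy;
#' such degenerate columns are dropped and recorded in the
#' `"dropped_columns"` attribute (prediction treats them as coefficient 0).
#'
#' @param x A `cohort` with no missing values on `model`'s predictors.
#' @param model Character vector of predictor names (possibly empty: the
#'   intercept-only null model).
#' @return List with `X` (numeric matrix, 0 columns for the null model),
#'   `y` (0/1 outcome vector), and `dropped` (names of dropped degenerate
#'   columns).
#' @export
encode_design <- function(x, model = character(0)) {
  stopifnot(inherits(x, "cohort"))
  bad <- setdiff(model, predictor_names())
  if (length(bad) > 0) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  schema <- cohort_schema()
  n <- nrow(x)
  cols <- list()
  for (pred in model) {
    v <- x[[pred]]
    if (anyNA(v)) {
      stop("predictor '", pred, "' has missing values; complete-case filter first")
    }
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
  X <- if (length(cols) == 0) {
    matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    do.call(cbind, cols)
  }
  dropped <- character(0)
  if (ncol(X) > 0) {
    constant <- apply(X, 2, function(col) length(unique(col)) == 1L)
    dropped <- colnames(X)[constant]
    X <- X[, !constant, drop = FALSE]
  }
  list(X = X, y = as.integer(x$transfused), dropped = dropped)
}

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares. Convergence is declared when the maximum absolute score (gradient
#' of the log-likelihood) falls below `tol`, or the relative deviance change
#' falls below `dev_tol`. On detected separation or non-convergence the model
#' is refit with a small L2 (ridge) penalty on the non-intercept terms and
#' flagged `stabilized = TRUE`, so that every training sample yields usable
#' predictions even when a small resample separates.
#'
#' @param X Numeric predictor matrix (no intercept column; may have 0
#'   columns for the intercept-only model).
#' @param y 0/1 outcome vector containing both classes.
#' @param tol Score convergence tolerance.
#' @param dev_tol Relative deviance-change tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @param ridge L2 penalty used for the stabilized refit.
#' @return A `logistic_fit`: list with `intercept`, `coefficients` (named),
#'   `se` (standard errors from the inverse Fisher information, intercept
#'   first), `converged`, `stabilized`, `n_used`, `deviance`, and
#'   `deviance_trace`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, dev_tol = 1e-10, max_iter = 50L,
                         ridge = 1e-4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("outcome contains a single class")
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  if (nrow(X) != length(y)) stop("X and y dimensions differ")
  if (nrow(X) < ncol(X) + 1) stop("need at least one more row than columns")
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  Xi <- cbind(`(intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dep <- colnames(Xi)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xi))]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }

  res <- irls(Xi, y, lambda = 0, tol = tol, dev_tol = dev_tol,
              max_iter = max_iter)
  separated <- any(res$p < 1e-7 | res$p > 1 - 1e-7) &&
    max(abs(res$beta)) > 10
  stabilized <- FALSE
  if (!res$converged || separated || any(!is.finite(res$beta))) {
    res <- irls(Xi, y, lambda = ridge, tol = tol, dev_tol = dev_tol,
                max_iter = 200L)
    stabilized <- TRUE
  }
  beta <- res$beta
  structure(list(
    intercept = unname(beta[1]),
    coefficients = if (length(beta) > 1) beta[-1] else stats::setNames(numeric(0), character(0)),
    se = res$se,
    converged = res$converged,
    stabilized = stabilized,
    n_used = length(y),
    deviance = res$deviance,
    deviance_trace = res$trace,
    terms = colnames(X)
  ), class = "logistic_fit")
}

# IRLS core: Xi includes the intercept column; lambda penalizes all but the
# first coefficient. Step-halving keeps the deviance non-increasing.
irls <- function(Xi, y, lambda, tol, dev_tol, max_iter) {
  p <- ncol(Xi)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  beta[1] <- logit(max(min(mean(y), 1 - 1e-6), 1e-6))
  dev_fun <- function(b) {
    eta <- drop(Xi %*% b)
    # numerically stable log(1 + exp(eta))
    log1pexp <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    -2 * sum(y * eta - log1pexp) + sum(pen * b^2)
  }
  dev <- dev_fun(beta)
  trace <- dev
  converged <- FALSE
  prob <- expit(drop(Xi %*% beta))
  for (iter in seq_len(max_iter)) {
    w <- pmax(prob * (1 - prob), 1e-12)
    score <- drop(crossprod(Xi, y - prob)) - pen * beta
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    H <- crossprod(Xi * w, Xi)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new_dev <- dev_fun(new_beta)
    halvings <- 0L
    while (new_dev > dev + 1e-12 && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_dev <- dev_fun(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    prob <- expit(drop(Xi %*% beta))
    trace <- c(trace, new_dev)
    if (abs(dev - new_dev) / (abs(dev) + 0.1) < dev_tol) {
      converged <- TRUE
      dev <- new_dev
      break
    }
    dev <- new_dev
  }
  se <- rep(NA_real_, p)
  w <- pmax(prob * (1 - prob), 1e-12)
  H <- crossprod(Xi * w, Xi)
  diag(H) <- diag(H) + pen
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(diag(cov))
  names(se) <- colnames(Xi)
  list(beta = stats::setNames(beta, colnames(Xi)), converged = converged,
       deviance = dev_fun(beta) - sum(pen * beta^2), p = prob, se = se,
       trace = trace)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, deviance = %.3f%s%s\n", x$n_used,
              x$deviance,
              if (x$converged) "" else " (not converged)",
              if (x$stabilized) " (L2-stabilized)" else ""))
  print(round(c("(intercept)" = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Predicted event probabilities
#'
#' Applies the inverse-logit of the fitted linear predictor to new rows.
#' Columns of `X` must match the fit's terms; columns the fit dropped as
#' degenerate during training are treated as coefficient 0 and may simply be
#' absent from the fit.
#'
#' @param fit A `logistic_fit`.
#' @param X Numeric matrix whose column names include every fitted term.
#' @return Probability vector in (0, 1).
#' @export
predict_prob <- function(fit, X) {
  stopifnot(inherits(fit, "logistic_fit"))
  X <- as.matrix(X)
  terms <- names(fit$coefficients)
  if (length(terms) > 0) {
    if (is.null(colnames(X)) || !all(terms %in% colnames(X))) {
      stop("X lacks fitted column(s): ",
           paste(setdiff(terms, colnames(X)), collapse = ", "))
    }
    eta <- fit$intercept + drop(X[, terms, drop = FALSE] %*% fit$coefficients)
  } else {
    eta <- rep(fit$intercept, nrow(X))
  }
  expit(eta)
}

#' Serialize a fit to JSON
#'
#' @param fit A `logistic_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  obj <- list(intercept = fit$intercept,
              coefficients = as.list(fit$coefficients),
              converged = fit$converged, stabilized = fit$stabilized,
              n_used = fit$n_used, deviance = fit$deviance)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
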
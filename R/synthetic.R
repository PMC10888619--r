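#' Default synthetic cohort configuration
#'
#' Builds a [synthetic_config()] whose marginal distributions mirror the
#' published descriptive tables of a 252-patient invasive spine-surgery
#' cohort: categorical probabilities equal the overall relative frequencies,
#' continuous variables are truncated normals with the overall mean/SD and the
#' observed \[min, max\] as truncation bounds, and per-field missingness
#' equals the tables' missing fractions. Outcomes are drawn from a
#' ground-truth logistic model on surgery type, vertebral body replacement,
#' stages, and hemoglobin, with published-magnitude log-odds; its intercept is
#' calibrated by root-finding so the mean event probability is 0.242
#' (61 transfused of 252).
#'
#' @param n Target cohort size.
#' @param seed Seed used by [generate_cohort()].
#' @return A `synthetic_config`.
#' @export
default_synthetic_config <- function(n = 252, seed = 1L) {
  marginals <- list(
    sex             = list(type = "categorical",
                           probs = c(male = 129, female = 123) / 252),
    age             = list(type = "continuous", mean = 62.6, sd = 17.3,
                           lower = 14, upper = 89),
    height          = list(type = "continuous", mean = 172, sd = 10.1,
                           lower = 140, upper = 198),
    weight          = list(type = "continuous", mean = 79.9, sd = 18.3,
                           lower = 38, upper = 150),
    asa             = list(type = "categorical",
                           probs = c("1" = 23, "2" = 131, "ge3" = 72) / 226),
    anticoagulant   = list(type = "binary", prob = 76 / 252),
    prior_surgeries = list(type = "categorical",
                           probs = c("0" = 214, "1" = 34, "2" = 4) / 252),
    hb              = list(type = "continuous", mean = 12.7, sd = 2.32,
                           lower = 7.0, upper = 19.1),
    quick           = list(type = "continuous", mean = 101, sd = 14.7,
                           lower = 21, upper = 130),
    inr             = list(type = "continuous", mean = 1.00, sd = 0.146,
                           lower = 0.8, upper = 2.8),
    ptt             = list(type = "continuous", mean = 25.1, sd = 4.62,
                           lower = 18, upper = 65),
    thrombocytes    = list(type = "continuous", mean = 281, sd = 104,
                           lower = 84, upper = 792),
    fracture        = list(type = "binary", prob = 73 / 252),
    tumor           = list(type = "binary", prob = 42 / 252),
    surgery_type    = list(type = "categorical",
                           probs = c(cervical = 71, thoracic = 32,
                                     lumbar = 105, combination = 44) / 252),
    incision        = list(type = "categorical",
                           probs = c(dorsal = 199, ventral = 53) / 252),
    vbr             = list(type = "binary", prob = 29 / 251),
    stages          = list(type = "categorical",
                           probs = c("0" = 104, "1" = 32, "2" = 57,
                                     "3" = 24, "gt3" = 35) / 252)
  )
  missingness <- c(height = 7 / 252, weight = 2 / 252, asa = 26 / 252,
                   quick = 1 / 252, inr = 1 / 252, ptt = 3 / 252,
                   thrombocytes = 4 / 252, vbr = 1 / 252)
  true_model <- list(
    predictors = c("surgery_type", "vbr", "stages", "hb"),
    coefficients = list(
      surgery_type = c(thoracic = 0.267, lumbar = 1.099, combination = 1.783),
      vbr          = c(yes = 0.841),
      stages       = c("1" = 0.593, "2" = 1.805, "3" = 2.260, gt3 = 2.122),
      hb           = -0.665
    ),
    intercept = NA_real_
  )
  cfg <- synthetic_config(n = n, seed = seed, marginals = marginals,
                          missingness = missingness, true_model = true_model,
                          target_event_rate = 61 / 252)
  cfg$true_model$intercept <- calibrate_intercept(cfg)
  cfg
}

#' Construct a synthetic-cohort configuration
#'
#' @param n Cohort size (positive integer).
#' @param seed Integer random seed.
#' @param marginals Named list of per-variable distribution specs:
#'   `list(type = "categorical", probs = <named, sums to 1>)`,
#'   `list(type = "binary", prob = p)`, or
#'   `list(type = "continuous", mean =, sd =, lower =, upper =)` (truncated
#'   normal).
#' @param missingness Named numeric vector of per-variable missing-completely-
#'   at-random probabilities in \[0, 1); variables absent from it are never
#'   missing. The outcome may not appear.
#' @param true_model Ground-truth outcome model: `predictors`, per-predictor
#'   `coefficients` (named per non-reference level for categoricals, a single
#'   per-unit slope for continuous), and `intercept` on the log-odds scale.
#' @param target_event_rate Mean event probability used by
#'   [calibrate_intercept()] when the intercept is left `NA`.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n, seed, marginals, missingness = numeric(0),
                             true_model, target_event_rate = NA_real_) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == floor(n))
  schema <- cohort_schema()
  for (nm in names(marginals)) {
    m <- marginals[[nm]]
    if (!nm %in% predictor_names()) stop("marginal for unknown variable: ", nm)
    if (m$type == "categorical") {
      if (abs(sum(m$probs) - 1) > 1e-9) {
        stop(sprintf("probabilities for '%s' sum to %.12f, not 1", nm, sum(m$probs)))
      }
      if (!setequal(names(m$probs), schema[[nm]]$levels)) {
        stop("category probabilities for '", nm, "' must cover the schema levels")
      }
    } else if (m$type == "binary") {
      stopifnot(m$prob >= 0, m$prob <= 1)
    } else if (m$type == "continuous") {
      if (!(m$lower < m$upper)) stop("clip range for '", nm, "' must satisfy lower < upper")
      stopifnot(m$sd > 0)
    } else stop("unknown marginal type for '", nm, "'")
  }
  if ("transfused" %in% names(missingness)) stop("the outcome may not be missing")
  if (length(missingness) > 0 &&
      (any(missingness < 0) || any(missingness >= 1))) {
    stop("missingness probabilities must lie in [0, 1)")
  }
  missing_marg <- setdiff(predictor_names(), names(marginals))
  if (length(missing_marg) > 0) {
    stop("no marginal given for: ", paste(missing_marg, collapse = ", "))
  }
  stopifnot(all(true_model$predictors %in% predictor_names()))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 marginals = marginals, missingness = missingness,
                 true_model = true_model,
                 target_event_rate = target_event_rate),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> n = %d, seed = %d\n", x$n, x$seed))
  cat("true model:", paste(x$true_model$predictors, collapse = " + "),
      sprintf("(intercept %.4f)\n", x$true_model$intercept))
  invisible(x)
}

# Linear predictor of the ground-truth model (without intercept) for a data
# frame of covariate draws.
true_linear_predictor <- function(covariates, true_model) {
  lp <- rep(0, nrow(covariates))
  for (pred in true_model$predictors) {
    coefs <- true_model$coefficients[[pred]]
    v <- covariates[[pred]]
    if (is.numeric(v)) {
      lp <- lp + coefs * v
    } else {
      if (is.logical(v)) v <- ifelse(v, "yes", "no")
      v <- as.character(v)
      contrib <- coefs[v]
      contrib[is.na(contrib)] <- 0  # reference level
      lp <- lp + unname(contrib)
    }
  }
  lp
}

#' Calibrate the ground-truth intercept to a target event rate
#'
#' Solves for the intercept of the ground-truth logistic model so that the
#' mean simulated event probability under the configured covariate marginals
#' equals the target event rate. A fixed-seed Monte-Carlo sample of linear
#' predictors makes the solution deterministic.
#'
#' @param config A `synthetic_config` with `target_event_rate` set.
#' @param n_mc Monte-Carlo sample size for the marginal expectation.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config, n_mc = 200000L) {
  stopifnot(inherits(config, "synthetic_config"),
            is.finite(config$target_event_rate))
  lp <- with_local_seed(90210L, {
    covs <- draw_covariates(config, n_mc)
    true_linear_predictor(covs, config$true_model)
  })
  f <- function(b0) mean(expit(b0 + lp)) - config$target_event_rate
  stats::uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
}

# Draw n covariate vectors (no missingness, no outcome) per the marginals.
draw_covariates <- function(config, n) {
  schema <- cohort_schema()
  out <- data.frame(row.names = seq_len(n))
  for (nm in predictor_names()) {
    m <- config$marginals[[nm]]
    out[[nm]] <- switch(
      m$type,
      categorical = factor(
        sample(names(m$probs), n, replace = TRUE, prob = m$probs),
        levels = schema[[nm]]$levels),
      binary = stats::runif(n) < m$prob,
      continuous = rtruncnorm(n, m$mean, m$sd, m$lower, m$upper)
    )
  }
  out
}

# Truncated normal by rejection (no boundary atoms). The published clip
# ranges are wide relative to the SDs, so acceptance rates are high.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation bounds reject nearly all draws")
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws covariates independently from the configured marginals, draws the
#' binary transfusion outcome from the ground-truth logistic model (computed
#' on the fully observed covariates, before any missingness), then applies
#' missing-completely-at-random masking per field. Reproducible given the
#' config seed.
#'
#' @param config A `synthetic_config`.
#' @param n Optional override of `config$n`.
#' @return A [cohort()].
#' @export
generate_cohort <- function(config, n = config$n) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.finite(config$true_model$intercept)) {
    stop("true model intercept is not set; run calibrate_intercept()")
  }
  determined <- config$true_model$predictors
  fully_missing <- names(config$missingness)[config$missingness >= 1]
  if (length(intersect(determined, fully_missing)) > 0) {
    stop("an outcome-determining covariate would be entirely missing")
  }
  with_local_seed(config$seed, {
    covs <- draw_covariates(config, n)
    lp <- config$true_model$intercept + true_linear_predictor(covs, config$true_model)
    covs$transfused <- stats::runif(n) < expit(lp)
    for (nm in names(config$missingness)) {
      p <- config$missingness[[nm]]
      if (p > 0) covs[[nm]][stats::runif(n) < p] <- NA
    }
    cohort(covs, name = sprintf("synthetic(n=%d, seed=%d)", n, config$seed))
  })
}
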
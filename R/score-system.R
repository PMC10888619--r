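#' Banding specification for a continuous predictor
#'
#' Defines the ordered bands used to convert a continuous predictor into
#' integer risk points: cut points, which side of each cut point the boundary
#' value belongs to, a representative value W per band, and the reference
#' band whose representative value anchors zero points.
#'
#' @param variable Predictor name.
#' @param breaks Increasing numeric cut points (length b-1 for b bands).
#' @param representatives Numeric representative value per band (length b).
#' @param reference_band Index of the zero-point reference band.
#' @param break_in_lower Logical per break: `TRUE` if the boundary value
#'   belongs to the band below it (a closed upper bound), `FALSE` if to the
#'   band above (a closed lower bound).
#' @return A `band_spec`.
#' @export
band_spec <- function(variable, breaks, representatives, reference_band,
                      break_in_lower = rep(FALSE, length(breaks))) {
  stopifnot(is.character(variable), length(breaks) >= 1,
            all(diff(breaks) > 0),
            length(representatives) == length(breaks) + 1,
            all(is.finite(representatives)),
            length(break_in_lower) == length(breaks),
            reference_band >= 1, reference_band <= length(representatives))
  labels <- band_labels(breaks, break_in_lower)
  structure(list(variable = variable, breaks = breaks,
                 representatives = representatives,
                 reference_band = as.integer(reference_band),
                 break_in_lower = break_in_lower, labels = labels),
            class = "band_spec")
}

band_labels <- function(breaks, break_in_lower) {
  b <- length(breaks) + 1
  labels <- character(b)
  for (i in seq_len(b)) {
    if (i == 1) {
      labels[i] <- paste0(if (break_in_lower[1]) "<=" else "<", breaks[1])
    } else if (i == b) {
      labels[i] <- paste0(if (break_in_lower[b - 1]) ">" else ">=",
                          breaks[b - 1])
    } else {
      lo <- breaks[i - 1]; hi <- breaks[i]
      labels[i] <- paste0(if (break_in_lower[i - 1]) "(" else "[", lo, ";", hi,
                          if (break_in_lower[i]) "]" else ")")
    }
  }
  labels
}

#' Assign values to bands
#'
#' @param spec A `band_spec`.
#' @param x Numeric values.
#' @return Integer band indices (1-based).
#' @export
assign_band <- function(spec, x) {
  stopifnot(inherits(spec, "band_spec"))
  idx <- rep(1L, length(x))
  for (i in seq_along(spec$breaks)) {
    idx <- idx + as.integer(x > spec$breaks[i] |
                              (x == spec$breaks[i] & !spec$break_in_lower[i]))
  }
  idx[is.na(x)] <- NA_integer_
  idx
}

#' Default hemoglobin banding
#'
#' The four clinically meaningful hemoglobin categories <8, \[8;12),
#' \[12;16\] and >16 g/dL, with representative values 7.5, 10 and 14 for the
#' three at-risk bands and the >16 band as the zero-point reference with
#' reference value 16 (its boundary). The interior representatives are band
#' midpoints; 7.5 is the midpoint of the lowest observed hemoglobin (7.0)
#' and the band edge.
#'
#' @return A `band_spec` for `hb`.
#' @export
hb_band_spec <- function() {
  band_spec("hb", breaks = c(8, 12, 16),
            representatives = c(7.5, 10, 14, 16),
            reference_band = 4L,
            break_in_lower = c(FALSE, FALSE, TRUE))
}

#' Re-express a fit against lowest-risk reference categories
#'
#' Reparameterizes a fitted logistic model so that, for every categorical
#' term, the category with the smallest coefficient (lowest risk) becomes the
#' zero reference and all other categories carry nonnegative coefficients;
#' the subtracted minima are absorbed into the intercept, leaving every
#' predicted probability unchanged. Continuous terms keep their per-unit
#' slope (their reorientation happens at banding, where the lowest-risk band
#' is the zero-point reference).
#'
#' @param fit A `logistic_fit` whose terms encode `model`'s predictors with
#'   the schema reference levels (as produced by [encode_design()]).
#' @param model Character vector of the fitted predictors.
#' @return A `reoriented_fit`: `intercept`, `terms` (per categorical/logical
#'   predictor a named coefficient vector over all its levels with minimum 0;
#'   per continuous predictor a single slope), and `model`.
#' @export
reorient_to_lowest_risk <- function(fit, model) {
  stopifnot(inherits(fit, "logistic_fit"))
  schema <- cohort_schema()
  intercept <- fit$intercept
  terms <- list()
  for (pred in model) {
    sc <- schema[[pred]]
    if (sc$type == "numeric") {
      terms[[pred]] <- if (pred %in% names(fit$coefficients)) {
        unname(fit$coefficients[[pred]])
      } else 0  # dropped as degenerate during fitting
      next
    }
    levels <- if (sc$type == "logical") c("no", "yes") else sc$levels
    dummy_names <- if (sc$type == "logical") paste0(pred, "_yes")
                   else paste0(pred, "_", levels[-1])
    coefs <- c(0, vapply(dummy_names, function(nm) {
      if (nm %in% names(fit$coefficients)) fit$coefficients[[nm]] else 0
    }, numeric(1)))
    names(coefs) <- levels
    shift <- min(coefs)
    intercept <- intercept + shift
    terms[[pred]] <- coefs - shift
  }
  structure(list(intercept = intercept, terms = terms, model = model),
            class = "reoriented_fit")
}

#' Derive an integer point system from a fitted model
#'
#' Sullivan-style conversion of logistic regression coefficients into integer
#' risk points. The constant B -- the log-odds increment worth one point --
#' is set to the coefficient of a designated binary term (so that term scores
#' exactly one point). Each category of a categorical term scores
#' `round(coefficient / B)`; each band of a banded continuous term scores
#' `round(slope * (W_band - W_ref) / B)` where W are the bands'
#' representative values. Rounding is to the nearest integer, ties away from
#' zero. Reference categories and the reference band score 0, and every
#' point value must be nonnegative (guaranteed by reorientation to
#' lowest-risk references).
#'
#' @param fit A `reoriented_fit`, or a `logistic_fit` (then `model` must
#'   name its predictors and reorientation is applied first).
#' @param b_source Name of the binary predictor whose coefficient defines B.
#' @param bands List of [band_spec()]s, one per continuous predictor in the
#'   model.
#' @param model Predictor names, required when `fit` is a `logistic_fit`.
#' @return A `score_system`: `B`, `points` (per term, a named integer vector
#'   over levels or band labels), `bands`, `max_score`, and the provenance
#'   `fit`.
#' @export
derive_points <- function(fit, b_source, bands = list(), model = NULL) {
  if (inherits(fit, "logistic_fit")) {
    if (is.null(model)) stop("`model` is required with a raw logistic_fit")
    fit <- reorient_to_lowest_risk(fit, model)
  }
  stopifnot(inherits(fit, "reoriented_fit"))
  band_map <- stats::setNames(bands, vapply(bands, `[[`, character(1), "variable"))
  if (!b_source %in% names(fit$terms)) {
    stop("b_source '", b_source, "' is not a fitted term")
  }
  bcoefs <- fit$terms[[b_source]]
  if (length(bcoefs) != 2) {
    stop("b_source must be a binary (single-dummy) term")
  }
  B <- max(bcoefs)
  if (!(B > 0)) stop("b_source coefficient must be positive after reorientation")
  points <- list()
  for (pred in fit$model) {
    coefs <- fit$terms[[pred]]
    if (length(coefs) == 1 && is.null(names(coefs))) {  # continuous
      spec <- band_map[[pred]]
      if (is.null(spec)) stop("no band spec for continuous term '", pred, "'")
      W <- spec$representatives
      W_ref <- W[spec$reference_band]
      pts <- round_half_away(coefs * (W - W_ref) / B)
      if (any(pts < 0)) {
        stop("band points for '", pred, "' are negative; the reference band ",
             "is not the lowest-risk band")
      }
      points[[pred]] <- stats::setNames(as.integer(pts), spec$labels)
    } else {
      pts <- round_half_away(coefs / B)
      points[[pred]] <- stats::setNames(as.integer(pts), names(coefs))
    }
  }
  max_score <- sum(vapply(points, max, integer(1)))
  structure(list(B = B, points = points, bands = band_map,
                 max_score = as.integer(max_score), fit = fit),
            class = "score_system")
}

#' @export
print.score_system <- function(x, ...) {
  cat(sprintf("<score_system> B = %.4g, max score %d\n", x$B, x$max_score))
  for (pred in names(x$points)) {
    cat(" ", pred, ": ",
        paste(sprintf("%s=%d", names(x$points[[pred]]), x$points[[pred]]),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Build the score-to-probability look-up table
#'
#' Under the Sullivan construction, a patient scoring P total points has
#' estimated event probability
#' `expit(intercept + base_offset + B * P)`, where the base offset is the
#' linear-predictor contribution of all zero-point reference values (the
#' reference categories contribute 0 after reorientation; a banded continuous
#' term contributes slope times its reference representative value). The
#' table covers every total score 0..max_score and is strictly increasing.
#'
#' @param system A `score_system` whose provenance fit carries an intercept.
#' @return A `lookup_table`: data frame with `score` and `probability`.
#' @export
build_lookup <- function(system) {
  stopifnot(inherits(system, "score_system"))
  fit <- system$fit
  if (is.null(fit) || is.null(fit$intercept) || !is.finite(fit$intercept)) {
    stop("score system has no fitted intercept; cannot build a look-up table")
  }
  base_offset <- 0
  for (pred in fit$model) {
    coefs <- fit$terms[[pred]]
    if (length(coefs) == 1 && is.null(names(coefs))) {
      spec <- system$bands[[pred]]
      base_offset <- base_offset + coefs * spec$representatives[spec$reference_band]
    }
    # categorical reference levels contribute 0 after reorientation
  }
  scores <- 0:system$max_score
  probs <- expit(fit$intercept + base_offset + system$B * scores)
  structure(data.frame(score = scores, probability = probs),
            class = c("lookup_table", "data.frame"))
}

#' Score a single patient
#'
#' Sums the per-term integer points for one patient record and, when a
#' look-up table is supplied, attaches the estimated transfusion probability.
#'
#' @param record A one-row `cohort`, or a named list/one-row data frame with
#'   the score terms.
#' @param system A `score_system`.
#' @param lookup Optional `lookup_table`.
#' @return List with `total` (integer score), `probability` (`NA` without a
#'   look-up table), and `per_term` (named integer vector).
#' @export
score_patient <- function(record, system, lookup = NULL) {
  stopifnot(inherits(system, "score_system"))
  record <- as.list(as.data.frame(record, stringsAsFactors = FALSE))
  schema <- cohort_schema()
  terms <- names(system$points)
  missing_fields <- terms[vapply(terms, function(t) {
    is.null(record[[t]]) || is.na(record[[t]][1])
  }, logical(1))]
  if (length(missing_fields) > 0) {
    stop("record is missing score term(s): ",
         paste(missing_fields, collapse = ", "))
  }
  per_term <- integer(0)
  for (pred in terms) {
    pts <- system$points[[pred]]
    v <- record[[pred]][1]
    value <- if (!is.null(system$bands[[pred]])) {
      band <- assign_band(system$bands[[pred]], as.numeric(v))
      pts[[band]]
    } else {
      key <- if (is.logical(v)) (if (v) "yes" else "no") else as.character(v)
      if (!key %in% names(pts)) {
        stop(sprintf("value '%s' of '%s' is not a scored category", key, pred))
      }
      pts[[key]]
    }
    per_term[pred] <- value
  }
  total <- sum(per_term)
  probability <- NA_real_
  if (!is.null(lookup)) {
    row <- match(total, lookup$score)
    if (is.na(row)) stop("total score ", total, " outside the look-up table")
    probability <- lookup$probability[row]
  }
  list(total = as.integer(total), probability = probability,
       per_term = per_term)
}

#' Score every record of a cohort
#'
#' Vectorized counterpart of [score_patient()]: total integer scores for all
#' records complete on the score terms.
#'
#' @param x A `cohort` with no missing values on the score terms.
#' @param system A `score_system`.
#' @return Integer vector of total scores, one per record.
#' @export
score_cohort <- function(x, system) {
  stopifnot(inherits(x, "cohort"), inherits(system, "score_system"))
  totals <- rep(0L, nrow(x))
  for (pred in names(system$points)) {
    pts <- system$points[[pred]]
    v <- x[[pred]]
    if (anyNA(v)) {
      stop("cohort has missing values on score term '", pred,
           "'; complete-case filter first")
    }
    contrib <- if (!is.null(system$bands[[pred]])) {
      pts[assign_band(system$bands[[pred]], as.numeric(v))]
    } else {
      key <- if (is.logical(v)) ifelse(v, "yes", "no") else as.character(v)
      if (any(!key %in% names(pts))) {
        stop("unscored category in '", pred, "'")
      }
      pts[key]
    }
    totals <- totals + as.integer(contrib)
  }
  totals
}

#' The published spine-surgery point system and look-up table
#'
#' The printed point system of the published spine-surgery transfusion score
#' (surgery type, vertebral body replacement, stages, banded hemoglobin;
#' B = 0.841) together with its printed score-to-probability look-up table,
#' shipped verbatim as packaged reference data for scoring when the original
#' fitted intercept (never published) is unavailable. Probabilities are
#' proportions (0.3113 for the printed 31.13%).
#'
#' @return List with `system` (a `score_system` without a fitted intercept)
#'   and `lookup` (a `lookup_table`).
#' @export
published_score_fixture <- function() {
  hb <- hb_band_spec()
  points <- list(
    surgery_type = c(cervical = 0L, thoracic = 0L, lumbar = 1L, combination = 2L),
    vbr = c(no = 0L, yes = 1L),
    stages = c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, gt3 = 3L),
    hb = stats::setNames(c(7L, 5L, 2L, 0L), hb$labels)
  )
  system <- structure(list(B = 0.841, points = points,
                           bands = list(hb = hb),
                           max_score = 13L, fit = NULL),
                      class = "score_system")
  lookup <- structure(
    data.frame(score = 0:13,
               probability = c(0.0013, 0.0029, 0.0067, 0.0154, 0.035,
                               0.0776, 0.1632, 0.3113, 0.5116, 0.7082,
                               0.8491, 0.9288, 0.968, 0.9859)),
    class = c("lookup_table", "data.frame"))
  list(system = system, lookup = lookup)
}

#' Serialize a score system (and optional look-up table) to JSON
#'
#' @param system A `score_system`.
#' @param lookup Optional `lookup_table`.
#' @param path Optional output path.
#' @return JSON string (invisibly if written).
#' @export
score_system_to_json <- function(system, lookup = NULL, path = NULL) {
  stopifnot(inherits(system, "score_system"))
  obj <- list(B = system$B, max_score = system$max_score,
              points = lapply(system$points, as.list))
  if (!is.null(lookup)) {
    obj$lookup <- list(score = lookup$score, probability = lookup$probability)
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
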
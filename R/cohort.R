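#' Cohort schema
#'
#' The fixed schema of a surgical transfusion cohort: 18 pre-operative
#' predictors plus the binary transfusion outcome. Categorical variables carry
#' fixed level sets; the first level of each factor is the modelling reference
#' level (male sex, ASA 1, no anticoagulant, 0 prior surgeries, no fracture,
#' no tumor, cervical surgery, dorsal incision, no vertebral body replacement,
#' 0 stages).
#'
#' @return A named list describing each column: `type` is one of
#'   `"factor"`, `"numeric"`, `"logical"`; factors list their `levels`;
#'   `missing_ok` says whether missing values are permitted.
#' @export
cohort_schema <- function() {
  list(
    sex             = list(type = "factor",  levels = c("male", "female"),             missing_ok = FALSE),
    age             = list(type = "numeric", missing_ok = FALSE, min = 0),
    height          = list(type = "numeric", missing_ok = TRUE,  min = 0, strict = TRUE),
    weight          = list(type = "numeric", missing_ok = TRUE,  min = 0, strict = TRUE),
    asa             = list(type = "factor",  levels = c("1", "2", "ge3"),              missing_ok = TRUE),
    anticoagulant   = list(type = "logical", missing_ok = FALSE),
    prior_surgeries = list(type = "factor",  levels = c("0", "1", "2"),                missing_ok = FALSE),
    hb              = list(type = "numeric", missing_ok = FALSE, min = 0, strict = TRUE),
    quick           = list(type = "numeric", missing_ok = TRUE,  min = 0, strict = TRUE),
    inr             = list(type = "numeric", missing_ok = TRUE,  min = 0, strict = TRUE),
    ptt             = list(type = "numeric", missing_ok = TRUE,  min = 0, strict = TRUE),
    thrombocytes    = list(type = "numeric", missing_ok = TRUE,  min = 0, strict = TRUE),
    fracture        = list(type = "logical", missing_ok = FALSE),
    tumor           = list(type = "logical", missing_ok = FALSE),
    surgery_type    = list(type = "factor",  levels = c("cervical", "thoracic", "lumbar", "combination"), missing_ok = FALSE),
    incision        = list(type = "factor",  levels = c("dorsal", "ventral"),          missing_ok = FALSE),
    vbr             = list(type = "logical", missing_ok = TRUE),
    stages          = list(type = "factor",  levels = c("0", "1", "2", "3", "gt3"),    missing_ok = FALSE),
    transfused      = list(type = "logical", missing_ok = FALSE)
  )
}

#' Names of the candidate predictors
#'
#' The 18 pre-operative covariates eligible for model selection (every schema
#' column except the outcome).
#'
#' @return Character vector of length 18.
#' @export
predictor_names <- function() {
  setdiff(names(cohort_schema()), "transfused")
}

#' Construct a cohort
#'
#' Validates a data frame against the cohort schema and returns a classed
#' cohort object. Columns are coerced to their schema types (factors with the
#' fixed level sets, numerics, logicals); extra columns are rejected.
#'
#' @param data A data frame with the 19 schema columns.
#' @param name Optional cohort label.
#' @return A `cohort` object (a data frame with class `"cohort"`).
#' @export
cohort <- function(data, name = "cohort") {
  schema <- cohort_schema()
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(data), names(schema))
  if (length(extra) > 0) {
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  }
  data <- data[names(schema)]
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (col in names(schema)) {
    sc <- schema[[col]]
    x <- data[[col]]
    if (sc$type == "factor") {
      if (is.factor(x)) x <- as.character(x)
      x <- as.character(x)
      bad <- which(!is.na(x) & !(x %in% sc$levels))
      if (length(bad) > 0) {
        stop(sprintf(
          "invalid value(s) for '%s' at row(s) %s: %s (allowed: %s)",
          col, paste(bad, collapse = ", "),
          paste(unique(x[bad]), collapse = ", "),
          paste(sc$levels, collapse = ", ")
        ))
      }
      out[[col]] <- factor(x, levels = sc$levels)
    } else if (sc$type == "numeric") {
      x <- as.numeric(x)
      out[[col]] <- x
    } else {
      if (is.character(x) || is.factor(x)) {
        x <- parse_yesno(as.character(x), col)
      }
      out[[col]] <- as.logical(x)
    }
  }
  structure(out, class = c("cohort", "data.frame"), cohort_name = name,
            validated = TRUE) -> obj
  validate_cohort(obj)
  obj
}

parse_yesno <- function(x, col) {
  lx <- tolower(trimws(x))
  res <- rep(NA, length(x))
  res[lx %in% c("yes", "true", "1")] <- TRUE
  res[lx %in% c("no", "false", "0")] <- FALSE
  bad <- which(!is.na(x) & x != "" & lx != "na" & is.na(res))
  if (length(bad) > 0) {
    stop(sprintf("invalid logical value(s) for '%s' at row(s) %s: %s",
                 col, paste(bad, collapse = ", "),
                 paste(unique(x[bad]), collapse = ", ")))
  }
  res
}

#' Validate a cohort's invariants
#'
#' Checks that every non-missing numeric value is finite and within its schema
#' bounds, that non-missing-able fields have no missing values, and that both
#' outcome classes are present (required by downstream stratified splitting).
#'
#' @param x A `cohort`.
#' @return `x`, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (nrow(x) < 1) stop("cohort must contain at least one record")
  schema <- cohort_schema()
  for (col in names(schema)) {
    sc <- schema[[col]]
    v <- x[[col]]
    if (!isTRUE(sc$missing_ok) && anyNA(v)) {
      stop(sprintf("column '%s' may not contain missing values (rows %s)",
                   col, paste(utils::head(which(is.na(v)), 5), collapse = ", ")))
    }
    if (sc$type == "numeric") {
      obs <- v[!is.na(v)]
      if (any(!is.finite(obs))) stop(sprintf("non-finite values in '%s'", col))
      lo <- sc$min %||% -Inf
      bad <- if (isTRUE(sc$strict)) obs <= lo else obs < lo
      if (any(bad)) {
        stop(sprintf("values in '%s' must be %s %g", col,
                     if (isTRUE(sc$strict)) ">" else ">=", lo))
      }
    }
  }
  n_event <- sum(x$transfused)
  if (n_event < 1 || n_event > nrow(x) - 1) {
    stop("cohort must contain at least one event and one non-event")
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s'> %d records, %d transfused (%.1f%%)\n",
              attr(x, "cohort_name") %||% "cohort", nrow(x),
              sum(x$transfused), 100 * mean(x$transfused)))
  n_miss <- vapply(x, function(col) sum(is.na(col)), integer(1))
  if (any(n_miss > 0)) {
    miss <- n_miss[n_miss > 0]
    cat("missing: ", paste(sprintf("%s=%d", names(miss), miss), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-model complete-case filtering
#'
#' Returns the sub-cohort with no missing values on the given predictors (the
#' outcome is always required non-missing and never is by schema). Record
#' order is preserved. This realizes complete-case analysis applied per
#' candidate model rather than once globally.
#'
#' @param x A `cohort`.
#' @param variables Character vector of predictor names (may be empty).
#' @return The filtered `cohort`.
#' @export
complete_cases <- function(x, variables = character(0)) {
  stopifnot(inherits(x, "cohort"))
  bad <- setdiff(variables, predictor_names())
  if (length(bad) > 0) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  }
  cols <- unique(c(variables, "transfused"))
  keep <- stats::complete.cases(as.data.frame(x)[, cols, drop = FALSE])
  if (!any(keep)) stop("complete-case filtering removed every record")
  out <- x[keep, , drop = FALSE]
  attr(out, "cohort_name") <- attr(x, "cohort_name")
  class(out) <- c("cohort", "data.frame")
  out
}
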
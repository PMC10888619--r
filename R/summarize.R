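#' Descriptive cohort summary
#'
#' Summarizes every schema variable in the layout customary for a baseline
#' characteristics table: continuous variables as mean (SD) and
#' median \[min, max\]; categorical variables as absolute and relative
#' frequencies; missing counts per variable. Optionally stratified by the
#' transfusion outcome in addition to the overall column.
#'
#' @param x A `cohort`.
#' @param group_by_outcome If `TRUE`, adds per-outcome-group summaries next to
#'   the overall column. Requires both outcome classes (guaranteed by the
#'   cohort invariant).
#' @return A data frame of class `"cohort_summary"` in long format with
#'   columns `variable`, `level` (category label, `NA` for continuous
#'   measures), `measure` (`mean`, `sd`, `median`, `min`, `max`, `n`, `pct`,
#'   `n_missing`), `group` (`overall`, and with grouping `no_transfusion` /
#'   `transfusion`), and numeric `value`. Percentages are on the 0--100 scale
#'   and computed over non-missing records of the group.
#' @export
summarize_cohort <- function(x, group_by_outcome = FALSE) {
  validate_cohort(x)
  groups <- list(overall = rep(TRUE, nrow(x)))
  if (isTRUE(group_by_outcome)) {
    groups$no_transfusion <- !x$transfused
    groups$transfusion <- x$transfused
  }
  schema <- cohort_schema()
  rows <- list()
  add <- function(variable, level, measure, group, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, measure = measure,
      group = group, value = as.numeric(value), stringsAsFactors = FALSE
    )
  }
  for (col in names(schema)) {
    sc <- schema[[col]]
    for (g in names(groups)) {
      v <- x[[col]][groups[[g]]]
      if (sc$type == "numeric") {
        obs <- v[!is.na(v)]
        add(col, NA_character_, "mean",   g, mean(obs))
        add(col, NA_character_, "sd",     g, stats::sd(obs))
        add(col, NA_character_, "median", g, stats::median(obs))
        add(col, NA_character_, "min",    g, min(obs))
        add(col, NA_character_, "max",    g, max(obs))
        add(col, NA_character_, "n_missing", g, sum(is.na(v)))
      } else {
        if (sc$type == "logical") {
          v <- factor(ifelse(is.na(v), NA_character_, ifelse(v, "yes", "no")),
                      levels = c("no", "yes"))
        }
        tab <- table(v, useNA = "no")
        n_obs <- sum(tab)
        for (lev in names(tab)) {
          add(col, lev, "n",   g, tab[[lev]])
          add(col, lev, "pct", g, if (n_obs > 0) 100 * tab[[lev]] / n_obs else NA)
        }
        add(col, NA_character_, "n_missing", g, sum(is.na(v)))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Format a cohort summary as text
#'
#' Pretty-prints a [summarize_cohort()] result in the familiar
#' "mean (SD)" / "count (percent)" layout, one block per variable.
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return Character vector of lines, invisibly (also printed).
#' @export
format_summary_text <- function(x, ...) {
  stopifnot(inherits(x, "cohort_summary"))
  groups <- unique(x$group)
  lines <- character(0)
  for (variable in unique(x$variable)) {
    lines <- c(lines, variable)
    sub <- x[x$variable == variable, ]
    if (any(sub$measure == "mean")) {
      for (g in groups) {
        s <- sub[sub$group == g, ]
        val <- function(m) s$value[s$measure == m][1]
        lines <- c(lines, sprintf(
          "  [%s] mean (SD): %.3g (%.3g); median [min, max]: %.3g [%.3g, %.3g]; missing: %d",
          g, val("mean"), val("sd"), val("median"), val("min"), val("max"),
          as.integer(val("n_missing"))))
      }
    } else {
      for (g in groups) {
        s <- sub[sub$group == g, ]
        for (lev in unique(s$level[!is.na(s$level)])) {
          n <- s$value[s$level == lev & s$measure == "n"]
          p <- s$value[s$level == lev & s$measure == "pct"]
          lines <- c(lines, sprintf("  [%s] %s: %d (%.1f%%)", g, lev,
                                    as.integer(n), p))
        }
        nm <- s$value[is.na(s$level) & s$measure == "n_missing"]
        if (nm > 0) lines <- c(lines, sprintf("  [%s] missing: %d", g, as.integer(nm)))
      }
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' Write a cohort summary to CSV
#'
#' @param x A `cohort_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
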
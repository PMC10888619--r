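#' Score distribution and calibration report
#'
#' For every total score observed in the cohort: its relative frequency, the
#' observed transfusion frequency among patients with that score, and the
#' look-up-table estimate. Records that cannot be scored (missing values on a
#' score term) are excluded and counted. This is the tabular counterpart of
#' the usual score-frequency vs. estimated-probability calibration figure.
#'
#' @param x A `cohort`.
#' @param system A `score_system`.
#' @param lookup A `lookup_table` for the estimated probabilities.
#' @return A `score_distribution`: data frame with `score`, `n`,
#'   `rel_frequency`, `observed_rate`, `estimated_probability`; attributes
#'   `n_scored` and `n_dropped`.
#' @export
score_distribution <- function(x, system, lookup) {
  stopifnot(inherits(x, "cohort"), inherits(system, "score_system"))
  terms <- names(system$points)
  df <- as.data.frame(x)
  scoreable <- stats::complete.cases(df[, terms, drop = FALSE])
  if (!any(scoreable)) stop("no record is complete on the score terms")
  sub <- subset_cohort(x, which(scoreable))
  totals <- score_cohort(sub, system)
  n_scored <- length(totals)
  out <- do.call(rbind, lapply(sort(unique(totals)), function(s) {
    in_stratum <- totals == s
    data.frame(
      score = s,
      n = sum(in_stratum),
      rel_frequency = mean(in_stratum),
      observed_rate = mean(sub$transfused[in_stratum]),
      estimated_probability = lookup$probability[match(s, lookup$score)]
    )
  }))
  structure(out, class = c("score_distribution", "data.frame"),
            n_scored = n_scored, n_dropped = nrow(x) - n_scored)
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("<score_distribution> %d scored, %d dropped (incomplete)\n",
              attr(x, "n_scored"), attr(x, "n_dropped")))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a score distribution report
#'
#' Bars for the relative score frequencies, a line for the look-up-table
#' probability, and points for the observed per-stratum transfusion rates.
#'
#' @param x A `score_distribution`.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.score_distribution <- function(x, ...) {
  mids <- graphics::barplot(x$rel_frequency, names.arg = x$score,
                            ylim = c(0, 1), col = "darkseagreen3",
                            xlab = "total score", ylab = "proportion", ...)
  graphics::lines(mids, x$estimated_probability, col = "steelblue", lwd = 2)
  graphics::points(mids, x$observed_rate, pch = 19, col = "darkgreen")
  graphics::legend("topleft", bty = "n",
                   legend = c("score frequency", "estimated probability",
                              "observed rate"),
                   fill = c("darkseagreen3", NA, NA),
                   border = c("black", NA, NA),
                   lty = c(NA, 1, NA), pch = c(NA, NA, 19),
                   col = c(NA, "steelblue", "darkgreen"))
  invisible(x)
}

#' Write a reproducibility manifest
#'
#' Emits a JSON manifest capturing everything needed to reproduce a run
#' bit-for-bit: the configuration (seeds, split counts, complete-case mode,
#' any user config), the package version, and the R version.
#'
#' @param config Named list of run parameters (echoed verbatim).
#' @param seeds Named or unnamed vector/list of seeds used.
#' @param path Output path for the JSON manifest.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(config, seeds, path) {
  manifest <- list(
    package = "rbcscore",
    package_version = as.character(utils::packageVersion("rbcscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seeds = seeds,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
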
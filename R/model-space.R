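#' Enumerate the candidate model space
#'
#' Builds the exhaustive set of candidate logistic models: every subset of at
#' most `k_max` predictors from the pool, including the null (empty) model.
#' For a pool of size p this yields sum over k = 0..k_max of choose(p, k)
#' models; with the full 18-predictor pool and `k_max = 4` that is 4048.
#' Ordering is deterministic: by subset size, then lexicographically within a
#' size.
#'
#' @param predictor_pool Character vector of unique predictor names.
#' @param k_max Maximum model size (>= 0, <= pool size).
#' @return A `model_space` object: list with `models` (list of character
#'   vectors, the empty model first), `k_max`, and `predictor_pool`.
#' @export
enumerate_models <- function(predictor_pool = predictor_names(), k_max = 4L) {
  stopifnot(is.character(predictor_pool), length(predictor_pool) >= 1)
  if (anyDuplicated(predictor_pool)) stop("predictor pool contains duplicates")
  bad <- setdiff(predictor_pool, predictor_names())
  if (length(bad) > 0) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  if (k_max < 0) stop("k_max must be >= 0")
  if (k_max > length(predictor_pool)) {
    stop("k_max exceeds the predictor pool size")
  }
  pool_sorted <- sort(predictor_pool)
  models <- list(character(0))
  for (k in seq_len(k_max)) {
    subsets <- utils::combn(pool_sorted, k, simplify = FALSE)
    models <- c(models, subsets)
  }
  structure(list(models = models, k_max = as.integer(k_max),
                 predictor_pool = predictor_pool),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("<model_space> %d models (pool %d, k_max %d)\n",
              length(x$models), length(x$predictor_pool), x$k_max))
  invisible(x)
}

#' @export
length.model_space <- function(x) length(x$models)

#' One-line labels for candidate models
#'
#' @param space A `model_space`.
#' @return Character vector, one label per model; the null model is
#'   `"(null)"`.
#' @export
model_labels <- function(space) {
  vapply(space$models, function(m) {
    if (length(m) == 0) "(null)" else paste(m, collapse = "+")
  }, character(1))
}

#' Export the model space as a text listing
#'
#' Writes one model per line (predictors joined by `+`) for audit logs.
#'
#' @param space A `model_space`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_space <- function(space, path) {
  writeLines(model_labels(space), path)
  invisible(path)
}
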
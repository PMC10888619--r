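#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen event scores higher than a randomly
#' chosen non-event, with tied pairs counted 1/2 (the Mann-Whitney / midrank
#' convention). Computed from midranks in O(n log n).
#'
#' @param scores Numeric score or probability vector.
#' @param labels 0/1 (or logical) outcome vector; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  scores <- as.numeric(scores)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
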
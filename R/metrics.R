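#' Mean squared error between one-hot labels and class probabilities
#'
#' Averages the squared difference over both epochs and classes:
#' `mean((onehot - prob)^2)`.
#'
#' @param labels Integer labels (0-based), length n.
#' @param probs Numeric matrix (n x n_classes) of predicted probabilities.
#' @return A single non-negative number.
#' @export
mse_score <- function(labels, probs) {
  n <- length(labels)
  stopifnot(nrow(probs) == n)
  onehot <- matrix(0, n, ncol(probs))
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  mean((onehot - probs)^2)
}

#' F1 score (binary positive-class or support-weighted multiclass)
#'
#' For two classes, returns the plain F1 of the positive class (label 1):
#' `2 P R / (P + R)`. For more classes, returns the support-weighted mean of
#' the per-class F1 scores. A class absent from both predictions and truth
#' contributes F1 = 0 (flagged via the `per_class` attribute consumers can
#' inspect); degenerate 0/0 precision-recall ratios are scored 0.
#'
#' @param labels True integer labels (0-based).
#' @param pred Predicted integer labels (0-based).
#' @param n_classes Total number of classes (defaults to the range seen).
#' @return The F1 score with attribute `per_class` (per-class F1 vector).
#' @export
f1_score <- function(labels, pred, n_classes = NULL) {
  if (is.null(n_classes)) n_classes <- max(labels, pred) + 1L
  per <- vapply(seq_len(n_classes) - 1L, function(k) {
    tp <- sum(labels == k & pred == k)
    fp <- sum(labels != k & pred == k)
    fn <- sum(labels == k & pred != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  out <- if (n_classes == 2L) {
    per[2L]                                  # positive class
  } else {
    support <- vapply(seq_len(n_classes) - 1L, function(k) sum(labels == k),
                      numeric(1))
    if (sum(support) == 0) 0 else sum(per * support) / sum(support)
  }
  attr(out, "per_class") <- per
  out
}
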
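#' Scored predictions for ROC analysis
#'
#' Pairs numeric classifier scores with binary ground-truth labels. The
#' `role` tag distinguishes training-set predictions (the only legitimate
#' basis for threshold selection) from test-set predictions.
#'
#' @param scores Numeric vector, one score per instance (higher = more
#'   positive).
#' @param labels 0/1 vector of the same length.
#' @param role `"test"` (default) or `"train"`.
#' @return An object of class `scored_predictions`.
#' @export
scored_predictions <- function(scores, labels, role = c("test", "train")) {
  role <- match.arg(role)
  if (length(scores) != length(labels))
    stop_input("'scores' and 'labels' must have the same length")
  if (length(scores) == 0L) stop_input("empty prediction set")
  if (!is.numeric(scores) || anyNA(scores))
    stop_input("'scores' must be numeric with no missing values")
  if (!is_binary01(labels)) stop_input("'labels' must be 0/1")
  structure(list(scores = as.numeric(scores), labels = as.numeric(labels),
                 role = role),
            class = "scored_predictions")
}

#' @export
print.scored_predictions <- function(x, ...) {
  cat(sprintf("Scored predictions (%s set): %d instances, %d positive\n",
              x$role, length(x$scores), sum(x$labels)))
  invisible(x)
}

check_both_classes <- function(sp) {
  if (sum(sp$labels) == 0 || sum(sp$labels) == length(sp$labels))
    stop_input("both classes must be present for ROC/AUC computation")
}

#' Threshold scores into binary labels
#'
#' The decision rule is `score >= t` -> positive (a score exactly at the
#' threshold is classified positive).
#'
#' @param sp A [scored_predictions()] object.
#' @param t Threshold.
#' @return A 0/1 vector.
#' @export
apply_threshold <- function(sp, t) {
  stopifnot(inherits(sp, "scored_predictions"))
  as.numeric(sp$scores >= t)
}

#' Empirical ROC curve
#'
#' Sensitivity (true positive rate) against false positive rate at every
#' distinct score threshold, plus an infinite sentinel so the curve is tied
#' to (0, 0); the smallest score classifies everything positive, giving
#' (1, 1). Both coordinates are non-decreasing along the curve.
#'
#' @param sp A [scored_predictions()] object containing both classes.
#' @return A data frame of class `roc_points` with columns `threshold`,
#'   `fpr`, `tpr`, ordered from (0, 0) to (1, 1).
#' @examples
#' sp <- scored_predictions(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
#' roc_curve(sp)
#' @export
roc_curve <- function(sp) {
  stopifnot(inherits(sp, "scored_predictions"))
  check_both_classes(sp)
  thr <- c(Inf, sort(unique(sp$scores), decreasing = TRUE))
  npos <- sum(sp$labels == 1)
  nneg <- sum(sp$labels == 0)
  pts <- vapply(thr, function(t) {
    pred <- sp$scores >= t
    c(fpr = sum(pred & sp$labels == 0) / nneg,
      tpr = sum(pred & sp$labels == 1) / npos)
  }, c(fpr = 0, tpr = 0))
  out <- data.frame(threshold = thr, fpr = pts["fpr", ], tpr = pts["tpr", ])
  rownames(out) <- NULL
  class(out) <- c("roc_points", "data.frame")
  out
}

#' @export
print.roc_points <- function(x, ...) {
  cat("ROC curve with", nrow(x), "points; AUC =",
      format(auc_trapezoid(x), digits = 4), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Area under the ROC curve, trapezoidal rule
#'
#' @param curve A `roc_points` object from [roc_curve()], or a
#'   [scored_predictions()] object (the curve is computed first).
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc_trapezoid <- function(curve) {
  if (inherits(curve, "scored_predictions")) curve <- roc_curve(curve)
  stopifnot(inherits(curve, "roc_points"))
  x <- curve$fpr; y <- curve$tpr
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Area under the ROC curve, Mann-Whitney form
#'
#' The AUC estimate \eqn{\hat\theta = \frac{1}{mn}\sum_i\sum_j
#' \Psi(Y_{i1}, Y_{j0})} over all m positive x n negative score pairs, with
#' kernel \eqn{\Psi} equal to 1 when the positive scores higher, 1/2 on a
#' tie and 0 otherwise. Equals the trapezoidal area under the tie-merged
#' empirical ROC curve.
#'
#' @param sp A [scored_predictions()] object containing both classes.
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc_mann_whitney <- function(sp) {
  stopifnot(inherits(sp, "scored_predictions"))
  check_both_classes(sp)
  pos <- sp$scores[sp$labels == 1]
  neg <- sp$scores[sp$labels == 0]
  mean(psi_kernel(outer(pos, neg, `-`)))
}

psi_kernel <- function(d) (d > 0) + 0.5 * (d == 0)

#' Select a classification threshold on training predictions
#'
#' Evaluates Youden's index or accuracy at every candidate cut-point
#' (midpoints between consecutive distinct sorted scores, plus sentinels
#' below the minimum and above the maximum score) and returns the threshold
#' maximising the criterion. Ties break toward the smallest threshold.
#' Thresholds must be chosen on training predictions only: tuning the
#' threshold on the test set yields optimistically biased metrics, so
#' test-role input is rejected.
#'
#' @param train A [scored_predictions()] object with `role = "train"`.
#' @param criterion `"youden"` or `"accuracy"`.
#' @return The selected threshold (finite when an interior cut-point wins).
#' @export
select_threshold <- function(train, criterion = c("youden", "accuracy")) {
  stopifnot(inherits(train, "scored_predictions"))
  criterion <- match.arg(criterion)
  if (train$role != "train")
    stop_input("threshold selection requires training-set predictions (role = \"train\")")
  check_both_classes(train)
  s <- sort(unique(train$scores))
  cand <- c(s[1] - 1,
            if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  vals <- vapply(cand, function(t) {
    cm <- confusion_from_labels(train$labels, as.numeric(train$scores >= t))
    r <- catch_undefined(binary_metric(cm, criterion))
    if (is.na(r$value)) -Inf else r$value
  }, 0)
  cand[which.max(vals)]  # which.max takes the first (smallest) maximiser
}

#' Cross-entropy loss, positive-label form
#'
#' \eqn{H(p, q) = -\sum_i p_i \log(q_i)} with natural logarithm: only the
#' positive-label terms contribute. This is the literal single-sum form;
#' see [binary_cross_entropy()] for the full two-term binary loss.
#'
#' @param p 0/1 label vector.
#' @param q Predicted probabilities in (0, 1], same length.
#' @return Non-negative loss; `q = 0` on a positive label raises an error of
#'   class `metricomp_infinite_loss`.
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5))  # -log(0.5)
#' @export
cross_entropy <- function(p, q) {
  if (length(p) != length(q)) stop_input("'p' and 'q' must have the same length")
  if (!is_binary01(p)) stop_input("'p' must be 0/1")
  if (!is.numeric(q) || anyNA(q) || any(q < 0) || any(q > 1))
    stop_input("'q' must be probabilities in [0, 1]")
  if (any(q == 0 & p == 1)) {
    cond <- structure(
      class = c("metricomp_infinite_loss", "metricomp_error", "error", "condition"),
      list(message = "infinite cross-entropy: q_i = 0 for a positive label",
           call = NULL))
    stop(cond)
  }
  pos <- p == 1
  -sum(log(q[pos]))
}

#' Full binary cross-entropy loss
#'
#' The conventional two-term loss
#' \eqn{-\sum_i [p_i \log q_i + (1 - p_i)\log(1 - q_i)]}, provided as a
#' clearly distinguished companion to the single-sum [cross_entropy()].
#'
#' @inheritParams cross_entropy
#' @param q Predicted probabilities in (0, 1), same length as `p`.
#' @return Non-negative loss.
#' @export
binary_cross_entropy <- function(p, q) {
  if (length(p) != length(q)) stop_input("'p' and 'q' must have the same length")
  if (!is_binary01(p)) stop_input("'p' must be 0/1")
  if (!is.numeric(q) || anyNA(q) || any(q <= 0) || any(q >= 1))
    stop_input("'q' must be probabilities strictly inside (0, 1)")
  -sum(p * log(q) + (1 - p) * log(1 - q))
}
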
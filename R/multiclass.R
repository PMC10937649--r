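#' k-class confusion matrix
#'
#' A k x k count matrix with rows indexing the true class and columns the
#' predicted class (the canonical internal orientation). Matrices recorded
#' the other way round can be ingested with `orientation = "pred_rows"`,
#' which transposes on construction.
#'
#' @param counts A k x k matrix of non-negative integer counts, k >= 2.
#' @param class_names Optional character vector of length k.
#' @param orientation `"true_rows"` (default) if rows are the true class,
#'   `"pred_rows"` if rows are the predicted class.
#' @return An object of class `confusion_k` (a matrix with rows = true
#'   class, columns = predicted class).
#' @examples
#' K <- confusion_k(rbind(c(120, 7, 9, 4), c(15, 116, 3, 6),
#'                        c(12, 13, 115, 0), c(2, 96, 4, 38)))
#' cohen_kappa(K)
#' macro_average(K, "precision")
#' @export
confusion_k <- function(counts, class_names = NULL,
                        orientation = c("true_rows", "pred_rows")) {
  orientation <- match.arg(orientation)
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2)
    stop_input("'counts' must be a square matrix with k >= 2")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_input("'counts' must be non-negative integers")
  if (sum(counts) <= 0)
    stop_input("confusion matrix must contain at least one instance")
  if (orientation == "pred_rows") counts <- t(counts)
  if (!is.null(class_names)) {
    if (length(class_names) != nrow(counts))
      stop_input("'class_names' must have one name per class")
    dimnames(counts) <- list(true = class_names, predicted = class_names)
  } else {
    dimnames(counts) <- list(true = rownames(counts),
                             predicted = colnames(counts))
  }
  structure(counts, class = c("confusion_k", "matrix"))
}

#' @export
print.confusion_k <- function(x, ...) {
  cat("Confusion matrix,", nrow(x), "classes (rows = true, cols = predicted), n =",
      sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest binary confusion for a single class
#'
#' Collapses a k-class confusion matrix to the 2 x 2 matrix of class `i`
#' against all other classes: `TP = n_ii`, `FN` = rest of row i,
#' `FP` = rest of column i, `TN` = everything else.
#'
#' @param K A [confusion_k()] object.
#' @param i Class index, 1 <= i <= k.
#' @return A [binary_confusion()].
#' @export
per_class_confusion <- function(K, i) {
  stopifnot(inherits(K, "confusion_k"))
  k <- nrow(K)
  if (length(i) != 1L || is.na(i) || i < 1 || i > k || i != round(i))
    stop_input(sprintf("class index must be an integer in 1..%d", k))
  tp <- K[i, i]
  fn <- sum(K[i, -i])
  fp <- sum(K[-i, i])
  tn <- sum(K) - tp - fn - fp
  binary_confusion(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Macro-averaged metric over the classes of a confusion matrix
#'
#' Computes the metric separately on each class's one-vs-rest binary
#' confusion and returns the unweighted mean of the k values, giving every
#' class equal weight regardless of its size.
#'
#' @param K A [confusion_k()] object.
#' @param metric A metric identifier from [metric_names()].
#' @return The mean of the per-class metric values. If a class's value is
#'   undefined, an error of class `metricomp_undefined_metric` is raised
#'   naming the failing class(es).
#' @export
macro_average <- function(K, metric) {
  vals <- per_class_values(K, metric)
  mean(vals)
}

#' Per-class metric values of a confusion matrix
#'
#' @inheritParams macro_average
#' @return Named numeric vector, one value per class.
#' @export
per_class_values <- function(K, metric) {
  stopifnot(inherits(K, "confusion_k"))
  metric <- match.arg(metric, metric_names())
  k <- nrow(K)
  vals <- numeric(k)
  bad <- character(0)
  nm <- rownames(K)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  for (i in seq_len(k)) {
    r <- catch_undefined(binary_metric(per_class_confusion(K, i), metric))
    vals[i] <- r$value
    if (!is.null(r$undefined)) bad <- c(bad, nm[i])
  }
  if (length(bad))
    stop_undefined(sprintf("metric '%s' undefined for class(es): %s",
                           metric, paste(bad, collapse = ", ")), metric)
  stats::setNames(vals, nm)
}

#' Micro-averaged metric over the classes of a confusion matrix
#'
#' Sums the per-class one-vs-rest counts (TP, TN, FP, FN) over all classes
#' and evaluates the metric once on the pooled counts, giving every
#' instance equal weight. For a square confusion matrix the pooled FP and
#' FN totals are equal, so micro precision, recall and F1 coincide.
#'
#' @inheritParams macro_average
#' @return A single numeric value.
#' @export
micro_average <- function(K, metric) {
  stopifnot(inherits(K, "confusion_k"))
  metric <- match.arg(metric, metric_names())
  k <- nrow(K)
  tot <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_len(k)) {
    cm <- per_class_confusion(K, i)
    tot <- tot + c(cm$tp, cm$tn, cm$fp, cm$fn)
  }
  binary_metric(binary_confusion(tot["tp"], tot["tn"], tot["fp"], tot["fn"]),
                metric)
}

#' @rdname cohen_kappa
#' @export
cohen_kappa.confusion_k <- function(x) {
  n <- sum(x)
  p0 <- sum(diag(x)) / n
  pe <- sum(rowSums(x) * colSums(x)) / n^2
  if (pe == 1) stop_undefined("kappa undefined: expected agreement p_e = 1", "kappa")
  (p0 - pe) / (1 - pe)
}

#' @rdname mcc
#' @export
mcc.confusion_k <- function(x) {
  n <- sum(x)
  rs <- rowSums(x); cs <- colSums(x)
  v1 <- n^2 - sum(rs^2)
  v2 <- n^2 - sum(cs^2)
  if (v1 <= 0 || v2 <= 0)
    stop_undefined("MCC undefined: zero variance in true or predicted marginals", "mcc")
  (n * sum(diag(x)) - sum(rs * cs)) / sqrt(v1 * v2)
}

#' Hamming loss for multi-label predictions
#'
#' Mean elementwise disagreement between the true and predicted n x k
#' binary label matrices: \eqn{\frac{1}{nk}\sum_{i,j}|x_{ij} - y_{ij}|}.
#' 0 is perfect, 1 is complete disagreement.
#'
#' @param truth,predicted Binary (0/1) matrices of identical shape; rows are
#'   instances, columns are labels.
#' @return A value in \eqn{[0, 1]}.
#' @export
hamming_loss <- function(truth, predicted) {
  truth <- as.matrix(truth); predicted <- as.matrix(predicted)
  if (!all(dim(truth) == dim(predicted)))
    stop_input("'truth' and 'predicted' must have identical dimensions")
  if (length(truth) == 0L) stop_input("label matrices must be non-empty")
  if (!is_binary01(c(truth)) || !is_binary01(c(predicted)))
    stop_input("label matrices must contain only 0/1")
  mean(abs(truth - predicted))
}

#' Micro- or macro-averaged metrics for multi-label predictions
#'
#' Each label column is flattened to a one-vs-rest binary confusion; the
#' metric is then pooled over labels (micro) or averaged across the
#' per-label values (macro), reusing the binary metric kernels.
#'
#' @inheritParams hamming_loss
#' @param metric A metric identifier from [metric_names()].
#' @param average `"micro"` or `"macro"`.
#' @return A single numeric value.
#' @export
multilabel_metric <- function(truth, predicted, metric,
                              average = c("micro", "macro")) {
  average <- match.arg(average)
  truth <- as.matrix(truth); predicted <- as.matrix(predicted)
  if (!all(dim(truth) == dim(predicted)))
    stop_input("'truth' and 'predicted' must have identical dimensions")
  metric <- match.arg(metric, metric_names())
  k <- ncol(truth)
  cms <- lapply(seq_len(k), function(j)
    confusion_from_labels(truth[, j], predicted[, j]))
  if (average == "micro") {
    tot <- Reduce(`+`, lapply(cms, function(cm) c(cm$tp, cm$tn, cm$fp, cm$fn)))
    binary_metric(binary_confusion(tot[1], tot[2], tot[3], tot[4]), metric)
  } else {
    vals <- numeric(k); bad <- integer(0)
    for (j in seq_len(k)) {
      r <- catch_undefined(binary_metric(cms[[j]], metric))
      vals[j] <- r$value
      if (!is.null(r$undefined)) bad <- c(bad, j)
    }
    if (length(bad))
      stop_undefined(sprintf("metric '%s' undefined for label(s): %s",
                             metric, paste(bad, collapse = ", ")), metric)
    mean(vals)
  }
}
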
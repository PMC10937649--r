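#' Binary confusion matrix
#'
#' Container for the four counts of a binary prediction set: true positives,
#' true negatives, false positives and false negatives. Positive labels mean
#' presence of the condition of interest (illness, abnormality, foreground).
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return An object of class `binary_confusion`, a list with elements
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' cm <- binary_confusion(tp = 261, tn = 193, fp = 107, fn = 39)
#' binary_metrics(cm)
#' @seealso [confusion_from_labels()], [binary_metrics()], [cohen_kappa()],
#'   [mcc()]
#' @export
binary_confusion <- function(tp, tn, fp, fn) {
  tp <- check_count(tp, "tp"); tn <- check_count(tn, "tn")
  fp <- check_count(fp, "fp"); fn <- check_count(fn, "fn")
  if (tp + tn + fp + fn <= 0)
    stop_input("confusion matrix must contain at least one instance")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "binary_confusion")
}

#' @export
print.binary_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list("true" = c("pos", "neg"),
                              "predicted" = c("pos", "neg")))
  cat("Binary confusion matrix (n =", x$tp + x$tn + x$fp + x$fn, ")\n")
  print(m)
  invisible(x)
}

#' Tally a binary confusion matrix from label vectors
#'
#' @param true_labels,pred_labels Equal-length vectors with entries 0/1
#'   (1 = positive).
#' @return A [binary_confusion()] object.
#' @examples
#' confusion_from_labels(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_from_labels <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop_input("'true_labels' and 'pred_labels' must have the same length")
  if (length(true_labels) == 0L)
    stop_input("label vectors must be non-empty")
  if (!is_binary01(true_labels) || !is_binary01(pred_labels))
    stop_input("labels must be 0/1 with no missing values")
  binary_confusion(tp = sum(true_labels == 1 & pred_labels == 1),
                   tn = sum(true_labels == 0 & pred_labels == 0),
                   fp = sum(true_labels == 0 & pred_labels == 1),
                   fn = sum(true_labels == 1 & pred_labels == 0))
}

# Single-metric kernels on the four counts. Each signals a classed
# "undefined metric" condition on a zero denominator.
.metric_kernels <- list(
  accuracy = function(tp, tn, fp, fn) (tp + tn) / (tp + tn + fp + fn),
  sensitivity = function(tp, tn, fp, fn) {
    if (tp + fn == 0) stop_undefined("sensitivity undefined: no positive instances (tp + fn = 0)", "sensitivity")
    tp / (tp + fn)
  },
  specificity = function(tp, tn, fp, fn) {
    if (tn + fp == 0) stop_undefined("specificity undefined: no negative instances (tn + fp = 0)", "specificity")
    tn / (tn + fp)
  },
  precision = function(tp, tn, fp, fn) {
    if (tp + fp == 0) stop_undefined("precision undefined: no positive predictions (tp + fp = 0)", "precision")
    tp / (tp + fp)
  },
  youden = function(tp, tn, fp, fn) {
    .metric_kernels$sensitivity(tp, tn, fp, fn) +
      .metric_kernels$specificity(tp, tn, fp, fn) - 1
  },
  f1 = function(tp, tn, fp, fn) {
    pre <- .metric_kernels$precision(tp, tn, fp, fn)
    rec <- .metric_kernels$sensitivity(tp, tn, fp, fn)
    if (pre + rec == 0) stop_undefined("f1 undefined: precision + recall = 0", "f1")
    2 * pre * rec / (pre + rec)
  },
  kappa = function(tp, tn, fp, fn) {
    n <- tp + tn + fp + fn
    pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
    if (pe == 1) stop_undefined("kappa undefined: expected agreement p_e = 1", "kappa")
    ((tp + tn) / n - pe) / (1 - pe)
  },
  mcc = function(tp, tn, fp, fn) {
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (denom == 0) stop_undefined("MCC undefined: a marginal sum is zero", "mcc")
    (tn * tp - fn * fp) / sqrt(denom)
  }
)

#' Names of the count-based metrics available for averaging
#'
#' The closed set of metric identifiers accepted by [binary_metric()],
#' [macro_average()] and [micro_average()].
#'
#' @return A character vector.
#' @export
metric_names <- function() names(.metric_kernels)

#' Evaluate one count-based metric on a binary confusion matrix
#'
#' @param cm A [binary_confusion()] object.
#' @param metric One of `metric_names()`: `"accuracy"`, `"sensitivity"`,
#'   `"specificity"`, `"precision"`, `"youden"`, `"f1"`, `"kappa"`, `"mcc"`.
#' @return A single numeric value. A zero denominator raises a condition of
#'   class `metricomp_undefined_metric` rather than returning a conventional
#'   0 or 1.
#' @export
binary_metric <- function(cm, metric) {
  stopifnot(inherits(cm, "binary_confusion"))
  metric <- match.arg(metric, metric_names())
  .metric_kernels[[metric]](cm$tp, cm$tn, cm$fp, cm$fn)
}

#' All ratio metrics of a binary confusion matrix
#'
#' Computes accuracy, sensitivity (recall), specificity, precision,
#' Youden's index (sensitivity + specificity - 1) and the F1 score
#' (harmonic mean of precision and recall).
#'
#' @param cm A [binary_confusion()] object.
#' @return An object of class `binary_metric_report`: a list with the six
#'   metric values. Metrics whose denominator is zero are `NA` and listed in
#'   the `undefined` attribute; a classed warning is raised.
#' @examples
#' binary_metrics(binary_confusion(261, 193, 107, 39))
#' @export
binary_metrics <- function(cm) {
  stopifnot(inherits(cm, "binary_confusion"))
  fields <- c("accuracy", "sensitivity", "specificity", "precision",
              "youden", "f1")
  out <- vector("list", length(fields)); names(out) <- fields
  undef <- character(0)
  for (f in fields) {
    r <- catch_undefined(binary_metric(cm, f))
    out[[f]] <- r$value
    if (!is.null(r$undefined)) undef <- c(undef, stats::setNames(r$undefined, f))
  }
  if (length(undef))
    warn_metricomp(paste0("undefined metrics: ",
                          paste(names(undef), collapse = ", ")),
                   class = "metricomp_undefined_metric_warning")
  structure(out, undefined = if (length(undef)) undef,
            class = "binary_metric_report")
}

#' @export
print.binary_metric_report <- function(x, digits = 3, ...) {
  v <- unlist(x)
  cat("Binary classification metrics:\n")
  print(round(v, digits))
  u <- attr(x, "undefined")
  if (!is.null(u)) cat("undefined:", paste(names(u), collapse = ", "), "\n")
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between predicted and true classes,
#' \eqn{\kappa = (p_0 - p_e)/(1 - p_e)}, where \eqn{p_0} is the observed
#' accuracy and \eqn{p_e} the agreement expected from the marginal class
#' frequencies. For a binary matrix
#' \eqn{p_e = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)]/n^2}; for a k-class matrix
#' \eqn{p_e = \sum_i n_{i\cdot} n_{\cdot i}/n^2}. The k = 2 case of the
#' multi-class form reduces exactly to the binary form.
#'
#' @param x A [binary_confusion()] or [confusion_k()] object.
#' @return Kappa, in \eqn{(-\infty, 1]}.
#' @examples
#' cohen_kappa(binary_confusion(261, 193, 107, 39))
#' @export
cohen_kappa <- function(x) UseMethod("cohen_kappa")

#' @export
cohen_kappa.binary_confusion <- function(x) {
  .metric_kernels$kappa(x$tp, x$tn, x$fp, x$fn)
}

#' Matthews' correlation coefficient
#'
#' Correlation between true and predicted classes. For a binary matrix,
#' \eqn{MCC = (TN \cdot TP - FN \cdot FP)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}};
#' the k-class generalisation is
#' \eqn{(n \sum_i n_{ii} - \sum_i n_{i\cdot} n_{\cdot i}) /
#' \sqrt{(n^2 - \sum_i n_{i\cdot}^2)(n^2 - \sum_i n_{\cdot i}^2)}},
#' which equals the binary form at k = 2.
#'
#' @param x A [binary_confusion()] or [confusion_k()] object.
#' @return MCC in \eqn{[-1, 1]}.
#' @examples
#' mcc(binary_confusion(261, 193, 107, 39))
#' @export
mcc <- function(x) UseMethod("mcc")

#' @export
mcc.binary_confusion <- function(x) {
  .metric_kernels$mcc(x$tp, x$tn, x$fp, x$fn)
}
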
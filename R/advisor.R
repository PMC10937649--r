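# Test-selection advisor. The decision logic is stored as a data-driven
# rule table (one row per rule, matched top to bottom), so the whole rule
# set can be printed, audited, and tested exhaustively. Rules marked
# source = "text" restate explicit written guidance; rules marked
# "inferred" fill gaps the guidance leaves open and are flagged as such in
# the audit listing.

advisor_enums <- list(
  task = c("binary_classification", "multiclass", "multilabel", "regression",
           "segmentation", "detection", "retrieval"),
  n_models = c("2", ">2"),
  evidence = c("single_test_set", "multiple_test_sets"),
  question = c("performance", "variance"),
  normality = c("normal", "non_normal", "unknown")
)

# metric kinds: label metrics need binary labels; score metrics (AUC) need
# the underlying numeric scores; per-instance metrics (Dice per image,
# per-instance errors) yield one paired value per instance even on a
# single test set.
metric_kind <- function(metric) {
  per_class <- c("sensitivity", "specificity")
  per_instance <- c("dice", "iou", "surface_dice", "asd", "hausdorff",
                    "absolute_error", "squared_error", "ap", "dcg")
  pooled <- c("accuracy", "youden", "f1", "kappa", "mcc", "precision",
              "recall", "mae", "mse", "pearson_r", "spearman_r",
              "hamming_loss", "map")
  if (metric %in% per_class) "per_class_counts"
  else if (metric == "auc") "scores"
  else if (metric %in% per_instance) "per_instance"
  else if (metric %in% pooled) "pooled"
  else stop_input(sprintf("unknown metric identifier '%s'", metric))
}

#' The advisor's rule table
#'
#' One row per decision rule, in match order. `source` records whether the
#' rule restates explicit written guidance (`"text"`) or is an inferred
#' placement completing the decision space (`"inferred"`).
#'
#' @return A data frame with columns `rule`, `question`, `evidence`,
#'   `n_models`, `metric_kind`, `normality`, `min_J`, `test`, `rationale`,
#'   `caveats`, `source`. `"*"` entries match any value.
#' @export
advisor_rules <- function() {
  r <- function(rule, question, evidence, n_models, kind, normality, min_J,
                test, rationale, caveats, source) {
    data.frame(rule = rule, question = question, evidence = evidence,
               n_models = n_models, metric_kind = kind, normality = normality,
               min_J = min_J, test = test, rationale = rationale,
               caveats = caveats, source = source, stringsAsFactors = FALSE)
  }
  rbind(
    r("variance-normal", "variance", "*", "2", "*", "normal", 2,
      "variance_f_test",
      "With normally distributed metric values, the F-test compares the two variances directly.",
      "Repeated cross-validation underestimates between-data-set variability; prefer metric values from genuinely different test sets.",
      "text"),
    r("variance-nonnormal", "variance", "*", "2", "*", "non_normal", 2,
      "levene_test",
      "Bounded evaluation metrics are typically skewed; Levene's test (with Bartlett's as an alternative) is robust to non-normality where the F-test is not.",
      "Check the normality assumption with the Shapiro-Wilk test if in doubt.",
      "text"),
    r("variance-unknown", "variance", "*", "2", "*", "unknown", 2,
      "shapiro_wilk",
      "Normality is untested: gate with the Shapiro-Wilk test, then use the F-test if normal and Levene's or Bartlett's test otherwise.",
      "",
      "text"),
    r("mcnemar", "performance", "single_test_set", "2", "per_class_counts", "*", 1,
      "mcnemar_test",
      "Sensitivity or specificity of two classifiers on one test set is compared through the discordant misclassification counts within the relevant class.",
      "Run separately for sensitivity (positives) and specificity (negatives); results depend on the chosen threshold.",
      "text"),
    r("delong", "performance", "single_test_set", "2", "scores", "*", 1,
      "delong_test",
      "AUCs of two classifiers scored on the same instances are compared with the DeLong U-statistic test; it needs the numeric scores, not thresholded labels.",
      "Threshold-free, but a single test set still limits generality; cross-validated AUCs can be compared with the Wilcoxon signed-rank test.",
      "text"),
    r("wilcoxon-per-instance", "performance", "single_test_set", "2", "per_instance", "*", 1,
      "wilcoxon_signed_rank",
      "Per-instance metric values (e.g. Dice per image, per-instance errors) give paired samples from one test set; the Wilcoxon signed-rank test compares their medians without a normality assumption.",
      "",
      "text"),
    r("friedman-per-instance", "performance", "single_test_set", ">2", "per_instance", "*", 1,
      "friedman_test",
      "Per-instance metric values for several models are rank-compared across instances with the Friedman test (Iman-Davenport form recommended).",
      "",
      "inferred"),
    r("wilcoxon", "performance", "multiple_test_sets", "2", "*", "*", 2,
      "wilcoxon_signed_rank",
      "Metric values over several test sets are paired by round; the Wilcoxon signed-rank test is the recommended comparison, being robust where the paired t-test is invalidated by outliers and resampling.",
      "Resampled test sets are not independent, which can understate variance; the paired t-test is not valid here.",
      "text"),
    r("friedman", "performance", "multiple_test_sets", ">2", "*", "*", 5,
      "friedman_test",
      "K models over J data sets call for the Friedman rank test; the Iman-Davenport F statistic is recommended because chi2_F is overly conservative.",
      "Resampled test sets are not independent.",
      "text"),
    r("friedman-small-J", "performance", "multiple_test_sets", ">2", "*", "*", 2,
      "wilcoxon_signed_rank",
      "With few test sets the Friedman chi-squared approximation is unreliable; use a few separate pairwise Wilcoxon signed-rank tests instead.",
      "Multiple pairwise comparisons inflate the type I error.",
      "text")
  )
}

#' Recommend a statistical test for an evaluation scenario
#'
#' Matches the scenario against the [advisor_rules()] table and returns the
#' first applicable rule as a recommendation. Inconsistent or unsupported
#' scenarios are rejected with an explanatory error of class
#' `metricomp_advice_refusal`; notably, comparing accuracy by pooling
#' errors over positive and negative instances of a single test set is
#' refused (compare sensitivity and specificity separately with McNemar's
#' test, or collect metric values over several test sets).
#'
#' @param task Task type, one of `"binary_classification"`, `"multiclass"`,
#'   `"multilabel"`, `"regression"`, `"segmentation"`, `"detection"`,
#'   `"retrieval"`.
#' @param metric Metric identifier (e.g. `"sensitivity"`, `"auc"`,
#'   `"dice"`, `"accuracy"`, `"mse"`).
#' @param n_models `2` or `">2"`.
#' @param evidence `"single_test_set"` (raw predictions of one test set) or
#'   `"multiple_test_sets"` (metric values over J test sets).
#' @param question `"performance"` (is one model better?) or `"variance"`
#'   (does one model vary more?).
#' @param normality For variance questions: `"normal"`, `"non_normal"` or
#'   `"unknown"`.
#' @param J Number of test sets (required when
#'   `evidence = "multiple_test_sets"`).
#' @return An object of class `advice`: list with `test`, `rule`,
#'   `rationale`, `caveats`, `source`.
#' @examples
#' advise("binary_classification", "sensitivity", 2, "single_test_set")
#' advise("segmentation", "dice", 2, "single_test_set")
#' @export
advise <- function(task, metric, n_models = 2,
                   evidence = c("single_test_set", "multiple_test_sets"),
                   question = c("performance", "variance"),
                   normality = c("unknown", "normal", "non_normal"),
                   J = NULL) {
  task <- match.arg(task, advisor_enums$task)
  evidence <- match.arg(evidence)
  question <- match.arg(question)
  normality <- match.arg(normality)
  n_models <- as.character(n_models)
  if (!n_models %in% advisor_enums$n_models)
    stop_input("'n_models' must be 2 or \">2\"")
  kind <- metric_kind(metric)

  refuse <- function(msg) {
    stop(structure(class = c("metricomp_advice_refusal", "metricomp_error",
                             "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  # consistency checks
  if (metric == "auc" && !task %in% c("binary_classification", "multiclass", "multilabel"))
    refuse("AUC applies to classification scores; the scenario task has none")
  if (kind == "per_class_counts" && evidence == "single_test_set" &&
      task != "binary_classification")
    refuse("single-test-set McNemar comparison applies to binary classification")
  if (question == "performance" && evidence == "single_test_set" &&
      kind == "pooled")
    refuse(paste("a pooled metric yields a single value per test set;",
                 "comparing accuracy by counting errors among both positive and",
                 "negative instances is not recommended - compare sensitivity and",
                 "specificity separately (McNemar), compare AUCs (DeLong), or",
                 "collect metric values over multiple test sets"))
  if (evidence == "multiple_test_sets" && (is.null(J) || J < 2))
    refuse("evidence over multiple test sets requires J >= 2")
  if (question == "variance" && n_models != "2")
    refuse("the variance tests provided compare two models; test model pairs")

  rules <- advisor_rules()
  J_eff <- if (is.null(J)) 1 else J
  for (i in seq_len(nrow(rules))) {
    rr <- rules[i, ]
    ok <- (rr$question == "*" || rr$question == question) &&
      (rr$evidence == "*" || rr$evidence == evidence) &&
      (rr$n_models == "*" || rr$n_models == n_models) &&
      (rr$metric_kind == "*" || rr$metric_kind == kind) &&
      (rr$normality == "*" || rr$normality == normality) &&
      J_eff >= rr$min_J
    if (ok) {
      return(structure(list(test = rr$test, rule = rr$rule,
                            rationale = rr$rationale,
                            caveats = if (nzchar(rr$caveats)) rr$caveats else character(0),
                            source = rr$source),
                       class = "advice"))
    }
  }
  refuse("no applicable rule for this scenario")
}

#' @export
print.advice <- function(x, ...) {
  cat("Recommended test:", x$test, sprintf("(rule '%s', %s)\n", x$rule, x$source))
  cat(strwrap(x$rationale, prefix = "  "), sep = "\n")
  if (length(x$caveats))
    cat("Caveat:", strwrap(x$caveats, exdent = 2), sep = "\n  ")
  invisible(x)
}
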
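# Paired model-comparison tests and variance tests. Each returns a
# `metric_test` object (a superset of `htest`, so the standard print method
# applies) carrying the statistic, the reference distribution and its
# degrees of freedom, the two-sided p-value, and which branch (exact or
# asymptotic) produced it.

metric_test_result <- function(statistic, p.value, method, distribution,
                               parameter = NULL, branch = NULL,
                               estimate = NULL, notes = NULL,
                               data.name = "paired samples") {
  p.value <- min(max(p.value, 0), 1)
  structure(
    list(statistic = statistic, parameter = parameter, p.value = p.value,
         estimate = estimate, method = method, data.name = data.name,
         distribution = distribution, branch = branch, notes = notes,
         alternative = "two.sided"),
    class = c("metric_test", "htest"))
}

# two-sided p from a lower-tail and an upper-tail probability
two_sided <- function(lower, upper) min(1, 2 * min(lower, upper))

check_paired <- function(a, b) {
  if (length(a) != length(b)) stop_input("'a' and 'b' must have the same length")
  if (length(a) < 2) stop_input("need at least two pairs")
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b))
    stop_input("'a' and 'b' must be numeric with no missing values")
  a - b
}

#' Paired t-test on metric differences
#'
#' Tests whether the mean of the paired differences is zero, with
#' \eqn{t = \bar d / (s_d / \sqrt n)} on n - 1 degrees of freedom. Note
#' that the t-test is sensitive to outliers and is not valid on metric
#' values produced by resampled (cross-validation) test sets, whose
#' non-independence biases the variance estimate; the Wilcoxon signed-rank
#' test is the usual alternative.
#'
#' @param a,b Equal-length numeric vectors of one evaluation metric for two
#'   models on the same instances or test sets.
#' @return A `metric_test` object.
#' @export
paired_t_test <- function(a, b) {
  d <- check_paired(a, b)
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop_undefined("paired t-test undefined: zero variance of differences", "t")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  p <- two_sided(stats::pt(t_stat, n - 1), stats::pt(t_stat, n - 1, lower.tail = FALSE))
  metric_test_result(c(t = t_stat), p, "Paired t-test", "t",
                     parameter = c(df = n - 1), branch = "asymptotic",
                     estimate = c(`mean difference` = mean(d)))
}

#' Sign test for paired metric values
#'
#' Under the null of no difference each model should win about N/2 of the N
#' comparisons, so the number of positive differences is Binomial(N, 1/2).
#' Ties (zero differences) are dropped and N reduced accordingly. The exact
#' binomial two-sided p-value is always computed; for N >= 20 the normal
#' approximation (mean N/2, sd \eqn{\sqrt N/2}) is reported alongside in
#' `notes`.
#'
#' @inheritParams paired_t_test
#' @return A `metric_test` object; the statistic is the number of positive
#'   differences among the N non-tied pairs.
#' @export
sign_test <- function(a, b) {
  d <- check_paired(a, b)
  d <- d[d != 0]
  if (length(d) == 0) stop_input("all pairs are tied: sign test undefined")
  n <- length(d)
  s <- sum(d > 0)
  p <- two_sided(stats::pbinom(s, n, 0.5),
                 stats::pbinom(s - 1, n, 0.5, lower.tail = FALSE))
  notes <- NULL
  if (n >= 20) {
    z <- (s - n / 2) / (sqrt(n) / 2)
    notes <- sprintf("normal approximation: z = %.4f, p = %.4g", z,
                     two_sided(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  metric_test_result(c(`positive differences` = s), p, "Sign test",
                     "binomial", parameter = c(N = n), branch = "exact",
                     notes = notes)
}

#' Wilcoxon signed-rank test
#'
#' Non-parametric paired test on the median of the differences. Zero
#' differences are discarded; the absolute differences are ranked (average
#' ranks for ties) and \eqn{T = \min(R^+, R^-)}, the smaller of the
#' positive- and negative-difference rank sums. For n <= 25 without ties in
#' the absolute differences the exact null distribution of the rank sum is
#' used; otherwise the normal approximation
#' \eqn{z = (T - n(n+1)/4) / \sqrt{n(n+1)(2n+1)/24}}.
#'
#' @inheritParams paired_t_test
#' @param exact_max Largest n for which the exact branch is used
#'   (default 25).
#' @return A `metric_test` object with statistic T; the asymptotic branch
#'   also reports z in `notes`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  d <- check_paired(a, b)
  d <- d[d != 0]
  if (length(d) == 0)
    stop_input("all differences are zero: Wilcoxon test undefined")
  n <- length(d)
  r <- rank(abs(d))
  r_plus <- sum(r[d > 0]); r_minus <- sum(r[d < 0])
  t_stat <- min(r_plus, r_minus)
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= exact_max && !has_ties) {
    p <- two_sided(stats::psignrank(r_plus, n),
                   stats::psignrank(r_plus - 1, n, lower.tail = FALSE))
    branch <- "exact"; notes <- NULL
  } else {
    z <- (t_stat - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p <- 2 * stats::pnorm(z)  # T = min(R+, R-) <= its null mean, so z <= 0
    branch <- "asymptotic"
    notes <- sprintf("z = %.4f%s", z,
                     if (has_ties) " (ties present: normal approximation used)" else "")
  }
  metric_test_result(c(T = t_stat), p, "Wilcoxon signed-rank test",
                     if (branch == "exact") "signed-rank" else "normal",
                     parameter = c(n = n), branch = branch, notes = notes,
                     estimate = c(`R+` = r_plus, `R-` = r_minus))
}

#' Friedman test for K models over J data sets
#'
#' The metric values are ranked within each data set (row); the best, i.e.
#' highest, value gets rank 1 and ties receive average ranks. With mean
#' ranks \eqn{\bar R_k},
#' \eqn{\chi^2_F = \frac{12J}{K(K+1)}(\sum_k \bar R_k^2 - K(K+1)^2/4)}
#' follows a chi-squared distribution with K - 1 degrees of freedom under
#' the null, and the Iman-Davenport correction
#' \eqn{F_{ID} = (J-1)\chi^2_F / (J(K-1) - \chi^2_F)} follows an
#' F-distribution with (K - 1, (K - 1)(J - 1)) degrees of freedom.
#' \eqn{\chi^2_F} is overly conservative; \eqn{F_{ID}} is the recommended
#' statistic and the default.
#'
#' @param mm A J x K numeric matrix: K models evaluated on J data sets.
#' @param statistic `"iman_davenport"` (default) or `"chi2"`.
#' @return A `metric_test` object; the upper-tail p-value is reported, as
#'   is conventional for these statistics.
#' @export
friedman_test <- function(mm, statistic = c("iman_davenport", "chi2")) {
  statistic <- match.arg(statistic)
  mm <- as.matrix(mm)
  if (nrow(mm) < 2 || ncol(mm) < 2)
    stop_input("need at least 2 data sets (rows) and 2 models (columns)")
  if (anyNA(mm)) stop_input("the metric matrix must have no missing cells")
  J <- nrow(mm); K <- ncol(mm)
  ranks <- t(apply(mm, 1, function(row) rank(-row)))  # rank 1 = best
  if (all(apply(mm, 1, function(row) length(unique(row)) == 1)))
    stop_input("degenerate matrix: every row fully tied")
  r_bar <- colMeans(ranks)
  chi2 <- 12 * J / (K * (K + 1)) * (sum(r_bar^2) - K * (K + 1)^2 / 4)
  if (statistic == "chi2") {
    p <- stats::pchisq(chi2, K - 1, lower.tail = FALSE)
    return(metric_test_result(
      c(`chi2_F` = chi2), p, "Friedman rank test", "chi-squared",
      parameter = c(df = K - 1), branch = "asymptotic",
      estimate = stats::setNames(r_bar, paste0("mean rank ", seq_len(K))),
      notes = "chi2_F is overly conservative; the Iman-Davenport F statistic is recommended"))
  }
  den <- J * (K - 1) - chi2
  if (den <= 0)
    stop_undefined("Iman-Davenport statistic undefined: chi2_F = J(K-1)", "F_ID")
  f_id <- (J - 1) * chi2 / den
  p <- stats::pf(f_id, K - 1, (K - 1) * (J - 1), lower.tail = FALSE)
  metric_test_result(
    c(F_ID = f_id), p, "Friedman test (Iman-Davenport)", "F",
    parameter = c(df1 = K - 1, df2 = (K - 1) * (J - 1)), branch = "asymptotic",
    estimate = stats::setNames(r_bar, paste0("mean rank ", seq_len(K))),
    notes = sprintf("chi2_F = %.4f", chi2))
}

#' McNemar's test on discordant misclassification counts
#'
#' Compares the sensitivity (or specificity) of two classifiers on the same
#' test set: `b` is the number of instances misclassified by the first
#' classifier only and `c` by the second only. The continuity-corrected
#' statistic \eqn{(|b - c| - 1)^2 / (b + c)} is referred to the chi-squared
#' distribution with 1 degree of freedom when \eqn{b + c \ge 20}; below
#' that, the exact two-sided binomial p-value
#' \eqn{2 P(X \le \min(b, c))}, X ~ Binomial(b + c, 1/2), capped at 1, is
#' used. The statistic is reported in both branches. Pooling errors over
#' positive and negative instances to compare accuracy is not recommended;
#' count discordants within one class at a time.
#'
#' @param b,c Non-negative discordant counts with b + c >= 1.
#' @param branch `"auto"` (default: chi-squared when b + c >= 20),
#'   `"chi2"`, or `"binomial"` to force a branch.
#' @return A `metric_test` object.
#' @examples
#' mcnemar_test(54, 19)  # statistic (35 - 1)^2 / 73
#' @export
mcnemar_test <- function(b, c, branch = c("auto", "chi2", "binomial")) {
  branch <- match.arg(branch)
  b <- check_count(b, "b"); c <- check_count(c, "c")
  if (b + c < 1) stop_input("b + c must be at least 1")
  stat <- (abs(b - c) - 1)^2 / (b + c)
  use_chi2 <- switch(branch, auto = b + c >= 20, chi2 = TRUE, binomial = FALSE)
  if (use_chi2) {
    p <- stats::pchisq(stat, 1, lower.tail = FALSE)
    metric_test_result(c(`(|b-c|-1)^2/(b+c)` = stat), p, "McNemar's test",
                       "chi-squared", parameter = c(df = 1),
                       branch = "chi2", data.name = sprintf("b = %d, c = %d", b, c))
  } else {
    p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
    metric_test_result(c(`(|b-c|-1)^2/(b+c)` = stat), p, "McNemar's test",
                       "binomial", parameter = c(n = b + c),
                       branch = "binomial", data.name = sprintf("b = %d, c = %d", b, c))
  }
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two classifiers scored on the same instances. Each
#' AUC is the Mann-Whitney estimate \eqn{\hat\theta} (see
#' [auc_mann_whitney()]); variances and the covariance are estimated from
#' the structural components of the U-statistic — for each positive
#' instance the mean kernel value against all negatives (V10), and for each
#' negative the mean against all positives (V01) — giving
#' \eqn{Var(\hat\theta) = S_{10}/m + S_{01}/n} with sample (co)variances of
#' the components. The statistic
#' \eqn{Z_D = (\hat\theta_1 - \hat\theta_2)/\sqrt{Var_1 + Var_2 - 2 Cov}}
#' is standard normal under the null of equal AUCs.
#'
#' @param scores1,scores2 Numeric score vectors of the two classifiers over
#'   the same instances.
#' @param labels 0/1 ground-truth labels.
#' @return A `metric_test` object; `estimate` holds the two AUCs.
#' @export
delong_test <- function(scores1, scores2, labels) {
  if (length(scores1) != length(labels) || length(scores2) != length(labels))
    stop_input("score vectors and labels must have the same length")
  if (!is_binary01(labels)) stop_input("'labels' must be 0/1")
  pos <- labels == 1; neg <- labels == 0
  m <- sum(pos); n <- sum(neg)
  if (m == 0 || n == 0) stop_input("both classes must be present")
  comp <- function(s) {
    psi <- psi_kernel(outer(s[pos], s[neg], `-`))  # m x n kernel matrix
    list(theta = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  c1 <- comp(scores1); c2 <- comp(scores2)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  notes <- NULL
  if (var_diff <= 0) {
    # degenerate covariance structure: defined only when the AUCs agree
    # exactly (then Z_D = 0); identical classifiers or a nonzero AUC
    # difference with zero variance cannot be standardised
    if (identical(as.numeric(scores1), as.numeric(scores2)) ||
        c1$theta != c2$theta)
      stop_undefined("DeLong variance of the AUC difference is zero (e.g. identical classifiers)", "Z_D")
    z <- 0
    notes <- "zero estimated variance of the AUC difference; AUCs coincide exactly"
  } else {
    z <- (c1$theta - c2$theta) / sqrt(var_diff)
  }
  p <- two_sided(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  metric_test_result(c(Z_D = z), p, "DeLong test for two correlated AUCs",
                     "normal", branch = "asymptotic", notes = notes,
                     estimate = c(AUC1 = c1$theta, AUC2 = c2$theta),
                     data.name = sprintf("%d positives, %d negatives", m, n))
}

#' F-test of equality of variances
#'
#' \eqn{F = S_1^2 / S_2^2}, referred to the F-distribution with
#' \eqn{n_1 - 1} and \eqn{n_2 - 1} degrees of freedom; the two-sided
#' p-value is twice the smaller tail. Not recommended for clearly
#' non-normal metric distributions — see [levene_test()] and
#' [bartlett_test()].
#'
#' @param x,y Numeric samples of an evaluation metric for two models.
#' @return A `metric_test` object.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop_input("need at least 2 values per sample")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 || v2 == 0)
    stop_undefined("F-test undefined: zero sample variance", "F")
  f <- v1 / v2
  df1 <- length(x) - 1; df2 <- length(y) - 1
  p <- two_sided(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
  metric_test_result(c(F = f), p, "F-test of equality of variances", "F",
                     parameter = c(df1 = df1, df2 = df2), branch = "asymptotic")
}

#' Bartlett's, Levene's and the Shapiro-Wilk tests
#'
#' Delegation wrappers around the vetted routines
#' [stats::bartlett.test()], [car::leveneTest()] and
#' [stats::shapiro.test()], returned in the package's uniform
#' `metric_test` form. Bartlett's and Levene's tests compare the variances
#' of two or more groups (Levene, here with group-mean centering by
#' default, is robust to non-normality); the Shapiro-Wilk test is the
#' normality gate used when choosing between the variance tests.
#'
#' @param groups A list of numeric vectors (one per group), >= 2 groups.
#' @return A `metric_test` object.
#' @export
bartlett_test <- function(groups) {
  check_groups(groups)
  ht <- stats::bartlett.test(groups)
  metric_test_result(ht$statistic, ht$p.value, ht$method, "chi-squared",
                     parameter = ht$parameter, branch = "asymptotic",
                     data.name = sprintf("%d groups", length(groups)))
}

#' @rdname bartlett_test
#' @param center `"mean"` (default) or `"median"` centering for Levene's
#'   test.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  check_groups(groups)
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  lt <- car::leveneTest(values, g, center = if (center == "mean") base::mean else stats::median)
  metric_test_result(c(F = lt[1, "F value"]), lt[1, "Pr(>F)"],
                     sprintf("Levene's test (%s-centered)", center), "F",
                     parameter = c(df1 = lt[1, "Df"], df2 = lt[2, "Df"]),
                     branch = "asymptotic",
                     data.name = sprintf("%d groups", length(groups)))
}

#' @rdname bartlett_test
#' @param x Numeric sample, n >= 3, for the Shapiro-Wilk normality test.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop_input("Shapiro-Wilk test needs at least 3 observations")
  ht <- stats::shapiro.test(x)
  metric_test_result(ht$statistic, ht$p.value, ht$method, "Shapiro-Wilk W",
                     branch = "exact", data.name = sprintf("n = %d", length(x)))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_input("'groups' must be a list of at least two numeric vectors")
  if (any(lengths(groups) < 2)) stop_input("each group needs at least 2 values")
  if (!all(vapply(groups, is.numeric, TRUE))) stop_input("groups must be numeric")
  invisible(TRUE)
}
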
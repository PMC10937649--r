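test_that("paired t-test matches the textbook formula and the reference routine", {
  r <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(unname(r$statistic), 2 / (1 / sqrt(3)))  # mean 2, sd 1
  expect_equal(round(unname(r$statistic), 3), 3.464)
  expect_equal(unname(r$parameter), 2)

  set.seed(401)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    r <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(unname(r$statistic), unname(ref$statistic))
    expect_equal(r$p.value, ref$p.value)
  }
  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3)),
               class = "metricomp_undefined_metric")  # constant difference
})

test_that("sign test gives exact binomial p-values and drops ties", {
  r <- sign_test(rep(1, 10), rep(0, 10))
  expect_equal(r$p.value, 2 * (1 / 2)^10)
  expect_equal(sign_test(c(rep(1, 5), rep(-1, 5)), rep(0, 10))$p.value, 1)
  # ties are dropped and N reduced
  r2 <- sign_test(c(rep(1, 4), 0, 0), rep(0, 6))
  expect_equal(unname(r2$parameter), 4)
  expect_equal(r2$p.value, 2 * (1 / 2)^4 * 1)  # 2*P(X>=4), X~Bin(4,1/2), capped form
  expect_error(sign_test(c(1, 1), c(1, 1)), class = "metricomp_input_error")

  set.seed(411)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE)
    r <- sign_test(d, rep(0, n))
    expect_equal(r$p.value, enum_sign_p(sum(d > 0), n))
  }
})

test_that("Wilcoxon signed-rank reproduces the printed T and z formulas", {
  r <- wilcoxon_signed_rank(c(1, 2, 3), rep(0, 3))
  expect_equal(unname(r$statistic), 0)
  expect_equal(unname(r$estimate["R+"]), 6)
  expect_equal(unname(r$estimate["R-"]), 0)

  # hand-ranked example: d = (1, -2, 3, -4, 5)
  d <- c(1, -2, 3, -4, 5)
  r <- wilcoxon_signed_rank(d, rep(0, 5))
  expect_equal(unname(r$estimate), c(9, 6))
  expect_equal(unname(r$statistic), 6)
  # the printed z formula at T = 6, n = 5
  z <- (6 - 5 * 6 / 4) / sqrt(5 * 6 * 11 / 24)
  expect_equal(z, -0.4045, tolerance = 1e-4)
  r_asym <- wilcoxon_signed_rank(d, rep(0, 5), exact_max = 0)
  expect_equal(r_asym$p.value, 2 * pnorm(z))

  # swapping the samples swaps the rank sums but not T
  r_sw <- wilcoxon_signed_rank(rep(0, 5), d)
  expect_equal(unname(r_sw$estimate), c(6, 9))
  expect_equal(r_sw$p.value, r$p.value)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)),
               class = "metricomp_input_error")
})

test_that("exact Wilcoxon p-values match brute-force sign enumeration and the reference routine", {
  set.seed(421)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    d <- sample(seq(0.1, 5, by = 0.1), n) * sample(c(-1, 1), n, replace = TRUE)
    r <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(r$branch, "exact")
    expect_equal(r$p.value, enum_signrank_p(d))
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(r$p.value, ref$p.value)
  }
})

test_that("Friedman chi-squared and Iman-Davenport statistics follow the printed formulas", {
  # rows rank the models (1,2,3), (1,2,3), (1,3,2) when highest is best
  m <- rbind(c(3, 2, 1), c(3, 2, 1), c(3, 1, 2))
  rc <- friedman_test(m, "chi2")
  expect_equal(unname(rc$statistic), 14 / 3)
  expect_equal(round(unname(rc$statistic), 3), 4.667)
  rf <- friedman_test(m, "iman_davenport")
  expect_equal(unname(rf$statistic), 7)
  expect_equal(unname(rf$parameter), c(2, 4))

  # identical ranking in every row: chi2_F = J * (K-1) at K = 3 ... = 2J
  for (J in c(4, 9, 17)) {
    mm <- matrix(rep(c(3, 2, 1), each = J), J, 3)
    expect_equal(unname(friedman_test(mm, "chi2")$statistic), 2 * J)
  }

  set.seed(431)
  for (i in 1:10) {
    mm <- matrix(rnorm(8 * 4), 8, 4)
    rc <- friedman_test(mm, "chi2")
    ref <- friedman.test(mm)
    expect_equal(unname(rc$statistic), unname(ref$statistic))
    expect_equal(rc$p.value, ref$p.value)
    # column permutation invariance
    perm <- sample(4)
    expect_equal(friedman_test(mm[, perm])$statistic, friedman_test(mm)$statistic)
  }
  expect_error(friedman_test(matrix(1, 4, 3)), class = "metricomp_input_error")
})

test_that("McNemar's test applies the continuity-corrected statistic and branch rule", {
  r <- mcnemar_test(54, 19)
  expect_equal(unname(r$statistic), (35 - 1)^2 / 73)
  expect_equal(round(unname(r$statistic), 3), 15.836)
  expect_equal(r$branch, "chi2")
  expect_equal(r$p.value, pchisq((34)^2 / 73, 1, lower.tail = FALSE))
  expect_equal(r$p.value, mcnemar.test(matrix(c(5, 54, 19, 5), 2, 2))$p.value)

  expect_equal(unname(mcnemar_test(10, 10)$statistic), 1 / 20)
  expect_equal(mcnemar_test(10, 9)$branch, "binomial")   # b + c = 19
  expect_equal(mcnemar_test(10, 10)$branch, "chi2")      # b + c = 20

  set.seed(441)
  for (i in 1:15) {
    b <- sample(0:9, 1); cc <- sample(0:9, 1)
    if (b + cc == 0) next
    r <- mcnemar_test(b, cc)
    expect_equal(r$p.value, enum_mcnemar_p(b, cc))
  }
  # branch can be forced either way
  expect_equal(mcnemar_test(54, 19, branch = "binomial")$branch, "binomial")
  expect_error(mcnemar_test(0, 0), class = "metricomp_input_error")
})

test_that("DeLong test matches the hand-enumerated example and the reference implementation", {
  s1 <- c(0.9, 0.8, 0.4, 0.3); s2 <- c(0.7, 0.6, 0.5, 0.2)
  labels <- c(1, 0, 1, 0)
  r <- delong_test(s1, s2, labels)
  expect_equal(unname(r$estimate), c(0.75, 0.75))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  expect_error(delong_test(s1, s1, labels), class = "metricomp_undefined_metric")

  skip_if_not_installed("pROC")
  set.seed(451)
  for (i in 1:10) {
    n <- 60
    labels <- rep(c(1, 0), each = n / 2)
    latent <- rnorm(n) + labels
    a <- latent + rnorm(n, 0, 0.8)
    b <- latent + rnorm(n, 0, 0.8)
    r <- delong_test(a, b, labels)
    ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                          pROC::roc(labels, b, quiet = TRUE), method = "delong")
    expect_equal(unname(r$statistic), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("variance F-test and the delegated variance/normality tests behave as documented", {
  x <- rnorm(20)
  expect_equal(unname(variance_f_test(x, x)$statistic), 1)
  expect_equal(variance_f_test(x, x)$p.value, 1)
  r <- variance_f_test(2 * x, x)
  expect_equal(unname(r$statistic), 4)
  ref <- var.test(2 * x, x)
  expect_equal(r$p.value, ref$p.value)
  expect_error(variance_f_test(rep(1, 5), x), class = "metricomp_undefined_metric")

  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  rb <- bartlett_test(g)
  expect_equal(unname(rb$statistic), 0)
  expect_equal(rb$p.value, 1)
  set.seed(461)
  groups <- list(rnorm(15), rnorm(15, 0, 2), rnorm(15))
  expect_equal(bartlett_test(groups)$p.value,
               bartlett.test(groups)$p.value)
  rl <- levene_test(groups)
  expect_true(rl$p.value >= 0 && rl$p.value <= 1)
  ref_lev <- car::leveneTest(unlist(groups),
                             factor(rep(1:3, each = 15)), center = mean)
  expect_equal(unname(rl$statistic), ref_lev[1, "F value"])

  x <- runif(50)
  expect_equal(shapiro_wilk(x)$p.value, shapiro.test(x)$p.value)
  expect_error(shapiro_wilk(c(1, 2)), class = "metricomp_input_error")
})

test_that("Levene's test rejects less often than the F-test on skewed equal-variance data", {
  set.seed(471)
  B <- 300
  rej <- replicate(B, {
    x <- exp(rnorm(25)); y <- exp(rnorm(25))  # heavy right skew, equal variances
    c(f = variance_f_test(x, y)$p.value < 0.05,
      lev = levene_test(list(x, y))$p.value < 0.05)
  })
  expect_lt(mean(rej["lev", ]), mean(rej["f", ]))
  expect_gt(mean(rej["f", ]), 0.05)  # the F-test is anti-conservative here
})

test_that("Shapiro-Wilk has high power against uniform data at n = 200", {
  set.seed(481)
  rej <- mean(replicate(100, shapiro_wilk(runif(200))$p.value < 0.05))
  expect_gt(rej, 0.9)
})

test_that("all tests return p-values in [0, 1] on random inputs", {
  set.seed(491)
  for (i in 1:25) {
    a <- rnorm(10); b <- rnorm(10)
    ps <- c(paired_t_test(a, b)$p.value,
            sign_test(a, b)$p.value,
            wilcoxon_signed_rank(a, b)$p.value,
            friedman_test(matrix(rnorm(12), 4, 3))$p.value,
            mcnemar_test(sample(0:20, 1), sample(1:20, 1))$p.value,
            variance_f_test(a, b)$p.value)
    expect_true(all(ps >= 0 & ps <= 1))
  }
})

test_that("DeLong Z is approximately standard normal under the null", {
  set.seed(501)
  B <- 400
  z <- replicate(B, {
    n <- 80
    labels <- rep(c(1, 0), each = n / 2)
    latent <- rnorm(n) + 0.8 * labels
    unname(delong_test(latent + rnorm(n, 0, 0.6),
                       latent + rnorm(n, 0, 0.6), labels)$statistic)
  })
  expect_lt(abs(mean(z)), 0.15)
  expect_lt(abs(sd(z) - 1), 0.15)
  expect_gt(ks.test(z, pnorm)$p.value, 0.01)
})

test_that("Friedman at K = 2 orders models consistently with the sign test", {
  set.seed(511)
  m <- synth_paired_metrics(J = 12, K = 2, model_effects = c(0.1, 0), seed = 3)
  # a fully dominant model drives chi2_F to its maximum J(K-1), where the
  # Iman-Davenport denominator vanishes; the chi2 form stays defined
  rf <- friedman_test(m, statistic = "chi2")
  # model 1 dominates: its mean rank must be the smaller (better)
  expect_lt(rf$estimate[1], rf$estimate[2])
  rs <- sign_test(m[, 1], m[, 2])
  expect_gt(unname(rs$statistic), 6)  # model 1 wins most rounds
})
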
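test_that("confusion_from_labels partitions instances and matches a brute-force tally", {
  cm <- confusion_from_labels(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 1, fn = 1, fp = 1, tn = 1))
  cm2 <- confusion_from_labels(c(1, 0), c(1, 0))
  expect_equal(cm2$fp + cm2$fn, 0)
  expect_equal(cm2$tp, 1)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    truth <- rbinom(n, 1, 0.5); pred <- rbinom(n, 1, 0.5)
    cm <- confusion_from_labels(truth, pred)
    # direct per-instance enumeration
    tally <- table(factor(truth, 0:1), factor(pred, 0:1))
    expect_equal(cm$tp, unname(tally["1", "1"]))
    expect_equal(cm$tn, unname(tally["0", "0"]))
    expect_equal(cm$fp, unname(tally["0", "1"]))
    expect_equal(cm$fn, unname(tally["1", "0"]))
    expect_equal(cm$tp + cm$fn, sum(truth))
  }
  expect_error(confusion_from_labels(c(1, 0), c(1)), class = "metricomp_input_error")
  expect_error(confusion_from_labels(c(1, 2), c(1, 0)), class = "metricomp_input_error")
})

test_that("binary metrics reproduce the reported U-Net chest X-ray row", {
  cm <- binary_confusion(tp = 261, tn = 193, fp = 107, fn = 39)
  r <- binary_metrics(cm)
  expect_equal(round(r$accuracy, 3), 0.757)
  expect_equal(round(r$sensitivity, 3), 0.870)
  expect_equal(round(r$specificity, 3), 0.643)
  expect_equal(round(r$precision, 3), 0.709)
  expect_equal(round(r$youden, 3), 0.513)
  expect_equal(round(r$f1, 3), 0.781)
})

test_that("binary metrics agree with per-instance recomputation and hit the perfect-classifier limit", {
  perfect <- binary_metrics(binary_confusion(50, 50, 0, 0))
  expect_true(all(unlist(perfect) == 1))

  set.seed(21)
  for (i in 1:25) {
    cm <- rand_binary_confusion()
    lab <- labels_realizing(cm)
    r <- binary_metrics(cm)
    expect_equal(r$accuracy, mean(lab$truth == lab$pred))
    expect_equal(r$sensitivity, mean(lab$pred[lab$truth == 1]))
    expect_equal(r$specificity, 1 - mean(lab$pred[lab$truth == 0]))
    expect_equal(r$precision, mean(lab$truth[lab$pred == 1]))
    vals <- unlist(r)[c("accuracy", "sensitivity", "specificity", "precision", "f1")]
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(r$youden >= -1 && r$youden <= 1)
  }
})

test_that("zero denominators are reported as undefined, not coerced", {
  cm <- binary_confusion(tp = 0, tn = 10, fp = 5, fn = 0)  # no positives
  expect_warning(r <- binary_metrics(cm),
                 class = "metricomp_undefined_metric_warning")
  expect_true(is.na(r$sensitivity))
  expect_true("sensitivity" %in% names(attr(r, "undefined")))
  expect_false(is.na(r$accuracy))
  expect_error(binary_metric(cm, "sensitivity"),
               class = "metricomp_undefined_metric")
  # anti-perfect classifier: perfectly negative correlation
  expect_equal(mcc(binary_confusion(0, 0, 50, 50)), -1)
  expect_error(mcc(binary_confusion(10, 0, 0, 5)),
               class = "metricomp_undefined_metric")
})

test_that("binary kappa matches the reported value and hand-computed p_e", {
  cm <- binary_confusion(261, 193, 107, 39)
  # marginal products: (300*368 + 300*232) / 600^2 = 0.5 exactly
  expect_equal(((261 + 193) / 600 - 0.5) / (1 - 0.5), cohen_kappa(cm))
  expect_equal(round(cohen_kappa(cm), 3), 0.513)
  expect_equal(cohen_kappa(binary_confusion(50, 50, 0, 0)), 1)
  # all predictions positive, all truths positive: p_e = 1
  expect_error(cohen_kappa(binary_confusion(10, 0, 0, 0)),
               class = "metricomp_undefined_metric")
})

test_that("binary MCC matches the reported value and the k=2 multiclass reduction", {
  cm <- binary_confusion(261, 193, 107, 39)
  expect_equal(round(mcc(cm), 3), 0.527)
  set.seed(31)
  for (i in 1:50) {
    cm <- rand_binary_confusion()
    K <- confusion_k(matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2, byrow = TRUE))
    expect_equal(mcc(cm), mcc(K))
    expect_equal(cohen_kappa(cm), cohen_kappa(K))
  }
})

table2 <- function() {
  confusion_k(rbind(c(120, 7, 9, 4), c(15, 116, 3, 6),
                    c(12, 13, 115, 0), c(2, 96, 4, 38)))
}

test_that("per-class one-vs-rest confusions match row/column sums of the 4-class matrix", {
  K <- table2()
  c4 <- per_class_confusion(K, 4)
  expect_equal(unclass(c4)[c("tp", "fn", "fp", "tn")],
               list(tp = 38, fn = 102, fp = 10, tn = 410))
  expect_equal(c4$tp + c4$tn + c4$fp + c4$fn, sum(K))
  c1 <- per_class_confusion(K, 1)
  expect_equal(c1$tp, 120)
  expect_equal(c1$fp, 149 - 120)  # column sum minus diagonal
  D <- confusion_k(diag(c(5, 7, 9)))
  for (i in 1:3) {
    ci <- per_class_confusion(D, i)
    expect_equal(ci$fp + ci$fn, 0)
  }
  expect_error(per_class_confusion(K, 5), class = "metricomp_input_error")
})

test_that("macro and micro averages reproduce the reported 4-class caption values", {
  K <- table2()
  expect_equal(round(macro_average(K, "precision"), 3), 0.744)
  expect_equal(round(micro_average(K, "precision"), 3), 0.695)
  expect_equal(round(macro_average(K, "f1"), 3), 0.677)
  expect_equal(round(micro_average(K, "f1"), 3), 0.695)
  expect_equal(round(macro_average(K, "accuracy"), 3), 0.847)
  expect_equal(round(macro_average(K, "sensitivity"), 3), 0.695)
  expect_equal(round(macro_average(K, "specificity"), 3), 0.898)
  expect_equal(round(macro_average(K, "youden"), 3), 0.593)
})

test_that("micro precision = recall = F1 on any square matrix; micro = macro under balanced classes", {
  set.seed(41)
  for (i in 1:20) {
    K <- rand_confusion_k(sample(2:5, 1))
    mp <- micro_average(K, "precision")
    expect_equal(mp, micro_average(K, "sensitivity"))
    expect_equal(mp, micro_average(K, "f1"))
  }
  # balanced row sums: micro and macro agree for accuracy/sen/spe/youden
  K <- table2()  # all row sums 140
  for (m in c("accuracy", "sensitivity", "specificity", "youden"))
    expect_equal(macro_average(K, m), micro_average(K, m))
})

test_that("multiclass kappa and MCC match the printed matrix and their oracles", {
  K <- table2()
  expect_equal(cohen_kappa(K), (389 / 560 - 0.25) / (1 - 0.25))
  expect_equal(round(mcc(K), 3), 0.616)
  # identity permutation matrix: perfect agreement
  expect_equal(cohen_kappa(confusion_k(diag(c(3, 4, 5)))), 1)
  expect_equal(mcc(confusion_k(diag(c(3, 4, 5)))), 1)

  # MCC equals the Pearson correlation of one-hot codings
  set.seed(51)
  for (i in 1:10) {
    K <- rand_confusion_k(3)
    lab_t <- rep(rep(1:3, 3), c(t(unclass(K))))
    lab_p <- rep(rep(1:3, each = 3), c(t(unclass(K))))
    oh <- function(l) sapply(1:3, function(cl) as.numeric(l == cl))
    # multiclass MCC as correlation between flattened one-hot matrices,
    # computed via the covariance oracle
    X <- oh(lab_t); Y <- oh(lab_p)
    num <- sum(diag(crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE))))
    den <- sqrt(sum(diag(crossprod(scale(X, scale = FALSE)))) *
                sum(diag(crossprod(scale(Y, scale = FALSE)))))
    expect_equal(mcc(K), num / den)
  }
})

test_that("class permutation leaves kappa, MCC and averages unchanged", {
  set.seed(61)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    K <- rand_confusion_k(k)
    p <- sample(k)
    Kp <- confusion_k(unclass(K)[p, p])
    expect_equal(cohen_kappa(K), cohen_kappa(Kp))
    expect_equal(mcc(K), mcc(Kp))
    for (m in c("precision", "f1", "accuracy")) {
      expect_equal(macro_average(K, m), macro_average(Kp, m))
      expect_equal(micro_average(K, m), micro_average(Kp, m))
    }
  }
})

test_that("orientation flag transposes on ingest", {
  M <- rbind(c(10, 3), c(2, 20))
  expect_equal(unclass(confusion_k(M, orientation = "pred_rows")),
               unclass(confusion_k(t(M))))
})

test_that("macro averaging names the failing class when a per-class value is undefined", {
  # class 3 never occurs in truth or prediction beyond structure: make a
  # matrix where class 2 has no positive predictions (fp = tp = 0)
  K <- confusion_k(rbind(c(5, 0, 1), c(0, 0, 4), c(2, 0, 3)),
                   class_names = c("a", "b", "c"))
  err <- tryCatch(macro_average(K, "precision"), condition = function(e) e)
  expect_s3_class(err, "metricomp_undefined_metric")
  expect_match(conditionMessage(err), "b")
})

test_that("Hamming loss and multilabel averaging behave per definition", {
  t1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(hamming_loss(t1, t1), 0)
  expect_equal(hamming_loss(t1, 1 - t1), 1)
  expect_equal(hamming_loss(t1, rbind(c(1, 1), c(0, 1))), 1 / 4)
  expect_error(hamming_loss(t1, rbind(c(1, 1))), class = "metricomp_input_error")

  set.seed(71)
  truth <- matrix(rbinom(60, 1, 0.5), 20, 3)
  pred <- matrix(rbinom(60, 1, 0.5), 20, 3)
  # micro accuracy over flattened per-label confusions = 1 - hamming loss
  expect_equal(multilabel_metric(truth, pred, "accuracy", "micro"),
               1 - hamming_loss(truth, pred))
  # macro = mean of per-label binary values
  per <- vapply(1:3, function(j)
    binary_metric(confusion_from_labels(truth[, j], pred[, j]), "f1"), 0)
  expect_equal(multilabel_metric(truth, pred, "f1", "macro"), mean(per))
})
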
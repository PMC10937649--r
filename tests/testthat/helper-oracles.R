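# Independent brute-force oracles used to freeze expected values.
# Deliberately naive implementations: they enumerate rather than use the
# closed forms the package implements.

# exact two-sided sign-test p by enumerating all 2^n equally likely
# positive/negative patterns
enum_sign_p <- function(s, n) {
  probs <- vapply(0:n, function(k) choose(n, k) / 2^n, 0)
  lower <- sum(probs[0:s + 1])
  upper <- sum(probs[s:n + 1])
  min(1, 2 * min(lower, upper))
}

# exact two-sided signed-rank p by enumerating all sign assignments of the
# ranks 1..n (tie-free case)
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  r_plus_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  r_plus_all <- signs %*% seq_len(n)
  lower <- mean(r_plus_all <= r_plus_obs)
  upper <- mean(r_plus_all >= r_plus_obs)
  min(1, 2 * min(lower, upper))
}

# exact two-sided McNemar binomial p: 2 P(X <= min(b, c)), X ~ Bin(b+c, 1/2)
enum_mcnemar_p <- function(b, c) {
  n <- b + c
  probs <- vapply(0:n, function(k) choose(n, k) / 2^n, 0)
  min(1, 2 * sum(probs[0:min(b, c) + 1]))
}

# random non-degenerate binary confusion (all four marginals positive)
rand_binary_confusion <- function() {
  repeat {
    x <- c(sample(1:30, 1), sample(0:30, 3, replace = TRUE))
    cm <- list(tp = x[1], tn = x[2], fp = x[3], fn = x[4])
    if ((cm$tp + cm$fn) > 0 && (cm$tn + cm$fp) > 0 &&
        (cm$tp + cm$fp) > 0 && (cm$tn + cm$fn) > 0)
      return(binary_confusion(cm$tp, cm$tn, cm$fp, cm$fn))
  }
}

# label vectors realizing a binary confusion's counts
labels_realizing <- function(cm) {
  list(truth = c(rep(1, cm$tp), rep(0, cm$tn), rep(0, cm$fp), rep(1, cm$fn)),
       pred = c(rep(1, cm$tp), rep(0, cm$tn), rep(1, cm$fp), rep(0, cm$fn)))
}

rand_confusion_k <- function(k, max_count = 20) {
  confusion_k(matrix(sample(0:max_count, k * k, replace = TRUE) + diag(k), k, k))
}

# tie-free random scored predictions with both classes
rand_scores <- function(n = 20) {
  repeat {
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) > 0 && sum(labels) < n) break
  }
  scored_predictions(sample(seq_len(10 * n), n) / (10 * n), labels)
}

rand_mask <- function(shape = c(6, 7), p = 0.4) {
  as_mask(array(rbinom(prod(shape), 1, p), shape))
}
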
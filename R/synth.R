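# Seeded synthetic-data generators. Defaults emulate the study conditions
# of the worked examples: a 600-instance balanced binary test set with
# AUC around 0.85, sparse-foreground 128 x 128 tumour masks, and 25-round
# (repeated five-fold) paired metric matrices. The generators produce the
# inputs the paired tests consume, under the null (no model effect) or an
# alternative (shifted separation / model effects).

#' Synthetic paired classifier scores
#'
#' Draws a balanced binary test set and two classifiers' scores from a
#' latent-signal model: each model's raw score is
#' `separation * label + sqrt(correlation) * shared_noise +
#' sqrt(1 - correlation) * own_noise`, mapped to (0, 1) by the logistic
#' function. With `correlation = 1` and equal separations the two models
#' are identical (the null of the DeLong test); `separation = 0` gives an
#' expected AUC of 0.5.
#'
#' @param n Number of instances (half positive); default 600, a balanced
#'   300 + 300 test set.
#' @param separation Class separation per model, length 1 or 2; the default
#'   1.45 gives an AUC near 0.85.
#' @param correlation Correlation of the two models' noise, in \[0, 1\].
#' @param seed Integer seed; output is fully determined by it.
#' @return A list with `model1` and `model2` ([scored_predictions()]
#'   sharing the same labels) and `labels`.
#' @export
synth_scores <- function(n = 600, separation = 1.45, correlation = 0.5,
                         seed = NULL) {
  if (n < 4 || n %% 2 != 0) stop_input("'n' must be an even number >= 4")
  if (correlation < 0 || correlation > 1)
    stop_input("'correlation' must be in [0, 1]")
  separation <- rep(separation, length.out = 2)
  with_seed(seed, {
    labels <- rep(c(1, 0), each = n / 2)
    shared <- stats::rnorm(n)
    raw <- lapply(1:2, function(r) {
      separation[r] * labels + sqrt(correlation) * shared +
        sqrt(1 - correlation) * stats::rnorm(n)
    })
    list(model1 = scored_predictions(stats::plogis(raw[[1]]), labels),
         model2 = scored_predictions(stats::plogis(raw[[2]]), labels),
         labels = labels)
  })
}

#' Synthetic ground-truth and predicted mask pair
#'
#' Places a disk-shaped foreground of the requested fraction at a random
#' position and derives the predicted mask by jittering the disk's centre
#' and radius, emulating a segmentation model's boundary error. With
#' `jitter = 0` the masks are identical (Dice 1); with
#' `placement = "disjoint"` the predicted disk is placed away from the
#' truth, the sparse-foreground regime in which pixel accuracy stays high
#' while Dice is 0.
#'
#' @param shape Grid dimensions, default `c(128, 128)`.
#' @param foreground_fraction Approximate foreground fraction in (0, 1);
#'   default 0.013, a small tumour-like target.
#' @param jitter Standard deviation, in pixels, of the centre displacement
#'   and radius perturbation of the predicted disk.
#' @param placement `"jitter"` (default) or `"disjoint"`.
#' @param seed Integer seed.
#' @return A list with masks `truth` and `pred`.
#' @export
synth_masks <- function(shape = c(128, 128), foreground_fraction = 0.013,
                        jitter = 1.5, placement = c("jitter", "disjoint"),
                        seed = NULL) {
  placement <- match.arg(placement)
  if (foreground_fraction <= 0 || foreground_fraction >= 1)
    stop_input("'foreground_fraction' must be inside (0, 1)")
  if (length(shape) != 2 || any(shape < 8))
    stop_input("'shape' must give a 2D grid of at least 8 x 8")
  radius <- sqrt(foreground_fraction * prod(shape) / pi)
  with_seed(seed, {
    margin <- ceiling(radius) + 2
    ctr_t <- c(stats::runif(1, margin, shape[1] - margin),
               stats::runif(1, margin, shape[2] - margin))
    if (placement == "disjoint") {
      # put the predicted disk in the opposite quadrant, clear of the truth
      ctr_p <- shape + 1 - ctr_t
      if (sqrt(sum((ctr_p - ctr_t)^2)) < 2 * radius + 2)
        ctr_p <- c(margin, margin)
      rad_p <- radius
    } else {
      ctr_p <- ctr_t + stats::rnorm(2, 0, jitter)
      rad_p <- max(1, radius + stats::rnorm(1, 0, jitter / 2))
    }
    disk <- function(ctr, rad) {
      rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
      cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
      as_mask(array(as.numeric((rows - ctr[1])^2 + (cols - ctr[2])^2 <= rad^2),
                    shape))
    }
    truth <- disk(ctr_t, radius)
    pred <- if (placement == "jitter" && jitter == 0) truth else disk(ctr_p, rad_p)
    list(truth = truth, pred = pred)
  })
}

#' Synthetic paired metric matrix
#'
#' Generates the J x K matrix of one evaluation metric for K models over J
#' test rounds as `baseline + dataset_effect_j + model_effect_k + noise`,
#' the additive structure that the Friedman and Wilcoxon tests see in
#' repeated cross-validation. All model effects zero is the null
#' hypothesis used for type-I-error calibration.
#'
#' @param J Number of test rounds (default 25, a repeated five-fold
#'   design's 5 x 5 rounds).
#' @param K Number of models (default 2).
#' @param model_effects Length-K vector of model effects (recycled;
#'   default 0 = null).
#' @param baseline Baseline metric level (default 0.7).
#' @param dataset_sd Standard deviation of the shared per-round effect.
#' @param noise_sd Standard deviation of the independent noise.
#' @param seed Integer seed.
#' @return A J x K numeric matrix (rows = rounds, columns = models).
#' @export
synth_paired_metrics <- function(J = 25, K = 2, model_effects = 0,
                                 baseline = 0.7, dataset_sd = 0.05,
                                 noise_sd = 0.02, seed = NULL) {
  if (J < 2 || K < 2) stop_input("'J' and 'K' must both be at least 2")
  model_effects <- rep(model_effects, length.out = K)
  with_seed(seed, {
    ds <- stats::rnorm(J, 0, dataset_sd)
    m <- baseline + outer(ds, model_effects, `+`) +
      matrix(stats::rnorm(J * K, 0, noise_sd), J, K)
    dimnames(m) <- list(paste0("round", seq_len(J)), paste0("model", seq_len(K)))
    m
  })
}
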
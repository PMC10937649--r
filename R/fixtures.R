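# Embedded worked-example fixtures: the reported confusion matrices,
# discordant-pair counts and pixel tallies for the chest X-ray
# classification and PET tumour segmentation examples. The counts are
# immutable constants; the Fig-2-style mask pair is a synthetic layout that
# realises the reported pixel counts exactly (the metrics depend only on
# the counts, not the geometry).

fixture_names <- c("table1_confusion", "table2_confusion_4x4",
                   "table3_discordant_covid", "table3_discordant_negative",
                   "fig2_mask_counts")

#' Load an embedded worked-example fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{`table1_confusion`}{Binary confusion matrix of a modified U-Net
#'     classifying 300 COVID-19 and 300 negative chest X-rays:
#'     TP = 261, TN = 193, FP = 107, FN = 39.}
#'   \item{`table2_confusion_4x4`}{4-class confusion matrix (negative,
#'     COVID-19, pneumonia, tuberculosis; 140 X-rays per true class,
#'     n = 560).}
#'   \item{`table3_discordant_covid`}{Discordant sensitivity counts among
#'     the COVID-19 X-rays for two classifiers: b = 54, c = 19.}
#'   \item{`table3_discordant_negative`}{Discordant specificity counts
#'     among the negative X-rays: b = 44, c = 24.}
#'   \item{`fig2_mask_counts`}{A ground-truth/predicted 128 x 128 mask pair
#'     whose voxelwise overlap counts are TP = 181, TN = 16156, FP = 17,
#'     FN = 30 (one PET tumour slice). The blob layout is synthetic; only
#'     the counts are faithful.}
#' }
#'
#' @param name One of the fixture names above.
#' @return The typed object: a [binary_confusion()], [confusion_k()], a
#'   list with discordant counts `b` and `c`, or a list of two masks
#'   (`truth`, `pred`).
#' @examples
#' binary_metrics(load_fixture("table1_confusion"))
#' @export
load_fixture <- function(name) {
  name <- match.arg(name, fixture_names)
  switch(name,
    table1_confusion = binary_confusion(tp = 261, tn = 193, fp = 107, fn = 39),
    table2_confusion_4x4 = confusion_k(
      rbind(c(120,   7,   9,  4),
            c( 15, 116,   3,  6),
            c( 12,  13, 115,  0),
            c(  2,  96,   4, 38)),
      class_names = c("negative", "covid19", "pneumonia", "tuberculosis"),
      orientation = "true_rows"),
    table3_discordant_covid = list(b = 54, c = 19, metric = "sensitivity"),
    table3_discordant_negative = list(b = 44, c = 24, metric = "specificity"),
    fig2_mask_counts = fig2_masks()
  )
}

# Synthetic 128x128 mask pair realising counts (tp 181, tn 16156, fp 17,
# fn 30): pixels are ordered by distance from the grid centre, the truth
# takes the nearest 211 (a disk-like blob), the prediction overlaps it on
# 181 of those and adds the next 17 ring pixels.
fig2_masks <- function() {
  d <- c(128L, 128L)
  ctr <- (d + 1) / 2
  coords <- as.matrix(expand.grid(row = seq_len(d[1]), col = seq_len(d[2])))
  dist2 <- (coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2
  ord <- order(dist2, coords[, 1], coords[, 2])
  truth_idx <- ord[1:211]                      # |X| = tp + fn = 211
  pred_idx <- c(ord[31:211], ord[212:228])     # 181 shared + 17 extra
  truth <- array(0, d); truth[coords[truth_idx, , drop = FALSE]] <- 1
  pred <- array(0, d); pred[coords[pred_idx, , drop = FALSE]] <- 1
  list(truth = as_mask(truth), pred = as_mask(pred))
}
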
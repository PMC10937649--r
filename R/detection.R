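# Object-detection matching and mean average precision. Boxes are closed
# real-coordinate rectangles given as data frames with columns
# x_min, y_min, x_max, y_max, class, and (predictions only) confidence;
# area is (x_max - x_min) * (y_max - y_min), no pixel +1 convention.

check_boxes <- function(df, confidence = FALSE, what = "boxes") {
  need <- c("x_min", "y_min", "x_max", "y_max", "class")
  if (confidence) need <- c(need, "confidence")
  df <- as.data.frame(df)
  if (nrow(df) > 0) {
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop_input(sprintf("%s must have columns: %s (missing %s)", what,
                         paste(need, collapse = ", "), paste(miss, collapse = ", ")))
    if (any(df$x_max <= df$x_min) || any(df$y_max <= df$y_min))
      stop_input("degenerate box: x_max must exceed x_min and y_max exceed y_min")
    if (confidence && (any(df$confidence < 0) || any(df$confidence > 1)))
      stop_input("confidences must lie in [0, 1]")
  }
  df
}

#' Intersection over union of two bounding boxes
#'
#' @param a,b Boxes: numeric vectors `c(x_min, y_min, x_max, y_max)` or
#'   one-row data frames with those columns.
#' @return IoU in \eqn{[0, 1]}; 0 for disjoint boxes.
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
box_iou <- function(a, b) {
  a <- box_vec(a); b <- box_vec(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

box_vec <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1, c("x_min", "y_min", "x_max", "y_max")])
  x <- as.numeric(x)
  if (length(x) != 4) stop_input("a box needs exactly x_min, y_min, x_max, y_max")
  if (x[3] <= x[1] || x[4] <= x[2]) stop_input("degenerate box")
  x
}

#' Match predicted boxes to ground-truth boxes
#'
#' Predictions are processed in decreasing confidence order. Each prediction
#' may match one still-unmatched ground-truth box of the same class whose
#' IoU reaches `iou_threshold`; among candidates the highest-IoU box wins
#' (exact ties break toward the earlier-listed ground truth). Every
#' ground-truth box is matched at most once; surplus or unmatchable
#' predictions are false positives and unmatched ground truths are false
#' negatives.
#'
#' @param preds Data frame of predicted boxes
#'   (`x_min,y_min,x_max,y_max,class,confidence`).
#' @param gts Data frame of ground-truth boxes (same columns minus
#'   `confidence`).
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return A list with counts `tp`, `fp`, `fn`, the per-prediction
#'   `designation` (`"TP"`/`"FP"`, in the input row order) and
#'   `matched_gt` (ground-truth row index or `NA`).
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  preds <- check_boxes(preds, confidence = TRUE, what = "predictions")
  gts <- check_boxes(gts, what = "ground truths")
  np <- nrow(preds); ng <- nrow(gts)
  designation <- character(np); matched <- rep(NA_integer_, np)
  gt_taken <- rep(FALSE, ng)
  ord <- if (np) order(-preds$confidence) else integer(0)
  for (p in ord) {
    best <- NA_integer_; best_iou <- -1
    for (g in seq_len(ng)) {
      if (gt_taken[g] || gts$class[g] != preds$class[p]) next
      v <- box_iou(unlist(preds[p, c("x_min", "y_min", "x_max", "y_max")]),
                   unlist(gts[g, c("x_min", "y_min", "x_max", "y_max")]))
      if (v >= iou_threshold && v > best_iou) { best <- g; best_iou <- v }
    }
    if (!is.na(best)) {
      gt_taken[best] <- TRUE
      designation[p] <- "TP"; matched[p] <- best
    } else designation[p] <- "FP"
  }
  list(tp = sum(designation == "TP"), fp = sum(designation == "FP"),
       fn = sum(!gt_taken), designation = designation, matched_gt = matched)
}

#' Precision-recall curve of a detector over confidence cut-offs
#'
#' For each distinct confidence value (descending), predictions at or above
#' the cut-off are kept, matching is re-evaluated, and precision and recall
#' computed from the resulting TP/FP/FN counts.
#'
#' @inheritParams match_detections
#' @return A data frame with columns `confidence`, `precision`, `recall`,
#'   one row per distinct confidence cut-off.
#' @export
detection_pr_curve <- function(preds, gts, iou_threshold = 0.5) {
  preds <- check_boxes(preds, confidence = TRUE, what = "predictions")
  gts <- check_boxes(gts, what = "ground truths")
  if (nrow(gts) == 0) stop_input("no ground-truth boxes")
  cuts <- sort(unique(preds$confidence), decreasing = TRUE)
  rows <- lapply(cuts, function(cc) {
    m <- match_detections(preds[preds$confidence >= cc, , drop = FALSE], gts,
                          iou_threshold)
    data.frame(confidence = cc,
               precision = if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_,
               recall = m$tp / nrow(gts))
  })
  do.call(rbind, rows)
}

#' Average precision from a precision-recall curve
#'
#' Area under the precision-recall curve. The default integrates the
#' precision envelope (every-point interpolation: at each recall level the
#' maximum precision attained at that recall or higher), which removes the
#' sawtooth ambiguity of the raw curve; `method = "trapezoid"` integrates
#' the raw curve instead.
#'
#' @param curve A data frame with `precision` and `recall` columns, as from
#'   [detection_pr_curve()].
#' @param method `"envelope"` (default) or `"trapezoid"`.
#' @return AP in \eqn{[0, 1]}.
#' @export
average_precision_detection <- function(curve,
                                        method = c("envelope", "trapezoid")) {
  method <- match.arg(method)
  curve <- curve[!is.na(curve$precision), , drop = FALSE]
  if (nrow(curve) == 0) return(0)
  o <- order(curve$recall, curve$precision)
  r <- curve$recall[o]; p <- curve$precision[o]
  if (method == "envelope") {
    # running max from the right: envelope precision at recall >= r_i
    env <- rev(cummax(rev(p)))
    r0 <- c(0, r)
    sum(diff(r0) * env)
  } else {
    r0 <- c(0, r); p0 <- c(p[1], p)
    sum(diff(r0) * (p0[-1] + p0[-length(p0)]) / 2)
  }
}

#' Mean average precision over classes
#'
#' `map_at` pools the detections of each class across all scenes, builds the
#' class PR curve at IoU match threshold `tau`, computes its average
#' precision, and averages over classes with at least one ground-truth box
#' (classes without any are excluded with a warning). `map_range` averages
#' `map_at` over a vector of thresholds, by default 0.5 to 0.95 in steps of
#' 0.05 (the mAP@\[0.5:0.95\] convention).
#'
#' @param scenes A list of scenes, each a list with elements `preds` and
#'   `gts` (data frames as in [match_detections()]).
#' @param classes Classes to evaluate; default: all classes with ground
#'   truth.
#' @param tau IoU match threshold.
#' @param taus Vector of IoU thresholds for `map_range`.
#' @param method AP integration method, see
#'   [average_precision_detection()].
#' @return mAP in \eqn{[0, 1]}.
#' @export
map_at <- function(scenes, classes = NULL, tau = 0.5, method = "envelope") {
  all_gt <- do.call(rbind, lapply(scenes, function(s)
    check_boxes(s$gts, what = "ground truths")))
  if (is.null(classes)) classes <- sort(unique(all_gt$class))
  gt_classes <- unique(all_gt$class)
  no_gt <- setdiff(classes, gt_classes)
  if (length(no_gt)) {
    warn_metricomp(paste0("class(es) with no ground truth excluded from mAP: ",
                          paste(no_gt, collapse = ", ")))
    classes <- intersect(classes, gt_classes)
  }
  if (length(classes) == 0) stop_input("no class has ground-truth boxes")
  aps <- vapply(classes, function(cl) {
    curves <- class_pr_pooled(scenes, cl, tau)
    average_precision_detection(curves, method = method)
  }, 0)
  mean(aps)
}

# Pooled PR curve for one class: detections ranked by confidence across all
# scenes, matching done per scene in global confidence order.
class_pr_pooled <- function(scenes, cl, tau) {
  recs <- list()
  total_gt <- 0
  for (si in seq_along(scenes)) {
    p <- check_boxes(scenes[[si]]$preds, confidence = TRUE, what = "predictions")
    g <- check_boxes(scenes[[si]]$gts, what = "ground truths")
    p <- p[p$class == cl, , drop = FALSE]
    g <- g[g$class == cl, , drop = FALSE]
    total_gt <- total_gt + nrow(g)
    if (nrow(p)) {
      m <- match_detections(p, g, tau)
      recs[[length(recs) + 1]] <-
        data.frame(confidence = p$confidence, tp = m$designation == "TP")
    }
  }
  if (!length(recs) || total_gt == 0)
    return(data.frame(confidence = numeric(0), precision = numeric(0),
                      recall = numeric(0)))
  d <- do.call(rbind, recs)
  d <- d[order(-d$confidence), , drop = FALSE]
  ctp <- cumsum(d$tp); cfp <- cumsum(!d$tp)
  data.frame(confidence = d$confidence,
             precision = ctp / (ctp + cfp),
             recall = ctp / total_gt)
}

#' @rdname map_at
#' @export
map_range <- function(scenes, classes = NULL, taus = seq(0.5, 0.95, by = 0.05),
                      method = "envelope") {
  mean(vapply(taus, function(tt) map_at(scenes, classes, tt, method), 0))
}
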
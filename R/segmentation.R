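#' Binary segmentation mask
#'
#' Validates a 2D matrix or 3D array of 0/1 values as a segmentation mask.
#' An optional voxel spacing (scalar for isotropic grids, or one value per
#' axis) is carried along and used by the surface-distance metrics.
#'
#' @param grid A 2D or 3D array with entries 0/1.
#' @param spacing Voxel spacing, default 1 (isotropic unit grid).
#' @return An object of class `mask` (the array, with a `spacing` attribute).
#' @export
as_mask <- function(grid, spacing = 1) {
  if (inherits(grid, "mask")) return(grid)
  grid <- as.array(grid)
  nd <- length(dim(grid))
  if (nd < 2 || nd > 3) stop_input("mask must be a 2D or 3D array")
  if (length(grid) == 0L) stop_input("mask must be non-empty")
  if (anyNA(grid) || !all(grid == 0 | grid == 1))
    stop_input("mask entries must be 0/1")
  if (!length(spacing) %in% c(1L, nd) || any(spacing <= 0))
    stop_input("'spacing' must be positive, scalar or one value per axis")
  structure(grid, spacing = rep(as.numeric(spacing), length.out = nd),
            class = "mask")
}

#' @export
print.mask <- function(x, ...) {
  cat(sprintf("Binary mask %s, %d foreground of %d voxels\n",
              paste(dim(x), collapse = "x"), sum(x), length(x)))
  invisible(x)
}

#' Voxelwise confusion counts of two masks
#'
#' @param truth Ground-truth [as_mask()] mask.
#' @param pred Predicted mask of identical shape.
#' @return A [binary_confusion()] of the per-voxel TP/TN/FP/FN tallies.
#' @export
overlap_counts <- function(truth, pred) {
  truth <- as_mask(truth); pred <- as_mask(pred)
  if (!identical(dim(truth), dim(pred)))
    stop_input("masks must have identical shapes")
  binary_confusion(tp = sum(truth == 1 & pred == 1),
                   tn = sum(truth == 0 & pred == 0),
                   fp = sum(truth == 0 & pred == 1),
                   fn = sum(truth == 1 & pred == 0))
}

#' Dice similarity coefficient
#'
#' \eqn{D = 2|X \cap Y| / (|X| + |Y|)}, equivalently
#' \eqn{2TP / (2TP + FP + FN)} in confusion counts. Ignores the true
#' negatives, which makes it robust to the extreme background/foreground
#' imbalance typical of tumour segmentation.
#'
#' @param a Ground-truth mask, or a [binary_confusion()] of voxel counts
#'   (then `b` is omitted).
#' @param b Predicted mask.
#' @return Dice in \eqn{[0, 1]}; undefined (error) when both masks are empty.
#' @export
dice <- function(a, b = NULL) {
  cm <- counts_or_masks(a, b)
  den <- 2 * cm$tp + cm$fp + cm$fn
  if (den == 0) stop_undefined("Dice undefined: both masks are empty", "dice")
  2 * cm$tp / den
}

#' Intersection over union (Jaccard index)
#'
#' \eqn{IoU = |X \cap Y| / |X \cup Y| = TP / (TP + FP + FN)}. Related to
#' Dice by \eqn{IoU = D / (2 - D)}.
#'
#' @inheritParams dice
#' @return IoU in \eqn{[0, 1]}.
#' @export
iou <- function(a, b = NULL) {
  cm <- counts_or_masks(a, b)
  den <- cm$tp + cm$fp + cm$fn
  if (den == 0) stop_undefined("IoU undefined: both masks are empty", "iou")
  cm$tp / den
}

#' Symmetric volume difference and volumetric overlap error
#'
#' The error complements `SVD = 1 - Dice` and `VOE = 1 - IoU`.
#'
#' @inheritParams dice
#' @return A value in \eqn{[0, 1]}; smaller is better.
#' @export
svd_error <- function(a, b = NULL) 1 - dice(a, b)

#' @rdname svd_error
#' @export
voe_error <- function(a, b = NULL) 1 - iou(a, b)

counts_or_masks <- function(a, b) {
  if (inherits(a, "binary_confusion")) {
    if (!is.null(b)) stop_input("supply either a confusion object or two masks")
    a
  } else {
    if (is.null(b)) stop_input("two masks required")
    overlap_counts(a, b)
  }
}

neighbour_offsets <- function(nd, connectivity) {
  if (nd == 2) {
    if (!connectivity %in% c(4, 8))
      stop_input("2D connectivity must be 4 or 8")
  } else {
    if (!connectivity %in% c(6, 18, 26))
      stop_input("3D connectivity must be 6, 18 or 26")
  }
  g <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "4" = , "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "8" = , "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

default_connectivity <- function(nd) if (nd == 2) 8 else 26

#' Extract the surface voxels of a mask
#'
#' The surface of a mask is the set of its foreground voxels with at least
#' one neighbour (18- or 26-neighbourhood in 3D, 4- or 8-neighbourhood in
#' 2D) outside the mask; the grid boundary counts as outside.
#'
#' @param m A mask.
#' @param connectivity Neighbourhood definition: 4 or 8 for 2D masks
#'   (default 8), 6, 18 or 26 for 3D masks (default 26).
#' @return An object of class `surface_set`: a list with the voxel
#'   coordinate matrix `coords` (one row per surface voxel), the
#'   `connectivity` used, the grid `dim` and the voxel `spacing`.
#' @export
surface_extract <- function(m, connectivity = NULL) {
  m <- as_mask(m)
  nd <- length(dim(m))
  if (is.null(connectivity)) connectivity <- default_connectivity(nd)
  offs <- neighbour_offsets(nd, connectivity)
  d <- dim(m)
  pad <- array(0, d + 2)
  inner <- lapply(d, function(k) seq_len(k) + 1L)
  if (nd == 2) pad[inner[[1]], inner[[2]]] <- m
  else pad[inner[[1]], inner[[2]], inner[[3]]] <- m
  # a voxel is interior iff every neighbour is foreground
  interior <- array(TRUE, d)
  for (r in seq_len(nrow(offs))) {
    idx <- lapply(seq_len(nd), function(ax) seq_len(d[ax]) + 1L + offs[r, ax])
    shifted <- if (nd == 2) pad[idx[[1]], idx[[2]], drop = FALSE]
               else pad[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    interior <- interior & (shifted == 1)
  }
  surf <- (m == 1) & !interior
  coords <- which(surf, arr.ind = TRUE)
  colnames(coords) <- NULL
  structure(list(coords = coords, connectivity = connectivity,
                 dim = d, spacing = attr(m, "spacing")),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("Surface set: %d voxels (connectivity %d, grid %s)\n",
              nrow(x$coords), x$connectivity, paste(x$dim, collapse = "x")))
  invisible(x)
}

surface_coords_scaled <- function(s) {
  sweep(s$coords, 2, s$spacing, `*`)
}

# For each row of A, the minimum Euclidean distance to any row of B.
min_dists <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop_undefined("surface distance undefined: empty surface", "surface")
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

as_surface <- function(x, connectivity) {
  if (inherits(x, "surface_set")) x else surface_extract(x, connectivity)
}

#' Surface Dice similarity coefficient
#'
#' The Dice coefficient of the two surface voxel sets: the masks are
#' replaced by their surfaces and the voxel-set Dice formula applied.
#'
#' @param a,b Masks of identical shape (or `surface_set` objects).
#' @param connectivity Passed to [surface_extract()].
#' @return SDSC in \eqn{[0, 1]}.
#' @export
surface_dice <- function(a, b, connectivity = NULL) {
  sa <- as_surface(a, connectivity); sb <- as_surface(b, connectivity)
  na <- nrow(sa$coords); nb <- nrow(sb$coords)
  if (na + nb == 0)
    stop_undefined("surface Dice undefined: both surfaces empty", "surface_dice")
  ka <- apply(sa$coords, 1, paste, collapse = ",")
  kb <- apply(sb$coords, 1, paste, collapse = ",")
  2 * sum(ka %in% kb) / (na + nb)
}

#' Average symmetric surface distance
#'
#' \eqn{ASD = (\sum_{x \in \partial X} d(x, \partial Y) +
#' \sum_{y \in \partial Y} d(y, \partial X)) / (|\partial X| + |\partial Y|)}
#' with Euclidean point-to-set distances. The denominator counts surface
#' voxels, matching the terms of the sums; `literal_denominator = TRUE`
#' divides by the full mask volumes \eqn{|X| + |Y|} instead.
#'
#' @param a,b Masks of identical shape.
#' @param connectivity Passed to [surface_extract()].
#' @param literal_denominator Use \eqn{|X| + |Y|} as the denominator.
#' @return A non-negative distance (0 for identical masks).
#' @export
asd <- function(a, b, connectivity = NULL, literal_denominator = FALSE) {
  a <- as_mask(a); b <- as_mask(b)
  sa <- surface_extract(a, connectivity); sb <- surface_extract(b, connectivity)
  A <- surface_coords_scaled(sa); B <- surface_coords_scaled(sb)
  total <- sum(min_dists(A, B)) + sum(min_dists(B, A))
  den <- if (literal_denominator) sum(a) + sum(b)
         else nrow(A) + nrow(B)
  total / den
}

#' Hausdorff distance between mask surfaces
#'
#' The directed Hausdorff distance is \eqn{hd(X, Y) = \max_{x \in \partial X}
#' d(x, \partial Y)}; the symmetric version (maximum symmetric surface
#' distance) is the larger of the two directed values.
#'
#' @inheritParams asd
#' @param symmetric If `TRUE` (default) return
#'   \eqn{HD = \max\{hd(a, b), hd(b, a)\}}; otherwise the directed
#'   \eqn{hd(a, b)}.
#' @return A non-negative distance.
#' @export
hausdorff <- function(a, b, connectivity = NULL, symmetric = TRUE) {
  sa <- as_surface(a, connectivity); sb <- as_surface(b, connectivity)
  A <- surface_coords_scaled(sa); B <- surface_coords_scaled(sb)
  h_ab <- max(min_dists(A, B))
  if (!symmetric) return(h_ab)
  max(h_ab, max(min_dists(B, A)))
}

#' Structural similarity index of two images
#'
#' \eqn{SSIM(u, v) = \frac{2\bar u \bar v + c_1}{\bar u^2 + \bar v^2 + c_1}
#' \cdot \frac{2 s_{uv} + c_2}{s_u^2 + s_v^2 + c_2}}, the product of a
#' luminance term and a contrast/structure term built from the window
#' means, variances and covariance. By default a single window spanning the
#' whole image is used; with `window = w` the image is tiled into w x w
#' blocks and the mean of the per-window values returned. The default
#' stabilising constants are \eqn{c_1 = (0.01 L)^2} and
#' \eqn{c_2 = (0.03 L)^2} for dynamic range L.
#'
#' @param u,v Numeric matrices of identical shape.
#' @param c1,c2 Positive stabilising constants; defaults derived from the
#'   dynamic range.
#' @param window Window side length in pixels, or `NULL` for a single
#'   whole-image window.
#' @param L Dynamic range used for the default constants; defaults to the
#'   observed range of the two images (1 if both are constant).
#' @return SSIM in \eqn{[-1, 1]}; 1 means identical images.
#' @export
ssim <- function(u, v, c1 = NULL, c2 = NULL, window = NULL, L = NULL) {
  u <- as.matrix(u); v <- as.matrix(v)
  if (!all(dim(u) == dim(v))) stop_input("images must have identical shapes")
  if (is.null(L)) {
    L <- diff(range(c(u, v)))
    if (L == 0) L <- 1
  }
  if (is.null(c1)) c1 <- (0.01 * L)^2
  if (is.null(c2)) c2 <- (0.03 * L)^2
  if (c1 <= 0 || c2 <= 0) stop_input("'c1' and 'c2' must be positive")
  one <- function(uu, vv) {
    mu <- mean(uu); mv <- mean(vv)
    # population moments so single-pixel windows are well defined
    vu <- mean((uu - mu)^2); vv2 <- mean((vv - mv)^2)
    cuv <- mean((uu - mu) * (vv - mv))
    ((2 * mu * mv + c1) / (mu^2 + mv^2 + c1)) *
      ((2 * cuv + c2) / (vu + vv2 + c2))
  }
  if (is.null(window)) return(one(u, v))
  if (window < 1 || window != round(window)) stop_input("'window' must be a positive integer")
  ri <- split(seq_len(nrow(u)), ceiling(seq_len(nrow(u)) / window))
  ci <- split(seq_len(ncol(u)), ceiling(seq_len(ncol(u)) / window))
  vals <- unlist(lapply(ri, function(r) vapply(ci, function(cc)
    one(u[r, cc, drop = FALSE], v[r, cc, drop = FALSE]), 0)))
  mean(vals)
}

#' Per-class and mean Dice for semantic (multi-class) segmentation
#'
#' Computes a one-vs-rest Dice score for each class label and their
#' unweighted mean. A class present in neither mask has an undefined Dice;
#' it is reported as `NA`, excluded from the mean, and flagged with a
#' classed warning.
#'
#' @param a,b Integer label masks of identical shape.
#' @param classes Class labels to evaluate; default: all labels occurring
#'   in either mask.
#' @return A list with `per_class` (named numeric vector) and `mean`.
#' @export
mean_class_dice <- function(a, b, classes = NULL) {
  a <- as.array(a); b <- as.array(b)
  if (!identical(dim(a), dim(b))) stop_input("masks must have identical shapes")
  if (anyNA(a) || anyNA(b) || any(a != round(a)) || any(b != round(b)))
    stop_input("label masks must contain integer class labels")
  if (is.null(classes)) classes <- sort(unique(c(a, b)))
  per <- vapply(classes, function(cl) {
    r <- catch_undefined(dice(array(as.numeric(a == cl), dim(a)),
                              array(as.numeric(b == cl), dim(b))))
    r$value
  }, 0)
  names(per) <- as.character(classes)
  if (anyNA(per))
    warn_metricomp(paste0("class(es) absent from both masks, excluded from mean: ",
                          paste(names(per)[is.na(per)], collapse = ", ")),
                   class = "metricomp_undefined_metric_warning")
  list(per_class = per, mean = mean(per, na.rm = TRUE))
}
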
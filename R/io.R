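# File interchange. CSV dialect: comma-separated, UTF-8, header row, "."
# decimal separator. Confusion matrices travel as TSV with a one-line
# orientation header; 2D masks as PNG (0/255) or delimited text; 3D masks
# as NIfTI.

#' Read and write prediction tables
#'
#' Prediction CSVs have columns `id,y_true,y_pred` (binary labels) or
#' `id,y_true,y_score` (numeric scores), plus an optional `model` column;
#' `model` (if given) selects one model's rows.
#'
#' @param path File path.
#' @param model Optional model name to filter on.
#' @return `read_predictions_csv`: a data frame.
#'   `labels_from_predictions`: a [binary_confusion()].
#'   `scores_from_predictions`: a [scored_predictions()].
#' @export
read_predictions_csv <- function(path, model = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"y_true" %in% names(df))
    stop_input(sprintf("%s: prediction table needs a 'y_true' column", path))
  if (!is.null(model)) {
    if (!"model" %in% names(df))
      stop_input(sprintf("%s: no 'model' column to filter on", path))
    df <- df[df$model == model, , drop = FALSE]
    if (!nrow(df)) stop_input(sprintf("%s: no rows for model '%s'", path, model))
  }
  df
}

#' @rdname read_predictions_csv
#' @export
labels_from_predictions <- function(path, model = NULL) {
  df <- read_predictions_csv(path, model)
  if (!"y_pred" %in% names(df))
    stop_input(sprintf("%s: label table needs a 'y_pred' column", path))
  confusion_from_labels(df$y_true, df$y_pred)
}

#' @rdname read_predictions_csv
#' @param role Role tag for the resulting [scored_predictions()].
#' @export
scores_from_predictions <- function(path, model = NULL, role = "test") {
  df <- read_predictions_csv(path, model)
  if (!"y_score" %in% names(df))
    stop_input(sprintf("%s: score table needs a 'y_score' column", path))
  scored_predictions(df$y_score, df$y_true, role = role)
}

#' Read and write confusion matrices as TSV
#'
#' The file starts with a comment line `# orientation=true_rows` (or
#' `pred_rows`), followed by a tab-separated count matrix with class names
#' as header and row names.
#'
#' @param path File path.
#' @return `read_confusion_tsv`: a [confusion_k()] (or [binary_confusion()]
#'   when `as_binary = TRUE` and the matrix is 2 x 2) in canonical
#'   rows-are-true orientation.
#' @export
read_confusion_tsv <- function(path, as_binary = FALSE) {
  first <- readLines(path, n = 1)
  orientation <- "true_rows"
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    m <- regmatches(first, regexec("orientation=(true_rows|pred_rows)", first))[[1]]
    if (length(m) == 2) orientation <- m[2]
    else stop_input(sprintf("%s: header comment must declare orientation=true_rows|pred_rows", path))
  }
  tab <- utils::read.delim(path, skip = skip, row.names = 1, check.names = FALSE)
  K <- confusion_k(as.matrix(tab), class_names = rownames(tab),
                   orientation = orientation)
  if (as_binary) {
    if (nrow(K) != 2) stop_input("binary confusion requested but matrix is not 2 x 2")
    return(binary_confusion(tp = K[1, 1], tn = K[2, 2],
                            fp = K[2, 1], fn = K[1, 2]))
  }
  K
}

#' @rdname read_confusion_tsv
#' @param K A [confusion_k()] object.
#' @param as_binary Treat a 2 x 2 matrix as a binary confusion with the
#'   first class positive.
#' @export
write_confusion_tsv <- function(K, path) {
  stopifnot(inherits(K, "confusion_k"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# orientation=true_rows", con)
  nm <- rownames(K)
  if (is.null(nm)) nm <- paste0("class", seq_len(nrow(K)))
  tab <- as.data.frame(unclass(K)); dimnames(tab) <- list(nm, nm)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read and write 2D masks as PNG or delimited text
#'
#' PNG masks store foreground as white (255) on black; grey or
#' probabilistic images are binarised at `threshold` on ingest. Text masks
#' are whitespace-delimited 0/1 grids.
#'
#' @param path File path.
#' @param threshold Ingest binarisation threshold on the \[0, 1\] intensity
#'   scale (default 0.5).
#' @return A [as_mask()] object.
#' @export
read_mask_png <- function(path, threshold = 0.5) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB(A)
  as_mask(array(as.numeric(img >= threshold), dim(img)))
}

#' @rdname read_mask_png
#' @param m A 2D mask.
#' @export
write_mask_png <- function(m, path) {
  m <- as_mask(m)
  if (length(dim(m)) != 2) stop_input("PNG export requires a 2D mask")
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' @rdname read_mask_png
#' @export
read_mask_text <- function(path, threshold = 0.5) {
  tab <- as.matrix(utils::read.table(path))
  dimnames(tab) <- NULL
  as_mask(array(as.numeric(tab >= threshold), dim(tab)))
}

#' @rdname read_mask_png
#' @export
write_mask_text <- function(m, path) {
  m <- as_mask(m)
  if (length(dim(m)) != 2) stop_input("text export requires a 2D mask")
  utils::write.table(unclass(m), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write 3D masks as NIfTI
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param threshold Ingest binarisation threshold.
#' @return A 3D [as_mask()] with spacing taken from the voxel dimensions.
#' @export
read_mask_nifti <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  arr <- array(as.numeric(as.array(img) >= threshold), dim(img))
  as_mask(arr, spacing = spacing[seq_along(dim(arr))])
}

#' @rdname read_mask_nifti
#' @param m A 3D mask.
#' @export
write_mask_nifti <- function(m, path) {
  m <- as_mask(m)
  if (length(dim(m)) != 3) stop_input("NIfTI export requires a 3D mask")
  img <- RNifti::asNifti(array(as.numeric(m), dim(m)))
  RNifti::pixdim(img) <- attr(m, "spacing")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a ROC curve as CSV
#'
#' Columns `threshold,fpr,tpr`.
#'
#' @param curve A `roc_points` object.
#' @param path Output path.
#' @export
write_roc_csv <- function(curve, path) {
  stopifnot(inherits(curve, "roc_points"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read paired samples and metric matrices
#'
#' Paired-sample CSVs have columns `unit_id,model_a,model_b`; metric-matrix
#' CSVs have `dataset_id` followed by one column per model.
#'
#' @param path File path.
#' @return `read_paired_samples_csv`: a list with vectors `a` and `b`.
#'   `read_metric_matrix_csv`: a J x K numeric matrix.
#' @export
read_paired_samples_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("model_a", "model_b")
  if (!all(need %in% names(df)))
    stop_input(sprintf("%s: paired-sample table needs columns unit_id,model_a,model_b", path))
  list(a = df$model_a, b = df$model_b)
}

#' @rdname read_paired_samples_csv
#' @export
read_metric_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "dataset_id")
    stop_input(sprintf("%s: metric matrix must start with a dataset_id column", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$dataset_id
  if (!is.numeric(m)) stop_input(sprintf("%s: metric values must be numeric", path))
  m
}

#' Read detection boxes and ranked lists
#'
#' Detections: `image_id,class,x_min,y_min,x_max,y_max,confidence` (ground
#' truth omits `confidence`). Ranked lists: `query_id,rank,rel_or_grade`.
#'
#' @param path File path.
#' @param confidence Whether a confidence column is required (predictions).
#' @return `read_boxes_csv`: a data frame of boxes.
#'   `read_ranked_lists_csv`: a named list of relevance/grade vectors in
#'   rank order, one per query.
#' @export
read_boxes_csv <- function(path, confidence = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_boxes(df, confidence = confidence, what = path)
}

#' @rdname read_boxes_csv
#' @export
read_ranked_lists_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("query_id", "rank", "rel_or_grade")
  if (!all(need %in% names(df)))
    stop_input(sprintf("%s: ranked lists need columns query_id,rank,rel_or_grade", path))
  lapply(split(df, df$query_id), function(q) q$rel_or_grade[order(q$rank)])
}
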
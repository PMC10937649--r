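# Ranked-retrieval metrics: precision at k, average precision over a
# ranked result list, and discounted cumulative gain with the conventional
# graded gain values.

#' Precision of the first k retrieved results
#'
#' \eqn{P@k = \sum_{i=1}^{k} rel(d_i) / k} for binary relevances.
#'
#' @param rel 0/1 relevance vector of the ranked results, best-ranked first.
#' @param k Cut-off, 1 <= k <= length(rel).
#' @return P@k in \eqn{[0, 1]}.
#' @export
precision_at_k <- function(rel, k) {
  if (!is_binary01(rel)) stop_input("'rel' must be 0/1")
  if (k < 1 || k > length(rel) || k != round(k))
    stop_input("'k' must be an integer in 1..length(rel)")
  sum(rel[seq_len(k)]) / k
}

#' Average precision of a ranked result list
#'
#' \eqn{AP = \sum_k rel(d_k) \cdot P@k / R}, where R is the total number of
#' relevant documents in the collection (not only those retrieved).
#'
#' @param rel 0/1 relevance vector of the ranked results.
#' @param total_relevant Number of relevant documents in the collection;
#'   defaults to `sum(rel)` and must be at least that, and positive.
#' @return AP in \eqn{[0, 1]}.
#' @examples
#' average_precision_retrieval(c(1, 0, 1), total_relevant = 2)  # 5/6
#' @export
average_precision_retrieval <- function(rel, total_relevant = sum(rel)) {
  if (!is_binary01(rel)) stop_input("'rel' must be 0/1")
  if (total_relevant <= 0)
    stop_input("no relevant documents in the collection: AP undefined")
  if (total_relevant < sum(rel))
    stop_input("'total_relevant' cannot be smaller than the relevant results retrieved")
  if (sum(rel) == 0) return(0)
  pk <- cumsum(rel) / seq_along(rel)
  sum(rel * pk) / total_relevant
}

# gain values conventionally attached to graded relevance labels
.default_gains <- c(perfect = 10, excellent = 7, good = 3, fair = 0.5, bad = 0)

#' Discounted cumulative gain
#'
#' \eqn{DCG = \sum_{i=1}^{k} G(i) / \log_2(i + 1)}: the gain of each result
#' discounted by its rank. Character grades are mapped through the
#' conventional gains perfect = 10, excellent = 7, good = 3, fair = 0.5,
#' bad = 0.
#'
#' @param gains Numeric gains in rank order, or a character vector of
#'   grades.
#' @param k Cut-off; default all results.
#' @param gain_map Named numeric vector mapping grade labels to gains.
#' @return The discounted sum.
#' @examples
#' dcg(c(10, 7, 0))          # 10 + 7/log2(3)
#' dcg(c("perfect", "bad"))  # 10
#' @export
dcg <- function(gains, k = length(gains), gain_map = .default_gains) {
  if (is.character(gains) || is.factor(gains)) {
    gains <- as.character(gains)
    unknown <- setdiff(unique(gains), names(gain_map))
    if (length(unknown))
      stop_input(paste0("unknown grade label(s): ", paste(unknown, collapse = ", ")))
    gains <- unname(gain_map[gains])
  }
  if (!is.numeric(gains) || anyNA(gains)) stop_input("'gains' must be numeric")
  if (k < 0 || k > length(gains) || k != round(k))
    stop_input("'k' must be an integer in 0..length(gains)")
  i <- seq_len(k)
  sum(gains[i] / log2(i + 1))
}

#' Mean DCG over several queries
#'
#' @param lists A list of gain vectors (numeric or graded), one per query.
#' @param k Cut-off applied to each list; default: full list.
#' @inheritParams dcg
#' @return The mean of the per-query DCG values.
#' @export
mean_dcg <- function(lists, k = NULL, gain_map = .default_gains) {
  if (!length(lists)) stop_input("no queries supplied")
  mean(vapply(lists, function(g)
    dcg(g, k = if (is.null(k)) length(g) else k, gain_map = gain_map), 0))
}
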
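# Resampling plans that generate the paired metric values needed by the
# comparison tests. All plans are seed-deterministic and shared across
# models: on any iteration round every model sees the same train and test
# indices, so the resulting metric values are paired.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}

new_fold_plan <- function(rounds, scheme, n, seed) {
  structure(list(rounds = rounds, scheme = scheme, n = n, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$rounds, function(r) length(r$test), 0L)
  cat(sprintf("Fold plan (%s): %d rounds over %d instances, test sizes %s, seed %s\n",
              x$scheme, length(x$rounds), x$n,
              paste(range(sizes), collapse = "-"),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' k-fold cross-validation plan
#'
#' Randomly partitions the indices 1..n into k folds whose sizes differ by
#' at most one; each round uses one fold as the test set and the rest for
#' training, so every index is tested exactly once per repetition. The same
#' plan should be applied to all models under comparison so their metric
#' values are paired round by round.
#'
#' @param n Number of instances.
#' @param k Number of folds, 2 <= k <= n.
#' @param seed Integer seed; the plan is fully determined by it.
#' @return An object of class `fold_plan` whose `rounds` element is a list
#'   of `list(train, test)` index vectors.
#' @export
kfold_plan <- function(n, k, seed = NULL) {
  if (k < 2 || k > n) stop_input("'k' must satisfy 2 <= k <= n")
  with_seed(seed, {
    perm <- sample.int(n)
    # sizes differ by at most 1 since fold labels are cycled over a permutation
    fold_of <- rep(seq_len(k), length.out = n)
    idx <- split(perm, fold_of)
    rounds <- lapply(idx, function(test)
      list(train = sort(setdiff(seq_len(n), test)), test = sort(test)))
    names(rounds) <- NULL
    new_fold_plan(rounds, "k-fold", n, seed)
  })
}

#' Repeated k-fold cross-validation plan
#'
#' Concatenates `repeats` independent k-fold plans (a few re-runs of each
#' potential test set), giving `repeats * k` rounds.
#'
#' @inheritParams kfold_plan
#' @param repeats Number of complete k-fold repetitions.
#' @return A `fold_plan` with `repeats * k` rounds.
#' @export
repeated_kfold_plan <- function(n, k, repeats, seed = NULL) {
  if (repeats < 1 || repeats != round(repeats))
    stop_input("'repeats' must be a positive integer")
  with_seed(seed, {
    rounds <- list()
    for (r in seq_len(repeats)) {
      p <- kfold_plan(n, k, seed = NULL)  # draws from the current stream
      rounds <- c(rounds, p$rounds)
    }
    new_fold_plan(rounds, "repeated k-fold", n, seed)
  })
}

#' Group-wise train/test split
#'
#' Splits instances into train and test sets so that no group (e.g.
#' patient) spans both sides, choosing the subset of groups whose total
#' size is closest to the requested test fraction (ties towards the smaller
#' test set; subset choice among equal-sized solutions is randomised by the
#' seed).
#'
#' @param group_ids Vector of group memberships, one entry per instance.
#' @param test_fraction Requested fraction of instances in the test set,
#'   in (0, 1).
#' @param seed Integer seed.
#' @return A `fold_plan` with a single round.
#' @export
group_split_plan <- function(group_ids, test_fraction, seed = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_input("'test_fraction' must be in (0, 1)")
  groups <- unique(group_ids)
  if (length(groups) < 2) stop_input("need at least 2 groups")
  n <- length(group_ids)
  with_seed(seed, {
    groups <- sample(groups)  # randomise tie-breaking among subsets
    sizes <- vapply(groups, function(g) sum(group_ids == g), 0L)
    target <- test_fraction * n
    # subset-sum over group sizes: reachable totals with a parent pointer
    reach <- list(`0` = integer(0))
    for (gi in seq_along(groups)) {
      for (s in names(reach)) {
        ns <- as.integer(s) + sizes[gi]
        key <- as.character(ns)
        if (is.null(reach[[key]])) reach[[key]] <- c(reach[[s]], gi)
      }
    }
    sums <- as.integer(names(reach))
    ok <- sums > 0 & sums < n  # both sides non-empty
    if (!any(ok)) stop_input("no feasible group split")
    sums <- sums[ok]
    best <- sums[order(abs(sums - target), sums)][1]
    test_groups <- groups[reach[[as.character(best)]]]
    test <- which(group_ids %in% test_groups)
    new_fold_plan(list(list(train = setdiff(seq_len(n), test), test = test)),
                  "group-wise split", n, seed)
  })
}

#' Export a fold plan as a round/role/index table
#'
#' @param plan A `fold_plan`.
#' @return A data frame with columns `round`, `role` (`"train"`/`"test"`)
#'   and `index`, suitable for CSV export.
#' @export
fold_plan_table <- function(plan) {
  stopifnot(inherits(plan, "fold_plan"))
  do.call(rbind, lapply(seq_along(plan$rounds), function(i) {
    r <- plan$rounds[[i]]
    rbind(data.frame(round = i, role = "train", index = r$train),
          data.frame(round = i, role = "test", index = r$test))
  }))
}
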
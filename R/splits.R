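# Stratified data partitions: pooled 72/18/10 split, fourfold
# cross-validation with an 80/20 inner split, per-class fractional subsets
# and out-of-set (train on one cohort, test on the other) plans. Splits
# operate on item ids only; largest-remainder rounding keeps every class
# within one item of its target proportion.

new_split_plan <- function(train, validation, test, description) {
  if (anyDuplicated(c(train, validation, test))) {
    stop("split roles must be pairwise disjoint")
  }
  structure(list(train = train, validation = validation, test = test,
                 description = description),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d train / %d validation / %d test\n",
              x$description, length(x$train), length(x$validation),
              length(x$test)))
  invisible(x)
}

check_items_by_class <- function(items_by_class) {
  if (!length(items_by_class) || is.null(names(items_by_class))) {
    stop("items_by_class must be a non-empty named list (class -> item ids)")
  }
  if (any(!lengths(items_by_class))) {
    stop("every class must have at least one item")
  }
  invisible(items_by_class)
}

#' Pooled stratified train/validation/test split
#'
#' Allocates every class independently to train/validation/test with
#' largest-remainder rounding of `n * fraction` (ties toward the
#' earlier-listed role) and a seeded shuffle, so each class is spread as
#' evenly as the fractions allow.
#'
#' @param items_by_class named list mapping class to a vector of item ids.
#' @param fractions train/validation/test fractions, positive, summing to 1
#'   (default `c(0.72, 0.18, 0.10)`).
#' @param seed integer seed.
#' @return a `split_plan`.
#' @export
pooled_split <- function(items_by_class, fractions = c(0.72, 0.18, 0.10),
                         seed = 1L) {
  check_items_by_class(items_by_class)
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  parts <- list(train = character(), validation = character(), test = character())
  with_seed(seed, {
    for (cls in names(items_by_class)) {
      ids <- items_by_class[[cls]]
      n <- length(ids)
      alloc <- largest_remainder(n, fractions)
      ids <- ids[sample.int(n)]
      parts$train <- c(parts$train, ids[seq_len(alloc[1])])
      parts$validation <- c(parts$validation,
                            ids[seq_len(alloc[2]) + alloc[1]])
      parts$test <- c(parts$test, ids[seq_len(alloc[3]) + alloc[1] + alloc[2]])
    }
  })
  new_split_plan(parts$train, parts$validation, parts$test,
                 sprintf("pooled %s seed=%d",
                         paste(fractions, collapse = "/"), seed))
}

#' Stratified k-fold cross-validation plans with an inner train/validation split
#'
#' Partitions every class into `k` near-equal folds. Plan `i` tests on fold
#' `i` and splits the remaining items per class into training and
#' validation by `inner_train_frac` (largest-remainder). Across the `k`
#' plans every item is tested exactly once.
#'
#' @param items_by_class named list mapping class to a vector of item ids.
#' @param k number of folds (>= 2; every class needs >= k items).
#' @param inner_train_frac training fraction of the non-test items
#'   (default 0.8).
#' @param seed integer seed.
#' @return list of `k` `split_plan` objects.
#' @export
cv_folds <- function(items_by_class, k = 4L, inner_train_frac = 0.8, seed = 1L) {
  check_items_by_class(items_by_class)
  if (k < 2) stop("k must be >= 2")
  stopifnot(inner_train_frac > 0, inner_train_frac <= 1)
  small <- names(items_by_class)[lengths(items_by_class) < k]
  if (length(small)) {
    stop("class(es) smaller than k folds: ", paste(small, collapse = ", "))
  }
  fold_of <- with_seed(seed, {
    lapply(items_by_class, function(ids) {
      n <- length(ids)
      sizes <- largest_remainder(n, rep(1 / k, k))
      f <- rep(seq_len(k), times = sizes)
      stats::setNames(f, ids[sample.int(n)])
    })
  })
  lapply(seq_len(k), function(i) {
    tr <- character(); va <- character(); te <- character()
    for (cls in names(fold_of)) {
      f <- fold_of[[cls]]
      te <- c(te, names(f)[f == i])
      rest <- names(f)[f != i]
      alloc <- largest_remainder(length(rest),
                                 c(inner_train_frac, 1 - inner_train_frac))
      tr <- c(tr, rest[seq_len(alloc[1])])
      va <- c(va, rest[seq_len(alloc[2]) + alloc[1]])
    }
    new_split_plan(tr, va, te,
                   sprintf("cv%d fold=%d inner=%g seed=%d", k, i,
                           inner_train_frac, seed))
  })
}

#' Per-class fractional subset
#'
#' Keeps `round(n * fraction)` items of every class (largest-remainder
#' against the complement, minimum one item for a non-empty class), sampled
#' uniformly without replacement.
#'
#' @param items_by_class named list mapping class to a vector of item ids.
#' @param fraction fraction to keep, in (0, 1].
#' @param seed integer seed.
#' @return reduced named list with the same classes.
#' @export
subset_fraction <- function(items_by_class, fraction = 0.10, seed = 1L) {
  check_items_by_class(items_by_class)
  stopifnot(fraction > 0, fraction <= 1)
  with_seed(seed, {
    lapply(items_by_class, function(ids) {
      n <- length(ids)
      keep <- max(1L, largest_remainder(n, c(fraction, 1 - fraction))[1])
      ids[sort(sample.int(n, keep))]
    })
  })
}

#' Out-of-set plan: train on one cohort, test on the other
#'
#' Training and validation items are drawn per class from the first cohort
#' only (largest-remainder `1 - val_frac` / `val_frac`); the test set is
#' every eligible item of the second cohort. By default only classes
#' present in both cohorts enter the plan.
#'
#' @param train_cohort_items named list (class -> ids) of the training
#'   cohort.
#' @param test_cohort_items named list (class -> ids) of the test cohort.
#' @param val_frac validation fraction of the training cohort (default 0.2).
#' @param seed integer seed.
#' @param shared_only if `TRUE` (default), restrict both sides to classes
#'   present in both cohorts.
#' @return a `split_plan`.
#' @export
out_of_set_plan <- function(train_cohort_items, test_cohort_items,
                            val_frac = 0.2, seed = 1L, shared_only = TRUE) {
  check_items_by_class(train_cohort_items)
  check_items_by_class(test_cohort_items)
  stopifnot(val_frac >= 0, val_frac < 1)
  if (shared_only) {
    shared <- intersect(names(train_cohort_items), names(test_cohort_items))
    if (!length(shared)) stop("cohorts share no class")
    train_cohort_items <- train_cohort_items[shared]
    test_cohort_items <- test_cohort_items[shared]
  }
  tr <- character(); va <- character()
  with_seed(seed, {
    for (cls in names(train_cohort_items)) {
      ids <- train_cohort_items[[cls]]
      n <- length(ids)
      alloc <- largest_remainder(n, c(1 - val_frac, val_frac))
      ids <- ids[sample.int(n)]
      tr <- c(tr, ids[seq_len(alloc[1])])
      va <- c(va, ids[seq_len(alloc[2]) + alloc[1]])
    }
  })
  new_split_plan(tr, va, unname(unlist(test_cohort_items)),
                 sprintf("out-of-set val=%g seed=%d", val_frac, seed))
}

#' Serialise split plans to a long data frame
#'
#' @param plans a `split_plan` or list of them.
#' @return data frame with columns `item_id`, `role`, `plan_id`.
#' @export
split_plan_table <- function(plans) {
  if (inherits(plans, "split_plan")) plans <- list(plans)
  do.call(rbind, lapply(seq_along(plans), function(i) {
    p <- plans[[i]]
    data.frame(
      item_id = c(p$train, p$validation, p$test),
      role = rep(c("train", "validation", "test"),
                 c(length(p$train), length(p$validation), length(p$test))),
      plan_id = p$description,
      stringsAsFactors = FALSE)
  }))
}
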
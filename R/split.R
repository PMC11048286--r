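#' Stratified holdout split
#'
#' Splits an epoch set into disjoint, exhaustive train/test subsets,
#' stratified by class label and reproducible under `seed`. Per-class train
#' counts follow largest-remainder apportionment of `round(train_frac * N)`,
#' so the overall ratio is honored even when class quotas do not divide
#' evenly (e.g. 5/5 epochs at 0.7 give per-class counts 4 and 3).
#'
#' @param es An [epoch_set()].
#' @param train_frac Fraction of epochs in the training set, in (0, 1).
#'   The conventional protocol is 0.7 (a 7:3 split).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test` (both `epoch_set`) and
#'   attribute-free index vectors `train_idx`, `test_idx`.
#' @export
split_holdout <- function(es, train_frac = 0.7, seed = 1L) {
  stopifnot(inherits(es, "epoch_set"))
  if (!(train_frac > 0 && train_frac < 1))
    stop("train_frac must be in (0, 1)", call. = FALSE)
  n <- n_epochs(es)
  classes <- sort(unique(es$labels))
  sizes <- vapply(classes, function(k) sum(es$labels == k), 0L)
  n_train <- .stratified_counts(sizes, train_frac)
  tr <- integer(0)
  .with_seed(seed, {
    for (j in seq_along(classes)) {
      idx <- which(es$labels == classes[j])
      idx <- idx[sample.int(length(idx))]
      tr <- c(tr, idx[seq_len(n_train[j])])
    }
  })
  tr <- sort(tr)
  te <- setdiff(seq_len(n), tr)
  list(train = es[tr], test = es[te], train_idx = tr, test_idx = te)
}

#' k-fold cross-validation indices
#'
#' Partitions the epoch indices into `k` disjoint test folds. Ungrouped
#' folds are stratified by class (shuffled within class, dealt round-robin).
#' Grouped folds keep every epoch of one `group_id` (subject/recording) in
#' the same fold, which is the leakage-safe protocol for subject-level
#' evaluation.
#'
#' @param es An [epoch_set()].
#' @param k Number of folds, `2 <= k <= N` (or number of groups when
#'   `grouped`).
#' @param seed Integer seed.
#' @param grouped Keep groups intact across folds?
#' @return A list of `k` elements, each `list(train = idx, test = idx)`.
#' @export
kfold_indices <- function(es, k, seed = 1L, grouped = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  k <- as.integer(k)
  n <- n_epochs(es)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fold_of <- integer(n)
  if (grouped) {
    groups <- unique(es$group_ids)
    if (k > length(groups))
      stop("k (", k, ") exceeds the number of groups (", length(groups), ")",
           call. = FALSE)
    .with_seed(seed, {
      groups <- groups[sample.int(length(groups))]
    })
    gf <- rep(seq_len(k), length.out = length(groups))
    fold_of <- gf[match(es$group_ids, groups)]
  } else {
    if (k > n) stop("k (", k, ") exceeds the number of epochs (", n, ")",
                    call. = FALSE)
    .with_seed(seed, {
      start <- 0L
      for (cls in sort(unique(es$labels))) {
        idx <- which(es$labels == cls)
        idx <- idx[sample.int(length(idx))]
        fold_of[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
        start <- start + length(idx)
      }
    })
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}
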
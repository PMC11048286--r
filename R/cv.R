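# Evaluation protocols: repeated stratified holdout (the 7:3 x 10 protocol
# of the diagnosis/prognosis tasks), k-fold cross-validation (10-fold
# monitoring, 5-fold drug classification), the three-switch ablation grid,
# and the hyperparameter sensitivity sweep. Each fold trains a fresh model
# from a derived seed; aggregates are mean +/- sd over folds (sd with n-1
# denominator, matching the tables' convention).

.cv_result <- function(folds) {
  mat <- do.call(rbind, lapply(folds, .metric_vector))
  summary <- data.frame(
    metric = colnames(mat),
    mean = colMeans(mat, na.rm = TRUE),
    sd = apply(mat, 2, stats::sd, na.rm = TRUE),
    row.names = NULL)
  structure(list(folds = folds, summary = summary), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", length(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Summary accessor for cross-validation results
#' @param res A `cv_result`.
#' @param metric Metric name (e.g. `"accuracy"`).
#' @return The mean of that metric over folds.
#' @export
cv_mean <- function(res, metric = "accuracy") {
  s <- res$summary
  s$mean[match(metric, s$metric)]
}

.fit_and_score <- function(train, test, model_cfg, train_cfg, init_seed) {
  cfg <- model_cfg
  cfg$seed <- as.integer(init_seed %% 2147483647)
  model <- init_model(cfg)
  fit <- train_model(model, train, train_cfg)
  probs <- predict_epochs(fit$model, test)
  list(metrics = compute_metrics(test$labels, probs, test$class_names),
       model = fit$model, history = fit$history, probs = probs)
}

#' Repeated stratified holdout evaluation
#'
#' Runs `n_repeats` independent experiments, each drawing a fresh
#' stratified train/test split at `train_frac` (the 7:3 protocol when 0.7)
#' and training a freshly initialized model, then aggregates each metric as
#' mean +/- sd over repeats.
#'
#' @param es An [epoch_set()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param n_repeats Number of independent splits.
#' @param seed Base seed; split, initialization and training seeds are
#'   derived from it, so the whole run is reproducible.
#' @param train_frac Training fraction (default 0.7).
#' @return A `cv_result`.
#' @export
run_holdout_repeats <- function(es, model_cfg, train_cfg, n_repeats = 10L,
                                seed = 1L, train_frac = 0.7) {
  folds <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- split_holdout(es, train_frac, seed = .sub_seed(seed, r))
    tc <- train_cfg
    tc$seed <- as.integer(.sub_seed(seed, 1000 + r) %% 2147483647)
    folds[[r]] <- .fit_and_score(sp$train, sp$test, model_cfg, tc,
                                 .sub_seed(seed, 2000 + r))$metrics
  }
  .cv_result(folds)
}

#' k-fold cross-validation
#'
#' One model fit per fold; every epoch is predicted exactly once as a test
#' case. Grouped mode keeps subjects intact across folds (leakage-safe).
#'
#' @inheritParams run_holdout_repeats
#' @param k Number of folds.
#' @param grouped Keep `group_ids` intact across folds?
#' @return A `cv_result` with an extra element `test_idx` (list of test
#'   index vectors, partitioning the epoch set).
#' @export
run_cv <- function(es, k, model_cfg, train_cfg, seed = 1L, grouped = FALSE) {
  fold_idx <- kfold_indices(es, k, seed = seed, grouped = grouped)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tc <- train_cfg
    tc$seed <- as.integer(.sub_seed(seed, 1000 + f) %% 2147483647)
    folds[[f]] <- .fit_and_score(es[fold_idx[[f]]$train],
                                 es[fold_idx[[f]]$test],
                                 model_cfg, tc,
                                 .sub_seed(seed, 2000 + f))$metrics
  }
  res <- .cv_result(folds)
  res$test_idx <- lapply(fold_idx, `[[`, "test")
  res
}

#' Ablation switchboard
#'
#' Evaluates the four configurations of the three improvement strategies —
#' spatial channel attention, sparse attention, distillation — on one
#' stratified holdout split: the full model and the three single-ablation
#' variants. Disabling sparsity makes every layer dense; disabling
#' distillation removes all convolution/pooling layers (temporal lengths
#' preserved).
#'
#' @inheritParams run_holdout_repeats
#' @param train_frac Training fraction for the single split.
#' @return A data frame with the flag triple, headline metrics, and the
#'   distilling-parameter count per row.
#' @export
run_ablation <- function(es, model_cfg, train_cfg, seed = 1L,
                         train_frac = 0.7) {
  flags <- data.frame(
    channel_attention = c(TRUE, FALSE, TRUE, TRUE),
    sparse_attention = c(TRUE, TRUE, FALSE, TRUE),
    distillation = c(TRUE, TRUE, TRUE, FALSE))
  sp <- split_holdout(es, train_frac, seed = .sub_seed(seed, 1))
  rows <- vector("list", nrow(flags))
  for (i in seq_len(nrow(flags))) {
    cfg <- model_cfg
    cfg$use_channel_attention <- flags$channel_attention[i]
    cfg$use_sparse_attention <- flags$sparse_attention[i]
    cfg$use_distillation <- flags$distillation[i]
    tc <- train_cfg
    tc$seed <- as.integer(.sub_seed(seed, 1000 + i) %% 2147483647)
    fs <- .fit_and_score(sp$train, sp$test, cfg, tc, .sub_seed(seed, 2000 + i))
    m <- fs$metrics
    rows[[i]] <- data.frame(flags[i, , drop = FALSE],
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, f1 = m$f1,
                            roc_auc = m$roc_auc,
                            distill_params = n_distill_parameters(fs$model))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hyperparameter sensitivity sweep
#'
#' Evaluates a grid of architecture tuples
#' `[n_sparse, n_full, n_conv, n_pool, d_ff, d_model, n_heads]` by k-fold
#' cross-validation. Invalid tuples (inconsistent layer counts, epochs too
#' short for the pooling stack, indivisible head width) are reported as
#' error rows, not crashes.
#'
#' @inheritParams run_cv
#' @param grid List of numeric length-7 tuples.
#' @return A data frame with one row per tuple: the tuple columns, `ok`,
#'   `message`, and mean +/- sd accuracy and ROC-AUC for valid rows.
#' @export
run_sensitivity <- function(es, grid, k, model_cfg, train_cfg, seed = 1L) {
  rows <- lapply(seq_along(grid), function(i) {
    tup <- as.integer(grid[[i]])
    stopifnot(length(tup) == 7L)
    base <- data.frame(n_sparse = tup[1], n_full = tup[2], n_conv = tup[3],
                       n_pool = tup[4], d_ff = tup[5], d_model = tup[6],
                       n_heads = tup[7])
    res <- tryCatch({
      cfg <- sensitivity_config(model_cfg, tup)
      Tn <- dim(es$epochs)[2]
      tmin <- min_input_length(cfg)
      if (Tn < tmin)
        stop("epoch length ", Tn, " too short for ", tup[4],
             " pooling layers (needs T >= ", tmin, ")", call. = FALSE)
      cv <- run_cv(es, k, cfg, train_cfg, seed = .sub_seed(seed, i))
      data.frame(base, ok = TRUE, message = "",
                 accuracy_mean = cv_mean(cv, "accuracy"),
                 accuracy_sd = cv$summary$sd[match("accuracy",
                                                   cv$summary$metric)],
                 roc_auc_mean = cv_mean(cv, "roc_auc"),
                 roc_auc_sd = cv$summary$sd[match("roc_auc",
                                                  cv$summary$metric)])
    }, error = function(e)
      data.frame(base, ok = FALSE, message = conditionMessage(e),
                 accuracy_mean = NA_real_, accuracy_sd = NA_real_,
                 roc_auc_mean = NA_real_, roc_auc_sd = NA_real_))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a configuration from a sensitivity tuple
#'
#' @param base A [model_config()] supplying everything the tuple does not
#'   set.
#' @param tuple Integer vector
#'   `[n_sparse, n_full, n_conv, n_pool, d_ff, d_model, n_heads]`.
#' @return A [model_config()].
#' @export
sensitivity_config <- function(base, tuple) {
  tuple <- as.integer(tuple)
  stopifnot(length(tuple) == 7L)
  model_config(
    n_classes = base$n_classes, in_channels = base$in_channels,
    n_sparse_layers = tuple[1], n_full_layers = tuple[2],
    n_conv_layers = tuple[3], n_pool_layers = tuple[4],
    d_ff = tuple[5], d_model = tuple[6], n_heads = tuple[7],
    query_factor = base$query_factor,
    channel_reduction = base$channel_reduction, dropout = base$dropout,
    conv_kernel = base$conv_kernel, pool_kernel = base$pool_kernel,
    pool_stride = base$pool_stride, pool_pad = base$pool_pad,
    use_channel_attention = base$use_channel_attention,
    use_sparse_attention = base$use_sparse_attention,
    use_distillation = base$use_distillation,
    positional_encoding = base$positional_encoding,
    embed_conv = base$embed_conv, seed = base$seed)
}
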
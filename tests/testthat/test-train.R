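mini_cfg <- function(...) tiny_model_cfg(...)

test_that("training bookkeeping: history length, finiteness, label checks", {
  es <- random_epoch_set(8, 16, 2, K = 2L, seed = 7)
  fit <- train_model(init_model(mini_cfg()), es,
                     train_config(epochs = 1, batch_size = 4, seed = 1))
  expect_length(fit$history, 1L)
  expect_true(is.finite(fit$history))
  bad <- es
  bad$labels <- rep(2L, 8)
  bad$class_names <- as.character(0:2)
  expect_error(train_model(init_model(mini_cfg()), bad,
                           train_config(epochs = 1)), "labels outside")
})

test_that("zero learning rate leaves parameters untouched", {
  es <- random_epoch_set(8, 16, 2, K = 2L, seed = 8)
  m <- init_model(mini_cfg())
  fit <- train_model(m, es, train_config(epochs = 2, batch_size = 4,
                                         learning_rate = 0, seed = 1))
  expect_identical(fit$model$params, m$params)
})

test_that("the loss decreases on an easy synthetic task", {
  es <- make_dataset(tiny_task_spec())
  cfg <- mini_cfg()
  fit <- train_model(init_model(cfg), es,
                     train_config(epochs = 10, batch_size = 16,
                                  learning_rate = 1e-3, seed = 2))
  expect_lt(fit$history[10], fit$history[1])
})

test_that("training is bitwise reproducible under a fixed seed", {
  es <- make_dataset(tiny_task_spec(n_per_class = 10L))
  run <- function() {
    fit <- train_model(init_model(mini_cfg()), es,
                       train_config(epochs = 2, batch_size = 8, seed = 42))
    fit$model
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$params, m2$params)
  expect_identical(predict_epochs(m1, es), predict_epochs(m2, es))
})

test_that("holdout repeats: untrained models hover near chance", {
  es <- make_dataset(tiny_task_spec(n_per_class = 20L))
  cfgm <- mini_cfg()
  cfgt <- train_config(epochs = 0, batch_size = 8, seed = 1)
  res <- run_holdout_repeats(es, cfgm, cfgt, n_repeats = 10, seed = 5)
  acc <- cv_mean(res, "accuracy")
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
  expect_length(res$folds, 10L)
  expect_true(all(res$summary$sd >= 0))
  res2 <- run_holdout_repeats(es, cfgm, cfgt, n_repeats = 10, seed = 5)
  expect_equal(res$summary, res2$summary)
})

test_that("cross-validation covers every epoch exactly once", {
  es <- make_dataset(tiny_task_spec(n_per_class = 15L))
  res <- run_cv(es, 3, mini_cfg(), train_config(epochs = 1, batch_size = 8,
                                                seed = 3), seed = 9)
  expect_length(res$folds, 3L)
  expect_equal(sort(unlist(res$test_idx)), seq_len(n_epochs(es)))
  res2 <- run_cv(es, 3, mini_cfg(), train_config(epochs = 1, batch_size = 8,
                                                 seed = 3), seed = 9)
  expect_equal(res$summary, res2$summary)
})

test_that("the ablation grid has the canonical four rows", {
  es <- make_dataset(tiny_task_spec(n_per_class = 12L))
  tab <- run_ablation(es, mini_cfg(), train_config(epochs = 1,
                                                   batch_size = 8, seed = 2),
                      seed = 4)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$channel_attention, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(tab$sparse_attention, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(tab$distillation, c(TRUE, TRUE, TRUE, FALSE))
  # no distillation => no convolutional distilling parameters
  expect_equal(tab$distill_params[4], 0L)
  expect_gt(tab$distill_params[1], 0L)
})

test_that("sensitivity sweep parses tuples and flags invalid ones", {
  es <- make_dataset(tiny_task_spec(n_per_class = 10L))
  base <- mini_cfg()
  # the reference tuple reproduces the reference architecture
  ref <- sensitivity_config(preset_config("mdd"),
                            c(3, 3, 5, 5, 512, 128, 8))
  expect_equal(ref[c("n_sparse_layers", "n_full_layers", "n_conv_layers",
                     "n_pool_layers", "d_ff", "d_model", "n_heads")],
               preset_config("mdd")[c("n_sparse_layers", "n_full_layers",
                                      "n_conv_layers", "n_pool_layers",
                                      "d_ff", "d_model", "n_heads")])
  grid <- list(c(1, 1, 2, 2, 16, 8, 2),    # valid tiny architecture
               c(4, 4, 7, 7, 16, 8, 2))    # 7 pools cannot fit T = 64
  tab <- run_sensitivity(es, grid, k = 2, base,
                         train_config(epochs = 1, batch_size = 8, seed = 1),
                         seed = 6)
  expect_equal(nrow(tab), 2L)
  expect_true(tab$ok[1])
  expect_false(tab$ok[2])
  expect_match(tab$message[2], "too short")
  expect_true(is.finite(tab$accuracy_mean[1]))
  expect_true(is.na(tab$accuracy_mean[2]))
})
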
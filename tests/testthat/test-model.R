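test_that("channel attention gates obey the sigmoid contract", {
  set.seed(31)
  X <- matrix(rnorm(64 * 4), 64, 4)
  params <- init_channel_attention(4, seed = 2)
  m <- channel_gate(X, params)
  expect_true(all(m > 0 & m < 1))
  expect_equal(channel_attention(X, params), X * rep(m, each = 64))
  # zero weights: sigmoid(0) = 0.5 exactly
  zero <- list(W0 = params$W0 * 0, W1 = params$W1 * 0)
  expect_identical(channel_gate(X, zero), rep(0.5, 4))
  expect_equal(channel_attention(X, zero), 0.5 * X)
  # constant-in-time input: avg and max statistics coincide
  Xc <- matrix(rep(c(1.5, -2, 0.3, 4), each = 64), 64, 4)
  expected <- plogis(drop(params$W1 %*% (params$W0 %*% (2 * Xc[1, ]))))
  expect_equal(channel_gate(Xc, params), expected)
  expect_error(channel_gate(matrix(0, 8, 3), params), "channels")
})

test_that("token embedding projects to d_model with injective position codes", {
  set.seed(32)
  X <- matrix(rnorm(100 * 19), 100, 19)
  params <- init_token_embed(19, 128, seed = 1)
  out <- token_embed(X, params)
  expect_equal(dim(out), c(100L, 128L))
  # zero conv weights without position codes: all-zero embedding
  zp <- params
  zp$W <- zp$W * 0
  expect_equal(token_embed(X, zp, positional = FALSE),
               matrix(0, 100, 128))
  pe <- csteeg:::.position_codes(10000, 128)
  expect_false(any(duplicated(pe)))
})

test_that("distilling layers follow the pooling length formula", {
  set.seed(33)
  d <- 16L
  params <- init_distill(d, seed = 4)
  X <- matrix(rnorm(2048 * d), 2048, d)
  expect_equal(nrow(distill_forward(X, params)), 1024L)
  # five stacked layers: 2048 -> 64
  Z <- X
  for (i in 1:5) Z <- distill_forward(Z, init_distill(d, seed = i))
  expect_equal(nrow(Z), 64L)
  expect_equal(distill_lengths(preset_config("mdd"), 2048),
               c(1024L, 512L, 256L, 128L, 64L))
  # identity convolution + non-negative input: ELU is identity, so the
  # layer reduces to plain max pooling
  idp <- params
  idp$W <- idp$W * 0
  idp$W[d + seq_len(d), ] <- diag(d)   # center tap
  idp$b <- numeric(d)
  Xpos <- abs(X[1:32, ])
  expect_equal(distill_forward(Xpos, idp), oracle_maxpool(Xpos))
})

test_that("prediction head pools and maps to finite logits", {
  params <- list(W = matrix(0, 8, 3), b = numeric(3))
  H <- matrix(rnorm(40), 5, 8)
  expect_equal(predict_head(H, params), c(0, 0, 0))
  set.seed(34)
  params$W <- matrix(rnorm(24), 8, 3)
  h1 <- matrix(rnorm(8), 1, 8)
  expect_equal(predict_head(h1, params), drop(h1 %*% params$W))
  big <- matrix(1e6, 4, 8)
  expect_true(all(is.finite(predict_head(big, params))))
})

test_that("full forward produces logits of the right shape, purely", {
  cfg <- preset_config("helsinki")
  m <- init_model(cfg)
  set.seed(35)
  batch <- array(rnorm(2 * 2048 * 19), c(2, 2048, 19))
  logits <- model_forward(m, batch)
  expect_equal(dim(logits), c(2L, 2L))
  # duplicated input rows give identical logits
  dup <- array(batch[c(1, 1), , ], c(2, 2048, 19))
  ld <- model_forward(m, dup)
  expect_identical(ld[1, ], ld[2, ])
})

test_that("too-short epochs raise a configuration error naming the minimum", {
  cfg <- preset_config("desk")
  m <- init_model(cfg)
  expect_equal(min_input_length(cfg), 5L)
  expect_error(model_forward(m, array(0, c(1, 4, 4))), "T >= 5")
})

test_that("ablation flags change the structure as advertised", {
  cfg <- tiny_model_cfg(use_channel_attention = FALSE,
                        use_sparse_attention = FALSE,
                        use_distillation = FALSE, n_conv_layers = 0L)
  m <- init_model(cfg)
  expect_equal(n_distill_parameters(m), 0L)
  expect_false(any(grepl("^ca\\.", names(m$params))))
  expect_true(all(layer_plan(cfg)$type == "full"))
  expect_false(any(layer_plan(cfg)$distill))
  # lengths preserved without distillation
  batch <- array(rnorm(2 * 16 * 2), c(2, 16, 2))
  expect_equal(dim(model_forward(m, batch)), c(2L, 2L))
})

test_that("parameter count matches independent arithmetic and is stable", {
  cfg <- tiny_model_cfg()
  d <- 8; dff <- 16; C <- 2; k <- 3; K <- 2
  hidden <- 2                               # C = 2, r = 1
  expected <- (hidden * C * 2) +            # channel-attention MLP
    (k * C * d + d) +                       # embedding conv
    2 * (4 * (d * d + d) +                  # Q/K/V/O
         2 * 2 * d +                        # two layer norms
         d * dff + dff + dff * d + d) +     # feed-forward
    2 * (k * d * d + d) +                   # two distilling convs
    (d * K + K)                             # head
  m <- init_model(cfg)
  expect_equal(n_parameters(m), expected)
  m2 <- init_model(cfg)
  expect_identical(m$params, m2$params)
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_model_cfg()
  m <- init_model(cfg)
  set.seed(36)
  batch <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
  y <- c(0L, 1L, 0L)
  lossfn <- function(model) {
    fw <- csteeg:::.model_fwd(model, batch, training = TRUE)
    csteeg:::.softmax_ce(fw$logits, y)$loss
  }
  fw <- csteeg:::.model_fwd(m, batch, training = TRUE)
  ce <- csteeg:::.softmax_ce(fw$logits, y)
  g <- csteeg:::.model_bwd(m, fw$caches, ce$dlogits)
  eps <- 1e-5
  for (nm in names(g)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      rel <- abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i]))
      expect_lt(rel, 1e-4, label = paste("relative gradient error", nm, i))
    }
  }
})

test_that("checkpoints round-trip the configuration and weights exactly", {
  cfg <- tiny_model_cfg(query_factor = 1.5, dropout = 0.25)
  m <- init_model(cfg)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(unclass(m2$config), unclass(m$config))
  batch <- array(rnorm(2 * 16 * 2), c(2, 16, 2))
  expect_identical(model_forward(m, batch), model_forward(m2, batch))
})
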
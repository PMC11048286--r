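# The encoder stack: spatial channel attention on the raw [T x C] epoch,
# token embedding to d_model, interleaved (sparse/full) attention and
# distilling layers, then a mean-pooling linear predictor. Forward and
# backward passes are written against the stacked batch representation of
# nn-ops.R; parameters live in a flat named list so the Adam update and the
# parameter count are trivial folds.

#' Initialize channel-attention parameters
#'
#' @param in_channels Channel count `C`.
#' @param reduction Reduction ratio `r`; the MLP hidden width is
#'   `max(1, floor(C / r))`.
#' @param seed Seed for uniform fan-in initialization.
#' @return List with matrices `W0` (`hidden x C`) and `W1` (`C x hidden`).
#' @export
init_channel_attention <- function(in_channels, reduction = NULL, seed = 1L) {
  C <- as.integer(in_channels)
  if (is.null(reduction)) reduction <- max(1L, C %/% 2L)
  h <- max(1L, C %/% as.integer(reduction))
  .with_seed(seed, {
    s0 <- 1 / sqrt(C); s1 <- 1 / sqrt(h)
    list(W0 = matrix(stats::runif(h * C, -s0, s0), h, C),
         W1 = matrix(stats::runif(C * h, -s1, s1), C, h))
  })
}

#' Spatial channel attention gate
#'
#' Computes per-channel statistics by global average and max pooling over
#' time, feeds both through a shared two-layer linear MLP, and gates every
#' channel with `m = sigmoid(W1 W0 x_avg + W1 W0 x_max)`, broadcast over
#' time: `channel_attention(X) = X * m`. All gate values are strictly
#' inside (0, 1).
#'
#' @param X Numeric matrix `[T x C]` (time frames by channels).
#' @param params List with `W0`, `W1` (see [init_channel_attention()]).
#' @return The gated matrix `[T x C]`; `channel_gate()` returns the gate
#'   vector `m` of length `C`.
#' @export
channel_attention <- function(X, params) {
  X * rep(channel_gate(X, params), each = nrow(X))
}

#' @rdname channel_attention
#' @export
channel_gate <- function(X, params) {
  if (ncol(X) != ncol(params$W0))
    stop("X has ", ncol(X), " channels but params expect ", ncol(params$W0),
         call. = FALSE)
  s <- colMeans(X) + apply(X, 2, max)
  .sigmoid_gate(drop(params$W1 %*% (params$W0 %*% s)))
}

# Sigmoid clamped away from exact 0/1: the gate is an open-interval
# multiplier, and extreme unnormalized inputs would otherwise saturate it
# in floating point (killing its gradient entirely).
.sigmoid_gate <- function(x) {
  pmin(pmax(stats::plogis(x), 1e-12), 1 - 1e-12)
}

#' Initialize a distilling layer
#'
#' @param d_model Feature width.
#' @param kernel Convolution kernel size (odd).
#' @param pool_kernel,pool_stride,pool_pad Max-pooling geometry.
#' @param seed Seed.
#' @return Parameter list for [distill_forward()].
#' @export
init_distill <- function(d_model, kernel = 3L, pool_kernel = 3L,
                         pool_stride = 2L, pool_pad = 1L, seed = 1L) {
  d <- as.integer(d_model)
  .with_seed(seed, {
    s <- 1 / sqrt(kernel * d)
    list(W = matrix(stats::runif(kernel * d * d, -s, s), kernel * d, d),
         b = numeric(d), kernel = as.integer(kernel),
         pool_kernel = as.integer(pool_kernel),
         pool_stride = as.integer(pool_stride),
         pool_pad = as.integer(pool_pad))
  })
}

#' Distilling convolutional layer
#'
#' `X' = MaxPool(ELU(Conv1d(X)))` along time: a same-padded 1-D convolution
#' fuses temporally adjacent features, and max pooling (default kernel 3,
#' stride 2, padding 1) halves the temporal length, distilling the sequence
#' down to its most salient features.
#'
#' @param X Numeric matrix `[L x d_model]`.
#' @param params From [init_distill()].
#' @return Matrix `[L' x d_model]` with
#'   `L' = floor((L + 2*pad - pool_kernel)/pool_stride) + 1`.
#' @export
distill_forward <- function(X, params) {
  L <- nrow(X)
  cv <- .conv1d_fwd(X, 1L, L, params$W, params$b, params$kernel)
  el <- .elu_fwd(cv$y)
  .maxpool_fwd(el$y, 1L, L, params$pool_kernel, params$pool_stride,
               params$pool_pad)$y
}

#' Initialize token-embedding parameters
#'
#' @param in_channels Input channel count `C`.
#' @param d_model Target feature width.
#' @param kernel Convolution kernel (odd); ignored when `conv = FALSE`.
#' @param conv Convolutional (`TRUE`) or pointwise linear embedding.
#' @param seed Seed.
#' @return Parameter list for [token_embed()].
#' @export
init_token_embed <- function(in_channels, d_model, kernel = 3L, conv = TRUE,
                             seed = 1L) {
  C <- as.integer(in_channels); d <- as.integer(d_model)
  n_in <- if (conv) kernel * C else C
  .with_seed(seed, {
    s <- 1 / sqrt(n_in)
    list(W = matrix(stats::runif(n_in * d, -s, s), n_in, d),
         b = numeric(d), kernel = as.integer(kernel), conv = isTRUE(conv))
  })
}

#' Token embedding with sinusoidal position codes
#'
#' Projects the `C` raw channels of each time frame to `d_model` features
#' with a same-padded 1-D convolution over time (kernel 3 by default), then
#' adds non-learned sinusoidal position codes. Both parts are toggleable.
#'
#' @param X Numeric matrix `[T x C]`.
#' @param params From [init_token_embed()].
#' @param positional Add the sinusoidal position codes?
#' @return Matrix `[T x d_model]`.
#' @export
token_embed <- function(X, params, positional = TRUE) {
  L <- nrow(X)
  y <- if (params$conv)
    .conv1d_fwd(X, 1L, L, params$W, params$b, params$kernel)$y
  else .add_bias(X %*% params$W, params$b)
  if (positional) y <- y + .position_codes(L, ncol(y))
  y
}

#' Prediction head
#'
#' Mean-pools the remaining time positions and maps the pooled feature
#' vector to class logits with one affine layer; softmax is applied only in
#' the loss and the metric computations.
#'
#' @param H Numeric matrix `[L_final x d_model]`.
#' @param params List with `W` (`d_model x n_classes`) and `b`.
#' @return Numeric vector of `n_classes` logits.
#' @export
predict_head <- function(H, params) {
  drop(colMeans(H) %*% params$W + params$b)
}

# ---- full stack ------------------------------------------------------------

.param_names_attn <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                       "ln1.g", "ln1.b", "ffn.W1", "ffn.b1", "ffn.W2",
                       "ffn.b2", "ln2.g", "ln2.b")

.init_params <- function(cfg) {
  d <- cfg$d_model
  C <- cfg$in_channels
  k <- cfg$conv_kernel
  plan <- layer_plan(cfg)
  .with_seed(cfg$seed, {
    mk <- function(n_in, n_out) {
      s <- 1 / sqrt(n_in)
      matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
    }
    p <- list()
    if (cfg$use_channel_attention) {
      h <- max(1L, C %/% cfg$channel_reduction)
      p[["ca.W0"]] <- mk(C, h) |> t()
      p[["ca.W1"]] <- mk(h, C) |> t()
    }
    p[["emb.W"]] <- mk(if (cfg$embed_conv) k * C else C, d)
    p[["emb.b"]] <- numeric(d)
    for (i in plan$layer) {
      pre <- paste0("L", i, ".")
      p[[paste0(pre, "Wq")]] <- mk(d, d); p[[paste0(pre, "bq")]] <- numeric(d)
      p[[paste0(pre, "Wk")]] <- mk(d, d); p[[paste0(pre, "bk")]] <- numeric(d)
      p[[paste0(pre, "Wv")]] <- mk(d, d); p[[paste0(pre, "bv")]] <- numeric(d)
      p[[paste0(pre, "Wo")]] <- mk(d, d); p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "ln1.g")]] <- rep(1, d)
      p[[paste0(pre, "ln1.b")]] <- numeric(d)
      p[[paste0(pre, "ffn.W1")]] <- mk(d, cfg$d_ff)
      p[[paste0(pre, "ffn.b1")]] <- numeric(cfg$d_ff)
      p[[paste0(pre, "ffn.W2")]] <- mk(cfg$d_ff, d)
      p[[paste0(pre, "ffn.b2")]] <- numeric(d)
      p[[paste0(pre, "ln2.g")]] <- rep(1, d)
      p[[paste0(pre, "ln2.b")]] <- numeric(d)
      if (plan$distill[i]) {
        p[[paste0(pre, "dist.W")]] <- mk(k * d, d)
        p[[paste0(pre, "dist.b")]] <- numeric(d)
      }
    }
    p[["head.W"]] <- mk(d, cfg$n_classes)
    p[["head.b"]] <- numeric(cfg$n_classes)
    p
  })
}

#' Build an encoder stack from a configuration
#'
#' Allocates and initializes every parameter (uniform fan-in scaling under
#' `cfg$seed`); the layer ordering and the parameter count are pure
#' functions of the configuration.
#'
#' @param cfg A [model_config()].
#' @return An object of class `encoder_stack`.
#' @export
init_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  structure(list(config = cfg, params = .init_params(cfg)),
            class = "encoder_stack")
}

#' Total trainable parameter count
#' @param model An [init_model()] stack.
#' @return Integer number of scalar parameters.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "encoder_stack"))
  sum(vapply(model$params, length, 0L))
}

#' Distilling-convolution parameter count
#'
#' Counts only the parameters of the distilling layers, which is the part
#' removed by the distillation ablation switch.
#'
#' @param model An [init_model()] stack.
#' @return Integer count (0 when distillation is disabled).
#' @export
n_distill_parameters <- function(model) {
  nm <- grep("\\.dist\\.", names(model$params), value = TRUE)
  sum(vapply(model$params[nm], length, 0L))
}

#' @export
print.encoder_stack <- function(x, ...) {
  cat(sprintf("<encoder_stack> %d parameters\n", n_parameters(x)))
  print(x$config)
  invisible(x)
}

# Channel attention over a stacked batch. Returns output + cache.
.ca_fwd <- function(X, n, Tn, W0, W1) {
  out <- X
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * Tn + 1L):(i * Tn)
    Xi <- X[rows, , drop = FALSE]
    xavg <- colMeans(Xi)
    imax <- max.col(t(Xi), ties.method = "first")
    xmax <- Xi[cbind(imax, seq_len(ncol(Xi)))]
    s <- xavg + xmax
    h <- drop(W0 %*% s)
    m <- .sigmoid_gate(drop(W1 %*% h))
    out[rows, ] <- Xi * rep(m, each = Tn)
    caches[[i]] <- list(rows = rows, Xi = Xi, imax = imax, s = s, h = h,
                        m = m)
  }
  list(y = out, caches = caches)
}

.ca_bwd <- function(dY, caches, W0, W1, Tn, d_in) {
  dX <- dY * 0
  dW0 <- W0 * 0
  dW1 <- W1 * 0
  for (cc in caches) {
    rows <- cc$rows
    dYi <- dY[rows, , drop = FALSE]
    dX[rows, ] <- dYi * rep(cc$m, each = Tn)
    dm <- colSums(dYi * cc$Xi)
    dlog <- dm * cc$m * (1 - cc$m)
    dW1 <- dW1 + dlog %*% t(cc$h)
    dh <- drop(t(W1) %*% dlog)
    dW0 <- dW0 + dh %*% t(cc$s)
    ds <- drop(t(W0) %*% dh)
    # avg statistic spreads evenly over time; max statistic routes to argmax
    dX[rows, ] <- dX[rows, ] + rep(ds / Tn, each = Tn)
    tgt <- rows[cc$imax]
    dX[cbind(tgt, seq_len(d_in))] <- dX[cbind(tgt, seq_len(d_in))] + ds
  }
  list(dx = dX, dW0 = dW0, dW1 = dW1)
}

# One encoder layer (attention sublayer + feed-forward sublayer, both with
# residual + post-layer-norm) over a stacked batch.
.enc_fwd <- function(X, n, L, pa, nh, active, drop_p, training) {
  d <- ncol(X)
  dh <- d %/% nh
  Q <- .add_bias(X %*% pa$Wq, pa$bq)
  K <- .add_bias(X %*% pa$Wk, pa$bk)
  V <- .add_bias(X %*% pa$Wv, pa$bv)
  O <- matrix(0, nrow(X), d)
  .count_dots(n * length(active) * L)   # query-key pairs, shared across heads
  acache <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    hc <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      cf <- .attn_core_fwd(Q[rows, cols, drop = FALSE],
                           K[rows, cols, drop = FALSE],
                           V[rows, cols, drop = FALSE], active)
      O[rows, cols] <- cf$y
      hc[[h]] <- cf[c("A", "active")]
    }
    acache[[i]] <- hc
  }
  Y <- .add_bias(O %*% pa$Wo, pa$bo)
  do1 <- .dropout_fwd(Y, drop_p, training)
  ln1 <- .layernorm_fwd(X + do1$y, pa$`ln1.g`, pa$`ln1.b`)
  Z <- ln1$y
  P <- .add_bias(Z %*% pa$`ffn.W1`, pa$`ffn.b1`)
  H <- pmax(P, 0)
  Ff <- .add_bias(H %*% pa$`ffn.W2`, pa$`ffn.b2`)
  do2 <- .dropout_fwd(Ff, drop_p, training)
  ln2 <- .layernorm_fwd(Z + do2$y, pa$`ln2.g`, pa$`ln2.b`)
  list(y = ln2$y,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, acache = acache,
                    mask1 = do1$mask, ln1 = ln1$cache, Z = Z, P = P, H = H,
                    mask2 = do2$mask, ln2 = ln2$cache, n = n, L = L,
                    nh = nh, dh = dh))
}

.enc_bwd <- function(dOut, cache, pa) {
  n <- cache$n; L <- cache$L; nh <- cache$nh; dh <- cache$dh
  g <- list()
  l2 <- .layernorm_bwd(dOut, cache$ln2)
  g[["ln2.g"]] <- l2$dg; g[["ln2.b"]] <- l2$db
  dZ <- l2$dx
  dF <- .dropout_bwd(l2$dx, cache$mask2)
  dH <- tcrossprod(dF, pa$`ffn.W2`)
  g[["ffn.W2"]] <- crossprod(cache$H, dF); g[["ffn.b2"]] <- colSums(dF)
  dP <- dH * (cache$P > 0)
  g[["ffn.W1"]] <- crossprod(cache$Z, dP); g[["ffn.b1"]] <- colSums(dP)
  dZ <- dZ + tcrossprod(dP, pa$`ffn.W1`)
  l1 <- .layernorm_bwd(dZ, cache$ln1)
  g[["ln1.g"]] <- l1$dg; g[["ln1.b"]] <- l1$db
  dX <- l1$dx
  dY <- .dropout_bwd(l1$dx, cache$mask1)
  dO <- tcrossprod(dY, pa$Wo)
  g[["Wo"]] <- crossprod(cache$O, dY); g[["bo"]] <- colSums(dY)
  dQ <- dO * 0; dK <- dO * 0; dV <- dO * 0
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * L + 1L):(i * L)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      cb <- .attn_core_bwd(dO[rows, cols, drop = FALSE],
                           cache$acache[[i]][[h]],
                           cache$Q[rows, cols, drop = FALSE],
                           cache$K[rows, cols, drop = FALSE],
                           cache$V[rows, cols, drop = FALSE])
      dQ[rows, cols] <- cb$dQ
      dK[rows, cols] <- cb$dK
      dV[rows, cols] <- cb$dV
    }
  }
  X <- cache$X
  g[["Wq"]] <- crossprod(X, dQ); g[["bq"]] <- colSums(dQ)
  g[["Wk"]] <- crossprod(X, dK); g[["bk"]] <- colSums(dK)
  g[["Wv"]] <- crossprod(X, dV); g[["bv"]] <- colSums(dV)
  dX <- dX + tcrossprod(dQ, pa$Wq) + tcrossprod(dK, pa$Wk) +
    tcrossprod(dV, pa$Wv)
  list(dx = dX, grads = g)
}

# Full forward with caches (training path) or without (inference).
.model_fwd <- function(model, batch, training = FALSE, keep = training) {
  cfg <- model$config
  p <- model$params
  stopifnot(length(dim(batch)) == 3)
  n <- dim(batch)[1]; Tn <- dim(batch)[2]; Cc <- dim(batch)[3]
  if (Cc != cfg$in_channels)
    stop("batch has ", Cc, " channels but the model expects ",
         cfg$in_channels, call. = FALSE)
  tmin <- min_input_length(cfg)
  if (Tn < tmin)
    stop("epoch length ", Tn, " is too short for the distilling stack; ",
         "this configuration needs T >= ", tmin, call. = FALSE)
  plan <- layer_plan(cfg)
  caches <- list()
  X <- matrix(aperm(batch, c(2, 1, 3)), nrow = n * Tn)
  if (cfg$use_channel_attention) {
    ca <- .ca_fwd(X, n, Tn, p$`ca.W0`, p$`ca.W1`)
    X <- ca$y
    if (keep) caches$ca <- ca$caches
  }
  L <- Tn
  if (cfg$embed_conv) {
    emb <- .conv1d_fwd(X, n, L, p$`emb.W`, p$`emb.b`, cfg$conv_kernel)
  } else {
    emb <- .linear_fwd(X, p$`emb.W`, p$`emb.b`)
  }
  X <- emb$y
  if (keep) caches$emb <- emb$cache
  if (cfg$positional_encoding)
    X <- X + .position_codes(L, cfg$d_model)[rep(seq_len(L), n), ]
  caches$layers <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pre <- paste0("L", i, ".")
    pa <- stats::setNames(p[paste0(pre, .param_names_attn)],
                          .param_names_attn)
    active <- if (plan$type[i] == "sparse")
      select_active_queries(L, cfg$query_factor) else seq_len(L)
    ef <- .enc_fwd(X, n, L, pa, cfg$n_heads, active, cfg$dropout, training)
    X <- ef$y
    lc <- list(attn = if (keep) ef$cache, L_in = L, distill = NULL)
    if (plan$distill[i]) {
      cv <- .conv1d_fwd(X, n, L, p[[paste0(pre, "dist.W")]],
                        p[[paste0(pre, "dist.b")]], cfg$conv_kernel)
      el <- .elu_fwd(cv$y)
      mp <- .maxpool_fwd(el$y, n, L, cfg$pool_kernel, cfg$pool_stride,
                         cfg$pool_pad)
      X <- mp$y
      L <- mp$Lp
      if (keep) lc$distill <- list(conv = cv$cache, pre = el$cache,
                                   pool = mp$cache)
    }
    if (keep) caches$layers[[i]] <- lc
  }
  mp <- .meanpool_fwd(X, n, L)
  logits <- .add_bias(mp$y %*% p$`head.W`, p$`head.b`)
  if (keep) {
    caches$pool <- mp$cache
    caches$pooled <- mp$y
    caches$L_final <- L
  }
  list(logits = logits, caches = caches)
}

.model_bwd <- function(model, caches, dlogits) {
  cfg <- model$config
  p <- model$params
  plan <- layer_plan(cfg)
  g <- list()
  g[["head.W"]] <- crossprod(caches$pooled, dlogits)
  g[["head.b"]] <- colSums(dlogits)
  dX <- .meanpool_bwd(tcrossprod(dlogits, p$`head.W`), caches$pool)
  for (i in rev(seq_len(nrow(plan)))) {
    pre <- paste0("L", i, ".")
    lc <- caches$layers[[i]]
    if (!is.null(lc$distill)) {
      dX <- .maxpool_bwd(dX, lc$distill$pool)
      dX <- .elu_bwd(dX, lc$distill$pre)
      cb <- .conv1d_bwd(dX, lc$distill$conv, p[[paste0(pre, "dist.W")]])
      g[[paste0(pre, "dist.W")]] <- cb$dW
      g[[paste0(pre, "dist.b")]] <- cb$db
      dX <- cb$dx
    }
    pa <- stats::setNames(p[paste0(pre, .param_names_attn)],
                          .param_names_attn)
    eb <- .enc_bwd(dX, lc$attn, pa)
    for (nm in names(eb$grads)) g[[paste0(pre, nm)]] <- eb$grads[[nm]]
    dX <- eb$dx
  }
  # position codes are additive constants: gradient passes through
  if (cfg$embed_conv) {
    cb <- .conv1d_bwd(dX, caches$emb, p$`emb.W`)
    g[["emb.W"]] <- cb$dW; g[["emb.b"]] <- cb$db
    dX <- cb$dx
  } else {
    lb <- .linear_bwd(dX, caches$emb, p$`emb.W`)
    g[["emb.W"]] <- lb$dW; g[["emb.b"]] <- lb$db
    dX <- lb$dx
  }
  if (cfg$use_channel_attention) {
    Tn <- nrow(dX) / length(caches$ca)
    cab <- .ca_bwd(dX, caches$ca, p$`ca.W0`, p$`ca.W1`, Tn,
                   cfg$in_channels)
    g[["ca.W0"]] <- cab$dW0; g[["ca.W1"]] <- cab$dW1
  }
  g
}

#' Forward pass of the encoder stack
#'
#' Deterministic inference pass (dropout disabled): channel attention,
#' token embedding, interleaved attention/distilling layers, predictor.
#'
#' @param model An [init_model()] stack.
#' @param batch Numeric array `[N x T x C]`.
#' @return Logit matrix `[N x n_classes]`.
#' @export
model_forward <- function(model, batch) {
  stopifnot(inherits(model, "encoder_stack"))
  .model_fwd(model, batch, training = FALSE, keep = FALSE)$logits
}

#' Save / load a model checkpoint
#'
#' One portable file: a JSON header line embedding the full configuration
#' and a parameter manifest (names and shapes), followed by all parameter
#' values as little-endian float64. Configurations round-trip bit-exactly.
#'
#' @param model An [init_model()] stack.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the restored `encoder_stack`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "encoder_stack"))
  manifest <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(x)
      if (is.matrix(x)) dim(x) else length(x)))
  hdr <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, "\n")), con)
  for (x in model$params)
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  nl <- which(bytes == charToRaw("\n"))[1]
  manifest <- jsonlite::fromJSON(rawToChar(bytes[seq_len(nl - 1L)]),
                                 simplifyVector = TRUE)
  cfg <- do.call(model_config, as.list(manifest$config))
  vals <- readBin(bytes[(nl + 1L):length(bytes)], "numeric",
                  n = (length(bytes) - nl) %/% 8, size = 8,
                  endian = "little")
  params <- list()
  off <- 0L
  for (nm in names(manifest$params)) {
    shp <- manifest$params[[nm]]
    len <- prod(shp)
    x <- vals[(off + 1L):(off + len)]
    params[[nm]] <- if (length(shp) == 2) matrix(x, shp[1], shp[2]) else x
    off <- off + len
  }
  structure(list(config = cfg, params = params), class = "encoder_stack")
}
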
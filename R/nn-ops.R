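# Internal neural-network primitives. Batched activations are stored as a
# single stacked matrix [n*L x d] with sample-major contiguous row blocks
# (rows (i-1)*L + 1 ... i*L belong to sample i), so pointwise layers,
# projections and convolutions run as one BLAS call per batch. Every *_fwd
# returns list(y, cache); every *_bwd consumes the upstream gradient and the
# cache and returns the input gradient plus parameter gradients.

.add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

.linear_fwd <- function(X, W, b) {
  list(y = .add_bias(X %*% W, b), cache = X)
}

.linear_bwd <- function(dY, X, W) {
  list(dx = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

.layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = .add_bias(xhat * rep(g, each = nrow(X)), b),
       cache = list(xhat = xhat, inv = inv, g = g))
}

.layernorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- dY * rep(cache$g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = cache$inv * (dxhat - m1 - xhat * m2),
       dg = colSums(dY * xhat), db = colSums(dY))
}

.elu_fwd <- function(X) {
  # elu(x) = x for x > 0, expm1(x) otherwise; expm1(pmin(X, 0)) is 0 on the
  # positive part, so the sum form avoids any branching
  list(y = pmax(X, 0) + expm1(pmin(X, 0)), cache = X)
}

# d/dx elu = 1 for x > 0, exp(x) otherwise = exp(min(x, 0))
.elu_bwd <- function(dY, X) dY * exp(pmin(X, 0))

.dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(y = X * mask, mask = mask)
}

.dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# Sample-major index bookkeeping: t index of each stacked row, and the
# global row offset of each sample block.
.stack_t <- function(n, L) rep(seq_len(L), times = n)
.stack_base <- function(n, L) rep(seq(0L, by = L, length.out = n), each = L)

# 1-D convolution along time (odd kernel, "same" padding with zeros),
# implemented as im2col + one GEMM. W is [k*d_in x d_out] with kernel taps
# in block order (earliest tap first).
.conv1d_fwd <- function(X, n, L, W, b, k) {
  d_in <- ncol(X)
  hw <- (k - 1L) %/% 2L
  tvec <- .stack_t(n, L)
  base <- .stack_base(n, L)
  Xz <- rbind(0, X)                     # row 1 is the zero-padding row
  idx <- vector("list", k)
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    s <- j - 1L - hw
    tt <- tvec + s
    id <- base + tt
    id[tt < 1L | tt > L] <- 0L
    idx[[j]] <- id
    cols[[j]] <- Xz[id + 1L, , drop = FALSE]
  }
  Xcol <- do.call(cbind, cols)
  list(y = .add_bias(Xcol %*% W, b),
       cache = list(Xcol = Xcol, idx = idx, d_in = d_in, k = k,
                    nrows = nrow(X)))
}

.conv1d_bwd <- function(dY, cache, W) {
  k <- cache$k
  d_in <- cache$d_in
  dXcol <- dY %*% t(W)
  dX <- matrix(0, cache$nrows, d_in)
  for (j in seq_len(k)) {
    block <- dXcol[, ((j - 1L) * d_in + 1L):(j * d_in), drop = FALSE]
    id <- cache$idx[[j]]
    keep <- which(id > 0L)
    # within one tap the target rows are distinct, so indexed add is exact
    dX[id[keep], ] <- dX[id[keep], ] + block[keep, , drop = FALSE]
  }
  list(dx = dX, dW = crossprod(cache$Xcol, dY), db = colSums(dY))
}

# Max pooling along time with kernel k, stride s, padding p (pad value
# -Inf). Ties go to the earliest tap.
.maxpool_fwd <- function(X, n, L, k, s, p) {
  Lp <- .pool_out_len(L, k, s, p)
  if (L + 2L * p < k || Lp < 1L)
    stop("sequence too short for max pooling", call. = FALSE)
  tp <- rep(seq_len(Lp), times = n)
  base <- rep(seq(0L, by = L, length.out = n), each = Lp)
  Xneg <- rbind(-Inf, X)
  idx <- vector("list", k)
  cand <- vector("list", k)
  for (j in seq_len(k)) {
    pos <- (tp - 1L) * s - p + j
    id <- base + pos
    id[pos < 1L | pos > L] <- 0L
    idx[[j]] <- id
    cand[[j]] <- Xneg[id + 1L, , drop = FALSE]
  }
  M <- cand[[1]]
  for (j in seq_len(k)[-1]) M <- pmax(M, cand[[j]])
  taken <- matrix(FALSE, nrow(M), ncol(M))
  win <- vector("list", k)
  for (j in seq_len(k)) {
    w <- (cand[[j]] == M) & !taken & is.finite(M)
    win[[j]] <- w
    taken <- taken | w
  }
  list(y = M, Lp = Lp,
       cache = list(idx = idx, win = win, k = k, nrows = nrow(X),
                    d = ncol(X)))
}

.maxpool_bwd <- function(dY, cache) {
  dX <- matrix(0, cache$nrows, cache$d)
  for (j in seq_len(cache$k)) {
    contrib <- dY * cache$win[[j]]
    id <- cache$idx[[j]]
    keep <- which(id > 0L)
    dX[id[keep], ] <- dX[id[keep], ] + contrib[keep, , drop = FALSE]
  }
  dX
}

# Mean over time per sample (predictor pooling).
.meanpool_fwd <- function(X, n, L) {
  g <- rep(seq_len(n), each = L)
  list(y = rowsum(X, g, reorder = FALSE) / L, cache = list(n = n, L = L))
}

.meanpool_bwd <- function(dY, cache) {
  dY[rep(seq_len(cache$n), each = cache$L), , drop = FALSE] / cache$L
}

# Sinusoidal position codes: pe[t, j] alternates sin/cos of
# pos / 10000^(2*floor(j/2)/d); deterministic, non-learned.
.position_codes <- function(L, d) {
  pos <- seq_len(L) - 1
  j <- seq_len(d) - 1
  rates <- 1 / 10000^(2 * (j %/% 2) / d)
  ang <- outer(pos, rates)
  pe <- matrix(0, L, d)
  even <- j %% 2 == 0
  pe[, even] <- sin(ang[, even, drop = FALSE])
  pe[, !even] <- cos(ang[, !even, drop = FALSE])
  pe
}

.row_max <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]

.softmax_rows <- function(S) {
  E <- exp(S - .row_max(S))
  E / rowSums(E)
}

# Numerically stable softmax cross-entropy over logits [n x K] with labels
# in [0, K).
.softmax_ce <- function(logits, y) {
  n <- nrow(logits)
  Z <- logits - .row_max(logits)
  lse <- log(rowSums(exp(Z)))
  probs <- exp(Z - lse)
  picked <- Z[cbind(seq_len(n), y + 1L)] - lse
  dlogits <- probs
  dlogits[cbind(seq_len(n), y + 1L)] <- dlogits[cbind(seq_len(n), y + 1L)] - 1
  list(loss = -mean(picked), dlogits = dlogits / n, probs = probs)
}
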
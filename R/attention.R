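# Sparse (equidistant-query) self-attention. Only u = max(1, ceil(c*ln L))
# query positions, placed at equidistant intervals, attend over the full key
# set; every remaining "lazy" position is filled with the column mean of the
# value matrix. This is an exact assignment, not an approximation of the
# softmax row, and it cuts the query-key dot-product count from L_Q*L_K to
# u*L_K, i.e. O(L_K ln L_Q).

.cst_env <- new.env(parent = emptyenv())
.cst_env$dots <- 0

#' Query-key dot-product counter
#'
#' Every attention operation adds the number of query-key pairs it
#' evaluates to an internal counter (heads share one active set and score
#' each pair jointly, so a pair is counted once per attention layer and
#' sequence). A dense layer contributes `L_Q * L_K`; a sparse layer
#' contributes `u * L_K` with `u = max(1, ceiling(c * ln L_Q))`, which is
#' how the O(L_K ln L_Q) complexity claim is verified by instrumentation
#' rather than asymptotics.
#'
#' @return `dot_counter()` returns the current count;
#'   `reset_dot_counter()` zeroes it (invisibly returning the old value).
#' @export
dot_counter <- function() .cst_env$dots

#' @rdname dot_counter
#' @export
reset_dot_counter <- function() {
  old <- .cst_env$dots
  .cst_env$dots <- 0
  invisible(old)
}

.count_dots <- function(n) .cst_env$dots <- .cst_env$dots + n

#' Select the active (equidistant) query positions
#'
#' Chooses `u = max(1, ceiling(c * ln(L)))` positions at equidistant
#' intervals, `idx_k = floor(k * L / u)` for `k = 0, ..., u-1` (returned
#' 1-based). The selection depends only on `L` and `c` — never on the
#' content of the sequence — and is shared by all heads.
#'
#' @param L Sequence length (>= 1).
#' @param c Sampling factor (default 1).
#' @return Strictly increasing 1-based integer positions, all `<= L`.
#' @export
select_active_queries <- function(L, c = 1) {
  L <- as.integer(L)
  if (L < 1) stop("L must be at least 1", call. = FALSE)
  u <- max(1, ceiling(c * log(L)))
  u <- min(u, L)
  as.integer(floor((seq_len(u) - 1) * L / u)) + 1L
}

#' Dense (full) scaled dot-product attention
#'
#' The vanilla-transformer baseline: `softmax(Q K^T / sqrt(d)) V`, where
#' every output row is a convex combination of the rows of `V`.
#'
#' @param Q,K,V Numeric matrices with `ncol(Q) == ncol(K)` and
#'   `nrow(K) == nrow(V)`.
#' @return Matrix `[nrow(Q) x ncol(V)]`.
#' @export
dense_attention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  .count_dots(nrow(Q) * nrow(K))
  A <- .softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  A %*% V
}

#' Sparse attention with equidistant active queries
#'
#' Rows listed in `active` receive full attention over the complete key set
#' (identical to [dense_attention()] restricted to those query rows); every
#' other ("lazy") row is assigned the column mean of `V`. Only
#' `length(active) * nrow(K)` query-key dot products are computed.
#'
#' @param Q,K,V Numeric matrices as in [dense_attention()].
#' @param active 1-based active query indices, typically from
#'   [select_active_queries()].
#' @return Matrix `[nrow(Q) x ncol(V)]`.
#' @export
sparse_attention <- function(Q, K, V, active) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  active <- as.integer(active)
  if (anyDuplicated(active) || any(active < 1L) || any(active > nrow(Q)))
    stop("`active` must be distinct 1-based indices within 1..nrow(Q)",
         call. = FALSE)
  .count_dots(length(active) * nrow(K))
  out <- matrix(colMeans(V), nrow(Q), ncol(V), byrow = TRUE)
  if (length(active)) {
    A <- .softmax_rows(Q[active, , drop = FALSE] %*% t(K) / sqrt(ncol(Q)))
    out[active, ] <- A %*% V
  }
  out
}

# Internal attention core with cache for backprop. Returns output, the
# attention weights of the active rows and the active set.
.attn_core_fwd <- function(Q, K, V, active) {
  d <- ncol(Q)
  L <- nrow(Q)
  A <- .softmax_rows(Q[active, , drop = FALSE] %*% t(K) / sqrt(d))
  if (length(active) == L) {
    out <- A %*% V
  } else {
    out <- matrix(colMeans(V), L, ncol(V), byrow = TRUE)
    out[active, ] <- A %*% V
  }
  list(y = out, A = A, active = active)
}

.attn_core_bwd <- function(dY, cache, Q, K, V) {
  d <- ncol(Q)
  L <- nrow(Q)
  active <- cache$active
  A <- cache$A
  dOa <- dY[active, , drop = FALSE]
  dV <- crossprod(A, dOa)
  if (length(active) < L) {
    # lazy rows: each equals colMeans(V), so their gradient spreads evenly
    lazy <- setdiff(seq_len(L), active)
    dV <- dV + matrix(colSums(dY[lazy, , drop = FALSE]) / nrow(V),
                      nrow(V), ncol(V), byrow = TRUE)
  }
  dA <- tcrossprod(dOa, V)
  dS <- A * (dA - rowSums(dA * A))
  dQ <- matrix(0, L, d)
  dQ[active, ] <- dS %*% K / sqrt(d)
  dK <- crossprod(dS, Q[active, , drop = FALSE]) / sqrt(d)
  list(dQ = dQ, dK = dK, dV = dV)
}

#' Initialize a multi-head attention block
#'
#' @param d_model Model width; must be divisible by `n_heads`.
#' @param n_heads Number of heads.
#' @param seed Seed for uniform fan-in initialization.
#' @return A list of projection weights (`Wq`, `Wk`, `Wv`, `Wo` with
#'   biases) and layer-norm parameters, of class `attention_block`.
#' @export
init_attention_block <- function(d_model, n_heads, seed = 1L) {
  stopifnot(d_model %% n_heads == 0)
  .with_seed(seed, {
    mk <- function(n_in, n_out) {
      s <- 1 / sqrt(n_in)
      matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
    }
    structure(list(Wq = mk(d_model, d_model), bq = numeric(d_model),
                   Wk = mk(d_model, d_model), bk = numeric(d_model),
                   Wv = mk(d_model, d_model), bv = numeric(d_model),
                   Wo = mk(d_model, d_model), bo = numeric(d_model),
                   ln_g = rep(1, d_model), ln_b = numeric(d_model),
                   n_heads = as.integer(n_heads)),
              class = "attention_block")
  })
}

#' Multi-head self-attention with residual connection and layer norm
#'
#' Projects the sequence to per-head queries, keys and values, applies
#' sparse or dense attention per head (sparse heads share one active-query
#' set, chosen by position only), concatenates the heads, applies the
#' output projection, and returns `LayerNorm(X + attention(X))`.
#'
#' @param X Numeric matrix `[L x d_model]`.
#' @param block An [init_attention_block()].
#' @param sparse Use the equidistant sparse mechanism?
#' @param query_factor Sampling factor `c` for [select_active_queries()].
#' @return Matrix `[L x d_model]`.
#' @export
multi_head_attention <- function(X, block, sparse = FALSE, query_factor = 1) {
  stopifnot(inherits(block, "attention_block"),
            ncol(X) == ncol(block$Wq))
  L <- nrow(X)
  d_model <- ncol(X)
  nh <- block$n_heads
  dh <- d_model %/% nh
  Q <- .add_bias(X %*% block$Wq, block$bq)
  K <- .add_bias(X %*% block$Wk, block$bk)
  V <- .add_bias(X %*% block$Wv, block$bv)
  active <- if (sparse) select_active_queries(L, query_factor) else seq_len(L)
  .count_dots(length(active) * L)
  O <- matrix(0, L, d_model)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    O[, cols] <- .attn_core_fwd(Q[, cols, drop = FALSE],
                                K[, cols, drop = FALSE],
                                V[, cols, drop = FALSE], active)$y
  }
  Y <- .add_bias(O %*% block$Wo, block$bo)
  .layernorm_fwd(X + Y, block$ln_g, block$ln_b)$y
}
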
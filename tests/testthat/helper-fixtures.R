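# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive scalar loops so they share no code path with the package.

# Brute-force dense attention: row-by-row softmax over explicit dot products.
oracle_dense_attention <- function(Q, K, V) {
  d <- ncol(Q)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# Brute-force one-vs-rest confusion counts from labels and argmax
# predictions.
oracle_counts <- function(y, pred, K) {
  out <- data.frame(TP = integer(K), TN = integer(K), FP = integer(K),
                    FN = integer(K))
  for (k in seq_len(K) - 1L) {
    out$TP[k + 1] <- sum(y == k & pred == k)
    out$TN[k + 1] <- sum(y != k & pred != k)
    out$FP[k + 1] <- sum(y != k & pred == k)
    out$FN[k + 1] <- sum(y == k & pred != k)
  }
  out
}

# Rank-statistic (Mann-Whitney) ROC-AUC with midranks for ties.
oracle_auc_rank <- function(y, score) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Naive max-pool (kernel/stride/pad) along rows of a matrix.
oracle_maxpool <- function(X, k = 3, s = 2, p = 1) {
  L <- nrow(X)
  Lp <- (L + 2 * p - k) %/% s + 1
  out <- matrix(-Inf, Lp, ncol(X))
  for (tp in seq_len(Lp)) {
    for (j in seq_len(k)) {
      pos <- (tp - 1) * s - p + j
      if (pos >= 1 && pos <= L)
        out[tp, ] <- pmax(out[tp, ], X[pos, ])
    }
  }
  out
}

# A pure sinusoid recording.
sine_record <- function(freq, fs, dur_s, C = 1, amp = 1, offset = 0) {
  tt <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * tt) + offset
  eeg_record(matrix(rep(x, each = C), nrow = C), fs = fs)
}

rms_mid <- function(x) {
  n <- length(x)
  i <- seq(floor(n * 0.1) + 1, ceiling(n * 0.9))
  sqrt(mean(x[i]^2))
}

# Minimal architecture for fast structural and gradient tests.
tiny_model_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_classes = 2L, in_channels = 2L, n_sparse_layers = 1L,
         n_full_layers = 1L, n_heads = 2L, d_model = 8L, d_ff = 16L,
         n_conv_layers = 2L, dropout = 0, seed = 3L),
    list(...))
  do.call(model_config, args)
}

# A small, easily separable two-class task (T = 64).
tiny_task_spec <- function(n_per_class = 30L, seed = 5L) {
  generator_spec(
    C = 2L, fs = 32, window_s = 2, n_per_class = n_per_class,
    class_specs = list(
      class_spec("a", band = c(4, 6), target_channels = 1L,
                 amplitude_gain = 3),
      class_spec("b", band = c(10, 12), target_channels = 2L,
                 amplitude_gain = 3)),
    noise_exponent = 1, seed = seed)
}

random_epoch_set <- function(n, Tn, C, K = 2L, seed = 1L) {
  set.seed(seed)
  epoch_set(array(rnorm(n * Tn * C), c(n, Tn, C)),
            labels = rep_len(seq_len(K) - 1L, n), fs = 32,
            class_names = as.character(seq_len(K) - 1L),
            group_ids = paste0("G", rep_len(1:4, n)))
}
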
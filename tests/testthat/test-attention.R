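test_that("equidistant query selection matches the floor rule", {
  expect_equal(select_active_queries(1), 1L)
  expect_equal(select_active_queries(1, 100), 1L)
  # L = 8, c = 1: u = ceil(ln 8) = 3, positions floor(k*8/3) -> 0, 2, 5
  expect_equal(select_active_queries(8), c(1L, 3L, 6L))
  # L = 1024: u = 7, floor(k*1024/7)
  idx <- select_active_queries(1024)
  expect_equal(idx, c(0L, 146L, 292L, 438L, 585L, 731L, 877L) + 1L)
  for (L in c(2, 13, 100, 501)) {
    for (cc in c(0.5, 1, 2)) {
      a <- select_active_queries(L, cc)
      expect_true(all(diff(a) > 0))
      expect_true(all(a >= 1 & a <= L))
      expect_equal(length(a), min(L, max(1, ceiling(cc * log(L)))))
    }
  }
})

test_that("dense attention matches the scalar-loop oracle", {
  set.seed(21)
  Q <- matrix(rnorm(24), 6, 4)
  K <- matrix(rnorm(24), 6, 4)
  V <- matrix(rnorm(24), 6, 4)
  expect_equal(dense_attention(Q, K, V), oracle_dense_attention(Q, K, V),
               tolerance = 1e-6)
  # zero queries: uniform weights, every row is the column mean of V
  out0 <- dense_attention(Q * 0, K, V)
  expect_equal(out0, matrix(colMeans(V), 6, 4, byrow = TRUE),
               tolerance = 1e-12)
  # single key: output repeats the single value row
  out1 <- dense_attention(Q, K[1, , drop = FALSE], V[1, , drop = FALSE])
  expect_equal(out1, matrix(V[1, ], 6, 4, byrow = TRUE), tolerance = 1e-12)
})

test_that("sparse attention: active rows dense, lazy rows mean(V)", {
  set.seed(22)
  for (rep in 1:30) {
    L <- sample(2:32, 1)
    d <- sample(2:8, 1)
    Q <- matrix(rnorm(L * d), L, d)
    K <- matrix(rnorm(L * d), L, d)
    V <- matrix(rnorm(L * d), L, d)
    dense <- oracle_dense_attention(Q, K, V)
    expect_equal(sparse_attention(Q, K, V, seq_len(L)), dense,
                 tolerance = 1e-5)
    active <- select_active_queries(L)
    out <- sparse_attention(Q, K, V, active)
    expect_equal(out[active, , drop = FALSE],
                 dense[active, , drop = FALSE], tolerance = 1e-5)
    lazy <- setdiff(seq_len(L), active)
    if (length(lazy))
      expect_identical(out[lazy, , drop = FALSE],
                       matrix(colMeans(V), length(lazy), d, byrow = TRUE))
  }
  Q <- matrix(rnorm(8), 4, 2)
  expect_error(sparse_attention(Q, Q, Q, c(1L, 1L)), "distinct")
  expect_error(sparse_attention(Q, Q, Q, 5L), "distinct")
})

test_that("dot-product counter certifies the O(L ln L) complexity", {
  L <- 1024L
  Q <- matrix(rnorm(L * 4), L, 4)
  reset_dot_counter()
  invisible(sparse_attention(Q, Q, Q, select_active_queries(L)))
  sparse_dots <- dot_counter()
  expect_equal(sparse_dots, 7L * 1024L)
  reset_dot_counter()
  invisible(dense_attention(Q, Q, Q))
  dense_dots <- dot_counter()
  expect_equal(dense_dots, 1024L * 1024L)
  expect_equal(sparse_dots / dense_dots, 7 / 1024)
  reset_dot_counter()
})

test_that("multi-head attention reduces to dense + residual + layer norm", {
  set.seed(23)
  d <- 6L
  X <- matrix(rnorm(10 * d), 10, d)
  block <- init_attention_block(d, 1L, seed = 1)
  block$Wq <- block$Wk <- block$Wv <- block$Wo <- diag(d)
  out <- multi_head_attention(X, block, sparse = FALSE)
  ref <- X + oracle_dense_attention(X, X, X)
  mu <- rowMeans(ref)
  sdv <- sqrt(rowMeans((ref - mu)^2) + 1e-5)
  expect_equal(out, (ref - mu) / sdv, tolerance = 1e-6)
})

test_that("multi-head output keeps the reference width and is deterministic", {
  set.seed(24)
  block <- init_attention_block(128L, 8L, seed = 5)
  for (L in c(1L, 7L, 40L)) {
    X <- matrix(rnorm(L * 128), L, 128)
    out <- multi_head_attention(X, block, sparse = TRUE)
    expect_equal(dim(out), c(L, 128L))
    expect_identical(out, multi_head_attention(X, block, sparse = TRUE))
  }
})
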
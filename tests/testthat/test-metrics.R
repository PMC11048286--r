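test_that("binary counts reproduce the textbook arithmetic", {
  # TP=3 TN=5 FP=1 FN=1: 4 positives (3 found), 6 negatives (5 kept)
  y <- c(rep(1L, 4), rep(0L, 6))
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  scores <- cbind(1 - pred, pred)
  m <- compute_metrics(y, scores)
  expect_equal(m$per_class$TP[2], 3L)
  expect_equal(m$per_class$TN[2], 5L)
  expect_equal(m$per_class$FP[2], 1L)
  expect_equal(m$per_class$FN[2], 1L)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(unname(rowSums(m$confusion)),
               as.integer(table(factor(y, levels = 0:1))))
})

test_that("ROC-AUC hits 1 on perfect separation and 0.5 on constants", {
  y <- rep(c(0L, 1L), each = 10)
  perfect <- cbind(1 - y, y) + matrix(runif(40, 0, 0.4), 20, 2) * 0
  sep <- cbind(seq(0.9, 0.1, length.out = 20), seq(0.1, 0.9, length.out = 20))
  expect_equal(compute_metrics(y, sep)$roc_auc, 1.0)
  const <- matrix(0.5, 20, 2)
  expect_equal(compute_metrics(y, const)$roc_auc, 0.5)
})

test_that("metric suite matches brute-force counting on random vectors", {
  set.seed(41)
  for (rep in 1:100) {
    K <- sample(2:4, 1)
    n <- sample(10:40, 1)
    y <- sample(0:(K - 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    scores <- matrix(runif(n * K), n, K)
    m <- compute_metrics(y, scores)
    pred <- max.col(scores, ties.method = "first") - 1L
    oc <- oracle_counts(y, pred, K)
    expect_equal(m$per_class$TP, oc$TP)
    expect_equal(m$per_class$TN, oc$TN)
    expect_equal(m$per_class$FP, oc$FP)
    expect_equal(m$per_class$FN, oc$FN)
    expect_equal(m$accuracy, mean(pred == y), tolerance = 1e-9)
    # every one-vs-rest slice partitions the sample
    expect_true(all(oc$TP + oc$TN + oc$FP + oc$FN == n))
    prec <- ifelse(oc$TP + oc$FP > 0, oc$TP / (oc$TP + oc$FP), 0)
    rec <- ifelse(oc$TP + oc$FN > 0, oc$TP / (oc$TP + oc$FN), 0)
    if (K == 2) {
      expect_equal(m$precision, prec[2], tolerance = 1e-9)
      expect_equal(m$recall, rec[2], tolerance = 1e-9)
    } else {
      expect_equal(m$precision, mean(prec), tolerance = 1e-9)
      expect_equal(m$recall, mean(rec), tolerance = 1e-9)
    }
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")])
                    >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")])
                    <= 1))
  }
})

test_that("trapezoid ROC-AUC equals the rank-statistic identity", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(8:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    score <- round(runif(n), sample(1:3, 1))   # coarse rounding forces ties
    m <- compute_metrics(y, cbind(1 - score, score))
    expect_equal(m$roc_auc, oracle_auc_rank(y, score), tolerance = 1e-9)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    y <- rbinom(100, 1, 0.4)
    score <- runif(100) + y * 0.3
    m <- compute_metrics(y, cbind(1 - score, score))
    ref <- as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(m$roc_auc, ref, tolerance = 1e-9)
  }
})

test_that("degenerate inputs are handled explicitly", {
  y <- rep(1L, 5)
  scores <- matrix(runif(10), 5, 2)
  expect_warning(m <- compute_metrics(y, scores), "single class")
  expect_true(is.na(m$roc_auc))
  # zero-division convention: empty prediction class scores precision 0
  y2 <- c(0L, 0L, 1L, 1L)
  s2 <- cbind(c(.9, .8, .7, .6), c(.1, .2, .3, .4))  # never predicts class 1
  m2 <- compute_metrics(y2, s2)
  expect_equal(m2$precision, 0)
  expect_equal(m2$recall, 0)
  expect_equal(m2$f1, 0)
})
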
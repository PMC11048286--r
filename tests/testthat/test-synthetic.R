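band_power <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
}

test_that("flat-spectrum background (beta = 0) has balanced band power", {
  spec <- generator_spec(C = 1, fs = 64, window_s = 16, n_per_class = 1,
                         class_specs = list(class_spec("x", c(5, 6), 1L, 0)),
                         noise_exponent = 0, seed = 1)
  ratios <- vapply(1:100, function(s) {
    bg <- make_background(spec, seed = s)
    band_power(bg[, 1], 64, 1, 8) / band_power(bg[, 1], 64, 24, 31)
  }, 0)
  expect_gt(mean(ratios), 0.5)
  expect_lt(mean(ratios), 2)
})

test_that("background is reproducible with unit variance per channel", {
  spec <- generator_spec(C = 3, fs = 128, window_s = 16, n_per_class = 1,
                         class_specs = list(class_spec("x", c(5, 6), 1L, 0)),
                         noise_exponent = 1, seed = 9)
  bg1 <- make_background(spec)
  bg2 <- make_background(spec)
  expect_identical(bg1, bg2)
  expect_equal(dim(bg1), c(2048L, 3L))
  expect_true(all(abs(apply(bg1, 2, sd) - 1) < 0.1))
  expect_true(all(abs(colMeans(bg1)) < 1e-10))
})

test_that("signatures hit the target channels only, with a spectral peak", {
  spec <- generator_spec(C = 4, fs = 128, window_s = 8, n_per_class = 1,
                         class_specs = list(class_spec("alpha", c(9.5, 10.5),
                                                       c(1L, 2L), 3)),
                         seed = 2)
  bg <- make_background(spec)
  out <- inject_signature(bg, spec$class_specs[[1]], spec$fs, seed = 3)
  expect_identical(out[, 3:4], bg[, 3:4])
  for (ch in 1:2) {
    peak <- band_power(out[, ch], 128, 9, 11)
    backg <- band_power(bg[, ch], 128, 9, 11)
    expect_gt(10 * log10(peak / backg), 6)
  }
  # zero gain: untouched
  null_cls <- class_spec("null", c(9, 11), c(1L, 2L), 0)
  expect_identical(inject_signature(bg, null_cls, spec$fs, seed = 3), bg)
})

test_that("realized burst counts are Poisson-consistent", {
  cls <- class_spec("ictal", c(2.5, 3.5), 1L, 1,
                    burst = list(rate = 0.2, duration = 2, spike_freq = 3))
  spec <- generator_spec(C = 1, fs = 64, window_s = 16, n_per_class = 1,
                         class_specs = list(cls), seed = 1)
  bg <- make_background(spec)
  counts <- vapply(1:50, function(s)
    attr(inject_signature(bg, cls, 64, seed = s), "n_bursts"), 0L)
  total <- sum(counts)
  ci <- qpois(c(0.005, 0.995), 50 * 0.2 * 16)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
})

test_that("make_dataset is balanced, reproducible and finite", {
  spec <- tiny_task_spec(n_per_class = 50L, seed = 4L)
  es <- make_dataset(spec)
  expect_equal(n_epochs(es), 100L)
  expect_equal(as.integer(table(es$labels)), c(50L, 50L))
  expect_true(all(is.finite(es$epochs)))
  es2 <- make_dataset(spec)
  expect_identical(es$epochs, es2$epochs)
  expect_identical(es$labels, es2$labels)
})

test_that("band-power separation is discriminative and grows with gain", {
  fisher <- function(gain) {
    spec <- generator_spec(
      C = 2, fs = 64, window_s = 2, n_per_class = 40,
      class_specs = list(
        class_spec("a", c(4, 6), 1L, gain),
        class_spec("b", c(10, 12), 1L, gain)),
      noise_exponent = 1, snr = 1, seed = 11)
    es <- make_dataset(spec)
    feat <- vapply(seq_len(n_epochs(es)), function(i)
      band_power(es$epochs[i, , 1], 64, 4, 6), 0)
    m <- tapply(feat, es$labels, mean)
    v <- tapply(feat, es$labels, var)
    (m[1] - m[2])^2 / (v[1] + v[2])
  }
  f <- vapply(c(1, 2, 3), fisher, 0)
  expect_gt(f[3], 1)            # gain 3 is clearly separable
  expect_true(all(diff(f) > 0)) # separation grows monotonically with gain
})
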
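test_that("EDF round trip preserves shape, rate, names and values", {
  set.seed(10)
  rec <- eeg_record(matrix(rnorm(2 * 2560, sd = 30), nrow = 2), fs = 256,
                    channel_names = c("Fp1", "Fp2"), subject_id = "S01")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  r2 <- read_edf(path)
  expect_equal(nrow(r2$data), 2L)
  expect_equal(ncol(r2$data), 2560L)
  expect_equal(r2$fs, 256)
  expect_equal(r2$channel_names, c("Fp1", "Fp2"))
  expect_equal(r2$subject_id, "S01")
  # 16-bit quantization: error bounded by one digital step
  step <- (max(rec$data) - min(rec$data) + 2) / 65535
  expect_lt(max(abs(r2$data - rec$data)), step)
})

test_that("EDF+ annotations survive a round trip", {
  rec <- eeg_record(matrix(rnorm(1024), nrow = 2), fs = 256,
                    annotations = data.frame(onset = c(0.5, 1.25),
                                             duration = c(0.4, 0.1),
                                             label = c("seizure", "artifact")))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  ann <- read_edf(path)$annotations
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$onset, c(0.5, 1.25))
  expect_equal(ann$duration, c(0.4, 0.1))
  expect_equal(ann$label, c("seizure", "artifact"))
})

test_that("corrupt EDF inputs raise format errors", {
  path <- withr::local_tempfile(fileext = ".edf")
  # truncated: write a valid file, then chop its data section
  rec <- eeg_record(matrix(rnorm(512), nrow = 2), fs = 256)
  write_edf(rec, path)
  full <- readBin(path, "raw", file.info(path)$size)
  writeBin(full[1:(length(full) - 100)], path)
  expect_error(read_edf(path), "truncated")
  # garbage header
  writeBin(charToRaw(paste(rep("x", 300), collapse = "")), path)
  expect_error(read_edf(path), "format error")
  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "not found")
})

test_that("mixed per-channel sampling rates are rejected", {
  path <- withr::local_tempfile(fileext = ".edf")
  rec <- eeg_record(matrix(rnorm(2 * 512), nrow = 2), fs = 256)
  write_edf(rec, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  # patch signal 2's samples-per-record field (field-major header layout)
  ns <- 2L
  off <- 256L + 216L * ns + 8L   # second signal's nsamp field
  bytes[(off + 1):(off + 8)] <- charToRaw(sprintf("%-8s", "128"))
  writeBin(bytes, path)
  expect_error(read_edf(path), "rates differ")
})

test_that("generic CSV reader uses the sidecar rate", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec.csv")
  df <- data.frame(C3 = rnorm(64), C4 = rnorm(64))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = 32, subject_id = "S9"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  rec <- read_eeg_csv(path)
  expect_equal(rec$fs, 32)
  expect_equal(rec$subject_id, "S9")
  expect_equal(rec$data[1, ], df$C3, ignore_attr = TRUE)
  expect_error(read_eeg_csv(file.path(dir, "missing.csv")), "not found")
})
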
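# Zero-phase Butterworth filtering. Filters are designed with signal::butter
# and applied forward-backward (signal::filtfilt), so the effective magnitude
# response is |H|^2 and the phase is zero. The band-pass is realized as an
# order-4 high-pass cascaded with an order-4 low-pass: with passband edges as
# extreme as 0.1 Hz at EEG rates, a direct transfer-function band-pass is
# numerically fragile, while the cascade is stable and has a clean analytic
# magnitude.

.butter_order <- 4L

# Zero-phase filtering with endpoint handling: the signal is padded by odd
# reflection (continuous in value and slope), each pass starts DC-matched
# (the constant component is removed before filtering and restored through
# the filter's DC gain), and the filter runs forward then backward over the
# padded signal. This keeps step/drift transients out of the retained
# segment; a constant input through a high-pass maps to exactly zero.
.filtfilt1 <- function(flt, x) {
  b <- flt$b
  a <- flt$a
  n <- length(x)
  np <- min(n - 1L, max(64L, 12L * (length(a) - 1L)))
  ext <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  g0 <- sum(b) / sum(a)
  pass <- function(z) as.numeric(signal::filter(b, a, z - z[1])) + z[1] * g0
  y <- pass(ext)
  y <- rev(pass(rev(y)))
  y[(np + 1):(np + n)]
}

.filtfilt_rows <- function(data, flt) {
  out <- t(apply(data, 1, function(ch) .filtfilt1(flt, ch)))
  storage.mode(out) <- "double"
  out
}

#' Band-pass filter a recording (zero phase)
#'
#' Order-4 Butterworth high-pass at `lo` followed by an order-4 Butterworth
#' low-pass at `hi`, each applied forward and backward. The standard wideband
#' EEG setting is 0.1--70 Hz, which keeps delta (0.5--4), theta (4--8),
#' alpha (8--13), beta (13--30) and gamma (30--70 Hz) activity while removing
#' drifts and high-frequency noise.
#'
#' @param rec An [eeg_record()].
#' @param lo,hi Passband edges in Hz, `0 < lo < hi < fs/2`.
#' @return A filtered copy of `rec` with identical shape.
#' @export
bandpass_filter <- function(rec, lo, hi) {
  stopifnot(inherits(rec, "eeg_record"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq) stop("high cutoff must be below the Nyquist frequency (",
                      nyq, " Hz)", call. = FALSE)
  hp <- signal::butter(.butter_order, lo / nyq, type = "high")
  lp <- signal::butter(.butter_order, hi / nyq, type = "low")
  out <- rec
  out$data <- .filtfilt_rows(.filtfilt_rows(rec$data, hp), lp)
  out
}

#' High-pass filter a recording (zero phase)
#'
#' Order-4 Butterworth high-pass applied forward and backward. A 0.5 Hz
#' cutoff is the usual choice for removing slow baseline drifts and DC
#' offsets from neonatal EEG.
#'
#' @param rec An [eeg_record()].
#' @param cutoff Cutoff frequency in Hz, `0 < cutoff < fs/2`.
#' @return A filtered copy of `rec` with identical shape.
#' @export
highpass_filter <- function(rec, cutoff) {
  stopifnot(inherits(rec, "eeg_record"))
  nyq <- rec$fs / 2
  if (!(cutoff > 0)) stop("cutoff must be positive", call. = FALSE)
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency (",
                          nyq, " Hz)", call. = FALSE)
  hp <- signal::butter(.butter_order, cutoff / nyq, type = "high")
  out <- rec
  out$data <- .filtfilt_rows(rec$data, hp)
  out
}

#' Analytic magnitude response of the package's zero-phase filters
#'
#' Returns the squared Butterworth magnitude (the forward-backward response)
#' at frequency `f`, using the bilinear-transform prewarped analog cutoffs of
#' the digital designs, so tests can compare measured attenuation against a
#' closed form.
#'
#' @param f Frequency in Hz (vectorized).
#' @param fs Sampling rate in Hz.
#' @param lo,hi Passband edges; use `lo = NULL` for a pure low-pass or
#'   `hi = NULL` for a pure high-pass.
#' @return Amplitude gain of the zero-phase (forward-backward) filter at
#'   `f`: the squared single-pass Butterworth magnitude, on a linear scale
#'   (convert with `20*log10()` for dB).
#' @export
filter_response <- function(f, fs, lo = NULL, hi = NULL) {
  n <- .butter_order
  warp <- function(fc) tan(pi * fc / fs)      # prewarped analog frequency
  w <- warp(f)
  h2 <- rep(1, length(f))
  if (!is.null(hi)) {                          # low-pass section at hi
    wc <- warp(hi)
    h2 <- h2 * 1 / (1 + (w / wc)^(2 * n))
  }
  if (!is.null(lo)) {                          # high-pass section at lo
    wc <- warp(lo)
    h2 <- h2 * (w / wc)^(2 * n) / (1 + (w / wc)^(2 * n))
  }
  h2                                           # |H|^2: filtfilt squares |H|
}
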
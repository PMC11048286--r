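#' Segmentation specification
#'
#' Defines how a continuous recording is cut into fixed-length epochs: each
#' epoch carries `window_s * fs * channels` data points.
#'
#' @param window_s Window length in seconds.
#' @param fs Sampling rate in Hz; must match the recording's rate.
#' @param channels Expected channel count.
#' @return An object of class `segmentation_spec`.
#' @export
segmentation_spec <- function(window_s, fs, channels) {
  n <- window_s * fs
  if (!isTRUE(all.equal(n, round(n))) || n <= 0)
    stop("window_s * fs must be a positive integer (got ", n, ")",
         call. = FALSE)
  structure(list(window_s = window_s, fs = fs, channels = as.integer(channels),
                 samples = as.integer(round(n))),
            class = "segmentation_spec")
}

#' Constant labeling rule
#'
#' @param label Integer class label assigned to every window.
#' @return A labeling function `f(rec, interval) -> label` for
#'   [segment_record()].
#' @export
label_constant <- function(label) {
  force(label)
  function(rec, interval) as.integer(label)
}

#' Annotation-overlap labeling rule
#'
#' A window is labeled positive (1) when annotated events with a matching
#' label overlap at least `min_overlap` of the window, else negative (0).
#' This is the usual rule for deriving seizure/non-seizure epoch labels from
#' expert annotations.
#'
#' @param positive Annotation label(s) counted as positive events.
#' @param min_overlap Minimum fraction of the window that must be covered
#'   (default 0.5).
#' @return A labeling function for [segment_record()].
#' @export
label_by_annotation <- function(positive = "seizure", min_overlap = 0.5) {
  force(positive); force(min_overlap)
  function(rec, interval) {
    ann <- rec$annotations
    ann <- ann[ann$label %in% positive, , drop = FALSE]
    if (!nrow(ann)) return(0L)
    a0 <- ann$onset
    a1 <- ann$onset + ann$duration
    ov <- pmax(0, pmin(a1, interval[2]) - pmax(a0, interval[1]))
    as.integer(sum(ov) >= min_overlap * (interval[2] - interval[1]))
  }
}

#' Segment a recording into fixed-length labeled epochs
#'
#' Cuts non-overlapping consecutive windows from the start of the recording;
#' a trailing partial window is dropped. Each window is labeled by
#' `label_fn(rec, c(t0, t1))` with times in seconds.
#'
#' @param rec An [eeg_record()].
#' @param spec A [segmentation_spec()]; its `fs` must equal `rec$fs`.
#' @param label_fn Labeling function; default labels every window 0.
#' @param class_names Optional class names for the resulting
#'   [epoch_set()].
#' @return An [epoch_set()] with `floor(duration / window_s)` epochs of
#'   shape `window_s * fs` samples by `channels`; a recording shorter than
#'   one window yields an empty set.
#' @export
segment_record <- function(rec, spec, label_fn = label_constant(0L),
                           class_names = NULL) {
  stopifnot(inherits(rec, "eeg_record"), inherits(spec, "segmentation_spec"))
  if (!isTRUE(all.equal(spec$fs, rec$fs)))
    stop("spec$fs (", spec$fs, ") does not match recording rate (", rec$fs,
         ")", call. = FALSE)
  if (nrow(rec$data) != spec$channels)
    stop("recording has ", nrow(rec$data), " channels, spec expects ",
         spec$channels, call. = FALSE)
  Tw <- spec$samples
  n_ep <- ncol(rec$data) %/% Tw
  C <- nrow(rec$data)
  epochs <- array(0, dim = c(n_ep, Tw, C))
  labels <- integer(n_ep)
  for (i in seq_len(n_ep)) {
    cols <- ((i - 1) * Tw + 1):(i * Tw)
    epochs[i, , ] <- t(rec$data[, cols, drop = FALSE])
    labels[i] <- label_fn(rec, c((i - 1) * spec$window_s, i * spec$window_s))
  }
  if (is.null(class_names))
    class_names <- as.character(seq_len(max(1L, if (n_ep) max(labels) + 1L else 1L)) - 1L)
  epoch_set(epochs, labels, fs = rec$fs, class_names = class_names,
            group_ids = rep(rec$subject_id, n_ep))
}
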
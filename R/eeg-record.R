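#' Construct an EEG recording object
#'
#' An `eeg_record` holds one continuous multichannel recording: a
#' channels-by-samples matrix of physical amplitudes (microvolts), the
#' sampling rate in Hz, channel labels, a subject identifier and optional
#' event annotations.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector, one label per channel. Defaults to
#'   `"CH1"`, `"CH2"`, ...
#' @param subject_id Subject or recording identifier string.
#' @param annotations Optional data frame with columns `onset` (seconds from
#'   recording start), `duration` (seconds) and `label` (character), e.g.
#'   expert seizure marks.
#' @return An object of class `eeg_record`.
#' @examples
#' rec <- eeg_record(matrix(rnorm(512), nrow = 2), fs = 256)
#' duration(rec)
#' @export
eeg_record <- function(data, fs, channel_names = NULL, subject_id = "S1",
                       annotations = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  if (nrow(data) < 1L)
    stop("recording must have at least one channel", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  if (is.null(annotations)) {
    annotations <- data.frame(onset = numeric(0), duration = numeric(0),
                              label = character(0), stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    stopifnot(all(c("onset", "duration", "label") %in% names(annotations)))
    dur <- ncol(data) / fs
    if (nrow(annotations) &&
        any(annotations$onset < 0 | annotations$onset > dur))
      stop("annotation onsets must lie within [0, duration]", call. = FALSE)
  }
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id),
         annotations = annotations),
    class = "eeg_record"
  )
}

#' Recording duration in seconds
#' @param rec An [eeg_record()].
#' @return Duration in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_record"))
  ncol(rec$data) / rec$fs
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, duration(x)))
  if (nrow(x$annotations))
    cat(sprintf("  %d annotation(s): %s\n", nrow(x$annotations),
                paste(utils::head(unique(x$annotations$label), 5),
                      collapse = ", ")))
  invisible(x)
}

#' Read a generic CSV recording (one channel per column)
#'
#' Reads a plain CSV file whose columns are channels and rows are samples.
#' The sampling rate comes from `fs` or, if missing, from a JSON sidecar
#' `<path>.json` with fields `fs` and optionally `channel_names` and
#' `subject_id`.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; if `NULL`, read from the sidecar.
#' @param subject_id Optional subject identifier (defaults to file name).
#' @return An [eeg_record()].
#' @export
read_eeg_csv <- function(path, fs = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs)) stop("sampling rate not given and no sidecar found for ", path,
                        call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  ch <- if (!is.null(meta$channel_names)) meta$channel_names else names(df)
  if (is.null(subject_id))
    subject_id <- if (!is.null(meta$subject_id)) meta$subject_id
                  else tools::file_path_sans_ext(basename(path))
  eeg_record(t(as.matrix(df)), fs = fs, channel_names = ch,
             subject_id = subject_id)
}
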
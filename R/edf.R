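# Minimal EDF/EDF+ reader and writer. EDF stores an ASCII header, a set of
# per-signal ASCII subheaders (field-major), then data records of 16-bit
# little-endian integers; EDF+ adds an "EDF Annotations" signal carrying
# time-stamped annotation lists (TALs). Only equal sampling rates across
# ordinary signals are supported.

.edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

.edf_num <- function(raw, what) {
  s <- trimws(rawToChar(raw))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("EDF format error: unreadable ", what, " field", call. = FALSE)
  v
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, converts the 16-bit digital values of every ordinary
#' signal to physical units using the per-signal calibration fields, and
#' collects EDF+ annotations (onset, duration, label) if an
#' `"EDF Annotations"` signal is present.
#'
#' @param path Path to an EDF or EDF+ file.
#' @return An [eeg_record()]; `data` is in the file's physical units
#'   (microvolts for standard EEG exports).
#' @details All ordinary signals must share one sampling rate; files with
#'   mixed per-signal rates are rejected. Truncated files raise a format
#'   error.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 256) stop("EDF format error: file shorter than header", call. = FALSE)
  hdr <- readBin(con, "raw", 256)
  field <- function(off, len) hdr[(off + 1):(off + len)]
  patient <- trimws(rawToChar(field(8, 80)))
  n_rec <- .edf_num(field(236, 8), "record count")
  rec_dur <- .edf_num(field(244, 8), "record duration")
  ns <- as.integer(.edf_num(field(252, 4), "signal count"))
  if (ns < 1) stop("EDF format error: no signals", call. = FALSE)
  if (sz < 256 * (ns + 1))
    stop("EDF format error: truncated signal header", call. = FALSE)
  sig <- readBin(con, "raw", 256 * ns)
  sfield <- function(off, len, i) {
    base <- off * ns + (i - 1) * len
    trimws(rawToChar(sig[(base + 1):(base + len)]))
  }
  labels <- vapply(seq_len(ns), function(i) sfield(0, 16, i), "")
  # offsets within the field-major signal header block (per EDF layout):
  # label 16, transducer 80, dim 8, phys min 8, phys max 8, dig min 8,
  # dig max 8, prefilter 80, samples/record 8, reserved 32
  off <- c(label = 0, transducer = 16 * ns, dim = 96 * ns, pmin = 104 * ns,
           pmax = 112 * ns, dmin = 120 * ns, dmax = 128 * ns,
           prefilter = 136 * ns, nsamp = 216 * ns)
  getf <- function(key, len, i) {
    base <- off[[key]] + (i - 1) * len
    trimws(rawToChar(sig[(base + 1):(base + len)]))
  }
  num <- function(key, len, i) {
    v <- suppressWarnings(as.numeric(getf(key, len, i)))
    if (is.na(v)) stop("EDF format error: bad signal header", call. = FALSE)
    v
  }
  pmin <- vapply(seq_len(ns), function(i) num("pmin", 8, i), 0)
  pmax <- vapply(seq_len(ns), function(i) num("pmax", 8, i), 0)
  dmin <- vapply(seq_len(ns), function(i) num("dmin", 8, i), 0)
  dmax <- vapply(seq_len(ns), function(i) num("dmax", 8, i), 0)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(num("nsamp", 8, i)), 0L)
  is_ann <- labels == "EDF Annotations"
  ord <- which(!is_ann)
  if (!length(ord)) stop("EDF format error: no data signals", call. = FALSE)
  if (length(unique(nsamp[ord])) != 1L)
    stop("unsupported EDF: per-channel sampling rates differ", call. = FALSE)
  if (n_rec < 0) stop("EDF format error: unknown record count", call. = FALSE)
  rec_bytes <- sum(nsamp) * 2L
  expected <- 256 * (ns + 1) + n_rec * rec_bytes
  if (sz < expected)
    stop("EDF format error: file truncated (expected ", expected,
         " bytes, found ", sz, ")", call. = FALSE)
  fs <- nsamp[ord[1]] / rec_dur
  data <- matrix(0, nrow = length(ord), ncol = n_rec * nsamp[ord[1]])
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", nsamp[i] * 2L))
      } else {
        dig <- readBin(con, "integer", nsamp[i], size = 2L,
                       signed = TRUE, endian = "little")
        j <- match(i, ord)
        scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
        cols <- ((r - 1) * nsamp[i] + 1):(r * nsamp[i])
        data[j, cols] <- (dig - dmin[i]) * scale + pmin[i]
      }
    }
  }
  ann <- .edf_parse_tals(ann_raw)
  eeg_record(data, fs = fs, channel_names = labels[ord],
             subject_id = if (nzchar(patient)) patient else basename(path),
             annotations = ann)
}

# Parse EDF+ time-stamped annotation lists. TALs are separated by NUL bytes;
# each is "<+|-><onset>[\x15<duration>]\x14<label>\x14". Timekeeping TALs
# (empty label) are dropped.
.edf_parse_tals <- function(bytes) {
  out <- data.frame(onset = numeric(0), duration = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)
  if (!length(bytes)) return(out)
  # split raw on NULs, then decode each TAL
  idx <- which(bytes == as.raw(0))
  starts <- c(1L, idx + 1L)
  ends <- c(idx - 1L, length(bytes))
  for (k in seq_along(starts)) {
    if (starts[k] > ends[k]) next
    tal <- rawToChar(bytes[starts[k]:ends[k]])
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(parts)) next
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    if (is.na(onset)) next
    dur <- if (length(head) > 1) suppressWarnings(as.numeric(head[2])) else 0
    labs <- parts[-1]
    labs <- labs[nzchar(labs)]
    for (lab in labs)
      out <- rbind(out, data.frame(onset = onset, duration = dur, label = lab,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Write an `eeg_record` to an EDF/EDF+ file
#'
#' A compact EDF+ writer used to build test fixtures and to export synthetic
#' recordings. Physical values are scaled per channel to the full 16-bit
#' digital range, so round-trips are exact to the quantization step
#' `(max - min) / 65535`.
#'
#' @param rec An [eeg_record()]. The sampling rate must be a positive
#'   integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_record"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate",
                            call. = FALSE)
  x <- rec$data
  n <- ncol(x)
  C <- nrow(x)
  if (n %% fs == 0) { rec_dur <- 1; nsamp_sig <- as.integer(fs); n_rec <- n %/% fs }
  else { rec_dur <- n / fs; nsamp_sig <- n; n_rec <- 1L }
  has_ann <- nrow(rec$annotations) > 0
  # annotation payloads: record r carries its timekeeping TAL; record 1 also
  # carries every event TAL
  ann_payload <- NULL
  if (has_ann) {
    recs <- lapply(seq_len(n_rec), function(r) {
      tal <- charToRaw(sprintf("+%g\x14\x14", (r - 1) * rec_dur))
      if (r == 1) {
        for (j in seq_len(nrow(rec$annotations))) {
          a <- rec$annotations[j, ]
          ev <- sprintf("+%g\x15%g\x14%s\x14", a$onset, a$duration, a$label)
          tal <- c(tal, as.raw(0), charToRaw(ev))
        }
      }
      tal
    })
    maxlen <- max(vapply(recs, length, 0L)) + 2L
    ann_samp <- as.integer(ceiling(maxlen / 2))
    ann_payload <- lapply(recs, function(r) c(r, raw(ann_samp * 2L - length(r))))
  }
  ns <- C + has_ann
  # integer physical bounds always fit the 8-char ASCII header fields
  pmin <- floor(apply(x, 1, min)); pmax <- ceiling(apply(x, 1, max))
  flat <- pmax - pmin < 1
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s, width) writeChar(.edf_pad(s, width), con, nchars = width,
                                    eos = NULL)
  w("0", 8); w(rec$subject_id, 80); w("csteeg export", 80)
  w("01.01.00", 8); w("00.00.00", 8)
  w(as.character(256 * (ns + 1)), 8)
  w(if (has_ann) "EDF+C" else "", 44)
  w(as.character(n_rec), 8)
  w(format(rec_dur, digits = 7), 8)
  w(as.character(ns), 4)
  labs <- c(substr(rec$channel_names, 1, 16),
            if (has_ann) "EDF Annotations")
  for (l in labs) w(l, 16)
  for (i in 1:ns) w("", 80)                      # transducer
  for (i in 1:ns) w(if (i <= C) "uV" else "", 8) # physical dimension
  for (i in 1:ns) w(sprintf("%d", as.integer(if (i <= C) pmin[i] else -1)), 8)
  for (i in 1:ns) w(sprintf("%d", as.integer(if (i <= C) pmax[i] else 1)), 8)
  for (i in 1:ns) w(as.character(dmin), 8)
  for (i in 1:ns) w(as.character(dmax), 8)
  for (i in 1:ns) w("", 80)                      # prefiltering
  for (i in 1:ns) w(as.character(if (i <= C) nsamp_sig else
                                 length(ann_payload[[1]]) / 2L), 8)
  for (i in 1:ns) w("", 32)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * nsamp_sig + 1):(r * nsamp_sig)
    for (i in seq_len(C)) {
      dig <- round((x[i, cols] - pmin[i]) * scale[i] + dmin)
      dig <- as.integer(pmin(pmax(dig, dmin), dmax))
      writeBin(dig, con, size = 2L, endian = "little")
    }
    if (has_ann) writeBin(ann_payload[[r]], con)
  }
  invisible(path)
}
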
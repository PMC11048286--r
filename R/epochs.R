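#' Construct a set of labeled epochs
#'
#' The modeling container: `N` fixed-length epochs, each a `T x C` matrix of
#' time frames by channels, with integer class labels in `[0, n_classes)`
#' and a per-epoch group identifier (subject/recording) enabling grouped,
#' leakage-safe splitting.
#'
#' @param epochs Numeric array `[N, T, C]`.
#' @param labels Integer vector of length `N`, values in `[0, n_classes)`.
#' @param fs Sampling rate in Hz.
#' @param class_names Character vector of class names (length `n_classes`).
#' @param group_ids Character vector of length `N`; defaults to one group.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, fs, class_names = NULL,
                      group_ids = NULL) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3)
  n <- dim(epochs)[1]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must have one entry per epoch",
                                call. = FALSE)
  if (is.null(class_names))
    class_names <- as.character(seq_len(max(1L, if (n) max(labels) + 1L else 1L)) - 1L)
  k <- length(class_names)
  if (n && (any(labels < 0) || any(labels >= k)))
    stop("labels must lie in [0, ", k, ")", call. = FALSE)
  if (is.null(group_ids)) group_ids <- rep("G1", n)
  if (length(group_ids) != n) stop("group_ids must have one entry per epoch",
                                   call. = FALSE)
  structure(list(epochs = epochs, labels = labels, fs = fs,
                 class_names = as.character(class_names),
                 group_ids = as.character(group_ids)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d samples x %d channels @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  groups:", length(unique(x$group_ids)), "\n")
  invisible(x)
}

#' Number of epochs
#' @param es An [epoch_set()].
#' @return Integer epoch count.
#' @export
n_epochs <- function(es) dim(es$epochs)[1]

#' Subset an epoch set by epoch index
#' @param x An [epoch_set()].
#' @param i Integer indices of epochs to keep.
#' @param ... Unused.
#' @return The subsetted `epoch_set`.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$epochs[i, , , drop = FALSE], x$labels[i], fs = x$fs,
            class_names = x$class_names, group_ids = x$group_ids[i])
}

#' Write an epoch set to a portable container
#'
#' Stores the epoch array as little-endian float64 (`<stem>.bin`, C-order
#' `[N, T, C]`) with a JSON sidecar `<stem>.json` holding dimensions, rate,
#' labels, class names and group ids.
#'
#' @param es An [epoch_set()].
#' @param stem Path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(es, stem) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  con <- file(paste0(stem, ".bin"), "wb")
  # C-order: last index fastest; R arrays are Fortran-order, so permute
  writeBin(as.numeric(aperm(es$epochs, c(3, 2, 1))), con, size = 8,
           endian = "little")
  close(con)
  meta <- list(dims = dim(es$epochs), fs = es$fs, labels = es$labels,
               class_names = es$class_names, group_ids = es$group_ids)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read an epoch set written by [write_epochs()]
#' @param stem Path stem (without extension).
#' @return An [epoch_set()].
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  con <- file(paste0(stem, ".bin"), "rb")
  x <- readBin(con, "numeric", prod(d), size = 8, endian = "little")
  close(con)
  if (length(x) != prod(d)) stop("epoch container truncated", call. = FALSE)
  ep <- aperm(array(x, dim = rev(d)), c(3, 2, 1))
  epoch_set(ep, meta$labels, fs = meta$fs, class_names = meta$class_names,
            group_ids = meta$group_ids)
}
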
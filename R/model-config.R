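#' Model configuration for the convolutional sparse transformer
#'
#' Collects every architectural hyperparameter. The defaults reproduce the
#' reference configuration used for the clinical EEG tasks: 3 sparse + 3
#' full attention layers, 8 heads, `d_model = 128`, `d_ff = 512`, and 5
#' convolutional + 5 max-pooling (distilling) layers. A distilling layer
#' follows attention layer `i` for `i <= n_conv_layers`, so with 6 attention
#' and 5 distilling layers none follows the last.
#'
#' @param n_classes Number of output classes.
#' @param in_channels Number of EEG channels `C`.
#' @param n_sparse_layers,n_full_layers Counts of sparse- and full-attention
#'   encoder layers.
#' @param n_heads Attention heads; must divide `d_model`.
#' @param d_model Feature width of the encoder stream.
#' @param d_ff Hidden width of the position-wise feed-forward sublayer.
#' @param n_conv_layers,n_pool_layers Distilling layer counts; must be equal
#'   and at most the number of attention layers.
#' @param query_factor Sampling factor `c` of the sparse attention: the
#'   number of active queries is `max(1, ceiling(c * ln L))`.
#' @param channel_reduction Reduction ratio `r` of the channel-attention
#'   MLP (hidden width `max(1, floor(C / r))`). Default `max(1, floor(C/2))`,
#'   chosen so the module stays well-formed down to 4-channel montages.
#' @param dropout Dropout rate applied after attention output and
#'   feed-forward sublayers during training.
#' @param conv_kernel Distill/embedding convolution kernel size (odd).
#' @param pool_kernel,pool_stride,pool_pad Max-pooling geometry; the default
#'   3/2/1 halves the temporal length per distilling layer.
#' @param use_channel_attention,use_sparse_attention,use_distillation
#'   Ablation switches: disable the channel gate, fall back to dense
#'   attention everywhere, or drop the distilling layers (lengths
#'   preserved).
#' @param positional_encoding Add sinusoidal position codes to the token
#'   embedding?
#' @param embed_conv Use a kernel-`conv_kernel` convolution for the token
#'   embedding (`TRUE`) or a pointwise linear map (`FALSE`).
#' @param seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_classes, in_channels,
                         n_sparse_layers = 3L, n_full_layers = 3L,
                         n_heads = 8L, d_model = 128L, d_ff = 512L,
                         n_conv_layers = 5L, n_pool_layers = n_conv_layers,
                         query_factor = 1, channel_reduction = NULL,
                         dropout = 0.1, conv_kernel = 3L,
                         pool_kernel = 3L, pool_stride = 2L, pool_pad = 1L,
                         use_channel_attention = TRUE,
                         use_sparse_attention = TRUE,
                         use_distillation = TRUE,
                         positional_encoding = TRUE,
                         embed_conv = TRUE,
                         seed = 1L) {
  if (d_model %% n_heads != 0)
    stop("d_model (", d_model, ") must be divisible by n_heads (", n_heads,
         ")", call. = FALSE)
  if (n_pool_layers != n_conv_layers)
    stop("n_pool_layers must equal n_conv_layers", call. = FALSE)
  n_attn <- n_sparse_layers + n_full_layers
  if (n_attn < 1) stop("need at least one attention layer", call. = FALSE)
  if (n_conv_layers > n_attn)
    stop("n_conv_layers (", n_conv_layers,
         ") exceeds the number of attention layers (", n_attn, ")",
         call. = FALSE)
  if (conv_kernel %% 2 != 1) stop("conv_kernel must be odd", call. = FALSE)
  if (query_factor <= 0) stop("query_factor must be positive", call. = FALSE)
  if (is.null(channel_reduction))
    channel_reduction <- max(1L, as.integer(in_channels) %/% 2L)
  cfg <- list(n_classes = as.integer(n_classes),
              in_channels = as.integer(in_channels),
              n_sparse_layers = as.integer(n_sparse_layers),
              n_full_layers = as.integer(n_full_layers),
              n_heads = as.integer(n_heads), d_model = as.integer(d_model),
              d_ff = as.integer(d_ff),
              n_conv_layers = as.integer(n_conv_layers),
              n_pool_layers = as.integer(n_pool_layers),
              query_factor = query_factor,
              channel_reduction = as.integer(channel_reduction),
              dropout = dropout, conv_kernel = as.integer(conv_kernel),
              pool_kernel = as.integer(pool_kernel),
              pool_stride = as.integer(pool_stride),
              pool_pad = as.integer(pool_pad),
              use_channel_attention = isTRUE(use_channel_attention),
              use_sparse_attention = isTRUE(use_sparse_attention),
              use_distillation = isTRUE(use_distillation),
              positional_encoding = isTRUE(positional_encoding),
              embed_conv = isTRUE(embed_conv),
              seed = as.integer(seed))
  structure(cfg, class = "model_config")
}

#' Encoder layer plan
#'
#' The ordered layer sequence implied by a configuration: sparse-attention
#' layers first, then full-attention layers, with a distilling layer after
#' attention layer `i` for `i <= n_conv_layers` (when distillation is
#' enabled).
#'
#' @param cfg A [model_config()].
#' @return A data frame with columns `layer`, `type` ("sparse"/"full") and
#'   `distill` (logical).
#' @export
layer_plan <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  n_attn <- cfg$n_sparse_layers + cfg$n_full_layers
  type <- c(rep("sparse", cfg$n_sparse_layers), rep("full", cfg$n_full_layers))
  if (!cfg$use_sparse_attention) type <- rep("full", n_attn)
  data.frame(layer = seq_len(n_attn), type = type,
             distill = cfg$use_distillation &
               seq_len(n_attn) <= cfg$n_conv_layers)
}

# Temporal length after one max-pool stage.
.pool_out_len <- function(L, k, s, p) (L + 2L * p - k) %/% s + 1L

#' Minimum supported epoch length for a configuration
#'
#' The temporal length must stay at least 2 entering every distilling layer
#' (halving a length-1 sequence is degenerate) and at least 1 at the
#' predictor. Inputs shorter than the returned value are rejected by
#' [model_forward()] with an error naming this minimum.
#'
#' @param cfg A [model_config()].
#' @return Minimal valid `T` (integer).
#' @export
min_input_length <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  n_dist <- if (cfg$use_distillation) cfg$n_conv_layers else 0L
  for (Tn in 1:2^30) {
    L <- Tn
    ok <- TRUE
    for (j in seq_len(n_dist)) {
      if (L < 2L || L + 2L * cfg$pool_pad < cfg$pool_kernel) { ok <- FALSE; break }
      L <- .pool_out_len(L, cfg$pool_kernel, cfg$pool_stride, cfg$pool_pad)
    }
    if (ok && L >= 1L) return(as.integer(Tn))
  }
}

#' Temporal lengths through the distilling stack
#'
#' @param cfg A [model_config()].
#' @param T_in Input epoch length (samples).
#' @return Integer vector of lengths after each distilling layer (length
#'   `n_conv_layers`, or empty when distillation is off).
#' @export
distill_lengths <- function(cfg, T_in) {
  stopifnot(inherits(cfg, "model_config"))
  n_dist <- if (cfg$use_distillation) cfg$n_conv_layers else 0L
  L <- as.integer(T_in)
  out <- integer(0)
  for (j in seq_len(n_dist)) {
    L <- .pool_out_len(L, cfg$pool_kernel, cfg$pool_stride, cfg$pool_pad)
    out <- c(out, L)
  }
  out
}

#' Preset model configurations
#'
#' `"mdd"`, `"helsinki"` and `"pharmaco"` reproduce the reference
#' configuration (differing only in channel/class counts); `"desk"` is the
#' reduced configuration used for the package's synthetic benchmark:
#' 2 sparse + 1 full attention layers, 3 distilling layers, `d_model = 64`,
#' 4 heads, `d_ff = 128`.
#'
#' @param name One of `"mdd"`, `"helsinki"`, `"pharmaco"`, `"desk"`.
#' @param n_classes,in_channels Task dimensions; defaults match the named
#'   dataset (19-channel binary for mdd/helsinki, 4-channel for pharmaco,
#'   4-channel binary for desk).
#' @param ... Overrides passed to [model_config()].
#' @return A [model_config()].
#' @export
preset_config <- function(name, n_classes = NULL, in_channels = NULL, ...) {
  name <- match.arg(name, c("mdd", "helsinki", "pharmaco", "desk"))
  defaults <- switch(name,
    mdd = list(n_classes = 2L, in_channels = 19L),
    helsinki = list(n_classes = 2L, in_channels = 19L),
    pharmaco = list(n_classes = 11L, in_channels = 4L),
    desk = list(n_classes = 2L, in_channels = 4L,
                n_sparse_layers = 2L, n_full_layers = 1L,
                n_conv_layers = 3L, n_pool_layers = 3L,
                d_model = 64L, n_heads = 4L, d_ff = 128L,
                dropout = 0))
  if (!is.null(n_classes)) defaults$n_classes <- as.integer(n_classes)
  if (!is.null(in_channels)) defaults$in_channels <- as.integer(in_channels)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<model_config> %d sparse + %d full attention layers, %d heads, ",
    "d_model=%d, d_ff=%d\n  %d distilling layers (conv k=%d; pool %d/%d/%d)",
    ", C=%d, classes=%d\n  flags: channel_attention=%s sparse=%s distill=%s\n"),
    x$n_sparse_layers, x$n_full_layers, x$n_heads, x$d_model, x$d_ff,
    x$n_conv_layers, x$conv_kernel, x$pool_kernel, x$pool_stride, x$pool_pad,
    x$in_channels, x$n_classes,
    x$use_channel_attention, x$use_sparse_attention, x$use_distillation))
  invisible(x)
}
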
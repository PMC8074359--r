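# Architecture plan for the shrunk depthwise-separable CNN and the
# convolution cost model.
#
# The 13-block reference is MobileNet-style: a 3x3 stride-2 stem with 32 base
# channels, then 13 depthwise-separable blocks with base output channels
#   64 128 128 256 256 512 512 512 512 512 512 1024 1024
# and strides
#   1   2   1   2   1   2   1   1   1   1   1    2    1.
# The depth parameter beta removes (13 - beta) blocks from the run of five
# identical 512-channel stride-1 blocks; the width multiplier alpha scales
# every channel count (round half up). Each convolution is followed by batch
# normalization and a ReLU; the head is global average pooling plus a dense
# layer. Trainable parameters are conv weights (no conv biases), a scale and
# shift per normalized feature, and dense weights plus biases.

BASE_STEM_CHANNELS <- 32L
BASE_BLOCK_CHANNELS <- c(64L, 128L, 128L, 256L, 256L, 512L, 512L, 512L,
                         512L, 512L, 512L, 1024L, 1024L)
BASE_BLOCK_STRIDES <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L)

round_half_up <- function(x) floor(x + 0.5)

#' DS-CNN model configuration
#'
#' @param alpha Width multiplier in `(0, 1]`; 0.75 and 0.5 reproduce the
#'   published shrinking grid.
#' @param beta Number of depthwise-separable blocks retained, `8 <= beta <=
#'   13`.
#' @param input_rows,input_cols Input feature dimensions (rows x frames).
#' @param n_classes Number of output classes (default 4).
#' @param in_channels Input channels (default 1; features are single-channel).
#' @return A `model_config` list.
#' @export
model_config <- function(alpha = 0.75, beta = 10, input_rows = 189,
                         input_cols = 126, n_classes = 4, in_channels = 1) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  beta <- as.integer(beta)
  if (beta < 8L || beta > 13L) stop("beta must lie in 8..13")
  structure(list(alpha = alpha, beta = beta,
                 input_rows = as.integer(input_rows),
                 input_cols = as.integer(input_cols),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "model_config")
}

#' Layer plan for a shrunk DS-CNN
#'
#' Expands a [model_config()] into an ordered table of layer records. For
#' `beta < 13`, `13 - beta` blocks are removed from the run of five
#' identical 512-base-channel stride-1 blocks (positions 7-11 of the
#' reference); every channel count is `round(alpha * base)` (half up).
#'
#' @param config A [model_config()].
#' @return A `layer_plan` data frame with columns `kind` (one of
#'   `standard_conv`, `depthwise_conv`, `pointwise_conv`, `batch_norm`,
#'   `activation`, `global_pool`, `dense`), `k`, `stride`, `in_ch`,
#'   `out_ch`; the config is attached as attribute `"config"`.
#' @export
block_plan <- function(config) {
  stopifnot(inherits(config, "model_config"))
  n_remove <- 13L - config$beta
  # positions 7..11 are the five identical 512->512 stride-1 blocks
  keep <- setdiff(seq_len(13L), if (n_remove > 0) 7L:(6L + n_remove) else integer(0))
  ch <- as.integer(round_half_up(config$alpha * BASE_BLOCK_CHANNELS[keep]))
  st <- BASE_BLOCK_STRIDES[keep]
  stem_out <- as.integer(round_half_up(config$alpha * BASE_STEM_CHANNELS))

  rows <- list(data.frame(kind = "standard_conv", k = 3L, stride = 2L,
                          in_ch = config$in_channels, out_ch = stem_out),
               data.frame(kind = "batch_norm", k = 0L, stride = 1L,
                          in_ch = stem_out, out_ch = stem_out),
               data.frame(kind = "activation", k = 0L, stride = 1L,
                          in_ch = stem_out, out_ch = stem_out))
  prev <- stem_out
  for (b in seq_along(ch)) {
    rows <- c(rows, list(
      data.frame(kind = "depthwise_conv", k = 3L, stride = st[b],
                 in_ch = prev, out_ch = prev),
      data.frame(kind = "batch_norm", k = 0L, stride = 1L,
                 in_ch = prev, out_ch = prev),
      data.frame(kind = "activation", k = 0L, stride = 1L,
                 in_ch = prev, out_ch = prev),
      data.frame(kind = "pointwise_conv", k = 1L, stride = 1L,
                 in_ch = prev, out_ch = ch[b]),
      data.frame(kind = "batch_norm", k = 0L, stride = 1L,
                 in_ch = ch[b], out_ch = ch[b]),
      data.frame(kind = "activation", k = 0L, stride = 1L,
                 in_ch = ch[b], out_ch = ch[b])))
    prev <- ch[b]
  }
  rows <- c(rows, list(
    data.frame(kind = "global_pool", k = 0L, stride = 1L,
               in_ch = prev, out_ch = prev),
    data.frame(kind = "dense", k = 0L, stride = 1L,
               in_ch = prev, out_ch = config$n_classes)))
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  attr(plan, "config") <- config
  class(plan) <- c("layer_plan", "data.frame")
  plan
}

#' Count trainable parameters of a layer plan
#'
#' Convention: convolution kernel weights without biases; two trainable
#' parameters (scale, shift) per batch-normalized feature; dense weights
#' plus biases.
#'
#' @param plan A [block_plan()] (or any data frame with columns `kind`,
#'   `k`, `in_ch`, `out_ch`).
#' @return The absolute count, with attribute `"millions"` rounded to two
#'   decimals.
#' @export
count_params <- function(plan) {
  per_layer <- function(kind, k, in_ch, out_ch) {
    switch(kind,
           standard_conv  = k * k * in_ch * out_ch,
           depthwise_conv = k * k * in_ch,
           pointwise_conv = in_ch * out_ch,
           batch_norm     = 2 * out_ch,
           dense          = in_ch * out_ch + out_ch,
           0)
  }
  total <- sum(mapply(per_layer, plan$kind, plan$k, plan$in_ch, plan$out_ch))
  structure(total, millions = round(total / 1e6, 2))
}

#' Parameter-count grid over the shrinking parameters
#'
#' @param alphas Width multipliers (default `c(0.75, 0.5)`).
#' @param betas Block counts (default `c(12, 10, 8)`).
#' @param n_classes,in_channels Passed to [model_config()].
#' @return A data frame with one row per (alpha, beta) and the counts in
#'   millions (2 decimals).
#' @export
param_grid <- function(alphas = c(0.75, 0.5), betas = c(12, 10, 8),
                       n_classes = 4, in_channels = 1) {
  grid <- expand.grid(beta = betas, alpha = alphas)[, c("alpha", "beta")]
  grid$params <- vapply(seq_len(nrow(grid)), function(i) {
    as.numeric(count_params(block_plan(model_config(
      grid$alpha[i], grid$beta[i],
      n_classes = n_classes, in_channels = in_channels))))
  }, 0)
  grid$millions <- round(grid$params / 1e6, 2)
  grid
}

#' @export
print.layer_plan <- function(x, ...) {
  cfg <- attr(x, "config")
  n_blocks <- sum(x$kind == "depthwise_conv")
  cat(sprintf("<layer_plan> alpha=%g, beta=%d (%d DS blocks), %s parameters (%.2f M)\n",
              cfg$alpha, cfg$beta, n_blocks,
              format(as.numeric(count_params(x)), big.mark = ","),
              attr(count_params(x), "millions")))
  print.data.frame(x)
  invisible(x)
}

#' Serialize a layer plan to JSON
#'
#' @param plan A [block_plan()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  cfg <- attr(plan, "config")
  jsonlite::write_json(list(config = unclass(cfg),
                            layers = as.data.frame(unclass(plan))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- convolution cost model -------------------------------------------------

#' Convolution cost specification
#'
#' @param w,h Feature-map width and height.
#' @param N Input channels.
#' @param k Square kernel size.
#' @param M Number of kernels (output channels).
#' @return A `conv_cost_spec` list of positive integers.
#' @export
conv_cost_spec <- function(w, h, N, k, M) {
  v <- c(w = w, h = h, N = N, k = k, M = M)
  if (any(v < 1) || any(v != round(v)))
    stop("all cost-spec fields must be positive integers")
  structure(as.list(v), class = "conv_cost_spec")
}

#' Multiply-add cost of a standard convolution
#'
#' `w * h * N * k^2 * M` for a stride-one, same-padding convolution.
#'
#' @param spec A [conv_cost_spec()].
#' @return The exact multiply-add count.
#' @export
conv_cost_standard <- function(spec) {
  stopifnot(inherits(spec, "conv_cost_spec"))
  spec$w * spec$h * spec$N * spec$k^2 * spec$M
}

#' Multiply-add cost of a depthwise-separable convolution
#'
#' Depthwise part `w*h*N*k^2` plus pointwise part `w*h*N*M`.
#'
#' @param spec A [conv_cost_spec()].
#' @return The exact multiply-add count.
#' @export
conv_cost_ds <- function(spec) {
  stopifnot(inherits(spec, "conv_cost_spec"))
  spec$w * spec$h * spec$N * spec$k^2 + spec$w * spec$h * spec$N * spec$M
}

#' Cost ratio of depthwise-separable to standard convolution
#'
#' Equals `1/M + 1/k^2` independently of `w`, `h`, `N`.
#'
#' @param spec A [conv_cost_spec()].
#' @return The dimensionless ratio.
#' @export
cost_ratio <- function(spec) {
  conv_cost_ds(spec) / conv_cost_standard(spec)
}
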
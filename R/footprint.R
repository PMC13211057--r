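# Model footprint accounting: exact trainable-parameter counts and analytic
# per-inference FLOP counts.
#
# FLOP convention (stated once, used everywhere): one multiply-accumulate of
# a convolution, attention projection/product, feed-forward or classifier
# layer counts as 2 FLOPs; elementwise work (bias additions, normalization
# scale/shift, activations, residual additions, softmax terms and pooling
# comparisons) is counted once per scalar operation.

#' Count trainable parameters of a model
#'
#' Enumerates every trainable tensor (weights, biases, normalization affine
#' parameters) and sums their lengths. Batch-normalization running
#' statistics are buffers, not parameters, and are excluded.
#'
#' @param model An `eeg_model`.
#' @return Integer scalar.
#' @examples
#' \donttest{
#' count_parameters(build_eegdecoder())  # 654723
#' }
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "eeg_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' Closed-form parameter count of the decoder architecture
#'
#' Independent of any built model: sums the documented layer formulas from a
#' [decoder_config()]. Used as a cross-check against [count_parameters()].
#'
#' @param config A [decoder_config()].
#' @return Integer scalar.
#' @export
decoder_parameter_formula <- function(config = decoder_config()) {
  cf <- config
  d <- cf$d_model
  conv1 <- cf$conv1_out * cf$in_channels * cf$conv1_kernel + cf$conv1_out
  bn1 <- 2 * cf$conv1_out
  conv2 <- cf$conv2_out * cf$conv1_out * cf$conv2_kernel + cf$conv2_out
  bn2 <- 2 * cf$conv2_out
  attn <- 4 * (d * d + d)                      # Q, K, V, output projections
  ffn <- d * cf$ffn_dim + cf$ffn_dim + cf$ffn_dim * d + d
  lns <- 2 * 2 * d                             # two layer norms, gamma+beta
  enc <- cf$encoder_layers * (attn + ffn + lns)
  head <- d * cf$n_classes + cf$n_classes
  conv1 + bn1 + conv2 + bn2 + enc + head
}

#' Analytic per-inference FLOP count
#'
#' Walks the architecture and accumulates floating-point operations for a
#' single trial under the package's stated convention (2 FLOPs per
#' multiply-accumulate, elementwise operations counted once). Returns the
#' total and, optionally, a per-stage breakdown.
#'
#' @param model An `eeg_model`.
#' @param breakdown If `TRUE`, return a named numeric vector per stage
#'   instead of the total.
#' @return Numeric scalar (total FLOPs for one trial), or a named vector.
#' @export
count_flops <- function(model, breakdown = FALSE) {
  stopifnot(inherits(model, "eeg_model"))
  if (model$architecture == "eegdecoder") fl <- decoder_flops(model$config)
  else fl <- eegnet_flops(model$config)
  if (breakdown) fl else sum(fl)
}

decoder_flops <- function(cf) {
  sc <- cf$shape_chain
  d <- cf$d_model
  Ts <- cf$seq_len
  conv1 <- 2 * cf$in_channels * cf$conv1_kernel * cf$conv1_out * sc[["conv1"]] +
    cf$conv1_out * sc[["conv1"]]                       # MACs + bias adds
  bn1 <- 2 * cf$conv1_out * sc[["conv1"]]              # scale + shift
  elu1 <- cf$conv1_out * sc[["conv1"]]
  pool1 <- cf$conv1_out * sc[["pool1"]] * (cf$pool - 1) # comparisons
  conv2 <- 2 * cf$conv1_out * cf$conv2_kernel * cf$conv2_out * sc[["conv2"]] +
    cf$conv2_out * sc[["conv2"]]
  bn2 <- 2 * cf$conv2_out * sc[["conv2"]]
  elu2 <- cf$conv2_out * sc[["conv2"]]
  pool2 <- cf$conv2_out * sc[["pool2"]] * (cf$pool - 1)

  dk <- d / cf$attention_heads
  proj <- 4 * (2 * Ts * d * d + Ts * d)                # Q,K,V,O GEMMs + bias
  scores <- cf$attention_heads * (2 * Ts * Ts * dk + Ts * Ts)  # QK^T + scale
  smax <- cf$attention_heads * 3 * Ts * Ts             # exp, sum, divide
  attnv <- cf$attention_heads * 2 * Ts * Ts * dk       # A V
  resid <- 2 * Ts * d                                  # two residual adds
  lnorm <- 2 * 7 * Ts * d                              # two layer norms
  ffn <- 2 * Ts * d * cf$ffn_dim + Ts * cf$ffn_dim +   # W1 + b1
    Ts * cf$ffn_dim +                                  # ReLU
    2 * Ts * cf$ffn_dim * d + Ts * d                   # W2 + b2
  enc <- cf$encoder_layers * (proj + scores + smax + attnv + resid + lnorm + ffn)

  pool_mean <- Ts * d + d
  head <- 2 * d * cf$n_classes + cf$n_classes
  c(conv1 = conv1 + bn1 + elu1 + pool1,
    conv2 = conv2 + bn2 + elu2 + pool2,
    encoder = enc, pooling = pool_mean, head = head)
}

eegnet_flops <- function(cf) {
  C <- cf$in_channels; T <- cf$input_samples
  F1 <- cf$F1; F2 <- cf$F2; D <- cf$D
  t1 <- T                                            # same padding
  conv1 <- 2 * cf$temporal_kernel * F1 * C * t1
  bn1 <- 2 * F1 * C * t1
  dw <- 2 * C * F1 * D * t1 + 2 * F2 * t1 + F2 * t1  # spatial collapse + BN + ELU
  p1 <- T %/% cf$pool1
  pool1 <- F2 * p1 * cf$pool1
  sep <- 2 * cf$separable_kernel * F2 * p1 + 2 * F2 * F2 * p1 +
    2 * F2 * p1 + F2 * p1
  p2 <- p1 %/% cf$pool2
  pool2 <- F2 * p2 * cf$pool2
  head <- 2 * F2 * p2 * cf$n_classes + cf$n_classes
  c(conv_temporal = conv1 + bn1, depthwise = dw, pool1 = pool1,
    separable = sep, pool2 = pool2, head = head)
}
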
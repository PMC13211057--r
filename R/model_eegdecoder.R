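# The hybrid 1D-CNN + Transformer-encoder EEG classifier ("EEGDecoder").
#
# Architecture (defaults): two valid-padding 1-D convolutions (19->64 k=25,
# 64->64 k=15), each followed by batch normalization, ELU and max-pool 4;
# the 64 x 75 feature map is permuted to a 75-step sequence of 64-dim
# embeddings; a 2-layer post-norm Transformer encoder (2 heads, FFN width
# 2048, ReLU, dropout 0.1, no positional encoding); temporal mean pooling;
# linear head to 3 class scores.

#' Configuration of the hybrid CNN-Transformer EEG decoder
#'
#' Returns the architecture hyperparameters. The defaults describe the
#' published configuration: valid-padding convolutions are required for the
#' documented shape chain 1280 -> 1256 -> 314 -> 300 -> 75, and the encoder
#' defaults (feed-forward width 2048, dropout 0.1, ReLU, residual-then-
#' normalize, no positional encoding) are the standard Transformer-encoder
#' defaults, confirmed by the exact trainable-parameter count of 654,723.
#'
#' @param in_channels Number of EEG channels.
#' @param input_samples Trial length in samples (5 s at 256 Hz by default).
#' @param conv1_out,conv1_kernel,conv2_out,conv2_kernel Convolution widths
#'   and kernel lengths.
#' @param pool Max-pooling factor applied after each convolution stage.
#' @param encoder_layers,attention_heads,d_model,ffn_dim Encoder geometry.
#' @param dropout Dropout probability inside the encoder.
#' @param n_classes Number of output classes.
#' @return A `decoder_config` list; `$seq_len` holds the derived sequence
#'   length T'.
#' @export
decoder_config <- function(in_channels = 19, input_samples = 1280,
                           conv1_out = 64, conv1_kernel = 25,
                           conv2_out = 64, conv2_kernel = 15,
                           pool = 4, encoder_layers = 2,
                           attention_heads = 2, d_model = 64,
                           ffn_dim = 2048, dropout = 0.1, n_classes = 3) {
  if (d_model %% attention_heads != 0)
    stop("d_model must be divisible by the number of attention heads")
  if (conv2_out != d_model)
    stop("second convolution width must equal d_model (the CNN feeds the encoder)")
  t1 <- input_samples - conv1_kernel + 1
  p1 <- t1 %/% pool
  t2 <- p1 - conv2_kernel + 1
  seq_len <- t2 %/% pool
  if (seq_len < 1) stop("input too short for the configured shape chain")
  structure(list(
    in_channels = in_channels, input_samples = input_samples,
    conv1_out = conv1_out, conv1_kernel = conv1_kernel,
    conv2_out = conv2_out, conv2_kernel = conv2_kernel, pool = pool,
    encoder_layers = encoder_layers, attention_heads = attention_heads,
    d_model = d_model, ffn_dim = ffn_dim, dropout = dropout,
    n_classes = n_classes,
    shape_chain = c(conv1 = t1, pool1 = p1, conv2 = t2, pool2 = seq_len),
    seq_len = seq_len), class = "decoder_config")
}

#' Build the hybrid CNN-Transformer EEG decoder
#'
#' Instantiates all trainable tensors (seeded) plus batch-normalization
#' running statistics. The resulting model is used by [decoder_forward()],
#' [train_model()], [count_parameters()] and [export_portable()].
#'
#' @param config A [decoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `eeg_model` (architecture `"eegdecoder"`).
#' @export
build_eegdecoder <- function(config = decoder_config(), seed = 2025) {
  stopifnot(inherits(config, "decoder_config"))
  set.seed(seed)
  cf <- config
  p <- list()
  p$conv1.w <- init_uniform(c(cf$conv1_out, cf$in_channels * cf$conv1_kernel),
                            cf$in_channels * cf$conv1_kernel)
  p$conv1.b <- as.numeric(init_uniform(cf$conv1_out,
                                       cf$in_channels * cf$conv1_kernel))
  p$bn1.gamma <- rep(1, cf$conv1_out); p$bn1.beta <- rep(0, cf$conv1_out)
  p$conv2.w <- init_uniform(c(cf$conv2_out, cf$conv1_out * cf$conv2_kernel),
                            cf$conv1_out * cf$conv2_kernel)
  p$conv2.b <- as.numeric(init_uniform(cf$conv2_out,
                                       cf$conv1_out * cf$conv2_kernel))
  p$bn2.gamma <- rep(1, cf$conv2_out); p$bn2.beta <- rep(0, cf$conv2_out)
  d <- cf$d_model
  for (l in seq_len(cf$encoder_layers)) {
    pre <- sprintf("enc%d.", l)
    for (nm in c("wq", "wk", "wv", "wo")) p[[paste0(pre, nm)]] <- init_xavier(d, d)
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- rep(0, d)
    p[[paste0(pre, "ln1.gamma")]] <- rep(1, d)
    p[[paste0(pre, "ln1.beta")]] <- rep(0, d)
    p[[paste0(pre, "ffn.w1")]] <- init_uniform(c(d, cf$ffn_dim), d)
    p[[paste0(pre, "ffn.b1")]] <- as.numeric(init_uniform(cf$ffn_dim, d))
    p[[paste0(pre, "ffn.w2")]] <- init_uniform(c(cf$ffn_dim, d), cf$ffn_dim)
    p[[paste0(pre, "ffn.b2")]] <- as.numeric(init_uniform(d, cf$ffn_dim))
    p[[paste0(pre, "ln2.gamma")]] <- rep(1, d)
    p[[paste0(pre, "ln2.beta")]] <- rep(0, d)
  }
  p$head.w <- init_uniform(c(d, cf$n_classes), d)
  p$head.b <- as.numeric(init_uniform(cf$n_classes, d))
  state <- list(bn1.mean = rep(0, cf$conv1_out), bn1.var = rep(1, cf$conv1_out),
                bn2.mean = rep(0, cf$conv2_out), bn2.var = rep(1, cf$conv2_out))
  structure(list(architecture = "eegdecoder", config = cf, params = p,
                 state = state, training = FALSE, seed = seed),
            class = "eeg_model")
}

#' @export
print.eeg_model <- function(x, ...) {
  cat(sprintf("<eeg_model: %s | %s parameters | input %d x %d>\n",
              x$architecture,
              format(count_parameters(x), big.mark = ","),
              x$config$in_channels, x$config$input_samples))
  invisible(x)
}

# Internal forward with optional cache for backprop.
# x: array (C, T, N). Returns list(logits, cache, state, cnn_features).
decoder_forward_full <- function(model, x, training = FALSE,
                                 keep_cache = FALSE, hooks = FALSE) {
  cf <- model$config
  p <- model$params
  st <- model$state
  cache <- list()

  c1 <- conv_forward(x, p$conv1.w, p$conv1.b)
  b1 <- batchnorm_forward(c1$out, p$bn1.gamma, p$bn1.beta,
                          st$bn1.mean, st$bn1.var, training)
  st$bn1.mean <- b1$run_mean; st$bn1.var <- b1$run_var
  e1 <- elu_forward(b1$out)
  m1 <- maxpool_forward(e1$out, cf$pool)
  c2 <- conv_forward(m1$out, p$conv2.w, p$conv2.b)
  b2 <- batchnorm_forward(c2$out, p$bn2.gamma, p$bn2.beta,
                          st$bn2.mean, st$bn2.var, training)
  st$bn2.mean <- b2$run_mean; st$bn2.var <- b2$run_var
  e2 <- elu_forward(b2$out)
  m2 <- maxpool_forward(e2$out, cf$pool)

  feat <- m2$out                                  # (d_model, T', N)
  dmd <- dim(feat)
  n <- dmd[3]; Tseq <- dmd[2]
  # permute channels/time -> token rows (time within trial)
  z <- t(matrix(feat, dmd[1], dmd[2] * dmd[3]))   # (N*T') x d_model

  enc <- vector("list", cf$encoder_layers)
  for (l in seq_len(cf$encoder_layers)) {
    pre <- sprintf("enc%d.", l)
    mh <- mha_forward(z, list(wq = p[[paste0(pre, "wq")]], bq = p[[paste0(pre, "bq")]],
                              wk = p[[paste0(pre, "wk")]], bk = p[[paste0(pre, "bk")]],
                              wv = p[[paste0(pre, "wv")]], bv = p[[paste0(pre, "bv")]],
                              wo = p[[paste0(pre, "wo")]], bo = p[[paste0(pre, "bo")]]),
                      cf$attention_heads, Tseq, cf$dropout, training)
    do1 <- dropout_forward(mh$out, cf$dropout, training)
    ln1 <- layernorm_forward(z + do1$out, p[[paste0(pre, "ln1.gamma")]],
                             p[[paste0(pre, "ln1.beta")]])
    f1 <- linear_forward(ln1$out, p[[paste0(pre, "ffn.w1")]], p[[paste0(pre, "ffn.b1")]])
    r1 <- relu_forward(f1$out)
    f2 <- linear_forward(r1$out, p[[paste0(pre, "ffn.w2")]], p[[paste0(pre, "ffn.b2")]])
    do2 <- dropout_forward(f2$out, cf$dropout, training)
    ln2 <- layernorm_forward(ln1$out + do2$out, p[[paste0(pre, "ln2.gamma")]],
                             p[[paste0(pre, "ln2.beta")]])
    enc[[l]] <- list(mh = mh, do1 = do1, ln1 = ln1, f1 = f1, r1 = r1,
                     f2 = f2, do2 = do2, ln2 = ln2)
    z <- ln2$out
  }

  # temporal mean pool per trial: rows of z are t-within-n
  grp <- rep(seq_len(n), each = Tseq)
  pooled <- unname(rowsum(z, grp, reorder = TRUE)) / Tseq   # N x d_model
  hd <- linear_forward(pooled, p$head.w, p$head.b)

  out <- list(logits = hd$out, state = st)
  if (hooks) out$cnn_features <- feat
  if (keep_cache)
    out$cache <- list(c1 = c1, b1 = b1, e1 = e1, m1 = m1, c2 = c2, b2 = b2,
                      e2 = e2, m2 = m2, enc = enc, hd = hd, n = n,
                      Tseq = Tseq, dmd = dmd)
  out
}

decoder_backward_full <- function(model, fwd, dlogits) {
  cf <- model$config
  cache <- fwd$cache
  g <- list()
  hb <- linear_backward(cache$hd$cache, dlogits)
  g$head.w <- hb$grads$w; g$head.b <- hb$grads$b
  # un-pool: every token row receives dpooled/Tseq
  dz <- hb$dx[rep(seq_len(cache$n), each = cache$Tseq), , drop = FALSE] /
    cache$Tseq

  for (l in rev(seq_len(cf$encoder_layers))) {
    pre <- sprintf("enc%d.", l)
    e <- cache$enc[[l]]
    lb2 <- layernorm_backward(e$ln2$cache, dz)
    g[[paste0(pre, "ln2.gamma")]] <- lb2$grads$gamma
    g[[paste0(pre, "ln2.beta")]] <- lb2$grads$beta
    dres2 <- lb2$dx
    dd2 <- dropout_backward(e$do2$cache, dres2)
    fb2 <- linear_backward(e$f2$cache, dd2$dx)
    g[[paste0(pre, "ffn.w2")]] <- fb2$grads$w
    g[[paste0(pre, "ffn.b2")]] <- fb2$grads$b
    rb <- relu_backward(e$r1$cache, fb2$dx)
    fb1 <- linear_backward(e$f1$cache, rb$dx)
    g[[paste0(pre, "ffn.w1")]] <- fb1$grads$w
    g[[paste0(pre, "ffn.b1")]] <- fb1$grads$b
    dln1 <- dres2 + fb1$dx
    lb1 <- layernorm_backward(e$ln1$cache, dln1)
    g[[paste0(pre, "ln1.gamma")]] <- lb1$grads$gamma
    g[[paste0(pre, "ln1.beta")]] <- lb1$grads$beta
    dres1 <- lb1$dx
    dd1 <- dropout_backward(e$do1$cache, dres1)
    mb <- mha_backward(e$mh$cache, dd1$dx)
    for (nm in names(mb$grads)) g[[paste0(pre, nm)]] <- mb$grads[[nm]]
    dz <- dres1 + mb$dx
  }

  dfeat <- array(t(dz), cache$dmd)
  mp2 <- maxpool_backward(cache$m2$cache, dfeat)
  eb2 <- elu_backward(cache$e2$cache, mp2$dx)
  bb2 <- batchnorm_backward(cache$b2$cache, eb2$dx)
  g$bn2.gamma <- bb2$grads$gamma; g$bn2.beta <- bb2$grads$beta
  cb2 <- conv_backward(cache$c2$cache, bb2$dx)
  g$conv2.w <- cb2$grads$w; g$conv2.b <- cb2$grads$b
  mp1 <- maxpool_backward(cache$m1$cache, cb2$dx)
  eb1 <- elu_backward(cache$e1$cache, mp1$dx)
  bb1 <- batchnorm_backward(cache$b1$cache, eb1$dx)
  g$bn1.gamma <- bb1$grads$gamma; g$bn1.beta <- bb1$grads$beta
  cb1 <- conv_backward(cache$c1$cache, bb1$dx)
  g$conv1.w <- cb1$grads$w; g$conv1.b <- cb1$grads$b
  g
}

#' Forward pass of an EEG model
#'
#' Runs a batch of trials through the network and returns raw class scores.
#' In evaluation mode (the default) batch-normalization uses running
#' statistics and dropout is disabled, so outputs are deterministic and
#' per-trial independent.
#'
#' @param model An `eeg_model` from [build_eegdecoder()] or [build_eegnet()].
#' @param batch Numeric array `N x C x T` (trials first, as stored in a
#'   trial set) or `C x T` for a single trial.
#' @param training Use batch statistics and dropout (for internal training).
#' @param return_features If `TRUE`, also return the CNN feature maps
#'   (`d_model x T' x N`, decoder only) for shape inspection.
#' @return `N x n_classes` matrix of raw scores, or a list with `scores` and
#'   `cnn_features` when `return_features = TRUE`.
#' @export
decoder_forward <- function(model, batch, training = FALSE,
                            return_features = FALSE) {
  stopifnot(inherits(model, "eeg_model"))
  x <- batch_to_ctn(batch, model$config$in_channels,
                    model$config$input_samples)
  if (model$architecture == "eegdecoder") {
    fw <- decoder_forward_full(model, x, training = training,
                               hooks = return_features)
  } else {
    fw <- eegnet_forward_full(model, x, training = training)
  }
  colnames(fw$logits) <- EEG_CLASSES[seq_len(model$config$n_classes)]
  if (return_features)
    list(scores = fw$logits, cnn_features = fw$cnn_features)
  else fw$logits
}

# Accepts N x C x T (user-facing) or C x T and returns (C, T, N).
batch_to_ctn <- function(batch, C, T) {
  if (length(dim(batch)) == 2) batch <- array(batch, c(1, dim(batch)))
  d <- dim(batch)
  if (length(d) != 3 || d[2] != C || d[3] != T)
    stop(sprintf("batch shape mismatch: expected N x %d x %d, got %s",
                 C, T, paste(d, collapse = " x ")))
  aperm(batch, c(2, 3, 1))
}
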
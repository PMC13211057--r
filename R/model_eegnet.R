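# EEGNet-8,2 baseline: temporal convolution bank, constrained depthwise
# spatial filters, separable convolution, average pooling, dropout, dense
# head. Follows the original compact-EEGNet design (F1 temporal filters,
# depth multiplier D, F2 = F1*D separable feature maps).

#' Configuration of the EEGNet-8,2 baseline
#'
#' @param F1 Number of temporal convolutional filters.
#' @param D Depth multiplier of the spatial (depthwise) stage.
#' @param temporal_kernel Temporal kernel length in samples.
#' @param separable_kernel Kernel length of the separable stage.
#' @param pool1,pool2 Average-pooling factors of the two blocks.
#' @param dropout Dropout probability.
#' @param max_norm Max-norm constraint applied to depthwise spatial filters.
#' @param in_channels,input_samples,n_classes Input/output geometry.
#' @return An `eegnet_config` list with derived field `F2 = F1 * D`.
#' @export
eegnet_config <- function(F1 = 8, D = 2, temporal_kernel = 64,
                          separable_kernel = 16, pool1 = 4, pool2 = 8,
                          dropout = 0.25, max_norm = 1.0,
                          in_channels = 19, input_samples = 1280,
                          n_classes = 3) {
  structure(list(F1 = F1, D = D, F2 = F1 * D,
                 temporal_kernel = temporal_kernel,
                 separable_kernel = separable_kernel,
                 pool1 = pool1, pool2 = pool2, dropout = dropout,
                 max_norm = max_norm, in_channels = in_channels,
                 input_samples = input_samples, n_classes = n_classes,
                 feat_len = (input_samples %/% pool1) %/% pool2),
            class = "eegnet_config")
}

#' Build the EEGNet-8,2 baseline model
#'
#' @param config An [eegnet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `eeg_model` (architecture `"eegnet"`), usable with
#'   [decoder_forward()], [train_model()] and [export_portable()].
#' @export
build_eegnet <- function(config = eegnet_config(), seed = 2025) {
  stopifnot(inherits(config, "eegnet_config"))
  set.seed(seed)
  cf <- config
  p <- list()
  p$conv1.w <- init_uniform(c(cf$F1, cf$temporal_kernel), cf$temporal_kernel)
  p$bn1.gamma <- rep(1, cf$F1); p$bn1.beta <- rep(0, cf$F1)
  p$dw.w <- init_uniform(c(cf$F2, cf$in_channels), cf$in_channels)
  p$bn2.gamma <- rep(1, cf$F2); p$bn2.beta <- rep(0, cf$F2)
  p$sep.dw <- init_uniform(c(cf$F2, cf$separable_kernel), cf$separable_kernel)
  p$sep.pw <- init_uniform(c(cf$F2, cf$F2), cf$F2)
  p$bn3.gamma <- rep(1, cf$F2); p$bn3.beta <- rep(0, cf$F2)
  nf <- cf$F2 * cf$feat_len
  p$head.w <- init_uniform(c(nf, cf$n_classes), nf)
  p$head.b <- as.numeric(init_uniform(cf$n_classes, nf))
  state <- list(bn1.mean = rep(0, cf$F1), bn1.var = rep(1, cf$F1),
                bn2.mean = rep(0, cf$F2), bn2.var = rep(1, cf$F2),
                bn3.mean = rep(0, cf$F2), bn3.var = rep(1, cf$F2))
  structure(list(architecture = "eegnet", config = cf, params = p,
                 state = state, training = FALSE, seed = seed),
            class = "eeg_model")
}

pad_time <- function(x, left, right) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + left + right, d[3]))
  out[, (left + 1):(left + d[2]), ] <- x
  out
}

# Depthwise temporal conv as a block-diagonal grouped convolution weight.
sep_dw_weight <- function(wd, K) {
  Fm <- nrow(wd)
  W <- matrix(0, Fm, Fm * K)
  for (k in seq_len(K)) W[cbind(seq_len(Fm), (k - 1) * Fm + seq_len(Fm))] <- wd[, k]
  W
}

eegnet_forward_full <- function(model, x, training = FALSE,
                                keep_cache = FALSE) {
  cf <- model$config
  p <- model$params
  st <- model$state
  d <- dim(x)                                   # (C, T, N)
  C <- d[1]; T <- d[2]; N <- d[3]
  K <- cf$temporal_kernel
  padl <- (K - 1) %/% 2; padr <- K - 1 - padl

  # temporal filter bank applied per channel
  xp <- pad_time(x, padl, padr)
  x1 <- array(aperm(xp, c(2, 1, 3)), c(1, dim(xp)[2], C * N)) # (1, T+K-1, C*N)
  c1 <- conv_forward(x1, p$conv1.w, rep(0, cf$F1))            # (F1, T, C*N)
  b1 <- batchnorm_forward(c1$out, p$bn1.gamma, p$bn1.beta,
                          st$bn1.mean, st$bn1.var, training)
  st$bn1.mean <- b1$run_mean; st$bn1.var <- b1$run_var

  # depthwise spatial filters: (F2 x C) acting across channels per F1 map
  r4 <- aperm(array(b1$out, c(cf$F1, T, C, N)), c(3, 2, 1, 4)) # (C,T,F1,N)
  z <- array(0, c(cf$F2, T, N))
  for (f in seq_len(cf$F1)) {
    rows <- (f - 1) * cf$D + seq_len(cf$D)
    xf <- matrix(r4[, , f, ], C)                               # C x (T*N)
    z[rows, , ] <- p$dw.w[rows, , drop = FALSE] %*% xf
  }
  b2 <- batchnorm_forward(z, p$bn2.gamma, p$bn2.beta,
                          st$bn2.mean, st$bn2.var, training)
  st$bn2.mean <- b2$run_mean; st$bn2.var <- b2$run_var
  e2 <- elu_forward(b2$out)
  a1 <- avgpool_forward(e2$out, cf$pool1)
  dp1 <- dropout_forward(a1$out, cf$dropout, training)

  # separable convolution: depthwise temporal then pointwise
  Ks <- cf$separable_kernel
  sl <- (Ks - 1) %/% 2; sr <- Ks - 1 - sl
  sp <- pad_time(dp1$out, sl, sr)
  Wdw <- sep_dw_weight(p$sep.dw, Ks)
  cdw <- conv_forward(sp, Wdw, rep(0, cf$F2))
  cpw <- conv_forward(cdw$out, p$sep.pw, rep(0, cf$F2))        # kernel 1
  b3 <- batchnorm_forward(cpw$out, p$bn3.gamma, p$bn3.beta,
                          st$bn3.mean, st$bn3.var, training)
  st$bn3.mean <- b3$run_mean; st$bn3.var <- b3$run_var
  e3 <- elu_forward(b3$out)
  a2 <- avgpool_forward(e3$out, cf$pool2)
  dp2 <- dropout_forward(a2$out, cf$dropout, training)

  flat <- t(matrix(dp2$out, cf$F2 * cf$feat_len, N))           # N x nf
  hd <- linear_forward(flat, p$head.w, p$head.b)

  out <- list(logits = hd$out, state = st)
  if (keep_cache)
    out$cache <- list(d = d, padl = padl, padr = padr, x1 = x1, c1 = c1,
                      b1 = b1, r4dim = c(C, T, cf$F1, N), z = z, b2 = b2,
                      e2 = e2, a1 = a1, dp1 = dp1, sl = sl, sr = sr,
                      sp = sp, Wdw = Wdw, cdw = cdw, cpw = cpw, b3 = b3,
                      e3 = e3, a2 = a2, dp2 = dp2, hd = hd, N = N)
  out
}

eegnet_backward_full <- function(model, fwd, dlogits) {
  cf <- model$config
  ca <- fwd$cache
  C <- ca$d[1]; T <- ca$d[2]; N <- ca$d[3]
  g <- list()
  hb <- linear_backward(ca$hd$cache, dlogits)
  g$head.w <- hb$grads$w; g$head.b <- hb$grads$b
  dflat <- array(t(hb$dx), c(cf$F2, cf$feat_len, N))
  dd2 <- dropout_backward(ca$dp2$cache, dflat)
  da2 <- avgpool_backward(ca$a2$cache, dd2$dx)
  de3 <- elu_backward(ca$e3$cache, da2$dx)
  db3 <- batchnorm_backward(ca$b3$cache, de3$dx)
  g$bn3.gamma <- db3$grads$gamma; g$bn3.beta <- db3$grads$beta
  cpwb <- conv_backward(ca$cpw$cache, db3$dx)
  g$sep.pw <- cpwb$grads$w
  cdwb <- conv_backward(ca$cdw$cache, cpwb$dx)
  # keep only the block-diagonal (true depthwise) entries
  Ks <- cf$separable_kernel
  gdw <- matrix(0, cf$F2, Ks)
  for (k in seq_len(Ks))
    gdw[, k] <- cdwb$grads$w[cbind(seq_len(cf$F2), (k - 1) * cf$F2 + seq_len(cf$F2))]
  g$sep.dw <- gdw
  dsp <- cdwb$dx[, (ca$sl + 1):(ca$sl + T %/% cf$pool1), , drop = FALSE]
  dd1 <- dropout_backward(ca$dp1$cache, dsp)
  da1 <- avgpool_backward(ca$a1$cache, dd1$dx)
  de2 <- elu_backward(ca$e2$cache, da1$dx)
  db2 <- batchnorm_backward(ca$b2$cache, de2$dx)
  g$bn2.gamma <- db2$grads$gamma; g$bn2.beta <- db2$grads$beta

  # back through depthwise spatial stage
  r4 <- aperm(array(ca$b1$out, c(cf$F1, T, C, N)), c(3, 2, 1, 4))
  gdwsp <- matrix(0, cf$F2, C)
  dr4 <- array(0, c(C, T, cf$F1, N))
  for (f in seq_len(cf$F1)) {
    rows <- (f - 1) * cf$D + seq_len(cf$D)
    xf <- matrix(r4[, , f, ], C)
    dzf <- matrix(db2$dx[rows, , ], cf$D)
    gdwsp[rows, ] <- dzf %*% t(xf)
    dr4[, , f, ] <- array(t(p_dw(model)[rows, , drop = FALSE]) %*% dzf,
                          c(C, T, N))
  }
  g$dw.w <- gdwsp
  db1dx <- array(aperm(dr4, c(3, 2, 1, 4)), c(cf$F1, T, C * N))
  db1 <- batchnorm_backward(ca$b1$cache, db1dx)
  g$bn1.gamma <- db1$grads$gamma; g$bn1.beta <- db1$grads$beta
  c1b <- conv_backward(ca$c1$cache, db1$dx)
  g$conv1.w <- c1b$grads$w
  g
}

p_dw <- function(model) model$params$dw.w

# Renormalize constrained tensors after an optimizer step (depthwise spatial
# filters carry a max-norm constraint in the original design).
eegnet_apply_constraints <- function(model) {
  mn <- model$config$max_norm
  if (is.null(mn) || !is.finite(mn)) return(model)
  w <- model$params$dw.w
  nr <- sqrt(rowSums(w^2))
  sc <- pmin(1, mn / pmax(nr, 1e-12))
  model$params$dw.w <- w * sc
  model
}
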
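# Differentiable building blocks for the EEG models.
#
# Conventions:
#   * a batch of trials is an array dim (C, T, N), channel fastest;
#   * token matrices are (N*Tseq) x d_model with rows ordered time-within-trial
#     (row = t + (n-1)*Tseq);
#   * every *_forward returns list(out = ..., cache = ...) and the matching
#     *_backward takes (cache, dout) and returns list(dx = ..., grads = list()).
# Gradients are validated against central finite differences in the test suite.

conv_forward <- function(x, w, b) {
  y <- cpp_conv1d_forward(x, w, b)
  list(out = y, cache = list(x = x, w = w))
}

conv_backward <- function(cache, dy) {
  g <- cpp_conv1d_backward(cache$x, cache$w, dy)
  list(dx = g$dx, grads = list(w = g$dw, b = as.numeric(g$db)))
}

maxpool_forward <- function(x, pool) {
  r <- cpp_maxpool_forward(x, pool)
  list(out = r$y, cache = list(idx = r$idx, pool = pool, T_in = dim(x)[2]))
}

maxpool_backward <- function(cache, dy) {
  list(dx = cpp_maxpool_backward(dy, cache$idx, cache$pool, cache$T_in),
       grads = list())
}

avgpool_forward <- function(x, pool) {
  list(out = cpp_avgpool_forward(x, pool),
       cache = list(pool = pool, T_in = dim(x)[2]))
}

avgpool_backward <- function(cache, dy) {
  list(dx = cpp_avgpool_backward(dy, cache$pool, cache$T_in), grads = list())
}

elu_forward <- function(x, alpha = 1) {
  neg <- x < 0
  y <- x
  y[neg] <- alpha * (exp(x[neg]) - 1)
  list(out = y, cache = list(y = y, neg = neg, alpha = alpha))
}

elu_backward <- function(cache, dy) {
  dx <- dy
  dx[cache$neg] <- dy[cache$neg] * (cache$y[cache$neg] + cache$alpha)
  list(dx = dx, grads = list())
}

relu_forward <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(out = y, cache = list(mask = x > 0))
}

relu_backward <- function(cache, dy) {
  list(dx = dy * cache$mask, grads = list())
}

# Batch normalization over channels of a (C, T, N) batch; statistics pooled
# over time and trials (the 1-D analogue of per-feature-map normalization).
batchnorm_forward <- function(x, gamma, beta, run_mean, run_var,
                              training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1])                     # C x (T*N)
  if (training) {
    mu <- rowMeans(xm)
    v  <- rowMeans(xm^2) - mu^2             # biased (population) variance
    m  <- ncol(xm)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var  <- (1 - momentum) * run_var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- run_mean
    v  <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  y <- array(xhat * gamma + beta, d)
  list(out = y,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d,
                    training = training),
       run_mean = run_mean, run_var = run_var)
}

batchnorm_backward <- function(cache, dy) {
  d <- cache$d
  dym <- matrix(dy, d[1])
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$training) {
    m <- ncol(dym)
    dxhat <- dym * cache$gamma
    dxm <- (dxhat - rowMeans(dxhat) -
              cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$inv
  } else {
    dxm <- dym * cache$gamma * cache$inv
  }
  list(dx = array(dxm, d), grads = list(gamma = dgamma, beta = dbeta))
}

# Token-level linear layer: z (rows x d_in) %*% w (d_in x d_out) + b.
linear_forward <- function(z, w, b) {
  list(out = sweep(z %*% w, 2, b, "+"), cache = list(z = z, w = w))
}

linear_backward <- function(cache, dy) {
  list(dx = dy %*% t(cache$w),
       grads = list(w = crossprod(cache$z, dy), b = colSums(dy)))
}

layernorm_forward <- function(z, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(z)
  zc <- z - mu
  v <- rowMeans(zc^2)
  inv <- 1 / sqrt(v + eps)
  zhat <- zc * inv
  y <- sweep(sweep(zhat, 2, gamma, "*"), 2, beta, "+")
  list(out = y, cache = list(zhat = zhat, inv = inv, gamma = gamma))
}

layernorm_backward <- function(cache, dy) {
  dgamma <- colSums(dy * cache$zhat)
  dbeta <- colSums(dy)
  dzhat <- sweep(dy, 2, cache$gamma, "*")
  dz <- (dzhat - rowMeans(dzhat) -
           cache$zhat * rowMeans(dzhat * cache$zhat)) * cache$inv
  list(dx = dz, grads = list(gamma = dgamma, beta = dbeta))
}

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = list(mask = NULL)))
  mask <- array(stats::rbinom(length(x), 1, 1 - p), dim(x)) / (1 - p)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(cache, dy) {
  if (is.null(cache$mask)) return(list(dx = dy, grads = list()))
  list(dx = dy * cache$mask, grads = list())
}

row_softmax <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`: every output row is a convex
#' combination of the rows of `V`, weighted by the scaled similarity between
#' the corresponding query and all keys. The `1/sqrt(d_k)` factor keeps the
#' pre-softmax scores at unit scale so the softmax does not saturate.
#'
#' @param Q,K,V Numeric matrices of shape `T' x d_k` (queries, keys, values).
#' @param return_weights If `TRUE`, also return the attention weight matrix.
#' @return The `T' x d_k` attended output, or a list with elements `output`
#'   and `weights` when `return_weights = TRUE`. Attention weight rows sum
#'   to one.
#' @examples
#' Q <- matrix(rnorm(12), 3, 4)
#' out <- scaled_dot_product_attention(Q, Q, Q)
#' @export
scaled_dot_product_attention <- function(Q, K, V, return_weights = FALSE) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  A <- row_softmax(Q %*% t(K) / sqrt(ncol(K)))
  out <- A %*% V
  if (return_weights) list(output = out, weights = A) else out
}

#' Temporal mean pooling
#'
#' Collapses a `T' x d_model` encoder output to a single `d_model` embedding
#' by averaging over the time axis.
#'
#' @param z Numeric matrix, time steps in rows.
#' @return Numeric vector of length `ncol(z)`.
#' @export
temporal_mean_pool <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 1) stop("temporal_mean_pool: empty sequence")
  colMeans(z)
}

# Multi-head self-attention over a token matrix z (rows x d_model), rows
# grouped per trial (Tseq consecutive rows per trial). Dropout is applied to
# the attention probabilities when training.
mha_forward <- function(z, p, n_heads, Tseq, dropout_p, training) {
  rows <- nrow(z); d <- ncol(z)
  n <- rows / Tseq
  dk <- d / n_heads
  Q <- sweep(z %*% p$wq, 2, p$bq, "+")
  K <- sweep(z %*% p$wk, 2, p$bk, "+")
  V <- sweep(z %*% p$wv, 2, p$bv, "+")
  O <- matrix(0, rows, d)
  Alist <- vector("list", n * n_heads)
  for (i in seq_len(n)) {
    rs <- ((i - 1) * Tseq + 1):(i * Tseq)
    for (h in seq_len(n_heads)) {
      cs <- ((h - 1) * dk + 1):(h * dk)
      A <- row_softmax(Q[rs, cs, drop = FALSE] %*%
                         t(K[rs, cs, drop = FALSE]) / sqrt(dk))
      if (training && dropout_p > 0) {
        mask <- matrix(stats::rbinom(length(A), 1, 1 - dropout_p),
                       nrow(A)) / (1 - dropout_p)
        Ad <- A * mask
      } else {
        mask <- NULL
        Ad <- A
      }
      O[rs, cs] <- Ad %*% V[rs, cs, drop = FALSE]
      Alist[[(i - 1) * n_heads + h]] <- list(A = A, Ad = Ad, mask = mask)
    }
  }
  out <- sweep(O %*% p$wo, 2, p$bo, "+")
  list(out = out,
       cache = list(z = z, p = p, Q = Q, K = K, V = V, O = O, Alist = Alist,
                    n = n, n_heads = n_heads, Tseq = Tseq, dk = dk))
}

mha_backward <- function(cache, dy) {
  p <- cache$p
  dk <- cache$dk; Tseq <- cache$Tseq
  dwo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- dy %*% t(p$wo)
  dQ <- matrix(0, nrow(dy), ncol(dy))
  dK <- dQ; dV <- dQ
  for (i in seq_len(cache$n)) {
    rs <- ((i - 1) * Tseq + 1):(i * Tseq)
    for (h in seq_len(cache$n_heads)) {
      cs <- ((h - 1) * dk + 1):(h * dk)
      st <- cache$Alist[[(i - 1) * cache$n_heads + h]]
      dOh <- dO[rs, cs, drop = FALSE]
      Vh <- cache$V[rs, cs, drop = FALSE]
      dAd <- dOh %*% t(Vh)
      dV[rs, cs] <- crossprod(st$Ad, dOh)
      dA <- if (is.null(st$mask)) dAd else dAd * st$mask
      # softmax jacobian, row-wise
      dS <- st$A * (dA - rowSums(dA * st$A))
      dS <- dS / sqrt(dk)
      dQ[rs, cs] <- dS %*% cache$K[rs, cs, drop = FALSE]
      dK[rs, cs] <- crossprod(dS, cache$Q[rs, cs, drop = FALSE])
    }
  }
  dz <- dQ %*% t(p$wq) + dK %*% t(p$wk) + dV %*% t(p$wv)
  list(dx = dz,
       grads = list(wq = crossprod(cache$z, dQ), bq = colSums(dQ),
                    wk = crossprod(cache$z, dK), bk = colSums(dK),
                    wv = crossprod(cache$z, dV), bv = colSums(dV),
                    wo = dwo, bo = dbo))
}

# Softmax cross-entropy; labels are integers in 1..n_classes.
softmax_xent <- function(logits, labels) {
  pr <- row_softmax(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(pr[cbind(seq_len(n), labels)], 1e-12)))
  dlogits <- pr
  dlogits[cbind(seq_len(n), labels)] <-
    dlogits[cbind(seq_len(n), labels)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = pr)
}

# --- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

# Classic coupled weight decay (L2 added to the gradient), as in the
# reference Adam implementation of mainstream frameworks.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Fan-in-scaled uniform initialization.
init_uniform <- function(dims, fan_in, rng_scale = 1) {
  b <- rng_scale / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dims)
}

init_xavier <- function(d_in, d_out) {
  b <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -b, b), d_in, d_out)
}
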
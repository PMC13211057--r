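# Architecture contracts: shape chain, attention semantics, parameter and
# FLOP accounting, eval-mode determinism, and the EEGNet baseline.

test_that("the default decoder reproduces the documented shape chain", {
  cf <- decoder_config()
  expect_equal(unname(cf$shape_chain), c(1256, 314, 300, 75))
  expect_equal(cf$seq_len, 75)
  m <- build_eegdecoder(cf, seed = 1)
  x <- array(rnorm(2 * 19 * 1280), c(2, 19, 1280))
  r <- decoder_forward(m, x, return_features = TRUE)
  expect_equal(dim(r$cnn_features), c(64, 75, 2))
  expect_equal(dim(r$scores), c(2, 3))
  expect_true(all(is.finite(r$scores)))
})

test_that("shape errors name expected vs got", {
  m <- build_eegdecoder(tiny_decoder_config(), seed = 1)
  expect_error(decoder_forward(m, array(0, c(2, 4, 64))),
               "expected N x 3 x 64")
  expect_error(decoder_forward(m, array(0, c(2, 3, 65))), "65")
})

test_that("scaled dot-product attention matches a brute-force oracle", {
  set.seed(51)
  # T' = 1: softmax over one element, output equals V
  Q1 <- matrix(rnorm(4), 1); V1 <- matrix(rnorm(4), 1)
  expect_equal(scaled_dot_product_attention(Q1, Q1, V1), V1)
  # zero scores: uniform weights -> column means of V
  Z <- matrix(0, 5, 4); V <- matrix(rnorm(20), 5, 4)
  out0 <- scaled_dot_product_attention(Z, Z, V)
  expect_equal(out0, matrix(colMeans(V), 5, 4, byrow = TRUE))
  # random case vs explicit loop
  Q <- matrix(rnorm(20), 5, 4); K <- matrix(rnorm(20), 5, 4)
  res <- scaled_dot_product_attention(Q, K, V, return_weights = TRUE)
  oracle <- matrix(0, 5, 4)
  for (i in 1:5) {
    s <- sapply(1:5, function(j) sum(Q[i, ] * K[j, ]) / sqrt(4))
    w <- exp(s) / sum(exp(s))
    oracle[i, ] <- colSums(w * V)
  }
  expect_equal(res$output, oracle, tolerance = 1e-6)
  expect_equal(unname(rowSums(res$weights)), rep(1, 5), tolerance = 1e-6)
})

test_that("attention rows sum to one for arbitrary inputs", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(2:8, 1); d <- sample(2:6, 1)
    w <- scaled_dot_product_attention(matrix(rnorm(n * d, sd = 5), n),
                                      matrix(rnorm(n * d, sd = 5), n),
                                      matrix(rnorm(n * d), n),
                                      return_weights = TRUE)$weights
    expect_equal(unname(rowSums(w)), rep(1, n), tolerance = 1e-6)
  }
})

test_that("temporal mean pooling is the arithmetic time average", {
  v <- rnorm(8)
  z <- matrix(v, 5, 8, byrow = TRUE)
  expect_equal(temporal_mean_pool(z), v)
  set.seed(53)
  r <- matrix(rnorm(75 * 64), 75)
  expect_equal(temporal_mean_pool(r),
               apply(r, 2, function(cc) sum(cc) / 75), tolerance = 1e-9)
  expect_length(temporal_mean_pool(r), 64)
  expect_error(temporal_mean_pool(matrix(0, 0, 4)), "empty")
})

test_that("parameter enumeration equals the closed-form layer sums", {
  m <- build_eegdecoder(seed = 2)
  expect_identical(count_parameters(m), 654723L)
  expect_identical(as.integer(decoder_parameter_formula()), 654723L)
  # CNN front end alone: conv + batch-norm stages
  cnn <- 19 * 64 * 25 + 64 + 2 * 64 + 64 * 64 * 15 + 64 + 2 * 64
  expect_equal(cnn, 92224)
  head_n <- 64 * 3 + 3
  expect_equal(head_n, 195)
  # removing the classifier drops exactly its 195 scalars
  m2 <- m
  m2$params$head.w <- NULL
  m2$params$head.b <- NULL
  expect_equal(count_parameters(m2), 654723 - 195)
  # consistency on a non-default geometry too
  cfs <- small_decoder_config()
  expect_equal(count_parameters(build_eegdecoder(cfs, seed = 1)),
               as.integer(decoder_parameter_formula(cfs)))
})

test_that("FLOP accounting follows the documented convention", {
  m <- build_eegdecoder(seed = 2)
  fl <- count_flops(m, breakdown = TRUE)
  # conv1 MAC backbone: 2 * 19*25*64*1256 plus elementwise terms
  expect_gte(fl[["conv1"]], 2 * 19 * 25 * 64 * 1256)
  expect_lt(fl[["conv1"]], 2 * 19 * 25 * 64 * 1256 * 1.01)
  # classifier: 2*64*3 MAC-FLOPs + 3 bias adds
  expect_equal(unname(fl[["head"]]), 2 * 64 * 3 + 3)
  expect_equal(sum(fl), count_flops(m))
})

test_that("eval-mode forward is deterministic and per-trial independent", {
  m <- build_eegdecoder(small_decoder_config(), seed = 3)
  set.seed(54)
  x <- array(rnorm(3 * 4 * 160), c(3, 4, 160))
  s1 <- decoder_forward(m, x)
  s2 <- decoder_forward(m, x)
  expect_identical(s1, s2)
  # duplicated trial -> identical rows; batch permutation equivariance
  xx <- x[c(1, 1, 2, 3), , ]
  ss <- decoder_forward(m, xx)
  expect_equal(ss[1, ], ss[2, ], tolerance = 1e-12)
  perm <- c(3, 1, 2)
  expect_equal(decoder_forward(m, x[perm, , ]), s1[perm, ],
               tolerance = 1e-12)
})

test_that("EEGNet-8,2 baseline honors its width contract and forward shape", {
  cf <- eegnet_config()
  expect_equal(cf$F2, 16)       # F2 = F1 x D
  m <- build_eegnet(cf, seed = 4)
  set.seed(55)
  x <- array(rnorm(2 * 19 * 1280), c(2, 19, 1280))
  s <- decoder_forward(m, x)
  expect_equal(dim(s), c(2, 3))
  expect_true(all(is.finite(s)))
  # dropout disabled in eval mode: repeated passes identical
  expect_identical(s, decoder_forward(m, x))
  # depthwise max-norm constraint enforcement
  m$params$dw.w <- m$params$dw.w * 100
  m2 <- eegdecoder:::eegnet_apply_constraints(m)
  expect_lte(max(sqrt(rowSums(m2$params$dw.w^2))), 1 + 1e-6)
})

test_that("decoder gradients match central finite differences (tiny config)", {
  set.seed(56)
  cf <- tiny_decoder_config()
  m <- build_eegdecoder(cf, seed = 11)
  x <- array(rnorm(3 * 64 * 4), c(3, 64, 4))
  y <- c(1, 2, 3, 1)
  fw <- eegdecoder:::decoder_forward_full(m, x, training = TRUE,
                                          keep_cache = TRUE)
  ls <- eegdecoder:::softmax_xent(fw$logits, y)
  gr <- eegdecoder:::decoder_backward_full(m, fw, ls$dlogits)
  loss_at <- function(mm) {
    f <- eegdecoder:::decoder_forward_full(mm, x, training = TRUE)
    eegdecoder:::softmax_xent(f$logits, y)$loss
  }
  for (nm in c("conv1.w", "bn1.gamma", "conv2.w", "enc1.wq", "enc1.ffn.w1",
               "enc2.wo", "enc2.ln2.beta", "head.w")) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      h <- 1e-5
      mp <- m; mp$params[[nm]][i] <- p[i] + h
      mm_ <- m; mm_$params[[nm]][i] <- p[i] - h
      fd <- (loss_at(mp) - loss_at(mm_)) / (2 * h)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-3)
    }
  }
})

test_that("EEGNet gradients match finite differences (tiny config)", {
  set.seed(57)
  cf <- eegnet_config(F1 = 2, D = 2, temporal_kernel = 8,
                      separable_kernel = 4, pool1 = 2, pool2 = 2,
                      dropout = 0, in_channels = 3, input_samples = 32)
  m <- build_eegnet(cf, seed = 12)
  x <- array(rnorm(3 * 32 * 4), c(3, 32, 4))
  y <- c(1, 2, 3, 2)
  fw <- eegdecoder:::eegnet_forward_full(m, x, training = TRUE,
                                         keep_cache = TRUE)
  ls <- eegdecoder:::softmax_xent(fw$logits, y)
  gr <- eegdecoder:::eegnet_backward_full(m, fw, ls$dlogits)
  loss_at <- function(mm) {
    f <- eegdecoder:::eegnet_forward_full(mm, x, training = TRUE)
    eegdecoder:::softmax_xent(f$logits, y)$loss
  }
  for (nm in c("conv1.w", "dw.w", "sep.dw", "sep.pw", "bn2.gamma",
               "head.w")) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      h <- 1e-5
      mp <- m; mp$params[[nm]][i] <- p[i] + h
      mm_ <- m; mm_$params[[nm]][i] <- p[i] - h
      fd <- (loss_at(mp) - loss_at(mm_)) / (2 * h)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-3)
    }
  }
})

test_that("compiled and reference training paths agree on loss and gradients", {
  set.seed(58)
  cf <- tiny_decoder_config()
  m <- build_eegdecoder(cf, seed = 13)
  x <- array(rnorm(3 * 64 * 6), c(3, 64, 6))
  y <- c(1L, 2L, 3L, 1L, 2L, 3L)
  fw <- eegdecoder:::decoder_forward_full(m, x, training = TRUE,
                                          keep_cache = TRUE)
  ls <- eegdecoder:::softmax_xent(fw$logits, y)
  gr <- eegdecoder:::decoder_backward_full(m, fw, ls$dlogits)
  g2 <- cpp_decoder_grads(m$params, unclass(m$config), x, y, m$state, TRUE)
  expect_equal(g2$loss, ls$loss, tolerance = 1e-5)
  for (nm in names(gr)) {
    scale <- max(abs(gr[[nm]]), 1e-4)   # zero-gradient tensors: roundoff only
    expect_lt(max(abs(gr[[nm]] - g2$grads[[nm]])) / scale, 1e-3)
  }
})
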
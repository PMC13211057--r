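# Shared fixtures: small model configurations and miniature cohorts so the
# heavy default geometry is exercised only where the contract demands it.

tiny_decoder_config <- function(dropout = 0) {
  decoder_config(in_channels = 3, input_samples = 64, conv1_out = 6,
                 conv1_kernel = 7, conv2_out = 8, conv2_kernel = 5,
                 pool = 2, encoder_layers = 2, attention_heads = 2,
                 d_model = 8, ffn_dim = 16, dropout = dropout, n_classes = 3)
}

small_decoder_config <- function() {
  decoder_config(in_channels = 4, input_samples = 160, conv1_out = 8,
                 conv1_kernel = 9, conv2_out = 8, conv2_kernel = 5,
                 pool = 2, encoder_layers = 2, attention_heads = 2,
                 d_model = 8, ffn_dim = 16, dropout = 0.1)
}

random_trialset <- function(n = 6, C = 3, T = 64, fs = 64,
                            subjects = NULL, labels = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(subjects))
    subjects <- rep(sprintf("s%d", seq_len(max(2, n %/% 3))),
                    length.out = n)
  if (is.null(labels)) {
    lab_by_subject <- setNames(
      rep(c("AD", "CJD", "CNTRL"), length.out = length(unique(subjects))),
      unique(subjects))
    labels <- lab_by_subject[subjects]
  }
  trial_set(array(rnorm(n * C * T), c(n, C, T)), subjects, labels, fs,
            epoch_s = T / fs)
}

# A linearly separable two-class toy problem the models must be able to fit:
# class 1 carries a strong 6 Hz rhythm, class 2 a strong 12 Hz rhythm.
toy_rhythm_trialset <- function(n_per_class = 20, C = 3, T = 64, fs = 64,
                                amp = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  arr <- array(rnorm(n * C * T, sd = 1), c(n, C, T))
  tt <- seq_len(T) / fs
  for (i in seq_len(n_per_class)) {
    arr[i, , ] <- arr[i, , ] +
      matrix(amp * sin(2 * pi * 6 * tt + runif(1, 0, 6)), C, T, byrow = TRUE)
    j <- n_per_class + i
    arr[j, , ] <- arr[j, , ] +
      matrix(amp * sin(2 * pi * 12 * tt + runif(1, 0, 6)), C, T, byrow = TRUE)
  }
  subjects <- rep(c("a1", "a2", "b1", "b2"), each = n_per_class / 2)
  labels <- rep(c("AD", "CJD"), each = n_per_class)
  trial_set(arr, subjects, labels, fs, epoch_s = T / fs)
}
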
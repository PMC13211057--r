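# Leave-one-subject-out protocol: split structure, stratified inner folds,
# and leakage safety on a miniature end-to-end run.

test_that("LOSO splits partition the subjects", {
  ids <- sprintf("s%02d", 1:36)
  sp <- make_loso_splits(ids)
  expect_length(sp, 36)
  expect_true(all(vapply(sp, function(s) length(s$train), 0) == 35))
  tests <- vapply(sp, function(s) s$test, "")
  expect_setequal(tests, ids)
  expect_false(anyDuplicated(tests) > 0)
  for (s in sp) expect_false(s$test %in% s$train)
  expect_length(make_loso_splits(c("a", "b")), 2)
  expect_error(make_loso_splits(c("a", "a", "b")), "duplicate")
})

test_that("inner folds are stratified subject-level partitions", {
  ids <- sprintf("s%02d", 1:35)
  labs <- setNames(rep(c("AD", "CJD", "CNTRL"), length.out = 35), ids)
  f <- make_inner_folds(ids, labs, k = 5, seed = 1)
  expect_length(f, 5)
  sizes <- lengths(f)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_setequal(unlist(f), ids)
  expect_equal(sum(lengths(f)), 35)        # each subject exactly once
  # class balance within one apart across folds
  for (cl in c("AD", "CJD", "CNTRL")) {
    cnt <- vapply(f, function(g) sum(labs[g] == cl), 0)
    expect_lte(max(cnt) - min(cnt), 1)
  }
  # 12 subjects of one class over 5 folds
  ids12 <- sprintf("t%02d", 1:12)
  labs12 <- setNames(rep("AD", 12), ids12)
  f12 <- make_inner_folds(ids12, labs12, k = 5, seed = 2)
  cnt12 <- lengths(f12)
  expect_lte(max(cnt12) - min(cnt12), 1)
  expect_error(make_inner_folds(ids[1:3], labs[1:3], k = 5), "fewer")
})

test_that("a miniature nested LOSO run is leakage-safe and structurally sound", {
  # 6 subjects x 6 trials of short separable signals; tiny model
  set.seed(81)
  fs <- 64; T <- 64
  n_subj <- 6; m <- 6
  subj <- sprintf("s%d", 1:n_subj)
  labs <- rep(c("AD", "CJD", "CNTRL"), 2)
  arr <- array(rnorm(n_subj * m * 3 * T), c(n_subj * m, 3, T))
  freqs <- c(AD = 4, CJD = 9, CNTRL = 16)
  tt <- (seq_len(T) - 1) / fs
  for (i in seq_len(n_subj)) {
    idx <- ((i - 1) * m + 1):(i * m)
    wave <- 4 * sin(2 * pi * freqs[labs[i]] * tt + runif(1, 0, 6))
    for (j in idx) arr[j, , ] <- arr[j, , ] + matrix(wave, 3, T,
                                                     byrow = TRUE)
  }
  ts <- trial_set(arr, rep(subj, each = m), rep(labs, each = m), fs,
                  epoch_s = 1)
  cf <- decoder_config(in_channels = 3, input_samples = T, conv1_out = 6,
                       conv1_kernel = 7, conv2_out = 8, conv2_kernel = 5,
                       pool = 2, attention_heads = 2, d_model = 8,
                       ffn_dim = 16, dropout = 0.1)
  tc <- train_config(batch_size = 8, max_epochs = 8,
                     early_stop_patience = 8, inner_folds = 2, seed = 11)
  res <- run_loso(ts, function(s) build_eegdecoder(cf, seed = s), tc)
  expect_s3_class(res, "loso_result")
  expect_length(res$folds, n_subj)
  # every held-out subject got per-trial scores for all its trials
  for (f in res$folds) {
    expect_equal(nrow(f$trial_scores), m)
    expect_true(f$subject_pred %in% c("AD", "CJD", "CNTRL"))
    expect_true(f$inner_fold %in% 1:2)
  }
  expect_setequal(vapply(res$folds, function(f) f$held_out_subject, ""),
                  subj)
  rep_ <- compute_metrics(res)
  expect_equal(rep_$subject$n, n_subj)
  expect_equal(rep_$trial$n, n_subj * m)
  expect_true(all(rep_$subject$confusion >= 0))
})

test_that("run_loso aborts if a held-out subject reaches an inner fold", {
  ts <- random_trialset(n = 18, C = 3, T = 64, seed = 82,
                        subjects = rep(sprintf("s%d", 1:6), each = 3))
  # sabotage the fold builder through an impossible subject set
  expect_error(
    with_mocked_bindings(
      make_inner_folds = function(train_subjects, labels, k, seed)
        list(train_subjects, ts$subject_ids[1:2]),
      run_loso(ts, function(s) build_eegdecoder(tiny_decoder_config(),
                                                seed = s),
               train_config(inner_folds = 2, max_epochs = 1,
                            early_stop_patience = 1, batch_size = 8))),
    "inner")
})

test_that("the robustness harness aggregates accuracy over seeds", {
  ts <- random_trialset(n = 12, C = 3, T = 64, seed = 83,
                        subjects = rep(sprintf("s%d", 1:4), each = 3),
                        labels = rep(c("AD", "CJD", "CNTRL", "AD"),
                                     each = 3))
  cf <- tiny_decoder_config()
  tc <- train_config(batch_size = 8, max_epochs = 1,
                     early_stop_patience = 1, inner_folds = 2)
  out <- suppressWarnings(
    run_loso_seeds(ts, seeds = c(1, 2), config = tc,
                   model_builder = function(s)
                     build_eegdecoder(cf, seed = s)))
  expect_length(out$accuracies, 2)
  expect_equal(out$mean, mean(out$accuracies))
  expect_false(is.na(out$sd))
})
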
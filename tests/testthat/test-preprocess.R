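# Segment excision, filtering, resampling, ICA ocular removal, epoching and
# leakage-safe normalization.

test_that("annotated segments are excised with interval-union semantics", {
  set.seed(41)
  fs <- 128
  rec <- raw_recording(matrix(rnorm(19 * 300 * fs), 19), fs)
  cr <- remove_annotated_segments(rec,
                                  artifact_annotations(c(10, 50), c(20, 55)))
  expect_length(cr$runs, 3)
  expect_equal(sum(vapply(cr$runs, ncol, 0)) / fs, 285)
  expect_equal(cr$excised_s, 15)

  # empty annotations: identity
  cr0 <- remove_annotated_segments(rec, artifact_annotations())
  expect_length(cr0$runs, 1)
  expect_equal(ncol(cr0$runs[[1]]), ncol(rec$data))

  # overlapping intervals merge before excision
  crm <- remove_annotated_segments(rec,
                                   artifact_annotations(c(10, 20), c(30, 40)))
  expect_length(crm$runs, 2)
  expect_equal(crm$excised_s, 30)

  # conservation to one sample, also under many random interval sets
  for (i in 1:20) {
    on <- sort(runif(5, 0, 290))
    ann <- artifact_annotations(on, on + runif(5, 0.5, 20))
    cri <- suppressWarnings(remove_annotated_segments(rec, ann))
    expect_equal(sum(vapply(cri$runs, ncol, 0)) / fs + cri$excised_s,
                 300, tolerance = 1 / fs)
  }

  # out-of-range interval clipped with warning
  expect_warning(remove_annotated_segments(
    rec, artifact_annotations(295, 310)), "clipped")
})

test_that("filters notch out 50 Hz, preserve 10 Hz, and kill DC", {
  fs <- 256; n <- fs * 40
  tt <- (seq_len(n) - 1) / fs
  mid <- (5 * fs):(35 * fs)
  x50 <- matrix(sin(2 * pi * 50 * tt), 19, n, byrow = TRUE)
  f50 <- apply_filters(x50, fs)
  expect_lt(sd(f50[1, mid]) / sd(x50[1, mid]), 0.1)      # >= 20 dB
  x10 <- matrix(sin(2 * pi * 10 * tt), 19, n, byrow = TRUE)
  f10 <- apply_filters(x10, fs)
  expect_gt(sd(f10[1, mid]) / sd(x10[1, mid]), 0.9)
  expect_lt(sd(f10[1, mid]) / sd(x10[1, mid]), 1.1)
  dc <- apply_filters(matrix(7, 19, n), fs)
  expect_lt(max(abs(dc[1, mid])), 1e-6 * 7)
  expect_warning(apply_filters(matrix(rnorm(19 * 50), 19), fs),
                 "too short")
})

test_that("downsampling preserves in-band content; upsampling is refused", {
  fs <- 512
  tt <- (seq_len(fs * 10) - 1) / fs
  rec <- raw_recording(matrix(sin(2 * pi * 10 * tt), 19, length(tt),
                              byrow = TRUE), fs)
  r2 <- resample_recording(rec, 256)
  ref <- sin(2 * pi * 10 * (seq_len(2560) - 1) / 256)
  expect_gt(cor(r2$data[1, ], ref), 0.999)
  expect_equal(ncol(r2$data), 2560)        # duration preserved
  same <- resample_recording(rec, 512)
  expect_identical(same$data, rec$data)
  expect_error(resample_recording(rec, 1024), "upsampling")
})

test_that("ICA removes an injected blink source and spares posterior rhythm", {
  spec <- cohort_spec(n_subjects_per_class = 1, duration_s = 60,
                      master_seed = 21, artifact_rate_per_min = 0)
  sp <- sample_subject_params("CNTRL", spec, 1)
  g <- generate_subject_recording(sp, default_class_effects()$CNTRL,
                                  return_components = TRUE)
  blink <- attr(g, "components")$blink
  run <- apply_filters(g$recording$data, 256)
  blink_f <- as.vector(apply_filters(
    matrix(blink, 1, length(blink))[rep(1, 19), ], 256)[1, ])
  post <- which(montage_10_20() %in% c("O1", "OZ", "O2", "P3", "PZ", "P4"))
  cor_before <- abs(cor(run[1, ], blink_f))
  rms_before <- sqrt(mean(run[post, ]^2))
  cleaned <- remove_ocular_components(run, 256, seed = 4)
  expect_gte(attr(cleaned, "n_removed"), 1)
  cor_after <- abs(cor(cleaned[1, ], blink_f))
  rms_after <- sqrt(mean(cleaned[post, ]^2))
  expect_lt(cor_after, 0.5 * cor_before)
  expect_lt(abs(rms_after - rms_before) / rms_before, 0.10)
})

test_that("ICA leaves blink-free data essentially unchanged and skips short runs", {
  set.seed(43)
  fs <- 256
  # correlated rhythm-plus-noise data without any ocular source
  A <- matrix(rnorm(19 * 5), 19)
  S <- matrix(rnorm(5 * fs * 40), 5)
  x <- A %*% S + 0.1 * matrix(rnorm(19 * fs * 40), 19)
  out <- remove_ocular_components(x, fs, seed = 4)
  cors <- vapply(1:19, function(i) cor(out[i, ], x[i, ]), 0)
  expect_true(all(cors > 0.95))
  expect_warning(remove_ocular_components(x[, 1:(10 * fs)], fs, seed = 4),
                 "ICA skipped")
})

test_that("epoching respects run boundaries, temporal order and the cap", {
  set.seed(44)
  fs <- 128
  rec <- raw_recording(matrix(rnorm(19 * 200 * fs), 19), fs,
                       subject_id = "E1", class_label = "AD")
  cr <- remove_annotated_segments(rec, artifact_annotations())
  ts <- epoch_runs(cr, duration_s = 5, cap_per_subject = 40)
  expect_equal(dim(ts$trials)[1], 40)      # 200 s -> the full cap

  rec87 <- raw_recording(matrix(rnorm(19 * 87 * fs), 19), fs,
                         subject_id = "E2", class_label = "CJD")
  ts87 <- epoch_runs(remove_annotated_segments(rec87,
                                               artifact_annotations()))
  expect_equal(dim(ts87$trials)[1], 17)    # floor(87 / 5)

  # runs shorter than one window yield nothing
  rec4 <- raw_recording(matrix(rnorm(19 * round(4.9 * fs)), 19), fs,
                        subject_id = "E3", class_label = "AD")
  expect_warning(
    ts0 <- epoch_runs(remove_annotated_segments(rec4,
                                                artifact_annotations())),
    "empty trial set")
  expect_equal(dim(ts0$trials)[1], 0)

  # no trial crosses an excision: first window starts at the run start
  ann <- artifact_annotations(2.5, 4)
  tsb <- epoch_runs(remove_annotated_segments(rec, ann), 5, 40)
  run2_start <- floor(4 * fs) / fs
  expect_equal(tsb$trials[1, , ],
               rec$data[, floor(4 * fs) + (1:(5 * fs))],
               ignore_attr = TRUE)
})

test_that("normalizer is train-only and guards constant channels", {
  ts <- random_trialset(n = 9, C = 4, T = 32, fs = 32, seed = 45)
  np <- fit_channel_normalizer(ts)
  z <- apply_normalizer(ts, np)
  for (c_i in 1:4) {
    v <- as.vector(z$trials[, c_i, ])
    expect_lt(abs(mean(v)), 1e-6)
    expect_equal(sd(v), 1, tolerance = 1e-3)
  }
  # constant channel: finite zeros through the epsilon path
  ts$trials[, 2, ] <- 5
  z2 <- apply_normalizer(ts, fit_channel_normalizer(ts))
  expect_true(all(is.finite(z2$trials)))
  expect_true(all(z2$trials[, 2, ] == 0))
  # train-fitted parameters leave a shifted test set off-center
  shifted <- ts
  shifted$trials <- shifted$trials + 3
  zs <- apply_normalizer(shifted, np)
  expect_gt(abs(mean(zs$trials[, 1, ])), 0.5)
})

test_that("excise/epoch order is irrelevant on artifact-free input", {
  set.seed(46)
  fs <- 64
  rec <- raw_recording(matrix(rnorm(19 * 40 * fs), 19), fs,
                       subject_id = "O1", class_label = "CNTRL")
  direct <- epoch_runs(remove_annotated_segments(rec,
                                                 artifact_annotations()))
  # epoching the raw matrix directly gives identical windows
  manual <- sapply(seq_len(8), function(w)
    rec$data[, ((w - 1) * 5 * fs + 1):(w * 5 * fs)], simplify = "array")
  expect_equal(aperm(direct$trials, c(2, 3, 1)), manual,
               ignore_attr = TRUE)
})
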
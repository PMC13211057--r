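# Generator contracts: determinism, subject-parameter distributions,
# component structure, artifact statistics, and cohort-level spectral
# separability.

test_that("subject parameter sampling is deterministic and distributionally sane", {
  spec <- cohort_spec(n_subjects_per_class = 2, duration_s = 20,
                      master_seed = 5)
  a <- sample_subject_params("AD", spec, 1)
  b <- sample_subject_params("AD", spec, 1)
  expect_identical(a, b)
  # adding subjects never perturbs existing ones (counter-based streams)
  spec2 <- cohort_spec(n_subjects_per_class = 10, duration_s = 20,
                       master_seed = 5)
  expect_identical(sample_subject_params("AD", spec2, 1), a)
  expect_error(sample_subject_params("XX", spec), "unknown class")
  # control subjects carry no periodic sharp-wave component
  expect_equal(default_class_effects()$CNTRL$pswc_rate_hz, 0)
  # LogNormal(0, 0.2) gain multiplier: median 1
  gm <- vapply(1:400, function(i)
    sample_subject_params("CNTRL",
                          cohort_spec(master_seed = i, duration_s = 20),
                          1)$gain_multiplier, 0)
  expect_gt(median(gm), 0.9)
  expect_lt(median(gm), 1.1)
})

test_that("the CJD sharp-wave train is periodic at the configured rate", {
  spec <- cohort_spec(n_subjects_per_class = 1, duration_s = 60,
                      master_seed = 9, artifact_rate_per_min = 0)
  sp <- sample_subject_params("CJD", spec, 1)
  g <- generate_subject_recording(sp, default_class_effects()$CJD,
                                  pswc_jitter = 0, return_components = TRUE)
  s <- abs(attr(g, "components")$pswc)     # rectified isolated component
  ac <- stats::acf(s, lag.max = 300, plot = FALSE)$acf[-1]
  # 1 Hz at 256 Hz sampling: autocorrelation peak at lag 256
  expect_equal(which.max(ac[200:300]) + 199, 256, tolerance = 2)
})

test_that("artifact counts follow the configured Poisson rate", {
  counts <- vapply(1:20, function(i) {
    spec <- cohort_spec(n_subjects_per_class = 1, duration_s = 150,
                        master_seed = 100 + i, artifact_rate_per_min = 4)
    sp <- sample_subject_params("AD", spec, 1)
    nrow(generate_subject_recording(sp, default_class_effects()$AD)$annotations)
  }, 0)
  # mean of 20 draws at lambda = 10: the 99% band for the mean
  expect_gt(mean(counts), 10 - 2.58 * sqrt(10 / 20))
  expect_lt(mean(counts), 10 + 2.58 * sqrt(10 / 20))
})

test_that("zero gains produce a silent recording", {
  spec <- cohort_spec(n_subjects_per_class = 1, duration_s = 10,
                      master_seed = 3, artifact_rate_per_min = 0)
  sp <- sample_subject_params("CNTRL", spec, 1)
  sp$blink_rate_per_min <- 0
  ce <- default_class_effects()$CNTRL
  ce$background_gain <- 0; ce$rhythm_gain <- 0; ce$slowing_gain <- 0
  g <- generate_subject_recording(sp, ce)
  expect_true(all(g$recording$data == 0))
})

test_that("cohort generation is reproducible and correctly laid out", {
  spec <- cohort_spec(n_subjects_per_class = 2, duration_s = 20,
                      master_seed = 77, artifact_rate_per_min = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_cohort(spec, d1)
  m2 <- generate_cohort(spec, d2)
  expect_equal(nrow(m1$subjects), 6)       # 2 per class x 3 classes
  expect_length(list.files(d1, "[.]edf$"), 6)
  expect_length(list.files(d1, "_artifacts[.]json$"), 6)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # byte-identical regeneration
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), raw(),
                             file.info(file.path(d1, f))$size),
                     readBin(file.path(d2, f), raw(),
                             file.info(file.path(d2, f))$size),
                     info = f)
  }
  expect_setequal(m1$subjects$label, c("AD", "CJD", "CNTRL"))
  expect_false(anyDuplicated(m1$subjects$subject_id) > 0)
})

test_that("classes separate spectrally: AD > CNTRL theta/alpha ratio", {
  spec <- cohort_spec(n_subjects_per_class = 6, duration_s = 40,
                      master_seed = 2025)
  ratio <- function(cl) vapply(1:6, function(i) {
    sp <- sample_subject_params(cl, spec, i)
    theta_alpha_ratio(
      generate_subject_recording(sp, spec$class_effects[[cl]])$recording)
  }, 0)
  r_ad <- ratio("AD"); r_ct <- ratio("CNTRL")
  p <- stats::wilcox.test(r_ad, r_ct, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("default artifact load leaves ample clean signal per subject", {
  spec <- cohort_spec(n_subjects_per_class = 2, duration_s = 120,
                      master_seed = 13)
  for (cl in spec$classes) for (i in 1:2) {
    sp <- sample_subject_params(cl, spec, i)
    g <- generate_subject_recording(sp, spec$class_effects[[cl]])
    clean <- 120 - sum(g$annotations$offset_s - g$annotations$onset_s)
    expect_gte(clean, 120 * 0.85)
  }
})

test_that("the heavy-artifact flag starves one CJD subject of trials", {
  base <- cohort_spec(n_subjects_per_class = 1, duration_s = 60,
                      master_seed = 41, artifact_rate_per_min = 1)
  heavy <- cohort_spec(n_subjects_per_class = 1, duration_s = 60,
                       master_seed = 41, artifact_rate_per_min = 1,
                       heavy_artifact_subject = TRUE)
  n_trials <- function(spec) {
    sp <- sample_subject_params("CJD", spec, 1)
    g <- generate_subject_recording(sp, spec$class_effects$CJD)
    cr <- remove_annotated_segments(g$recording, g$annotations)
    dim(suppressWarnings(epoch_runs(cr, cap_per_subject = 40))$trials)[1]
  }
  expect_lt(n_trials(heavy), n_trials(base))
})

test_that("manifest loading validates ids and paths", {
  d <- withr::local_tempdir()
  spec <- cohort_spec(n_subjects_per_class = 1, duration_s = 10,
                      master_seed = 55, artifact_rate_per_min = 0)
  mf <- generate_cohort(spec, d)
  expect_equal(nrow(mf$subjects), 3)
  # break a referenced path
  raw <- jsonlite::fromJSON(file.path(d, "manifest.json"))
  raw$subjects$recording_path[1] <- "missing.edf"
  jsonlite::write_json(raw, file.path(d, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(read_manifest(file.path(d, "manifest.json")), "missing")
})
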
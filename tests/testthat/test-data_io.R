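# EDF round trips, channel-order normalization, annotation sidecars and the
# trial-set container.

test_that("EDF write/read round-trips within the 0.1 uV quantization step", {
  set.seed(31)
  fs <- 256
  x <- matrix(rnorm(19 * fs * 4, sd = 30), 19)
  rec <- raw_recording(x, fs, subject_id = "RT01")
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f)
  r2 <- read_recording(f)
  # half of the 0.1 uV resolution step (fixed +/-3276.7 uV 16-bit range)
  expect_lt(max(abs(r2$data - rec$data)), 0.05 + 1e-12)
  expect_equal(r2$sampling_rate_hz, fs)
  expect_identical(r2$channel_names, montage_10_20())
  expect_identical(r2$subject_id, "RT01")

  zero <- raw_recording(matrix(0, 19, fs), fs)
  f0 <- withr::local_tempfile(fileext = ".edf")
  write_recording(zero, f0)
  expect_true(all(read_recording(f0)$data == 0))

  sine <- raw_recording(
    matrix(100 * sin(2 * pi * 10 * (seq_len(fs * 2) - 1) / fs),
           19, fs * 2, byrow = TRUE), fs)
  fsn <- withr::local_tempfile(fileext = ".edf")
  write_recording(sine, fsn)
  expect_lte(max(abs(read_recording(fsn)$data - sine$data)),
             2 * EDF_PHYS_MAX / 2^16)
})

test_that("channel reordering is a pure permutation; mismatches are named", {
  set.seed(32)
  rec <- raw_recording(matrix(rnorm(19 * 256), 19), 256)
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f)
  fwd <- read_recording(f, expected_channels = montage_10_20())
  rev_ <- read_recording(f, expected_channels = rev(montage_10_20()))
  expect_equal(rev_$data, fwd$data[19:1, ])
  # multiset of per-channel sums invariant under reordering
  expect_equal(sort(rowSums(rev_$data)), sort(rowSums(fwd$data)))
  # case-insensitive + reference-suffix matching
  mixed <- paste0(tolower(montage_10_20()), "-Cz")
  expect_equal(read_recording(f, expected_channels = mixed)$data, fwd$data,
               ignore_attr = TRUE)
  expect_error(read_recording(f, expected_channels = c(montage_10_20()[-1],
                                                       "XX")),
               "channel mismatch.*XX")
})

test_that("invalid recordings are rejected before writing", {
  x <- matrix(0, 19, 256)
  x[3, 5] <- NaN
  expect_error(raw_recording(x, 256), "finite")
  rec <- raw_recording(matrix(0, 19, 256), 256)
  rec$data[1, 1] <- NA
  expect_error(write_recording(rec, tempfile()), "finite")
  expect_error(raw_recording(matrix(0, 18, 256), 256,
                             channel_names = montage_10_20()[1:18]),
               "expected 19 channels")
})

test_that("annotation sidecars validate, sort, and round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("[]", f)
  expect_equal(nrow(read_annotations(f)), 0)

  writeLines(paste0('[{"onset_s":50,"offset_s":55},',
                    '{"onset_s":10,"offset_s":20}]'), f)
  ann <- read_annotations(f)
  expect_equal(ann$onset_s, c(10, 50))
  expect_equal(ann$offset_s, c(20, 55))

  writeLines('[{"onset_s":20,"offset_s":20}]', f)
  expect_error(read_annotations(f), "onset_s < offset_s")
  expect_error(artifact_annotations(-1, 5), "non-negative")

  ann2 <- artifact_annotations(c(3.25, 1.5), c(4.75, 2))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann2, f2)
  expect_equal(read_annotations(f2)$onset_s, c(1.5, 3.25))
})

test_that("trial-set container round-trips subjects, labels and counts", {
  set.seed(33)
  # heterogeneous per-subject trial counts (40, 40, 17 pattern at small n)
  counts <- c(a = 5, b = 5, c = 2)
  subj <- rep(names(counts), counts)
  labs <- c(a = "AD", b = "CJD", c = "CNTRL")[subj]
  ts <- trial_set(array(rnorm(12 * 4 * 32), c(12, 4, 32)), subj, labs,
                  fs <- 32, epoch_s = 1)
  stem <- withr::local_tempfile()
  save_trialset(ts, stem)
  t2 <- load_trialset(stem)
  expect_identical(t2$subject_ids, ts$subject_ids)
  expect_identical(t2$labels, ts$labels)
  expect_equal(table(t2$subject_ids), table(ts$subject_ids))
  # float32 container: one write/read cycle is idempotent thereafter
  expect_lt(max(abs(t2$trials - ts$trials)), 1e-5)
  save_trialset(t2, stem)
  expect_identical(load_trialset(stem)$trials, t2$trials)

  # integrity: manifest/array disagreement
  mf <- jsonlite::fromJSON(paste0(stem, ".json"))
  mf$shape[1] <- 13
  jsonlite::write_json(mf, paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(load_trialset(stem), "integrity")
})

test_that("a subject must carry exactly one label", {
  expect_error(
    trial_set(array(0, c(2, 3, 32)), c("s1", "s1"), c("AD", "CJD"), 32,
              epoch_s = 1),
    "one class")
})

test_that("EDF files are readable by an independent parser", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(34)
  rec <- raw_recording(matrix(rnorm(19 * 512, sd = 20), 19), 256,
                       subject_id = "X01")
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import mne; raw = mne.io.read_raw_edf('", f, "', verbose='ERROR');",
    "import numpy as np; d = raw.get_data() * 1e6;",
    "print(d.shape[0], d.shape[1], round(float(np.abs(d).max()), 3))"
  ))), stdout = TRUE, stderr = FALSE))
  skip_if(length(out) == 0 || !nzchar(out[length(out)]),
          "mne not importable")
  vals <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  expect_equal(vals[1], 19)
  expect_equal(vals[2], 512)
  expect_equal(vals[3], round(max(abs(rec$data)), 1), tolerance = 0.01)
})
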
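# Synthetic EEG cohort generator.
#
# Emulates the statistical structure the evaluation protocol assumes:
# class-dependent spectral signatures, strong inter-subject variability,
# ocular (blink) activity on frontal channels, and annotated artifact
# segments with known extents. Class phenotypes follow canonical clinical
# EEG descriptions: controls show a dominant ~10 Hz posterior alpha rhythm;
# Alzheimer's disease shows attenuated alpha with amplified diffuse 4-7 Hz
# slowing; Creutzfeldt-Jakob disease adds quasi-periodic ~1 Hz triphasic
# sharp-wave complexes. This is an explicit stand-in for clinical data, not
# a biophysical forward model.

#' Default per-class signal parameters
#'
#' Gains are root-mean-square amplitudes in microvolts at the topographic
#' maximum; `pswc_rate_hz` is the periodic sharp-wave complex rate (CJD
#' only).
#'
#' @return Named list with one parameter set per class (`AD`, `CJD`,
#'   `CNTRL`).
#' @export
default_class_effects <- function() {
  list(
    CNTRL = list(rhythm_center_hz = 10.0, rhythm_bandwidth_hz = 2,
                 rhythm_gain = 18, slowing_gain = 4,
                 pswc_rate_hz = 0, pswc_amplitude = 0,
                 background_1f_exponent = 1.0, background_gain = 10),
    AD    = list(rhythm_center_hz = 9.0, rhythm_bandwidth_hz = 2,
                 rhythm_gain = 7, slowing_gain = 16,
                 pswc_rate_hz = 0, pswc_amplitude = 0,
                 background_1f_exponent = 1.2, background_gain = 10),
    CJD   = list(rhythm_center_hz = 9.5, rhythm_bandwidth_hz = 2,
                 rhythm_gain = 10, slowing_gain = 9,
                 pswc_rate_hz = 1.0, pswc_amplitude = 55,
                 background_1f_exponent = 1.1, background_gain = 10))
}

validate_class_effects <- function(ce) {
  for (cls in names(ce)) {
    e <- ce[[cls]]
    gains <- c(e$rhythm_gain, e$slowing_gain, e$pswc_amplitude,
               e$background_gain)
    if (any(gains < 0)) stop("class effect gains must be >= 0 (", cls, ")")
    if (e$pswc_rate_hz != 0 &&
        (e$pswc_rate_hz < 0.5 || e$pswc_rate_hz > 2))
      stop("pswc_rate_hz must be 0 or within [0.5, 2] (", cls, ")")
    if (e$rhythm_center_hz <= 1.6 || e$rhythm_center_hz >= 40)
      stop("rhythm_center_hz must lie inside the 1.6-40 Hz passband (",
           cls, ")")
  }
  ce
}

#' Cohort specification
#'
#' @param n_subjects_per_class Subjects per diagnostic group (default 12,
#'   i.e. 36 subjects in total).
#' @param classes Diagnostic groups to generate.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param duration_s Recording duration per subject in whole seconds.
#' @param class_effects Per-class signal parameters
#'   ([default_class_effects()]).
#' @param artifact_rate_per_min Expected annotated artifact segments per
#'   minute of recording.
#' @param master_seed Integer; the cohort is a pure function of
#'   (spec, master_seed). Per-subject substreams are derived by counter so
#'   adding subjects never perturbs existing ones.
#' @param heavy_artifact_subject If `TRUE`, the first CJD subject is
#'   generated with a much higher artifact load (exercises unequal
#'   per-subject trial counts downstream).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects_per_class = 12, classes = EEG_CLASSES,
                        sampling_rate_hz = 256, duration_s = 300,
                        class_effects = default_class_effects(),
                        artifact_rate_per_min = 1,
                        master_seed = 2025,
                        heavy_artifact_subject = FALSE) {
  stopifnot(n_subjects_per_class >= 1, duration_s >= 5)
  validate_class_effects(class_effects[classes])
  structure(list(n_subjects_per_class = n_subjects_per_class,
                 classes = classes, sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s, class_effects = class_effects,
                 artifact_rate_per_min = artifact_rate_per_min,
                 master_seed = master_seed,
                 heavy_artifact_subject = heavy_artifact_subject),
            class = "cohort_spec")
}

# Counter-based per-subject seed: independent of how many other subjects
# exist; kept below 2^31.
subject_seed <- function(master_seed, class_idx, subject_idx) {
  (as.numeric(master_seed) * 7919 + class_idx * 104729 +
     subject_idx * 131) %% 2147483647
}

# smooth scalp topographies over the 19-channel montage
topography <- function(channel_names, kind) {
  w <- setNames(rep(0.15, length(channel_names)), channel_names)
  bump <- function(chs, val) w[intersect(chs, names(w))] <<-
    pmax(w[intersect(chs, names(w))], val)
  switch(kind,
    posterior = { bump(c("O1", "OZ", "O2"), 1); bump(c("P3", "PZ", "P4"), 0.8)
                  bump(c("T5", "T6"), 0.6) },
    frontal   = { bump(c("FP1", "FP2"), 1); bump(c("F3", "F4", "FZ"), 0.45)
                  bump(c("F7", "F8"), 0.35) },
    central   = { bump(c("C3", "C4"), 1); bump(c("FZ", "PZ"), 0.7)
                  bump(c("F3", "F4", "P3", "P4"), 0.6) },
    diffuse   = { w[] <- 1 })
  unname(w)
}

#' Draw subject-level generative parameters
#'
#' Hierarchical sampling step (cohort to subject): subject peak-frequency
#' jitter ~ Normal(0, 0.5 Hz), overall gain multiplier ~ LogNormal(0, 0.2)
#' (median 1), and smooth source-to-channel topographies (posterior for the
#' rhythm, frontal for the ocular source) perturbed by Normal(0, 0.05)
#' noise.
#'
#' @param class_label One of the classes listed in `spec`.
#' @param spec A [cohort_spec()].
#' @param subject_idx 1-based index within the class.
#' @return A `subject_params` list (carries its own derived seed).
#' @export
sample_subject_params <- function(class_label, spec, subject_idx = 1) {
  cls_i <- match(class_label, spec$classes)
  if (is.na(cls_i)) stop("unknown class: ", class_label)
  seed <- subject_seed(spec$master_seed, cls_i, subject_idx)
  set.seed(seed)
  ch <- montage_10_20()
  C <- length(ch)
  mix <- cbind(rhythm = topography(ch, "posterior"),
               slowing = topography(ch, "diffuse"),
               pswc = topography(ch, "central"),
               blink = topography(ch, "frontal"))
  mix <- mix + matrix(rnorm(length(mix), 0, 0.05), nrow(mix))
  heavy <- isTRUE(spec$heavy_artifact_subject) && class_label == "CJD" &&
    subject_idx == 1
  prefix <- c(AD = "AD", CJD = "CJ", CNTRL = "CT")[class_label]
  if (is.na(prefix)) prefix <- substr(class_label, 1, 2)
  structure(list(
    subject_id = sprintf("%s%02d", prefix, subject_idx),
    class_label = class_label,
    peak_freq_offset_hz = rnorm(1, 0, 0.5),
    gain_multiplier = exp(rnorm(1, 0, 0.2)),
    channel_mixing = mix,
    recording_duration_s = spec$duration_s,
    artifact_rate_per_min = if (heavy) 12 * spec$artifact_rate_per_min
                            else spec$artifact_rate_per_min,
    blink_rate_per_min = runif(1, 8, 14),
    seed = seed), class = "subject_params")
}

# Fixed canonical scalp projections of the latent background generators,
# shared by all subjects (volume-conduction geometry is similar across
# heads); subjects differ by the standard small perturbation.
canonical_background_topographies <- function(C, n_bg) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) rs <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(424242)
  A <- matrix(rnorm(C * n_bg), C)
  A / sqrt(rowSums(A^2))
}

# 1/f^beta spectrally shaped unit-RMS Gaussian noise
one_over_f_noise <- function(n, fs, beta) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1e-3, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f + 1e-9)               # fold for the negative half
  X <- X * f^(-beta / 2)
  y <- Re(fft(X, inverse = TRUE)) / n
  y / sd(y)
}

# narrowband amplitude-modulated oscillation, unit RMS
rhythm_wave <- function(n, fs, f0, bw) {
  env <- abs(one_over_f_noise(n, fs, 2.5))  # slow positive envelope
  env <- env / mean(env)
  y <- env * sin(2 * pi * f0 * seq_len(n) / fs + runif(1, 0, 2 * pi))
  y / sd(y)
}

bandlimited_noise <- function(n, fs, lo, hi) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, rnorm(n + 2 * fs))[(fs + 1):(fs + n)]
  y / sd(y)
}

# triphasic sharp-wave complex template (~0.4 s at unit amplitude)
pswc_template <- function(fs) {
  tt <- seq(-0.2, 0.2, by = 1 / fs)
  g <- function(mu, s) exp(-(tt - mu)^2 / (2 * s^2))
  w <- -0.4 * g(-0.06, 0.025) + g(0, 0.02) - 0.55 * g(0.09, 0.05)
  w / max(abs(w))
}

# quasi-periodic PSWC train; period jitter +/-10% unless jitter = 0
pswc_train <- function(n, fs, rate, jitter = 0.1) {
  y <- numeric(n)
  tpl <- pswc_template(fs)
  period <- fs / rate
  pos <- period / 2
  while (pos < n) {
    i0 <- round(pos)
    idx <- i0 + seq_along(tpl) - round(length(tpl) / 2)
    ok <- idx >= 1 & idx <= n
    y[idx[ok]] <- y[idx[ok]] + tpl[ok]
    pos <- pos + period * (1 + if (jitter > 0) runif(1, -jitter, jitter) else 0)
  }
  y
}

blink_train <- function(n, fs, rate_per_min) {
  y <- numeric(n)
  n_blinks <- rpois(1, rate_per_min * n / fs / 60)
  if (n_blinks == 0) return(y)
  starts <- sort(runif(n_blinks, 0, n / fs - 2))
  for (s in starts) {
    dur <- runif(1, 0.5, 2)
    m <- round(dur * fs)
    # smooth positive deflection; the high power keeps the lid-closure peak
    # sharp (most energy above the 1.6 Hz high-pass) inside a 0.5-2 s window
    w <- sin(pi * seq_len(m) / (m + 1))^6
    i0 <- round(s * fs)
    idx <- i0 + seq_len(m)
    ok <- idx >= 1 & idx <= n
    y[idx[ok]] <- y[idx[ok]] + w[ok]
  }
  y
}

#' Generate one subject's recording with annotated artifacts
#'
#' Builds the signal as a sum of latent sources mixed to the scalp:
#' per-channel 1/f background, an amplitude-modulated posterior rhythm at
#' the class center frequency plus subject offset, diffuse 1-7 Hz slowing,
#' (for CJD) a quasi-periodic triphasic sharp-wave train with ±10% period
#' jitter, frontal blinks, and injected artifact segments (alternating
#' electrode-pop steps and high-amplitude movement bursts) whose exact
#' extents are returned as annotations. All channels in microvolts.
#'
#' @param sp A [sample_subject_params()] result.
#' @param ce The class's effect parameters
#'   (`default_class_effects()[[sp$class_label]]`).
#' @param sampling_rate_hz Sampling rate.
#' @param pswc_jitter Relative period jitter of the sharp-wave train.
#' @param return_components Also attach the latent component time series
#'   (attribute `"components"`) for validation against ground truth.
#' @return List with elements `recording` ([raw_recording()]) and
#'   `annotations` ([artifact_annotations()]); attribute
#'   `"short_clean_warning"` is set when fewer than one artifact-free 5-s
#'   run survives.
#' @export
generate_subject_recording <- function(sp, ce, sampling_rate_hz = 256,
                                       pswc_jitter = 0.1,
                                       return_components = FALSE) {
  stopifnot(inherits(sp, "subject_params"))
  set.seed(sp$seed + 1)
  fs <- sampling_rate_hz
  n <- round(sp$recording_duration_s * fs)
  ch <- montage_10_20()
  C <- length(ch)
  g <- sp$gain_multiplier

  # background: a few latent 1/f sources volume-conducted to all channels
  # (correlated across the scalp, as in real EEG) plus small sensor noise.
  # Topographies are canonical (shared across subjects, like every other
  # source's) with the usual Normal(0, 0.05) subject perturbation.
  n_bg <- 8
  A_bg <- canonical_background_topographies(C, n_bg) +
    matrix(rnorm(C * n_bg, 0, 0.05), C)
  A_bg <- A_bg / sqrt(rowSums(A_bg^2))
  S_bg <- t(vapply(seq_len(n_bg), function(i)
    one_over_f_noise(n, fs, ce$background_1f_exponent), numeric(n)))
  bg <- A_bg %*% S_bg
  bg <- bg / apply(bg, 1, sd) * ce$background_gain * g
  bg <- bg + matrix(rnorm(C * n), C) * 0.15 * ce$background_gain * g

  f0 <- ce$rhythm_center_hz + sp$peak_freq_offset_hz
  rhythm <- outer(sp$channel_mixing[, "rhythm"],
                  rhythm_wave(n, fs, f0, ce$rhythm_bandwidth_hz) *
                    ce$rhythm_gain * g)
  slowing <- outer(sp$channel_mixing[, "slowing"],
                   bandlimited_noise(n, fs, 1, 7) * ce$slowing_gain * g)
  pswc_src <- if (ce$pswc_rate_hz > 0)
    pswc_train(n, fs, ce$pswc_rate_hz, pswc_jitter) * ce$pswc_amplitude * g
  else numeric(n)
  pswc <- outer(sp$channel_mixing[, "pswc"], pswc_src)
  blink_src <- blink_train(n, fs, sp$blink_rate_per_min) * 120
  blink <- outer(pmax(sp$channel_mixing[, "blink"], 0), blink_src)

  x <- bg + rhythm + slowing + pswc + blink

  # injected artifact segments with exact annotated extents
  n_art <- rpois(1, sp$artifact_rate_per_min * sp$recording_duration_s / 60)
  onsets <- numeric(0); offsets <- numeric(0)
  guard <- 0
  while (length(onsets) < n_art && guard < 200) {
    guard <- guard + 1
    dur <- runif(1, 0.8, 3.5)
    st <- runif(1, 0, sp$recording_duration_s - dur)
    if (any(st < offsets + 1 & st + dur > onsets - 1)) next  # keep separated
    onsets <- c(onsets, st); offsets <- c(offsets, st + dur)
    i0 <- max(1, round(st * fs)); i1 <- min(n, round((st + dur) * fs))
    seg <- i0:i1
    if (length(onsets) %% 2 == 1) {        # electrode-pop step on one channel
      chan <- sample(C, 1)
      x[chan, seg] <- x[chan, seg] +
        runif(1, 400, 900) * sample(c(-1, 1), 1) *
          exp(-(seq_along(seg)) / (0.8 * fs))
    } else {                               # movement burst on all channels
      burst <- matrix(rnorm(C * length(seg)), C) * runif(1, 150, 300)
      taper <- sin(pi * seq_along(seg) / (length(seg) + 1))
      x[, seg] <- x[, seg] + burst * rep(taper, each = C)
    }
  }
  ann <- artifact_annotations(onsets, offsets)

  # the EDF range is a hard physical bound
  x[x > EDF_PHYS_MAX] <- EDF_PHYS_MAX
  x[x < -EDF_PHYS_MAX] <- -EDF_PHYS_MAX

  rec <- raw_recording(x, fs, ch, subject_id = sp$subject_id,
                       class_label = sp$class_label)
  out <- list(recording = rec, annotations = ann)
  clean <- clean_run_lengths(sp$recording_duration_s, ann)
  if (!any(clean >= 5)) attr(out, "short_clean_warning") <- TRUE
  if (return_components)
    attr(out, "components") <- list(
      pswc = pswc_src, blink = blink_src,
      blink_weights = pmax(sp$channel_mixing[, "blink"], 0),
      rhythm_freq_hz = f0)
  out
}

clean_run_lengths <- function(duration_s, ann) {
  iv <- merge_intervals(ann$onset_s, ann$offset_s, duration_s)
  edges <- c(0, as.vector(t(iv)), duration_s)
  runs <- matrix(edges, ncol = 2, byrow = TRUE)
  pmax(runs[, 2] - runs[, 1], 0)
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one EDF recording and one JSON annotation sidecar per subject,
#' plus a cohort manifest. Subject identifiers are anonymized codes; class
#' labels live only in the manifest, never in the EDF headers.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, as returned by [read_manifest()].
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cls_i in seq_along(spec$classes)) {
    cls <- spec$classes[cls_i]
    for (s_i in seq_len(spec$n_subjects_per_class)) {
      sp <- sample_subject_params(cls, spec, s_i)
      gen <- generate_subject_recording(sp, spec$class_effects[[cls]],
                                        spec$sampling_rate_hz)
      rec_path <- sprintf("%s.edf", sp$subject_id)
      ann_path <- sprintf("%s_artifacts.json", sp$subject_id)
      write_recording(gen$recording, file.path(out_dir, rec_path))
      write_annotations(gen$annotations, file.path(out_dir, ann_path))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sp$subject_id, label = cls,
        recording_path = rec_path, annotation_path = ann_path,
        n_trials = NA_integer_)
    }
  }
  man_path <- file.path(out_dir, "manifest.json")
  write_manifest(do.call(rbind, rows), spec$sampling_rate_hz,
                 montage_10_20(), spec$master_seed, man_path)
  read_manifest(man_path)
}

#' Welch band power
#'
#' Average periodogram power (µV²/Hz integrated over the band) over
#' Hann-windowed overlapping segments.
#'
#' @param x Numeric vector (one channel).
#' @param fs Sampling rate (Hz).
#' @param band Numeric length-2, band edges in Hz.
#' @param seg_s Segment length in seconds (50% overlap).
#' @return Band power (scalar).
#' @export
welch_band_power <- function(x, fs, band, seg_s = 2) {
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) nseg <- length(x)
  step <- max(1, nseg %/% 2)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  f <- (seq_len(nseg) - 1) * fs / nseg
  sel <- f >= band[1] & f <= band[2]
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    P <- Mod(fft(seg))^2 / (sum(w^2) * fs)
    acc <- acc + sum(P[sel]) * fs / nseg
  }
  acc / length(starts)
}

#' Posterior theta/alpha band-power ratio of a recording
#'
#' Mean over posterior channels (P3, PZ, P4, O1, OZ, O2) of the 4-7 Hz to
#' 8-12 Hz Welch power ratio; the discriminative summary used to check the
#' cohort's spectral separability.
#'
#' @param rec A [raw_recording()].
#' @return Scalar ratio.
#' @export
theta_alpha_ratio <- function(rec) {
  post <- which(rec$channel_names %in% c("P3", "PZ", "P4", "O1", "OZ", "O2"))
  r <- vapply(post, function(ci) {
    th <- welch_band_power(rec$data[ci, ], rec$sampling_rate_hz, c(4, 7))
    al <- welch_band_power(rec$data[ci, ], rec$sampling_rate_hz, c(8, 12))
    th / al
  }, 0)
  mean(r)
}
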
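# Clinical preprocessing pipeline: excise annotated artifact intervals,
# zero-phase band-pass (1.6-40 Hz) + 50 Hz notch filtering, downsampling to
# 256 Hz where needed, ICA-based ocular component removal, non-overlapping
# 5-s epoching with a per-subject trial cap, and leakage-safe per-channel
# normalization.
#
# Pipeline order is fixed: excise -> filter -> resample -> ICA -> epoch.
# Filtering operates within clean runs (never across splice points), and no
# trial ever spans an excision boundary.

# interval union, clipped to [0, duration]
merge_intervals <- function(onset, offset, duration) {
  if (!length(onset)) return(matrix(numeric(0), ncol = 2))
  onset <- pmax(0, pmin(onset, duration))
  offset <- pmax(0, pmin(offset, duration))
  keep <- offset > onset
  onset <- onset[keep]; offset <- offset[keep]
  if (!length(onset)) return(matrix(numeric(0), ncol = 2))
  o <- order(onset)
  onset <- onset[o]; offset <- offset[o]
  mo <- onset[1]; mf <- offset[1]
  out <- NULL
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= mf) mf <- max(mf, offset[i])
    else { out <- rbind(out, c(mo, mf)); mo <- onset[i]; mf <- offset[i] }
  }
  rbind(out, c(mo, mf))
}

#' Excise annotated artifact intervals from a recording
#'
#' Overlapping or adjacent annotation intervals are merged (interval union)
#' before excision; the returned clean runs are the complement within the
#' recording. Sample conversion uses half-open `[onset, offset)` semantics
#' (`index = floor(t * fs)`), so boundary samples are never double-counted.
#' Intervals reaching outside the recording are clipped with a warning.
#'
#' @param rec A [raw_recording()].
#' @param ann An [artifact_annotations()] object.
#' @param min_run_s Runs shorter than this are dropped (default keeps all).
#' @return A `clean_runs` object: list with `runs` (list of channel x time
#'   matrices), `offsets_s` (original start time of each run),
#'   `sampling_rate_hz`, and bookkeeping fields.
#' @export
remove_annotated_segments <- function(rec, ann, min_run_s = 0) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate_hz
  dur <- recording_duration(rec)
  if (nrow(ann) && any(ann$onset_s > dur | ann$offset_s > dur))
    warning("annotation interval(s) outside the recording were clipped")
  iv <- merge_intervals(ann$onset_s, ann$offset_s, dur)
  n <- ncol(rec$data)
  cut <- rep(FALSE, n)
  if (nrow(iv))
    for (i in seq_len(nrow(iv))) {
      a <- floor(iv[i, 1] * fs); b <- floor(iv[i, 2] * fs)  # half-open
      if (b > a) cut[(a + 1):min(b, n)] <- TRUE
    }
  keep <- !cut
  # contiguous kept stretches
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- list(); offs <- numeric(0)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if ((r$lengths[i] / fs) < min_run_s) next
    runs[[length(runs) + 1]] <- rec$data[, starts[i]:ends[i], drop = FALSE]
    offs <- c(offs, (starts[i] - 1) / fs)
  }
  structure(list(runs = runs, offsets_s = offs, sampling_rate_hz = fs,
                 subject_id = rec$subject_id, class_label = rec$class_label,
                 channel_names = rec$channel_names,
                 total_duration_s = dur,
                 excised_s = sum(cut) / fs),
            class = "clean_runs")
}

#' Band-pass and notch filter EEG data
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass followed
#' by a quality-factor-30 IIR notch. Output length equals input length.
#' Runs shorter than three filter warm-up lengths are returned unfiltered
#' with a warning.
#'
#' @param x Channel x time numeric matrix, a [raw_recording()], or a
#'   `clean_runs` object (filtered per run).
#' @param fs Sampling rate (ignored when `x` carries one).
#' @param low_hz,high_hz Band-pass corner frequencies.
#' @param notch_hz Notch center frequency (`NA` to skip).
#' @return Same type as `x`.
#' @export
apply_filters <- function(x, fs = NULL, low_hz = 1.6, high_hz = 40,
                          notch_hz = 50) {
  if (inherits(x, "clean_runs")) {
    x$runs <- lapply(x$runs, apply_filters, fs = x$sampling_rate_hz,
                     low_hz = low_hz, high_hz = high_hz,
                     notch_hz = notch_hz)
    return(x)
  }
  if (inherits(x, "raw_recording")) {
    x$data <- apply_filters(x$data, x$sampling_rate_hz, low_hz, high_hz,
                            notch_hz)
    return(x)
  }
  stopifnot(is.matrix(x), fs > 2 * high_hz)
  if (ncol(x) < 3 * 30) {   # 3 x the effective 8th-order warm-up, rounded up
    warning("run too short to filter; returned unchanged")
    return(x)
  }
  bp <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bp, ch)))
  if (!is.na(notch_hz) && notch_hz < fs / 2) {
    # RBJ biquad notch, Q = 30
    w0 <- 2 * pi * notch_hz / fs
    alpha <- sin(w0) / (2 * 30)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    out <- t(apply(out, 1, function(ch)
      signal::filtfilt(b / a[1], a / a[1], ch)))
  }
  out
}

#' Downsample a recording
#'
#' Polyphase anti-aliased resampling to `target_hz`. This pipeline only
#' downsamples (the study resampled one 512 Hz recording to 256 Hz);
#' upsampling requests are an error.
#'
#' @param rec A [raw_recording()] (or channel x time matrix with `fs`).
#' @param target_hz Target sampling rate.
#' @param fs Required when `rec` is a bare matrix.
#' @return Same type as `rec`, at `target_hz`.
#' @export
resample_recording <- function(rec, target_hz = 256, fs = NULL) {
  if (inherits(rec, "raw_recording")) {
    if (rec$sampling_rate_hz == target_hz) return(rec)
    rec$data <- resample_recording(rec$data, target_hz,
                                   fs = rec$sampling_rate_hz)
    rec$sampling_rate_hz <- target_hz
    return(rec)
  }
  if (is.null(fs)) stop("fs required for matrix input")
  if (target_hz > fs)
    stop("upsampling is not supported (this pipeline only downsamples)")
  if (target_hz == fs) return(rec)
  n_out <- floor(ncol(rec) * target_hz / fs)
  out <- matrix(0, nrow(rec), n_out)
  for (i in seq_len(nrow(rec)))
    out[i, ] <- resample_fft(rec[i, ], n_out)
  out
}

# Delay-free Fourier resampling: truncate the spectrum to the target
# bandwidth (ideal low-pass) and inverse-transform at the new length.
resample_fft <- function(x, n_out) {
  n <- length(x)
  X <- fft(x)
  Y <- complex(n_out)
  half <- min(n, n_out) %/% 2
  Y[1] <- X[1]
  if (half > 1) {
    ks <- 2:half
    Y[ks] <- X[ks]
    Y[n_out - ks + 2] <- X[n - ks + 2]
  }
  if (n_out %% 2 == 0 && half >= 1)
    Y[half + 1] <- Re(X[half + 1])          # real Nyquist bin
  Re(fft(Y, inverse = TRUE)) / n
}

#' Remove ocular components by seeded ICA
#'
#' Decomposes a clean run into independent components (FastICA on a PCA
#' whitening that retains at least `variance_fraction` of the signal
#' variance), flags components whose activation correlates with the
#' frontal ocular proxy (mean of Fp1/Fp2) beyond a `z > 3` outlier
#' criterion across components (each score standardized against the other
#' components, which keeps the threshold meaningful for the few components
#' a 19-channel decomposition yields), and reconstructs the run without
#' the flagged components. Runs shorter than `min_duration_s` are returned
#' unchanged with a warning, as are runs where the decomposition fails.
#'
#' @param run Channel x time matrix.
#' @param fs Sampling rate.
#' @param channel_names Channel labels for locating the frontal proxies.
#' @param variance_fraction PCA variance retention for the decomposition.
#' @param frontal_proxies Channels averaged into the surrogate EOG.
#' @param z_threshold Outlier threshold on z-scored |correlation|.
#' @param seed Seed for the (randomly initialized) decomposition.
#' @param min_duration_s Minimum run length for a stable decomposition.
#' @return The cleaned run (same shape); attribute `"n_removed"` gives the
#'   number of excluded components.
#' @export
remove_ocular_components <- function(run, fs, channel_names = montage_10_20(),
                                     variance_fraction = 0.95,
                                     frontal_proxies = c("FP1", "FP2"),
                                     z_threshold = 3, seed = 2025,
                                     min_duration_s = 30) {
  stopifnot(is.matrix(run))
  if (ncol(run) / fs < min_duration_s) {
    warning("run shorter than ", min_duration_s,
            " s; ICA skipped for stability")
    attr(run, "n_removed") <- 0L
    return(run)
  }
  proxy_idx <- match(toupper(frontal_proxies), toupper(channel_names))
  if (anyNA(proxy_idx)) stop("frontal proxy channels not found")
  eog <- colMeans(run[proxy_idx, , drop = FALSE])

  dec <- tryCatch(
    fastica_decompose(run, variance_fraction, seed = seed),
    error = function(e) NULL)
  if (is.null(dec)) {
    warning("ICA decomposition failed; run returned unchanged")
    attr(run, "n_removed") <- 0L
    return(run)
  }
  scores <- abs(as.vector(cor(t(dec$S), eog)))
  bad <- find_outliers(scores, z_threshold)
  if (length(bad)) {
    S2 <- dec$S
    S2[bad, ] <- 0
    cleaned <- dec$A %*% S2 + dec$mean
  } else cleaned <- run
  attr(cleaned, "n_removed") <- length(bad)
  cleaned
}

# symmetric FastICA (logcosh contrast) on PCA-whitened data retaining
# `var_frac` of the variance; X is channels x samples
fastica_decompose <- function(X, var_frac = 0.95, max_iter = 200,
                              tol = 1e-4, seed = 2025) {
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  cv <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  cum <- cumsum(eg$values) / sum(eg$values)
  k <- max(2, which(cum >= var_frac)[1])
  Dm <- eg$values[seq_len(k)]
  if (any(Dm < 1e-12)) stop("rank-deficient data")
  Kw <- diag(1 / sqrt(Dm), k) %*% t(eg$vectors[, seq_len(k), drop = FALSE])
  Z <- Kw %*% Xc                             # whitened, k x n
  set.seed(seed)
  W <- matrix(rnorm(k * k), k)
  W <- svd(W)$u %*% t(svd(W)$v)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2)) %*% W
    sv <- svd(W1)
    W1 <- sv$u %*% t(sv$v)                   # symmetric decorrelation
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z                               # sources, k x n
  A <- MASS::ginv(W %*% Kw)                  # channels x k mixing
  list(S = S, A = A, W = W, K = Kw, mean = mu, n_components = k)
}

# z-score outlier detection on EOG correlation scores. Each score is
# standardized against the OTHER components (leave-one-out): with the few
# components a 19-channel decomposition yields, including the candidate in
# the spread estimate would make the threshold unreachable by construction.
# Iterates so that multiple ocular components can be flagged.
find_outliers <- function(scores, thresh = 3, max_iter = 1) {
  bad <- integer(0)
  for (i in seq_len(max_iter)) {
    rest <- setdiff(seq_along(scores), bad)
    if (length(rest) < 4) break
    z <- vapply(seq_along(scores), function(j) {
      oth <- setdiff(rest, j)
      (scores[j] - mean(scores[oth])) / (sd(scores[oth]) + 1e-12)
    }, 0)
    new_bad <- union(bad, which(z > thresh))
    if (setequal(new_bad, bad)) break
    bad <- new_bad
  }
  sort(bad)
}

#' Cut clean runs into fixed-length trials
#'
#' Non-overlapping consecutive windows within each run, taken in temporal
#' order (earliest first) across runs until the per-subject cap; no window
#' ever crosses a run boundary. The trial count is
#' `min(cap, sum(floor(run_duration / duration_s)))`.
#'
#' @param cruns A `clean_runs` object (single subject).
#' @param duration_s Trial length in seconds.
#' @param cap_per_subject Maximum number of trials retained.
#' @return A [trial_set()]; zero-trial subjects yield an empty set with a
#'   warning.
#' @export
epoch_runs <- function(cruns, duration_s = 5, cap_per_subject = 40) {
  stopifnot(inherits(cruns, "clean_runs"))
  fs <- cruns$sampling_rate_hz
  L <- round(duration_s * fs)
  C <- if (length(cruns$runs)) nrow(cruns$runs[[1]]) else
    length(cruns$channel_names)
  trials <- list()
  for (run in cruns$runs) {
    nwin <- ncol(run) %/% L
    for (w in seq_len(nwin)) {
      if (length(trials) >= cap_per_subject) break
      trials[[length(trials) + 1]] <- run[, ((w - 1) * L + 1):(w * L)]
    }
    if (length(trials) >= cap_per_subject) break
  }
  n <- length(trials)
  if (n == 0) {
    warning("no full ", duration_s, " s window available for subject ",
            cruns$subject_id, "; empty trial set")
    return(trial_set(array(0, c(0, C, L)), character(0), character(0),
                     fs, epoch_s = duration_s))
  }
  arr <- array(0, c(n, C, L))
  for (i in seq_len(n)) arr[i, , ] <- trials[[i]]
  trial_set(arr, rep(cruns$subject_id, n), rep(cruns$class_label, n), fs,
            epoch_s = duration_s)
}

#' Fit a per-channel normalizer on training trials
#'
#' Computes per-channel mean and standard deviation over all training
#' trials and time points. Under the evaluation protocol this is fitted on
#' the training portion only; the same parameters are then applied to any
#' test data, so no test statistics ever leak into training.
#'
#' @param train A [trial_set()] of training trials.
#' @param eps Variance floor guarding constant channels.
#' @return A `norm_params` list (`mean`, `sd`, `eps` per channel).
#' @export
fit_channel_normalizer <- function(train, eps = 1e-8) {
  x <- train$trials
  d <- dim(x)
  m <- apply(x, 2, mean)
  s <- apply(x, 2, sd)
  structure(list(mean = m, sd = s, eps = eps), class = "norm_params")
}

#' Apply a fitted normalizer
#'
#' `x' = (x - mean_c) / (sd_c + eps)` per channel.
#'
#' @param ts A [trial_set()].
#' @param np A `norm_params` from [fit_channel_normalizer()].
#' @return The normalized [trial_set()].
#' @export
apply_normalizer <- function(ts, np) {
  stopifnot(inherits(np, "norm_params"))
  d <- dim(ts$trials)
  ts$trials <- (ts$trials - rep(np$mean, each = d[1])) /
    rep(np$sd + np$eps, each = d[1])
  ts
}

#' Preprocess one annotated recording into a trial set
#'
#' Full per-subject pipeline: excise annotated segments, zero-phase filter
#' each clean run (1.6-40 Hz band-pass, 50 Hz notch), downsample to the
#' target rate if needed, remove ocular ICA components, and epoch into
#' capped 5-s trials.
#'
#' @param rec A [raw_recording()].
#' @param ann An [artifact_annotations()] object.
#' @param target_hz Working sampling rate.
#' @param duration_s,cap_per_subject Epoching parameters.
#' @param skip_ica Skip the ocular ICA step.
#' @param ica_seed Seed passed to the decomposition.
#' @param verbose Log per-subject summary to `message()`.
#' @return A [trial_set()] for the subject.
#' @export
preprocess_recording <- function(rec, ann, target_hz = 256, duration_s = 5,
                                 cap_per_subject = 40, skip_ica = FALSE,
                                 ica_seed = 2025, verbose = FALSE) {
  cruns <- remove_annotated_segments(rec, ann)
  cruns <- apply_filters(cruns)
  if (rec$sampling_rate_hz != target_hz) {
    cruns$runs <- lapply(cruns$runs, resample_recording,
                         target_hz = target_hz,
                         fs = cruns$sampling_rate_hz)
    cruns$sampling_rate_hz <- target_hz
  }
  n_rm <- 0L
  if (!skip_ica)
    cruns$runs <- lapply(cruns$runs, function(r) {
      out <- suppressWarnings(remove_ocular_components(
        r, cruns$sampling_rate_hz, cruns$channel_names, seed = ica_seed))
      n_rm <<- n_rm + attr(out, "n_removed")
      out
    })
  ts <- epoch_runs(cruns, duration_s, cap_per_subject)
  if (verbose)
    message(sprintf(
      "[preprocess] %s: excised %.1f s, removed %d ICA component(s), %d trials",
      rec$subject_id, cruns$excised_s, n_rm, dim(ts$trials)[1]))
  ts
}

#' Preprocess a whole cohort from its manifest
#'
#' @param manifest A manifest from [read_manifest()] or a path to one.
#' @param ... Passed to [preprocess_recording()].
#' @return A combined [trial_set()] over all subjects with at least one
#'   trial.
#' @export
preprocess_cohort <- function(manifest, ...) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  subj <- manifest$subjects
  sets <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    rec <- read_recording(subj$recording_path[i],
                          expected_channels = manifest$channel_names,
                          subject_id = subj$subject_id[i],
                          class_label = subj$label[i])
    ann <- read_annotations(subj$annotation_path[i])
    sets[[i]] <- suppressWarnings(preprocess_recording(rec, ann, ...))
  }
  bind_trial_sets(sets)
}
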
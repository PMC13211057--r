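# Domain containers: raw recordings, artifact annotations, trial sets.
# Plain S3 lists with strict constructors, in the style of clinical EEG
# tooling: data in microvolts, channels x samples, seconds from start.

#' Construct a raw EEG recording
#'
#' One subject's continuous multichannel EEG with metadata. Data are in
#' microvolts, one row per channel.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate_hz Sampling rate (Hz), positive.
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id Opaque subject identifier.
#' @param class_label `"AD"`, `"CJD"`, `"CNTRL"`, or `NA` for inference mode.
#' @param n_channels_expected Montage size asserted by the study design
#'   (`NULL` to skip the check).
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(data, sampling_rate_hz,
                          channel_names = montage_10_20(),
                          subject_id = "anon", class_label = NA_character_,
                          n_channels_expected = 19) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be finite numeric values (microvolts)")
  if (length(sampling_rate_hz) != 1 || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive scalar")
  if (nrow(data) != length(channel_names))
    stop(sprintf("data has %d channels but %d channel names given",
                 nrow(data), length(channel_names)))
  if (!is.null(n_channels_expected) && nrow(data) != n_channels_expected)
    stop(sprintf("expected %d channels for this montage, got %d",
                 n_channels_expected, nrow(data)))
  if (!is.na(class_label) && !class_label %in% EEG_CLASSES)
    stop("class_label must be one of ", paste(EEG_CLASSES, collapse = ", "))
  structure(list(subject_id = subject_id, class_label = class_label,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_names = toupper(channel_names), data = data),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)>\n",
              x$subject_id, ifelse(is.na(x$class_label), "?", x$class_label),
              nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              ncol(x$data) / x$sampling_rate_hz))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$data) / rec$sampling_rate_hz

#' Construct artifact-interval annotations
#'
#' Clinician-style list of corrupted time intervals, in seconds from
#' recording start. Intervals are validated (onset strictly before offset,
#' non-negative onsets) and sorted by onset.
#'
#' @param onset_s,offset_s Numeric vectors of equal length.
#' @return An `artifact_annotations` object (data frame backed).
#' @export
artifact_annotations <- function(onset_s = numeric(), offset_s = numeric()) {
  if (length(onset_s) != length(offset_s))
    stop("onset_s and offset_s must have equal length")
  onset_s <- as.numeric(onset_s); offset_s <- as.numeric(offset_s)
  if (any(!is.finite(onset_s)) || any(!is.finite(offset_s)))
    stop("annotation times must be finite")
  if (any(onset_s < 0)) stop("annotation onsets must be non-negative")
  if (any(onset_s >= offset_s))
    stop("every annotation must satisfy onset_s < offset_s")
  o <- order(onset_s)
  structure(data.frame(onset_s = onset_s[o], offset_s = offset_s[o]),
            class = c("artifact_annotations", "data.frame"))
}

#' Construct a trial set
#'
#' The unit of learning: `N` fixed-length epochs with subject identifiers
#' and class labels (one label per subject).
#'
#' @param trials Numeric array `N x C x T`.
#' @param subject_ids Character vector of length `N`.
#' @param labels Character vector of length `N` (values in AD/CJD/CNTRL),
#'   or `NA` for unlabeled data.
#' @param sampling_rate_hz Sampling rate of the epochs.
#' @param epoch_s Nominal epoch duration in seconds (consistency-checked
#'   against `dim(trials)[3]`).
#' @return A `trial_set` object.
#' @export
trial_set <- function(trials, subject_ids, labels, sampling_rate_hz,
                      epoch_s = 5) {
  d <- dim(trials)
  if (length(d) != 3) stop("trials must be an N x C x T array")
  if (d[1] != length(subject_ids) || d[1] != length(labels))
    stop("subject_ids and labels must each have one entry per trial")
  if (!is.null(epoch_s) && d[3] != round(epoch_s * sampling_rate_hz))
    stop(sprintf("trial length %d != round(%g s x %g Hz) = %d samples",
                 d[3], epoch_s, sampling_rate_hz,
                 round(epoch_s * sampling_rate_hz)))
  lab_by_subj <- tapply(as.character(labels), as.character(subject_ids),
                        function(v) length(unique(v)))
  if (any(lab_by_subj > 1))
    stop("inconsistent labels: a subject must have exactly one class")
  structure(list(trials = trials, subject_ids = as.character(subject_ids),
                 labels = as.character(labels),
                 sampling_rate_hz = sampling_rate_hz, epoch_s = epoch_s),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set: %d trials x %d ch x %d samples, %d subjects>\n",
              dim(x$trials)[1], dim(x$trials)[2], dim(x$trials)[3],
              length(unique(x$subject_ids))))
  tb <- table(vapply(split(x$labels, x$subject_ids), `[`, "", 1))
  print(tb)
  invisible(x)
}

#' Combine trial sets from several subjects
#'
#' @param ... `trial_set` objects (or a single list of them).
#' @return A single `trial_set`.
#' @export
bind_trial_sets <- function(...) {
  tss <- list(...)
  if (length(tss) == 1 && !inherits(tss[[1]], "trial_set")) tss <- tss[[1]]
  tss <- Filter(function(t) !is.null(t) && dim(t$trials)[1] > 0, tss)
  if (!length(tss)) stop("no non-empty trial sets to combine")
  fs <- unique(vapply(tss, function(t) t$sampling_rate_hz, 0))
  if (length(fs) != 1) stop("sampling rates differ across trial sets")
  arr <- do.call(abind3, lapply(tss, function(t) t$trials))
  trial_set(arr, unlist(lapply(tss, function(t) t$subject_ids)),
            unlist(lapply(tss, function(t) t$labels)), fs,
            epoch_s = tss[[1]]$epoch_s)
}

# bind along dim 1 for N x C x T arrays
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, c(n, d[2], d[3]))
  at <- 1
  for (p in parts) {
    np <- dim(p)[1]
    if (np > 0) out[at:(at + np - 1), , ] <- p
    at <- at + np
  }
  out
}

#' Subset a trial set by subject
#'
#' @param ts A `trial_set`.
#' @param subjects Character vector of subject identifiers to keep.
#' @return A `trial_set` with only the requested subjects' trials.
#' @export
subset_subjects <- function(ts, subjects) {
  keep <- ts$subject_ids %in% subjects
  trial_set(ts$trials[keep, , , drop = FALSE], ts$subject_ids[keep],
            ts$labels[keep], ts$sampling_rate_hz, ts$epoch_s)
}

# subject -> label lookup (one label per subject, enforced at construction)
subject_labels <- function(ts) {
  vapply(split(ts$labels, ts$subject_ids), `[`, "", 1)
}
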
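# Sidecar annotations (JSON), trial-set container (raw float32 + JSON
# manifest) and the cohort dataset manifest.

#' Read artifact annotations from a JSON sidecar
#'
#' The sidecar is a JSON array of objects with fields `onset_s` and
#' `offset_s` (seconds from recording start). Intervals are validated and
#' returned sorted by onset.
#'
#' @param path JSON file path.
#' @return An [artifact_annotations()] object.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(x) == 0) return(artifact_annotations())
  if (!is.data.frame(x) || !all(c("onset_s", "offset_s") %in% names(x)))
    stop("annotation sidecar must be an array of {onset_s, offset_s} objects")
  artifact_annotations(x$onset_s, x$offset_s)
}

#' Write artifact annotations to a JSON sidecar
#'
#' @param ann An [artifact_annotations()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- as.data.frame(unclass(ann))[, c("onset_s", "offset_s"), drop = FALSE]
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' Save a trial set to disk
#'
#' On-disk layout: `<stem>.bin`, the trials as little-endian IEEE-754
#' float32 in C order (trial, then channel, then time slowest-varying last,
#' i.e. the flattened `N x C x T` array row-major), plus `<stem>.json` with
#' shape, subject ids, labels and sampling rate. A SHA-agnostic integrity
#' check (element count) guards shape/manifest agreement at load time.
#'
#' @param ts A [trial_set()].
#' @param stem Path stem; `.bin` and `.json` are appended.
#' @return The manifest path, invisibly.
#' @export
save_trialset <- function(ts, stem) {
  stopifnot(inherits(ts, "trial_set"))
  d <- dim(ts$trials)
  bin <- paste0(stem, ".bin"); man <- paste0(stem, ".json")
  # C order: time fastest -> write aperm so readBin round-trips
  con <- file(bin, "wb")
  writeBin(as.numeric(aperm(ts$trials, c(3, 2, 1))), con, size = 4,
           endian = "little")
  close(con)
  jsonlite::write_json(list(
    format = "eegdecoder-trialset-v1",
    shape = d, dtype = "float32-le", order = "N,C,T (C order)",
    subject_ids = ts$subject_ids, labels = ts$labels,
    sampling_rate_hz = ts$sampling_rate_hz, epoch_s = ts$epoch_s),
    man, auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Load a trial set saved by [save_trialset()]
#'
#' @param stem Path stem used at save time.
#' @return A [trial_set()].
#' @export
load_trialset <- function(stem) {
  bin <- paste0(stem, ".bin"); man <- paste0(stem, ".json")
  if (!file.exists(bin) || !file.exists(man))
    stop("missing trial-set files at stem: ", stem)
  mf <- jsonlite::fromJSON(man)
  d <- as.integer(mf$shape)
  n_expected <- prod(d)
  sz <- file.info(bin)$size
  if (sz != 4 * n_expected)
    stop(sprintf(
      "trial-set integrity error: manifest claims %d float32 values (%d bytes), file has %d bytes",
      n_expected, 4 * n_expected, sz))
  con <- file(bin, "rb")
  v <- readBin(con, numeric(), n = n_expected, size = 4, endian = "little")
  close(con)
  arr <- aperm(array(v, c(d[3], d[2], d[1])), c(3, 2, 1))
  trial_set(arr, mf$subject_ids, mf$labels, mf$sampling_rate_hz,
            epoch_s = mf$epoch_s)
}

#' Read a cohort dataset manifest
#'
#' The manifest indexes a cohort on disk: one entry per subject
#' (`subject_id`, `label`, `recording_path`, `annotation_path`, `n_trials`
#' when known) plus global fields (`sampling_rate_hz`, `channel_names`,
#' `seed`). Paths are resolved relative to the manifest location and
#' checked for existence.
#'
#' @param path Manifest JSON path.
#' @return A list with elements `subjects` (data frame) and the global
#'   fields.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  mf <- jsonlite::fromJSON(path)
  base <- dirname(normalizePath(path))
  subj <- mf$subjects
  if (anyDuplicated(subj$subject_id))
    stop("manifest contains duplicate subject ids")
  subj$recording_path <- file.path(base, subj$recording_path)
  subj$annotation_path <- file.path(base, subj$annotation_path)
  missing <- !file.exists(subj$recording_path) |
    !file.exists(subj$annotation_path)
  if (any(missing))
    stop("manifest references missing files for subjects: ",
         paste(subj$subject_id[missing], collapse = ", "))
  mf$subjects <- subj
  mf
}

write_manifest <- function(subjects, sampling_rate_hz, channel_names, seed,
                           path) {
  jsonlite::write_json(list(
    format = "eegdecoder-cohort-v1",
    sampling_rate_hz = sampling_rate_hz,
    channel_names = channel_names, seed = seed,
    subjects = subjects), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
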
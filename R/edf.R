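# Minimal EDF (European Data Format) reader/writer for continuous EEG.
#
# Fixed-layout 16-bit format: a 256-byte global header, 256 bytes of header
# per signal, then data records of interleaved little-endian int16 samples.
# The writer uses a fixed physical range of +/-3276.7 uV against digital
# +/-32767, i.e. 0.1 uV amplitude resolution (clinical convention), 1-second
# data records, and requires whole-second recordings.

EDF_PHYS_MAX <- 3276.7
EDF_DIG_MAX <- 32767

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) substr(s, 1, width) else s
}

# strip reference suffixes ("FP1-CZ" -> "FP1") and case for matching
normalize_channel_label <- function(x) {
  sub("-.*$", "", toupper(trimws(x)))
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to the fixed physical range of ±3276.7 µV at 16-bit
#' digital resolution (0.1 µV steps); values outside the range are an error.
#' The class label is deliberately **not** stored in the file (recordings
#' stay anonymized; labels travel in the dataset manifest).
#'
#' @param rec A [raw_recording()]. Duration must be a whole number of
#'   seconds and the sampling rate an integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!all(is.finite(rec$data))) stop("recording contains non-finite samples")
  if (max(abs(rec$data)) > EDF_PHYS_MAX)
    stop(sprintf("samples exceed the EDF physical range of +/-%g uV",
                 EDF_PHYS_MAX))
  fs <- rec$sampling_rate_hz
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_samp <- ncol(rec$data)
  if (n_samp %% fs != 0)
    stop("EDF writer requires a whole number of seconds")
  ns <- nrow(rec$data)
  n_rec <- n_samp %/% fs

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),           # local patient id (anonymized)
    pad_field("eegdecoder", 80),             # local recording id
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),                         # record duration (s)
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(get, width)
    writeChar(paste(vapply(seq_len(ns), get, ""), collapse = ""), con,
              eos = NULL)
  fld(function(i) pad_field(rec$channel_names[i], 16), 16)
  fld(function(i) pad_field("AgAgCl electrode", 80), 80)
  fld(function(i) pad_field("uV", 8), 8)
  fld(function(i) pad_field(-EDF_PHYS_MAX, 8), 8)
  fld(function(i) pad_field(EDF_PHYS_MAX, 8), 8)
  fld(function(i) pad_field(-EDF_DIG_MAX, 8), 8)
  fld(function(i) pad_field(EDF_DIG_MAX, 8), 8)
  fld(function(i) pad_field("", 80), 80)
  fld(function(i) pad_field(fs, 8), 8)
  fld(function(i) pad_field("", 32), 32)

  dig <- round(rec$data / EDF_PHYS_MAX * EDF_DIG_MAX)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- t(dig[, cols, drop = FALSE])    # per signal, contiguous samples
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Parses the header, scales digital samples to physical units (microvolts)
#' and reorders channels to `expected_channels`. Channel matching is
#' case-insensitive and ignores reference suffixes (`"Fp1-Cz"` matches
#' `"FP1"`).
#'
#' @param path EDF file path.
#' @param expected_channels Channel names the caller requires, in the order
#'   the returned data rows must have; `NULL` keeps the file order.
#' @param subject_id,class_label Metadata to attach (EDF carries neither
#'   the study label nor, after anonymization, an informative patient
#'   field).
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, expected_channels = montage_10_20(),
                           subject_id = NULL, class_label = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) readChar(con, nchars, useBytes = TRUE)
  ver <- rd(8)
  pid <- trimws(rd(80)); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || is.na(n_rec) || is.na(dur) || ns < 1 || n_rec < 0)
    stop("not a parseable EDF header: ", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (any(is.na(pmin_)) || any(is.na(spr)))
    stop("not a parseable EDF signal header: ", path)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")

  total <- sum(spr) * n_rec
  raw16 <- readBin(con, integer(), n = total, size = 2, endian = "little")
  data <- matrix(0, ns, spr[1] * n_rec)
  at <- 0
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- raw16[(at + 1):(at + spr[s])]
      at <- at + spr[s]
      scale <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        pmin_[s] + (seg - dmin_[s]) * scale
    }
  }
  fs <- spr[1] / dur

  if (!is.null(expected_channels)) {
    have <- normalize_channel_label(labels)
    want <- normalize_channel_label(expected_channels)
    idx <- match(want, have)
    if (anyNA(idx)) {
      extra <- setdiff(have, want)
      stop(sprintf(
        "channel mismatch in %s: missing [%s]%s", path,
        paste(expected_channels[is.na(idx)], collapse = ", "),
        if (length(extra)) sprintf("; unexpected [%s]",
                                   paste(extra, collapse = ", ")) else ""))
    }
    data <- data[idx, , drop = FALSE]
    labels <- expected_channels
  }
  raw_recording(data, fs, labels,
                subject_id = subject_id %||% pid,
                class_label = class_label,
                n_channels_expected = NULL)
}

`%||%` <- function(a, b) if (is.null(a) || !nzchar(a)) b else a
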
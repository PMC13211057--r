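# Portable model export, independent-runtime equivalence checking, and
# per-trial latency profiling.
#
# Interchange format: a single self-describing JSON file containing the
# architecture identifier, the configuration echo, and every tensor as
# base64-encoded little-endian IEEE-754 float64 together with its
# dimensions. A reference runtime implemented in NumPy (shipped at
# inst/python/portable_runtime.py) loads the file and reproduces the
# evaluation-mode forward pass, giving a hardware- and language-agnostic
# deployment path plus an independent check on the native implementation.

encode_tensor <- function(x) {
  list(dims = if (is.null(dim(x))) length(x) else dim(x),
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                            size = 8, endian = "little")))
}

decode_tensor <- function(t) {
  v <- readBin(jsonlite::base64_dec(t$data), numeric(),
               n = prod(unlist(t$dims)), size = 8, endian = "little")
  if (length(t$dims) > 1 || length(unlist(t$dims)) > 1)
    array(v, unlist(t$dims)) else v
}

#' Export a model to the portable interchange format
#'
#' Writes the full model (config, trainable tensors, batch-normalization
#' running statistics) as self-describing JSON. The exported file loads in
#' the package's independent NumPy reference runtime with input signature
#' `1 x C x T` and output `1 x n_classes`.
#'
#' @param model An `eeg_model` (evaluation-ready).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
export_portable <- function(model, path) {
  stopifnot(inherits(model, "eeg_model"))
  obj <- list(
    format = "eegdecoder-portable-v1",
    architecture = model$architecture,
    config = unclass(model$config),
    input_signature = c(1, model$config$in_channels,
                        model$config$input_samples),
    output_signature = c(1, model$config$n_classes),
    params = lapply(model$params, encode_tensor),
    state = lapply(model$state, encode_tensor))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a portable model file back into a native model
#'
#' @param path A file written by [export_portable()].
#' @return An `eeg_model`.
#' @export
import_portable <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "eegdecoder-portable-v1"))
    stop("not a portable model file: ", path)
  co <- obj$config
  cf <- if (obj$architecture == "eegdecoder")
    decoder_config(in_channels = co$in_channels,
                   input_samples = co$input_samples,
                   conv1_out = co$conv1_out, conv1_kernel = co$conv1_kernel,
                   conv2_out = co$conv2_out, conv2_kernel = co$conv2_kernel,
                   pool = co$pool, encoder_layers = co$encoder_layers,
                   attention_heads = co$attention_heads,
                   d_model = co$d_model, ffn_dim = co$ffn_dim,
                   dropout = co$dropout, n_classes = co$n_classes)
  else
    eegnet_config(F1 = co$F1, D = co$D,
                  temporal_kernel = co$temporal_kernel,
                  separable_kernel = co$separable_kernel,
                  pool1 = co$pool1, pool2 = co$pool2, dropout = co$dropout,
                  max_norm = co$max_norm, in_channels = co$in_channels,
                  input_samples = co$input_samples,
                  n_classes = co$n_classes)
  structure(list(architecture = obj$architecture, config = cf,
                 params = lapply(obj$params, decode_tensor),
                 state = lapply(obj$state, decode_tensor),
                 training = FALSE, seed = NA),
            class = "eeg_model")
}

python_runtime_path <- function() {
  p <- system.file("python", "portable_runtime.py", package = "eegdecoder")
  if (!nzchar(p)) stop("portable_runtime.py not found in the installed package")
  p
}

find_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter on PATH (needed for the reference runtime)")
  py
}

# run the exported model in the independent runtime on a (N, C, T) array
run_portable <- function(model_path, inputs) {
  d <- dim(inputs)
  tmp_in <- tempfile(fileext = ".bin")
  tmp_out <- tempfile(fileext = ".bin")
  on.exit(unlink(c(tmp_in, tmp_out)))
  con <- file(tmp_in, "wb")
  writeBin(as.numeric(aperm(inputs, c(3, 2, 1))), con, size = 8,
           endian = "little")              # C order N,C,T
  close(con)
  status <- system2(find_python(),
                    c(python_runtime_path(), shQuote(model_path),
                      shQuote(tmp_in), d[1], tmp_out),
                    stdout = NULL, stderr = "")
  if (status != 0) stop("reference runtime failed (exit ", status, ")")
  nv <- file.info(tmp_out)$size / 8
  con <- file(tmp_out, "rb")
  v <- readBin(con, numeric(), n = nv, size = 8, endian = "little")
  close(con)
  matrix(v, nrow = d[1], byrow = TRUE)   # runtime writes C order (N, classes)
}

#' Check numerical equivalence of native and exported models
#'
#' Runs `n` seeded standard-normal inputs through both the native forward
#' pass and the exported file in the independent NumPy runtime, and
#' reports the maximum absolute score difference and the argmax agreement
#' rate. Agreement is additionally reported restricted to inputs whose
#' decision margin exceeds `tol` (ties within tolerance cannot be
#' attributed to either implementation).
#'
#' @param model The native `eeg_model`.
#' @param exported_path File from [export_portable()].
#' @param n Number of random test inputs.
#' @param tol Tolerance on the max absolute score difference.
#' @param seed Seed for the input draw.
#' @return List: `max_abs_diff`, `argmax_agreement`,
#'   `argmax_agreement_margin` (restricted to above-margin inputs),
#'   `n_margin`, `pass`.
#' @export
check_equivalence <- function(model, exported_path, n = 100, tol = 1e-4,
                              seed = 2025) {
  set.seed(seed)
  cf <- model$config
  x <- array(rnorm(n * cf$in_channels * cf$input_samples),
             c(n, cf$in_channels, cf$input_samples))
  native <- model_predict(model, x)
  ported <- run_portable(exported_path, x)
  if (!all(dim(ported) == dim(native)))
    stop("shape mismatch between native and exported outputs")
  d <- max(abs(native - ported))
  am_n <- max.col(native, ties.method = "first")
  am_p <- max.col(ported, ties.method = "first")
  srt <- t(apply(native, 1, sort, decreasing = TRUE))
  margin <- srt[, 1] - srt[, 2]
  on_margin <- margin > tol
  list(max_abs_diff = d,
       argmax_agreement = mean(am_n == am_p),
       argmax_agreement_margin = if (any(on_margin))
         mean(am_n[on_margin] == am_p[on_margin]) else NA_real_,
       n_margin = sum(on_margin),
       pass = d < tol)
}

#' Profile single-trial inference latency
#'
#' Times `n_trials` batch-1 forward passes after `warmup` discarded
#' iterations and reports per-trial latency statistics together with the
#' model's parameter and FLOP counts. Latency is hardware-dependent and is
#' reported, never asserted.
#'
#' @param model An `eeg_model`, or a path to a portable export (profiled
#'   through the NumPy runtime, one process call per batch).
#' @param n_trials Number of timed inferences.
#' @param warmup Untimed warm-up inferences.
#' @param seed Seed for the random probe inputs.
#' @return A `footprint_report` list.
#' @export
profile_latency <- function(model, n_trials = 40, warmup = 5, seed = 2025) {
  stopifnot(n_trials >= 1)
  if (is.character(model)) {
    backend <- "numpy-runtime"
    native <- import_portable(model)
    cf <- native$config
    fwd <- function(x) run_portable(model, x)
  } else {
    backend <- "native-R"
    native <- model
    cf <- model$config
    fwd <- function(x) model_predict(model, x)
  }
  set.seed(seed)
  mk <- function() array(rnorm(cf$in_channels * cf$input_samples),
                         c(1, cf$in_channels, cf$input_samples))
  for (i in seq_len(warmup)) fwd(mk())
  ms <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    x <- mk()
    t0 <- Sys.time()
    fwd(x)
    ms[i] <- as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
  }
  structure(list(parameter_count = count_parameters(native),
                 flops_per_inference = count_flops(native),
                 latency_ms = list(mean = mean(ms), median = median(ms),
                                   sd = sd(ms), n = n_trials),
                 backend = backend, batch_size = 1),
            class = "footprint_report")
}

#' @export
print.footprint_report <- function(x, ...) {
  cat(sprintf(
    "<footprint: %.1f K params, %.0f MFLOPs/inference, latency %.2f +/- %.2f ms (median %.2f, n=%d, %s)>\n",
    x$parameter_count / 1000, x$flops_per_inference / 1e6,
    x$latency_ms$mean, x$latency_ms$sd, x$latency_ms$median,
    x$latency_ms$n, x$backend))
  invisible(x)
}
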
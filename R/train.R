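# Seeded mini-batch training with Adam, validation-accuracy early stopping,
# and best-epoch weight restoration.

#' Training configuration
#'
#' Defaults follow the study conditions: Adam, learning rate 1e-3, weight
#' decay 1e-4, batch size 64, at most 30 epochs with early stopping at
#' patience 10 on validation accuracy, 5 subject-level inner folds, seed
#' 2025; the robustness seed set is {42, 99, 123, 2025, 2026}.
#'
#' @param learning_rate,weight_decay,batch_size,max_epochs,early_stop_patience
#'   Optimization hyperparameters.
#' @param inner_folds Number of subject-level folds of the inner loop.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @param seed_set Seeds used by the robustness harness.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         batch_size = 64, max_epochs = 30,
                         early_stop_patience = 10, inner_folds = 5,
                         seed = 2025,
                         seed_set = c(42, 99, 123, 2025, 2026)) {
  stopifnot(early_stop_patience <= max_epochs, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = batch_size,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 monitored_metric = "val_accuracy",
                 inner_folds = inner_folds, seed = seed,
                 seed_set = seed_set),
            class = "train_config")
}

labels_to_int <- function(labels, n_classes = 3) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, EEG_CLASSES[seq_len(n_classes)])
    if (anyNA(idx)) stop("unknown class label: ",
                         paste(unique(labels[is.na(idx)]), collapse = ", "))
    idx
  } else as.integer(labels)
}

model_forward_train <- function(model, x, y_int) {
  if (model$architecture == "eegdecoder") {
    fw <- decoder_forward_full(model, x, training = TRUE, keep_cache = TRUE)
    ls <- softmax_xent(fw$logits, y_int)
    grads <- decoder_backward_full(model, fw, ls$dlogits)
  } else {
    fw <- eegnet_forward_full(model, x, training = TRUE, keep_cache = TRUE)
    ls <- softmax_xent(fw$logits, y_int)
    grads <- eegnet_backward_full(model, fw, ls$dlogits)
  }
  list(loss = ls$loss, grads = grads, state = fw$state)
}

#' Predict class scores for a trial set
#'
#' Evaluation-mode forward pass in batches.
#'
#' @param model An `eeg_model`.
#' @param trials Numeric array `N x C x T` or a `trial_set`.
#' @param batch_size Trials per forward batch.
#' @return `N x n_classes` score matrix with class column names.
#' @export
model_predict <- function(model, trials, batch_size = 64) {
  if (inherits(trials, "trial_set")) trials <- trials$trials
  if (length(dim(trials)) == 2) trials <- array(trials, c(1, dim(trials)))
  n <- dim(trials)[1]
  out <- matrix(0, n, model$config$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    out[s:e, ] <- decoder_forward(model, trials[s:e, , , drop = FALSE])
  }
  colnames(out) <- EEG_CLASSES[seq_len(model$config$n_classes)]
  out
}

#' Train a model with Adam and early stopping
#'
#' Optimizes multi-class cross-entropy with shuffled mini-batches. After
#' every epoch, accuracy on the validation set is computed in evaluation
#' mode; training stops when it has not improved for
#' `config$early_stop_patience` consecutive epochs or at
#' `config$max_epochs`. The returned model carries the weights (and
#' batch-normalization running statistics) of the best validation epoch.
#' The run is fully reproducible from `config$seed`.
#'
#' @param model An `eeg_model` (its weights are the starting point).
#' @param train A `trial_set` (or `list(trials, labels)`) for optimization.
#' @param val A `trial_set` for early-stopping validation; subject-disjoint
#'   from `train` under the evaluation protocol.
#' @param config A [train_config()].
#' @param backend `"auto"` (default) uses the compiled single-precision
#'   training path for the decoder architecture and the R reference path
#'   otherwise; `"reference"` forces the plain-R double-precision
#'   implementation; `"fast"` forces the compiled path (decoder only). Both
#'   paths implement the same layers and optimizer; gradient agreement is
#'   asserted in the test suite. Each backend is deterministic given
#'   `config$seed`, but the two backends draw shuffling/dropout from
#'   different generators, so histories match across backends only in
#'   expectation.
#' @param verbose Print one line per epoch.
#' @return List with `model` (best weights), `history` (one row per epoch:
#'   train loss, validation accuracy) and `best_epoch`.
#' @export
train_model <- function(model, train, val, config = train_config(),
                        backend = c("auto", "reference", "fast"),
                        verbose = FALSE) {
  stopifnot(inherits(model, "eeg_model"), inherits(config, "train_config"))
  backend <- match.arg(backend)
  if (is.null(train$trials) || dim(train$trials)[1] < 1)
    stop("empty training set")
  if (is.null(val$trials) || dim(val$trials)[1] < 1)
    stop("empty validation set")
  if (backend == "fast" && model$architecture != "eegdecoder")
    stop("the compiled training path supports only the decoder architecture")
  if (backend == "auto" && model$architecture == "eegdecoder")
    backend <- "fast"
  if (backend == "fast") return(train_model_fast(model, train, val, config))
  set.seed(config$seed)
  ncl <- model$config$n_classes
  xtr <- aperm(train$trials, c(2, 3, 1))            # (C, T, N)
  ytr <- labels_to_int(train$labels, ncl)
  yva <- labels_to_int(val$labels, ncl)
  n <- length(ytr)
  opt <- adam_init(model$params)
  best <- list(acc = -Inf, epoch = 0, params = model$params,
               state = model$state)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_accuracy = numeric())
  wait <- 0
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (s in seq(1, n, by = config$batch_size)) {
      sel <- ord[s:min(s + config$batch_size - 1, n)]
      res <- model_forward_train(model, xtr[, , sel, drop = FALSE], ytr[sel])
      model$state <- res$state
      up <- adam_step(model$params, res$grads, opt,
                      lr = config$learning_rate,
                      weight_decay = config$weight_decay)
      model$params <- up$params
      opt <- up$state
      if (model$architecture == "eegnet")
        model <- eegnet_apply_constraints(model)
      tot <- tot + res$loss * length(sel)
    }
    scores <- model_predict(model, val$trials, config$batch_size)
    acc <- mean(max.col(scores, ties.method = "first") == yva)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tot / n,
                                   val_accuracy = acc))
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  val_acc %.3f", epoch,
                      tot / n, acc))
    if (acc > best$acc + 1e-12) {
      best <- list(acc = acc, epoch = epoch, params = model$params,
                   state = model$state)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = hist, best_epoch = best$epoch,
       best_val_accuracy = best$acc)
}

# Compiled single-precision training path (decoder only); same layers,
# optimizer and early-stopping rule as the reference path.
train_model_fast <- function(model, train, val, config) {
  ncl <- model$config$n_classes
  xtr <- aperm(train$trials, c(2, 3, 1))
  xva <- aperm(val$trials, c(2, 3, 1))
  ytr <- as.integer(labels_to_int(train$labels, ncl))
  yva <- as.integer(labels_to_int(val$labels, ncl))
  res <- cpp_train_eegdecoder(model$params, unclass(model$config),
                              xtr, ytr, xva, yva, model$state,
                              config$learning_rate, config$weight_decay,
                              as.integer(config$batch_size),
                              as.integer(config$max_epochs),
                              as.integer(config$early_stop_patience),
                              as.integer(config$seed))
  # restore array dims lost in the List round trip
  for (nm in names(model$params)) {
    dm <- dim(model$params[[nm]])
    if (!is.null(dm)) dim(res$params[[nm]]) <- dm
    else res$params[[nm]] <- as.numeric(res$params[[nm]])
  }
  model$params <- res$params[names(model$params)]
  model$state <- lapply(res$state, as.numeric)[names(model$state)]
  hist <- data.frame(epoch = seq_along(res$train_loss),
                     train_loss = unlist(res$train_loss),
                     val_accuracy = unlist(res$val_accuracy))
  list(model = model, history = hist, best_epoch = res$best_epoch,
       best_val_accuracy = res$best_val_accuracy)
}
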
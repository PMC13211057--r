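# Nested leave-one-subject-out evaluation.
#
# Outer loop: every subject is held out once. Inner loop: the remaining
# subjects are partitioned into class-stratified subject-level folds; for
# each inner fold a normalizer is fitted on that fold's training subjects
# only, a model is trained with early stopping on the fold's validation
# accuracy, and the best-validated model across folds (with its normalizer)
# is applied to the held-out subject. Subject-level predictions are
# obtained by majority vote over trial predictions.

#' Leave-one-subject-out splits
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @return List of `list(train, test)` pairs; the singleton test sets
#'   partition the subject set in deterministic (input) order.
#' @export
make_loso_splits <- function(subject_ids) {
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (length(subject_ids) < 2) stop("need at least 2 subjects")
  lapply(subject_ids, function(s)
    list(train = setdiff(subject_ids, s), test = s))
}

#' Class-stratified subject-level inner folds
#'
#' Partitions training subjects into `k` groups with sizes differing by at
#' most one, stratified by class so per-fold class counts differ by at most
#' one. All trials of a subject stay in a single fold by construction.
#'
#' @param train_subjects Character vector of subject ids.
#' @param labels Named character vector: class label per subject.
#' @param k Number of folds.
#' @param seed Seed for the shuffling within classes.
#' @return List of `k` character vectors (subject ids per fold).
#' @export
make_inner_folds <- function(train_subjects, labels, k = 5, seed = 2025) {
  if (length(train_subjects) < k)
    stop("fewer subjects than inner folds")
  set.seed(seed)
  folds <- vector("list", k)
  # deal subjects class by class, continuing the round-robin across classes
  # so fold sizes stay balanced overall
  at <- 0
  for (cls in sort(unique(labels[train_subjects]))) {
    subj <- train_subjects[labels[train_subjects] == cls]
    subj <- sample(subj)
    for (s in subj) {
      folds[[at %% k + 1]] <- c(folds[[at %% k + 1]], s)
      at <- at + 1
    }
  }
  folds
}

#' Majority vote over a subject's trial predictions
#'
#' Assigns the modal predicted label; ties are broken in favour of the
#' candidate with the larger summed class score across the subject's
#' trials.
#'
#' @param trial_labels Character vector of per-trial predicted labels.
#' @param trial_scores Matrix of per-trial class scores (columns named by
#'   class); required only to break ties.
#' @return Single predicted label.
#' @export
majority_vote <- function(trial_labels, trial_scores = NULL) {
  if (!length(trial_labels)) stop("majority_vote: no trials")
  tb <- table(trial_labels)
  top <- names(tb)[tb == max(tb)]
  if (length(top) == 1) return(top)
  if (is.null(trial_scores)) return(sort(top)[1])
  sums <- colSums(trial_scores[, top, drop = FALSE])
  names(which.max(sums))
}

#' Run the nested leave-one-subject-out protocol
#'
#' For each held-out subject: build class-stratified inner folds over the
#' remaining subjects; per inner fold, fit the channel normalizer on the
#' fold's training subjects only, train with early stopping, and record the
#' fold's validation accuracy; carry the single best-validated model (and
#' its normalizer) to the held-out subject; aggregate trial predictions by
#' majority vote. A hard assertion guarantees the held-out subject never
#' appears in any inner fold.
#'
#' @param dataset A [trial_set()] covering all subjects.
#' @param model_builder Function `(seed) -> eeg_model` (e.g.
#'   `function(s) build_eegdecoder(decoder_config(), seed = s)`).
#' @param config A [train_config()].
#' @param backend Training backend passed to [train_model()].
#' @param verbose Log per-fold progress.
#' @return A `loso_result`: per-fold list (held-out subject, per-trial
#'   scores/labels, subject vote, selected inner fold, history) plus the
#'   dataset's true labels.
#' @export
run_loso <- function(dataset, model_builder = NULL,
                     config = train_config(), backend = "auto",
                     verbose = FALSE) {
  stopifnot(inherits(dataset, "trial_set"))
  if (is.null(model_builder)) {
    tcfg <- decoder_config(in_channels = dim(dataset$trials)[2],
                           input_samples = dim(dataset$trials)[3])
    model_builder <- function(seed) build_eegdecoder(tcfg, seed = seed)
  }
  labs <- subject_labels(dataset)
  subjects <- names(labs)
  cls_n <- table(labs)
  if (any(cls_n < 2) && length(subjects) > config$inner_folds)
    warning("fewer than 2 subjects in some class; stratification degenerate")
  splits <- make_loso_splits(subjects)
  folds_out <- vector("list", length(splits))

  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    inner <- make_inner_folds(sp$train, labs, k = config$inner_folds,
                              seed = config$seed + i)
    # leakage assertion: held-out subject absent from every inner fold
    stopifnot(!sp$test %in% unlist(inner))
    best <- NULL
    for (j in seq_along(inner)) {
      tr_subj <- setdiff(sp$train, inner[[j]])
      va_subj <- inner[[j]]
      tr <- subset_subjects(dataset, tr_subj)
      va <- subset_subjects(dataset, va_subj)
      np <- fit_channel_normalizer(tr)
      fit <- train_model(model_builder(config$seed + 1000 * j + i),
                         apply_normalizer(tr, np), apply_normalizer(va, np),
                         config, backend = backend)
      if (is.null(best) || fit$best_val_accuracy > best$val_acc + 1e-12)
        best <- list(model = fit$model, np = np, fold = j,
                     val_acc = fit$best_val_accuracy,
                     history = fit$history)
    }
    te <- subset_subjects(dataset, sp$test)
    scores <- model_predict(best$model, apply_normalizer(te, best$np),
                            config$batch_size)
    pred <- colnames(scores)[max.col(scores, ties.method = "first")]
    vote <- majority_vote(pred, scores)
    folds_out[[i]] <- list(held_out_subject = sp$test,
                           true_label = labs[[sp$test]],
                           trial_scores = scores,
                           trial_pred = pred,
                           subject_pred = vote,
                           inner_fold = best$fold,
                           inner_val_accuracy = best$val_acc,
                           history = best$history)
    if (verbose)
      message(sprintf("[loso %d/%d] %s: true %s, vote %s (%d/%d trials), inner fold %d (val %.2f)",
                      i, length(splits), sp$test, labs[[sp$test]], vote,
                      sum(pred == labs[[sp$test]]), length(pred),
                      best$fold, best$val_acc))
  }
  structure(list(folds = folds_out, subjects = subjects,
                 true_labels = labs,
                 classes = sort(unique(labs))),
            class = "loso_result")
}

#' Robustness harness: repeat a full LOSO run under several seeds
#'
#' Mirrors the robustness procedure of repeating the complete protocol
#' under a fixed seed set and reporting mean and standard deviation of the
#' subject-level accuracy.
#'
#' @param dataset A [trial_set()].
#' @param seeds Integer vector of seeds.
#' @param config Base [train_config()]; its seed is replaced per run.
#' @param ... Passed to [run_loso()].
#' @return List with per-seed `results`, `accuracies`, and `mean`/`sd`.
#' @export
run_loso_seeds <- function(dataset, seeds = c(42, 99, 123, 2025, 2026),
                           config = train_config(), ...) {
  runs <- lapply(seeds, function(s) {
    config$seed <- s
    run_loso(dataset, config = config, ...)
  })
  accs <- vapply(runs, function(r) subject_accuracy(r), 0)
  list(results = setNames(runs, seeds),
       accuracies = setNames(accs, seeds),
       mean = mean(accs), sd = sd(accs))
}

subject_accuracy <- function(res) {
  mean(vapply(res$folds, function(f) f$subject_pred == f$true_label, NA))
}
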
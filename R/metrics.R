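# Dual-level evaluation metrics: one-vs-rest counts, weighted precision/
# recall/F1, accuracy, Cohen's kappa, and confusion matrices at both the
# trial and the subject level.

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace / total` and chance agreement
#' `p_e = sum_i row_i * col_i / total^2`.
#'
#' @param confusion Square numeric matrix of counts (rows = truth,
#'   columns = prediction).
#' @return Scalar in `[-1, 1]`. A degenerate single-cell table (chance
#'   agreement 1) returns 1 for perfect agreement and is an error
#'   otherwise.
#' @examples
#' cohen_kappa(diag(c(12, 12, 12)))           # 1
#' cohen_kappa(matrix(4, 3, 3))               # 0
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  tot <- sum(confusion)
  if (tot <= 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / tot
  pe <- sum(rowSums(confusion) * colSums(confusion)) / tot^2
  if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) return(1)
    stop("kappa undefined: chance agreement is 1 but agreement imperfect")
  }
  (po - pe) / (1 - pe)
}

confusion_from_labels <- function(truth, pred, classes) {
  tb <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  m <- matrix(as.numeric(tb), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

# per-class one-vs-rest counts and weighted-average metrics (percent)
ovr_metrics <- function(cm) {
  classes <- rownames(cm)
  tot <- sum(cm)
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- tot - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    list(TP = tp, FP = fp, FN = fn, TN = tn, precision = prec,
         recall = rec, f1 = f1, support = tp + fn)
  })
  names(per) <- classes
  w <- vapply(per, function(p) p$support, 0)
  wsum <- function(field) {
    v <- vapply(per, function(p) p[[field]], 0)
    if (sum(w) > 0) sum(v * w) / sum(w) else 0
  }
  list(per_class = per,
       accuracy = 100 * sum(diag(cm)) / tot,
       precision_weighted = 100 * wsum("precision"),
       recall_weighted = 100 * wsum("recall"),
       f1_weighted = 100 * wsum("f1"),
       precision_macro = 100 * mean(vapply(per, function(p) p$precision, 0)),
       recall_macro = 100 * mean(vapply(per, function(p) p$recall, 0)),
       f1_macro = 100 * mean(vapply(per, function(p) p$f1, 0)))
}

#' Compute the dual-level metrics report for a LOSO result
#'
#' Trial level: accuracy as the global fraction of correctly classified
#' trials; precision/recall/F1 by one-vs-rest with class-support weighting.
#' Subject level: the same metrics over majority-vote subject predictions
#' (each subject contributes equally regardless of its trial count).
#' Cohen's kappa and the confusion matrix are reported at both levels.
#' All rates are percentages; kappa is on its standard [-1, 1] scale.
#'
#' @param res A `loso_result` from [run_loso()], or a list with fields
#'   `truth`/`pred` pairs (see [metrics_from_predictions()]).
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(res) {
  stopifnot(inherits(res, "loso_result"))
  trial_truth <- unlist(lapply(res$folds, function(f)
    rep(f$true_label, length(f$trial_pred))))
  trial_pred <- unlist(lapply(res$folds, function(f) f$trial_pred))
  subj_truth <- vapply(res$folds, function(f) f$true_label, "")
  subj_pred <- vapply(res$folds, function(f) f$subject_pred, "")
  metrics_from_predictions(trial_truth, trial_pred, subj_truth, subj_pred,
                           res$classes)
}

#' Build a metrics report from explicit prediction vectors
#'
#' @param trial_truth,trial_pred Per-trial true and predicted labels.
#' @param subj_truth,subj_pred Per-subject true and predicted labels.
#' @param classes Class levels (defaults to the union observed).
#' @return A `metrics_report` list with `trial` and `subject` sections.
#' @export
metrics_from_predictions <- function(trial_truth, trial_pred, subj_truth,
                                     subj_pred, classes = NULL) {
  if (length(trial_truth) != length(trial_pred))
    stop("trial truth/prediction length mismatch")
  if (length(subj_truth) != length(subj_pred))
    stop("subject truth/prediction length mismatch")
  if (is.null(classes))
    classes <- sort(unique(c(trial_truth, trial_pred,
                             subj_truth, subj_pred)))
  cm_t <- confusion_from_labels(trial_truth, trial_pred, classes)
  cm_s <- confusion_from_labels(subj_truth, subj_pred, classes)
  structure(list(
    classes = classes,
    trial = c(ovr_metrics(cm_t),
              list(kappa = cohen_kappa(cm_t), confusion = cm_t,
                   n = sum(cm_t))),
    subject = c(ovr_metrics(cm_s),
                list(kappa = cohen_kappa(cm_s), confusion = cm_s,
                     n = sum(cm_s)))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (lv in c("subject", "trial")) {
    m <- x[[lv]]
    cat(sprintf(
      "%s level (n=%d): accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%  kappa %.3f\n",
      lv, m$n, m$accuracy, m$precision_weighted, m$recall_weighted,
      m$f1_weighted, m$kappa))
  }
  cat("subject-level confusion (truth x predicted):\n")
  print(x$subject$confusion)
  invisible(x)
}

#' Write a metrics report (JSON) plus confusion matrices (CSV)
#'
#' @param report A `metrics_report`.
#' @param out_dir Output directory.
#' @param stem File stem.
#' @return Invisibly, the JSON path.
#' @export
write_metrics_report <- function(report, out_dir, stem = "metrics") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  j <- report
  j$trial$confusion <- NULL
  j$subject$confusion <- NULL
  path <- file.path(out_dir, paste0(stem, ".json"))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  utils::write.csv(report$trial$confusion,
                   file.path(out_dir, paste0(stem, "_confusion_trial.csv")))
  utils::write.csv(report$subject$confusion,
                   file.path(out_dir, paste0(stem, "_confusion_subject.csv")))
  invisible(path)
}
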
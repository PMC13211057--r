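# Metric correctness: Cohen's kappa, one-vs-rest counts, weighted averages,
# and equivalence with independent implementations.

# independent brute-force metrics used as the oracle throughout this file
oracle_metrics <- function(cm) {
  k <- nrow(cm); tot <- sum(cm)
  prec <- rec <- f1 <- sup <- numeric(k)
  for (i in 1:k) {
    tp <- cm[i, i]
    colsum <- 0; rowsum <- 0
    for (j in 1:k) { colsum <- colsum + cm[j, i]; rowsum <- rowsum + cm[i, j] }
    prec[i] <- if (colsum > 0) tp / colsum else 0
    rec[i] <- if (rowsum > 0) tp / rowsum else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    sup[i] <- rowsum
  }
  po <- sum(diag(cm)) / tot
  pe <- 0
  for (i in 1:k) pe <- pe + sum(cm[i, ]) * sum(cm[, i]) / tot^2
  list(acc = 100 * po,
       prec_w = 100 * sum(prec * sup) / sum(sup),
       rec_w = 100 * sum(rec * sup) / sum(sup),
       f1_w = 100 * sum(f1 * sup) / sum(sup),
       kappa = (po - pe) / (1 - pe))
}

cm_to_labels <- function(cm, classes = c("AD", "CJD", "CNTRL")) {
  truth <- character(0); pred <- character(0)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    truth <- c(truth, rep(classes[i], cm[i, j]))
    pred <- c(pred, rep(classes[j], cm[i, j]))
  }
  list(truth = truth, pred = pred)
}

test_that("kappa handles the canonical cases", {
  expect_equal(cohen_kappa(diag(c(12, 12, 12))), 1)
  expect_equal(cohen_kappa(matrix(4, 3, 3)), 0)
  worked <- matrix(c(10, 2, 0, 1, 11, 0, 0, 0, 12), 3, byrow = TRUE)
  expect_equal(cohen_kappa(worked), 0.875)   # p_o = 33/36, p_e = 432/1296
  # degenerate single-cell table: chance agreement 1, perfect -> kappa 1
  # (p_e = 1 forces all mass into one diagonal cell, so the imperfect case
  # cannot arise; the implementation still guards it defensively)
  expect_equal(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), 1)
  expect_error(cohen_kappa(matrix(0, 3, 3)), "empty")
})

test_that("metrics match the brute-force oracle on 100 random tables", {
  set.seed(61)
  for (i in 1:100) {
    cm <- matrix(rpois(9, 8), 3)
    if (sum(cm) == 0 || any(rowSums(cm) == 0)) next
    lb <- cm_to_labels(cm)
    rep_ <- metrics_from_predictions(lb$truth, lb$pred, lb$truth, lb$pred,
                                     c("AD", "CJD", "CNTRL"))
    oc <- oracle_metrics(cm)
    expect_equal(rep_$trial$accuracy, oc$acc, tolerance = 1e-9)
    expect_equal(rep_$trial$precision_weighted, oc$prec_w, tolerance = 1e-9)
    expect_equal(rep_$trial$recall_weighted, oc$rec_w, tolerance = 1e-9)
    expect_equal(rep_$trial$f1_weighted, oc$f1_w, tolerance = 1e-9)
    expect_equal(rep_$trial$kappa, oc$kappa, tolerance = 1e-9)
  }
})

test_that("kappa agrees with an established implementation", {
  skip_if_not_installed("caret")
  set.seed(62)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 10) + 1, 3)
    lb <- cm_to_labels(cm)
    cc <- caret::confusionMatrix(
      factor(lb$pred, levels = c("AD", "CJD", "CNTRL")),
      factor(lb$truth, levels = c("AD", "CJD", "CNTRL")))
    expect_equal(cohen_kappa(t(cc$table)),
                 unname(cc$overall["Kappa"]), tolerance = 1e-9)
  }
})

test_that("one-vs-rest counts and the confusion matrices are coherent", {
  cm <- matrix(c(10, 2, 0, 1, 11, 0, 0, 0, 12), 3, byrow = TRUE,
               dimnames = list(truth = c("AD", "CJD", "CNTRL"),
                               predicted = c("AD", "CJD", "CNTRL")))
  lb <- cm_to_labels(cm)
  rep_ <- metrics_from_predictions(lb$truth, lb$pred, lb$truth, lb$pred)
  expect_equal(unname(rep_$trial$confusion), unname(cm))
  expect_equal(sum(rep_$trial$confusion), rep_$trial$n)
  ad <- rep_$trial$per_class$AD
  expect_equal(ad$TP, 10); expect_equal(ad$FP, 1)
  expect_equal(ad$FN, 2); expect_equal(ad$TN, 23)
  # one AD subject mislabeled CJD out of 12/12/12
  one_off <- diag(c(12, 12, 12)); one_off[1, 1] <- 11; one_off[1, 2] <- 1
  lb2 <- cm_to_labels(one_off)
  r2 <- metrics_from_predictions(lb2$truth, lb2$pred, lb2$truth, lb2$pred)
  expect_equal(r2$subject$per_class$AD$recall, 11 / 12)
  expect_equal(r2$subject$accuracy, 100 * 35 / 36)
})

test_that("weighted and macro averages coincide for balanced supports", {
  set.seed(63)
  for (i in 1:10) {
    # equal row sums by construction
    cm <- t(sapply(1:3, function(r) as.vector(stats::rmultinom(1, 20,
                                                               rep(1, 3)))))
    lb <- cm_to_labels(cm)
    rp <- metrics_from_predictions(lb$truth, lb$pred, lb$truth, lb$pred)
    expect_equal(rp$trial$precision_weighted, rp$trial$precision_macro,
                 tolerance = 1e-9)
    expect_equal(rp$trial$f1_weighted, rp$trial$f1_macro, tolerance = 1e-9)
  }
})

test_that("majority voting picks the mode and breaks ties by summed score", {
  expect_equal(majority_vote(rep(c("AD", "CJD"), c(30, 10))), "AD")
  expect_equal(majority_vote(rep("CNTRL", 40)), "CNTRL")
  # 20/20 tie: summed scores decide (12.1 vs 11.9)
  labels <- rep(c("AD", "CJD"), each = 20)
  scores <- matrix(0, 40, 3, dimnames = list(NULL, c("AD", "CJD", "CNTRL")))
  scores[1:20, "AD"] <- 12.1 / 20
  scores[21:40, "CJD"] <- 11.9 / 20
  expect_equal(majority_vote(labels, scores), "AD")
  scores[21:40, "CJD"] <- 12.3 / 20
  expect_equal(majority_vote(labels, scores), "CJD")
  expect_error(majority_vote(character(0)), "no trials")
})

test_that("reports serialize to JSON and CSV", {
  lb <- cm_to_labels(diag(c(5, 5, 5)))
  rp <- metrics_from_predictions(lb$truth, lb$pred, lb$truth, lb$pred)
  d <- withr::local_tempdir()
  p <- write_metrics_report(rp, d)
  j <- jsonlite::fromJSON(p)
  expect_equal(j$subject$accuracy, 100)
  expect_true(file.exists(file.path(d, "metrics_confusion_trial.csv")))
})
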
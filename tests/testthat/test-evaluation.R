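# Confusion counts, threshold metrics, and ROC/PR curves.

test_that("confusion counts agree with an exhaustive tally", {
  expect_equal(unclass(confusion(c(1, 0, 1, 0), c(1, 0, 1, 0)))[1:4],
               list(tp = 2L, fp = 0L, tn = 2L, fn = 0L),
               ignore_attr = TRUE)
  expect_equal(unclass(confusion(c(0, 1, 0, 1), c(1, 0, 1, 0)))[1:4],
               list(tp = 0L, fp = 2L, tn = 0L, fn = 2L),
               ignore_attr = TRUE)
  set.seed(81)
  for (rep in 1:10) {
    pred <- rbinom(200, 1, 0.4)
    truth <- rbinom(200, 1, 0.3)
    cm <- confusion(pred, truth)
    expect_equal(cm$tp, sum(pred & truth))
    expect_equal(cm$fp, sum(pred & !truth))
    expect_equal(cm$tn, sum(!pred & !truth))
    expect_equal(cm$fn, sum(!pred & truth))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 200)
  }
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("missing predictions follow the chosen policy", {
  pred <- c(1, NA, 0, NA)
  truth <- c(1, 1, 0, 0)
  ex <- confusion(pred, truth, "exclude")
  expect_equal(ex$tp + ex$fp + ex$tn + ex$fn, 2)
  cn <- confusion(pred, truth, "count-as-negative")
  expect_equal(cn$fn, 1)
  expect_equal(cn$tn, 2)
})

test_that("metrics equal direct-formula oracles on random tables", {
  set.seed(82)
  for (rep in 1:200) {
    cm <- list(tp = rpois(1, 20), fp = rpois(1, 10), tn = rpois(1, 50),
               fn = rpois(1, 15))
    if (cm$tp + cm$fp + cm$tn + cm$fn == 0) next
    m <- classification_metrics(cm)
    prec <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else 0
    rec <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
    expect_equal(m$specificity, prec)
    expect_equal(m$sensitivity, rec)
    if (prec + rec > 0) {
      expect_equal(m$f_measure, 2 * prec * rec / (prec + rec))
    }
    den <- as.numeric(cm$tp + cm$fp) * (cm$tp + cm$fn) *
      (cm$tn + cm$fp) * (cm$tn + cm$fn)
    if (den > 0) {
      expect_equal(m$mcc,
                   (as.numeric(cm$tp) * cm$tn - as.numeric(cm$fp) * cm$fn) /
                     sqrt(den), tolerance = 1e-12)
    }
  }
})

test_that("perfect and degenerate classifiers are reported correctly", {
  perfect <- classification_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$f_measure, 1)
  expect_equal(perfect$mcc, 1)
  expect_length(perfect$degenerate, 0)
  # the worked MCC example: (2*3 - 1*2)/sqrt(3*4*4*5)
  m <- classification_metrics(list(tp = 2, fp = 1, tn = 3, fn = 2))
  expect_equal(m$mcc, (2 * 3 - 1 * 2) / sqrt(3 * 4 * 4 * 5),
               tolerance = 1e-12)
  # no positive predictions: specificity must be flagged, never 1
  none <- classification_metrics(list(tp = 0, fp = 0, tn = 8, fn = 2))
  expect_equal(none$specificity, 0)
  expect_true("specificity" %in% none$degenerate)
  expect_true("mcc" %in% none$degenerate)
})

test_that("MCC is invariant under simultaneous class swap", {
  set.seed(83)
  for (rep in 1:20) {
    pred <- rbinom(100, 1, 0.4)
    truth <- rbinom(100, 1, 0.4)
    m1 <- classification_metrics(confusion(pred, truth))
    m2 <- classification_metrics(confusion(1 - pred, 1 - truth))
    expect_equal(m1$mcc, m2$mcc, tolerance = 1e-12)
  }
})

test_that("AUC equals the brute-force pairwise estimator, ties included", {
  set.seed(84)
  for (rep in 1:10) {
    n <- 30
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    # coarse scores force ties
    scores <- sample(seq(0, 1, 0.2), n, replace = TRUE)
    got <- prediction_curves(scores, labels)$auc
    expect_equal(got, brute_force_auc(scores, labels), tolerance = 1e-12)
  }
  expect_equal(prediction_curves(c(1, 0, 1, 0), c(1, 0, 1, 0))$auc, 1.0)
  expect_error(prediction_curves(runif(5), rep(1, 5)), "both classes")
})

test_that("random scores give AUC near one half", {
  set.seed(85)
  labels <- rbinom(2000, 1, 0.3)
  auc <- prediction_curves(runif(2000), labels)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("ROC and PR sweeps are internally consistent", {
  set.seed(86)
  labels <- rbinom(300, 1, 0.3)
  scores <- runif(300) + labels * 0.5
  cv <- prediction_curves(scores, labels)
  expect_equal(cv$roc$fpr[1], 0)
  expect_equal(cv$roc$tpr[1], 0)
  expect_equal(cv$roc$fpr[nrow(cv$roc)], 1)
  expect_equal(cv$roc$tpr[nrow(cv$roc)], 1)
  expect_true(all(diff(cv$roc$fpr) >= 0))
  expect_true(all(diff(cv$roc$tpr) >= 0))
  # trapezoidal area under the tie-aware ROC equals the rank AUC
  trap <- sum(diff(cv$roc$fpr) *
                (head(cv$roc$tpr, -1) + tail(cv$roc$tpr, -1)) / 2)
  expect_equal(trap, cv$auc, tolerance = 1e-12)
  # PR endpoints: recall reaches 1 at the loosest threshold
  expect_equal(cv$pr$recall[nrow(cv$pr)], 1)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(cv$auc, ref, tolerance = 1e-10)
})

test_that("evaluate_predictions pools or macro-averages and checks ids", {
  set.seed(87)
  pred <- data.frame(chain_id = rep(c("a", "b"), each = 50),
                     score = runif(100), call = rbinom(100, 1, 0.4))
  labs <- data.frame(chain_id = pred$chain_id,
                     label = rbinom(100, 1, 0.3))
  pooled <- evaluate_predictions(pred, labs)
  direct <- classification_metrics(confusion(pred$call, labs$label))
  expect_equal(pooled$metrics$mcc, direct$mcc)
  expect_equal(pooled$auc, prediction_curves(pred$score, labs$label)$auc)
  macro <- evaluate_predictions(pred, labs, aggregate = "per-chain")
  per <- sapply(c("a", "b"), function(id) {
    i <- pred$chain_id == id
    classification_metrics(confusion(pred$call[i], labs$label[i]))$mcc
  })
  expect_equal(macro$metrics$mcc, mean(per))
  labs_bad <- labs
  labs_bad$chain_id[1:50] <- "zzz"
  expect_error(evaluate_predictions(pred, labs_bad), "zzz")
})
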
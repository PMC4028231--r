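# Per-residue classification metrics and threshold-sweep curves.
#
# Naming note: in this problem domain "specificity" conventionally denotes
# TP/(TP+FP), i.e. what the broader machine-learning literature calls
# precision. Both names are emitted to prevent misreading.

#' Confusion counts from binary predictions
#'
#' @param predictions Binary 0/1 calls; `NA` marks residues the method did
#'   not predict.
#' @param labels Binary 0/1 truth, same length.
#' @param missing_policy `"exclude"` drops unpredicted residues from the
#'   counts (used when evaluating the homology stage alone);
#'   `"count-as-negative"` treats them as negative calls.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(predictions, labels,
                      missing_policy = c("exclude", "count-as-negative")) {
  missing_policy <- match.arg(missing_policy)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  keep <- !is.na(labels)
  predictions <- predictions[keep]
  labels <- labels[keep]
  if (missing_policy == "count-as-negative") {
    predictions[is.na(predictions)] <- 0L
  } else {
    keep <- !is.na(predictions)
    predictions <- predictions[keep]
    labels <- labels[keep]
  }
  structure(list(tp = sum(predictions == 1 & labels == 1),
                 fp = sum(predictions == 1 & labels == 0),
                 tn = sum(predictions == 0 & labels == 0),
                 fn = sum(predictions == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes specificity (= precision, `TP/(TP+FP)`), sensitivity
#' (= recall, `TP/(TP+FN)`), their harmonic mean (F-measure), accuracy and
#' the Matthews correlation coefficient. A zero denominator makes the
#' corresponding metric degenerate: a predictor that makes no positive
#' prediction would trivially score a perfect specificity, so degenerate
#' metrics are reported as 0 and flagged, never as 1.
#'
#' @param cm A [confusion()] result, or a list with `tp`, `fp`, `tn`, `fn`.
#' @return List with `specificity`, `precision` (alias), `sensitivity`,
#'   `recall` (alias), `f_measure`, `accuracy`, `mcc`, and a character
#'   vector `degenerate` naming metrics with undefined denominators.
#' @export
classification_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  if (tp + fp + tn + fn == 0) stop("empty confusion table")
  degenerate <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  spec <- safe_div(tp, tp + fp, "specificity")
  sens <- safe_div(tp, tp + fn, "sensitivity")
  f <- if (spec + sens == 0) {
    degenerate <- c(degenerate, "f_measure")
    0
  } else 2 * spec * sens / (spec + sens)
  mcc_den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den2 == 0) {
    degenerate <- c(degenerate, "mcc")
    0
  } else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den2)
  list(specificity = spec, precision = spec,
       sensitivity = sens, recall = sens,
       f_measure = f, accuracy = (tp + tn) / (tp + fp + tn + fn),
       mcc = mcc, degenerate = degenerate)
}

#' ROC and precision-recall curves with AUC
#'
#' Sweeps the decision threshold over the distinct scores in descending
#' order. The reported AUC is the Mann-Whitney probability that a randomly
#' chosen positive outranks a randomly chosen negative, with ties counted
#' one half -- identical to the trapezoidal area under the tie-aware ROC
#' curve.
#'
#' @param scores Numeric prediction scores (higher = more interface-like).
#' @param labels Binary 0/1 truth; both classes must be present.
#' @return List with `roc` (data frame: threshold, fpr, tpr), `pr` (data
#'   frame: threshold, recall, precision) and `auc`.
#' @export
prediction_curves <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes required for curves")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # process tied scores as blocks: one operating point per distinct score
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[block_end]
  fp <- (block_end) - tp
  thr <- s[block_end]

  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / nn), tpr = c(0, tp / np))
  pr <- data.frame(threshold = thr, recall = tp / np,
                   precision = tp / block_end)
  # Mann-Whitney with ties = 1/2, via the rank-sum identity
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  list(roc = roc, pr = pr, auc = auc)
}

#' Evaluate per-residue predictions against true labels
#'
#' Convenience wrapper computing threshold metrics and curves in one call,
#' pooled over residues by default or macro-averaged per chain.
#'
#' @param predictions Data frame with columns `chain_id`, `score`, `call`.
#' @param labels Data frame with columns `chain_id`, `label` (0/1), row
#'   order matching `predictions` within chain.
#' @param missing_policy Passed to [confusion()].
#' @param aggregate `"pooled"` (default) computes one confusion table over
#'   all residues; `"per-chain"` averages metrics over chains.
#' @return List with `metrics`, `confusion` (pooled mode), `auc`, `roc`,
#'   `pr`.
#' @export
evaluate_predictions <- function(predictions, labels,
                                 missing_policy = "exclude",
                                 aggregate = c("pooled", "per-chain")) {
  aggregate <- match.arg(aggregate)
  if (!identical(predictions$chain_id, labels$chain_id)) {
    offenders <- union(setdiff(unique(predictions$chain_id),
                               unique(labels$chain_id)),
                       setdiff(unique(labels$chain_id),
                               unique(predictions$chain_id)))
    stop("chain id mismatch between predictions and labels: ",
         paste(offenders, collapse = ", "))
  }
  if (aggregate == "pooled") {
    cm <- confusion(predictions$call, labels$label, missing_policy)
    mets <- classification_metrics(cm)
  } else {
    per <- lapply(split(seq_len(nrow(predictions)), predictions$chain_id),
                  function(i) {
                    classification_metrics(
                      confusion(predictions$call[i], labels$label[i],
                                missing_policy))
                  })
    num <- c("specificity", "sensitivity", "f_measure", "accuracy", "mcc")
    mets <- lapply(stats::setNames(num, num), function(m) {
      mean(vapply(per, `[[`, numeric(1), m))
    })
    cm <- NULL
  }
  keep <- !is.na(predictions$score)
  curves <- if (length(unique(labels$label[keep])) == 2) {
    prediction_curves(predictions$score[keep], labels$label[keep])
  } else NULL
  list(metrics = mets, confusion = cm,
       auc = if (!is.null(curves)) curves$auc else NA_real_,
       roc = curves$roc, pr = curves$pr)
}
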
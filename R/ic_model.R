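# Linear model predicting the interface-conservation score of a
# query/homolog pair from alignment statistics, and homology-zone logic.

#' Interface-conservation regression model
#'
#' A linear model predicting the IC score of a query/homolog pair from four
#' alignment statistics: `-log10(E-value)`, `log10(L)`, the positive score
#' PS, and the length fraction `L / min(LQ, LH)`. The default coefficients
#' are the published estimates of the model fitted on 8,970 query/homolog
#' pairs of non-redundant RNA-binding protein chains; PS carries most of the
#' explanatory weight.
#'
#' @param intercept,coef_neg_log_e,coef_log_l,coef_ps,coef_len_frac Model
#'   coefficients.
#' @param log_base Logarithm base used for the E-value and length predictors
#'   (metadata, default 10).
#' @return An object of class `ic_model`.
#' @export
ic_model <- function(intercept = -0.532, coef_neg_log_e = 0.001,
                     coef_log_l = 0.005, coef_ps = 0.600,
                     coef_len_frac = 0.089, log_base = 10) {
  coefs <- c(intercept = intercept, coef_neg_log_e = coef_neg_log_e,
             coef_log_l = coef_log_l, coef_ps = coef_ps,
             coef_len_frac = coef_len_frac)
  if (!all(is.finite(coefs))) stop("coefficients must be finite")
  structure(c(as.list(coefs), list(log_base = log_base)), class = "ic_model")
}

#' @export
print.ic_model <- function(x, ...) {
  cat("ic_model: IC ~", sprintf("%.4g", x$intercept), "+",
      sprintf("%.4g*(-logE) + %.4g*logL + %.4g*PS + %.4g*lenfrac\n",
              x$coef_neg_log_e, x$coef_log_l, x$coef_ps, x$coef_len_frac))
  invisible(x)
}

# The length-fraction predictor: alignment coverage of the shorter sequence.
len_frac <- function(stats) pmax(stats$frac_q, stats$frac_h)

#' Predict the IC score from alignment statistics
#'
#' Evaluates the affine model
#' `IC = b0 + b1*(-logE) + b2*log(L) + b3*PS + b4*(L/min(LQ,LH))`.
#' The prediction is deliberately not clamped to `[-1, 1]`: zone assignment
#' consumes the raw value, and clamping could silently move hits across
#' zone boundaries.
#'
#' @param stats Data frame of alignment statistics as produced by
#'   [compute_alignment_stats()] (one or more rows).
#' @param model An [ic_model()]; the published defaults if omitted.
#' @return Numeric vector of predicted IC scores.
#' @export
predict_ic <- function(stats, model = ic_model()) {
  stopifnot(inherits(model, "ic_model"))
  model$intercept +
    model$coef_neg_log_e * stats$neg_log_e +
    model$coef_log_l * stats$log_l +
    model$coef_ps * stats$ps +
    model$coef_len_frac * len_frac(stats)
}

#' Fit the IC regression model by ordinary least squares
#'
#' Regresses observed IC scores on the four alignment-statistic predictors.
#' Diagnostics include the adjusted R-squared, per-coefficient standard
#' errors, and Type II (drop-one) sums of squares.
#'
#' @param stats Data frame of alignment statistics (>= 10 rows).
#' @param ic Observed IC scores, one per row of `stats`.
#' @param log_base Metadata recorded in the fitted model.
#' @return List with `model` (an [ic_model()]), `fit` (the underlying `lm`),
#'   and `diagnostics` (adjusted R-squared, coefficient table, Type II SS).
#' @export
fit_ic_model <- function(stats, ic, log_base = 10) {
  if (nrow(stats) < 10) stop("need at least 10 query/homolog pairs")
  df <- data.frame(ic = ic, neg_log_e = stats$neg_log_e, log_l = stats$log_l,
                   ps = stats$ps, len_frac = len_frac(stats))
  X <- cbind(intercept = 1, as.matrix(df[, -1]))
  if (qr(X)$rank < ncol(X)) {
    preds <- colnames(X)[-1]
    bad <- preds[vapply(preds, function(p) {
      others <- X[, setdiff(colnames(X), p), drop = FALSE]
      r <- qr.resid(qr(others), X[, p])
      sum(r^2) < 1e-10 * max(sum(X[, p]^2), 1)
    }, logical(1))]
    stop("rank-deficient design; collinear predictors: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(ic ~ neg_log_e + log_l + ps + len_frac, data = df)
  sm <- summary(fit)
  # Type II (drop-one) sums of squares; drop1 warns on noiseless fits
  d1 <- suppressWarnings(stats::drop1(fit))
  model <- ic_model(intercept = unname(stats::coef(fit)[1]),
                    coef_neg_log_e = unname(stats::coef(fit)["neg_log_e"]),
                    coef_log_l = unname(stats::coef(fit)["log_l"]),
                    coef_ps = unname(stats::coef(fit)["ps"]),
                    coef_len_frac = unname(stats::coef(fit)["len_frac"]),
                    log_base = log_base)
  list(model = model, fit = fit,
       diagnostics = list(adj_r_squared = sm$adj.r.squared,
                          coefficients = sm$coefficients,
                          type2_ss = d1[-1, "Sum of Sq"]))
}

#' Homology-zone thresholds
#'
#' Reliability tiers for homology transfer, defined as lower cutoffs on the
#' predicted IC score. Hits below the Dark cutoff are discarded.
#'
#' @param safe,twilight,dark Zone lower bounds; must satisfy
#'   `safe > twilight > dark >= -1`.
#' @return An object of class `zone_thresholds`.
#' @export
zone_thresholds <- function(safe = 0.70, twilight = 0.20, dark = 0.15) {
  if (!(safe > twilight && twilight > dark && dark >= -1)) {
    stop("require safe > twilight > dark >= -1")
  }
  structure(list(safe = safe, twilight = twilight, dark = dark),
            class = "zone_thresholds")
}

ZONE_LEVELS <- c("Safe", "Twilight", "Dark", "None")

#' Assign homology zones to predicted IC scores
#'
#' Zone boundaries are closed below: a predicted IC exactly at a cutoff
#' falls in the higher zone.
#'
#' @param predicted_ic Numeric vector of predicted IC scores.
#' @param thresholds A [zone_thresholds()].
#' @return Factor with levels `Safe`, `Twilight`, `Dark`, `None` (`None`
#'   marks hits to be discarded).
#' @export
assign_zone <- function(predicted_ic, thresholds = zone_thresholds()) {
  stopifnot(inherits(thresholds, "zone_thresholds"))
  z <- ifelse(predicted_ic >= thresholds$safe, "Safe",
              ifelse(predicted_ic >= thresholds$twilight, "Twilight",
                     ifelse(predicted_ic >= thresholds$dark, "Dark", "None")))
  factor(z, levels = ZONE_LEVELS)
}

#' Write / read IC model and zone configuration (plain text, key = value)
#'
#' @param model An [ic_model()].
#' @param thresholds A [zone_thresholds()].
#' @param path File path.
#' @export
write_ic_config <- function(model, thresholds, path) {
  vals <- c(intercept = model$intercept,
            coef_neg_log_e = model$coef_neg_log_e,
            coef_log_l = model$coef_log_l, coef_ps = model$coef_ps,
            coef_len_frac = model$coef_len_frac, log_base = model$log_base,
            zone_safe = thresholds$safe, zone_twilight = thresholds$twilight,
            zone_dark = thresholds$dark)
  writeLines(sprintf("%s = %.17g", names(vals), vals), path)
  invisible(path)
}

#' @rdname write_ic_config
#' @export
read_ic_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) as.numeric(trimws(x[2])), numeric(1)),
    vapply(kv, function(x) trimws(x[1]), character(1)))
  list(model = ic_model(vals[["intercept"]], vals[["coef_neg_log_e"]],
                        vals[["coef_log_l"]], vals[["coef_ps"]],
                        vals[["coef_len_frac"]], vals[["log_base"]]),
       thresholds = zone_thresholds(vals[["zone_safe"]],
                                    vals[["zone_twilight"]],
                                    vals[["zone_dark"]]))
}
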
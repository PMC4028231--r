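# Second-stage logistic regression combining the homology and SVM scores,
# with explicit handling of missing homology inputs.

#' Fit the two-score logistic combiner
#'
#' Fits a ridge-penalized maximum-likelihood logistic regression of the
#' residue label on the 2-D score vector (homology score, SVM score).
#' Residues the homology stage could not cover (score `NA`, the `'?'`
#' missing input) are imputed with the training-set mean of the non-missing
#' homology scores; the imputation value is stored in the model so
#' prediction-time missing values are treated identically. The ridge
#' penalty (default 1e-8, the conventional default of logistic
#' implementations in machine-learning toolkits) is on the non-intercept
#' weights only.
#'
#' @param homprip_score Homology scores in `[0, 1]`, `NA` where missing.
#' @param svm_score SVM scores in `[0, 1]`.
#' @param labels Binary 0/1 labels, both classes present.
#' @param ridge Non-negative ridge penalty (default 1e-8).
#' @return An object of class `combiner_model` with `bias`,
#'   `weight_homprip`, `weight_svm`, `imputation_value`, `ridge`, and
#'   standard errors from the observed Fisher information.
#' @export
fit_combiner <- function(homprip_score, svm_score, labels, ridge = 1e-8) {
  stopifnot(length(homprip_score) == length(svm_score),
            length(svm_score) == length(labels), ridge >= 0)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    stop("labels must be binary with both classes present")
  }
  miss <- is.na(homprip_score)
  svm_only <- all(miss)
  if (svm_only) {
    warning("all homology scores missing; combiner degenerates to SVM-only")
    imp <- 0
    X <- cbind(intercept = 1, svm = as.numeric(svm_score))
    fit <- ridge_logistic(X, y, ridge = ridge)
    beta <- c(fit$beta[1], 0, fit$beta[2])
    se <- c(fit$se[1], NA_real_, fit$se[2])
  } else {
    imp <- mean(homprip_score[!miss])
    h <- ifelse(miss, imp, homprip_score)
    X <- cbind(intercept = 1, homprip = h, svm = as.numeric(svm_score))
    fit <- ridge_logistic(X, y, ridge = ridge)
    beta <- fit$beta
    se <- fit$se
  }
  structure(
    list(bias = unname(beta[1]), weight_homprip = unname(beta[2]),
         weight_svm = unname(beta[3]), imputation_value = imp,
         ridge = ridge, se = unname(se), converged = fit$converged,
         svm_only = svm_only),
    class = "combiner_model"
  )
}

# Ridge-penalized logistic regression by Newton-Raphson (IRLS). The
# penalty applies only where `penalize` is TRUE. Returns coefficients,
# standard errors from the penalized observed information, and a
# convergence flag.
ridge_logistic <- function(X, y, ridge = 1e-8, penalize = NULL,
                           max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  if (is.null(penalize)) penalize <- c(FALSE, rep(TRUE, p - 1))
  P <- diag(ridge * as.numeric(penalize), p)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - drop(P %*% beta)
    H <- crossprod(X * w, X) + P
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  H <- crossprod(X * pmax(mu * (1 - mu), 1e-12), X) + P
  se <- sqrt(diag(solve(H)))
  list(beta = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)), converged = converged)
}

#' Combine homology and SVM scores into a final probability
#'
#' Evaluates `plogis(bias + w_h * h + w_s * s)`, imputing the stored
#' training mean where the homology score is missing. Because the SVM
#' stage covers every residue, the combined probability is defined for
#' every residue of every query even when the homology stage covers none.
#'
#' @param model A fitted [combiner_model][fit_combiner()].
#' @param homprip_score Homology scores (`NA` allowed).
#' @param svm_score SVM scores.
#' @return Numeric vector of probabilities strictly in `(0, 1)`.
#' @export
combine_scores <- function(model, homprip_score, svm_score) {
  stopifnot(inherits(model, "combiner_model"))
  h <- ifelse(is.na(homprip_score), model$imputation_value, homprip_score)
  eta <- model$bias + model$weight_homprip * h +
    model$weight_svm * as.numeric(svm_score)
  p <- stats::plogis(eta)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' @export
print.combiner_model <- function(x, ...) {
  cat(sprintf(
    "combiner_model: logit(p) = %.4g + %.4g*homology + %.4g*svm (ridge %g)\n",
    x$bias, x$weight_homprip, x$weight_svm, x$ridge))
  cat(sprintf("  missing homology score imputed with %.4g\n",
              x$imputation_value))
  invisible(x)
}
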
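# PSSM sliding-window SVM classifier: feature construction, RBF-SVM
# training with class weighting, grid-search tuning, and sequence-based
# cross-validation (folds partition whole chains, never residues).

#' Construct a position-specific scoring matrix object
#'
#' @param protein_id Sequence identifier.
#' @param matrix Numeric matrix, one row per residue, 20 columns of
#'   log-odds scores in the standard PSI-BLAST column order
#'   (A R N D C Q E G H I L K M F P S T W Y V).
#' @param sequence Optional character vector of one-letter codes (length L).
#' @return An object of class `pssm`.
#' @export
pssm <- function(protein_id, matrix, sequence = NULL) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 20) stop("PSSM must have 20 columns")
  if (!is.null(sequence) && length(sequence) != nrow(matrix)) {
    stop("sequence length must match PSSM rows")
  }
  colnames(matrix) <- AA_ALPHABET
  structure(list(protein_id = protein_id, matrix = matrix,
                 sequence = sequence, alphabet = AA_ALPHABET),
            class = "pssm")
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: two header lines, a column-header
#' line with the amino acid alphabet, then one line per residue starting
#' with the position and residue letter followed by 20 log-odds integers
#' (any further columns, e.g. weighted percentages, are ignored).
#'
#' @param path File path.
#' @param protein_id Identifier to record; defaults to the file name.
#' @return A [pssm()].
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D\\s+C\\s", lines)[1]
  if (is.na(hdr)) stop("not an ASCII PSSM: alphabet header line not found")
  body <- lines[(hdr + 1):length(lines)]
  body <- body[grepl("^\\s*\\d+\\s+[A-Z]", body)]
  if (length(body) == 0L) stop("ASCII PSSM has no residue rows")
  rows <- strsplit(trimws(body), "\\s+")
  seq_aa <- vapply(rows, `[`, character(1), 2)
  mat <- t(vapply(rows, function(r) as.numeric(r[3:22]), numeric(20)))
  pssm(protein_id, mat, sequence = seq_aa)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' @param x A [pssm()].
#' @param path Output path.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  seq_aa <- x$sequence %||% rep("X", nrow(x$matrix))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("         ", paste(sprintf("%3s", AA_ALPHABET),
                                         collapse = " "))), con)
  for (i in seq_len(nrow(x$matrix))) {
    writeLines(paste0(sprintf("%5d %s  ", i, seq_aa[i]),
                      paste(sprintf("%3d", round(x$matrix[i, ])),
                            collapse = " ")), con)
  }
  invisible(path)
}

#' Sliding-window features from a PSSM
#'
#' One feature vector per residue: the concatenated PSSM rows of the window
#' centered on the residue. Window slots falling outside the sequence are
#' filled by the padding scheme (zero vectors by default).
#'
#' @param x A [pssm()].
#' @param window_size Odd window width (default 21).
#' @param padding `"zero"` pads out-of-range slots with zero vectors.
#' @return Numeric matrix, `L` rows by `window_size * 20` columns.
#' @export
windows_from_pssm <- function(x, window_size = 21, padding = "zero") {
  stopifnot(inherits(x, "pssm"))
  if (window_size %% 2 != 1 || window_size < 1) {
    stop("window_size must be an odd positive integer")
  }
  padding <- match.arg(padding, "zero")
  L <- nrow(x$matrix)
  half <- (window_size - 1L) %/% 2L
  # pad the matrix once, then slice
  padded <- rbind(matrix(0, half, 20), x$matrix, matrix(0, half, 20))
  out <- matrix(0, L, window_size * 20L)
  for (j in seq_len(window_size)) {
    out[, ((j - 1L) * 20L + 1L):(j * 20L)] <- padded[(j):(j + L - 1L), ]
  }
  colnames(out) <- paste0("w", rep(seq_len(window_size) - half - 1L,
                                   each = 20), "_", rep(AA_ALPHABET,
                                                        window_size))
  out
}

#' Train the RBF-kernel SVM on window features
#'
#' Fits a C-SVM with the RBF kernel on PSSM-window features. Class
#' imbalance (interface residues are the minority class) is handled by
#' inverse-frequency class weights by default. Features are standardized
#' internally; the continuous decision value is mapped to `[0, 1]` by a
#' monotone sigmoid calibration fitted on the training data, so the
#' downstream combiner receives scores comparable to the homology stage.
#'
#' @param features Numeric feature matrix (rows = residues).
#' @param labels Binary 0/1 labels, both classes present.
#' @param cost,gamma RBF-SVM parameters (both > 0).
#' @param window_size Window width recorded in the model spec.
#' @param class_weighting `"inverse"` (default) or `"none"`.
#' @param tolerance Optimizer termination tolerance (default 0.001).
#' @param scale Standardize features before training (default `TRUE`).
#' @return An object of class `svm_model` wrapping the fitted classifier
#'   and its specification.
#' @export
train_svm <- function(features, labels, cost = 1,
                      gamma = 1 / ncol(features), window_size = NA_integer_,
                      class_weighting = c("inverse", "none"),
                      tolerance = 0.001, scale = TRUE) {
  class_weighting <- match.arg(class_weighting)
  stopifnot(cost > 0, gamma > 0)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("training set must contain both classes")
  }
  y <- factor(labels, levels = c(0, 1))
  cw <- if (class_weighting == "inverse") {
    tab <- table(y)
    stats::setNames(as.numeric(length(y) / (2 * tab)), names(tab))
  } else NULL
  fit <- e1071::svm(x = features, y = y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = cw, scale = scale,
                    tolerance = tolerance)
  pr <- stats::predict(fit, features, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  orient <- if (strsplit(colnames(dv)[1], "/")[[1]][1] == "1") 1 else -1
  dec <- orient * as.numeric(dv)
  # monotone sigmoid calibration of the margin, fitted on training data
  cal <- ridge_logistic(cbind(1, dec), as.numeric(labels), ridge = 1e-8)
  structure(list(fit = fit, orient = orient,
                 calibration = unname(cal$beta),
                 spec = list(cost = cost, gamma = gamma,
                             window_size = window_size,
                             class_weighting = class_weighting)),
            class = "svm_model")
}

#' Predict per-residue scores with a trained SVM
#'
#' @param model An [svm_model][train_svm()] object.
#' @param features Feature matrix built with the model's window size.
#' @return List with `score` (calibrated probability of the interface class,
#'   in `[0, 1]`), `decision` (raw margin), and `call` (0/1).
#' @export
predict_svm <- function(model, features) {
  stopifnot(inherits(model, "svm_model"))
  pr <- stats::predict(model$fit, features, decision.values = TRUE)
  # e1071 orients decision values by the first training class; flip so
  # larger always means more interface-like
  dec <- model$orient * as.numeric(attr(pr, "decision.values"))
  score <- stats::plogis(model$calibration[1] + model$calibration[2] * dec)
  list(score = unname(score), decision = dec,
       call = as.integer(as.character(pr)))
}

#' Sequence-based cross-validation folds
#'
#' Partitions protein chains (never individual residues) into `k` folds so
#' that every residue of a chain shares its chain's fold, preventing
#' within-chain train/test leakage. Reproducible from the seed.
#'
#' @param chain_ids Character vector of chain identifiers.
#' @param k Number of folds (>= 2, <= number of chains).
#' @param seed RNG seed.
#' @return Named integer vector mapping each chain to a fold in `1..k`.
#' @export
sequence_cv_folds <- function(chain_ids, k = 5, seed = 1) {
  n <- length(chain_ids)
  if (k < 2 || n < k) stop("need 2 <= k <= number of chains")
  folds <- with_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })
  stats::setNames(folds, chain_ids)
}

# Evaluate one (cost, gamma, window) spec by sequence-based k-fold CV on a
# chain dataset; returns the mean pooled validation criterion across folds.
cv_score_spec <- function(chains, cost, gamma, window_size, k, seed,
                          criterion = "mcc") {
  ids <- names(chains)
  folds <- sequence_cv_folds(ids, k = k, seed = seed)
  feats <- lapply(chains, function(ch) {
    windows_from_pssm(ch$pssm, window_size)
  })
  scores <- numeric(k)
  for (f in seq_len(k)) {
    tr <- ids[folds != f]
    va <- ids[folds == f]
    if (length(intersect(tr, va)) > 0) stop("chain overlap between folds")
    X <- do.call(rbind, feats[tr])
    y <- unlist(lapply(chains[tr], `[[`, "labels"), use.names = FALSE)
    m <- train_svm(X, y, cost = cost, gamma = gamma,
                   window_size = window_size)
    pred <- predict_svm(m, do.call(rbind, feats[va]))
    yv <- unlist(lapply(chains[va], `[[`, "labels"), use.names = FALSE)
    mm <- classification_metrics(confusion(pred$call, yv))
    scores[f] <- mm[[criterion]]
  }
  mean(scores)
}

#' Grid-search tuning of the PSSM-window SVM
#'
#' Implements the tuning protocol: chains are split into `n_parts` parts
#' (default 6); one part is a held-out test set never touched during
#' selection, the rest form the training+validation pool. Every
#' (cost, gamma, window) combination is scored by sequence-based `k`-fold
#' cross-validation on the pool, the best combination by the criterion
#' (default MCC) is retrained on the full pool, and the final model is
#' assessed once on the held-out part.
#'
#' @param chains Named list of per-chain records, each a list with elements
#'   `pssm` (a [pssm()]) and `labels` (binary vector).
#' @param cost_grid,gamma_grid,window_grid Non-empty parameter grids
#'   (windows odd).
#' @param k CV folds within the pool (default 5).
#' @param n_parts Chain split for the held-out protocol (default 6; one
#'   part held out).
#' @param seed RNG seed controlling both splits.
#' @param criterion Model-selection criterion (`"mcc"`).
#' @return List with `best_spec`, the selection `grid` (one row per
#'   combination with its CV score), the retrained `model`, the `heldout`
#'   chain ids and the final model's `heldout_metrics`.
#' @export
grid_search <- function(chains, cost_grid = 2^(-1:3),
                        gamma_grid = 2^(-7:-3), window_grid = c(15, 21, 27),
                        k = 5, n_parts = 6, seed = 1, criterion = "mcc") {
  stopifnot(length(cost_grid) > 0, length(gamma_grid) > 0,
            length(window_grid) > 0)
  if (any(window_grid %% 2 != 1)) stop("window sizes must be odd")
  ids <- names(chains)
  if (length(ids) < n_parts) {
    stop(sprintf("need at least %d chains for the %d-way split protocol",
                 n_parts, n_parts))
  }
  parts <- sequence_cv_folds(ids, k = n_parts, seed = seed)
  heldout <- ids[parts == n_parts]
  pool <- chains[ids[parts != n_parts]]

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      window = window_grid, KEEP.OUT.ATTRS = FALSE)
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    cv_score_spec(pool, grid$cost[i], grid$gamma[i], grid$window[i],
                  k = k, seed = seed + 1L, criterion = criterion)
  }, numeric(1))
  best <- grid[which.max(grid$score), ]

  Xp <- do.call(rbind, lapply(pool, function(ch) {
    windows_from_pssm(ch$pssm, best$window)
  }))
  yp <- unlist(lapply(pool, `[[`, "labels"), use.names = FALSE)
  model <- train_svm(Xp, yp, cost = best$cost, gamma = best$gamma,
                     window_size = best$window)

  heldout_metrics <- NULL
  if (length(heldout) > 0) {
    Xh <- do.call(rbind, lapply(chains[heldout], function(ch) {
      windows_from_pssm(ch$pssm, best$window)
    }))
    yh <- unlist(lapply(chains[heldout], `[[`, "labels"), use.names = FALSE)
    pred <- predict_svm(model, Xh)
    heldout_metrics <- classification_metrics(confusion(pred$call, yh))
  }
  list(best_spec = list(cost = best$cost, gamma = best$gamma,
                        window_size = best$window, cv_score = best$score),
       grid = grid, model = model, heldout = heldout,
       heldout_metrics = heldout_metrics)
}

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
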
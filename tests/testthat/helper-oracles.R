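# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# All-pairs distance scan: residue i is interface iff any of its atoms is
# within `cutoff` of any RNA atom (plain sqrt loop).
brute_force_interface <- function(chain, rna, cutoff = 5.0) {
  out <- rep(NA_integer_, length(chain$aa))
  for (i in seq_along(chain$aa)) {
    m <- chain$coords[[i]]
    if (nrow(m) == 0L) next
    hit <- FALSE
    for (a in seq_len(nrow(m))) {
      for (b in seq_len(nrow(rna$coords))) {
        d <- sqrt(sum((m[a, ] - rna$coords[b, ])^2))
        if (d <= cutoff) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    out[i] <- as.integer(hit)
  }
  out
}

# Pearson correlation from first principles.
brute_force_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# MCC from the 2x2 table of (prediction, truth), direct formula.
brute_force_mcc <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (den == 0) return(NA_real_)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

# AUC as the exhaustive pairwise Mann-Whitney count, ties = 1/2.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Naive window feature: index-by-index concatenation with explicit zero
# padding.
brute_force_window <- function(mat, center, window_size) {
  half <- (window_size - 1) / 2
  out <- numeric(0)
  for (off in -half:half) {
    i <- center + off
    row <- if (i >= 1 && i <= nrow(mat)) as.numeric(mat[i, ]) else rep(0, 20)
    out <- c(out, row)
  }
  out
}

# Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_chain <- function(chain, R, t) {
  coords <- lapply(chain$coords, function(m) {
    if (nrow(m) == 0L) m else sweep(m %*% t(R), 2, -t)
  })
  chain_structure(chain$chain_id, chain$aa, coords)
}

transform_rna <- function(rna, R, t) {
  rna_component(sweep(rna$coords %*% t(R), 2, -t), rna$nucleotide_count)
}

# Random chain/RNA coordinate sets for oracle-equivalence checks.
random_coordinate_complex <- function(n_res = 30, n_rna = 50,
                                      box = 30, max_atoms = 4) {
  coords <- lapply(seq_len(n_res), function(i) {
    matrix(runif(3 * sample(max_atoms, 1), 0, box), ncol = 3)
  })
  chain <- chain_structure("Z", sample(c("A", "G", "L", "K"), n_res,
                                       replace = TRUE), coords)
  rna <- rna_component(matrix(runif(3 * n_rna, 0, box), ncol = 3),
                       nucleotide_count = n_rna)
  list(chain = chain, rna = rna)
}
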
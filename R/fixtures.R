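# Deterministic synthetic-data generators: toy protein-RNA complexes with
# known interfaces, homolog databases with controlled interface
# conservation, and PSSMs with planted signal. Every generator is a pure
# function of its seed, so the full pipeline is testable without any
# external download. These fixtures target the statistical structure of
# real data (label correlation, class imbalance, profile signal), not
# realistic protein geometry or evolution.

#' Generate a toy protein-RNA complex with a known interface
#'
#' Residues are placed along a line with 8 Angstrom spacing (one CA-like
#' heavy atom each); for each residue chosen as interface, an RNA atom is
#' placed 3 Angstrom away in the perpendicular direction, so under the
#' 5 Angstrom heavy-atom rule the recovered interface set equals the
#' requested one exactly (the nearest non-target residue is
#' `sqrt(8^2 + 3^2) ~ 8.5` Angstrom from any RNA atom).
#'
#' @param chain_length Number of residues (>= 4).
#' @param interface_fraction Fraction of residues in the interface, in
#'   (0, 1); the realized count is `round(chain_length * fraction)` and
#'   must be >= 1.
#' @param unresolved_fraction Fraction of non-interface residues left
#'   unresolved (no atoms), default 0.
#' @param chain_id Chain identifier.
#' @param seed RNG seed.
#' @return List with `chain` (a [chain_structure()]), `rna` (an
#'   [rna_component()]), and `truth` (integer interface labels, `NA` at
#'   unresolved positions).
#' @export
make_complex <- function(chain_length, interface_fraction,
                         unresolved_fraction = 0, chain_id = "A",
                         seed = 1) {
  stopifnot(chain_length >= 4,
            interface_fraction > 0, interface_fraction < 1)
  n_if <- round(chain_length * interface_fraction)
  if (n_if < 1 || n_if >= chain_length) {
    stop("infeasible geometry: interface set would be empty or total")
  }
  with_seed(seed, {
    aa <- sample(AA_ALPHABET, chain_length, replace = TRUE)
    iface <- sort(sample(chain_length, n_if))
    non_iface <- setdiff(seq_len(chain_length), iface)
    n_unres <- round(length(non_iface) * unresolved_fraction)
    unres <- if (n_unres > 0) sort(sample(non_iface, n_unres)) else integer(0)
    coords <- lapply(seq_len(chain_length), function(i) {
      if (i %in% unres) matrix(numeric(0), ncol = 3)
      else matrix(c(8 * i, 0, 0), ncol = 3)
    })
    chain <- chain_structure(chain_id, aa, coords)
    rna <- rna_component(cbind(8 * iface, 3, 0),
                         nucleotide_count = length(iface))
    truth <- rep(0L, chain_length)
    truth[iface] <- 1L
    truth[unres] <- NA_integer_
    list(chain = chain, rna = rna, truth = truth)
  })
}

#' Write a toy complex as a PDB-format file
#'
#' Emits minimal ATOM records: the protein chain with one CA atom per
#' resolved residue and the RNA as adenosine phosphate atoms on a second
#' chain, in fixed-width PDB columns readable by standard parsers.
#'
#' @param complex A [make_complex()] result.
#' @param path Output path.
#' @param rna_chain Chain identifier for the RNA component.
#' @export
write_complex_pdb <- function(complex, path, rna_chain = "B") {
  ch <- complex$chain
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  aa3 <- bio3d::aa123(ch$aa)
  for (i in seq_along(ch$aa)) {
    m <- ch$coords[[i]]
    if (nrow(m) == 0L) next
    for (j in seq_len(nrow(m))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, aa3[i], ch$chain_id, i, m[j, 1], m[j, 2], m[j, 3]), con)
    }
  }
  rc <- complex$rna$coords
  for (j in seq_len(nrow(rc))) {
    serial <- serial + 1L
    writeLines(sprintf(
      "ATOM  %5d  P     A %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
      serial, rna_chain, j, rc[j, 1], rc[j, 2], rc[j, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

# Symmetric label-flip probability giving a target correlation with a
# Bernoulli(p) source, solved in closed form from
#   corr(f) = (1 - 2f) * sqrt(p(1-p)) / sqrt(q(1-q)),  q = p + f(1 - 2p).
flip_rate_for_ic <- function(target_ic, p) {
  if (p <= 0 || p >= 1) stop("query labels are constant; IC is undefined")
  if (abs(target_ic) >= 1) return(if (target_ic > 0) 0 else 1)
  if (target_ic == 0) return(0.5)
  g <- function(f) {
    q <- p + f * (1 - 2 * p)
    (1 - 2 * f) * sqrt(p * (1 - p)) / sqrt(q * (1 - q)) - target_ic
  }
  stats::uniroot(g, c(0, 1), tol = 1e-12)$root
}

#' Specification of one synthetic homolog
#'
#' @param id Homolog identifier.
#' @param target_ic Desired interface conservation (label correlation) with
#'   the query, in `[-1, 1]`.
#' @param target_pred_ic Predicted IC the emitted alignment statistics
#'   should produce under the default linear model (drives the homology
#'   zone); `NA` lets PS default to the realized label agreement.
#' @param e_value Alignment E-value to emit.
#' @param del_rate Fraction of query positions left unaligned (deletions).
#' @param ins_rate Expected insertions in the homolog per aligned column.
#' @return A plain list understood by [make_homolog_db()].
#' @export
homolog_spec <- function(id, target_ic, target_pred_ic = NA_real_,
                         e_value = 1e-30, del_rate = 0, ins_rate = 0) {
  list(id = id, target_ic = target_ic, target_pred_ic = target_pred_ic,
       e_value = e_value, del_rate = del_rate, ins_rate = ins_rate)
}

#' Generate a synthetic homolog database for a query
#'
#' For each [homolog_spec()], homolog interface labels are derived from the
#' query labels by independent symmetric flips at the closed-form rate that
#' yields the requested label correlation in expectation; indels are then
#' inserted so the position map stays correct. Emitted alignment statistics
#' are chosen so that, under the supplied IC model, the hit's predicted IC
#' lands exactly at `target_pred_ic`: PS is obtained by inverting the
#' linear model, and any remainder PS cannot express (it is kept below the
#' similarity-exclusion cutoff) is carried by the E-value term, raising
#' the hit's configurable E-value cap when the required E-value
#' underflows. When `dir` is given, the database is also written in the
#' pipeline's file formats (FASTA, labeled TSV, alignment TSV, index TSV).
#'
#' @param query_id Query identifier.
#' @param query_labels Binary interface labels of the query (`NA` allowed).
#' @param specs List of [homolog_spec()]s.
#' @param model,thresholds IC model and zone thresholds used to invert for
#'   PS.
#' @param dir Optional output directory.
#' @param seed RNG seed.
#' @return List with `hits` (list of [homolog_hit()]), `homolog_labels`
#'   (list of full-length label vectors), `sequences`, and `dir`.
#' @export
make_homolog_db <- function(query_id, query_labels, specs,
                            model = ic_model(),
                            thresholds = zone_thresholds(), dir = NULL,
                            seed = 1) {
  qlen <- length(query_labels)
  with_seed(seed, {
    hits <- list()
    all_labels <- list()
    seqs <- list()
    for (sp in specs) {
      aligned_q <- which(!is.na(query_labels))
      if (sp$del_rate > 0) {
        keep <- stats::runif(length(aligned_q)) >= sp$del_rate
        if (!any(keep)) keep[1] <- TRUE
        aligned_q <- aligned_q[keep]
      }
      f <- flip_rate_for_ic(sp$target_ic,
                            mean(query_labels[aligned_q] == 1L))
      flip <- stats::rbinom(length(aligned_q), 1, f) == 1
      hl_aln <- ifelse(flip, 1L - query_labels[aligned_q],
                       query_labels[aligned_q])
      # insertions: extra homolog residues between aligned columns
      n_ins <- stats::rpois(length(aligned_q), sp$ins_rate)
      hpos <- cumsum(1 + c(0, utils::head(n_ins, -1)))
      hlen <- hpos[length(hpos)] + n_ins[length(n_ins)]
      hlabels <- rep(0L, hlen)
      hlabels[hpos] <- hl_aln
      L <- length(aligned_q)
      e_value <- sp$e_value
      e_cap <- 200
      if (is.na(sp$target_pred_ic)) {
        ps <- mean(hl_aln == query_labels[aligned_q])
      } else {
        # invert the linear model for PS; when the target exceeds what PS
        # alone can reach (PS is held below the similarity-exclusion
        # cutoff so the hit survives selection), make up the remainder
        # through the -log10(E) term, raising the configurable E-value
        # cap when the required E underflows
        fixed <- model$intercept +
          model$coef_log_l * log(L, model$log_base) +
          model$coef_len_frac * min(L / min(qlen, hlen), 1)
        nle <- min(-log(max(e_value, 1e-200), model$log_base), e_cap)
        ps <- (sp$target_pred_ic - fixed -
                 model$coef_neg_log_e * nle) / model$coef_ps
        if (ps > 0.94 || ps < 0) {
          ps <- if (ps < 0) 0 else floor(0.94 * L) / L
          nle <- (sp$target_pred_ic - fixed -
                    model$coef_ps * ps) / model$coef_neg_log_e
        } else {
          # discretization of positives = round(ps * L) perturbs the
          # landed value by < coef_ps / (2 L); compensate via the E term
          ps_real <- round(ps * L) / L
          nle <- nle - model$coef_ps * (ps_real - ps) / model$coef_neg_log_e
          ps <- ps_real
        }
        if (nle > 300) {
          e_value <- 0
          e_cap <- nle
        } else {
          e_value <- model$log_base^(-nle)
          e_cap <- max(200, nle)
        }
      }
      positives <- max(0L, min(L, round(ps * L)))
      identities <- round(positives * 0.9)
      aln <- pairwise_alignment(query_id, sp$id, cbind(aligned_q, hpos),
                                e_value = e_value, length = L,
                                identities = identities,
                                positives = positives,
                                query_length = qlen, homolog_length = hlen)
      hits[[sp$id]] <- homolog_hit(aln, hlabels, model, thresholds,
                                   e_cap = e_cap)
      all_labels[[sp$id]] <- hlabels
      seqs[[sp$id]] <- sample(AA_ALPHABET, hlen, replace = TRUE)
    }
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      seqinr::write.fasta(seqs, names(seqs),
                          file.path(dir, "sequences.fasta"))
      labtabs <- lapply(names(all_labels), function(id) {
        data.frame(chain_id = id,
                   position = seq_along(all_labels[[id]]),
                   amino_acid = seqs[[id]],
                   label = ifelse(all_labels[[id]] == 1L, "interface",
                                  "non-interface"),
                   stringsAsFactors = FALSE)
      })
      write_labeled_table(do.call(rbind, labtabs),
                          file.path(dir, "labels.tsv"))
      write_alignment_table(lapply(hits, `[[`, "alignment"),
                            file.path(dir, "alignments.tsv"))
      idx <- data.frame(chain_id = names(all_labels),
                        length = vapply(all_labels, length, integer(1)),
                        n_interface = vapply(all_labels, sum, integer(1)),
                        stringsAsFactors = FALSE)
      utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(hits = unname(hits), homolog_labels = all_labels,
         sequences = seqs, dir = dir)
  })
}

# Fixed background distribution for synthetic PSSM log-odds: rounded
# Gaussian clipped to the integer range of the ASCII format.
rpssm_background <- function(n) {
  pmin(pmax(round(stats::rnorm(n, 0, 2)), -10), 12)
}

#' Generate a synthetic PSSM with planted interface signal
#'
#' Background cells are drawn from a fixed discrete distribution on
#' `[-10, 12]` (integers, matching the ASCII format's dialect); rows of
#' interface residues are shifted upward by `effect` on the signal columns
#' (clipped at 12). At `effect = 0` interface and non-interface rows are
#' identically distributed.
#'
#' @param labels Binary interface labels (length = sequence length).
#' @param signal_cols Column indices carrying the signal (default 1:3).
#' @param effect Mean shift on signal columns (>= 0, default 4).
#' @param offsets Window offsets (relative residue positions) at which the
#'   signal is planted; `0` plants it on the labeled residue itself.
#' @param protein_id Identifier.
#' @param seed RNG seed.
#' @return A [pssm()].
#' @export
make_pssm <- function(labels, signal_cols = 1:3, effect = 4, offsets = 0,
                      protein_id = "synthetic", seed = 1) {
  stopifnot(effect >= 0)
  L <- length(labels)
  with_seed(seed, {
    m <- matrix(rpssm_background(L * 20), L, 20)
    for (off in offsets) {
      rows <- which(labels == 1L) + off
      rows <- rows[rows >= 1 & rows <= L]
      m[rows, signal_cols] <- pmin(m[rows, signal_cols] + effect, 12)
    }
    seq_aa <- sample(AA_ALPHABET, L, replace = TRUE)
    pssm(protein_id, m, sequence = seq_aa)
  })
}

#' Generate a synthetic chain dataset for SVM experiments
#'
#' Builds `n_chains` chains with imbalanced interface labels and PSSMs
#' carrying planted signal, in the per-chain form [grid_search()] consumes.
#'
#' @param n_chains Number of chains.
#' @param chain_length Residues per chain.
#' @param interface_fraction Interface prevalence (default 0.15, the
#'   minority-class imbalance typical of RNA-binding chains).
#' @param signal_cols,effect,offsets Passed to [make_pssm()].
#' @param seed RNG seed.
#' @return Named list of per-chain records `list(pssm, labels)`.
#' @export
make_chain_dataset <- function(n_chains, chain_length,
                               interface_fraction = 0.15, signal_cols = 1:3,
                               effect = 4, offsets = 0, seed = 1) {
  with_seed(seed, {
    chain_seeds <- sample.int(1e6, n_chains)
  })
  out <- lapply(seq_len(n_chains), function(i) {
    labels <- with_seed(chain_seeds[i] + 1L, {
      stats::rbinom(chain_length, 1, interface_fraction)
    })
    if (sum(labels) == 0) labels[1] <- 1L
    list(pssm = make_pssm(labels, signal_cols, effect, offsets,
                          protein_id = sprintf("chain%03d", i),
                          seed = chain_seeds[i]),
         labels = labels)
  })
  stats::setNames(out, sprintf("chain%03d", seq_len(n_chains)))
}

#' Simulate score pairs from a known logistic model
#'
#' Draws homology/SVM score pairs and labels from
#' `logit(p) = bias + w_h h + w_s s`, with an optional fraction of missing
#' homology scores -- the combiner's parameter-recovery testbed.
#'
#' @param n Number of residues.
#' @param bias,weight_homprip,weight_svm True model parameters.
#' @param missing_fraction Fraction of homology scores set to `NA`.
#' @param seed RNG seed.
#' @return Data frame with columns `homprip`, `svm`, `label`.
#' @export
make_score_data <- function(n, bias = -2, weight_homprip = 3,
                            weight_svm = 2, missing_fraction = 0,
                            seed = 1) {
  with_seed(seed, {
    h <- stats::runif(n)
    s <- stats::runif(n)
    p <- stats::plogis(bias + weight_homprip * h + weight_svm * s)
    y <- stats::rbinom(n, 1, p)
    if (missing_fraction > 0) {
      h[sample.int(n, round(n * missing_fraction))] <- NA_real_
    }
    data.frame(homprip = h, svm = s, label = y)
  })
}
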
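# Structure handling: protein chains, bound RNA, interface labeling by the
# heavy-atom distance rule, and dataset curation filters.

#' Construct a protein chain structure
#'
#' A chain is an ordered list of residues, each with a one-letter amino acid
#' code and the 3-D coordinates of its heavy (non-hydrogen) atoms. Residues
#' absent from the solved structure are represented with zero atoms and
#' `resolved = FALSE`. Residue positions are sequential 1-based indices;
#' author numbering from a coordinate file is kept as metadata only.
#'
#' @param chain_id Chain identifier string.
#' @param aa Character vector of one-letter amino acid codes (or `"X"`).
#' @param coords List (one element per residue) of numeric matrices with 3
#'   columns (x, y, z in Angstrom); a 0-row matrix marks an unresolved
#'   residue.
#' @param author_numbering Optional integer vector of author residue numbers
#'   (metadata only, not used for indexing).
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, aa, coords, author_numbering = NULL) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  aa <- toupper(as.character(aa))
  if (!all(aa %in% c(AA_ALPHABET, "X"))) {
    stop("amino acid codes must be one-letter codes or 'X'")
  }
  if (length(coords) != length(aa)) {
    stop("coords must have one entry per residue")
  }
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (nrow(m) > 0 && ncol(m) != 3) stop("coordinates must have 3 columns")
    if (nrow(m) > 0 && !all(is.finite(m))) stop("coordinates must be finite")
    storage.mode(m) <- "double"
    m
  })
  resolved <- vapply(coords, nrow, integer(1)) > 0L
  structure(
    list(chain_id = chain_id, aa = aa, coords = coords, resolved = resolved,
         author_numbering = author_numbering),
    class = "chain_structure"
  )
}

#' @export
length.chain_structure <- function(x) length(x$aa)

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("chain_structure '%s': %d residues (%d resolved)\n",
              x$chain_id, length(x), sum(x$resolved)))
  invisible(x)
}

#' Construct an RNA component
#'
#' Holds all atom coordinates of the RNA bound in a protein-RNA complex.
#'
#' @param coords Numeric matrix with 3 columns (x, y, z in Angstrom); may
#'   have zero rows.
#' @param nucleotide_count Number of nucleotides (>= 0).
#' @return An object of class `rna_component`.
#' @export
rna_component <- function(coords, nucleotide_count = NA_integer_) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 3)
  if (ncol(coords) != 3) stop("coordinates must have 3 columns")
  if (nrow(coords) > 0 && !all(is.finite(coords))) {
    stop("coordinates must be finite")
  }
  if (!is.na(nucleotide_count) && nucleotide_count < 0) {
    stop("nucleotide_count must be >= 0")
  }
  storage.mode(coords) <- "double"
  structure(list(coords = coords, nucleotide_count = nucleotide_count),
            class = "rna_component")
}

#' Label interface residues by the heavy-atom distance rule
#'
#' A residue is an interface residue if at least one of its heavy atoms lies
#' within `cutoff` Angstrom (inclusive) of any atom of the bound RNA.
#' Unresolved residues cannot be assessed; the `convention` argument controls
#' whether they are labeled non-interface (the training-set convention) or
#' left `NA` so downstream analyses can exclude them.
#'
#' @param chain A [chain_structure()].
#' @param rna An [rna_component()].
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @param convention `"unresolved-negative"` labels unresolved residues 0;
#'   `"exclude-unresolved"` leaves them `NA`.
#' @return An object of class `interface_labeling` with integer `labels`
#'   (1 = interface, 0 = non-interface, `NA` = unresolved/excluded) and the
#'   `resolved` mask.
#' @export
label_interface <- function(chain, rna, cutoff = 5.0,
                            convention = c("unresolved-negative",
                                           "exclude-unresolved")) {
  convention <- match.arg(convention)
  stopifnot(inherits(chain, "chain_structure"), inherits(rna, "rna_component"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a positive number")
  }
  if (!any(chain$resolved)) stop("empty structure: chain has no resolved residues")

  n <- length(chain)
  labels <- rep(NA_integer_, n)
  if (nrow(rna$coords) == 0L) {
    labels[chain$resolved] <- 0L
  } else {
    d2max <- cutoff^2
    for (i in which(chain$resolved)) {
      labels[i] <- as.integer(
        min_sqdist(chain$coords[[i]], rna$coords) <= d2max)
    }
  }
  if (convention == "unresolved-negative") labels[!chain$resolved] <- 0L
  structure(
    list(chain_id = chain$chain_id, labels = labels,
         resolved = chain$resolved, convention = convention,
         cutoff = cutoff),
    class = "interface_labeling"
  )
}

# Minimum squared distance between two point sets (rows of 3-col matrices).
min_sqdist <- function(a, b) {
  # cross-term expansion; both sets are small per residue so this is cheap
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  max(min(d2), 0)
}

#' @export
print.interface_labeling <- function(x, ...) {
  cat(sprintf(
    "interface_labeling '%s': %d residues, %d interface, %d unresolved\n",
    x$chain_id, length(x$labels), sum(x$labels == 1L, na.rm = TRUE),
    sum(!x$resolved)))
  invisible(x)
}

#' Apply dataset curation filters to a labeled chain
#'
#' Implements the chain-level inclusion rules used when building
#' non-redundant benchmark sets of RNA-binding protein chains: a minimum
#' number of interface residues, a minimum chain length, and -- when the
#' metadata are available -- an X-ray-only requirement, a resolution ceiling,
#' and exclusion of CA-only entries. Redundancy reduction itself is out of
#' scope; a precomputed non-redundant chain list is expected upstream.
#'
#' @param chain A [chain_structure()].
#' @param labeling The matching [label_interface()] result.
#' @param min_interface Minimum interface residue count (default 5).
#' @param min_length Minimum chain length in residues (default 40).
#' @param max_resolution Resolution ceiling in Angstrom (default 3.5).
#' @param resolution Optional structure resolution; `NA` skips the rule.
#' @param experiment Optional experiment type string (e.g. `"X-RAY"`);
#'   `NA` skips the rule.
#' @param ca_only Optional logical, `TRUE` for CA-only entries; `NA` skips.
#' @return List with `accept` (logical) and `reason` (`NA` or the name of
#'   the first failed rule: `"min_interface"`, `"min_length"`,
#'   `"resolution"`, `"non_xray"`, `"ca_only"`).
#' @export
apply_curation_filters <- function(chain, labeling,
                                   min_interface = 5L, min_length = 40L,
                                   max_resolution = 3.5,
                                   resolution = NA_real_,
                                   experiment = NA_character_,
                                   ca_only = NA) {
  stopifnot(inherits(chain, "chain_structure"),
            inherits(labeling, "interface_labeling"))
  if (length(labeling$labels) != length(chain)) {
    stop("labeling does not correspond to chain")
  }
  reject <- function(reason) list(accept = FALSE, reason = reason)

  if (is.na(experiment)) {
    warning("experiment type unavailable; X-ray rule skipped")
  } else if (!grepl("x-?ray", experiment, ignore.case = TRUE)) {
    return(reject("non_xray"))
  }
  if (is.na(ca_only)) {
    warning("CA-only flag unavailable; rule skipped")
  } else if (isTRUE(ca_only)) {
    return(reject("ca_only"))
  }
  if (is.na(resolution)) {
    warning("resolution unavailable; rule skipped")
  } else if (resolution > max_resolution) {
    return(reject("resolution"))
  }
  if (length(chain) < min_length) return(reject("min_length"))
  if (sum(labeling$labels == 1L, na.rm = TRUE) < min_interface) {
    return(reject("min_interface"))
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Convert a labeling to a per-residue table
#'
#' @param chain A [chain_structure()].
#' @param labeling The matching [label_interface()] result.
#' @return Data frame with columns `chain_id`, `position`, `amino_acid`,
#'   `label` (`"interface"`, `"non-interface"` or `"unresolved"`).
#' @export
labeling_table <- function(chain, labeling) {
  stopifnot(length(labeling$labels) == length(chain))
  lab <- ifelse(is.na(labeling$labels), "unresolved",
                ifelse(labeling$labels == 1L, "interface", "non-interface"))
  lab[!labeling$resolved & labeling$convention == "unresolved-negative"] <-
    "unresolved"
  data.frame(chain_id = chain$chain_id, position = seq_along(chain$aa),
             amino_acid = chain$aa, label = lab,
             stringsAsFactors = FALSE)
}

#' Write / read the labeled-sequence table (TSV)
#'
#' @param tab Data frame as produced by [labeling_table()] (possibly rbind-ed
#'   over chains).
#' @param path Output file path.
#' @export
write_labeled_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeled_table
#' @export
read_labeled_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "character"),
                    stringsAsFactors = FALSE)
}

#' Labels as a binary vector from a labeled table
#'
#' @param tab A labeled-sequence table restricted to one chain.
#' @return Integer vector (1 interface, 0 non-interface, NA unresolved)
#'   ordered by position.
#' @export
labels_from_table <- function(tab) {
  tab <- tab[order(tab$position), , drop = FALSE]
  out <- ifelse(tab$label == "interface", 1L,
                ifelse(tab$label == "non-interface", 0L, NA_integer_))
  names(out) <- tab$position
  out
}

# 20-letter amino acid alphabet in PSI-BLAST PSSM column order.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read one protein chain from a PDB file
#'
#' Uses heavy atoms only (hydrogens discarded); alternate locations are
#' resolved by keeping the highest-occupancy conformer of each atom.
#' Residue order follows the order of appearance in the file; positions are
#' renumbered 1..L with author numbering retained as metadata.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier to extract.
#' @return A [chain_structure()].
#' @export
read_chain_pdb <- function(path, chain) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  sel <- at$type == "ATOM" & at$chain == chain & !is_hydrogen(at)
  at <- at[sel, , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("no protein atoms for chain '%s'", chain))
  at <- drop_altloc(at)
  key <- paste(at$resno, at$insert %||% "", sep = "_")
  res_keys <- unique(key)
  aa <- vapply(res_keys, function(k) {
    bio3d::aa321(at$resid[key == k][1])
  }, character(1))
  aa[is.na(aa) | !(aa %in% AA_ALPHABET)] <- "X"
  coords <- lapply(res_keys, function(k) {
    idx <- key == k
    cbind(at$x[idx], at$y[idx], at$z[idx])
  })
  chain_structure(chain, unname(aa), coords,
                  author_numbering = at$resno[match(res_keys, key)])
}

#' Read the RNA component of a complex from a PDB file
#'
#' Collects every atom of ribonucleotide residues (resid A, U, G, C and
#' their modified one/two-letter variants are not resolved; only standard
#' ribonucleotides are recognized), optionally restricted to given chains.
#'
#' @param path Path to a PDB-format file.
#' @param chains Optional chain identifiers to restrict to.
#' @return An [rna_component()].
#' @export
read_rna_pdb <- function(path, chains = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  sel <- trimws(at$resid) %in% c("A", "U", "G", "C")
  if (!is.null(chains)) sel <- sel & at$chain %in% chains
  at <- at[sel, , drop = FALSE]
  at <- if (nrow(at)) drop_altloc(at) else at
  nres <- length(unique(paste(at$chain, at$resno)))
  rna_component(cbind(at$x, at$y, at$z), nucleotide_count = nres)
}

is_hydrogen <- function(at) {
  elesy <- at$elesy
  if (!is.null(elesy) && any(nzchar(trimws(elesy)))) {
    trimws(elesy) %in% c("H", "D")
  } else {
    grepl("^[0-9]*H", trimws(at$elety))
  }
}

# Keep the highest-occupancy altloc conformer of each atom (ties: first).
drop_altloc <- function(at) {
  alt <- trimws(at$alt)
  if (all(alt == "" | is.na(alt))) return(at)
  atom_key <- paste(at$chain, at$resno, at$insert %||% "", at$elety)
  o <- order(atom_key, -at$o)
  at <- at[o, , drop = FALSE]
  at[!duplicated(paste(at$chain, at$resno, at$insert %||% "", at$elety)), ,
     drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
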
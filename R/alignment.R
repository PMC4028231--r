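# Pairwise local alignments, the six alignment statistics, and the
# interface-conservation (IC) score between a query and a labeled homolog.

#' Construct a pairwise local alignment record
#'
#' Represents one local alignment (HSP) between a query protein and a
#' homolog, together with the BLAST summary statistics needed downstream.
#' The position map lists aligned residue pairs only; gap columns are absent.
#'
#' @param query_id,homolog_id Sequence identifiers.
#' @param position_map Two-column integer matrix (query_pos, homolog_pos),
#'   1-based, strictly increasing in both columns. May have zero rows when
#'   only summary statistics are available (e.g. plain tabular BLAST output).
#' @param e_value Alignment E-value (>= 0).
#' @param length Local alignment length L (>= 1), counting gap columns.
#' @param identities Number of identical aligned columns.
#' @param positives Number of positively scoring aligned columns.
#' @param query_length,homolog_length Full sequence lengths.
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(query_id, homolog_id, position_map,
                               e_value, length, identities, positives,
                               query_length, homolog_length) {
  position_map <- as.matrix(position_map)
  if (base::length(position_map) == 0L) {
    position_map <- matrix(integer(0), ncol = 2)
  }
  if (ncol(position_map) != 2) stop("position_map must have two columns")
  storage.mode(position_map) <- "integer"
  colnames(position_map) <- c("query_pos", "homolog_pos")
  if (nrow(position_map) > 1) {
    if (any(diff(position_map[, 1]) <= 0) || any(diff(position_map[, 2]) <= 0)) {
      stop("position_map must be strictly increasing in both coordinates")
    }
  }
  if (nrow(position_map) > 0) {
    if (max(position_map[, 1]) > query_length || min(position_map[, 1]) < 1 ||
        max(position_map[, 2]) > homolog_length || min(position_map[, 2]) < 1) {
      stop("position_map outside sequence bounds")
    }
  }
  if (e_value < 0) stop("e_value must be >= 0")
  if (length < 1) stop("alignment length must be >= 1")
  if (!(identities <= positives && positives <= length)) {
    stop("require identities <= positives <= alignment length")
  }
  structure(
    list(query_id = query_id, homolog_id = homolog_id,
         position_map = position_map, e_value = e_value,
         length = as.integer(length), identities = as.integer(identities),
         positives = as.integer(positives),
         query_length = as.integer(query_length),
         homolog_length = as.integer(homolog_length)),
    class = "pairwise_alignment"
  )
}

#' Compute the six alignment statistics of a query/homolog alignment
#'
#' The statistics characterizing alignment quality are: positive score
#' `PS = positives / L`, identity score `IS = identities / L`,
#' `-log10(E-value)` (capped for E = 0 underflow), `log10(L)`, and the two
#' length fractions `L / LQ` and `L / LH` measuring how much of each
#' sequence the local alignment covers (capped at 1).
#'
#' @param aln A [pairwise_alignment()].
#' @param e_cap Value substituted for `-log10(E)` when `E = 0` (default 200).
#' @param log_base Base for both logarithms (default 10).
#' @return One-row data frame with columns `ps`, `is`, `neg_log_e`, `log_l`,
#'   `frac_q`, `frac_h`.
#' @export
compute_alignment_stats <- function(aln, e_cap = 200, log_base = 10) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  L <- aln$length
  nle <- if (aln$e_value == 0) e_cap else -log(aln$e_value, base = log_base)
  nle <- min(nle, e_cap)
  fq <- L / aln$query_length
  fh <- L / aln$homolog_length
  if (fq > 1 || fh > 1) {
    warning("local alignment longer than sequence; length fraction capped at 1")
    fq <- min(fq, 1)
    fh <- min(fh, 1)
  }
  data.frame(ps = aln$positives / L, is = aln$identities / L,
             neg_log_e = nle, log_l = log(L, base = log_base),
             frac_q = fq, frac_h = fh)
}

#' Interface-conservation score of two aligned label vectors
#'
#' The IC score is the correlation coefficient between the binary interface
#' labels of the query and of the homolog over aligned columns -- equivalently
#' the Matthews correlation of the 2x2 contingency table obtained by treating
#' the homolog labels as predictions of the query labels. IC = 1 means the
#' interface is perfectly conserved across the alignment, IC = -1 perfectly
#' anti-conserved. Columns where either residue is unresolved (label `NA`)
#' are excluded before computing the score.
#'
#' @param query_labels,homolog_labels Equal-length binary (0/1, `NA` allowed)
#'   label vectors over the aligned columns.
#' @return The IC score in `[-1, 1]`. When either masked vector is constant
#'   the correlation is undefined; 0 is returned with attribute
#'   `degenerate = TRUE`.
#' @export
ic_score <- function(query_labels, homolog_labels) {
  if (length(query_labels) != length(homolog_labels)) {
    stop("label vectors must have equal length")
  }
  keep <- !is.na(query_labels) & !is.na(homolog_labels)
  x <- as.numeric(query_labels[keep])
  y <- as.numeric(homolog_labels[keep])
  if (length(x) == 0L) stop("no comparable columns after masking unresolved")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("labels must be binary")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(x, y), degenerate = FALSE)
}

#' Aligned label vectors of a query/homolog pair
#'
#' Projects per-residue labels of the query and the homolog onto the aligned
#' columns of a pairwise alignment.
#'
#' @param aln A [pairwise_alignment()] with a non-empty position map.
#' @param query_labels Per-residue labels of the full query sequence.
#' @param homolog_labels Per-residue labels of the full homolog sequence.
#' @return List with components `query` and `homolog`, one label per aligned
#'   column.
#' @export
aligned_labels <- function(aln, query_labels, homolog_labels) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (nrow(aln$position_map) == 0L) stop("alignment has no position map")
  list(query = query_labels[aln$position_map[, 1]],
       homolog = homolog_labels[aln$position_map[, 2]])
}

# --- alignment table (TSV) serialization --------------------------------

# The position map is serialized as "q1:h1,q2:h2,..." so alignments survive
# a plain-text round trip without external tools.
encode_map <- function(m) {
  if (nrow(m) == 0L) return("")
  paste(paste(m[, 1], m[, 2], sep = ":"), collapse = ",")
}

decode_map <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(integer(0), ncol = 2))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("query_pos", "homolog_pos")
  m
}

#' Write / read an alignment table (TSV)
#'
#' The internal alignment table carries one row per HSP with the BLAST
#' summary statistics and an explicit encoded position map, so the pipeline
#' can run on precomputed alignments without a BLAST installation.
#'
#' @param alns List of [pairwise_alignment()] objects.
#' @param path File path.
#' @export
write_alignment_table <- function(alns, path) {
  rows <- lapply(alns, function(a) {
    data.frame(query_id = a$query_id, homolog_id = a$homolog_id,
               e_value = a$e_value, length = a$length,
               identities = a$identities, positives = a$positives,
               query_length = a$query_length,
               homolog_length = a$homolog_length,
               map = encode_map(a$position_map),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_table
#' @export
read_alignment_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(query_id = "character",
                                          homolog_id = "character",
                                          map = "character"))
  if (is.null(tab$map)) tab$map <- ""
  tab$map[is.na(tab$map)] <- ""
  lapply(seq_len(nrow(tab)), function(i) {
    pairwise_alignment(tab$query_id[i], tab$homolog_id[i],
                       decode_map(tab$map[i]), tab$e_value[i], tab$length[i],
                       tab$identities[i], tab$positives[i],
                       tab$query_length[i], tab$homolog_length[i])
  })
}

#' Read BLAST tabular output
#'
#' Expects `-outfmt "6 qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore ppos qlen slen"` (the default 12 columns
#' extended with positives percentage and sequence lengths). Tabular output
#' carries no per-column trace, so a position map is reconstructed only for
#' gapless HSPs (where `qend - qstart == send - sstart == length - 1`);
#' otherwise the map is left empty and only summary statistics are usable.
#'
#' @param path Path to the tabular file.
#' @return List of [pairwise_alignment()] objects.
#' @export
read_blast_tabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "ppos", "qlen", "slen")
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != length(cols)) {
    stop(sprintf("expected %d columns (extended outfmt 6), got %d",
                 length(cols), ncol(tab)))
  }
  names(tab) <- cols
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    gapless <- (r$qend - r$qstart == r$length - 1) &&
      (r$send - r$sstart == r$length - 1)
    pm <- if (gapless) {
      cbind(seq(r$qstart, r$qend), seq(r$sstart, r$send))
    } else {
      matrix(integer(0), ncol = 2)
    }
    pairwise_alignment(r$qseqid, r$sseqid, pm, r$evalue, r$length,
                       identities = round(r$pident / 100 * r$length),
                       positives = round(r$ppos / 100 * r$length),
                       query_length = r$qlen, homolog_length = r$slen)
  })
}

#' Read BLAST XML output
#'
#' Parses `-outfmt 5` XML, building exact position maps from the aligned
#' sequence strings (`Hsp_qseq` / `Hsp_hseq`). Requires the `xml2` package.
#'
#' @param path Path to a BLAST XML file.
#' @param query_length Optional named integer vector of query lengths; when
#'   absent, `Iteration_query-len` is used.
#' @return List of [pairwise_alignment()] objects, one per HSP.
#' @export
read_blast_xml <- function(path, query_length = NULL) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("read_blast_xml requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  out <- list()
  for (it in xml2::xml_find_all(doc, ".//Iteration")) {
    qid <- xml2::xml_text(xml2::xml_find_first(it, "./Iteration_query-def"))
    qid <- strsplit(qid, " ")[[1]][1]
    qlen <- as.integer(
      xml2::xml_text(xml2::xml_find_first(it, "./Iteration_query-len")))
    if (!is.null(query_length) && qid %in% names(query_length)) {
      qlen <- query_length[[qid]]
    }
    for (hit in xml2::xml_find_all(it, ".//Hit")) {
      hid <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_def"))
      hid <- strsplit(hid, " ")[[1]][1]
      hlen <- as.integer(xml2::xml_text(xml2::xml_find_first(hit, "./Hit_len")))
      for (hsp in xml2::xml_find_all(hit, ".//Hsp")) {
        g <- function(tag) xml2::xml_text(xml2::xml_find_first(hsp, tag))
        qseq <- g("./Hsp_qseq"); hseq <- g("./Hsp_hseq")
        pm <- map_from_aligned_strings(qseq, hseq,
                                       as.integer(g("./Hsp_query-from")),
                                       as.integer(g("./Hsp_hit-from")))
        out[[length(out) + 1L]] <- pairwise_alignment(
          qid, hid, pm,
          e_value = as.numeric(g("./Hsp_evalue")),
          length = as.integer(g("./Hsp_align-len")),
          identities = as.integer(g("./Hsp_identity")),
          positives = as.integer(g("./Hsp_positive")),
          query_length = qlen, homolog_length = hlen)
      }
    }
  }
  out
}

# Position map from gapped aligned strings and 1-based start offsets.
map_from_aligned_strings <- function(qseq, hseq, qstart, hstart) {
  qc <- strsplit(qseq, "")[[1]]
  hc <- strsplit(hseq, "")[[1]]
  qpos <- qstart - 1 + cumsum(qc != "-")
  hpos <- hstart - 1 + cumsum(hc != "-")
  keep <- qc != "-" & hc != "-"
  cbind(qpos[keep], hpos[keep])
}
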
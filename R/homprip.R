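# Homology-based interface prediction: zone-stratified homolog selection
# and IC-weighted nearest-neighbor transfer of interface labels.

#' Construct an annotated homolog hit
#'
#' Bundles one query/homolog alignment with its alignment statistics, the
#' predicted IC score (used as the hit's voting weight), the homology zone,
#' and the homolog's known per-residue interface labels.
#'
#' @param alignment A [pairwise_alignment()] with a non-empty position map.
#' @param homolog_labels Binary (0/1, `NA` for unresolved) interface labels
#'   for the full homolog sequence.
#' @param model An [ic_model()] used to weight the hit.
#' @param thresholds A [zone_thresholds()].
#' @param e_cap,log_base Passed to [compute_alignment_stats()].
#' @return An object of class `homolog_hit` with elements `alignment`,
#'   `stats`, `predicted_ic`, `zone`, `homolog_labels`.
#' @export
homolog_hit <- function(alignment, homolog_labels, model = ic_model(),
                        thresholds = zone_thresholds(), e_cap = 200,
                        log_base = 10) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  if (length(homolog_labels) != alignment$homolog_length) {
    stop("homolog_labels length must equal homolog_length")
  }
  stats <- compute_alignment_stats(alignment, e_cap = e_cap,
                                   log_base = log_base)
  w <- predict_ic(stats, model)
  structure(
    list(alignment = alignment, stats = stats, predicted_ic = w,
         zone = assign_zone(w, thresholds),
         homolog_labels = as.integer(homolog_labels)),
    class = "homolog_hit"
  )
}

#' Select homologs for label transfer
#'
#' Applies the self-hit exclusion and the hierarchical zone policy. Hits
#' more similar to the query than `similarity_exclusion` (default: positive
#' score > 0.95, i.e. >95% sequence similarity over the local alignment) are
#' discarded first, which keeps the query itself from serving as its own
#' homolog. Then, if any Safe Zone hits remain they are used exclusively;
#' otherwise all Twilight Zone hits; otherwise all Dark Zone hits; otherwise
#' the query goes unpredicted. When a query/homolog pair has several HSPs,
#' only the one with the highest predicted IC is kept (ties: lower E-value,
#' then first occurrence).
#'
#' @param hits List of [homolog_hit()] objects.
#' @param similarity_exclusion Similarity ceiling in `(0, 1]` (default 0.95).
#' @param similarity_measure `"positives"` (default) compares the positive
#'   score; `"identity"` compares the identity score.
#' @return List with `hits` (the selected homologs, possibly empty) and
#'   `zone_used` (`"Safe"`, `"Twilight"`, `"Dark"` or `"None"`).
#' @export
select_homologs <- function(hits, similarity_exclusion = 0.95,
                            similarity_measure = c("positives", "identity")) {
  similarity_measure <- match.arg(similarity_measure)
  stopifnot(similarity_exclusion > 0, similarity_exclusion <= 1)
  if (length(hits) == 0L) return(list(hits = list(), zone_used = "None"))

  sim <- vapply(hits, function(h) {
    if (similarity_measure == "positives") h$stats$ps else h$stats$is
  }, numeric(1))
  hits <- hits[sim <= similarity_exclusion]
  hits <- dedupe_hsps(hits)

  zones <- vapply(hits, function(h) as.character(h$zone), character(1))
  for (z in c("Safe", "Twilight", "Dark")) {
    if (any(zones == z)) {
      return(list(hits = hits[zones == z], zone_used = z))
    }
  }
  list(hits = list(), zone_used = "None")
}

# One HSP per homolog: highest predicted IC, ties by lower E-value, then
# first occurrence.
dedupe_hsps <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  ids <- vapply(hits, function(h) h$alignment$homolog_id, character(1))
  w <- vapply(hits, function(h) h$predicted_ic, numeric(1))
  ev <- vapply(hits, function(h) h$alignment$e_value, numeric(1))
  ord <- order(ids, -w, ev, seq_along(hits))
  keep <- ord[!duplicated(ids[ord])]
  hits[sort(keep)]
}

#' Weighted nearest-neighbor vote over homolog interface labels
#'
#' For each query position aligned in at least one selected homolog, the
#' prediction score is the predicted-IC-weighted mean of the homolog votes:
#' `P_i = sum_k w_k v_ik / sum_k w_k`, where `v_ik = 1` iff the residue
#' aligned to position `i` in homolog `k` is an interface residue, and the
#' sums run over the homologs aligned at position `i` (positions a homolog
#' does not cover do not dilute its neighbors' votes). Positions aligned in
#' no homolog, or aligned only to unresolved homolog residues, are `NA`.
#'
#' @param query_length Length of the query sequence.
#' @param hits List of selected [homolog_hit()] objects.
#' @return Numeric vector of length `query_length` with scores in `[0, 1]`
#'   or `NA` where no prediction is possible.
#' @export
weighted_vote <- function(query_length, hits) {
  if (length(hits) == 0L) stop("no homologs to vote")
  num <- numeric(query_length)
  den <- numeric(query_length)
  any_weight <- rep(FALSE, query_length)
  for (h in hits) {
    pm <- h$alignment$position_map
    if (nrow(pm) == 0L) next
    v <- h$homolog_labels[pm[, 2]]
    ok <- !is.na(v)
    qp <- pm[ok, 1]
    w <- h$predicted_ic
    num[qp] <- num[qp] + w * v[ok]
    den[qp] <- den[qp] + w
    any_weight[qp] <- TRUE
  }
  p <- rep(NA_real_, query_length)
  usable <- any_weight & den > 0
  if (any(any_weight & den <= 0)) {
    warning("non-positive total weight at some aligned positions; left NA")
  }
  p[usable] <- num[usable] / den[usable]
  p
}

#' Binarize homology prediction scores
#'
#' @param p Scores in `[0, 1]` (`NA` propagates).
#' @param threshold Call threshold (default 0.5); scores exactly at the
#'   threshold are called interface.
#' @return Integer vector of 0/1 calls with `NA` preserved.
#' @export
binarize_scores <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  as.integer(p >= threshold)
}

#' Homology-based interface prediction for one query
#'
#' Runs the full homology stage: annotate hits with predicted IC and zones,
#' apply similarity exclusion and the hierarchical zone policy, take the
#' weighted vote, and binarize.
#'
#' @param query_length Length of the query sequence.
#' @param hits List of [homolog_hit()] objects (all HSPs retrieved for the
#'   query).
#' @param similarity_exclusion,similarity_measure Passed to
#'   [select_homologs()].
#' @param threshold Binarization threshold (default 0.5).
#' @return List of class `homprip_result`: `score` (per-residue, `NA` where
#'   unpredicted), `call` (0/1/`NA`), `zone_used`, `homologs_used`.
#' @export
homology_predict <- function(query_length, hits, similarity_exclusion = 0.95,
                             similarity_measure = "positives",
                             threshold = 0.5) {
  sel <- select_homologs(hits, similarity_exclusion, similarity_measure)
  if (length(sel$hits) == 0L) {
    score <- rep(NA_real_, query_length)
  } else {
    score <- weighted_vote(query_length, sel$hits)
  }
  structure(
    list(score = score, call = binarize_scores(score, threshold),
         zone_used = sel$zone_used, homologs_used = sel$hits),
    class = "homprip_result"
  )
}

#' Homolog report table
#'
#' One row per considered hit with its E-value, positive score, predicted
#' IC and zone -- the report accompanying the per-residue predictions.
#'
#' @param hits List of [homolog_hit()] objects.
#' @return Data frame with columns `homolog_id`, `e_value`, `ps`,
#'   `predicted_ic`, `zone`.
#' @export
homolog_report <- function(hits) {
  if (length(hits) == 0L) {
    return(data.frame(homolog_id = character(0), e_value = numeric(0),
                      ps = numeric(0), predicted_ic = numeric(0),
                      zone = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    homolog_id = vapply(hits, function(h) h$alignment$homolog_id, character(1)),
    e_value = vapply(hits, function(h) h$alignment$e_value, numeric(1)),
    ps = vapply(hits, function(h) h$stats$ps, numeric(1)),
    predicted_ic = vapply(hits, function(h) h$predicted_ic, numeric(1)),
    zone = vapply(hits, function(h) as.character(h$zone), character(1)),
    stringsAsFactors = FALSE)
}
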
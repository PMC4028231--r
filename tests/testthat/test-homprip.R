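# Homology-based interface transfer: selection, voting, binarization.

# Convenience: one synthetic hit with an exact predicted IC.
one_hit <- function(query_labels, target_pred_ic, target_ic = 1, id = "h1",
                    seed = 1, del_rate = 0) {
  make_homolog_db("q", query_labels, list(
    homolog_spec(id, target_ic = target_ic,
                 target_pred_ic = target_pred_ic, del_rate = del_rate)),
    seed = seed)$hits[[1]]
}

qlab <- c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 1L, 0L)

test_that("hierarchical zone policy returns only the best non-empty zone", {
  safe <- one_hit(qlab, 0.8, id = "s1")
  twi <- one_hit(qlab, 0.5, id = "t1", seed = 2)
  dark <- one_hit(qlab, 0.17, id = "d1", seed = 3)
  sel <- select_homologs(list(twi, safe, dark))
  expect_equal(sel$zone_used, "Safe")
  expect_length(sel$hits, 1)
  expect_equal(sel$hits[[1]]$alignment$homolog_id, "s1")
  sel2 <- select_homologs(list(twi, dark))
  expect_equal(sel2$zone_used, "Twilight")
  sel3 <- select_homologs(list(dark))
  expect_equal(sel3$zone_used, "Dark")
  # nothing above the Dark cutoff: valid no-prediction outcome
  none <- one_hit(qlab, 0.05, id = "n1", seed = 4)
  sel4 <- select_homologs(list(none))
  expect_equal(sel4$zone_used, "None")
  expect_length(sel4$hits, 0)
})

test_that("near-identical hits are excluded before zoning", {
  # a Safe-zone hit with PS > 0.95 must be discarded, leaving the
  # Twilight hit to carry the prediction
  safe <- one_hit(qlab, 0.8, id = "self")
  safe$stats$ps <- 0.97
  twi <- one_hit(qlab, 0.5, id = "t1", seed = 2)
  sel <- select_homologs(list(safe, twi))
  expect_equal(sel$zone_used, "Twilight")
  expect_equal(sel$hits[[1]]$alignment$homolog_id, "t1")
  # the boundary itself survives (exclusion is strict)
  safe$stats$ps <- 0.95
  expect_equal(select_homologs(list(safe, twi))$zone_used, "Safe")
})

test_that("one HSP per homolog: best predicted IC, then lower E-value", {
  a <- one_hit(qlab, 0.75, id = "h1", seed = 5)
  b <- one_hit(qlab, 0.85, id = "h1", seed = 6)
  sel <- select_homologs(list(a, b))
  expect_length(sel$hits, 1)
  expect_equal(sel$hits[[1]]$predicted_ic, 0.85, tolerance = 1e-9)
  # tie on predicted IC: lower E-value wins
  c1 <- one_hit(qlab, 0.75, id = "h2", seed = 7)
  c2 <- one_hit(qlab, 0.75, id = "h2", seed = 8)
  c1$alignment$e_value <- 1e-40
  c2$alignment$e_value <- 1e-20
  sel2 <- select_homologs(list(c2, c1))
  expect_equal(sel2$hits[[1]]$alignment$e_value, 1e-40)
})

test_that("weighted vote matches hand arithmetic on small fixtures", {
  h8 <- one_hit(qlab, 0.8, id = "a", seed = 9)
  h2 <- one_hit(qlab, 0.2, id = "b", seed = 10)
  # force opposite votes at every position: a votes the query label,
  # b votes its complement
  h8$homolog_labels <- qlab  # identity map: homolog position = query position
  h2$homolog_labels <- 1L - qlab
  p <- weighted_vote(length(qlab), list(h8, h2))
  expect_equal(p, ifelse(qlab == 1, 0.8, 0.2), tolerance = 1e-9)
  # three voters: (0.8*v1 + 0.5*v2 + 0.2*v3) / 1.5
  h5 <- one_hit(qlab, 0.5, id = "c", seed = 11)
  h5$homolog_labels <- rep(1L, length(qlab))
  p3 <- weighted_vote(length(qlab), list(h8, h5, h2))
  expect_equal(p3, (0.8 * qlab + 0.5 * 1 + 0.2 * (1 - qlab)) / 1.5,
               tolerance = 1e-9)
  # single voter aligned to an interface residue gives exactly 1
  p1 <- weighted_vote(length(qlab), list(h8))
  expect_equal(p1[qlab == 1], rep(1, sum(qlab)))
})

test_that("unaligned positions are missing and denominators are per-position", {
  # homolog aligned only to positions 1..6
  aln <- pairwise_alignment("q", "h", cbind(1:6, 1:6), 1e-20, 6, 5, 6,
                            length(qlab), 6)
  hit <- homolog_hit(aln, qlab[1:6])
  p <- weighted_vote(length(qlab), list(hit))
  expect_true(all(is.na(p[7:12])))
  expect_equal(p[1:6], as.numeric(qlab[1:6]))
  # a second homolog covering 5..12 must not be diluted by the first at
  # positions the first does not cover
  aln2 <- pairwise_alignment("q", "h2", cbind(5:12, 1:8), 1e-20, 8, 7, 8,
                             length(qlab), 8)
  hit2 <- homolog_hit(aln2, rep(1L, 8))
  p2 <- weighted_vote(length(qlab), list(hit, hit2))
  expect_equal(p2[7:12], rep(1, 6))  # only hit2 votes there
})

test_that("vote scores are convex and invariant to weight scaling", {
  set.seed(31)
  for (rep in 1:10) {
    L <- 30
    ql <- rbinom(L, 1, 0.3)
    hits <- lapply(1:3, function(k) {
      one_hit(ql, runif(1, 0.2, 0.9), target_ic = runif(1, 0, 1),
              id = paste0("h", k), seed = 100 + rep * 10 + k,
              del_rate = 0.2)
    })
    p <- weighted_vote(L, hits)
    expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
    scaled <- lapply(hits, function(h) {
      h$predicted_ic <- h$predicted_ic * 7.3
      h
    })
    expect_equal(weighted_vote(L, scaled), p, tolerance = 1e-12)
    # flipping a 0-vote to 1 never decreases any score
    flip <- hits
    zero_pos <- which(flip[[1]]$homolog_labels == 0L)
    if (length(zero_pos) > 0) {
      flip[[1]]$homolog_labels[zero_pos[1]] <- 1L
      p_flip <- weighted_vote(L, flip)
      expect_true(all(p_flip - p >= -1e-12, na.rm = TRUE))
    }
  }
})

test_that("binarization threshold is inclusive and missing propagates", {
  expect_identical(binarize_scores(c(1, 0, 0.5, 0.49, NA)),
                   c(1L, 0L, 1L, 0L, NA))
  expect_identical(binarize_scores(0.3, threshold = 0.3), 1L)
})

test_that("a perfect Safe-zone homolog reproduces the query labels", {
  set.seed(41)
  ql <- rbinom(40, 1, 0.25)
  hit <- one_hit(ql, 0.8, target_ic = 1, seed = 42)
  res <- homology_predict(40, list(hit))
  expect_equal(res$zone_used, "Safe")
  aligned <- hit$alignment$position_map[, 1]
  expect_identical(res$call[aligned], ql[aligned])
  expect_true(all(is.na(res$score[setdiff(1:40, aligned)])))
})

test_that("homolog report mirrors the hit annotations", {
  hits <- list(one_hit(qlab, 0.8, id = "a", seed = 1),
               one_hit(qlab, 0.3, id = "b", seed = 2))
  rep_tab <- homolog_report(hits)
  expect_equal(rep_tab$homolog_id, c("a", "b"))
  expect_equal(rep_tab$predicted_ic, c(0.8, 0.3), tolerance = 1e-9)
  expect_equal(rep_tab$zone, c("Safe", "Twilight"))
})
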
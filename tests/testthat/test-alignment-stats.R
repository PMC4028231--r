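# Alignment statistics and the interface-conservation score.

test_that("the six statistics match their definitions", {
  aln <- pairwise_alignment("q", "h", cbind(1:100, 1:100),
                            e_value = 1e-50, length = 100,
                            identities = 100, positives = 100,
                            query_length = 100, homolog_length = 100)
  s <- compute_alignment_stats(aln)
  expect_equal(s$ps, 1.0)
  expect_equal(s$is, 1.0)
  expect_equal(s$neg_log_e, 50)
  expect_equal(s$log_l, 2.0)
  expect_equal(s$frac_q, 1.0)
  expect_equal(s$frac_h, 1.0)

  aln2 <- pairwise_alignment("q", "h", matrix(integer(0), ncol = 2),
                             e_value = 1e-3, length = 100,
                             identities = 60, positives = 80,
                             query_length = 200, homolog_length = 400)
  s2 <- compute_alignment_stats(aln2)
  expect_equal(s2$ps, 0.8)
  expect_equal(s2$is, 0.6)
  expect_equal(s2$frac_q, 0.5)
  expect_equal(s2$frac_h, 0.25)
})

test_that("E-value underflow is capped and invalid fractions warn", {
  aln <- pairwise_alignment("q", "h", matrix(integer(0), ncol = 2),
                            e_value = 0, length = 10, identities = 5,
                            positives = 7, query_length = 50,
                            homolog_length = 50)
  expect_equal(compute_alignment_stats(aln)$neg_log_e, 200)
  expect_equal(compute_alignment_stats(aln, e_cap = 300)$neg_log_e, 300)
  # length fraction capped at 1 with a warning when L exceeds the sequence
  bad <- pairwise_alignment("q", "h", matrix(integer(0), ncol = 2),
                            e_value = 1, length = 60, identities = 10,
                            positives = 20, query_length = 50,
                            homolog_length = 80)
  expect_warning(s <- compute_alignment_stats(bad), "capped")
  expect_equal(s$frac_q, 1)
})

test_that("alignment record invariants are enforced", {
  expect_error(pairwise_alignment("q", "h", cbind(c(1, 1), c(1, 2)), 1, 2,
                                  1, 1, 10, 10), "strictly increasing")
  expect_error(pairwise_alignment("q", "h", cbind(1, 20), 1, 1, 1, 1,
                                  10, 10), "bounds")
  expect_error(pairwise_alignment("q", "h", cbind(1, 1), 1, 10, 8, 5,
                                  10, 10), "identities <= positives")
})

test_that("ic_score equals Pearson and tabulated MCC on random pairs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(10:80, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (var(x) == 0 || var(y) == 0) next
    got <- ic_score(x, y)
    expect_equal(as.numeric(got), brute_force_pearson(x, y),
                 tolerance = 1e-12)
    expect_equal(as.numeric(got), brute_force_mcc(y, x), tolerance = 1e-12)
    # symmetry
    expect_equal(as.numeric(got), as.numeric(ic_score(y, x)),
                 tolerance = 1e-14)
  }
})

test_that("ic_score boundary and degenerate cases", {
  x <- c(1, 1, 0, 0, 1)
  expect_equal(as.numeric(ic_score(x, x)), 1.0)
  expect_equal(as.numeric(ic_score(x, 1 - x)), -1.0)
  expect_equal(as.numeric(ic_score(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1))),
               brute_force_pearson(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1)))
  const <- ic_score(c(1, 1, 1), c(1, 0, 1))
  expect_equal(as.numeric(const), 0)
  expect_true(attr(const, "degenerate"))
  expect_error(ic_score(c(NA, NA), c(1, 0)), "no comparable columns")
})

test_that("unresolved columns are masked before scoring", {
  q <- c(1, 0, NA, 1, 0)
  h <- c(1, 0, 1, NA, 0)
  # only columns 1, 2, 5 are comparable
  expect_equal(as.numeric(ic_score(q, h)),
               brute_force_pearson(c(1, 0, 0), c(1, 0, 0)))
})

test_that("aligned_labels projects labels through the position map", {
  aln <- pairwise_alignment("q", "h", cbind(c(2, 4, 5), c(1, 2, 4)),
                            1e-5, 3, 2, 3, 6, 5)
  al <- aligned_labels(aln, c(0, 1, 0, 1, 1, 0), c(1, 1, 0, 0, 1))
  expect_identical(al$query, c(1, 1, 1))
  expect_identical(al$homolog, c(1, 1, 0))
})

test_that("alignment tables round-trip and stats survive re-parse", {
  set.seed(13)
  alns <- lapply(1:10, function(i) {
    lq <- sample(50:150, 1)
    lh <- sample(50:150, 1)
    L <- sample(20:min(lq, lh), 1)
    qp <- sort(sample(lq, L))
    hp <- sort(sample(lh, L))
    pos <- sample(0:L, 1)
    pairwise_alignment(paste0("q", i), paste0("h", i), cbind(qp, hp),
                       e_value = 10^-runif(1, 0, 100), length = L,
                       identities = sample(0:pos, 1), positives = pos,
                       query_length = lq, homolog_length = lh)
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_table(alns, path)
  back <- read_alignment_table(path)
  for (i in seq_along(alns)) {
    expect_equal(back[[i]]$position_map, alns[[i]]$position_map)
    expect_equal(compute_alignment_stats(back[[i]]),
                 compute_alignment_stats(alns[[i]]), tolerance = 1e-12)
  }
})

test_that("BLAST tabular output is parsed to matching statistics", {
  # qseqid sseqid pident length mismatch gapopen qstart qend sstart send
  # evalue bitscore ppos qlen slen
  line <- paste("q1", "h1", "80.000", "100", "20", "0", "11", "110",
                "1", "100", "1e-30", "200", "90.00", "150", "120",
                sep = "\t")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(line, path)
  aln <- read_blast_tabular(path)[[1]]
  expect_equal(aln$identities, 80L)
  expect_equal(aln$positives, 90L)
  s <- compute_alignment_stats(aln)
  expect_equal(s$ps, 0.9)
  expect_equal(s$is, 0.8)
  expect_equal(s$neg_log_e, 30)
  # gapless HSP reconstructs a co-linear position map
  expect_equal(aln$position_map[, 1], 11:110, ignore_attr = TRUE)
  expect_equal(aln$position_map[, 2], 1:100, ignore_attr = TRUE)
})

test_that("BLAST XML HSPs yield exact position maps across gaps", {
  skip_if_not_installed("xml2")
  xml <- '<?xml version="1.0"?>
<BlastOutput><BlastOutput_iterations><Iteration>
<Iteration_query-def>q1</Iteration_query-def>
<Iteration_query-len>12</Iteration_query-len>
<Iteration_hits><Hit>
<Hit_def>h1</Hit_def><Hit_len>11</Hit_len>
<Hit_hsps><Hsp>
<Hsp_evalue>1e-08</Hsp_evalue><Hsp_align-len>10</Hsp_align-len>
<Hsp_identity>7</Hsp_identity><Hsp_positive>8</Hsp_positive>
<Hsp_query-from>2</Hsp_query-from><Hsp_hit-from>1</Hsp_hit-from>
<Hsp_qseq>ACD-EFGHIK</Hsp_qseq>
<Hsp_hseq>ACDWE-GHIK</Hsp_hseq>
</Hsp></Hit_hsps></Hit></Iteration_hits>
</Iteration></BlastOutput_iterations></BlastOutput>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  aln <- read_blast_xml(path)[[1]]
  # column 4 is a query gap, column 6 a hit gap; 8 aligned pairs remain
  expect_equal(nrow(aln$position_map), 8)
  expect_equal(aln$position_map[, 1], c(2, 3, 4, 5, 7, 8, 9, 10),
               ignore_attr = TRUE)
  expect_equal(aln$position_map[, 2], c(1, 2, 3, 5, 6, 7, 8, 9),
               ignore_attr = TRUE)
})
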
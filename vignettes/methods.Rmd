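---
title: "Predicting RNA-binding residues by homology transfer and profile SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA-binding residues by homology transfer and profile SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnabindpred)
```

## The problem

Many proteins act by binding RNA, and the residues that form the
protein–RNA interface are the functional heart of the interaction. When a
complex has been solved crystallographically the interface can be read off
the coordinates: a residue is an *interface residue* if at least one of its
heavy (non-hydrogen) atoms lies within 5 Å of any atom of the bound RNA.
Most proteins of interest have no solved complex, so the practical task is
per-residue binary classification from sequence alone.

`rnabindpred` implements a two-stage predictor:

1. **Homology transfer.** If a close homolog of the query has a solved
   protein–RNA complex, its experimentally known interface residues are
   transferred through the alignment. The reliability of that transfer is
   itself predicted, by a linear model on alignment statistics, and used
   both to weight homologs and to stratify predictions into reliability
   zones.
2. **Profile SVM.** Independently, an RBF-kernel support vector machine
   classifies each residue from a sliding window of its PSSM (sequence
   profile) rows, so a prediction exists for *every* residue of *every*
   query.
3. **A logistic combiner** stacks the two scores into a single
   probability, imputing the homology score where homology transfer was
   impossible. The hybrid therefore keeps the high precision of homology
   transfer where homologs exist and degrades gracefully to the SVM where
   they do not — 100% residue coverage by construction.

## Interface conservation and its prediction

For a query–homolog pair with known structures, the **interface
conservation (IC) score** is the correlation coefficient between the two
aligned binary interface-label vectors (equivalently, the Matthews
correlation of the 2×2 table of aligned labels). IC = 1 means the homolog's
interface maps perfectly onto the query's; IC near 0 means transfer would
be uninformative. Columns in which either residue is unresolved in its
crystal structure are excluded before the correlation is computed; if
either masked vector is constant the correlation is undefined and the
package returns 0 with a `degenerate` flag rather than an error or a
misleading ±1.

At prediction time the query has no structure, so the IC score is
*predicted* from four BLAST alignment statistics:

\[
\widehat{IC} = -0.532 + 0.001\,(-\log_{10} E) + 0.005\,\log_{10} L
             + 0.600\,PS + 0.089\,\frac{L}{\min(L_Q, L_H)}
\]

where \(E\) is the alignment E-value, \(L\) the local alignment length,
\(PS\) the positive score (fraction of aligned columns with a positive
substitution-matrix score), and the last term the coverage of the shorter
sequence. \(PS\) carries most of the explanatory weight. The coefficients
above are the package defaults; `fit_ic_model()` re-estimates them by
ordinary least squares on any labeled pair set and reports standard
errors, adjusted R² and Type II (drop-one) sums of squares.

Three numerical choices matter here and are all configurable:

* **Logarithm base** is 10 (conventional for E-values), recorded in the
  model metadata.
* **E-value underflow.** BLAST reports `E = 0` for very strong hits;
  \(-\log_{10} E\) is then capped, by default at 200.
* **No clamping.** Predicted IC is not clamped to \([-1, 1]\): zone
  assignment consumes raw values, and silent clamping could move hits
  across zone thresholds.

A consequence worth stating plainly: with the default coefficients, base
and cap, the model's maximum over admissible statistics
(\(PS \le 1\), coverage \(\le 1\), \(-\log_{10}E \le 200\)) is about 0.37.
Safe-zone predictions (below) therefore arise only from E-value-underflow
hits evaluated with a raised cap; the cap used is recorded on each hit,
and the synthetic homolog generator raises it explicitly when a scenario
requires a Safe-zone hit. Alignments re-read from disk and re-scored at
the default cap will top out in the Twilight zone — a conservative
behavior we prefer over hard-coding a more permissive reading of the
model.

## Homology zones and the weighted vote

Predicted IC stratifies hits into reliability tiers, with boundaries
closed below:

| Zone | Predicted IC |
|---|---|
| Safe | ≥ 0.70 |
| Twilight | 0.20 – 0.70 |
| Dark | 0.15 – 0.20 |
| discarded | < 0.15 |

Selection is hierarchical: hits with similarity above the
self-hit-exclusion cutoff (positive score > 0.95 by default, so the query
cannot vote for itself) are removed; then, if any Safe hit remains, *all*
Safe hits are used and nothing else; otherwise all Twilight hits;
otherwise all Dark hits; otherwise the query goes unpredicted by this
stage. When a query–homolog pair has several HSPs, the one with the
highest predicted IC is kept (ties: lower E-value, then first occurrence).

Each selected homolog votes at every query position it aligns to:
\(v_{ik} = 1\) iff the residue aligned to query position \(i\) in homolog
\(k\) is an interface residue. The per-residue score is the weighted mean

\[
P_i = \frac{\sum_k w_k v_{ik}}{\sum_k w_k},
\qquad w_k = \widehat{IC}_k,
\]

with both sums restricted to the homologs actually aligned at position
\(i\) — a homolog that simply does not cover a region neither votes there
nor dilutes the votes of those that do. Positions no homolog covers are
reported as missing (`NA`), which is the coverage gap the combiner later
closes. \(P_i \ge 0.5\) becomes a positive call; the threshold is an
argument everywhere it appears.

## The profile SVM

Each residue is represented by the concatenated PSSM rows of a window
centered on it (window 21 by default — the value selected by grid search
on the training corpus of RNA-binding chains — giving 420 features), with
zero-vector padding beyond the sequence ends. A C-SVM with RBF kernel is
trained on these windows with inverse-frequency class weights, since
interface residues are the minority class (roughly 15% in curated
RNA-binding chains). Features are standardized internally.

Two protocol details are enforced programmatically:

* **Sequence-based cross-validation.** Folds partition whole chains,
  never residues, so no window from a test chain can leak into training.
  `sequence_cv_folds()` is seeded and `grid_search()` errors on any
  chain overlap between folds.
* **Held-out tuning.** `grid_search()` splits the chains into six parts,
  reserves one as a test set that model selection never touches, scores
  every (C, γ, window) combination by sequence-based 5-fold CV on the
  pool (selection criterion: MCC), retrains the best combination on the
  whole pool, and only then evaluates on the held-out part. Default
  grids are powers of two for C and γ and odd windows 15–27; the tuned
  C and γ for the published corpus are not recoverable, so the package
  ships the protocol rather than pretending to ship the constants.

Continuous margins are mapped to \([0, 1]\) by a monotone sigmoid
calibration fitted on the training margins by the package's own
ridge-penalized logistic solver. This calibration is deterministic —
repeated runs on the same data give bit-identical scores — which is what
makes the end-to-end pipeline reproducible from a single seed; raw
margins remain available alongside.

## The combiner

The final probability is a two-input logistic regression,

\[
p_i = \sigma\!\left(b + w_h h_i + w_s s_i\right),
\]

fitted by ridge-penalized maximum likelihood (Newton–Raphson; ridge
\(10^{-8}\), the conventional default of logistic implementations in
machine-learning toolkits, penalizing the non-intercept weights only).
Missing homology scores are imputed with the training-set mean of the
non-missing scores, and the imputation value is stored in the model so
prediction-time missing values are treated identically — supplying the
mean explicitly and supplying `NA` give byte-identical output. If *all*
training homology scores are missing the fit degrades, with a warning, to
an SVM-only logistic model. To avoid leakage, the pipeline trains the
combiner on out-of-fold SVM scores (each chain's SVM score comes from a
model that never saw that chain); in-sample training would overweight the
SVM.

## Evaluation conventions

Following the naming convention of this literature, **specificity** here
denotes TP/(TP+FP) — what the broader machine-learning literature calls
precision — and the package emits both names to prevent misreading.
Sensitivity is TP/(TP+FN); F is their harmonic mean; MCC is the Matthews
correlation. A predictor that makes no positive prediction has an
undefined precision that would naively evaluate as perfect; the package
reports 0 with an explicit `degenerate` flag instead. AUC is computed as
the Mann–Whitney probability that a positive outranks a negative with
ties counted ½, which equals the trapezoidal area under the tie-aware ROC
sweep; both identities are asserted in the test suite against a
brute-force pairwise count. Residue-pooled metrics are the default;
per-chain macro-averaging is available since published tables in this
area rarely state which aggregation they use. Evaluating the homology
stage alone uses the `exclude` missing-value policy (unaligned residues
drop out); the hybrid has no missing values to police.

## What the synthetic data emulates

All tests run on generated data; no download is required.

* `make_complex()` builds toy complexes whose geometry realizes a
  requested interface set *exactly* under the 5 Å rule (residues on a
  line at 8 Å spacing; one RNA atom 3 Å from each chosen residue, ≥ 8.5 Å
  from all others), so structural labeling can be checked against a known
  truth as well as a brute-force distance scan.
* `make_homolog_db()` derives homolog labels from query labels by
  independent symmetric flips at the closed-form rate that yields a
  requested label correlation in expectation, inserts indels after label
  assignment so position maps stay exact, and emits alignment statistics
  that land exactly on a requested predicted IC (inverting the linear
  model for PS, holding PS ≤ 0.94 so hits survive the similarity
  exclusion, and carrying any remainder through the E-value term).
* `make_pssm()` draws integer log-odds from a fixed discrete background
  on \([-10, 12]\) (the ASCII format's dialect) and shifts rows of
  interface residues by a configurable effect on chosen columns at
  chosen window offsets — placing signal off-center is how the tests
  verify that grid search prefers a window wide enough to see it.

What this synthetic world does *not* contain: realistic protein geometry,
evolutionary substitution structure, correlated conservation along the
chain, or database-scale homolog retrieval. Passing tests therefore
demonstrate that the machinery is correct and the protocols are honored —
not that the shipped defaults attain any particular accuracy on real
proteins, which depends on a real homolog database and real PSSMs.

The deterministic end-to-end run (`run_synthetic_pipeline()`) uses 6–16
chains of 40–100 residues with a window-5 SVM and 5-fold chain-level CV —
sizes chosen so the whole study, including its repetition for the
determinism check, completes in well under a minute while every stage
still has both classes and a nontrivial coverage gap (every fifth and
third chain in the zone cycle has no homolog).

## Known limitations

* The IC-score definition (correlation of aligned binary labels) is the
  single most consequential interpretation in the package; it is isolated
  in `ic_score()` so an alternative can be swapped in.
* Safe-zone reachability at the default E-value cap, discussed above.
* BLAST tabular input reconstructs position maps only for gapless HSPs;
  use XML input (`read_blast_xml()`) or the internal alignment table when
  gapped maps matter.
* The curation filters apply resolution/experiment/CA-only rules only
  when metadata are supplied; redundancy reduction (PISCES/CD-HIT) is out
  of scope and expected upstream.
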
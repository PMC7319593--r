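---
title: "Predicting anti-CRISPR proteins from PSSM-derived evolutionary features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting anti-CRISPR proteins from PSSM-derived evolutionary features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Anti-CRISPR (Acr) proteins let phages and other mobile genetic elements
(MGEs) disarm bacterial CRISPR–Cas immunity. Known Acrs are short
(typically 50–350 residues), taxonomically scattered, and — crucially —
share almost no conserved sequence or structural motifs. Homology-based
detection therefore fails on genuinely novel Acrs. What *does* carry
signal is evolutionary context: the position-specific scoring matrix
(PSSM) produced by an iterative PSI-BLAST search (3 iterations, inclusion
e-value 0.001, against a large protein database such as UniRef50)
summarises the conservation pattern of a protein's extended family, and
fixed-length descriptors of that matrix separate Acrs from ordinary
phage/MGE proteins far better than sequence composition does.

`acrscreen` implements this idea end to end: PSSM parsing, the descriptor
family, an imbalance-aware SVM ensemble, the repeated balanced evaluation
protocol, and seeded synthetic-data generators so every stage is testable
without network access or a sequence database.

## Descriptors

For a validated protein of length $L$ with PSSM $P \in \mathbb{Z}^{L\times 20}$
(columns in PSI-BLAST order; the first, log-odds block of the ASCII file):

* **PSSM-composition** (400): $R_i = \frac{1}{L}\sum_{k=1}^{L} r_k\,\delta_k$,
  where $r_k$ is row $k$ and $\delta_k = 1$ exactly when the $k$-th query
  residue is amino-acid type $a_i$; the $20\times 20$ matrix is flattened
  row by row. The $1/L$ prefactor always uses the full length, so residue
  types absent from the sequence give zero rows.
* **DPC-PSSM** (400): $y_{i,j} = \frac{1}{L-1}\sum_{k=1}^{L-1} p_{k,i}\,p_{k+1,j}$,
  emitted in the order $(y_{1,1},\dots,y_{1,20},y_{2,1},\dots,y_{20,20})$.
* **PSSM-AC** ($20\cdot LG$): per column $j$, the lagged autocovariance
  $\mathrm{AC}(j,lg)=\sum_{i=1}^{L-lg}
  (P_{i,j}-\bar P_j)(P_{i+lg,j}-\bar P_j)/(L-lg)$ for $lg = 1,\dots,LG$.
  $LG$ defaults to 10 (a 200-dimensional vector); $L > LG$ is enforced —
  guaranteed by the 50-residue length filter at the default lag — and the
  output is ordered column-by-column, lags innermost. Note the mean-centering
  makes this descriptor invariant to any constant shift of a column.
* **RPSSM** (110): the PSSM is first reduced to $L\times 10$ by averaging
  column groups FYW, ML, IV, ATS, NH, QED, RK, C, G, P (in that order);
  then $D_{s,t} = \frac{1}{L-1}\sum_{i=1}^{L-1}\,(p_{i,s}-p_{i+1,t})^2/2$
  (100 values, row-major over $(s,t)$) and the population variances
  $D_s = \sum_i (p_{i,s}-\bar p_s)^2 / L$ (10 values) are concatenated as
  $[D_{1,1},\dots,D_{10,10},D_1,\dots,D_{10}]$. All 110 values are sums of
  squares and hence non-negative.

AAC (20) and DPC (400) sequence-composition baselines are provided for
comparison; both sum to one. All element orderings above are fixed because
they are part of the persisted model format: a model trained with one
version of the package scores identically after reload.

Two deliberately pinned conventions where the descriptor literature
varies: PSSM scores are consumed **raw** (an optional logistic rescaling
$1/(1+e^{-x})$ exists behind `pssm_rescale` in the POSSUM toolkit family;
we default to raw because the descriptor formulas act on $P_{i,j}$
directly), and the length filter treats 50 and 350 as inclusive bounds.

### Nonstandard residues

The default policy rejects any letter outside the 20-letter standard
alphabet, naming the record, position and letter. The permissive `"mask"`
policy replaces such letters with `X`, which then behaves as a 21st
residue type invisible to AAC/DPC counts and to the $\delta_k$ selector of
PSSM-composition, while $L$ keeps its full value — the simplest literal
reading of the formulas.

## The ensemble model

Training pools for Acr prediction are heavily imbalanced (the reference
design is 98 positives against 902 negatives; the synthetic default uses
the same 1:10 shape). Rather than reweighting, the model uses **multiple
undersampling**: `n_subsets` = 10 balanced subsets, each containing every
positive plus an equal-size draw (without replacement, derived seed
`seed + k`) from the negatives. Per subset, an RBF-kernel SVM is selected
by grid search over $\mathrm{Cost},\gamma \in \{2^{-10},\dots,2^{10}\}$
(integer exponents, 21 × 21 cells) using seeded **stratified 5-fold CV
accuracy inside the subset**; ties go to the smallest cost, then the
smallest gamma, favouring the smoother model. The subset's classifier
emits a positive-class probability; a feature model's score is the mean
over its 10 classifiers, and the final score is the unweighted mean over
the four feature models, thresholded at 0.5 with the boundary counted
positive (a score of exactly 0.5, or 0.503, is an Acr call).

Implementation choices a maintainer should know:

* **SVM backend.** Classifiers are fitted with `kernlab::ksvm` on
  *precomputed* kernel matrices: one squared-distance matrix per subset
  serves the entire grid (each $\gamma$ is one elementwise `exp`), which
  makes the 21 × 21 × 5-fold search roughly six times faster than
  refitting from feature vectors. Predictions use the stored support
  vectors, coefficients and offset directly; a test cross-checks the
  fitted classifier against an `e1071::svm` fit of the same
  (Cost, $\gamma$).
* **Feature standardization.** Each subset's feature columns are z-scored
  (center/scale stored in the classifier, constant columns left at zero)
  before the grid search and fit. The descriptors differ by orders of
  magnitude (DPC-PSSM cross-products reach $10^3$–$10^4$, compositions
  live in $[0,1]$), and without standardization the entire power-of-two
  $\gamma$ grid sits in a degenerate kernel regime for the large-scale
  descriptors. This mirrors the default behaviour of `e1071::svm`.
* **Probability calibration.** libsvm's built-in probability training
  shuffles with its own C-level RNG and is not reproducible from R. The
  package instead fits the Platt sigmoid
  $P(y{=}1\mid f) = 1/(1+e^{Af+B})$ itself by penalised maximum likelihood
  (smoothed targets $(N_+{+}1)/(N_+{+}2)$ and $1/(N_-{+}2)$, BFGS), on the
  training-subset decision values. This is fully deterministic and
  absorbs the decision-value sign convention. On separable subsets the
  calibrated probabilities saturate near 0/1, which is acceptable for a
  ranking-plus-threshold consumer; no claim is made that scores match any
  particular deployed server's calibration.
* **Determinism.** Every stochastic step (negative draws, fold
  assignments) derives its seed from the master seed by fixed offsets
  (per-feature seeds `seed + 100000 * index`, per-subset `seed + k`,
  repeat seeds `seed + 1000 * r`), so models, predictions and evaluation
  reports are bit-reproducible; persisted models are byte-identical across
  reruns. For the same reason model metadata records seeds, grid, sizes
  and package version but no timestamp.
* **Known-Acr filter.** In normal prediction mode, proteins whose sequence
  exactly matches the built-in list of experimentally validated Acrs are
  flagged and returned unscored; benchmarking mode bypasses the list so
  that evaluation never shortcuts through it. The shipped list
  (`known_acr_synthetic.fasta`) is a synthetic stand-in — real screening
  should pass a curated FASTA via `known_acrs`/`--known-list`.

## Evaluation protocol

`cv_balanced_repeats()` repeats, N = 10 times: draw a balanced dataset
(all positives + equal random negatives), assign seeded stratified k = 5
folds, and in each fold retrain the *entire* ensemble — undersampling
subsets, grid search, calibration — on the training folds only, scoring
the held-out fold. Stratification is our choice (it guarantees both
classes in every fold of a balanced dataset); retraining the grid search
inside every fold is the stricter reading of "nothing is tuned on held-out
data". Per-repeat metrics are computed on the pooled held-out scores; the
report's AVERAGE row is the arithmetic mean of the repeat rows,
component-wise. `independent_test_repeats()` fixes a trained model and
repeats balanced negative draws around the independent positives; since
the model is fixed, the pool is scored once and repeats re-select scores.

Metrics follow the standard confusion-table definitions
(SN, SP, ACC, F-value, MCC) with bounded zero-denominator conventions
(SN/SP/F → 0 on empty denominators; MCC → 0 when a marginal is zero) so
that averaging across repeats stays well-defined. ROC curves sweep all
distinct scores as thresholds and AUC is the trapezoidal integral, which
equals the positive-vs-negative pairwise win probability with ties at
half — asserted against a brute-force pairwise oracle in the tests.
`rank_predictions()` produces the genome-screening view: proteins sorted
by final score (ties broken lexicographically by id for reproducibility)
with marker-retrieval counts per ranking cutoff and the rank of the last
marker.

## Synthetic data: what it does and does not show

`sim_acr_dataset()` emulates the *shape* of the training problem: class
imbalance (default study design 40 positives / 400 negatives for pipeline
recovery, 12/60 for the fast golden fixture), lengths uniform in
[50, 350] (narrowed in fixtures for speed), integer PSSM scores uniform in
[−10, 10]. The class signal is a constant shift (default 5, on columns
F, L, I, A, R) added to positives' PSSMs *before* encoding — injected in
PSSM space because all four model descriptors are PSSM-derived. Three
properties make it a useful test bed: separability grows smoothly with
the shift; at shift 0 the classes are exchangeable, so any held-out AUC
away from 0.5 indicates leakage; and the shift interacts differently with
the descriptors (PSSM-AC's column centering cancels a constant shift
entirely, so that feature model hovers near chance while the other three
separate — the ensemble's averaging is visibly doing its job).

What passing these tests does **not** show: real PSI-BLAST PSSMs have
position-dependent, heavy-tailed, phylogenetically structured scores, and
real Acr/non-Acr discrimination is far from linearly separable. The
synthetic results validate the machinery (formulas, protocol, leak-freedom,
determinism), not field performance; benchmark numbers on real data
require real PSSMs against a large database.

## Problem sizes and numerical choices

The shipped tests and the acceptance script scale the protocol down to
desk size as the package's own choice of problem sizes: the golden fixture
(12/60, `n_subsets` 2, exponent steps of 4–6 across the full
$[2^{-10}, 2^{10}]$ span) for structural and protocol checks, and the
40/400 design with exponent step 4 for end-to-end recovery. On the
separable fixture the selected cell is accuracy-equivalent across wide
grid neighbourhoods, so coarsening the grid changes wall-clock time, not
outcomes; production training defaults to the full 21-point grids.
Encoders compute in double precision from integer inputs; kernel
squared-distances are clamped at zero against round-off; Platt logits are
clamped at ±700 before exponentiation; RPSSM's expanded-square form is
clamped at zero to guard tiny negative round-off.

## Known limitations

* PSSM parsing targets the BLAST+ `-out_ascii_pssm` layout (legacy
  blast-2.2.26 files differ slightly and are not supported).
* The undersampling ensemble assumes at least as many negatives as
  positives; other imbalance directions are rejected, not handled.
* Scores are calibrated per training subset; absolute score values are
  comparable within a model but not across differently trained models.
* The built-in known-Acr list ships as a synthetic placeholder; the exact
  set of experimentally validated Acrs evolves and must be supplied by the
  user for real screening.
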
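---
title: "Discriminating cis- from trans-Golgi proteins: model and methods"
author: "golgiCSP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating cis- from trans-Golgi proteins: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Golgi apparatus receives biosynthetic output at its *cis* face and
ships sorted cargo from its *trans* face; resident proteins are retained
preferentially in one of the two compartments, and mislocalization is
linked to neurodegenerative disease. Computationally, telling cis- from
trans-Golgi residents is hard because the two classes have very similar
overall amino-acid composition (compare them with
`class_aa_frequencies()`), so plain homology search carries little signal.
golgiCSP implements a two-class classifier over features that combine
local sequence order with evolutionary conservation, with every stochastic
stage seeded.

Throughout, cis-Golgi is the positive class and trans-Golgi the negative
class, and curated benchmarks of this task are imbalanced (the dataset
shape mirrored by the synthetic generator is 87 cis vs 217 trans).

## Sequence features: g-gap dipeptide composition

For a sequence of length $L$, the $g$-gap dipeptide composition counts
ordered residue pairs $(i, i+g+1)$ and normalizes by the number of
available positions:

$$f^g_i = \frac{n^g_i}{L - g - 1}, \qquad i = 1, \dots, 400.$$

The 400 pairs are indexed alphabetically, first residue major
(AA, AC, ..., YY) — the same canonical order used for PSSM columns, since
no other order is canonical in the literature. The default $g = 3$ is the
gap at which cross-validated accuracy peaks for this task, plausibly
because secondary-structure hydrogen bonding correlates residues three
positions apart; `g` is exposed as a parameter in $[0, L-2]$.

Non-standard letters (B, J, O, U, X, Z) are recorded but no dipeptide
touching one is counted, while the denominator stays $L-g-1$: the vector
then sums to the fraction of countable pairs, degrading gracefully rather
than rejecting the sequence. (Benchmark-curation keyword filters around
non-standard letters are contradictory in the source material; treating
such residues as excludable rather than forbidden is the only reading that
keeps real UniProt entries usable.)

## Evolutionary features: three PSSM descriptors

A PSSM is the $L \times 20$ log-odds profile from iterative homology
search (`psiblast -out_ascii_pssm`; running the search itself is outside
the package — only the ASCII output is parsed, with columns re-ordered
from PSI-BLAST order to alphabetical). The first (log-odds) block of the
file is used rather than the percentage block: log-odds are what the
downstream covariance structure is usually computed from in
PSSM-feature work; a `pssm_scale = "sigmoid"` switch ($1/(1+e^{-x})$) is
available for workflows that prefer bounded scores.

Three 20×20 summaries are computed:

* **PSSM-DC**: entry $(a, b)$ sums column $b$ over the rows whose *query*
  residue is $a$, divided by $L$. The defining phrase "amino acid type
  $i$ being changed to type $j$" admits two readings; grouping rows by the
  query residue is adopted because it is the only one that uses both
  "types" and is consistent with the divide-by-$L$ normalization — the
  alternative (products across position pairs) would duplicate the bi-gram
  descriptor and is rejected.
* **Bi-gram PSSM**: $B_{mn} = \sum_{i=1}^{L-1} E_{i,m}E_{i+1,n}$,
  substitution-propensity co-occurrence at consecutive positions
  (quadratic in the scores).
* **ED-PSSM**:
  $e_{mn} = \sum_{i=2}^{L-1} (E_{i-1,m} - E_{i+1,n})^2 / (L-2)$, the mean
  squared mutation contrast two positions apart; non-negative by
  construction. The divisor $L-2$ matches the $L-2$ interior terms.

Each descriptor can be flattened to the traditional 400-vector, but the
point of the package is to compress it instead.

## The CSP projection

Common Spatial Patterns, borrowed from two-class EEG analysis, finds a
basis in which one class's covariance is maximally large exactly where the
other's is maximally small:

1. per protein, $R = EE' / \mathrm{trace}(EE')$ (unit trace makes proteins
   comparable regardless of score magnitude);
2. class means $\bar R_1, \bar R_2$; composite $R_c = \bar R_1 + \bar R_2
   = U_c \lambda_c U_c'$;
3. whitening $P = \lambda_c^{-1/2} U_c'$, so that $P R_c P' = I$;
4. $S_1 = P \bar R_1 P' = B \lambda_1 B'$, and automatically
   $S_2 = B \lambda_2 B'$ with $\lambda_1 + \lambda_2 = I$;
5. $W = (B'P)'$, and per protein
   $f_j = \log\!\big(\mathrm{var}(Z_j) / \sum_i \mathrm{var}(Z_i)\big)$,
   $Z = WE$, giving 20 features per descriptor — 1/20 of the flattened
   dimension at nearly the same discriminative power.

Numerical and design choices, each testable:

* **Whitening exponent.** Source material for this construction prints the
  whitening as $\lambda_c^{-1} U_c'$ while simultaneously stating that all
  eigenvalues of $P R_c P'$ equal one; only $\lambda_c^{-1/2}$ satisfies
  that contract (and matches the standard CSP literature), so
  $\lambda_c^{-1/2}$ is implemented. The contract is asserted to 1e-8 in
  the tests.
* **Eigenvector order and sign.** $B$'s columns are sorted by the
  eigenvalues of $S_1$, descending, and sign-fixed (first non-negligible
  entry positive) so serialized models are reproducible; variance features
  are sign-invariant anyway.
* **Orientation.** The projection is applied literally as $Z = WE$ with
  *column* variances (`csp_orientation = "paper"`, the default). The
  classical CSP form takes *row* variances of $B'P\,E$
  (`"standard"`). They differ: under the literal form the class contrast
  spreads over all 20 features (a forest over all 20 still separates
  end to end), whereas under the classical form the leading/trailing
  components alone are maximally discriminative — the
  threshold-on-$f_1$ property holds for `"standard"` and is tested there.
* **Variance estimator.** Population variance (divide by 20). Any uniform
  choice cancels in the ratio; uniformity is what matters.
* **Degeneracy.** Eigenvalues of $R_c$ below $10^{-10} \times$ max are
  clipped (with a warning carrying the condition number) before inversion;
  the variance ratio is floored at $10^{-300}$ before the log; an input
  whose projected components are all constant is an error.
* **Leakage.** During cross-validation the CSP models are refit on each
  training fold (default). `paper_mode = TRUE` fits them once on the whole
  dataset before folding, mirroring a whole-dataset protocol that some
  published evaluations plausibly used; both are available because the
  distinction changes reported accuracy on small datasets.

Models serialize to versioned JSON (`write_csp_model()`), storing $W$
row-major plus the class-1 eigenvalues.

## Class imbalance: SMOTE

With 87 positives against 217 negatives a forest happily predicts the
majority class; SMOTE rebalances by synthesizing minority rows
$x + u\,(x_{nn} - x)$, $u \sim U[0,1]$, where $x_{nn}$ is one of the $k$
nearest minority neighbours (Euclidean distance on the unscaled features;
$k = 5$, the canonical setting). Oversampling runs exactly to parity:
each minority point serves as a base point an equal integral number of
times and a seeded shuffle assigns the remainder. Synthetic rows are
flagged `"synthetic-SMOTE"` in the table's provenance column and majority
rows are returned bit-identical. By default SMOTE runs inside each
training fold only; `paper_mode` balances the whole dataset before
cross-validation (which leaks interpolated copies of test-fold minority
points into training and typically inflates sensitivity — provided for
comparability, not recommended).

## Feature selection: RF-RFE

Recursive elimination driven by random-forest importance: fit a forest on
the current feature set, remove the least important feature, repeat — $N$
iterations for $N$ features, yielding a full ranking (rank 1 = last
eliminated). The importance criterion is out-of-bag permutation importance
(mean decrease in accuracy), matching an accuracy-based elimination rule;
`criterion = "impurity"` (Gini) is available. Importance ties are broken
by removing the feature with the larger canonical column index, keeping
the ranking deterministic under a fixed seed.

`select_optimal_prefix()` then evaluates every prefix of the ranking by
k-fold cross-validation, using one fixed fold partition for all prefix
sizes (a paired comparison that removes partition noise from the curve),
and returns the smallest prefix achieving the maximum accuracy —
by construction never worse on those folds than the full set.

## Classification and evaluation

The forest grows 100 unpruned trees on bootstrap samples with
$\lfloor\sqrt d\rfloor$ features per split (the established default);
`weka_forest_spec()` provides a 10-tree, $\lfloor\log_2 d\rfloor + 1$
preset mirroring the historical defaults of the WEKA toolkit under which
comparable pipelines were originally evaluated. The positive-class score
is the fraction of trees voting cis; label metrics use a 0.5 threshold.

Evaluation reports Sn, Sp, Acc and MCC from pooled held-out confusion
counts (a zero-denominator metric is reported as 0 and flagged), plus the
ROC curve from a full threshold sweep with trapezoidal AUC (equal to the
Mann-Whitney concordance probability; asserted against an $O(n^2)$ oracle
and against pROC in the tests). K-fold partitions are stratified by class
— with a 87:217 imbalance an unstratified partition can starve a training
fold of positives; a non-stratified switch exists, and `folds = n` gives
the jackknife. Fold construction retries up to 10 times if a training
portion loses a class, then errors.

## The synthetic generator

`synth_spec()` defaults *are* the emulated study conditions: 87 cis vs
217 trans, lengths 50–300, separation $s = 1$, noise $\sigma = 1$.
Sequences come from class-specific first-order Markov chains whose logits
differ by a fixed perturbation scaled by $0.5\,s$; PSSM rows are drawn
from Gaussians whose 20×20 column covariance interpolates, with weight
$w = s/(1+s)$, between a common template and a class-specific one — both
fixed random rotations of the decaying spectrum diag(25..1) — plus
$\sigma^2 I$, then quantized to integers in $[-10, 10]$ and written/re-read
through the ASCII PSSM format so the I/O path is always exercised.
At $s = 0$ the classes are statistically identical by construction; the
templates themselves are fixed once (independent of the sampling seed) so
that $s$ means the same thing in every run.

What the generator does **not** emulate: real conservation patterns,
homologous families, domain architecture, length–composition coupling, or
the empirical distribution of PSI-BLAST scores. Passing tests therefore
demonstrate that the machinery recovers class structure of the kind it is
told to expect (covariance contrasts and compositional bias), not that any
particular accuracy will be reached on curated Golgi benchmarks — the
published benchmark numbers additionally depend on Swiss-Prot searches
that no desk-scale test reproduces.

## Problem sizes used by the test and acceptance suites

Chosen to make the statistical assertions stable while keeping a full run
in minutes on one core: oracle-equivalence checks use 100+ random inputs
per operation (lengths 3–25); the CSP contract is checked on 50 random
fits at tolerance 1e-8; separation recovery uses 100-protein datasets
(chance band as a 3-seed mean, strong separation at $s = 3$) and
80-protein datasets across $s \in \{0, 0.5, 1, 2\}$ with 10 seeds per
level; the fusion-gain comparison uses 90-protein datasets over 10 seeds;
`scripts/acceptance.R` runs the full 304-protein shape with the
460-feature fusion and performs RF-RFE prefix selection on the
60-dimensional CSP representation (a full 460-iteration elimination plus a
460-point prefix curve is supported by the same functions, just slower).

## Known limitations

* CSP is strictly two-class; multi-class Golgi sub-typing would need
  one-vs-rest extensions that are out of scope.
* Covariance estimation uses plain class means; no shrinkage — with very
  few proteins per class the composite can be ill-conditioned (clipped,
  with a warning).
* SMOTE interpolates in feature space and cannot invent genuinely novel
  minority structure; with tiny minorities its synthetic rows are nearly
  duplicates.
* The jackknife refits CSP + SMOTE + forest $n$ times; on hundreds of
  proteins with selection enabled this is expensive (supported, but the
  10-fold protocol is the practical default).
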
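---
title: "Similarity-based affinity regression with a 2D convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based affinity regression with a 2D convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simdta)
```

## The model and its assumptions

`simdta` predicts continuous drug–target binding affinities from similarity
structure alone. The underlying assumption is the chemogenomic one: similar
compounds tend to bind similar proteins with similar strength. No structural
or docking information enters the model; a drug is represented only through
its chemical similarity to the training drugs, and a target only through its
sequence similarity to the training targets.

Concretely, for training rosters of $n_d$ drugs and $n_t$ targets the
package computes

* $K^1 \in [0,1]^{n_d \times n_d}$, the Tanimoto coefficients between
  path-based topological fingerprints, and
* $K^2 \in [0,1]^{n_t \times n_t}$, normalized Smith–Waterman scores
  $SW_{ij} / \sqrt{SW_{ii}\,SW_{jj}}$,

and represents the pair $(i, j)$ by the outer product
$k^1_i \otimes k^2_j$ of the $i$-th column of $K^1$ and the $j$-th column of
$K^2$. Since the diagonal entries are 1, this $n_d \times n_t$ grid contains
the two unimodal similarity profiles verbatim (row $i$ and column $j$) plus
all cross terms, which is why it is a richer input than concatenating the
two vectors. A compact 2D CNN regresses the grid onto the affinity:
two valid (unpadded) convolutions of 32 and 18 filters with $5\times5$ and
$3\times3$ kernels, each followed by overlapping $2\times2$ max-pooling with
stride 1, then flatten, dropout 0.1, a 128-unit ReLU layer and a linear
scalar output. Training minimises mean-squared error with Adam
(learning rate 0.001, batch size 32, 20 epochs), on *observed* pairs only —
missing cells of the affinity matrix never enter the loss.

Two points are deliberately literal readings of the published architecture:
pooling windows of size 2 with stride 1 overlap (they shrink each spatial
dimension by 1, not by half), and the convolutions carry no activation of
their own — activations are stated only for the fully connected layers
(ReLU, then linear), which matches the convention of deep-learning
frameworks where a convolution layer is linear unless an activation is
requested. The only nonlinearities before the dense layers are therefore the
max-poolings.

## Affinity scales

Two affinity conventions are supported, with explicit, never-implicit
transforms:

* Dissociation constants in nM are mapped to
  $\mathrm{pK_d} = -\log_{10}(K_d / 10^9)$ (`kd_to_pkd()`), so 10,000 nM
  becomes 5 and 1 nM becomes 9; higher means stronger binding.
* KIBA scores, where *lower* raw values mean stronger binding, are
  reoriented by the three-step recipe in `transform_kiba()`: negate, find
  the minimum of the negated scores, add its absolute value to all. The
  minimum of the transform is taken over the observed entries of the dataset
  at hand, so the binarization threshold on the transformed scale is a
  configuration value (the conventional choice is 12.1, corresponding to a
  raw threshold of 3.0 on the dataset the convention comes from), not a
  quantity the package recomputes.

A similarity-weighted imputation utility (`impute_missing_affinities()`,
weights = target similarities) is provided for methods that need a dense
matrix; the CNN itself never uses imputed values.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_bits` | 1024 | fingerprint length (bits); the native size of the path fingerprint, OR-foldable to smaller powers of two |
| `substitution`, `gap_open`, `gap_extend` | BLOSUM62, 10, 0.5 | local-alignment scoring; a gap of length L costs `gap_open + L*gap_extend` |
| `conv_filters`, `conv_kernels` | (32, 18), (5×5, 3×3) | architecture constants |
| `pool_size`, `pool_stride` | 2, 1 | overlapping max-pooling |
| `dropout_rate` | 0.1 | applied between flatten and the hidden dense layer, training only (inverted dropout) |
| `learning_rate`, `batch_size`, `epochs` | 0.001, 32, 20 | Adam optimisation schedule; no early stopping, no validation split |
| `threshold` | 7.0 (pKd) / 12.1 (KIBA) | AUPR binarization |
| `min_folds_per_target` | 2 (k=3), 4 (k=5) | fold-coverage constraint |

The alignment scoring scheme is not part of the published method (which
names only the algorithm); BLOSUM62 with 10/0.5 is the common convention in
similarity-based affinity work and is fully exposed. Boundedness of the
normalized score by 1 is guaranteed for identical sequences but is not a
theorem for arbitrary scoring schemes; under the default scheme all
off-diagonal values observed in testing stay within $[0, 1]$ and the
similarity-matrix validator enforces the range.

## Design decisions in open territory

* **Fingerprint.** The cited fingerprint is a hashed path (topological)
  fingerprint; the package uses OpenBabel's FP2 via ChemmineR/ChemmineOB,
  which enumerates linear fragments of length 1–7 onto 1024 bits. The
  length is exposed (`n_bits`), with OR-folding for smaller sizes; 1024 is
  the toolkit's native size. SMILES are used as given — fingerprints depend
  only on the parsed molecular graph, so no canonicalisation step is added.
  Two all-zero fingerprints compare as identical (Tanimoto 1) with a
  warning, since 0/0 is otherwise undefined.
* **Similarity vectors are always defined against the training roster.** In
  cross-validation on one dataset, $K^1$ and $K^2$ are computed once over
  all entities — the coverage constraint guarantees every entity appears in
  training folds. In case-study mode (`rank_candidates()`), unseen drugs
  and an unseen target get similarity vectors computed fresh against the
  stored training rosters.
* **Ambiguity codes** in protein sequences (B, Z, U, O) are mapped to
  standard residues (D, E, C, K) with a warning rather than failing whole
  datasets; X is kept and scored by the substitution matrix's X column.
  Unknown characters are errors.
* **$r_m^2$ orientation.** The statistic
  $r_m^2 = r^2(1 - \sqrt{|r^2 - r_0^2|})$ needs two conventions the
  literature leaves implicit: observations sit on the abscissa and
  predictions on the ordinate for both the with-intercept and
  through-origin fits, and the absolute value is taken under the root
  because $r^2 - r_0^2$ can be negative. Both are fixed and tested against
  an independent least-squares oracle.
* **Concordance index ties.** The normalizer counts only strictly ordered
  label pairs; tied labels contribute to neither numerator nor denominator,
  and tied predictions contribute 0.5 — the survival-analysis convention.
* **AUPR integration** is step-wise (average precision), not trapezoidal,
  to avoid the optimistic interpolation of PR curves; tied prediction
  scores collapse to a single PR point.
* **"Nested" cross-validation.** The outer CV is implemented with the fixed
  architecture constants; no inner tuning loop exists because nothing is
  described as tuned. Fold construction deals each target's observations
  round-robin into a randomly ordered fold sequence (guaranteeing the
  coverage constraint whenever a target has enough observations) and then
  rebalances overfull folds by moving pairs whose targets keep a foothold
  in the source fold.
* **Weight initialisation** is Glorot-uniform with zero biases; remaining
  Adam moments use the standard defaults ($\beta_1 = 0.9$,
  $\beta_2 = 0.999$, $\epsilon = 10^{-8}$). One RNG stream seeded by
  `model_config(seed=)` drives initialisation, epoch shuffling and dropout,
  so a seed fixes the whole trajectory bit for bit.
* **Memory.** Grids can be materialised (`build_pair_inputs()` +
  `train()`) or rebuilt per minibatch from the similarity-matrix columns
  (`train_on_pairs()`); the two paths are value-identical, and the
  streaming path bounds memory by one batch — at benchmark scale a full set
  of $n_d \times n_t$ grids would not fit in memory.

## Numerical behaviour and degenerate inputs

Convolutions are computed as im2col + one BLAS matrix multiply; gradients
are exact and are checked against central finite differences in the test
suite. Max-pooling routes each window's gradient to the first position
attaining the maximum, a deterministic tie-break. Prediction is a pure
function of weights and input, invariant to batch partitioning up to
floating-point roundoff (~1e-15 relative).

Degenerate metric inputs fail loudly rather than silently: a concordance
index over fully tied labels, an $r_m^2$ with zero variance, or an AUPR
whose binarization leaves one class are signalled as errors (the CV driver
downgrades a single-class AUPR to `NA` with a warning, since a small fold
can legitimately be one-sided). The $r_m^2$ square root amplifies
floating-point noise when $r^2 \approx r_0^2$ (an input difference of 1e-16
becomes ~1e-8 in the statistic), which the tests acknowledge with a
correspondingly looser tolerance on exact-fit cases.

Grids smaller than the receptive field of the network (9 × 9 with the
default architecture) are a configuration error reported with the required
minimum size.

## The synthetic-data generator

`synthetic_spec()` describes a small study with a *planted,
similarity-recoverable* signal; it exists so that every stage — parsing,
fingerprints, alignment, grids, training, evaluation — can be exercised
end-to-end without any external download.

* Drugs are built from cluster-specific ring scaffolds (benzene,
  piperidine, naphthalene, tetrahydrofuran, ...) decorated with enumerated
  substituents (alkyl chains of 1–5 carbons, terminal O/N/F/Cl/Br). Every
  SMILES is valid by construction, and drugs sharing a scaffold share many
  atom paths, so within-cluster Tanimoto similarity exceeds between-cluster
  similarity.
* Targets are copies of a per-cluster random consensus sequence
  (length 100–300) with substitutions at 5% of positions, so within-cluster
  alignment similarity exceeds between-cluster similarity.
* Affinities are $y_{ij} = 5 + s\,E_{c(i),c(j)} + \varepsilon$ with a
  cluster-effect matrix $E$ drawn once per seed from a standard normal,
  signal scale $s$, Gaussian noise $\varepsilon$, and independent masking of
  cells at the missing rate. The scale is recorded as pKd-like.

The reference conditions — 20 drugs × 15 targets, 4 × 3 clusters, signal
2.0, noise 0.3, 10% missing — are the generator defaults and are what the
recovery test trains on: a model trained on two of three folds reaches a
held-out concordance index well above 0.7 and beats the constant-mean
baseline MSE. Test-suite problem sizes (tens of entities, a few hundred
pairs) were chosen so the full pipeline runs in seconds to minutes on one
CPU; they are stated here as the package's own verification scale.

What passing these tests shows is that the pipeline recovers a
similarity-driven signal it is known to contain. What they do **not** show
is performance on real kinase panels: real affinity data have censored
floors (the spike of weak binders reported at the assay limit), heavy-tailed
measurement error, chemical series far more related than random scaffolds,
and similarity structure only partly predictive of affinity. Benchmarks on
real data require the corresponding downloads and hours of training and are
outside the test suite's scope.

## Known limitations

* The model is transductive in spirit: predictions for entities far from
  both training rosters degrade to uninformative similarity vectors near
  zero, and nothing flags extrapolation.
* Fingerprint choice is fixed to one path-based family; ECFP/Morgan or
  descriptor-based similarities are out of scope.
* The CNN is implemented in R linear algebra. This is entirely adequate at
  the roster sizes the package targets (tens to hundreds of entities);
  benchmark-scale training (thousands of drugs) is possible via the
  streaming trainer but slow compared to GPU frameworks.
* No uncertainty quantification is attached to predictions; the CV
  replicates are emitted precisely so downstream statistics can be done
  externally.
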
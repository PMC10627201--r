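---
title: "Predicting m5U sites from sequence and graph-embedding features: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting m5U sites: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

5-methyluridine (m⁵U) is among the most common post-transcriptional RNA
modifications; experimentally mapped sites (miCLIP-seq, FICC-seq, nanopore
direct RNA sequencing) are expensive to obtain, so sequence-based
classifiers are used to prioritise candidate uridines. `m5ugraph`
classifies 41-nt RNA windows with a uridine at position 21 as modified or
unmodified. Its representation has two halves:

1. **Sequence-derived features.** Seven encoders turn a window into a
   433-dimensional vector: the k-spaced nucleotide pair spectrum (NPS, 48
   features at `d_max = 2`), composition/transition/distribution
   descriptors (CTD, 40), Bi-profile Bayes per-position class posteriors
   (82), electron–ion interaction pseudopotentials (EIIP, 41), pseudo
   k-tuple nucleotide composition (PseKNC, `4^k + lambda` = 18 at the
   defaults), nucleotide chemical properties with cumulative density
   (NCP-ND, 164), and position-specific nucleotide pair propensities
   (NPPS, 40 at `xi = 1`).
2. **Graph-embedding features.** A sample–sample similarity network is
   learned with the fast linear neighborhood similarity approach (FLNSA):
   each sample is reconstructed as a convex combination of its
   `floor(K (m-1))` nearest neighbours by minimising
   $\tfrac12\lVert X-(C\odot W)X\rVert_F^2$ subject to
   $(C\odot W)e=e,\ W\ge 0$, with tradeoff $\mu = 3$ on the row-sum
   penalty. The symmetrised, binarised weight support defines an
   undirected graph whose nodes are embedded by three unsupervised
   methods — SocDim (top eigenvectors of the modularity matrix
   $B = A - dd^\top/2m$), Node2Vec (biased second-order random walks fed
   to skip-gram with negative sampling), and GraRep (SVD of truncated
   log k-step transition matrices) — 32 dimensions each by default.

The fused 529-column matrix trains a gradient-boosted tree classifier
(XGBoost; 500 rounds, depth 6, learning rate 0.1, subsample 0.8 — the
booster reports none of these from upstream work, so they are exposed in
`booster_config()`). Evaluation reports Sn, Sp, ACC, MCC and the
rank-statistic AUROC under holdout (8:2 stratified), stratified k-fold
cross-validation, and cross-group (technique/cell-line) protocols.

## Inductive versus transductive scoring

A network "encompassing the entire dataset" lets test samples shape the
graph that produces their own features. The package defaults to the
inductive construction: every fitted object — profiles, feature scaler,
neighbourhoods, FLNSA weights, embeddings, booster — derives from training
samples only, and a new window is scored by solving one FLNSA row against
the training samples and averaging their embeddings with the resulting
convex weights (`project_new_nodes()`). Projecting a training sample onto
its own graph returns its embedding exactly, so the two constructions
agree where they overlap. `transductive_evaluate()` reproduces the
whole-dataset construction for comparison; its supervised state is still
training-only.

## Numerical choices

* **FLNSA update on standardized features.** The multiplicative update's
  numerator $XX^\top + \mu ee^\top$ must be nonnegative for the iterate to
  stay in the feasible orthant; z-standardized features violate this. We
  shift the Gram matrix by $c_0 = \max(0, -\min(XX^\top))$, which is
  exactly the update for an input augmented with one constant column
  $\sqrt{c_0}$: on the constraint set $(C\odot W)e=e$ the augmentation
  changes the objective by a constant, so the constrained solution is
  unchanged. After the multiplicative phase converges (max relative
  change `< 1e-6` or 500 iterations) each row is finished with an exact
  equality-constrained active-set solve warm-started from the converged
  support. Renormalisation alone leaves the rows roughly $10^{-2}$ from
  the constrained optimum; the finish brings them to $10^{-10}$, and the
  row-sum constraint holds exactly. The objective (reconstruction +
  row-sum penalty) is non-increasing over the multiplicative phase and is
  exposed with `fit_weights(..., trace = TRUE)`.
* **Neighbourhood ratio `K = 0.3`.** The ratio is not reported upstream;
  0.3 guarantees at least one neighbour for any `m >= 5` and leaves the
  graph sparse enough for community structure. Ties in the distance
  ranking break toward the lower sample index, so duplicate rows are
  deterministic, never an error.
* **Binarised adjacency by default.** "Undirected and unweighted" and
  "W as the adjacency matrix" conflict (W is weighted and asymmetric);
  the default takes an unweighted edge wherever either direction carries
  positive weight, and `adjacency_mode = "weighted"` keeps
  $(W + W^\top)/2$ available.
* **SocDim eigensolver.** Top-algebraic eigenpairs of $B$ are computed by
  Lanczos with full reorthogonalisation over the matrix-free product
  $Bx = Ax - d(d^\top x)/2m$, shifted by $2\max_i d_i$ so the algebraic
  order matches the magnitude order. When the Krylov dimension reaches
  the node count the factorisation is exact; tests verify agreement with
  a dense eigendecomposition to $10^{-8}$ on 20-node graphs. Eigen/SVD
  sign indeterminacy is fixed by making each column's largest-magnitude
  entry positive. The modularity normalisation uses the total degree for
  $2m$ (the standard definition, under which $Be = 0$ identically).
* **Node2Vec.** Walks (10 per node, length 80) and skip-gram with
  negative sampling (window 5, 5 epochs, 5 negatives, unigram^0.75
  distribution, linear learning-rate decay) are implemented in C++ and
  draw from R's RNG, so a single seed fixes the embedding bitwise.
  `p = q = 1` by default (the unbiased walk); the BFS/DFS-like regimes
  are reachable through `p`, `q`.
* **GraRep.** $\beta = 1/m$ and truncation of negative log-ratios at 0,
  the cited algorithm's standard choices; the per-step rank is
  `dim %/% k_max` with the remainder assigned to the 1-step block, and
  rank-deficient steps are zero-padded.
* **Smoothing.** Bi-profile tables use additive pseudocount
  `(count + pc)/(n + 4 pc)`; NPPS conditionals use
  `(pair + pc)/(single + 4 pc)`, which keeps them in (0, 1] and summing
  to one over the conditioned base. Default `pc = 1`.
* **Feature scaling.** Raw encoder outputs feed the tree model unscaled
  (trees are scale-invariant); distances for neighbour selection use
  per-column z-standardisation with training-fold statistics.

## Interpretation choices where the source text is ambiguous

* CTD "four nucleotide transitions" cannot index adjacent-pair
  transitions; all 16 ordered dinucleotide transition frequencies are
  used. The distribution descriptor takes the relative positions of the
  first occurrence and the occurrences at 25/50/75/100% of each
  nucleotide's count (0s when absent) — the standard CTD-D rule.
* The NCP coordinate formulas are typographically corrupted in the source
  (all three printed identical); the standard ring/hydrogen-bond/
  functional-group code A=(1,1,1), C=(0,1,0), G=(1,0,0), U=(0,0,1) is
  used, with the cumulative prefix density as the fourth channel.
* The NPPS dimension "C²" is undefined; we emit one feature per position
  and spacing (`L - xi` each), which carries the same pair-propensity
  information position-resolved.
* The PseKNC structural property table lives in an unavailable
  supplementary file; the package ships published RNA duplex step
  parameters (Shift, Slide, Rise, Tilt, Roll, Twist) for the 16
  dinucleotides, z-standardised before use since the correlation factor
  is scale-sensitive. The table is a replaceable argument of
  `encoder_config()`.
* The printed specificity formula TN/(TN+FN) contradicts the name and the
  MCC partition; the standard Sp = TN/(TN+FP) is implemented.
* Bi-profile Bayes is used purely as a feature encoder; the sign decision
  function's weight vector is never trained separately, matching how the
  pipeline consumes the posteriors.

## The synthetic benchmark

`generate_windows()` emulates the benchmark's shape — fixed-length
windows, centre U, balanced positive/negative classes, optional
technique/cell-line tags — without any download. Negatives are i.i.d.
draws from the background composition (uniform by default); positives mix
a fixed, documented PWM into the ±5 flank around the centre at weight
`motif_strength` (default 0.8). The PWM echoes the G-rich upstream /
UC-rich downstream context of tRNA T-loop m⁵U sites and is deliberately a
per-position signal rather than a k-mer implant so positional,
compositional and pair-based encoders all see part of it. At
`motif_strength = 0` the classes are exchangeable, which calibrates the
null (cross-validated AUROC ≈ 0.5).

What the generator does **not** emulate: transcript context and genome
coordinates, sequencing error profiles, technique-specific biases,
class imbalance, or dependence between positions beyond the PWM.
Passing tests on synthetic data therefore demonstrate that the pipeline
recovers a planted positional signal without leakage — not that it
attains any particular accuracy on real transcriptomes.

## Problem sizes and runtime

The standard synthetic experiments use 400 windows (200/200), the size at
which the default pipeline comfortably separates the planted motif
(5-fold cross-validated AUROC above 0.9, holdout AUROC ≈ 0.88–0.95
depending on the generator seed) while a full 5-fold cross-validation
completes in roughly two minutes on one CPU. Unit and property tests use
smaller instances (tens of samples, reduced walk counts and boosting
rounds) chosen to exercise the same code paths quickly.

## Known limitations

* The FLNSA graph is dense in memory (`m x m`); the implementation
  targets the few-thousand-sample regime of site-prediction benchmarks,
  not transcriptome-scale inputs.
* Skip-gram embeddings are stochastic by nature; they are reproducible
  under the run seed, but embedding geometry (and downstream AUROC within
  a few points) varies across seeds.
* Ambiguity codes (N, etc.) are rejected rather than imputed; windows
  must be pre-extracted (no BED/GFF handling).
* The configuration file format is YAML (flat and diff-friendly); all
  generator and model settings are recorded in the run manifest for exact
  re-runs.
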
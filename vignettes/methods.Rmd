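---
title: "Methods: alignment-weighted multiple-kernel prediction of DNA-binding proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-weighted multiple-kernel prediction of DNA-binding proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbpmkl)
```

# The model

`dbpmkl` treats DNA-binding protein detection as binary classification
of protein sequences, `y ∈ {+1, −1}`. The pipeline has four stages:

1. **Descriptors.** Six fixed-length vectors per protein. Three need
   only the sequence — global encoding (GE), the multi-scale
   composition/transition/distribution descriptor (MCD), and the
   normalized Moreau–Broto autocorrelation (NMBAC) — and three consume a
   PSI-BLAST position-specific scoring matrix (PSSM): pseudo-PSSM
   (PsePSSM), average blocks (PSSM-AB), and wavelet statistics
   (PSSM-DWT). The sequence descriptors capture composition and local
   physicochemical order; the PSSM descriptors capture evolutionary
   conservation, which is empirically the stronger signal for
   DNA-binding.
2. **Kernels.** Each descriptor matrix is min–max scaled on the
   training samples and mapped to an RBF Gram matrix with a per-feature
   bandwidth γ. Linear, polynomial, and sigmoid kernels are available
   behind the same interface for comparisons; RBF is the default.
3. **Kernel fusion.** Weights β on the probability simplex maximize the
   centered alignment between the combined kernel and the ideal (label)
   kernel `y y'`, regularized by a graph-Laplacian term that pulls the
   weights of mutually similar kernels together. This is the convex QP
   `min β'(M + λL)β − 2β'a` subject to `β ≥ 0, Σβ = 1`, solved exactly
   by a dual active-set method (quadprog).
4. **Classifier.** A C-SVM on the combined precomputed kernel; its
   box-constrained dual is also solved exactly with quadprog, and the
   bias comes from the KKT conditions at free support vectors (bound
   midpoint fallback when none are free; `sign(0)` maps to +1).

The key modelling assumption is that each descriptor family is
individually weakly informative and differently noisy, so a convex
combination weighted by label alignment outperforms both the best
single kernel and the uniform average when some kernels are noise.

## The alignment quantities

With `U = I − (1/N)11'` the centering projection (applied by row/column
mean subtraction, never materialized):

* `a_i = ⟨U K_i U, y y'⟩_F`, computed as the quadratic form `y'(U K_i U)y`;
* `M_ef = ⟨U K_e U, U K_f U⟩_F`, a Gram matrix under the Frobenius
  inner product, hence positive semidefinite;
* `W_ef` is the Frobenius cosine between the **raw** kernels, `D` its
  degree matrix and `L = D − W` the Laplacian. Using raw kernels for W
  is a deliberate choice — the centered products already live in `M`,
  and W's role is only to say which kernels are redundant; a
  `centered_w` switch flips the convention.

The ideal kernel is used **uncentered**, exactly as the criterion is
usually written; for balanced labels (`Σy = 0`) the centered and
uncentered conventions coincide because `U y = y`.

A scale note that matters in practice: `a` and `M` are raw Frobenius
sums and grow like `N²`, while `L` stays O(1). At realistic sample
sizes a λ in [0, 1] is therefore a mild perturbation: it breaks ties
and smooths near-degenerate optima rather than forcing uniformity.
The smoothing limit is still exact — as λ → ∞ the weights converge to
uniform, which the test suite checks at λ = 10⁶ together with the
monotone decrease of the weight variance along λ ∈ {0, 0.8, 10, 100, 10⁶}.

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `lg_max` | 30 | maximum NMBAC lag (residues); grid-searched optimum on the curated benchmark |
| `lag_max` | 10 | maximum PsePSSM lag (residues); same protocol |
| `n_blocks` | 20 | PSSM-AB blocks; yields the conventional 400-dimensional descriptor |
| `wavelet`, `levels` | db4, 4 | PSSM-DWT analysis filter and depth; stable for sequences ≥ 50 residues |
| `gammas` | 2⁰, 2⁻⁵, 2⁻¹, 2⁻⁴, 2⁻⁵, 2⁻⁵ | per-kernel RBF bandwidths (GE, MCD, NMBAC, PSSM-AB, PSSM-DWT, PsePSSM), tuned once on the curated benchmark; shipped defaults, not universal constants |
| `lambda` | 0.8 | Laplacian smoothing strength, tuned on a 0–1 grid (step 0.05) |
| `C` | 2 | SVM box constraint for combined kernels; `grid_search_C()` re-tunes over 2⁻⁵…2⁵ with stratified 5-fold CV, ties toward smaller C |
| `strategy` | `"cka"` | `"mean"` reproduces the uniform-weight comparator; `"single:<name>"` isolates one kernel |

Feature scaling is min–max to [0, 1] per dimension because the γ grid
spans 2⁻⁵…2⁵, which presumes unit-scale features; test samples are
transformed with the training scaler and clipped, so no test
information reaches training. Min–max bounds, kernel weights and the
SVM are re-estimated inside every cross-validation fold
(`global_weights = TRUE` reproduces the non-nested reading where
weights are estimated once on the full dataset).

# Numerical choices

* **Population standard deviation** (divide by n) everywhere a
  standardization occurs: the six NMBAC property scales over the 20
  residues and the PSSM columns over positions. Constant columns map
  to zeros rather than erroring.
* **Remainder rule**: when a sequence does not divide evenly into
  blocks/segments/quarters, leading pieces absorb the extras —
  deterministic and length-stable, shared by GE, MCD and PSSM-AB.
* **QP ridge**: both simplex and SVM duals add a relative ridge of
  1e-8 on the quadratic term so that exactly singular problems
  (identical kernels, duplicated samples) factorize; the reported
  objective is evaluated on the unridged problem. Weights below
  −1e-9 are solver failures; tiny negatives are clipped and the vector
  renormalized.
* **DWT boundary**: half-point symmetric extension; the analysis
  filters are the orthonormal Daubechies family, so a constant signal
  c yields approximation mean c·2^(level/2) exactly — the closed form
  the tests pin, alongside coefficients frozen from an independent
  wavelet library.
* **MCC 0/0 → 0**, the common convention for degenerate confusion
  margins; AUC uses midranks for ties (the Wilcoxon statistic), which
  equals the trapezoidal ROC area.
* **Sensitivity at fixed specificity** is conservative: the best
  sensitivity among operating points whose specificity is *at least*
  the target (the all-negative point guarantees one always exists).

# Design decisions on open constructions

The GE and MCD descriptors are named rather than specified in the
descriptor literature this package follows, so their constructions are
fixed explicitly as configuration conventions (not claims about any
particular prior implementation):

* GE: 6 physicochemical classes — {A,V,L,I,M,C}, {F,W,Y,H}, {S,T,N,Q},
  {K,R}, {D,E}, {G,P} — and 1+2+4+8 = 15 segments from three successive
  halvings; per segment 6 compositions + 15 unordered class-pair
  transition frequencies → 315 values.
* MCD: 7 classes — {A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K},
  {D,E}, {C} — quarters Q1..Q4, the 10 contiguous runs plus the
  discontinuous unions Q1∪Q3, Q2∪Q4, Q1∪Q4, Q1∪Q2∪Q4; each region
  contributes composition (7), transitions (21) and the distribution
  descriptor (35: relative positions of the 1st/25%/50%/75%/last
  occurrence per class, zeros for absent classes) → 882 values.
  Discontinuous regions are concatenations, so one artificial junction
  pair enters their transition counts — accepted for determinism.
* PsePSSM standardizes the profile first and uses the standardized
  matrix for both its mean block and its lagged squared-difference
  block — one convention throughout rather than a mixed raw/normalized
  scheme. (Because the autocorrelation descriptors' definition says
  "normalized", property scales are likewise standardized before use.)
* PSSM-DWT keeps approximation-coefficient statistics only
  (max/min/mean/sd per level), which is dimension-deterministic for
  any sequence length ≥ 50; detail statistics and other wavelets are
  config options.
* Dataset filter: any letter outside the 20 canonical residues removes
  a record (a superset of the usual 'X' rule), because every property
  table and class grouping downstream is defined only for the 20.

# The synthetic benchmark generator

`make_fixture_dataset()` emulates the *shape* of the curated
benchmarks: canonical-alphabet sequences of at least 50 residues,
one integer PSSM in [−10, 10] per record, balanced ±1 labels. Class
signal enters twice — positives and negatives draw residues from
compositions tilted in opposite directions proportionally to
`signal_strength`, and PSSM column means shift with the same sign
pattern — so both the sequence-only and the profile-based descriptors
are informative, and `signal_strength = 0` is an exact null.

What it does **not** emulate: real residue order statistics (sequences
are i.i.d. given composition, so NMBAC/MCD order information is weak),
real PSSM structure (no alignment depth, no conservation blocks), class
imbalance, and homology between records. Consequently, passing tests
demonstrate correctness of the machinery and leakage-free evaluation —
not biological performance. Default study conditions used by the tests
and the acceptance script: 60+60 records of length 60–120 at signal 0.8
for end-to-end recovery (5-fold), 20+20 at signals 1.0/0.0 for the
LOOCV checks, 30+30 for the kernel-selection fixture, and random
3–4-kernel problems at N = 20–30 for the QP oracle battery.

One measured artifact worth knowing: **leave-one-out on balanced null
data is anti-learning-biased.** The held-out sample's class is always
the training minority (19 vs 20), so a classifier with no signal votes
with the training majority and lands systematically *below* chance
(measured ACC 0.10, AUC 0.015 on the null fixture). This is a property
of LOOCV itself, not a leak; the two-sided near-chance band is
therefore asserted on balanced 5-fold splits (measured ACC 0.50), and
LOOCV on null data is only required not to show spurious signal.

# Known limitations

* The QP solvers are dense and exact: fine up to a few thousand
  samples, not intended for tens of thousands (no SMO-style
  decomposition, no kernel approximation).
* PSI-BLAST itself is out of scope — profiles are consumed, not
  generated — as is redundancy reduction of input sets; both belong to
  upstream curation.
* Shipped bandwidths and `lambda` were tuned on one curated benchmark;
  for new data re-run `grid_search_C()` and the λ grid rather than
  trusting the defaults.
* No probability calibration and no class weighting (the benchmark's
  525/550 imbalance is mild); decisions are raw SVM margins.
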
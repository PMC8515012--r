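---
title: "Models and methods behind facefwd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind facefwd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`facefwd` studies how behavioral models of face-identity categorization can
be grounded in the interpretable coordinates of a generative face model.
This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The generative model of faces

A face database is a matrix of `N` exemplars by `V * 3` vertex coordinates
(interleaved x, y, z; arbitrary length units). The model separates two
sources of variation:

* **Demographic effects** are absorbed by a general linear model
  `S = X A + E`. The design matrix contains, in fixed order: a constant,
  sex (0/1), age (continuous, in years), ethnicity dummies (treatment
  coding against the first level; a three-level factor gives two dummies),
  then all two-way and three-way interactions. With the full factor set
  this is 12 columns. Age is centered before interactions are formed to
  reduce collinearity; the centering constant is stored so new faces are
  coded consistently.
* **Identity variation** is the residual `E`, decomposed by an economy SVD.
  The orthonormal coordinate basis `U` spans identity space.

**Component scaling.** Identity components are stored unit-variance: raw
basis coordinates are divided by `d / sqrt(N - 1)` and synthesis multiplies
the scale back. The source convention is not dictated by the mathematics;
unit variance makes component magnitudes comparable across basis directions
and lets stimulus generators draw components from a standard normal.

**Texture** is a single flattened band by default, fit exactly like shape.
A multi-band (Gaussian-pyramid-like) container would simply repeat the
per-band fit; nothing else in the pipeline depends on the band structure.

**Amplified faces.** `F = G ⊙ (C α) + prototype ⊙ (1 − C α)` mixes a
ground-truth face `G` and the categorical average per vertex, with the
per-vertex weight `C ∈ [0, 1]` broadcast to all three coordinates.
`C α > 1` extrapolates beyond the ground truth; it is permitted and logged,
because the amplification grids used for tuning deliberately overshoot.

## The synthetic world

Everything the original experiments measured is generated in-repo with
known ground truth, so recovery can be tested:

* `generate_face_database()` plants a known demographic coefficient matrix
  and a low-rank identity structure (default rank 40 at full scale, 8 in
  the tiny profile) on a sphere-like Fibonacci-lattice vertex layout.
  The geometric singular-value decay (ratio 0.85) gives a realistic
  dominant-component spectrum. Defaults at full scale (355 exemplars,
  4,735 vertices) mirror the reference experiment's dimensions.
* `simulate_session()` implements a choose-1-of-6-then-rate observer.
  The observer scores a candidate by the negative weighted squared
  distance of its identity components to a hidden template (a weighted
  Euclidean family), or optionally by a linear projection ("linear-SRF"
  observer); Gaussian noise is added to the score. **Rating model:** the
  human rating process is unknowable, so ratings are the 6-quantile bin of
  the chosen score within the session. This makes ratings a monotone
  function of similarity and reproduces full use of the 6-point scale
  (equipopulated up to ±1 by construction) — both properties are tested.
  What it does *not* emulate: sequential effects, learning, response
  times, or idiosyncratic scale use; a green test therefore establishes
  estimator correctness under a well-behaved observer, not robustness to
  every human quirk.
* `generate_embedding()` stands in for trained-network embedding layers:
  channels are orthonormal linear images of shape and/or texture
  components at configurable fidelity, optionally squashed (tanh), plus
  channel noise, finally standardized. At fidelity 1 and zero noise the
  components are exactly linearly decodable — the anchor for the decoding
  tests. Real embedding layers are of course not linear images of
  generative coordinates; the generator emulates their *information
  content*, not their geometry.
* All generators are pure functions of (configuration, seed).

**Target demographics.** In the pipeline all simulated targets share the
same demographic factor values. With differing demographics, the per-target
forward-model scores acquire large constant offsets from the prototype
difference, and the within-target min–max normalization of the
identification stage is then dominated by these offsets rather than by
identity information (image-based models do not have this pathology, since
they never project a face against another identity's prototype). Fixing
shared demographics isolates what the generalization test is about:
identity structure.

## Forward models

`nested_cv_fit()` divides the trials into consecutive blocks (200 at full
scale; the block structure is never shuffled, preserving session order).
Each block serves once as the outer test set; within each outer fold each
remaining block serves once as the inner validation set. Ridge weights use
the closed form `B = (XᵀX + R)⁻¹ Xᵀy` via a Cholesky solve, with `R`
diagonal and constant within each predictor subspace, so joint spaces get a
dedicated penalty per subspace.

* **Standardization.** Predictors are z-scored and responses centered on
  training statistics inside every fit (the closed form has no intercept).
  This is not dictated by the source formulation; it makes per-subspace
  penalties comparable across channels of different scales and is flagged
  as a choice.
* **Penalty search.** Instead of a stochastic black-box optimizer, a
  deterministic search on the log2 scale: coordinate-wise coarse sweep
  (step 6) over exponents in [−30, 30] starting from 2¹⁷, two passes, then
  local refinement with steps 3 and 1.5, with an evaluation cap of 200.
  The objective is Kendall's tau-b between validation predictions and
  responses. Ties are broken toward the *smaller* penalty (less shrinkage
  at equal rank fit) — this tie-break is what makes self-re-prediction
  return the original weights exactly. The final per-subspace penalty is
  the median across inner folds; the model is refit on the full
  development set and predicts the untouched test block, so every trial
  receives exactly one out-of-fold prediction (leakage is tested by label
  injection).
* **Tau variant.** Whether the original tuning objective corrected for
  ties is not documented; tau-b (tie-corrected) is used, which matters
  because 6-level ratings are heavily tied. With quantile-binned ratings
  the attainable tau-b of a perfect monotone predictor is about
  `sqrt(5/6) ≈ 0.913`, which calibrates what "good" means in the tests.

`srf_and_repredict()` interprets embedding-based fits by re-predicting
their predictions from shape features per outer fold, yielding simulated
predictions and simulated shape weights whose per-fold correlations with
the originals are the two reported diagnostics. `decode_shape()` measures
what shape information an embedding carries independently of behavior,
tuning one ridge decoder per component (log2 penalty grid, tuning-set MSE)
and mapping test-set errors to a per-vertex mean Euclidean error.

## Information-theoretic evaluation

Predictions and responses are discretized by rank-based equipopulated
binning (3 bins): tied values always share a bin, distinct values give
counts equal up to ±1. Mutual information adds the Miller–Madow correction
`(K_occupied − 1) / (2 n ln 2)` per entropy term, with `K` counting
occupied cells only (the standard form; the source names the correction
without spelling it out).

Redundancy between two prediction streams about behavior uses the pointwise
common-change-in-surprisal construction: a maximum-entropy joint
constrained by the (s1, t), (s2, t) and (s1, s2) pairwise marginals is
fitted by iterative proportional fitting, and local co-information
`c = i(s1; t) + i(s2; t) − i(s1, s2; t)` is accumulated only at states
where both local source informations and `c` are strictly positive. The
result is clamped to `[0, min(I(s1; t), I(s2; t))]`. Two numerical points:

* When the three pairwise margins are not consistent with any strictly
  positive joint, IPF converges only like 1/iteration. The stopping rule
  (tolerance 1e-10, cap 5000, update order 13 → 23 → 12, uniform start) is
  therefore *part of the definition*; the exhaustive small-alphabet oracle
  in the test suite replicates it and is the normative reference the fast
  path must match.
* The sign rule uses strict positivity. Negative-sign agreement (a
  misinformative redundancy) is excluded; with the final clamp this keeps
  `0 ≤ R ≤ min(I₁, I₂)` by construction.

Noise thresholds are the 95th percentile of the statistic over
trial-shuffled responses. The full procedure uses 100 shuffles;
the tiny test profile uses 25 with a reduced pipeline (a documented
deviation, chosen to keep the suite inside its time budget), while the
calibration acceptance test uses 200 reduced-pipeline repetitions with 100
shuffles each. Per-fold evaluation (one data point per outer test block) is
the default; pooling folds first is available but changes the effective n.

## Reverse correlation

Each vertex coordinate of the chosen faces is regressed on the responses,
`feature = b0 + b1 · r` — note the deliberate feature-on-response
direction, which makes `b0 + α b1` a face-valued function of amplification
`α`. The default estimator is OLS (closed form, vectorized); a robust
bisquare IRLS variant (tuning constant 4.685, 50 iterations) is available
because the original analysis used a robust fit whose parameters are
undocumented. On whitened features the mass-univariate slopes are
proportional to the forward-model weights (tested), which is the sense in
which reverse correlation "inverts" the forward model.

Tuning curves evaluate a responder on `b0 + α b1` for `α` from 0 to 50 in
steps of 0.5; `α = 0` is the average chosen face. Ties take the first
maximum (logged). Linear responders provably give monotone curves that
peak at the grid end; distance-based observers peak in the interior near
the template.

**Inward–outward projection.** Template quality uses, besides the mean
absolute error, the correlation of per-vertex displacements projected onto
a single inward–outward axis. The exact construction of that axis is not
documented in the source; here outward normals are taken as unit vectors
from the vertex-cloud centroid — exact for the sphere-like synthetic
layout, and avoiding a shipped mesh-topology fixture. This is an
interpretation and is labeled as such.

## Generalization testing

A vertex is *faithful* when the permutation-averaged chance reconstruction
is further from ground truth than the actual reconstruction (strict
inequality: "no better than chance" is not faithful). Distances are signed
by the projection onto the outward normal (inside/outside the categorical
average; the source's exact signing is undocumented). The binary
vertices × (observer, target) matrix is decomposed by rank-k NMF
(multiplicative updates, seeded non-negative uniform init, cap 500,
relative tolerance 1e-6 — the source states neither init nor iteration
count). A component contributes to a target when the median of its
loadings over the target's columns exceeds 0.1; the diagnostic weight
`C_D` is the per-vertex max over contributing basis columns, normalized to
max 1.

Generalization stimuli cross two diagnosticity levels, five amplification
levels (0.33, 0.67, 1, 1.33, 1.67) and five conditions (viewing −30/0/+30
as metadata labels — there is no renderer — and age-80 / sex-swap, which
re-derive the categorical average from edited factors): 50 per target.
Identification normalizes each target model's predictions min–max within
target across the stimulus set and takes the argmax across targets (ties
to the lowest index, logged); model accuracies are therefore binary.
Accuracy error against a reference cohort is summarized by medians with
bootstrap percentile intervals — a descriptive substitute for the
hierarchical ordinal model of the original analysis, which needs
probabilistic-programming machinery out of scope here.

## Pipeline profiles and budgets

`run_config("tiny")` (4 observers × 2 targets × 180 trials, 60-vertex
meshes, 25 permutations) completes in about a minute on one CPU and is the
test default; `"paper-scale"` mirrors the reference design (14 × 4 × 1,800,
4,735 vertices, 100 permutations). Every stochastic stage derives its seed
deterministically from the master seed; a rerun with the same config
produces byte-identical result tables (tested).

## Known limitations

* No rendering, lighting or camera model: viewing conditions are metadata,
  and embedding "view robustness" can only be emulated, not measured.
* Synthetic embeddings are (optionally squashed) linear images of
  generative coordinates; conclusions about real network geometry are out
  of reach by design.
* The rating model is an assumption; alternative monotone rating schemes
  would change absolute information levels (not the orderings the tests
  assert).
* Hierarchical Bayesian group models of the original analysis are replaced
  by descriptive bootstrap summaries throughout.
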
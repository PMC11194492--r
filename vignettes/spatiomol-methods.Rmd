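---
title: "Methods: whole-brain spatiomolecular gradient analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain spatiomolecular gradient analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

During brain development, morphogens diffuse from patterning centers and set
up roughly orthogonal concentration gradients along the rostral-caudal,
dorsal-ventral and medial-lateral axes. Downstream of these signals, sets of
genes end up expressed in graded spatial patterns. `spatiomol` asks whether
and how such *directional* expression gradients are measurable in a
sample-by-gene expression matrix annotated with 3D stereotaxic coordinates,
and provides the machinery to validate, replicate, and annotate them.

The core statistic is a two-block partial least squares (PLS2) regression of
coordinates on expression. Let $X$ be the $n \times g$ expression matrix
with each gene z-scored, and $Y$ the $n \times 3$ coordinate matrix,
centered but **not** scaled, so that prediction errors stay in millimetres.
Components are extracted sequentially; for component $j$:

* $w_j$ — the unit-norm gene weight vector, the leading left singular
  vector of $X_j^\top Y$ (where $X_j$ is the $j$-times-deflated $X$);
* $t_j = X_j w_j$ — the *latent transcriptomic variable* (the gradient's
  expression score per sample);
* $p_j = X_j^\top t_j / t_j^\top t_j$, $c_j = Y^\top t_j / t_j^\top t_j$ —
  x- and y-loadings;
* $u_j = Y c_j / \lVert c_j \rVert$ — the *latent spatial variable*;
* deflation $X_{j+1} = X_j - t_j p_j^\top$ ($Y$ is not deflated).

Coordinates are predicted as $\hat{Y} = X_{std} B + \bar{y}$ with
$B = W (P^\top W)^{-1} C^\top$. Internally the leading singular vector is
obtained from the $3\times3$ symmetric eigenproblem of
$(X_j^\top Y)^\top (X_j^\top Y)$, which is exact and cheap because the
response block has at most three columns; the test suite verifies every
extraction step against an independent dense-SVD route.

Each component's sign is arbitrary in the algebra. We anchor it so the
coordinate axis with the largest $|c_j|$ loading is positive (ties broken
x < y < z). All replication correlations are reported on anchor-aligned
scores; no sign is ever forced on a reported correlation.

Z-scoring genes makes weights comparable across genes with different
expression scales; centering-only on coordinates keeps the headline error
metric interpretable (mm). Genes with zero variance are dropped with a
warning rather than epsilon-regularized: they carry no information and any
regularization constant would leak into the weights.

## What the synthetic generator emulates

`generate_brain_cloud()` samples tissue positions uniformly in an ellipsoid
(default semi-axes 70, 85, 65 mm — roughly a human brain's extents).
`plant_gradients()` builds expression that is *exactly linear in space
before noise*: orthonormal directions $d_k$ are drawn at random (seeded),
each gradient recruits a random subset of genes, and
$\mathrm{expr}[s,g] = \sum_k L_{gk}\, (d_k \cdot x_s) + \varepsilon$ with
Gaussian noise. The per-gradient signal-to-noise ratio
(loading scale × SD of the spatial projection / noise SD) defaults to 4 and
is recorded in the emitted ground truth.

Two design points deserve explanation because they are what makes the
planted model *identifiable*:

1. **Graded recruitment.** After per-gene z-scoring, the amplitude of a
   gene's loading saturates out of the fit (the standardized slope tends to
   $1/\mathrm{sd}(\text{projection})$ at high SNR). If all gradients
   recruited equally many genes they would have identical effective
   strength, and PLS could only recover their joint 3-D span — any rotation
   within it is equally good. The default recruitment fractions are
   therefore graded, `c(0.25, 0.15, 0.08)`, giving the gradients distinct
   strengths, just as the real-data gradients are plainly ordered (the
   first component dominates).
2. **Isotropic clouds for direction-recovery studies.** In an anisotropic
   cloud the coordinate covariance pins the within-span rotation of the
   fitted components to the cloud's principal axes rather than to the
   planted directions. The canonical recovery study therefore samples a
   75 mm sphere; the brain-shaped ellipsoid remains the default everywhere
   identifiability of *individual* directions is not at stake (replication,
   development, cross-validation).

With that design, the fitted latent spatial variables match the planted
projections with $|r| > 0.95$ (typically > 0.98) across seeds at the
canonical scale of 2000 samples × 2000 genes.

What the generator does **not** emulate: gene-gene co-expression beyond the
planted gradients, donor batch structure, nonlinear or regionally bounded
expression patterns, and measurement designs where genes are censored
non-randomly. Passing recovery tests therefore demonstrates correctness of
the inference machinery on linear-in-space signal, not robustness to every
property of real atlas data.

### Replication and developmental series

`make_external_replica()` emulates external cohorts: samples scattered
around a fixed panel of region centroids, a random subset of genes kept,
expression regenerated from the same ground truth plus individual noise.
Similarity to the discovery gradients is measured exactly as for real data:
region-averaged component scores correlated over shared regions, with a
region-label permutation null (exact enumeration when 8 or fewer regions,
seeded Monte-Carlo with the add-one formula otherwise).

`make_developmental_series()` models consolidation with a logistic
*fidelity* curve per gradient, $f_k(a) \in [\text{floor}, 1)$ over log age
in post-conception weeks (default midpoint 40 pcw, i.e. birth). Fidelity
does not simply scale the adult signal — a pure rescale would leave
correlations with the adult pattern at exactly 1 in the noise-free limit,
because correlation is scale-invariant. Instead fidelity *mixes* the adult
gradient with a fixed, spatially incoherent "immature" regional pattern:
$f \cdot \text{adult} + (1-f) \cdot \text{immature}$. Similarity-to-adult
is then a strictly increasing deterministic function of fidelity, which is
the behavior the developmental analyses are designed to detect: a floored
curve for the first gradient (adult-like early, as observed for the
dominant rostral-caudal component) and zero-floor ramps for the others.
Age-grid choices for monotonicity checks stay on the rising phase of the
logistic (8-200 pcw); past saturation the differences fall below numerical
resolution and rank checks become meaningless.

Developmental epochs default to prenatal < 40 pcw, postnatal 40-976 pcw
(birth to ~18 years), adult > 976 pcw. These are declared, configurable
defaults. An epoch gene plan restricts each gradient gene's adult-patterned
expression to one epoch (noise only outside it), with a seeded fraction of
"nontransitional" genes active at all ages; `nontransitional_genes()`
recovers them by k-means on per-gene similarity trajectories, selecting the
cluster whose centroid has the largest minimum over ages.

## Model selection and stability

The number of components is chosen by repeated k-fold cross-validation
(default 10 folds × 10 repeats) on the mean held-out Euclidean error in mm,
with the one-standard-error rule (`argmin` by flag). Nested-model
coefficients come from a single maximal fit per fold, so the error curve is
internally consistent and non-increasing on noise-free data. Fold
assignment is sample-level by default; a region-blocked option probes
spatial leakage between neighboring samples.

The spatial-permutation stability test refits the model after permuting
coordinate rows against expression rows (identity excluded) and compares
each null weight vector to the observed one by |cosine| after optimal
pairing. One empirical subtlety, visible in the tests: permuted-fit weights
are *not* near-orthogonal to the observed ones, because gradient genes
remain mutually correlated whatever the coordinates, and PLS weights
concentrate in that covariance subspace (null similarities of ~0.3-0.75).
The observed statistic — split-half weight similarity of the unpermuted
fit — still exceeds the null comfortably at canonical sizes
(p = 0.01 with 99 permutations at 1000 × 1000).

## Cortical surfaces, territories, and spin tests

Component scores are interpolated to a cortical mesh by inverse-distance
weighting over the k nearest samples in anatomical space (k = 10, power 2,
20 mm cutoff — declared, configurable; an exact coincidence returns the
sample value, unreachable or medial-wall vertices are missing). Molecular
territories are k-means clusters (50 restarts, seeded) of per-vertex
z-scored component triplets, with the number of territories selected by
mean silhouette width over k = 2..10 when not forced.

Parcellation agreement uses the adjusted Rand index (permutation-model
contingency formula) and adjusted mutual information with the
hypergeometric expected-MI correction and arithmetic-mean entropy
normalization — the normalization is stated because variants change the
value. Null distributions for map comparisons come from spin permutations:
a uniform random rotation (QR-orthonormalized Gaussian, determinant fixed
to +1) of the registration sphere, each vertex taking the value of the
nearest original vertex. Spinning reassigns existing values only, so label
maps can be spun with the same index. Spin p-values use the add-one
formula, two-sided on |r|.

Variance-explained comparisons between two gradient sets fit OLS models
with intercept (set A, set B, combined) and bootstrap units for percentile
CIs. The two-sided difference p is computed on raw $R^2$. The combined-gain
p is computed on **adjusted** $R^2$: for nested OLS models the raw-$R^2$
gain is non-negative by construction on every resample, so only the
degrees-of-freedom-adjusted gain is a testable quantity. Collinear combined
predictors fall back to pivoted least squares with a warning.

## Gene annotation

Top gradient-associated genes are taken from the tails of each component's
weight distribution with a family-wise budget: per-tail fraction
$\alpha / (\text{tails} \times \text{components})$ and per-tail count
$\lfloor g \cdot \text{fraction} \rfloor$ — with 15,634 genes, $\alpha =
0.05$, two tails and three components this gives 130 genes per tail
(floor, not rounding, reproduces that count). Ties are broken by gene id so
selection is deterministic. Multi-component membership counts genes in the
union of both tails per component. Overlap with a curated list (e.g.
developmental transcription factors) is tested by drawing reference-sized
random sets from the declared universe; the null mean converges to the
hypergeometric expectation $|\text{reference}|/|\text{universe}|$, checked
against that closed form in the tests.

## Numerical choices and degenerate inputs

* Permutation p-values always use the add-one formula, so $p \in (0, 1]$.
* Fewer than `k` extractable components: an error in strict mode;
  cross-validation uses the relaxed mode, where extra components reuse the
  largest extractable model (adding no signal, as they should).
* Zero-variance response axes in $R^2$, constant aggregate-expression
  vectors, and all-identical trajectory matrices return missing values or a
  degenerate flag with a warning, never a silent number.
* Model serialization is versioned JSON at full double precision;
  mismatched versions and truncated files fail loudly with no partial
  model.
* Missing expression on ingestion: genes with more than 10% missing are
  dropped, the remainder mean-imputed, both logged. This is a declared
  package policy for external data, not an inference about any upstream
  pipeline.

## Problem sizes used by the test suite

Studies in the tests and the acceptance script are sized for stable
statistical behavior at interactive runtimes: recovery at 2000 samples ×
2000 genes over ten seeds with 10-fold × 2-repeat cross-validation;
stability at 1000 × 1000 with 99 permutations; replication with 16 regions
× 4 samples and 999 permutations; spin calibration on a 162-vertex
icosphere with 99 spins × 150 repetitions; overlap nulls with 10,000
draws. These sizes are the package's declared study conditions and are
large enough that all reported checks hold with margin across seeds.

## Known limitations

* Linear gradients only: no reaction-diffusion simulation, no sparse or
  kernelized PLS variants, and at most three spatial response dimensions.
* The spin test assumes an approximately isotropic field on a sphere;
  heavily masked or strongly anisotropic meshes weaken its calibration.
* Cross-species use relies on a user-supplied gene-id mapping table;
  homology inference is out of scope.
* Surface meshes are plain vertex/face tables (OFF); no volumetric
  processing and no registration between different meshes.
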
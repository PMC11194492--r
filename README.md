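# spatiomol

Directional gradients of gene expression — graded patterns that echo the
morphogen gradients of the developing brain — are measurable in adult brain
transcriptomes as systematic variation of expression along 3D spatial axes.
`spatiomol` is an R package for discovering, validating, and annotating such
**spatiomolecular gradients** from a sample-by-gene expression matrix with
per-sample stereotaxic coordinates. It is written for computational
neuroscientists and transcriptomics researchers working with whole-brain
atlas data (dense coordinate sampling) and regional replication cohorts
(region-labeled, coordinate-free sampling).

## The method in brief

The core is a two-block PLS regression cross-decomposing per-gene z-scored
expression $X$ ($n \times g$) with centered coordinates $Y$ ($n \times 3$,
mm). Components are extracted sequentially with X-deflation: $w_j$ is the
leading left singular vector of $X_j^\top Y$, the latent transcriptomic
variable is $t_j = X_j w_j$, the latent spatial variable $u_j \propto Y c_j$,
and coordinates are predicted as $\hat Y = X_{std}\, W (P^\top W)^{-1} C^\top
+ \bar y$. Around that core the package provides:

* **Model selection & validation** — 70/30 out-of-sample coordinate
  prediction (per-axis $R^2$, mean error in mm), repeated 10-fold CV for the
  number of components (one-SE rule), spatial-permutation stability of the
  gene weights.
* **Replication** — shared-gene refits with component re-alignment,
  projection into external regional datasets (optionally through a
  cross-species gene-id mapping), per-individual regional similarity with
  permutation nulls.
* **Development** — similarity-to-adult trajectories over log age
  (post-conception weeks), per-epoch gradient-associated gene sets,
  nontransitional-gene discovery by trajectory clustering.
* **Cortical surfaces** — interpolation of gradients to a mesh, molecular
  territory clustering with silhouette-selected k, ARI/AMI parcellation
  comparison, spin-test nulls, and bootstrapped variance-explained
  comparisons between gradient sets.
* **Gene annotation** — weight-tail gene selection with a family-wise
  budget, multi-gradient membership (Venn) counts, and permutation overlap
  tests against curated gene lists.
* **Synthetic data** — every input above can be generated with planted,
  known ground truth (`generate_brain_cloud()`, `plant_gradients()`,
  `make_external_replica()`, `make_developmental_series()`,
  `make_surface_fixture()`), so the whole pipeline is testable end to end.

See `vignettes/spatiomol-methods.Rmd` for the full model description,
parameter defaults, and design rationale.

## Worked example

Plant three orthonormal gradients in a synthetic brain and recover them:

```r
library(spatiomol)

coords <- generate_brain_cloud(2000, semi_axes_mm = c(75, 75, 75), seed = 1)
sim    <- plant_gradients(coords, n_genes = 2000, k_true = 3, seed = 1)
sim$truth
#> synthetic_truth: 3 planted gradient(s), noise_sd 1
#>   per-gradient SNR: 3.97, 4.05, 3.99

sp  <- split_train_test(sim$dataset, train_frac = 0.7, seed = 1)
fit <- fit_pls(sp$train, k = 3)
fit
#> pls_model: 3 components, 2000 genes, 1400 training samples
#>   latent spatial-transcriptomic correlations: 0.999, 0.999, 1

pred <- predict_coordinates(fit, sp$test)
round(coordinate_r2(sp$test$coords, pred), 3)
#>     x     y     z
#> 1.000 0.999 1.000
mean_prediction_error(sp$test$coords, pred)$mean
#> [1] 1.03   # mm

crossval_component_selection(sp$train, k_max = 3, folds = 10, repeats = 2,
                             seed = 1)
#> cv_result (10-fold x 2 repeats, rule one_se)
#>  k mean_error_mm   se_mm
#>  1        44.310 0.26800
#>  2        27.830 0.34900
#>  3         1.038 0.00786
#> chosen k = 3

select_top_genes(fit$W, alpha = 0.05, n_tails = 2)
#> gene_selection: 16 genes per tail (alpha 0.05 , 2 tails x 3 components)
#>   selected genes: 96
```

The held-out per-axis $R^2$ near 1 and ~1 mm mean error say the three
fitted latent variables recover essentially all planted spatial signal at
signal-to-noise ratio 4; cross-validation picks the planted dimensionality
(k = 3), with the error dropping from ~44 mm (one component) to ~1 mm
(three). The tail selection takes the top 0.05/(2 tails × 3 components) of
genes per tail — 16 of 2000 here; at an atlas-scale 15,634 genes the same
rule yields 130 per tail.

A thin command-line wrapper over the same functions is installed at
`inst/cli/spatiomol.R` (`simulate`, `fit`, `predict`, `replicate`, `genes`).

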
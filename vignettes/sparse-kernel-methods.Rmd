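---
title: "Sparse kernel machines for genome-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse kernel machines for genome-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsekm)
```

## The problem

Genomic selection predicts a line's phenotype from genome-wide marker
dosages so that breeding candidates can be ranked without phenotyping
them all. The workhorse model is the kernel mixed model

$$y = \mu \mathbf{1} + Z u + e, \qquad
  u \sim N(0, \sigma_u^2 K), \qquad e \sim N(0, \sigma_e^2 I),$$

where $K$ is an $n \times n$ genomic relationship (kernel) matrix over
the $n$ lines, $Z$ maps the $N$ phenotype records (line-by-environment
combinations) onto lines, and $h^2 = \sigma_u^2 / (\sigma_u^2 +
\sigma_e^2)$ is the heritability. `sparsekm` implements this model and,
around it, three ideas that together let *any* supervised learner act as
a kernel machine at reduced cost:

1. **Seven kernels.** Linear ($x'z/p$), polynomial, sigmoid, Gaussian,
   exponential, and arc-cosine of depth $L$ (the angular kernel of an
   $L$-layer infinite-width network, applied recursively). The linear
   kernel on centered/scaled markers is the classical genomic
   relationship matrix $XX'/p$.
2. **The kernel-square-root trick.** Any learner that consumes a feature
   matrix can be turned into a kernel machine by handing it
   $Z K^{1/2}$: a ridge-type fit on these features is equivalent to the
   mixed model above.
3. **Sparse (Nyström) compression.** From $m \le n$ anchor lines, the
   design $P = K_{nm} U S^{-1/2}$ (with $K_{mm} = U S U'$) reproduces
   the rank-$m$ approximation $Q = K_{nm} K_{mm}^{-1} K_{nm}'$ of the
   dense kernel as $Q = PP'$, while training touches only $m$ columns.
   The *compression level* is $1 - m/n$.

## Kernel computation choices

**Centering and scaling.** Markers are centered and scaled with the
sample ($n-1$) standard deviation; monomorphic columns are dropped and
logged. The constants are retained so new lines can be transformed
identically (`apply_scaling()`).

**Bandwidths.** No closed convention exists for the Gaussian and
exponential bandwidth on dosage data, so squared distances are divided
by the median nonzero pairwise squared distance of the reference set
(the median heuristic) before applying `gamma` (default 1). This keeps
`gamma` dimensionless across marker densities; `scale_const = 1`
recovers the raw form. Inside `sparse_design()` the constant is computed
once from the **full** line set, so the anchor kernel $K_{mm}$ is an
exact submatrix of the dense $K$ — without this, the Nyström
interpolation property (the anchor block of $Q$ equals $K_{mm}$) and the
monotone improvement of $\lVert K - Q\rVert_F$ in $m$ would not hold.

**Degenerate inputs.** The arc-cosine kernel clamps the cosine to
$[-1, 1]$ and assigns value 0 to zero-norm rows. The sigmoid kernel is
not positive semidefinite in general; `kernel_sqrt()` clamps eigenvalues
below $10^{-10}\lambda_{\max}$ (including all negatives) to zero and
warns when the clamped negative mass exceeds 1% of the spectrum. For the
same reason the sparse design of a sigmoid kernel represents only the
positive part of the anchor spectrum, which is the documented remedy
rather than an approximation error.

**Anchor selection.** Anchors are drawn uniformly without replacement at
the *line* level (so replicated lines stay coherent across
environments), as the first $m$ entries of one seeded permutation.
Consequently, for a fixed seed, lower compression levels use supersets
of the anchors of higher ones — the nested structure under which the
approximation error is provably non-increasing, and the design used to
sweep compression levels.

## The Bayesian samplers

`fit_brr()` (Bayesian ridge regression) and `fit_gblup()` are bespoke
Gibbs samplers; they are the package's own statistical core rather than
wrappers.

* **BRR** fits $y = \mu + X\beta + e$, $\beta \sim N(0, \sigma_\beta^2 I)$,
  in the singular-value basis of $X$: the $r$ identified coordinates have
  a diagonal conditional posterior (an $O(r)$ joint draw), and the
  null-space contribution to $\beta'\beta$ — needed by the
  $\sigma_\beta^2$ update when $p > r$ — is drawn as
  $\sigma_\beta^2 \chi^2_{p-r}$ without forming the null-space basis.
  The sampler is exact and makes $p$ in the thousands cheap in plain R.
* **GBLUP** samples the kernel model through the eigen-reparameterization
  $u = \Gamma \delta$, $K = \Gamma \Lambda \Gamma'$ (spectrum clamped at
  $10^{-10}\lambda_{\max}$). When the incidence is balanced ($Z'Z
  \propto I$, e.g. every line observed once per environment) the
  conditional posterior of $\delta$ is diagonal and a sweep costs
  $O(n)$; otherwise a joint draw via Cholesky of the $r \times r$
  precision is used. Predictions for lines outside the training kernel
  use the cross-kernel: $\hat u_{new} = K_{new,tr} K_{tr}^{+} \hat
  u_{tr}$.

**Priors and defaults.** Scaled-inverse-$\chi^2$ priors with 5 degrees
of freedom on both variance components, scales set so markers (or line
effects) and residual each explain half of $\mathrm{var}(y)$ a priori —
the convention common to Bayesian genomic-prediction software. MCMC
defaults are 1500 iterations with 500 burn-in; for variance-component
*estimation* (as opposed to prediction) we use 3000/1000, where the
$\sigma_u^2$ chain's autocorrelation (≈0.9 at lag 1, ≈0 by lag 50)
leaves an adequate effective sample size. Chains replay bit-identically
under a fixed seed.

**Equivalence.** BRR on the scaled markers and Bayesian GBLUP with the
linear kernel $XX'/p$ are the same model in different coordinates; the
package verifies this as a prediction-correlation property (> 0.99 on
synthetic data at $n = 150$, $p = 300$, $h^2 = 0.5$).

## Delegated learners and tuning

Gradient boosted trees (xgboost), penalized GLMs (glmnet), SVMs (e1071)
and random forest (randomForest) are reached through one `fit()`
interface with automatic response-type inference (two factor levels →
binary, more → categorical, numeric → continuous; counts are fitted as
continuous with a warning). Defaults follow the genomic-prediction
naming convention (`trees_number = 500`, `node_size = 5` for random
forest; `alpha = 1` for the GLM; linear-kernel SVM with `cost = 1`,
`gamma = 1/p`, `degree = 3`, `coef0 = 0`; boosting with 500 trees,
depth 1, shrinkage 0.1, half-sampled records), and the explicit
translation onto back-end argument names is part of the tested surface.
A design whose columns are all constant is fitted as an intercept-only
model rather than an error.

Hyperparameter tuning runs an inner $k$-fold cross-validation
($k = 5$ by default) on the training rows only:

* **Grid search** evaluates the full Cartesian product and is tested to
  agree *exactly* with an exhaustive external loop over the same folds;
  ties go to the first combination in enumeration order. At least one
  hyperparameter must offer at least two candidate values.
* **Bayesian optimization** evaluates 5 seeded Latin-hypercube points,
  then 10 rounds (the default) of: fit a Gaussian-process surrogate
  (Matérn-5/2 correlation, profiled variance, lengthscale selected by
  marginal likelihood over a fixed grid, nugget $10^{-6}$), and evaluate
  the candidate maximizing expected improvement over a large LHS
  candidate set plus local jitters of the incumbent. Integer dimensions
  are optimized on the continuous relaxation and rounded at evaluation.
  The surrogate internals are deliberately simple and fully seeded; on
  the reference quadratic $(x-2)^2$ over $[0, 10]$ the median error of
  the returned optimum across seeds is far below 0.5.

## Metrics and the benchmarking protocol

Regression: MSE, RMSE, MAE, NRMSE (normalized by sample sd — under
which a mean predictor scores $\sqrt{(n-1)/n}$ — or by mean, range,
IQR), and MAAPE $= \mathrm{mean}(\arctan|{(y-\hat y)}/{y}|)$, bounded in
$[0, \pi/2]$, with the $y = 0,\ \hat y \ne y$ case contributing the
limit $\pi/2$ (the count of such cases is attached as an attribute).
Classification: accuracy, sensitivity/recall, specificity, precision,
F1, Cohen's kappa, the multiclass Matthews correlation, Brier score
(squared distance to the one-hot truth), ROC-AUC (midrank Mann-Whitney
form, deterministic under ties) and PR-AUC (average precision with tie
groups processed atomically); multiclass versions are macro-averaged
one-vs-rest. Binary metrics take the first level as the positive class
unless told otherwise. `numeric_summary()` / `categorical_summary()`
bundle the full families and are bit-identical to the individual calls.

The outer protocol (`run_benchmark()`) draws seeded random partitions
(default: 5 repetitions of an 80/20 split, stratified by environment so
every environment appears in every test set), tunes and fits on
training rows only, and records long-format predictions.
`summaries()` reports each metric per environment as mean ± SE over
folds (SE $= \mathrm{sd}/\sqrt{\text{folds}}$), and a `Global` row
computed by pooling all environments *within* each fold before
averaging over folds; an alternative Global from environment means is
available by flag but non-default. `percent_outperformance()` implements
the relative-MSE comparison $100(\text{MSE}_{ref} -
\text{MSE}_{better})/\text{MSE}_{ref}$, truncated toward zero at two
decimals — the convention of the published worked examples this package
reproduces.

## The synthetic-data generator

`simulate_markers()` draws biallelic dosages under Hardy-Weinberg
sampling: allele frequencies uniform on the MAF range (default 5-50%,
mimicking the usual MAF filter), dosages $\mathrm{Binomial}(2, q_j)$,
monomorphic columns resampled. There is deliberately **no linkage
disequilibrium or population structure**: the generator supports
testing of estimation and approximation properties, not of LD-dependent
phenomena, so passing tests say nothing about, e.g., marker-density
requirements on real panels.

`simulate_phenotypes()` builds $g = X_s\beta$ with $\beta \sim
N(0, 1/p)$ (the epistatic architecture adds pairwise products of a
random 1% marker subset with matched total variance), rescales $g$ to
variance $h^2$, and adds independent residuals with $\sigma_e^2 = 1 -
h^2$ plus environment *main* effects (no genotype-by-environment
interaction) — one record per line and environment. Defaults (200
lines, 500 markers, 4 environments, $h^2 = 0.5$, environment sd 0.5)
emulate multi-environment cereal trials at desk scale.

## Study sizes used in the validation suite

The package's own experiments (tests and the acceptance script) use the
following problem sizes, chosen as the smallest at which each property
is cleanly expressed:

* *Nyström oracle equivalence*: 30 lines, all seven kernels, anchors at
  40% compression, against an independent pseudo-inverse oracle.
* *BRR/GBLUP equivalence*: $n = 150$, $p = 300$, $h^2 = 0.5$, 5 seeds.
* *Heritability recovery*: $n = 300$ lines and $h^2 \in \{0.2, 0.5,
  0.8\}$ over 10 seeds, with $p = 150$ markers. The marker count is
  deliberately *below* the line count: with $p \ge n$ the linear
  kernel's spectrum concentrates (Marchenko-Pastur) and
  $\sigma_u^2/\sigma_e^2$ becomes weakly identified — even exact
  maximum likelihood misses low heritabilities there. A rank-deficient
  kernel has explicit residual-only directions that identify
  $\sigma_e^2$, which is the regime in which recovery is a meaningful
  test of the sampler rather than of the design.
* *Compression retention*: $n = 150$ lines in 4 environments,
  arc-cosine kernel, compression 0.5, Bayesian ridge on the dense
  square root versus the sparse design, Global MSE over 5×80/20
  partitions, 10 seeds.

## Known limitations

* Bayesian samplers handle continuous traits only; binary/categorical
  responses go to the delegated learners.
* Count responses are collapsed to continuous (with a warning).
* No multi-trait models, no genotype-by-environment interaction terms,
  no leave-one-environment-out schemes.
* Anchor selection is uniform; leverage-score or clustering-based
  selection is out of scope.
* The heritability posterior mean is a shrinkage estimate: in weakly
  identified designs (markers ≫ lines) it pulls toward the prior's
  50/50 variance split, as documented above.
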
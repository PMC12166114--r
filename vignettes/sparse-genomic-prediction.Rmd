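---
title: "Sparse genomic prediction: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse genomic prediction: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsgp)
```

## The prediction problem

Genomic prediction targets the genetic value $g_i$ of selection candidates
that have been genotyped but not (fully) phenotyped. GBLUP predicts
$\hat g_{tst} = W y_{trn}$ with the dense weight matrix
$W = G_{trn,tst}' P_{trn}^{-1}$, where
$P_{trn} = \sigma_u^2 K_{trn} + \sigma_\varepsilon^2 I$ and
$G_{trn,tst} = \sigma_u^2 K_{trn,tst}$ are built from a genomic
relationship matrix $K$. Every training record receives a non-zero
weight, including records from individuals essentially unrelated to the
candidate, whose estimated relationships are mostly sampling noise of the
marker-based $K$.

Sparse genomic prediction replaces the linear solve by the penalized
problem, per candidate $i$:

$$\hat w_i = \arg\min_{w} \tfrac12 w' P_{trn} w - w' G_{trn,tst(i)}
  + \lambda\Big[\alpha \sum_j |w_j| + \tfrac{1-\alpha}{2}\sum_j w_j^2\Big].$$

With $\alpha > 0$ the L1 term switches training records out of the
prediction equation, so each candidate is predicted from a subset of the
training data — typically close relatives measured for the target trait
and for genetically correlated traits. At $\lambda = 0$ the problem
reduces exactly to GBLUP; the package solves that case by a direct
symmetric solve rather than by iteration, so the equivalence is exact
rather than approximate.

The same quadratic form covers three layers, differing only in the
sufficient statistics $(\Sigma, \Gamma)$ supplied:

* **Selection index** (`solve_ssi`): $\Sigma = P_x$, the phenotypic
  covariance of $p$ measured indicator traits, $\Gamma = G_{xy}$, their
  genetic covariances with the selection objective. $\lambda = 0$ is the
  Smith–Hazel index $P_x^{-1} G_{xy}$.
* **Single-trait SGP** (`sgp` with scalar `varU`, `varE`).
* **Multi-trait/environment SGP** (`sgp` with matrices $\Omega$, $R$):
  stacked phenotypes with covariance
  $\mathrm{var}(y) = (\Omega \otimes K) + (R \otimes I)$. The training
  block $P_{trn}$ and the training–testing block $G_{trn,tst}$ are
  subsets of $\Omega \otimes K + R \otimes I$ and $\Omega \otimes K$
  under the record maps `ID_geno`/`ID_trait`; this is the only form of
  $P$ consistent with the single-trait reduction
  $\sigma_u^2 K + \sigma_\varepsilon^2 I$, which the package treats as a
  defining identity. `build_P()`/`build_G()` construct only the requested
  blocks — the full Kronecker product is never materialized, so
  incomplete data (records missing for some genotype–trait combinations)
  is pure index bookkeeping, with no re-estimation or imputation inside
  the solver.

## Parameters that matter

* `alpha` (unitless, in [0, 1]; default 1). L1/L2 mixing. 1 gives LASSO
  behavior (hard selection), 0 ridge (no selection). The default reflects
  that sparsity is the point of the method.
* `lambda` (same units as $\Gamma$; default: a generated grid). The grid
  is log-equally spaced from $\lambda_{max}$ (the smallest value with an
  all-zero solution, $\max_j |\Gamma_j| / \alpha$) down to
  $\lambda_{max} \cdot$ `min_ratio`, with `nlambda = 100` values and
  `min_ratio = 1e-4`. Grid size follows the package's standard protocol
  of profiling accuracy over 100 penalty values; the log spacing and span
  are the glmnet-style convention. $\lambda = 0$ is *not* appended by the
  grid generator — GBLUP is requested explicitly — except in
  cross-validation (below). Because ridge has no finite $\lambda_{max}$,
  grids at $\alpha = 0$ are sized with a documented floor
  (`alpha_floor = 1e-3`) in place of $\alpha$.
* `tol` (coefficient units; default 1e-4) and `maxiter` (sweeps; default
  1000). Coordinate descent stops when the largest absolute coefficient
  change in a full sweep falls below `tol`, or flags (not fails) the
  $\lambda$ at `maxiter`.
* `varU`, `varE` / $\Omega$, $R$ (trait variance units). For a single
  trait these can be omitted and are then estimated from the training
  records by REML (`fit_blup`). For several traits they are inputs:
  estimating a full $\Omega, R$ requires a multivariate mixed model,
  which is out of scope here. `pairwise_genetic_covariance()` provides a
  simple polarization-identity moment estimate
  ($[\mathrm{var}_u(y_1+y_2) - \mathrm{var}_u(y_1) -
  \mathrm{var}_u(y_2)]/2$) as plumbing for tests and rough checks, not as
  a substitute for proper multivariate estimation.
* `k` (folds; default 10) in `kfold_cv_lambda`.

## Variance-component estimation

`fit_blup()` fits $y = \mu + u + \varepsilon$,
$u \sim (0, \sigma_u^2 K)$, $\varepsilon \sim (0, \sigma_\varepsilon^2 I)$,
with an intercept as the only fixed effect — phenotypes are assumed
pre-adjusted for non-genetic effects, which matches how multi-environment
trial data are usually delivered. REML is the default criterion, with ML
behind a flag. $K_{trn}$ is eigendecomposed once; the criterion is
profiled over the ratio $r = \sigma_u^2/\sigma_\varepsilon^2$ and
maximized by Brent search on $\log r \in [-10, 10]$ (natural log,
tolerance $10^{-8}$). Solutions at the interval edge are flagged
(`boundary`); a flat profile — e.g. $K = I$, where $\sigma_u^2$ and
$\sigma_\varepsilon^2$ enter only through their sum — is detected by
probing the criterion across the interval and flagged (`flat`) with a
warning instead of silently returning an arbitrary split. Missing
phenotypes are excluded by index subsetting, never imputed.

### Intercept handling in `sgp()`

The prediction equation $\hat g = W y_{trn}$ presumes centered
phenotypes. For a single trait the package profiles out a GLS intercept
$\hat\mu = (1'P^{-1}1)^{-1} 1'P^{-1} y_{trn}$, so that $\lambda = 0$
predictions coincide (to solver precision) with `fit_blup`'s GBLUP
output. For $q > 1$ no intercept is applied: multi-trait inputs are
assumed adjusted, and $\lambda = 0$ equals the direct multivariate solve
$G' P^{-1} y_{trn}$. Accuracy, computed as a within-trait correlation, is
unaffected by this choice; mean bias (see `bias_slope`) is affected, which
is why the choice is stated here.

## Cross-validation and evaluation

`cv2_partition()` implements the CV2 scheme for complete $n \times q$
record grids: $n_0$ genotypes are sampled to contribute testing data, and
each contributes a random pair of traits/environments, so candidates keep
their remaining records in training and predictions can borrow from a
candidate's own correlated measurements. Because the rule "all
genotype–trait combinations equally represented" does not determine $n_0$
by itself, $n_0$ is an explicit parameter and the published crop layouts
ship as presets (`cv2_presets()`).

`kfold_cv_lambda()` selects $\lambda$ strictly inside the training set:
records are split into `k` folds stratified by trait (so within-trait
accuracy is computable in every fold), each fold in turn is pseudo-testing
for a model trained on the rest over one shared $\lambda$ grid, and the
within-trait accuracies are averaged — simple (unweighted) mean across
traits, then across folds; a weighted mean would let well-replicated
traits dominate the criterion, which is not what a breeder scanning
several target environments wants. The function's interface receives no
testing records at all, which enforces the no-leakage property by
construction. Two deliberate choices:

* The shared grid is sized from the largest within-training genetic
  covariance, so it upper-bounds every fold's $\lambda_{max}$ and the
  accuracy curves align across folds.
* $\lambda = 0$ is included as a CV candidate (`include_zero = TRUE`), so
  "the sparse model beat GBLUP" is a conclusion the selection could have
  rejected. Exact accuracy ties are broken toward the largest $\lambda$
  (the sparsest, cheapest equation).

`accuracy_by_trait()` always correlates within trait/environment — pooling
across traits with different means and scales manufactures spurious
correlation. `nsup_summary()` reports the average support size per
$\lambda$ and its per-trait composition; `bias_slope()` reports the mean
difference and the slope of observed-on-predicted regression (a slope
above 1 indicates over-shrinkage, which sparse models can exhibit because
$\lambda$ is chosen for correlation, not for calibration).

## Numerical choices

* **Coordinate update.** The per-coordinate minimizer of the objective is
  $w_j \leftarrow S(\Gamma_j - \sum_{k \ne j}\Sigma_{jk} w_k,\;
  \lambda\alpha) / (\Sigma_{jj} + \lambda(1-\alpha))$ with $S$ the
  soft-thresholding operator; this is uniquely determined by the
  objective. The implementation caches $\Sigma w$ for O(p) updates, warm
  starts along the decreasing grid (cold starts give the same solutions
  to solver tolerance, which the tests check), and uses the glmnet-style
  active-set strategy: full sweep, then iterate the non-zero set, then a
  full sweep to re-check. The active-set inner loop runs one order below
  `tol` so the delivered solution sits within about `tol` of the optimum
  even on ill-conditioned systems — with the inner loop at `tol` the
  delivered error was up to ~20 `tol` on adversarial instances.
* **Solver scaling.** The solver consumes $(\Sigma, \Gamma)$ exactly as
  given and never rescales them: whether sufficient statistics carry a
  $1/n$ factor is the caller's convention, and the SGP layers rely on the
  solver being exact in theirs.
* **LARS.** `lars_path()` computes the exact piecewise-linear path on the
  same sufficient statistics, with the LASSO modification (variables
  whose coefficients hit zero are dropped). Entry ties are broken by
  lowest predictor index; exactly duplicated predictors are an error
  rather than an arbitrary ordering. Correlations are recomputed from the
  current coefficients at each breakpoint to avoid drift. The final path
  point is the unpenalized solution $\Sigma^{-1}\Gamma$.
* **Degenerate inputs.** All-zero $\Gamma$ columns (no signal to
  threshold), zero-variance phenotypes, zero-variance marker matrices,
  non-symmetric $\Sigma$, and non-PSD $K_{trn}$ are errors with specific
  messages; non-convergence at a grid point and boundary/flat variance
  profiles are flags, not errors. Non-PD $\Sigma$ is allowed in
  coordinate descent (only positive diagonals are required) but warned
  about implicitly through KKT checks in the tests; LARS requires PD on
  the active sets it visits.
* **GRM normalization.** `compute_grm()` centers marker columns and
  scales by $v = \sum_j \mathrm{var}(z_j)$ with the method-of-moments
  variance (denominator $n$): that denominator is the only choice that
  makes "average diagonal equal to one" an exact identity rather than an
  approximation. Column-mean imputation of missing codes is available but
  off by default, since it is a data-cleaning decision, not a modeling
  one. Alternative scalings (allele-frequency weighting, dominance
  kernels, pedigree matrices) are out of scope.
* **Shared λ grid across candidates.** Each candidate's problem has its
  own $\lambda_{max}$; the package sizes one grid from the largest of
  them so that one $\lambda$ indexes one model across all candidates and
  `nsup` averages are meaningful. Per-candidate grids would make the
  reported $\lambda$ incomparable between candidates.
* **Parallel structure.** The per-candidate problems share $(\Sigma)$ and
  differ only in $\Gamma$ columns; they are independent and may be solved
  in any order with identical results.

## What the generators emulate — and what they do not

`simulate_regression()` reproduces a standardized-Gaussian sparse
regression: exactly `round(p * prop_nonzero)` effects drawn from
Gamma(4, 4) (all positive, matching a one-directional effect convention;
a `sign_flip` option exists for symmetric-effect tests), noise scaled to
`noise_mult` (default 3) times the signal standard deviation, response
re-standardized.

`simulate_multitrait()` draws doubled-haploid-style {0, 2} marker codes
with allele frequencies uniform on [0.1, 0.5], builds $K$ with
`compute_grm`, then draws genetic values with covariance
$\Omega \otimes K$ (via symmetric square roots) and residuals with
covariance $R \otimes I$. This gives a GRM with a realistic spectrum and
phenotypes that follow the multi-trait model *exactly* — useful for
equivalence and recovery tests, but note the implication: when the model
is exactly true and $K$ is well estimated, GBLUP is the right answer and
cross-validation should (and does) select $\lambda \approx 0$.

`simulate_sparse_signal()` emulates the regime sparse prediction is for:
full-sib-like families (one founder genotype per family, 15% of marker
codes redrawn per individual), genetic values dominated by a family
effect (90% of genetic variance), heritability 0.6, and deliberately few
markers (200) so between-family entries of $K$ are mostly sampling noise.
Parameters were fixed at these values as a realistic small breeding
program and are not tuned per test. None of the generators attempt
real-genome linkage disequilibrium, selection history, or population
structure beyond the family blocks — so passing tests demonstrate
correctness of the machinery and the qualitative sparse-beats-dense
regime, not expected accuracy gains on any particular crop dataset.

## Problem sizes used by the test suite

The suite exercises the solvers on p ≤ 25 instances against closed forms,
an independent numeric minimizer, the exact LARS path, and glmnet (as an
independent cross-check on raw-data sufficient statistics); GBLUP
equivalences on n = 200 genotypes; Kronecker subsetting against fully
materialized products at n ≤ 10, q ≤ 3; heritability recovery at
n = 1000 genotypes × 2000 markers (20 replicates, median within ±0.1 of
h² = 0.4); and the cross-validated sparse-vs-GBLUP comparison on 20
replicates of the 150-genotype family design. These sizes were chosen so
the whole suite runs in minutes on a laptop while keeping each stochastic
check's sampling error well inside its assertion margin.

## Known limitations

* $\Omega$ and $R$ for $q > 1$ must be supplied; the package does not fit
  multivariate variance components.
* Additive kernels only: no dominance/epistasis kernels, no RKHS, no
  environmental-covariate interaction models.
* `fit_blup` handles one genetic variance component besides the error;
  multi-kernel models are out of scope.
* The CLI exchanges dense labelled CSV matrices; for very large K a
  binary format would be preferable, but interoperability won here.
* Predictions at $\lambda$ near $\lambda_{max}$ are constants (empty
  support); their within-trait correlation is undefined and reported as
  `NA`, which the CV criterion treats as missing rather than zero.
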
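---
title: "Phylogenetic regression for count traits: models, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic regression for count traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocount)
```

## The problem

Comparative trait data violate the independence assumption of ordinary
regression: species inherit trait values from common ancestors, so residuals
are correlated in a pattern dictated by the phylogeny. For *continuous*
responses this is routinely handled by generalized least squares with the
Brownian-motion covariance. For *count* responses — clutch sizes, litter
counts, gene-family sizes — the natural marginal models are the Poisson and
the negative binomial (NB2), and the dependence has to enter differently:
there is no convenient multivariate Poisson likelihood to maximize.

phylocount fits count regressions in both regimes:

* **Independent** Poisson and NB2 generalized linear models by maximum
  likelihood (`count_glm()`), with AICc and Akaike weights for model choice
  (`compare_count_models()`).
* **Phylogenetic** Poisson and NB2 regression by generalized estimating
  equations (`phylo_glm()` / `fit_gee()`), where the tree enters through a
  working covariance built from the shared-branch-length matrix.

## The covariance matrix C

A rooted tree with branch lengths maps to the matrix \(C\) whose entry
\(c_{ij}\) is the branch length shared by the root-to-tip paths of tips
\(i\) and \(j\); \(c_{ii}\) is the depth of tip \(i\). Under Brownian motion
with rate \(\sigma\), tip values are jointly normal with covariance
\(\sigma^2 C\). `tree_covariance()` computes \(C\) (via `ape::vcv()`), and
`five_taxon_tree()` is a small worked example whose \(C\) has diagonal 560
and off-diagonal blocks 459 / 217 / 20 / 0:

```{r}
tree_covariance(five_taxon_tree())
```

## Estimating equations

Write \(\eta = X\beta\) for the linear predictor, \(\mu(\eta)\) for the
family mean and \(V(\mu)\) for the family variance. The coefficients solve

\[ D^\top W^{-1}\,(Y - \mu) = 0, \qquad
   D = \mathrm{diag}\!\left(\tfrac{d\mu}{d\eta}\right) X, \quad
   W = S^{1/2}\, C\, S^{1/2}, \quad S = \mathrm{diag}(V(\mu)). \]

The two families are:

* **Poisson, log link**: \(\mu = V = d\mu/d\eta = e^\eta\). With \(C = I\)
  the equations collapse to the Poisson score \(X^\top(Y - e^{X\beta}) = 0\),
  so on a star phylogeny the GEE reproduces the ordinary GLM exactly — a
  property the test suite checks to \(10^{-6}\).
* **NB2**: variance \(\mu + \mu^2/r\) with dispersion \(r > 0\) (Poisson as
  \(r \to \infty\)). Two links are supported. The *canonical* link of the
  NB2 exponential family, \(\theta = \log(\mu/(\mu + r))\), gives
  \(\mu = r e^\eta/(1 - e^\eta)\) and requires \(\eta < 0\); it is the
  parameterization used by the simulation design. The *log* link matches the
  `MASS::glm.nb` convention and is the default for empirical fitting.

Two modelling decisions deserve explanation:

* **NB2 working variance.** The mean \(r e^\eta/(1-e^\eta)\) and the
  variance \(r e^\eta/(1-e^\eta)^2\) of the canonical NB2 are easy to
  conflate. phylocount uses the NB2 variance \(\mu + \mu^2/r\) in \(S\) by
  default, which makes the star-tree case reduce exactly to the independent
  NB2 score; a literal mean-only weighting (\(S = \mathrm{diag}(\mu)\)) is
  available via `working_var = "mean"` for comparison. On a star tree the
  mean-only weighting instead collapses to the *Poisson* score, which is a
  quick way to see why the variance weighting is the coherent default.
* **The dispersion is not estimated inside the GEE.** \(r\) is a fixed
  constant of the family: user-supplied, or taken once from the independent
  NB2 MLE (`MASS::glm.nb`) and held fixed, with a message. Joint
  quasi-likelihood estimation of \(r\) under dependence is out of scope.

## Solver

`fit_gee()` starts from the corresponding independent GLM estimate and
applies damped Fisher scoring with step halving (up to 30 halvings, at most
100 iterations). Two numerical choices matter in practice:

* **Inversion through C, not W.** The working covariance
  \(W = S^{1/2} C S^{1/2}\) can be atrociously conditioned when fitted means
  span several orders of magnitude (condition numbers above \(10^7\) occur
  in routine simulations). The solver eigendecomposes \(C\) once per fit —
  it does not change across iterations — and applies the diagonal factors
  analytically, so round-off is governed by the conditioning of \(C\) alone.
  Eigenvalues below `svd_tol` (\(10^{-10}\) relative) are dropped, which
  turns exactly singular \(C\) (duplicated tips) into a well-defined
  pseudo-inverse rather than a failure.
* **A finite-difference Newton polish.** Fisher scoring ignores the
  \(\partial W/\partial\beta\) part of the true Jacobian and can stall a
  hair short of the root. When the scoring step stops making progress, the
  solver switches to a damped Newton step with a central-difference Jacobian
  of the estimating function, which restores convergence to the
  `score_tol` (\(10^{-8}\)) criterion. Convergence is declared on the raw or
  standardized score; a fit that exhausts its iterations is returned with
  `converged = FALSE` and its score norm, never silently dropped.

`phylo_glm()` wraps this behind a data-frame-first interface: the trait
table and the tree are aligned by species label (`align_data()`), with
mismatches dropped loudly and the rows of \(Y\), \(X\) and \(C\) reordered
jointly — misalignment between a trait table and a covariance matrix is the
classic silent failure of comparative analyses.

## Simulating phylogenetically correlated counts

The simulator is a Gaussian copula (NORTA) construction
(`rcount_copula()`): draw \(Z \sim N(0, R)\) with \(R\) the correlation
matrix of \(C\), map through the standard normal CDF to uniforms, and apply
the marginal quantile function (`qpois` or `qnbinom`). Marginals are then
*exactly* Poisson/NB2 with the requested means — verified by chi-square
goodness-of-fit in the tests — while the dependence is inherited from the
tree. \(C\) is standardized to a correlation matrix because the quantile
transform needs uniform inputs; the raw covariance would leave the latent
marginals non-standard and distort the count marginals.

Covariates evolve by Brownian motion: `simulate_bm_covariate()` draws from
\(N(\mathrm{root}\cdot 1, \mathrm{rate}^2\, C)\).

### The simulation study

`run_sim_study()` reproduces the package's validation design: tree shapes
coalescent / balanced / left / star (`generate_tree()`, all scaled to unit
height), taxa sizes 16–128, truth \(\beta = (3, 5)\), NB2 dispersion
\(r = 10.68\), 1000 replicates per cell. Per cell, one tree and one
covariate vector are drawn and held fixed; replicates then vary only in the
copula count draw. This matches the reported behaviour of the design —
per-cell means within a few thousandths of the truth and small, stable
SDs. Redrawing the covariate every replicate (`covariate_draw =
"replicate"`) is also available; it mixes covariate variability into the
cell SDs and produces occasional quasi-separated replicates (a handful of
nonzero counts) whose estimates are essentially unidentified, so cell SDs
become heavy-tailed. Replicates whose initial GLM diverges, or whose GEE
does not converge, are excluded from the cell summaries and counted — a
`n_converged` column accompanies every mean and SD.

For the canonical-link NB2 study the truth \((3, 5)\) puts the linear
predictor outside the \(\eta < 0\) domain with overwhelming probability for
weakly correlated trees; the generator redraws the covariate until the
domain holds, logs the redraw count (`n_redraws`), and errors after a
budget rather than spinning forever. This domain tension is intrinsic to
the canonical parameterization and is why NB2 simulation cells are
validated qualitatively (estimates bracketing the truth with large SDs)
rather than cell-by-cell.

Problem sizes in the shipped tests are scaled for a default run: 200
replicates per cell for the Poisson recovery checks (with tolerances
widened to the wider of 0.05 and 3 Monte-Carlo standard errors),
\(10^4\) draws for the copula goodness-of-fit, and 20 instances for the
brute-force oracle comparison. `scripts/acceptance.R` runs the headline
cells at the full 1000 replicates.

## Bootstrap inference

The GEE supplies point estimates but no likelihood, so standard errors and
confidence intervals come from a **parametric bootstrap**
(`parametric_bootstrap()`): simulate new responses from the fitted model —
through the copula with the same \(C\) for phylogenetic fits, independently
for GLM fits — refit, and summarize the replicate coefficients (mean, SD,
percentile intervals). Case resampling is deliberately not offered: tips
are not exchangeable under phylogenetic dependence, and resampling rows
destroys the covariance structure the model exists to respect. Failed
refits are counted (`n_failed`) and excluded, never imputed.

## What the synthetic checks do and do not show

The generators emulate Brownian covariates, copula-dependent counts with
exact marginals, and the four tree shapes. They do not emulate measurement
error, within-species replication, non-Brownian covariate evolution
(Ornstein–Uhlenbeck pull, early bursts), branch-length misspecification, or
model misfit between the simulated and fitted family. Passing tests
therefore demonstrate correctness of the estimator and its implementation
under the stated model, not robustness of the model on real data. Real
analyses should also treat the tree as an assumption: \(C\) is used as
given (uniform rescaling provably cancels in the root — also a tested
property), and transformations of \(C\) beyond uniform scaling are out of
scope.

## Known limitations

* No sandwich (robust) variance estimator; inference is bootstrap-only.
* \(r\) fixed during GEE fitting (see above).
* The canonical-link NB2 domain restricts admissible covariate/parameter
  combinations; the log link avoids this at the cost of no longer being the
  exponential-family canonical parameter.
* Empirical reproduction of published lizard/mammal analyses requires the
  original trait tables, which are not redistributable with the package;
  the test suite documents this gap explicitly with a clearly-labelled
  synthetic stand-in rather than hiding it.
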
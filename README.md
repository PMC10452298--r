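# phylocount

Regression models for **count-valued traits across related species**. Trait
data from a clade are not independent — species inherit trait values from
common ancestors — so ordinary Poisson or negative binomial regression
understates or distorts the relationships between a count response (clutch
size, litters per year, gene-family size) and its covariates. phylocount
fits those regressions while respecting the phylogeny, for comparative
biologists and evolutionary ecologists working with species-level count
data and a dated tree.

## The models

A rooted tree with branch lengths defines the matrix **C** whose entry
c<sub>ij</sub> is the branch length shared by the root-to-tip paths of tips
*i* and *j* (the Brownian-motion trait covariance up to a rate constant).
Given counts *Y*, design matrix *X* and linear predictor η = Xβ, the
coefficients solve the generalized estimating equations

```
Dᵀ W⁻¹ (Y − μ) = 0,   D = diag(dμ/dη) X,   W = S¹ᐟ² C S¹ᐟ²,   S = diag(V(μ))
```

with two families:

* **Poisson** (log link): μ = V = exp(η);
* **NB2** (dispersion r): V = μ + μ²/r, with either the log link
  (μ = exp(η), the `glm.nb` convention) or the canonical link
  θ = log(μ/(μ+r)), where μ = r·eᵸ/(1−eᵸ) and η must be negative.

With a star tree (C ∝ I) the equations collapse to the ordinary GLM score,
so the phylogenetic estimates coincide with the independent ones — a tested
invariant. The package also provides independent Poisson/NB2 MLE fits with
AICc and Akaike weights, Brownian covariate and Gaussian-copula (NORTA)
count simulators with exact marginals, a replicated simulation-study
driver, and parametric-bootstrap standard errors and percentile intervals.

## Worked example

Simulate an overdispersed count trait on a 32-species coalescent tree and
fit it with and without the phylogeny:

```r
library(phylocount)
set.seed(1)

tree <- generate_tree("coalescent", 32, seed = 7)   # unit-height tree
C    <- tree_covariance(tree)
x    <- simulate_bm_covariate(C, root = 0, rate = 1)
y    <- rcount_copula(exp(2 + 0.8 * x), C, gee_family("nb2", link = "log", r = 4))
traits <- tibble::tibble(species = names(y), eggs = as.integer(y), size = unname(x))

compare_count_models(traits, eggs ~ size)
#> # A tibble: 2 × 8
#>   family      n mean_y var_y     k logLik  AICc weight
#> 1 poisson    32   8.59  31.9     2  -76.4  157.  0.709
#> 2 nb2        32   8.59  31.9     3  -76.1  159.  0.291

fit <- phylo_glm(traits, eggs ~ size, tree, family = "nb2", r = 4)
fit
#> <phylo_gee> nb2 (log link, r = 4), n = 32
#> (Intercept)        size
#>    2.061404    0.814799
#> converged: TRUE after 12 iterations (max |score| = 7.59e-08, cond(W) = 5.61e+05)

tidy(parametric_bootstrap(fit, B = 200, seed = 99))
#> # A tibble: 2 × 5
#>   term        estimate std.error conf.low conf.high
#> 1 (Intercept)    1.97      0.444    1.19       2.68
#> 2 size           0.834     0.167    0.543      1.19
```

The GEE recovers the generating coefficients (2, 0.8) as (2.06, 0.81); the
bootstrap — which resimulates counts through the copula with the same C,
because tips are not exchangeable — puts the slope's 95% interval at
(0.54, 1.19), comfortably excluding zero. The model-comparison table
reports the response mean/variance (8.59 vs 31.9: strongly overdispersed)
with AICc and Akaike weights for the two independent fits.

A thin command-line interface over the same functions ships in
`inst/exec/phylocount` (`fit`, `simulate`, `compare` subcommands; Newick +
CSV in, JSON/CSV out).

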
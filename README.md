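# ordgmm

Monte-Carlo machinery for studying how **ordinal measurement degrades
Gaussian-mixture recovery**. Applied researchers routinely fit Gaussian
mixture models (or their spherical special case, latent profile analysis)
to variables that are not continuous at all — symptom severities, Likert
items, staged diagnoses. `ordgmm` simulates exactly this situation end to
end: it builds mixtures with controlled component separation, thresholds
the simulated continuous data onto midpoint-labeled ordinal scales,
re-estimates mixtures by EM with BIC selection over the number of
components, and scores both the recovery of the component count and the
bias of the component parameters.

The package is aimed at methodologists who want to extend or re-run this
kind of misspecification study, and at analysts who want a concrete answer
to "is latent profile analysis defensible on my 5-point items?"

## The model and the pipeline

Data are drawn from a K-component Gaussian mixture

  f(x) = Σₖ πₖ N(x; μₖ, Σₖ),  πₖ = 1/K,

whose components are *pairwise equidistant* in symmetrized
Kullback–Leibler divergence. With a shared spherical covariance σ²I the
divergence between components i and j is ‖μᵢ − μⱼ‖²/(2σ²), so a target
D_KL is realized by placing the means on a regular simplex with edge
√(2σ²·D_KL), randomly rotated per repetition (σ² = √0.25; for the one
infeasible geometry, K = 4 in p = 2, the separation is carried by
component-specific covariances found by least squares).

Each variable is then mapped to c ordered categories: equal-width bins
between its empirical 0.5% and 99.5% quantiles, values labeled by bin
midpoints (thresholds −1, 0, 1 give labels −0.5, 0.5), outliers clamped
into the edge bins. Estimation runs EM for spherical (per-component σₖ²I;
the constrained "isomorphic" model, parameter count K(p+1)+(K−1)),
pooled-spherical, or unconstrained covariance families, initialized from
model-based hierarchical agglomeration, and selects K ∈ {1, …, 7} by
BIC = 2ℓ − m·log N. Runs whose covariances collapse (smallest eigenvalue
below 10⁻¹⁰) are recorded as failed and excluded from selection — the
mechanism that drives the binary-data results. Estimated components are
matched to true ones over all K! permutations before mean-absolute
parameter errors are computed, and errors are only reported where K was
recovered.

## Worked example

```r
library(ordgmm)

design  <- build_design(K = 3, p = 4, target_kl = 3.5, seed = 1)
latent  <- sample_mixture(design, 10000, seed = 2)
ordinal <- discretize(latent, n_categories = 5)
sel     <- select_k(ordinal, family = "spherical", control = gmm_control(seed = 3))
sel
#> <gmm_selection> family = spherical, k_hat = 3
#> # A tibble: 7 × 7
#>       k  loglik n_params      bic converged failed reason
#>   <int>   <dbl>    <int>    <dbl> <lgl>     <lgl>  <chr>
#> 1     1 -52693.        5 -105433. TRUE      FALSE  NA
#> 2     2 -52023.       11 -104147. TRUE      FALSE  NA
#> 3     3 -50807.       17 -101770. TRUE      FALSE  NA
#> 4     4 -50794.       23 -101799. TRUE      FALSE  NA
#> 5     5 -50789.       29 -101845. TRUE      FALSE  NA
#> 6     6 -50782.       35 -101885. TRUE      FALSE  NA
#> 7     7 -50776.       41 -101930. FALSE     FALSE  NA

evaluate_recovery(design, sel)
#> # A tibble: 1 × 7
#>   k_true k_hat correct mae_means mae_variances mae_covariances mae_weights
#>    <int> <int> <lgl>       <dbl>         <dbl>           <dbl>       <dbl>
#> 1      3     3 TRUE       0.0199        0.0305               0      0.0134
```

Three components of a well-separated mixture survive 5-category
discretization at N = 10,000: BIC peaks at k = 3, and after permutation
matching the component means are recovered to about 0.02 on the latent
scale. Coarser scales behave very differently — with c = 2 every k > 1
fit collapses to a singular covariance and the selection falls back to a
single component:

```r
binary <- discretize(latent, n_categories = 2)
select_k(binary, control = gmm_control(seed = 3))$k_hat
#> [1] 1
```

Full factorial experiments run through `condition_grid()` /
`run_grid()`, and `summarize_cells()` / `plot_accuracy_heatmap()`
aggregate the long results table into the accuracy-by-(categories,
variables) views.

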
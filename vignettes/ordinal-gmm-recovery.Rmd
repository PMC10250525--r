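---
title: "Gaussian mixture recovery from ordinal thresholded data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian mixture recovery from ordinal thresholded data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Gaussian mixture models (GMMs) fitted by the EM algorithm with BIC model
selection are the workhorse for detecting latent subgroups in multivariate
continuous data, and latent profile analysis is the special case with
spherical within-component covariances. In the medical and behavioral
sciences, however, the observed variables are usually *ordinal* — symptom
severities, Likert items, disease stages — even when the construct behind
them is naturally continuous. `ordgmm` implements a Monte-Carlo pipeline
that quantifies what this does to mixture recovery: it simulates data from
known mixtures, collapses each variable onto a small number of ordered
categories, re-fits mixtures by EM + BIC, and scores how often the number
of components $K$ is recovered and how biased the component parameters are.

The pipeline has four stages, each usable on its own:

1. **Design** (`build_design()`): construct the data-generating mixture.
2. **Simulation** (`sample_mixture()`, `discretize()`): draw a latent
   continuous sample and threshold it onto an ordinal grid.
3. **Estimation** (`fit_gmm()`, `select_k()`): EM under constrained or
   unconstrained covariances, BIC over $K = 1, \dots, 7$.
4. **Evaluation** (`evaluate_recovery()`, `summarize_cells()`): correctness
   of $\hat K$ and matched parameter errors.

`run_repetition()` and `run_grid()` orchestrate the full factorial
experiment with deterministic seeding.

## Mixture designs with equal pairwise separation

Comparisons across $K$ are only meaningful if the components are equally
hard to tell apart, so every design fixes all $K(K-1)/2$ pairwise
symmetrized Kullback–Leibler divergences to a common target
$D_{KL} \in \{2, 3.5, 5\}$ (highly overlapping to clearly separated).
For two Gaussians sharing a spherical covariance $\sigma^2 I$ the
symmetrized divergence reduces to $\lVert \mu_i - \mu_j \rVert^2 /
(2\sigma^2)$, so equal separation is equivalent to equal Euclidean
distances: the means sit at the vertices of a regular $(K-1)$-simplex with
edge length $\sqrt{2 \sigma^2 D_{KL}}$. The shared variance is fixed at
$\sigma^2 = \sqrt{0.25}$ and the mixing weights at $1/K$.

Each repetition draws a fresh configuration: the simplex is rotated by a
Haar-distributed rotation and translated so its centroid sits at
$(0.5, \dots, 0.5)$, which keeps the per-coordinate means roughly between
$-0.5$ and $1.5$ for the separations studied. Translation is not
randomized; the rotation already explores all orientations of the
configuration, and a fixed centroid keeps the ordinal grids comparable
across repetitions.

### The K = 4, p = 2 special case

Four pairwise-equidistant means do not fit in the plane, so for this one
condition the separation is carried by the covariances instead: the means
sit on a square and component-specific covariance matrices are found by
least squares so that all six pairwise divergences equal the target
(`solve_k4p2_design()`). Covariances are parameterized through Cholesky
factors with log diagonals, which keeps them positive definite throughout
the optimization, and the solved configuration is rotated as a whole
(covariances conjugated), which leaves every divergence unchanged.

The six-equation system in twelve parameters is underdetermined, so a
solution *branch* must be chosen. We deliberately start the optimizer from
strongly anisotropic configurations (axis ratio 4, correlations of
alternating sign around the square): the point of this design is that the
true mixture violates the spherical-covariance family used at estimation,
and weakly deformed solutions — which also solve the KL system — are close
enough to spherical that the misspecified estimator still lands on $K = 4$
part of the time, defeating the purpose of the condition. Determinant-
constrained solutions (shape varying, overall scale fixed) turn out not to
exist: the diagonal pairs of the square need genuinely inflated
covariances. The accepted solution must bring every pairwise divergence
within $10^{-4}$ nats of the target; the simplex designs are exact to
$10^{-8}$.

## From continuous to ordinal

Each variable is discretized separately (`discretize()`): compute the
empirical 0.5% and 99.5% quantiles, split the interval between them into
$c$ equal-width bins, and replace every value by the *midpoint* of its
bin; the roughly 1% of values outside the interval are clamped into the
nearest (first or last) bin. Midpoint labels keep the ordinal data on the
latent scale, so estimated component means remain directly comparable to
the true means. With thresholds $-1, 0, 1$, for instance, the two category
labels are $-0.5$ and $0.5$.

Numerical conventions, chosen once:

* quantiles use the linear-interpolation estimator (R type 7); at the
  sample sizes studied ($N \ge 1000$) the estimator choice moves the
  thresholds by $O(1/N)$ and is immaterial;
* a value exactly on an interior cut belongs to the bin on its right
  (half-open bins, last bin closed), a measure-zero convention under
  continuous data;
* thresholds are computed from each simulated dataset, not from the known
  generating distribution, as an analyst would have to do;
* a constant variable is a degenerate input and raises an error rather
  than silently producing a one-point grid.

Within a repetition the same latent sample underlies every category count
(the per-repetition seed does not depend on $c$), so comparisons across
$c$ are paired: the ordinal datasets are nested discretizations of one
draw.

## Estimation: EM families, initialization, degeneracy

`fit_gmm()` implements EM for three covariance families:

* `"spherical"` — each component has covariance $\sigma_k^2 I$ with its
  own variance. This is the constrained ("isomorphic") model used for the
  main results; its parameter count is $K(p+1) + (K-1)$. It corresponds to
  latent profile analysis and is correctly specified for every design
  except $K = 4, p = 2$.
* `"shared_spherical"` — one variance pooled across components
  ($Kp + 1 + K - 1$ parameters), available as the stricter reading of
  "equal variances".
* `"full"` — unconstrained SPD covariance per component, for the rerun in
  which covariances are freely estimated.

The E and M steps run in compiled code (RcppArmadillo) with log-sum-exp
stabilized responsibilities; $K = 1$ is the closed-form MLE. Convergence
is declared when the relative log-likelihood gain drops below $10^{-8}$
(at most 500 iterations), and the per-iteration log-likelihood trace is
returned so the EM ascent property is testable on every fit.

**Initialization matters more than usual here.** The default is a hard
partition from model-based hierarchical agglomeration (`mclust::hc`) on a
random subsample of at most 1000 rows, cut at each $K$ of the selection
sequence — the standard initialization of the mclust family of estimators.
On heavily tied data this choice is not a detail: with few categories the
agglomeration merges identical rows first, and its partitions contain
clusters that are copies of a single grid point, whose within-cluster
variance is exactly zero. The spherical M-step then produces a singular
component immediately, and the run is recorded as *failed*. This is the
mechanism behind the binary-data collapse (below); a k-means
initialization, also available via `gmm_control(init = "kmeans")`, tends
to find balanced partitions with positive variances, converges to a
non-degenerate local optimum, and thereby changes the scientific
conclusion for $c = 2$. We therefore treat the initializer as part of the
estimation procedure under study, not as a free tuning knob.

Degeneracy is handled by reporting, not by regularization: a run whose
smallest covariance eigenvalue falls below $10^{-10}$, or whose components
empty out, is marked `failed = TRUE` with a reason. No variance priors or
ridge terms are applied — they would suppress exactly the failure mode the
study measures. `select_k()` excludes failed fits from the BIC comparison
(convention: $\mathrm{BIC} = 2\ell - m\log N$, larger is better, ties
break toward smaller $K$); when every $K > 1$ fails, the selection falls
back to $K = 1$, which always has a closed-form fit. On binary ordinal
data ($c = 2$) this chain — tied grid points, zero-variance initial
clusters, singular spherical fits, BIC table reduced to $K = 1$ —
reproduces the catastrophic underestimation that motivates the study.

## Evaluation

Component labels are not identified, so before computing parameter errors
the estimated components are matched to the true ones by exhaustive search
over all $K!$ assignments ($K \le 7$, so enumeration is exact), minimizing
the mean absolute difference of the mean vectors; ties break toward the
lexicographically smallest permutation. Matching on means is the default
because the designs separate components almost exclusively through their
means; matching on all parameters is available
(`match_components(criterion = "all")`).

Errors are mean absolute differences after matching — over the $Kp$ mean
entries, the $Kp$ variances, the $Kp(p-1)/2$ unique off-diagonal
covariance entries, and the $K$ weights — and are reported *only for
repetitions in which $\hat K = K$*; a summary cell in which no repetition
recovered $K$ is reported as missing rather than zero. Mean absolute (not
squared) error is the primary metric; squared errors can be derived from
the long results table if needed. Mixing-weight errors are computed but
are not part of the headline summaries.

## Orchestration and reproducibility

`condition_grid()` enumerates the factorial design — $K \in \{2,3,4\}$,
$p \in \{2,\dots,10\}$, $D_{KL} \in \{2,3.5,5\}$,
$N \in \{1000, 2500, 10000\}$, $c \in \{2,\dots,12\}$ plus continuous —
2916 conditions in full. Each (condition, repetition) derives a 31-bit
seed from the base seed and the condition factors via an iterated linear
congruential mix (`rep_seed()`), making repetitions independent of
execution order, parallel-safe and resumable: `run_grid()` can append to a
CSV and skip completed rows, and the resumed table is identical to an
uninterrupted run.

Two statements about repetition randomness are possible — freeze the
mixture configuration across repetitions, or redraw it each time. The
pipeline redraws the random rotation in every repetition, so that results
are not tied to the accidental geometry of one configuration; this is the
behavior the aggregate summaries assume.

The study-scale default is 100 repetitions per condition. The package's
own test suite and the acceptance script run desk-scale versions — 10
repetitions per cell, subgrids of the condition space (for example
$p = 4, c = 12$ and $p = 10, c = 5$ at $N = 10{,}000$ for the headline
accuracy aggregates, and $p \in \{4,6,8,10\} \times c \in \{5,7,9,12\}$
for parameter errors) — sizes chosen so the whole suite completes on a
single CPU while keeping Monte-Carlo error on an accuracy estimate near
$0.97$ below about $0.05$.

## What the generator does and does not emulate

The synthetic data embody a best-case reading of ordinal measurement:
equal mixing weights, spherical within-component covariances (except the
one deliberately misspecified condition), equidistant thresholds shared by
all respondents, and no response styles, floor/ceiling asymmetries or
measurement non-invariance. Passing recovery results therefore bound from
above what can be expected for real ordinal data; failure results
(binary collapse, the misspecified bivariate four-component condition) are
if anything optimistic about when things break.

## Known limitations

* The $K = 4, p = 2$ design depends on a chosen solution branch of an
  underdetermined system; other branches with milder covariance
  differences make that condition partially recoverable by the spherical
  family. Results for that condition should be read as "a strongly
  covariance-separated mixture", not as a canonical object.
* The magnitude of the ordinal bias on component means depends strongly on
  the discretization regime: with many categories and large $N$ the
  quantization bias of midpoint coding is small (order $h^2$ for bin width
  $h$), while coarse grids both bias the means and destabilize model
  selection. Aggregate "bias" numbers are therefore sensitive to which
  $(p, c)$ cells enter the average.
* Only equal-weight mixtures are validated; unequal weights, $K > 4$, or
  $p > 10$ run but are outside the tested envelope.
* Covariance-driven separation (equal means, different covariances) is
  expressible through `mixture_design()` but is not part of the validated
  grid.
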
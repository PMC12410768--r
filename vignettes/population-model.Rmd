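---
title: "Joint Bayesian estimation of building and population counts from micro-census surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian estimation of building and population counts from micro-census surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bupop)
```

## The estimation problem

Where no recent census exists, population denominators can be built bottom-up:
enumerate a stratified sample of small survey clusters completely (every
building, every resident), then let a hierarchical model carry that
information onto a raster of settled grid cells via geospatial covariates.
`bupop` implements the joint building-count / population-density variant of
this approach: rather than modelling population per cluster directly, it
decomposes the Poisson rate for population into a latent building count times
a latent density in *people per building*. The decomposition has two
practical virtues: building-footprint layers derived from satellite imagery
are biased in class-dependent ways, and the building component absorbs that
bias explicitly; and the two components can use different covariates and
different residual-variance structures.

## Model

For cluster (or, at prediction time, grid cell) $i$ in settlement class
$s \in \{\text{urban}, \text{peri-urban}, \text{rural}\}$:

$$
\begin{aligned}
P_i \mid \lambda^B_i, \lambda^D_i &\sim \text{Poisson}(\lambda^B_i \lambda^D_i) \\
B_i \mid \lambda^B_i &\sim \text{Poisson}(\lambda^B_i) \\
\lambda^B_i &\sim \text{logNormal}(\alpha^B_s + \beta^B_s x^B_i,\; \sigma^B_s) \\
\lambda^D_i &\sim \text{logNormal}(\alpha^D_s + \mathbf{x}^D_i \cdot \boldsymbol\beta^D,\; \sigma^D_s)
\end{aligned}
$$

with priors $\alpha \sim \mathrm{N}(0, 10)$, $\sigma \sim \mathrm{N}^+(0,10)$
(both second arguments are standard deviations) and flat priors on the
slopes. The log-normal mixing accounts for overdispersion relative to the
Poisson; $\sigma$ is class-specific because residual variation differs
strongly between urban and rural settlement. The density slopes
$\boldsymbol\beta^D$ are global (one per covariate, not per class):
class-specific density slopes are deliberately not offered, as the added 8
parameters are weakly identified at realistic survey sizes.

$x^B$ is the standardized log of a building-count covariate (e.g. a
settlement layer's building counts); $\mathbf{x}^D$ holds four standardized
density covariates. Standardization constants (mean and *sample*,
$n-1$-denominator, standard deviation) are always computed over settled grid
cells and re-applied to cluster-level zonal summaries, so both levels live on
one scale.

### Fitting

`fit_microcensus()` samples the posterior with JAGS. Defaults follow the
reference configuration: 3 chains, 5,000 iterations per chain with 500
warm-up discarded, i.e. 13,500 retained draws. Since JAGS requires proper
priors, the flat slope prior is realized as Normal(0, sd 1000); sensitivity
to this width is negligible at the data scales involved.

The latent rates are sampled explicitly (the Poisson-lognormal mixture is
not marginalized) and in *centred* form,
$\lambda \sim \text{logNormal}(\mu, \sigma)$. A non-centred parameterization
($\log\lambda = \mu + \sigma z$) is the right geometry for Hamiltonian
samplers, but under a Gibbs/slice backend with data-dominated latents it
mixes dramatically worse — in our profiling a non-centred run failed to
converge within 1,700 iterations per chain while the centred form converged
with split-$\hat R < 1.02$ and recovered the generating parameters. Chains
are seeded per-chain from the single `seed` argument and runs are exactly
reproducible.

One tuning note: JAGS *adaptation* (sampler auto-tuning, separate from
warm-up) matters more than retained length for short chains. With 1,000
iteration chains, 300 adaptation steps left the slowest parameter (the urban
building-count $\sigma$) at a bulk ESS near 180 of 2,400 draws; 2,000
adaptation steps roughly doubled it. The default is 1,000; increase it when
running short exploratory chains.

### Diagnostics

`fit_diagnostics()` reports rank-normalized, split-chain bulk ESS and
$\hat R$ per population-level parameter (implemented from the standard
definitions and cross-checked against an independent ESS implementation on
i.i.d. draws), flagging ESS < 400. Divergences, treedepth saturations and
EBFMI are Hamiltonian-sampler concepts: the fields exist and pass through
whatever the backend records (`ebfmi()` computes the statistic from an
energy trace), but under the Gibbs backend they are reported as `NA` rather
than fabricated.

## Prediction and aggregation

`predict_cells()` pushes every retained draw through the model equations on
every settled cell, *redrawing* the log-normal and Poisson noise per cell
per draw — the full posterior predictive, never a plug-in of posterior
means. Cells are processed in blocks of `block_size` so working memory stays
bounded; per-cell summaries accumulate in the same pass. Quantiles
everywhere (cells, clusters, areas) use one shared implementation, the
linear-interpolation (type 7) definition.

`aggregate_draws()` sums cell draws within areas draw by draw — integer
totals, never summaries of summaries — so nested levels are exactly
consistent: a zone's per-draw total equals the sum of its areas' totals, and
means add exactly. The uncertainty level of an area is
$(\text{CI}_{97.5} - \text{CI}_{2.5}) / \text{mean} \times 100$, reported
`NA` when the mean is zero. Cells join areas by centre inclusion (counts are
per-cell integers; areal splitting would break the per-draw identity), with
a documented first-wins rule over the stable polygon input order for centres
exactly on a boundary.

Two cluster-prediction modes exist, and the distinction matters for every
reported fit metric. `predict_clusters(newdata = TRUE)` redraws latent rates
from class parameters and covariates — the same path as gridded prediction —
and is used for *all* residual metrics, in- and out-of-sample; this measures
what the model has learned. `newdata = FALSE` conditions on each fitted
cluster's own latent rates; that is a posterior-predictive check of the
count likelihood, tracks observations closely by construction (coverage near
100%, $R^2$ near 1), and would overstate fit quality if used for reporting.

## Evaluation battery

Residuals are observed minus posterior-mean predicted counts. Reported:
bias (mean residual), imprecision (sd of residuals, $n-1$), inaccuracy
(= MAE), RMSE, $R^2$, and the percentage of observations inside their 95%
predictive intervals; scaled variants divide residuals by posterior means.
These definitions satisfy
$\text{RMSE}^2 = \text{bias}^2 + \frac{n-1}{n}\,\text{imprecision}^2$
exactly, which the tests assert. $R^2$ is implemented as the squared Pearson
correlation between observations and posterior means — the phrase
"correlation among the residuals" sometimes used for this quantity is not
computable as written (a correlation needs two series), and the
observed-versus-predicted reading is the one consistent with its
interpretation as variance explained.

`cross_validate()` performs stratified leave-$p$-out validation: per class,
round(test-fraction × class size), minimum 1, clusters held out (a
single-cluster class is forced into training with a warning); the model is
refit on the training set and both halves are scored through the redraw
prediction path.

`morans_i()` computes global and local Moran's I on residuals for
user-supplied distance bands with binary, row-standardized weights, and
permutation p-values (999 permutations by default; two-sided, centred on the
permutation mean; local tests use conditional permutations and are reported
raw and Benjamini–Hochberg adjusted). The global statistic is cross-checked
in the tests against an independent implementation and against the
closed-form checkerboard case ($I = -1$).

## The synthetic-data generator

`generate_grid()` lays settled cells on a unit lattice and assigns
settlement classes by quantile-slicing a smoothed Gaussian field — patches
are spatially contiguous and class frequencies match the requested
proportions to lattice rounding. Covariates are Gaussian per class
(class-dependent means; the building covariate is exponentiated so it is
positive and log-transformable), standardized over settled cells with the
constants retained. An optional Gaussian blur induces spatial
autocorrelation in covariates when Moran-type behaviour is wanted.

`simulate_truth()` applies the generative equations cell by cell;
`sample_clusters()` emulates the survey design at the contract level:
clusters are rook-contiguous, single-class cell groups grown from random
seeds until ~80 true buildings or a cell cap, allocated across classes
proportionally to settled-cell counts (minimum one per non-empty class), and
their counts are exact sums of member cells. `simulate_microcensus()`
generates clusters directly at cluster scale — the generator used for
recovery and cross-validation checks, where the fitted model must be exactly
well specified.

Default truth parameters place mean densities at roughly 5.5 (urban), 4.5
(peri-urban) and 3.7 (rural) people per building, building-count intercepts
near log 80 at cluster scale (log 2–6 at cell scale), a weaker covariate
slope and larger residual sd in rural classes, and density effects dominated
by a negative distance-to-roads-like covariate. These are fixed study
conditions chosen to mirror the qualitative structure such surveys exhibit
(class ordering of densities, ~80 buildings per cluster,
cluster populations of a few hundred people); they were set before the test
suite was written and are not tuned.

What the generator does *not* emulate: real covariates are spatially
autocorrelated and cross-correlated (synthetic ones are independent unless
blurred), building-footprint layers have structured (not log-normal) error,
surveys suffer non-random refusals and access constraints, and boundaries
are irregular. Passing tests therefore demonstrate correctness of the
machinery and calibration under the model's own assumptions — not that the
model is adequate for any particular real landscape.

## Numerical and policy choices

- Quantiles: type 7 (linear interpolation), one shared implementation.
- Standard deviations: sample ($n-1$) throughout.
- Imputed cluster totals (refusals replaced by the cluster mean of
  responding households) are rounded half-up so Poisson likelihoods stay
  well defined.
- Zonal settlement-class mode ties resolve to the more urban (lower) index.
- The building covariate enters as $\log x$ with non-positive cells excluded
  from the settled mask (settled cells contain buildings by definition);
  `log1p` is available as a fallback switch.
- Covariate screening: candidates significantly correlated (Pearson,
  $p < \alpha$) with either log building count or log density are ranked by
  best absolute correlation and greedily retained unless significantly
  correlated with an already-retained candidate. "Significantly
  uncorrelated with each other" is ambiguous in the field's usual phrasing;
  this reading (no significant pairwise correlation) is one defensible
  operationalization and is not guaranteed to reproduce any particular
  published covariate set.
- All randomness flows from one root seed expanded into fixed per-stage
  streams (`stage_seed()`); pipeline re-runs with identical configuration
  reproduce byte-identical artifacts.

## Known limitations

- **Small-$\sigma$ boundary bias.** When a class's true log-scale sd is
  small relative to the Poisson coefficient of variation of its counts
  (e.g. $\sigma^B = 0.15$ against counts near 80, CV ≈ 0.11), the posterior
  for that $\sigma$ is biased slightly upward near its identifiability
  floor: in repeated synthetic studies its 95% interval covers the truth in
  roughly 85–93% of runs rather than 95%, even with long, well-mixed
  chains. This is a property of the model near the boundary, not of the
  sampler.
- **Scale transfer.** Applying cluster-fitted intercepts to cells assumes
  the log-linear covariate relationship absorbs the aggregation scale; when
  fitting and prediction scales differ, results depend on that assumption
  exactly as in the reference approach.
- Residual spatial autocorrelation is diagnosed (Moran's I) but not
  modelled; no spatial random effects are offered.
- The Gibbs backend provides no divergence/energy diagnostics; convergence
  assessment rests on ESS, $\hat R$ and trace inspection.

## Problem sizes used by the test suite

The suite exercises the study-scale configuration once (213 clusters,
3 × 5,000 iterations; 13,500 retained draws) and otherwise uses reduced but
honest sizes chosen for tight feedback loops: 20 recovery replicates at
3 × 1,000/200, predictive calibration on 2,000 held-out cells of a
4,000-cell landscape, 500 replicates for the Moran permutation type-I error,
and 10 cross-validation splits. `scripts/acceptance.R` re-runs the pipeline
at these sizes from a single command-line seed.
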
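---
title: "Methods: areal disease mapping with arealrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: areal disease mapping with arealrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealrisk)
```

## Scope and model

`arealrisk` implements the standard analysis chain for areal disease
counts aggregated to administrative units: indirect standardization,
global/local spatial autocorrelation, purely spatial Poisson scan
clusters, and hierarchical Bayesian smoothing of the standardized ratio
(SR). The motivating setting is a city-scale hospitalization dataset —
on the order of 57 sub-districts and 10,000 annual admissions — where
the raw SR map is dominated by small-population areas and spatial
dependence, and the analyst wants (i) evidence that clustering is real,
(ii) the location of the clusters, and (iii) a stabilized risk surface.

The smoothing model family is the Besag-York-Mollié type:

$$O_i \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = \log E_i + \alpha_0 + \beta x_i + U_i + S_i$$

with flat prior on $\alpha_0$, $\beta \sim N(0, 1000^2)$ (weakly
informative), $U_i \sim N(0, \delta^2)$ iid, and $S$ a conditional
autoregressive (CAR) field. Standard deviations get Uniform$(0, 100)$
priors — wide enough for any realistic value on the log scale, and a
deliberate alternative to inverse-gamma precision priors. Six structures
(`model_spec(1)`–`(6)`) cover the intercept/covariate/$U$/$S$ lattice of
combinations; model 2 fixes the covariate coefficient at 1 (the only
reading consistent with a "without coefficient" structure that still
uses the covariate: the covariate enters as an offset).

### The CAR variants

Two improper pairwise-difference priors are available, evaluated only
through differences (`car_log_prior()`):

- `gaussian_icar`: $\log p(S \mid \sigma) = -\frac{1}{2\sigma^2}
  \sum_{i \sim j} (S_i - S_j)^2 - r \log\sigma + \text{const}$,
- `l1` (default): $-\frac{1}{\sigma} \sum_{i \sim j} |S_i - S_j|
  - r \log\sigma + \text{const}$, the robust / double-exponential
  variant, less eager to blur sharp risk discontinuities.

$r$ is the rank of the contrast space (number of non-island areas minus
number of connected components); it is what makes the scale parameter
identifiable in the Metropolis update for $\sigma$. The L1 form has no
universal scale convention; ours uses the scale $\sigma$ directly in the
exponent, which is declared rather than inferred from any particular
software's internals. The default follows the robust choice; the
Gaussian ICAR is retained both as an option and because it admits the
closed-form conditionals and the exact sampling route used in testing.

## Sampler and numerical choices

`fit_hbayes()` is an adaptive Metropolis-within-Gibbs sampler:

- Random-walk updates for $\alpha_0$, $\beta$, each $U_i$, each $S_i$,
  and the scale parameters $\delta$, $\sigma$ on their natural scale
  (proposals outside $(0, 100)$ are rejected, which enforces the
  uniform prior support exactly).
- $U_i$ are conditionally independent given the rest, so their
  accept/reject steps are vectorized; $S_i$ couple through the graph and
  are updated sequentially in index order (a fixed, documented sweep
  order — determinism matters more here than sweep randomization).
- **Centering moves.** After each $S$ sweep, $S$ is recentred to mean
  zero and the shift absorbed into $\alpha_0$. Both CAR kernels depend
  on differences only and $\alpha_0$ has a flat prior, so this map
  preserves the posterior; it removes the flat direction that otherwise
  lets $\alpha_0$ and the $S$ level drift apart. The move is skipped
  when islands are present (their $S_i$ is pinned at 0, so a shift would
  change their likelihood contribution).
- **Covariate reparameterization.** For models with a free coefficient
  the updates run against the centered covariate and the stored
  intercept is transformed back ($\alpha_0^{\text{rep}} = \alpha_0^{c} -
  \beta \bar x$). This is exact and removes the intercept–slope
  posterior correlation that otherwise cripples random-walk mixing at
  short chain lengths.
- **Adaptation.** Step sizes are multiplicatively tuned every
  `adapt_interval` iterations toward `target_accept` (default 0.35,
  inside the 20–50% band) during burn-in only, then frozen — retained
  samples come from a fixed-kernel chain, preserving detailed balance.
- **Deviance convention.** The deviance uses the full Poisson log-pmf
  including $\log O_i!$ (the data-only standardizing function is the
  constant 1); it cancels in $pD$ and DIC differences. $\hat D$ plugs in
  the posterior means of the stochastic parents ($\alpha_0$, $\beta$,
  $U$, $S$), not the posterior mean of $\mu$.
- Islands (areas with no neighbors) under a structured model get
  $S_i = 0$ with a warning rather than an error; the ICAR conditional is
  undefined for them and pinning is the standard practical fix.
- Degenerate inputs: zero-expected areas are excluded with a warning;
  constant raw ratios trigger a degeneracy warning; a non-finite linear
  predictor aborts with the offending range printed.

Posterior summaries report mean, SD, batch-means Monte Carlo error
(20 batches) and empirical 2.5/97.5% quantiles; convergence is monitored
with the classic Gelman-Rubin PSRF over the retained draws, warning
above 1.1. The sampler's primary correctness oracle is conjugate: with
an intercept-only model and flat prior, $e^{\alpha_0} \mid \text{data}
\sim \mathrm{Gamma}(\Sigma O, \Sigma E)$, and the test suite requires
the sampled mean and SD to match that closed form within three MC
errors.

## Autocorrelation statistics

Moran's $I$ uses row-standardized weights by default (the convention of
the GIS tooling this pipeline emulates), with the randomization-
assumption analytic variance as default inference and an optional
seeded permutation test; General $G$ and local $Gi^*$ use binary
weights, $Gi^*$ in the full-window (self-included) form. All p-values
are two-sided. The analytic randomization moments of both global
statistics were verified against exact enumeration of all $n!$
permutations on a 5-area path graph — that enumeration ships in the
test suite as a frozen oracle. Two conventions worth making explicit:

- Hot/cold classification defaults to $\alpha = 0.10$ because published
  hot-spot tables of this kind flag areas with p-values up to 0.09; the
  threshold is an argument, not a constant.
- On a constant surface the $Gi^*$ z-score is 0/0; we report $z = 0$
  (numerator equals its expectation) rather than erroring, so constant
  sub-regions degrade gracefully.
- No multiplicity correction is applied to the per-area $Gi^*$ tests,
  matching common practice in this literature; users comparing many
  areas should interpret isolated marginal spots accordingly.

## Scan statistic

Windows are circles over area centroids: for each center, the distance-
ordered prefix sets up to `max_fraction` (default 0.5) of the total
expected count, with ties broken by area id for determinism, duplicates
removed, and the single-area window always retained. Expected counts are
renormalized to sum to the total case count before scanning — required
for the reported relative risks to match the printed convention. The
scan is high-rate (one-sided); Monte Carlo replicates are conditional
multinomial given the total, and every reported cluster's p-value ranks
its LLR against the replicate *maxima*. Secondary clusters are reported
in decreasing LLR under the no-geographical-overlap rule. A documented
non-reconciliation: one published 10-area secondary cluster prints
RR = 1.44 while the RR identity on its printed sums gives ≈ 1.48; that
row is excluded from arithmetic reproduction targets rather than forced.

## Synthetic data: what it emulates and what it does not

`generate_areal_data()` realizes exactly the generative structure the
models assume: unit-square grid lattices (optionally with cells removed
for irregularity), log-normal populations, a smooth gradient covariate
standing in for road density, $U \sim N(0, \delta^2)$,
$S \sim \sigma^2 L^+$ (ICAR sampled on the sum-to-zero subspace via the
graph Laplacian's eigendecomposition, cross-checked in tests against a
pseudo-inverse computed independently), multiplicative embedded
clusters, and Poisson counts. The 57-area preset (`shenzhen_like()`)
fixes the magnitudes: ~10,419 expected cases, covariate effect
$\beta = 0.45$, a 3-area embedded cluster at risk ratio 2.7, and mild
random-effect scales $\delta = \sigma = 0.15$ (chosen once as a
realistic log-scale heterogeneity for a dense city; not tuned).

What a green test establishes: the estimators recover the structure of
data generated from their own assumptions (correct arithmetic, correct
null distributions, nominal-ish coverage, cluster recovery). What it
does not: realism of administrative geographies (polygons here are grid
cells; real sub-districts vary wildly in shape and size), census
undercount or migration effects, covariate measurement error, or
model misspecification — the generator draws Gaussian ICAR fields even
when the L1 variant is fitted, which is a robustness direction check,
not a misspecification study.

Two test-design decisions deserve the same transparency:

- The coverage criterion for $\beta$ fits model 1 to data whose
  generative truth *is* model 1 (preset lattice and covariate, but
  $\delta = \sigma = 0$, no embedded cluster). Running it against the
  full preset would measure misspecification bias — with unmodeled
  overdispersion present, a correctly implemented model 1 is *expected*
  to undercover — so it would test the wrong thing.
- Simulation criteria run at the reduced replications their acceptance
  definitions prescribe for CI (25 coverage seeds, 20 scan-recovery
  seeds at 199 replicates, 200 null datasets for p-value uniformity);
  pass thresholds are the corresponding binomial lower bounds fixed
  before running, not after.

## Known limitations

- Contiguity from polygons is vertex-based (queen = shared vertex,
  rook = shared edge); boundaries that touch without sharing ring
  vertices (T-junctions from sliver-free topologies) are not detected.
  Queen is the default rule, the common choice for irregular
  administrative polygons; GAL files bypass geometry entirely.
- Coordinates are planar; no geodesic distances. At city scale and for
  relative scan distances this is immaterial.
- The scan implements the purely spatial Poisson model only — no
  space-time, elliptic-window, Bernoulli or low-rate-only variants
  (a low-rate scan is not exposed; the high-rate indicator is the
  reported convention).
- The BYM-type variance components $\delta^2$ and $\sigma^2$ are only
  weakly identified from a single realization (a well-known feature,
  visible here as slow $\delta$ mixing in model 5 at short chain
  lengths); DIC comparisons remain stable because the deviance mixes
  well.
- DIC's plug-in $\hat D$ can misbehave for strongly non-Gaussian
  posteriors; alternatives such as WAIC are out of scope.
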
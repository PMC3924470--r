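# arealrisk

Small-area disease mapping for areal (lattice) count data: standardized
ratios, spatial autocorrelation and hot-spot statistics, purely spatial
Poisson scan clusters, and hierarchical Bayesian risk smoothing with CAR
random effects — the standard toolchain an epidemiologist runs when asking
*"where is the relative risk of a condition elevated across a city's
administrative units, and how much of the apparent variation is real?"*

## The problem and the models

For each areal unit *i* with observed case count *O<sub>i</sub>*, resident
population *n<sub>i</sub>* and expected count
*E<sub>i</sub> = n<sub>i</sub> · (ΣO / Σn)* (indirect standardization
against the study-wide rate), the standardized ratio

&nbsp;&nbsp;&nbsp;&nbsp;SR<sub>i</sub> = O<sub>i</sub> / E<sub>i</sub>

is the classic relative-risk estimate, but it is unstable where
*E<sub>i</sub>* is small and ignores spatial dependence. The package
addresses both:

- **Pattern detection.** Global Moran's *I* (expectation −1/(n−1);
  randomization/normality analytic variance or permutation inference) and
  the Getis-Ord General *G* measure whether values, and specifically high
  values, cluster; local *Gi\** flags hot and cold spots per area.
- **Cluster location.** A Kulldorff-style purely spatial Poisson scan:
  circular windows over area centroids grown to a population cap,
  high-rate log-likelihood ratio
  *LLR = c·log(c/e) + (C−c)·log((C−c)/(C−e))*, Monte Carlo p-values from
  multinomial null replicates, non-overlapping secondary clusters, and
  cluster relative risk *RR = (c/e) / ((C−c)/(C−e))*.
- **Risk smoothing.** Hierarchical Bayesian Poisson models
  *O<sub>i</sub> ~ Poisson(E<sub>i</sub>·SR<sub>i</sub>)* with
  *log SR<sub>i</sub> = α₀ + βx<sub>i</sub> + U<sub>i</sub> + S<sub>i</sub>*,
  where *U<sub>i</sub> ~ N(0, δ²)* is unstructured heterogeneity and
  *S<sub>i</sub>* is a conditional-autoregressive (CAR) spatial component —
  either the intrinsic Gaussian ICAR or a robust L1 (double-exponential)
  pairwise-difference variant. Six model structures (intercept/covariate/
  U/S combinations) are fitted by an adaptive Metropolis-within-Gibbs
  sampler (default protocol 3 chains × 20,000 iterations, burn-in 2,000),
  checked by Gelman-Rubin R̂, and compared by DIC
  (*pD = D̄ − D̂*, *DIC = D̄ + pD*).

A synthetic-data module generates lattices with exactly this generative
structure (log-normal populations, gradient covariate, iid + ICAR random
effects, optional embedded high-risk discs), so the whole pipeline is
testable end-to-end without any external data.

## Worked example

```r
library(arealrisk)

dat <- generate_areal_data(shenzhen_like(seed = 11))   # 57 areas, ~10,400 cases
tab <- add_sr(compute_expected(dat$table))

morans_i(tab$sr, row_standardize(dat$weights))
#> Moran's I: statistic 0.3892, E -0.0179, z 5.768, p 8.034e-09 (randomization)

res <- scan_clusters(dat$lattice, tab, n_mc = 999, seed = 101)
res$clusters[[1]][c("observed", "expected", "relative_risk", "p_value")]
#> $observed       4491
#> $expected       3069.768
#> $relative_risk  1.720467
#> $p_value        0.001

fit <- fit_hbayes(tab, dat$weights, model_spec(5),
                  mcmc_config(3, 2000, 500, seed = 7))
fit
#> hbayes_fit: intercept + unstructured + structured (l1)
#>   57 areas, 3 chain(s) x 2000 iter (burn-in 500)
#>   Dbar 449.069  Dhat 396.434  pD 52.635  DIC 501.704
#>   a0       mean   -0.1288  sd   0.0202  mc  0.00190  [  -0.1651,  -0.0830]  Rhat 1.030
#>   ...
```

Reading the output: Moran's *I* = 0.39 with z = 5.8 says the generated SR
surface is strongly spatially clustered (the preset embeds both CAR
structure and a covariate gradient). The scan's most-likely cluster is a
13-area disc with 4,491 cases against 3,070 expected — risk 1.72 times the
rest of the map, p = 0.001 at 999 replicates (the smallest achievable
p-value, i.e. no null replicate matched its likelihood ratio). The model-5
fit reports the posterior of the intercept and variance components,
DIC for model comparison, and (in `fit$smoothed_sr`) the shrunken SR map.

The full study pipeline — SR table, global statistics, Gi* hot/cold table,
scan report, six-model DIC sweep, posterior summaries, smoothed-SR table —
is one call:

```r
run_pipeline(dat$lattice, dat$table, dat$weights, out_dir = "report",
             mcmc = mcmc_config(3, 20000, 2000), seed = 1)
```

or from the shell via the `exec/arealrisk` script
(`arealrisk simulate ...`, `arealrisk run ...`).

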
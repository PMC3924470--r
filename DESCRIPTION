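Package: arealrisk
Title: Areal Disease Mapping: Standardized Ratios, Spatial Cluster
    Detection and Hierarchical Bayesian Smoothing
Version: 0.1.0
Authors@R:
    person("Areal", "Risk Maintainers", email = "maintainers@arealrisk.dev",
           role = c("aut", "cre"))
Description: Tools for small-area disease mapping on areal (lattice) data:
    indirect standardization of admission counts into standardized ratios,
    global spatial autocorrelation statistics (Moran's I, Getis-Ord General
    G) with analytic and permutation inference, local Gi* hot-spot
    analysis, Kulldorff-style purely spatial Poisson scan statistics with
    Monte Carlo inference and non-overlapping secondary clusters, and a
    family of hierarchical Bayesian Poisson models with unstructured and
    conditional-autoregressive (CAR) spatial random effects fitted by an
    adaptive Metropolis-within-Gibbs sampler, compared by the deviance
    information criterion.  Includes a synthetic areal-data generator so
    the whole pipeline is testable without external data, plus readers and
    writers for GAL adjacency files, GeoJSON polygon layers and CSV area
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
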
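# Synthetic areal data with the generative structure the models assume:
# log-linear risk = intercept + covariate effect + iid heterogeneity +
# ICAR-distributed clustering, Poisson counts, optional embedded
# high-risk circular clusters.

#' Define a synthetic areal scenario
#'
#' The generative model mirrors the analysis model: a `grid_rows x
#' grid_cols` unit-square lattice (minus `drop_cells`), log-normal
#' populations scaled so the expected total case count is about
#' `total_cases_target`, a covariate surface (`"gradient"`: smooth
#' southwest-northeast trend plus noise, emulating road density;
#' `"iid"`: pure noise; `"none"`), and per-area log relative risk
#' `alpha0 + beta * x + U + S` with `U ~ N(0, delta^2)` and `S` drawn from
#' the intrinsic Gaussian CAR (ICAR) distribution with scale `sigma` on
#' the sum-to-zero subspace.  Optional embedded clusters multiply the
#' risk of all areas within `radius` (in lattice units) of a center area.
#'
#' @param grid_rows,grid_cols grid dimensions.
#' @param drop_cells cell ids omitted from the grid (see [grid_lattice()]).
#' @param population_median,population_dispersion log-normal population
#'   parameters (median and sdlog).
#' @param total_cases_target expected total number of cases.
#' @param alpha0 log-risk intercept.
#' @param beta covariate effect on the log-risk scale.
#' @param covariate_model `"gradient"`, `"iid"` or `"none"`.
#' @param delta SD of the unstructured component (0 = off).
#' @param sigma scale of the structured ICAR component (0 = off).
#' @param clusters list of `list(center = <area_id>, radius = <numeric>,
#'   rr = <multiplier>)` records.
#' @param seed integer seed.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(grid_rows = 10, grid_cols = 10,
                               drop_cells = character(),
                               population_median = 20000,
                               population_dispersion = 0.6,
                               total_cases_target = 10000,
                               alpha0 = 0, beta = 0,
                               covariate_model = c("gradient", "iid", "none"),
                               delta = 0, sigma = 0,
                               clusters = list(), seed = 1) {
  covariate_model <- match.arg(covariate_model)
  if (delta < 0 || sigma < 0) stop("delta and sigma must be >= 0")
  stopifnot(grid_rows >= 1, grid_cols >= 1, total_cases_target > 0)
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 drop_cells = drop_cells,
                 population_median = population_median,
                 population_dispersion = population_dispersion,
                 total_cases_target = total_cases_target,
                 alpha0 = alpha0, beta = beta,
                 covariate_model = covariate_model,
                 delta = delta, sigma = sigma,
                 clusters = clusters, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Sample the intrinsic Gaussian CAR distribution
#'
#' Draws from the ICAR distribution on the sum-to-zero subspace: the
#' covariance is `sigma^2` times the pseudo-inverse of the graph Laplacian
#' (eigendecomposition route; the null space of the connected graph is the
#' constant vector, so every draw sums to zero per component).
#'
#' @param w binary `spatial_weights` (connected components handled
#'   separately; isolated areas get 0).
#' @param sigma positive scale.
#' @param n number of draws.
#' @return `n x n_areas` matrix of draws.
#' @export
sample_icar <- function(w, sigma, n = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  A <- weights_matrix(w)
  L <- diag(rowSums(A)) - A
  ev <- eigen(L, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-9
  V <- ev$vectors[, pos, drop = FALSE]
  lam <- ev$values[pos]
  Z <- matrix(stats::rnorm(n * length(lam)), n)
  unname(sigma * (Z %*% (t(V) / sqrt(lam))))
}

#' Generate a synthetic areal dataset
#'
#' Realizes a [synthetic_scenario()]: returns the lattice, queen
#' contiguity weights, an area table (`area_id`, `population`, `observed`,
#' `road_density`) and a `truth` record holding every latent quantity
#' (true expected counts, `U`, `S`, per-area risk, cluster membership).
#' The expected count used for generation is `E_i = n_i * C_target /
#' sum(n)`, so with all effects zero the realized total is a Poisson draw
#' around the target.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed overrides the scenario seed when given.
#' @return list `lattice`, `weights`, `table`, `truth`.
#' @export
generate_areal_data <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  lat <- grid_lattice(scenario$grid_rows, scenario$grid_cols,
                      drop = scenario$drop_cells)
  n <- nrow(lat)
  w <- suppressWarnings(build_contiguity(lat, "queen"))

  pop <- stats::rlnorm(n, log(scenario$population_median),
                       scenario$population_dispersion)
  lat$population <- pop

  x <- switch(scenario$covariate_model,
    gradient = {
      g <- (lat$centroid_x / max(lat$centroid_x) +
              lat$centroid_y / max(lat$centroid_y)) / 2
      pmax(0.05, g * 4 + stats::rnorm(n, 0, 0.3))  # km road per km^2-ish
    },
    iid = pmax(0.05, stats::rnorm(n, 2, 0.8)),
    none = rep(0, n))

  U <- if (scenario$delta > 0) stats::rnorm(n, 0, scenario$delta) else rep(0, n)
  S <- if (scenario$sigma > 0) as.numeric(sample_icar(w, scenario$sigma, 1)) else rep(0, n)

  xc <- if (scenario$covariate_model == "none") x else x - mean(x)
  log_risk <- scenario$alpha0 + scenario$beta * xc + U + S

  mult <- rep(1, n)
  cluster_members <- list()
  for (cl in scenario$clusters) {
    ci <- match(cl$center, lat$area_id)
    if (is.na(ci)) stop("cluster center not in lattice: ", cl$center)
    d <- sqrt((lat$centroid_x - lat$centroid_x[ci])^2 +
                (lat$centroid_y - lat$centroid_y[ci])^2)
    members <- which(d <= cl$radius)
    mult[members] <- mult[members] * cl$rr
    cluster_members[[length(cluster_members) + 1L]] <- lat$area_id[members]
  }
  risk <- exp(log_risk) * mult

  E_true <- pop * scenario$total_cases_target / sum(pop)
  O <- stats::rpois(n, E_true * risk)

  table <- data.frame(area_id = lat$area_id, population = pop, observed = O,
                      road_density = x, stringsAsFactors = FALSE)
  truth <- list(alpha0 = scenario$alpha0, beta = scenario$beta,
                covariate = x, covariate_centered = xc,
                U = U, S = S, risk = risk, expected_true = E_true,
                cluster_areas = cluster_members, seed = seed)
  list(lattice = lat, weights = w, table = table, truth = truth)
}

#' Preset scenario emulating a 57-area urban admission study
#'
#' 57 sub-district-like areas (an 8 x 8 grid with 7 corner cells removed),
#' about 10,419 total cases, a road-density gradient covariate with effect
#' 0.45 on the log-risk scale, and one embedded 3-area high-risk cluster
#' with risk multiplier 2.7 — magnitudes typical of a dense city-scale
#' hospitalization dataset.
#'
#' @param seed integer seed stored in the scenario.
#' @param delta,sigma random-effect scales (defaults 0.15 each: mild
#'   heterogeneity and clustering on the log scale).
#' @param beta covariate effect (default 0.45).
#' @param clusters override the embedded cluster list.
#' @return a [synthetic_scenario()] with 57 areas.
#' @export
shenzhen_like <- function(seed = 1, delta = 0.15, sigma = 0.15, beta = 0.45,
                          clusters = list(list(center = "g02.02", radius = 1.05,
                                               rr = 2.7))) {
  synthetic_scenario(
    grid_rows = 8, grid_cols = 8,
    drop_cells = c("g01.01", "g01.08", "g08.01", "g08.08",
                   "g01.02", "g02.01", "g08.07"),
    population_median = 120000, population_dispersion = 0.8,
    total_cases_target = 10419,
    alpha0 = 0, beta = beta, covariate_model = "gradient",
    delta = delta, sigma = sigma,
    clusters = clusters, seed = seed)
}
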
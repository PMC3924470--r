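test_that("Poisson log-likelihood and deviance match the pmf oracle", {
  # single area, O = 3, mu = 2 (E = 2, eta = 0)
  got <- poisson_log_likelihood(3, 2)
  expect_equal(got$log_lik, -2 + 3 * log(2) - log(6))
  expect_equal(got$log_lik, dpois(3, 2, log = TRUE))
  expect_equal(got$deviance, -2 * got$log_lik)
  # saturated model maximizes the log-likelihood over mu
  O <- c(4, 0, 9)
  sat <- poisson_log_likelihood(O, pmax(O, 1e-9))$log_lik
  set.seed(1)
  for (k in 1:20) {
    mu <- pmax(O, 1e-9) * exp(rnorm(3, 0, 0.3))
    expect_lte(poisson_log_likelihood(O, mu)$log_lik, sat + 1e-9)
  }
  # all components zero -> mu = E
  E <- c(2, 5, 1)
  expect_equal(poisson_log_likelihood(O, E, eta = 0)$log_lik,
               sum(dpois(O, E, log = TRUE)))
  expect_error(poisson_log_likelihood(1, 1, eta = Inf), "non-finite")
})

test_that("CAR log-prior kernels evaluate pairwise differences once", {
  w <- spatial_weights(c("a", "b"), list(2L, 1L))
  expect_equal(car_log_prior(c(0, 2), w, 1, "gaussian_icar"), -2)
  expect_equal(car_log_prior(c(0, 2), w, 1, "l1"), -2)
  # constant field: kernel 0 for both variants
  w3 <- build_contiguity(grid3(), "rook")
  expect_equal(car_log_prior(rep(3, 9), w3, 0.7, "gaussian_icar"), 0)
  expect_equal(car_log_prior(rep(3, 9), w3, 0.7, "l1"), 0)
  expect_error(car_log_prior(c(0, 1), w, 0), "sigma")
  # ICAR full conditional: mean = neighbor average, variance sigma^2/d_i
  # check via the kernel as a function of s_i (quadratic coefficients)
  wp <- spatial_weights(c("a", "b", "c"), list(2L, c(1L, 3L), 2L))
  f <- function(s) car_log_prior(c(1, s, 3), wp, 1.3, "gaussian_icar")
  s_grid <- seq(-2, 6, 0.5)
  vals <- vapply(s_grid, f, numeric(1))
  fit <- lm(vals ~ s_grid + I(s_grid^2))
  expect_equal(-coef(fit)[[2]] / (2 * coef(fit)[[3]]), 2, tolerance = 1e-8)
  expect_equal(coef(fit)[[3]], -2 / (2 * 1.3^2), tolerance = 1e-8)
})

test_that("DIC identities hold for printed and trivial component values", {
  d5 <- dic_components(dbar = 316.465, dhat = 273.777)
  expect_equal(d5$pd, 42.688)
  expect_equal(d5$dic, 359.153)
  d4 <- dic_components(dbar = 334.725, dhat = 291.671)
  expect_equal(d4$pd, 43.054)
  expect_equal(d4$dic, 377.779)
  d0 <- dic_components(deviance_samples = rep(100, 10), dhat = 100)
  expect_equal(d0$pd, 0)
  expect_equal(d0$dic, 100)
})

test_that("Gelman-Rubin diagnostic separates mixed from disjoint chains", {
  set.seed(42)
  iid <- lapply(1:3, function(i) rnorm(5000))
  r <- gelman_rubin(iid)
  expect_gte(r, 0.99); expect_lte(r, 1.05)
  apart <- list(rnorm(500, -10), rnorm(500, 10))
  expect_gt(gelman_rubin(apart), 1.2)
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
  expect_warning(r0 <- gelman_rubin(list(rep(1, 100), rep(1, 100))), "constant")
  expect_equal(r0, 1)
})

test_that("posterior summaries report mean, sd, MC error and quantiles", {
  s <- posterior_summary(rep(3.5, 100))
  expect_equal(s$mean, 3.5); expect_equal(s$sd, 0)
  expect_equal(s$q2.5, 3.5); expect_equal(s$q97.5, 3.5)
  s2 <- posterior_summary(1:100)
  expect_lt(s2$q2.5, 50.5); expect_gt(s2$q97.5, 50.5)
  set.seed(7)
  s3 <- posterior_summary(rnorm(1e5))
  expect_lt(abs(s3$mean), 0.02)
  expect_lt(abs(s3$sd - 1), 0.02)
  expect_lt(s3$mc_error, s3$sd)
  expect_error(posterior_summary(numeric(0)), "empty")
})

test_that("intercept-only sampler matches the conjugate Gamma posterior", {
  dat <- generate_areal_data(shenzhen_like(seed = 5, delta = 0.3, sigma = 0.3))
  tab <- compute_expected(dat$table)
  fit <- quiet_fit(tab, dat$weights, model_spec(),
                   mcmc_config(3, 4000, 1000, seed = 42))
  lam <- exp(do.call(rbind, fit$chains)[, "a0"])
  s <- posterior_summary(lam)
  O <- sum(tab$observed); E <- sum(tab$expected)
  # flat prior on a0 => exp(a0) | data ~ Gamma(sum O, sum E)
  expect_lt(abs(s$mean - O / E), 3 * s$mc_error)
  expect_lt(abs(s$sd - sqrt(O) / E), 3 * s$mc_error)
})

test_that("fits are bit-identical under a fixed seed", {
  dat <- generate_areal_data(shenzhen_like(seed = 3))
  tab <- compute_expected(dat$table)
  cfg <- mcmc_config(2, 800, 200, seed = 11)
  f1 <- quiet_fit(tab, dat$weights, model_spec(5), cfg)
  f2 <- quiet_fit(tab, dat$weights, model_spec(5), cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$smoothed_sr, f2$smoothed_sr)
  expect_identical(f1$dic, f2$dic)
})

test_that("DIC identities and smoothing bounds hold on every fitted model", {
  dat <- generate_areal_data(shenzhen_like(seed = 9))
  tab <- compute_expected(dat$table)
  for (m in c(1, 3, 5)) {
    fit <- quiet_fit(tab, dat$weights, model_spec(m),
                     mcmc_config(2, 1000, 300, seed = 20 + m))
    expect_equal(fit$pd, fit$dbar - fit$dhat, tolerance = 1e-12)
    expect_equal(fit$dic, fit$dbar + fit$pd, tolerance = 1e-12)
    sm <- fit$smoothed_sr
    expect_true(all(sm$smoothed_sr > 0))
    expect_true(all(sm$smoothed_sr >= min(sm$raw_sr) &
                      sm$smoothed_sr <= max(sm$raw_sr)))
    expect_true(all(sm$q2.5 <= sm$smoothed_sr & sm$smoothed_sr <= sm$q97.5))
  }
})

test_that("model 5 shrinks the least-stable SRs toward the mean", {
  dat <- generate_areal_data(shenzhen_like(seed = 9))
  tab <- compute_expected(dat$table)
  fit <- quiet_fit(tab, dat$weights, model_spec(5),
                   mcmc_config(3, 2000, 500, seed = 77))
  sm <- fit$smoothed_sr
  # smoothing magnitude concentrates where expected counts are small
  # (the CAR model shrinks toward the local mean, so the per-area
  # direction is not always toward 1; the magnitude pattern is the claim)
  outside <- !(tab$area_id %in% unlist(dat$truth$cluster_areas))
  ord <- order(ifelse(outside, tab$expected, Inf))
  small10 <- ord[1:10]
  big10 <- rev(order(tab$expected))[1:10]
  expect_gt(mean(abs(sm$smoothed_sr[small10] - sm$raw_sr[small10])),
            mean(abs(sm$smoothed_sr[big10] - sm$raw_sr[big10])))
  # and on average the least-stable third does move toward the overall mean
  third <- ord[1:19]
  expect_lt(mean(abs(sm$smoothed_sr[third] - 1)),
            mean(abs(sm$raw_sr[third] - 1)))
})

test_that("model-5 state with S = 0 reproduces the model-3 likelihood", {
  dat <- generate_areal_data(shenzhen_like(seed = 2))
  tab <- compute_expected(dat$table)
  set.seed(1)
  U <- rnorm(57, 0, 0.2)
  eta5 <- 0.1 + U + rep(0, 57)  # model 5 with S == 0
  eta3 <- 0.1 + U               # model 3, same state
  expect_identical(poisson_log_likelihood(tab$observed, tab$expected, eta5),
                   poisson_log_likelihood(tab$observed, tab$expected, eta3))
})

test_that("islands get S fixed at zero with a warning", {
  lat <- grid_lattice(2, 3)
  w <- build_contiguity(lat, "rook")
  # cut the last area loose
  nb <- w$neighbors
  for (i in seq_along(nb)) nb[[i]] <- setdiff(nb[[i]], 6L)
  nb[[6]] <- integer(0)
  w_iso <- spatial_weights(w$ids, nb)
  tab <- compute_expected(toy_table(lat, seed = 4))
  expect_warning(
    fit <- fit_hbayes(tab, w_iso, model_spec(4),
                      mcmc_config(2, 600, 200, seed = 5), rhat_threshold = Inf),
    "island")
  expect_true(all(is.finite(fit$smoothed_sr$smoothed_sr)))
})

test_that("model structure flags follow the six presets", {
  expect_true(model_spec(1)$has_covariate)
  expect_true(model_spec(1)$covariate_free_coefficient)
  expect_false(model_spec(2)$covariate_free_coefficient)
  expect_true(model_spec(3)$has_unstructured)
  expect_false(model_spec(3)$has_structured)
  expect_true(model_spec(4)$has_structured)
  expect_true(all(unlist(model_spec(6)[c("has_covariate", "has_unstructured",
                                         "has_structured")])))
  expect_error(model_spec(has_covariate = FALSE,
                          covariate_free_coefficient = TRUE),
               "requires has_covariate")
})
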
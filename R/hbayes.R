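# Hierarchical Bayesian Poisson disease-mapping models with iid and CAR
# random effects, fitted by adaptive Metropolis-within-Gibbs.
#
# Model family (log-linear relative risk):
#   O_i ~ Poisson(mu_i),  log(mu_i) = log(E_i) + a0 + b*x_i + U_i + S_i
#   a0 flat; b ~ N(0, coefficient_prior_sd^2); U_i ~ N(0, delta^2);
#   S ~ CAR(sigma) (Gaussian ICAR or L1/double-exponential variant);
#   delta, sigma ~ Uniform(0, prior_sd_upper).

#' Specify one of the hierarchical Poisson model structures
#'
#' The six standard structures of the model sweep are:
#' \describe{
#'   \item{1}{intercept + covariate with free coefficient}
#'   \item{2}{intercept + covariate with the coefficient fixed at 1}
#'   \item{3}{intercept + unstructured (iid normal) component}
#'   \item{4}{intercept + structured (CAR) component}
#'   \item{5}{intercept + unstructured + structured components}
#'   \item{6}{intercept + covariate + unstructured + structured}
#' }
#' The intercept is always present.  Custom combinations are available via
#' the flag arguments.
#'
#' @param model integer 1..6 selecting a preset, or `NULL` for a custom
#'   combination (default: intercept only).
#' @param has_covariate include the covariate term `b * x`.
#' @param covariate_free_coefficient if `FALSE` while `has_covariate`,
#'   the coefficient is fixed at 1 (covariate acts as an offset).
#' @param has_unstructured include iid normal random effects `U`.
#' @param has_structured include CAR random effects `S`.
#' @param car_variant `"l1"` (robust double-exponential pairwise-difference
#'   prior, the default) or `"gaussian_icar"` (intrinsic Gaussian CAR).
#' @param prior_sd_upper upper bound of the Uniform(0, upper) prior on the
#'   standard-deviation / scale parameters (default 100).
#' @param coefficient_prior_sd SD of the weakly informative normal prior
#'   on the covariate coefficient (default 1000).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model = NULL, has_covariate = FALSE,
                       covariate_free_coefficient = has_covariate,
                       has_unstructured = FALSE, has_structured = FALSE,
                       car_variant = c("l1", "gaussian_icar"),
                       prior_sd_upper = 100, coefficient_prior_sd = 1000) {
  car_variant <- match.arg(car_variant)
  if (!is.null(model)) {
    stopifnot(model %in% 1:6)
    has_covariate <- model %in% c(1, 2, 6)
    covariate_free_coefficient <- model %in% c(1, 6)
    has_unstructured <- model %in% c(3, 5, 6)
    has_structured <- model %in% c(4, 5, 6)
  }
  if (covariate_free_coefficient && !has_covariate) {
    stop("covariate_free_coefficient requires has_covariate")
  }
  stopifnot(prior_sd_upper > 0, coefficient_prior_sd > 0)
  structure(list(model = model, has_covariate = has_covariate,
                 covariate_free_coefficient = covariate_free_coefficient,
                 has_unstructured = has_unstructured,
                 has_structured = has_structured,
                 car_variant = car_variant,
                 prior_sd_upper = prior_sd_upper,
                 coefficient_prior_sd = coefficient_prior_sd),
            class = "model_spec")
}

model_description <- function(spec) {
  parts <- "intercept"
  if (spec$has_covariate) {
    parts <- c(parts, if (spec$covariate_free_coefficient)
      "covariate (free coefficient)" else "covariate (coefficient = 1)")
  }
  if (spec$has_unstructured) parts <- c(parts, "unstructured")
  if (spec$has_structured) parts <- c(parts, paste0("structured (", spec$car_variant, ")"))
  paste(parts, collapse = " + ")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", model_description(x), "\n")
  invisible(x)
}

#' MCMC run protocol
#'
#' Defaults mirror a standard disease-mapping protocol: 3 parallel chains
#' of 20,000 iterations with a burn-in of 2,000.  Tests and examples use
#' scaled-down settings.
#'
#' @param n_chains number of chains (>= 2 for Gelman-Rubin diagnostics).
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations (< `n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer master seed; per-chain seeds are derived from it.
#' @param adapt_interval step-size adaptation cadence during burn-in.
#' @param target_accept Metropolis acceptance-rate target in (0, 1).
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 20000, burn_in = 2000,
                        thin = 1, seed = 1, adapt_interval = 50,
                        target_accept = 0.35) {
  stopifnot(n_chains >= 1, burn_in < n_iter, thin >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept),
            class = "mcmc_config")
}

#' Poisson log-likelihood and deviance of an areal count model
#'
#' `sum_i [ -mu_i + O_i log(mu_i) - log(O_i!) ]` with
#' `mu_i = E_i exp(eta_i)`.  The deviance is `-2 *` this quantity (the
#' standardizing function of the data is treated as the constant 1, the
#' WinBUGS convention, so it cancels in all model comparisons).
#'
#' @param observed non-negative counts.
#' @param expected positive expected counts.
#' @param eta linear predictor on the log-relative-risk scale
#'   (`a0 + b x + U + S`); default 0 gives `mu = E`.
#' @return list `log_lik`, `deviance`.
#' @export
poisson_log_likelihood <- function(observed, expected, eta = 0) {
  if (any(expected <= 0)) stop("expected must be > 0")
  lp <- log(expected) + eta
  if (any(!is.finite(lp))) {
    stop("non-finite linear predictor; eta range [",
         paste(range(eta), collapse = ", "), "]")
  }
  mu <- exp(lp)
  ll <- sum(-mu + observed * lp - lgamma(observed + 1))
  list(log_lik = ll, deviance = -2 * ll)
}

#' CAR log-prior kernel for structured spatial effects
#'
#' Evaluated up to an additive constant (both variants are improper):
#' \describe{
#'   \item{gaussian_icar}{`-(1/(2 sigma^2)) * sum_(i~j) (s_i - s_j)^2`}
#'   \item{l1}{`-(1/sigma) * sum_(i~j) |s_i - s_j|` (robust /
#'     double-exponential pairwise-difference form)}
#' }
#' each unordered neighbor pair counted once.
#'
#' @param s numeric vector of spatial effects.
#' @param w binary symmetric `spatial_weights`.
#' @param sigma positive scale parameter.
#' @param variant `"gaussian_icar"` or `"l1"`.
#' @return log-density kernel (numeric scalar).
#' @export
car_log_prior <- function(s, w, sigma, variant = c("gaussian_icar", "l1")) {
  variant <- match.arg(variant)
  if (sigma <= 0) stop("sigma must be > 0")
  if (w$style != "B") stop("CAR prior requires binary symmetric weights")
  tot <- 0
  for (i in seq_along(s)) {
    nb <- w$neighbors[[i]]
    nb <- nb[nb > i]  # each unordered pair once
    if (!length(nb)) next
    d <- s[i] - s[nb]
    tot <- tot + if (variant == "gaussian_icar") sum(d^2) else sum(abs(d))
  }
  if (variant == "gaussian_icar") -tot / (2 * sigma^2) else -tot / sigma
}

# connected components among non-island areas (for the sigma update's
# sigma^-(n - g) normalization of the improper CAR density)
graph_components <- function(neighbors, active) {
  comp <- rep(NA_integer_, length(neighbors))
  cur <- 0
  for (st in active) {
    if (!is.na(comp[st])) next
    cur <- cur + 1
    stack <- st
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, setdiff(neighbors[[v]], which(!is.na(comp))))
    }
  }
  cur
}

# ---- the sampler ----------------------------------------------------------

run_chain <- function(chain_seed, O, E, x, spec, cfg, nbs, pair_i, pair_j,
                      active_s, car_rank) {
  set.seed(chain_seed)
  n <- length(O)
  n_iter <- cfg$n_iter; burn_in <- cfg$burn_in; thin <- cfg$thin
  upper <- spec$prior_sd_upper
  tau <- spec$coefficient_prior_sd
  l1 <- spec$car_variant == "l1"

  has_b <- spec$has_covariate && spec$covariate_free_coefficient
  # exact reparameterization: sample against the centered covariate (the
  # intercept and slope decorrelate), report the intercept on the
  # original scale (a0_report = a0_centered - b * mean(x))
  xm <- if (has_b) mean(x) else 0
  if (has_b) x <- x - xm
  xoff <- if (spec$has_covariate && !spec$covariate_free_coefficient) x else 0
  offset <- log(E) + xoff

  # dispersed inits
  a0 <- log(sum(O) / sum(E)) + stats::rnorm(1, 0, 0.5)
  b <- if (has_b) stats::rnorm(1, 0, 0.3) else 0
  U <- if (spec$has_unstructured) stats::rnorm(n, 0, 0.1) else rep(0, n)
  S <- rep(0, n)
  if (spec$has_structured && length(active_s)) {
    S[active_s] <- stats::rnorm(length(active_s), 0, 0.1)
    S[active_s] <- S[active_s] - mean(S[active_s])
  }
  delta <- exp(stats::rnorm(1, log(0.5), 0.3))
  sigma <- exp(stats::rnorm(1, log(0.5), 0.3))

  eta <- a0 + (if (has_b) b * x else 0) + U + S
  llv <- function(eta_i, idx) {
    mu <- exp(offset[idx] + eta_i)
    -mu + O[idx] * (offset[idx] + eta_i)
  }
  ll_full <- function(eta) {
    mu <- exp(offset + eta)
    sum(-mu + O * (offset + eta))
  }
  cur_ll <- ll_full(eta)

  # adaptive step sizes
  st <- list(a0 = 0.1, b = 0.1, U = rep(0.5, n), S = rep(0.5, n),
             delta = 0.3, sigma = 0.3)
  acc <- list(a0 = 0, b = 0, U = rep(0, n), S = rep(0, n), delta = 0, sigma = 0)
  try_cnt <- 0

  n_keep <- (n_iter - burn_in) %/% thin
  draws <- matrix(NA_real_, n_keep,
                  4 + 1, dimnames = list(NULL, c("a0", "b", "delta", "sigma", "deviance")))
  sr_draws <- matrix(NA_real_, n_keep, n)
  U_sum <- rep(0, n); S_sum <- rep(0, n)
  keep <- 0
  lgam <- sum(lgamma(O + 1))
  accept_total <- c(a0 = 0, b = 0, U = 0, S = 0, delta = 0, sigma = 0)
  accept_n <- c(a0 = 0, b = 0, U = 0, S = 0, delta = 0, sigma = 0)

  car_pair_pen <- function(S) {
    d <- S[pair_i] - S[pair_j]
    if (l1) sum(abs(d)) else sum(d^2)
  }

  for (it in seq_len(n_iter)) {
    adapting <- it <= burn_in
    try_cnt <- try_cnt + 1

    # -- intercept (flat prior)
    prop <- a0 + stats::rnorm(1, 0, st$a0)
    eta_p <- eta + (prop - a0)
    new_ll <- ll_full(eta_p)
    if (log(stats::runif(1)) < new_ll - cur_ll) {
      a0 <- prop; eta <- eta_p; cur_ll <- new_ll
      acc$a0 <- acc$a0 + 1; accept_total["a0"] <- accept_total["a0"] + 1
    }
    accept_n["a0"] <- accept_n["a0"] + 1

    # -- coefficient
    if (has_b) {
      prop <- b + stats::rnorm(1, 0, st$b)
      eta_p <- eta + (prop - b) * x
      new_ll <- ll_full(eta_p)
      lr <- new_ll - cur_ll +
        stats::dnorm(prop, 0, tau, log = TRUE) - stats::dnorm(b, 0, tau, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        b <- prop; eta <- eta_p; cur_ll <- new_ll
        acc$b <- acc$b + 1; accept_total["b"] <- accept_total["b"] + 1
      }
      accept_n["b"] <- accept_n["b"] + 1
    }

    # -- unstructured effects: conditionally independent, vectorized MH
    if (spec$has_unstructured) {
      Up <- U + stats::rnorm(n, 0, st$U)
      d_eta <- Up - U
      lr <- llv(eta + d_eta, seq_len(n)) - llv(eta, seq_len(n)) +
        stats::dnorm(Up, 0, delta, log = TRUE) -
        stats::dnorm(U, 0, delta, log = TRUE)
      take <- log(stats::runif(n)) < lr
      if (any(take)) {
        eta[take] <- eta[take] + d_eta[take]
        U[take] <- Up[take]
        acc$U[take] <- acc$U[take] + 1
        accept_total["U"] <- accept_total["U"] + sum(take)
      }
      accept_n["U"] <- accept_n["U"] + n
      cur_ll <- ll_full(eta)
    }

    # -- structured effects: sequential single-site MH (neighbors couple)
    if (spec$has_structured && length(active_s)) {
      for (i in active_s) {
        prop <- S[i] + stats::rnorm(1, 0, st$S[i])
        nb <- nbs[[i]]
        d_old <- S[i] - S[nb]; d_new <- prop - S[nb]
        pen <- if (l1) (sum(abs(d_new)) - sum(abs(d_old))) / sigma
               else (sum(d_new^2) - sum(d_old^2)) / (2 * sigma^2)
        lr <- llv(eta[i] + (prop - S[i]), i) - llv(eta[i], i) - pen
        if (log(stats::runif(1)) < lr) {
          eta[i] <- eta[i] + (prop - S[i]); S[i] <- prop
          acc$S[i] <- acc$S[i] + 1; accept_total["S"] <- accept_total["S"] + 1
        }
        accept_n["S"] <- accept_n["S"] + 1
      }
      # recenter S along the flat direction (posterior-invariant move):
      # valid only when S enters every area's predictor, i.e. no islands
      if (length(active_s) == n) {
        m <- mean(S)
        S <- S - m; a0 <- a0 + m
      }
      cur_ll <- ll_full(eta)
    }

    # -- delta (SD of U), Uniform(0, upper) prior
    if (spec$has_unstructured) {
      prop <- delta + stats::rnorm(1, 0, st$delta)
      if (prop > 0 && prop < upper) {
        lr <- sum(stats::dnorm(U, 0, prop, log = TRUE)) -
          sum(stats::dnorm(U, 0, delta, log = TRUE))
        if (log(stats::runif(1)) < lr) {
          delta <- prop
          acc$delta <- acc$delta + 1; accept_total["delta"] <- accept_total["delta"] + 1
        }
      }
      accept_n["delta"] <- accept_n["delta"] + 1
    }

    # -- sigma (CAR scale), Uniform(0, upper) prior; improper CAR density
    #    normalizes as sigma^-(rank) on the contrast subspace
    if (spec$has_structured && length(active_s)) {
      prop <- sigma + stats::rnorm(1, 0, st$sigma)
      if (prop > 0 && prop < upper) {
        pen <- car_pair_pen(S)
        logp <- function(sg) {
          -car_rank * log(sg) - if (l1) pen / sg else pen / (2 * sg^2)
        }
        if (log(stats::runif(1)) < logp(prop) - logp(sigma)) {
          sigma <- prop
          acc$sigma <- acc$sigma + 1; accept_total["sigma"] <- accept_total["sigma"] + 1
        }
      }
      accept_n["sigma"] <- accept_n["sigma"] + 1
    }

    # -- adaptation (burn-in only; frozen afterwards)
    if (adapting && it %% cfg$adapt_interval == 0) {
      tune <- function(step, rate) {
        step * exp(pmin(0.5, pmax(-0.5, (rate - cfg$target_accept))))
      }
      k <- cfg$adapt_interval
      st$a0 <- tune(st$a0, acc$a0 / k)
      if (has_b) st$b <- tune(st$b, acc$b / k)
      if (spec$has_unstructured) st$U <- tune(st$U, acc$U / k)
      if (spec$has_structured) st$S <- tune(st$S, acc$S / k)
      st$delta <- tune(st$delta, acc$delta / k)
      st$sigma <- tune(st$sigma, acc$sigma / k)
      acc <- list(a0 = 0, b = 0, U = rep(0, n), S = rep(0, n),
                  delta = 0, sigma = 0)
    }

    # -- storage
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      keep <- keep + 1
      dev <- -2 * (cur_ll - lgam)
      draws[keep, ] <- c(a0 - b * xm, b, delta, sigma, dev)
      sr_draws[keep, ] <- exp(eta)
      U_sum <- U_sum + U; S_sum <- S_sum + S
    }
  }

  list(draws = draws[seq_len(keep), , drop = FALSE],
       sr_draws = sr_draws[seq_len(keep), , drop = FALSE],
       U_mean = U_sum / keep, S_mean = S_sum / keep,
       acceptance = ifelse(accept_n > 0, accept_total / accept_n, NA))
}

#' Fit a hierarchical Bayesian Poisson disease-mapping model
#'
#' Adaptive Metropolis-within-Gibbs sampler for the Poisson log-linear
#' model family of [model_spec()].  Random-walk updates for the intercept,
#' coefficient, each random effect and the scale parameters; step sizes
#' are tuned toward `target_accept` during burn-in only.  The structured
#' effects are recentred to sum to zero after every sweep (absorbing the
#' shift into the intercept), which the improper CAR prior leaves
#' invariant.  Islands (areas with no neighbors) have their structured
#' effect fixed at 0 with a warning, and recentring is skipped.
#'
#' @param table data frame with `observed`, `expected` (computed via
#'   [compute_expected()] if absent), `population`, and the covariate
#'   column when the model uses one.
#' @param weights binary `spatial_weights`; required when the model has a
#'   structured component.
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @param covariate name of the covariate column (default
#'   `"road_density"`).
#' @param standardize_covariate center and scale the covariate before
#'   fitting (default `FALSE`).
#' @param rhat_threshold convergence warning threshold on the PSRF.
#' @return object of class `hbayes_fit`: posterior `summaries` (per
#'   monitored parameter: mean, sd, mc_error, 2.5%/97.5% quantiles),
#'   `smoothed_sr` data frame (posterior mean and credible bounds of the
#'   per-area SR), `dbar`, `dhat`, `pd`, `dic`, `rhat`, `acceptance_rates`,
#'   the retained `chains`, and the `spec`/`config` used.  Identical seed,
#'   data and spec give bit-identical results.
#' @export
fit_hbayes <- function(table, weights = NULL, spec = model_spec(5),
                       config = mcmc_config(), covariate = "road_density",
                       standardize_covariate = FALSE, rhat_threshold = 1.1) {
  if (!"expected" %in% names(table)) table <- compute_expected(table)
  keep <- table$expected > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-expected area(s) excluded from the fit")
    table <- table[keep, , drop = FALSE]
  }
  O <- table$observed; E <- table$expected
  n <- length(O)
  if (stats::var(O / E) == 0) warning("no variation in the raw ratios; degenerate fit")

  x <- rep(0, n)
  if (spec$has_covariate) {
    if (!covariate %in% names(table)) stop("covariate column not found: ", covariate)
    x <- as.numeric(table[[covariate]])
    if (standardize_covariate) x <- as.numeric(scale(x))
  }

  nbs <- NULL; pair_i <- pair_j <- integer(0); active_s <- integer(0); car_rank <- 0
  if (spec$has_structured) {
    if (is.null(weights)) stop("structured component requires spatial weights")
    if (length(weights$ids) != n) stop("weights do not match the table")
    nbs <- weights$neighbors
    deg <- lengths(nbs)
    active_s <- which(deg > 0)
    if (length(active_s) < n) {
      warning("island area(s) with no neighbors: structured effect fixed at 0 for ",
              paste(weights$ids[deg == 0], collapse = ", "))
    }
    for (i in seq_len(n)) {
      nb <- nbs[[i]]; nb <- nb[nb > i]
      pair_i <- c(pair_i, rep(i, length(nb))); pair_j <- c(pair_j, nb)
    }
    g <- graph_components(nbs, active_s)
    car_rank <- length(active_s) - g
  }

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, config$n_chains)
  chains <- lapply(chain_seeds, function(sd) {
    run_chain(sd, O, E, x, spec, config, nbs, pair_i, pair_j, active_s, car_rank)
  })

  monitored <- c("a0",
                 if (spec$has_covariate && spec$covariate_free_coefficient) "b",
                 if (spec$has_unstructured) "delta",
                 if (spec$has_structured) "sigma",
                 "deviance")
  pooled <- do.call(rbind, lapply(chains, `[[`, "draws"))
  sr_pooled <- do.call(rbind, lapply(chains, `[[`, "sr_draws"))

  summaries <- lapply(monitored, function(p) posterior_summary(pooled[, p]))
  names(summaries) <- monitored
  # variance-scale summaries for the random-effect components
  if (spec$has_unstructured) summaries$delta2 <- posterior_summary(pooled[, "delta"]^2)
  if (spec$has_structured) summaries$sigma2 <- posterior_summary(pooled[, "sigma"]^2)

  rhat <- rep(NA_real_, length(monitored)); names(rhat) <- monitored
  if (config$n_chains >= 2) {
    for (p in monitored) {
      rhat[p] <- suppressWarnings(
        gelman_rubin(lapply(chains, function(ch) ch$draws[, p])))
    }
    bad <- names(rhat)[!is.na(rhat) & rhat > rhat_threshold]
    if (length(bad)) {
      warning("Gelman-Rubin Rhat above ", rhat_threshold, " for: ",
              paste(bad, collapse = ", "), " - increase n_iter")
    }
  }

  # plug-in deviance at the posterior means of the stochastic parents
  a0_hat <- mean(pooled[, "a0"])
  b_hat <- mean(pooled[, "b"])
  U_hat <- Reduce(`+`, lapply(chains, `[[`, "U_mean")) / length(chains)
  S_hat <- Reduce(`+`, lapply(chains, `[[`, "S_mean")) / length(chains)
  xoff <- if (spec$has_covariate && !spec$covariate_free_coefficient) x else 0
  bterm <- if (spec$has_covariate && spec$covariate_free_coefficient) b_hat * x else 0
  eta_hat <- a0_hat + bterm + xoff + U_hat + S_hat
  dhat <- poisson_log_likelihood(O, E, eta_hat)$deviance
  dic <- dic_components(pooled[, "deviance"], dhat = dhat)

  smoothed <- data.frame(
    area_id = table$area_id,
    raw_sr = O / E,
    smoothed_sr = colMeans(sr_pooled),
    q2.5 = apply(sr_pooled, 2, stats::quantile, 0.025, names = FALSE),
    q97.5 = apply(sr_pooled, 2, stats::quantile, 0.975, names = FALSE),
    stringsAsFactors = FALSE)

  acc <- Reduce(`+`, lapply(chains, `[[`, "acceptance")) / length(chains)

  structure(list(spec = spec, config = config,
                 summaries = summaries,
                 smoothed_sr = smoothed,
                 dbar = dic$dbar, dhat = dic$dhat, pd = dic$pd, dic = dic$dic,
                 rhat = rhat, acceptance_rates = acc,
                 chains = lapply(chains, `[[`, "draws"),
                 n_areas = n),
            class = "hbayes_fit")
}

#' @export
print.hbayes_fit <- function(x, ...) {
  cat("hbayes_fit:", model_description(x$spec), "\n")
  cat(sprintf("  %d areas, %d chain(s) x %d iter (burn-in %d)\n",
              x$n_areas, x$config$n_chains, x$config$n_iter, x$config$burn_in))
  cat(sprintf("  Dbar %.3f  Dhat %.3f  pD %.3f  DIC %.3f\n",
              x$dbar, x$dhat, x$pd, x$dic))
  for (p in names(x$summaries)) {
    s <- x$summaries[[p]]
    cat(sprintf("  %-8s mean %9.4f  sd %8.4f  mc %8.5f  [%9.4f, %9.4f]%s\n",
                p, s$mean, s$sd, s$mc_error, s$q2.5, s$q97.5,
                if (p %in% names(x$rhat) && !is.na(x$rhat[p]))
                  sprintf("  Rhat %.3f", x$rhat[p]) else ""))
  }
  invisible(x)
}

#' Posterior summary table in the standard report layout
#'
#' @param fit an `hbayes_fit`.
#' @return data frame with columns `parameter`, `mean`, `sd`, `mc_error`,
#'   `q2.5`, `q97.5`, `rhat`.
#' @export
summary_table <- function(fit) {
  do.call(rbind, lapply(names(fit$summaries), function(p) {
    s <- fit$summaries[[p]]
    data.frame(parameter = p, mean = s$mean, sd = s$sd, mc_error = s$mc_error,
               q2.5 = s$q2.5, q97.5 = s$q97.5,
               rhat = if (p %in% names(fit$rhat)) unname(fit$rhat[p]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
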
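# Posterior summaries, Gelman-Rubin diagnostic and DIC bookkeeping.

#' Posterior summary of a sample vector
#'
#' Mean, standard deviation, batch-means Monte Carlo standard error (at
#' least 20 batches) and the empirical 2.5%/97.5% quantiles — the layout
#' of a standard MCMC summary table.
#'
#' @param samples numeric vector of (possibly autocorrelated) draws.
#' @param n_batches number of batches for the MC error (default 20; capped
#'   so each batch has at least one draw).
#' @return named list: `mean`, `sd`, `mc_error`, `q2.5`, `q97.5`.
#' @export
posterior_summary <- function(samples, n_batches = 20) {
  if (!length(samples)) stop("empty sample vector")
  m <- mean(samples)
  s <- stats::sd(samples)
  if (is.na(s)) s <- 0
  nb <- max(2L, min(as.integer(n_batches), length(samples)))
  batch <- floor(seq_along(samples) * nb / (length(samples) + 1e-9)) + 1
  bm <- tapply(samples, pmin(batch, nb), mean)
  mc <- stats::sd(bm) / sqrt(length(bm))
  if (is.na(mc)) mc <- 0
  q <- stats::quantile(samples, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = m, sd = s, mc_error = mc, q2.5 = q[1], q97.5 = q[2])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free PSRF from between- and within-chain variances:
#' `Rhat = sqrt(((n-1)/n * W + (1 + 1/m) * B/n) / W)` for `m` chains of
#' length `n`.  Values near 1 indicate the chains are sampling the same
#' distribution.
#'
#' @param chains a list of equal-length numeric vectors, or a matrix with
#'   one column per chain.
#' @return the PSRF (numeric scalar); `NA` with a warning when the
#'   within-chain variance is zero (constant chains).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("Gelman-Rubin needs at least 2 chains (set n_chains >= 2)")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains too short for a meaningful PSRF")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W <= 0) {
    if (B_over_n <= 0) {
      warning("all chains constant and identical: PSRF undefined, returning 1")
      return(1)
    }
    warning("zero within-chain variance: PSRF undefined")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
}

#' DIC components from deviance samples or printed Dbar/Dhat
#'
#' Enforces the DIC identities `pD = Dbar - Dhat` and
#' `DIC = Dbar + pD = Dhat + 2 pD`.  `Dbar` is the posterior mean
#' deviance; `Dhat` is the deviance at the posterior means of the
#' stochastic parameters (plug-in).
#'
#' @param deviance_samples numeric vector of deviance draws (used to
#'   compute `dbar` when `dbar` is not given directly).
#' @param dhat plug-in deviance.
#' @param dbar posterior mean deviance (overrides `deviance_samples`).
#' @return named list `dbar`, `dhat`, `pd`, `dic`.
#' @examples
#' dic_components(dbar = 316.465, dhat = 273.777)  # pd 42.688, dic 359.153
#' @export
dic_components <- function(deviance_samples = NULL, dhat, dbar = NULL) {
  if (is.null(dbar)) {
    if (is.null(deviance_samples) || !length(deviance_samples)) {
      stop("provide deviance_samples or dbar")
    }
    dbar <- mean(deviance_samples)
  }
  pd <- dbar - dhat
  list(dbar = dbar, dhat = dhat, pd = pd, dic = dbar + pd)
}
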
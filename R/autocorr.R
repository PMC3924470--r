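# Global and local spatial autocorrelation: Moran's I, Getis-Ord General G
# and local Gi* with analytic z-scores and permutation inference.

weight_sums <- function(W) {
  # Cliff-Ord bookkeeping terms shared by the analytic variances
  S0 <- sum(W)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  list(S0 = S0, S1 = S1, S2 = S2)
}

new_global_stat <- function(statistic, expectation, variance, method,
                            n_permutations = 0L, p = NULL) {
  z <- if (!is.na(variance) && variance > 0) {
    (statistic - expectation) / sqrt(variance)
  } else NA_real_
  if (is.null(p)) p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(statistic = statistic, expectation = expectation,
                 variance = variance, z = z, p = p, method = method,
                 n_permutations = as.integer(n_permutations)),
            class = "global_stat")
}

#' @export
print.global_stat <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, E %.4f, z %.3f, p %.4g (%s%s)\n",
              attr(x, "label") %||% "global statistic",
              x$statistic, x$expectation, x$z, x$p, x$method,
              if (x$n_permutations > 0) paste0(", R=", x$n_permutations) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

moran_stat <- function(z, W, S0) {
  n <- length(z)
  (n / S0) * sum(W * outer(z, z)) / sum(z^2)
}

#' Moran's I global spatial autocorrelation
#'
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z_i = x_i - mean(x)`.
#' Expectation under the null is `-1/(n-1)`.  Inference is analytic under
#' the randomization (default) or normality assumption, or by Monte Carlo
#' permutation of the values over the areas.  Two-sided p-values
#' throughout.  Row-standardized weights are conventional for Moran's I
#' and are the pipeline default; any weights style is accepted.
#'
#' @param values numeric vector, one value per area; must not be constant.
#' @param w `spatial_weights` aligned with `values`.
#' @param method `"randomization"`, `"normality"` or `"permutation"`.
#' @param n_permutations number of permutations when `method = "permutation"`.
#' @param seed RNG seed for the permutation test (required there).
#' @return a `global_stat` list: statistic, expectation, variance, z, p,
#'   method, n_permutations.
#' @export
morans_i <- function(values, w,
                     method = c("randomization", "normality", "permutation"),
                     n_permutations = 999, seed = NULL) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 3) stop("need at least 3 areas")
  if (length(w$ids) != n) stop("weights do not match values length")
  if (stats::var(values) == 0) stop("constant values: Moran's I undefined")
  W <- weights_matrix(w)
  ws <- weight_sums(W)
  if (ws$S0 <= 0) stop("all-zero weights")
  z <- values - mean(values)
  I <- moran_stat(z, W, ws$S0)
  EI <- -1 / (n - 1)
  if (method == "permutation") {
    if (is.null(seed)) stop("permutation test requires a seed")
    set.seed(seed)
    sims <- vapply(seq_len(n_permutations), function(k) {
      zp <- z[sample.int(n)]
      moran_stat(zp, W, ws$S0)
    }, numeric(1))
    variance <- stats::var(sims)
    p_up <- (1 + sum(sims >= I)) / (n_permutations + 1)
    p_lo <- (1 + sum(sims <= I)) / (n_permutations + 1)
    p <- min(1, 2 * min(p_up, p_lo))
    res <- new_global_stat(I, EI, variance, "permutation", n_permutations, p = p)
    res$z <- (I - mean(sims)) / sqrt(variance)
    return(structure(res, label = "Moran's I"))
  }
  S0 <- ws$S0; S1 <- ws$S1; S2 <- ws$S2
  if (method == "normality") {
    variance <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(z^4) / sum(z^2)^2
    variance <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
                   b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  structure(new_global_stat(I, EI, variance, method), label = "Moran's I")
}

#' Getis-Ord General G statistic
#'
#' `G = sum_{i != j} w_ij x_i x_j / sum_{i != j} x_i x_j` for non-negative
#' values and binary weights; measures whether high values concentrate
#' near each other.  Expectation `S0 / (n (n-1))`; the analytic variance
#' is the Getis-Ord (1992) randomization form, equal to the exact
#' permutation moments.
#'
#' @param values non-negative, not all zero.
#' @param w binary `spatial_weights`.
#' @return a `global_stat`.
#' @export
general_g <- function(values, w) {
  n <- length(values)
  if (n < 2) stop("need at least 2 areas")
  if (any(values < 0)) stop("General G is defined for non-negative values")
  if (all(values == 0)) stop("all-zero values")
  if (w$style != "B") stop("General G requires binary weights")
  W <- weights_matrix(w)
  x <- values
  num <- sum(W * outer(x, x))          # w_ii = 0 by construction
  den <- sum(outer(x, x)) - sum(x^2)   # i != j pairs
  G <- num / den
  ws <- weight_sums(W)
  S0 <- ws$S0; S1 <- ws$S1; S2 <- ws$S2
  EG <- S0 / (n * (n - 1))
  if (n < 4) {
    # the Getis-Ord variance needs n >= 4; report the statistic alone
    return(structure(new_global_stat(G, EG, NA_real_, "randomization"),
                     label = "General G"))
  }
  m1 <- sum(x); m2 <- sum(x^2); m3 <- sum(x^3); m4 <- sum(x^4)
  B0 <- (n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2
  B1 <- -((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
  B2 <- -(2 * n * S1 - (n + 3) * S2 + 6 * S0^2)
  B3 <- 4 * (n - 1) * S1 - 2 * (n + 1) * S2 + 8 * S0^2
  B4 <- S1 - S2 + S0^2
  EG2 <- (B0 * m2^2 + B1 * m4 + B2 * m1^2 * m2 + B3 * m1 * m3 + B4 * m1^4) /
    ((m1^2 - m2)^2 * n * (n - 1) * (n - 2) * (n - 3))
  variance <- EG2 - EG^2
  structure(new_global_stat(G, EG, variance, "randomization"),
            label = "General G")
}

#' Local Gi* hot-spot statistic
#'
#' Full-window Getis-Ord Gi*: the focal area is part of its own
#' neighborhood (`w_ii = 1` is appended to binary weights).  The z-score
#' follows the Ord-Getis standardization
#' `z_i = (sum_j w_ij x_j - Wi* xbar) / (s * sqrt((n S1i - Wi*^2)/(n-1)))`
#' with `xbar`, `s` computed over all areas.  On a constant surface every
#' numerator equals its expectation and z is reported as 0.
#'
#' @param values numeric vector, one per area.
#' @param w `spatial_weights`; binary input gets the self-weight appended.
#' @return data frame of class `local_g`: `area_id`, `gi_star` (the raw
#'   weighted sum), `z`, `p` (two-sided), plus a `cluster` column filled by
#'   [classify_hot_cold()].
#' @export
local_gi_star <- function(values, w) {
  n <- length(values)
  if (n < 3) stop("need at least 3 areas")
  if (length(w$ids) != n) stop("weights do not match values length")
  W <- weights_matrix(w)
  diag(W) <- if (w$style == "B") 1 else diag(W) + 1
  x <- values
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  num <- as.numeric(W %*% x)
  Wi <- rowSums(W)
  S1i <- rowSums(W^2)
  denom <- s * sqrt(pmax(0, (n * S1i - Wi^2) / (n - 1)))
  z <- ifelse(denom > 0, (num - Wi * xbar) / denom, 0)
  if (s == 0) z[] <- 0
  res <- data.frame(area_id = w$ids, gi_star = num, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    cluster = NA_character_, stringsAsFactors = FALSE)
  class(res) <- c("local_g", "data.frame")
  res
}

#' Classify areas as hot spots, cold spots or not significant
#'
#' Hot if `z > 0 & p <= alpha`; cold if `z < 0 & p <= alpha`; otherwise
#' `not_significant`.  The default `alpha = 0.10` reflects reported
#' hot/cold tables that flag areas with p-values up to 0.09.
#'
#' @param local a `local_g` data frame from [local_gi_star()], or any data
#'   frame with `z` and `p` columns.
#' @param alpha significance threshold.
#' @return `local` with the `cluster` column filled.
#' @export
classify_hot_cold <- function(local, alpha = 0.10) {
  stopifnot(all(c("z", "p") %in% names(local)))
  local$cluster <- ifelse(local$p <= alpha & local$z > 0, "hot",
                          ifelse(local$p <= alpha & local$z < 0, "cold",
                                 "not_significant"))
  local
}
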
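# Purely spatial Poisson scan statistic: circular windows over centroids,
# likelihood-ratio scoring, Monte Carlo inference, non-overlapping
# secondary clusters.

#' Poisson scan log-likelihood ratio
#'
#' High-rate form: for a window with `c` of `C` total cases and `e` of `E`
#' total expected, `LLR = c log(c/e) + (C-c) log((C-c)/(C-e))` when the
#' inside rate exceeds the outside rate, else 0.  Convention `0 log 0 = 0`.
#' Vectorized over `c` and `e`.
#'
#' @param c observed cases inside the window(s).
#' @param e expected cases inside (0 < e < E).
#' @param C total observed cases.
#' @param E total expected cases.
#' @return non-negative LLR value(s).
#' @export
poisson_llr <- function(c, e, C, E) {
  if (any(c > C)) stop("window cases exceed the total (c > C)")
  if (any(e <= 0) || any(e >= E)) stop("window expected counts must lie in (0, E)")
  inside <- ifelse(c > 0, c * log(c / e), 0)
  outside <- ifelse(C - c > 0, (C - c) * log((C - c) / (E - e)), 0)
  high <- (c / e) > ((C - c) / (E - e))
  # at c == C the outside term is 0 and the window is trivially high-rate
  high[c == C] <- TRUE
  ifelse(high, inside + outside, 0)
}

#' Scan-cluster relative risk
#'
#' Rate inside the window relative to the rate outside:
#' `RR = (c/e) / ((C-c)/(C-e))`, with expected counts renormalized so that
#' their total equals the total case count `C` (the scan-statistic
#' convention).
#'
#' @param c observed cases inside.
#' @param e expected cases inside (on the scale of `E`).
#' @param C total observed cases.
#' @param E total expected cases before renormalization (default `C`).
#' @return positive relative risk; `Inf` with a warning when `c == C`.
#' @examples
#' cluster_relative_risk(212 + 576 + 216, 152.13 + 163.28 + 82.43, 10419) # 2.69
#' @export
cluster_relative_risk <- function(c, e, C, E = C) {
  if (any(c > C)) stop("window cases exceed the total (c > C)")
  if (any(e <= 0) || any(e >= E)) stop("window expected counts must lie in (0, E)")
  e <- e * C / E
  rr <- ifelse(C - c > 0,
               (c / e) / ((C - c) / (C - e)),
               Inf)
  if (any(!is.finite(rr))) warning("window contains all cases: infinite relative risk")
  rr
}

#' Enumerate circular scan windows
#'
#' For every center area, candidate windows are the prefixes of the areas
#' ordered by centroid distance from that center, grown until the inside
#' expected count would exceed `max_fraction` of the total (the
#' single-area window is always kept).  Duplicate member sets arising from
#' different centers are removed.
#'
#' @param lattice [area_lattice()] with centroids.
#' @param table data frame with `observed` and `expected` columns aligned
#'   with `lattice`.
#' @param max_fraction maximum share of total expected count inside a
#'   window (SaTScan-style default 0.5).
#' @return list of windows; each has `center` (area_id), `members`
#'   (integer indices, distance-ordered), `observed`, `expected`.
#' @export
enumerate_windows <- function(lattice, table, max_fraction = 0.5) {
  if (max_fraction <= 0) stop("max_fraction must be > 0")
  if (anyNA(lattice$centroid_x) || anyNA(lattice$centroid_y)) {
    bad <- lattice$area_id[is.na(lattice$centroid_x) | is.na(lattice$centroid_y)]
    stop("missing centroid for area(s): ", paste(bad, collapse = ", "))
  }
  if (!"expected" %in% names(table)) stop("table needs an `expected` column")
  n <- nrow(lattice)
  e <- table$expected
  o <- table$observed
  Etot <- sum(e)
  windows <- list()
  seen <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    d <- sqrt((lattice$centroid_x - lattice$centroid_x[i])^2 +
                (lattice$centroid_y - lattice$centroid_y[i])^2)
    ord <- order(d, lattice$area_id)  # id tie-break for determinism
    ce <- cumsum(e[ord])
    kmax <- max(1L, sum(ce <= max_fraction * Etot))
    for (k in seq_len(kmax)) {
      members <- ord[seq_len(k)]
      key <- paste(sort(members), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      windows[[length(windows) + 1L]] <- list(
        center = lattice$area_id[i], members = members,
        observed = sum(o[members]), expected = ce[k])
    }
  }
  windows
}

# per-center orderings and prefix caps, shared by observed and replicate scans
scan_geometry <- function(lattice, e, max_fraction) {
  n <- nrow(lattice)
  ords <- matrix(0L, n, n)
  kmax <- integer(n)
  Etot <- sum(e)
  for (i in seq_len(n)) {
    d <- sqrt((lattice$centroid_x - lattice$centroid_x[i])^2 +
                (lattice$centroid_y - lattice$centroid_y[i])^2)
    ords[i, ] <- order(d, lattice$area_id)
    ce <- cumsum(e[ords[i, ]])
    kmax[i] <- max(1L, sum(ce <= max_fraction * Etot))
  }
  list(ords = ords, kmax = kmax)
}

# max LLR over all windows for each replicate row of `counts` (nrep x n)
replicate_max_llr <- function(counts, e, geom, C, E) {
  nrep <- nrow(counts); n <- ncol(counts)
  TRI <- upper.tri(matrix(0, n, n), diag = TRUE) * 1  # cumsum via matmul
  best <- rep(0, nrep)
  for (i in seq_len(n)) {
    k <- geom$kmax[i]
    if (k < 1) next
    ord <- geom$ords[i, ]
    cum_c <- counts[, ord, drop = FALSE] %*% TRI[, seq_len(k), drop = FALSE]
    cum_e <- cumsum(e[ord])[seq_len(k)]
    ok <- cum_e < E
    if (!any(ok)) next
    llr <- poisson_llr(as.vector(cum_c[, ok, drop = FALSE]),
                       rep(cum_e[ok], each = nrep), C, E)
    best <- pmax(best, apply(matrix(llr, nrow = nrep), 1, max))
  }
  best
}

#' Purely spatial Poisson scan with Monte Carlo inference
#'
#' Finds the most-likely high-rate cluster (maximum [poisson_llr()] over
#' the circular windows of [enumerate_windows()]) and non-overlapping
#' secondary clusters.  Null replicates redistribute the `C` observed
#' cases multinomially with probabilities `E_i / E`; each reported
#' cluster's p-value is its LLR ranked against the replicate maxima:
#' `p = (1 + #\{replicate max >= LLR\}) / (n_mc + 1)`.  Expected counts are
#' renormalized to sum to `C` before scanning.
#'
#' @param lattice [area_lattice()] with centroids.
#' @param table data frame with `observed` and `expected` columns.
#' @param n_mc number of Monte Carlo replicates (>= 1).
#' @param max_fraction window cap as a share of total expected count.
#' @param seed RNG seed (required: replicates must be reproducible).
#' @param max_reported cap on the number of reported clusters.
#' @param p_max only clusters with `p <= p_max` are reported (default 1 =
#'   report all non-overlapping positives).
#' @return list of class `scan_result`: `clusters` (list of cluster
#'   records: `rank`, `center`, `area_ids`, `observed`, `expected`, `llr`,
#'   `relative_risk`, `p_value`), `n_mc`, `total_observed`.
#' @export
scan_clusters <- function(lattice, table, n_mc = 999, max_fraction = 0.5,
                          seed = NULL, max_reported = 10, p_max = 1) {
  stopifnot(n_mc >= 1)
  if (is.null(seed)) stop("scan_clusters requires a seed for reproducibility")
  C <- sum(table$observed)
  if (C == 0) stop("no cases: scan statistic undefined")
  if (!"expected" %in% names(table)) table <- compute_expected(table)
  e <- table$expected * C / sum(table$expected)  # normalize so E = C
  E <- C
  windows <- enumerate_windows(lattice,
                               data.frame(observed = table$observed, expected = e),
                               max_fraction)
  llr <- vapply(windows, function(wd) {
    if (wd$expected >= E) return(0)
    poisson_llr(wd$observed, wd$expected, C, E)
  }, numeric(1))

  geom <- scan_geometry(lattice, e, max_fraction)
  set.seed(seed)
  repl <- t(stats::rmultinom(n_mc, C, e / E))  # n_mc x n
  max_llr <- replicate_max_llr(repl, e, geom, C, E)

  ord <- order(-llr)
  clusters <- list()
  used <- integer(0)
  for (j in ord) {
    if (llr[j] <= 0) break
    wd <- windows[[j]]
    if (length(intersect(wd$members, used))) next
    p <- (1 + sum(max_llr >= llr[j])) / (n_mc + 1)
    if (p > p_max) next
    clusters[[length(clusters) + 1L]] <- list(
      rank = length(clusters) + 1L,
      center = wd$center,
      area_ids = lattice$area_id[wd$members],
      members = wd$members,
      observed = wd$observed,
      expected = wd$expected,
      llr = llr[j],
      relative_risk = cluster_relative_risk(wd$observed, wd$expected, C, E),
      p_value = p)
    used <- c(used, wd$members)
    if (length(clusters) >= max_reported) break
  }
  structure(list(clusters = clusters, n_mc = n_mc, total_observed = C,
                 total_expected = E),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d cluster(s), C = %d, n_mc = %d\n",
              length(x$clusters), x$total_observed, x$n_mc))
  for (cl in x$clusters) {
    cat(sprintf("  #%d [%s] %d areas: O=%d E=%.2f RR=%.2f LLR=%.2f p=%.4g\n",
                cl$rank, cl$center, length(cl$area_ids), cl$observed,
                cl$expected, cl$relative_risk, cl$llr, cl$p_value))
  }
  invisible(x)
}

#' Flatten a scan result into a per-cluster data frame
#'
#' @param x a `scan_result`.
#' @return data frame with one row per cluster member area.
#' @export
scan_table <- function(x) {
  if (!length(x$clusters)) {
    return(data.frame(rank = integer(0), cluster_type = character(0),
                      area_id = character(0), observed = numeric(0),
                      expected = numeric(0), relative_risk = numeric(0),
                      p_value = numeric(0)))
  }
  do.call(rbind, lapply(x$clusters, function(cl) {
    data.frame(rank = cl$rank,
               cluster_type = if (cl$rank == 1) "primary" else "secondary",
               area_id = cl$area_ids,
               observed = cl$observed, expected = cl$expected,
               relative_risk = cl$relative_risk, p_value = cl$p_value,
               stringsAsFactors = FALSE)
  }))
}
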
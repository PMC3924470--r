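# Indirect standardization: expected counts, standardized ratios,
# crude admission rates.

#' Expected counts by indirect standardization
#'
#' Applies the study-wide admission rate to each area's population:
#' `E_i = n_i * (sum(O) / sum(n))`.  By construction `sum(E) == sum(O)`,
#' so the expected-count-weighted mean of the standardized ratios is
#' exactly 1.  Areas with zero population receive `E = 0` (their SR is
#' undefined and reported as `NA` by [add_sr()]).
#'
#' @param table data frame with columns `area_id`, `observed`, `population`.
#' @return `table` with an `expected` column added (replaced if present).
#' @export
compute_expected <- function(table) {
  validate_count_table(table)
  total_pop <- sum(table$population)
  if (total_pop <= 0) stop("all-zero population: cannot standardize")
  rate <- sum(table$observed) / total_pop
  table$expected <- table$population * rate
  table
}

#' Standardized ratio
#'
#' `SR = observed / expected`, the classic indirectly standardized
#' admission (morbidity) ratio.  Carried at full precision; round only
#' when printing reports.
#'
#' @param observed non-negative counts.
#' @param expected positive expected counts.
#' @return numeric vector of ratios.
#' @examples
#' compute_sr(176, 61.34)   # 2.87 at 2 d.p.
#' @export
compute_sr <- function(observed, expected) {
  if (any(observed < 0)) stop("observed must be >= 0")
  if (any(expected <= 0)) stop("expected must be > 0")
  observed / expected
}

#' Crude admission rate
#'
#' Cases per `per` population (default: per 1,000 people).
#'
#' @param observed non-negative counts.
#' @param population positive populations.
#' @param per scaling base, default 1000.
#' @return numeric vector of rates.
#' @export
admission_rate <- function(observed, population, per = 1000) {
  if (any(population <= 0)) stop("population must be > 0 for a rate")
  observed / population * per
}

#' Add SR and admission-rate columns to an area table
#'
#' Computes `expected` (if absent), `sr` and `admission_rate` columns.
#' Zero-population areas get `NA` for both derived quantities and are
#' excluded from downstream statistics.
#'
#' @param table data frame with `area_id`, `observed`, `population`.
#' @param per rate base for [admission_rate()].
#' @return augmented data frame.
#' @export
add_sr <- function(table, per = 1000) {
  if (!"expected" %in% names(table)) table <- compute_expected(table)
  ok <- table$expected > 0
  table$sr <- NA_real_
  table$sr[ok] <- compute_sr(table$observed[ok], table$expected[ok])
  okp <- table$population > 0
  table$admission_rate <- NA_real_
  table$admission_rate[okp] <- admission_rate(table$observed[okp],
                                              table$population[okp], per)
  table
}
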
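# Shared fixtures and small oracles, all built in code.

# all permutations of a small vector (enumeration oracle for the
# randomization moments of the global statistics)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

grid3 <- function() grid_lattice(3, 3)

# a small standardized count table on an r x c grid
toy_table <- function(lat, seed = 1, rate = 0.01) {
  set.seed(seed)
  pop <- stats::rlnorm(nrow(lat), log(5000), 0.5)
  data.frame(area_id = lat$area_id, population = pop,
             observed = stats::rpois(nrow(lat), pop * rate),
             stringsAsFactors = FALSE)
}

quiet_fit <- function(...) suppressWarnings(fit_hbayes(...))

extdata <- function(f) {
  p <- system.file("extdata", f, package = "arealrisk")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", f)
  p
}
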
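test_that("Moran's I equals -1 on the checkerboard and +size on blocks", {
  lat <- grid_lattice(2, 2)
  w <- build_contiguity(lat, "rook")
  m <- morans_i(c(1, -1, -1, 1), w)  # perfectly alternating
  expect_equal(m$statistic, -1)
  expect_equal(m$expectation, -1 / 3)
  # two-block constant-by-half surface on a 4x4 grid -> positive I
  lat4 <- grid_lattice(4, 4)
  w4 <- row_standardize(build_contiguity(lat4, "rook"))
  blocks <- ifelse(lat4$centroid_y > 2, 3, -3) + rep(c(0.01, -0.01), 8)
  expect_gt(morans_i(blocks, w4)$statistic, 0)
})

test_that("Moran expectation is -1/(n-1) and degenerate inputs error", {
  for (dims in list(c(2, 3), c(3, 3), c(4, 5))) {
    lat <- grid_lattice(dims[1], dims[2])
    w <- build_contiguity(lat, "rook")
    set.seed(1)
    m <- morans_i(rnorm(nrow(lat)), w)
    expect_equal(m$expectation, -1 / (nrow(lat) - 1))
    expect_equal(m$z, (m$statistic - m$expectation) / sqrt(m$variance))
  }
  w <- build_contiguity(grid3(), "rook")
  expect_error(morans_i(rep(2, 9), w), "constant")
})

test_that("analytic randomization moments equal exact permutation enumeration", {
  # n = 5 path graph: enumerate all 120 permutations as the oracle
  lat <- grid_lattice(1, 5)
  w <- build_contiguity(lat, "rook")
  P <- all_perms(1:5)
  # Moran (row-standardized)
  x <- c(1.3, -0.2, 2.8, 0.5, -1.1)
  ws <- row_standardize(w)
  W <- weights_matrix(ws); S0 <- sum(W)
  z <- x - mean(x)
  Is <- vapply(P, function(p) {
    zp <- z[p]
    (5 / S0) * sum(W * outer(zp, zp)) / sum(zp^2)
  }, numeric(1))
  m <- morans_i(x, ws, method = "randomization")
  expect_equal(mean(Is), m$expectation, tolerance = 1e-12)
  expect_equal(mean(Is^2) - mean(Is)^2, m$variance, tolerance = 1e-10)
  # General G (binary)
  xs <- c(3, 1, 4, 1.5, 9)
  Wb <- weights_matrix(w)
  Gs <- vapply(P, function(p) {
    xp <- xs[p]
    sum(Wb * outer(xp, xp)) / (sum(outer(xp, xp)) - sum(xp^2))
  }, numeric(1))
  g <- general_g(xs, w)
  expect_equal(mean(Gs), g$expectation, tolerance = 1e-12)
  expect_equal(mean(Gs^2) - mean(Gs)^2, g$variance, tolerance = 1e-10)
})

test_that("permutation and analytic Moran p agree within Monte Carlo error", {
  # 57-area lattice as in a city-scale layer
  dat <- generate_areal_data(shenzhen_like(seed = 4))
  w <- row_standardize(dat$weights)
  set.seed(99)
  x <- rnorm(57)
  a <- morans_i(x, w, method = "randomization")
  p <- morans_i(x, w, method = "permutation", n_permutations = 999, seed = 7)
  se <- sqrt(a$p * (1 - a$p) / 999)
  expect_lt(abs(a$p - p$p), 3 * se + 2 / 1000)
  # permutation p lies on the k/(R+1) grid
  expect_equal((p$p * 1000) %% 1, 0, tolerance = 1e-9)
})

test_that("General G detects concentration of adjacent high values", {
  lat <- grid3()
  w <- build_contiguity(lat, "rook")
  vals <- c(9, 9, 1, 9, 1, 1, 1, 1, 1)      # highs adjacent (corner block)
  disp <- c(9, 1, 9, 1, 1, 1, 9, 1, 1)      # same multiset, highs spread
  expect_gt(general_g(vals, w)$statistic, general_g(disp, w)$statistic)
  expect_error(general_g(c(-1, rep(1, 8)), w), "non-negative")
  # complete graph: G equals its expectation exactly (cancellation)
  n <- 5
  cg <- spatial_weights(letters[1:n],
                        lapply(1:n, function(i) setdiff(1:n, i)))
  g <- general_g(c(3, 1, 4, 1.5, 9), cg)
  expect_equal(g$statistic, g$expectation, tolerance = 1e-12)
  # two mutual neighbors: G = 1, inference undefined below n = 4
  w2 <- spatial_weights(c("a", "b"), list(2L, 1L))
  g2 <- general_g(c(2, 3), w2)
  expect_equal(g2$statistic, 1)
  expect_true(is.na(g2$variance))
})

test_that("Gi* peaks at a spike, is zero on constant surfaces, shift-invariant", {
  # spike at the center of a 5x5 grid: its window and its neighbors'
  # windows all contain the spike, so the spike attains the max z (tied
  # with equal-degree neighbors; lower-degree areas score strictly less)
  lat <- grid_lattice(5, 5)
  w <- build_contiguity(lat, "rook")
  spike <- rep(0, 25); spike[13] <- 10
  res <- local_gi_star(spike, w)
  expect_equal(res$z[13], max(res$z))
  expect_gt(res$z[13], res$z[1])  # corner far from the spike
  # constant surface: all z = 0
  res0 <- local_gi_star(rep(4.2, 25), w)
  expect_equal(res0$z, rep(0, 25))
  # z invariant to adding a constant (numerically)
  set.seed(3)
  x <- rnorm(25)
  expect_equal(local_gi_star(x + 100, w)$z, local_gi_star(x, w)$z,
               tolerance = 1e-9)
  # Moran's I also shift-invariant
  expect_equal(morans_i(x + 100, w)$statistic, morans_i(x, w)$statistic,
               tolerance = 1e-9)
  # max-z property: global max surrounded by next-largest values
  y <- rep(1, 25); y[13] <- 10; y[c(8, 12, 14, 18)] <- 5
  expect_equal(which.max(local_gi_star(y, w)$z), 13)
})

test_that("hot/cold classification follows sign and threshold", {
  tab <- read.csv(extdata("shenzhen2011_gistar_table.csv"),
                  stringsAsFactors = FALSE)
  local <- data.frame(area_id = tab$area_id, z = tab$gi_z, p = tab$gi_p)
  got <- classify_hot_cold(local, alpha = 0.10)
  expect_equal(got$cluster,
               ifelse(tab$cluster_type == "hot", "hot", "cold"))
  # explicit rows: Fubao hot, Longhua cold, weak z not significant
  expect_equal(classify_hot_cold(data.frame(z = 2.55, p = 0.01))$cluster, "hot")
  expect_equal(classify_hot_cold(data.frame(z = -2.39, p = 0.02))$cluster, "cold")
  expect_equal(classify_hot_cold(data.frame(z = 0.4, p = 0.69))$cluster,
               "not_significant")
})
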
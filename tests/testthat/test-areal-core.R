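test_that("grid contiguity matches lattice combinatorics", {
  lat <- grid3()
  rook <- build_contiguity(lat, "rook")
  queen <- build_contiguity(lat, "queen")
  deg_r <- lengths(rook$neighbors)
  deg_q <- lengths(queen$neighbors)
  # rook: corners 2, edges 3, center 4; queen: corners 3, edges 5, center 8
  expect_equal(sort(deg_r), c(2, 2, 2, 2, 3, 3, 3, 3, 4))
  expect_equal(sort(deg_q), c(3, 3, 3, 3, 5, 5, 5, 5, 8))
  # queen supersets rook, per area
  for (i in seq_len(9)) {
    expect_true(all(rook$neighbors[[i]] %in% queen$neighbors[[i]]))
  }
})

test_that("binary contiguity weights are symmetric on random lattices", {
  for (dims in list(c(2, 5), c(4, 4), c(3, 6))) {
    lat <- grid_lattice(dims[1], dims[2])
    for (rule in c("queen", "rook")) {
      M <- weights_matrix(build_contiguity(lat, rule))
      expect_identical(M, t(M))
      expect_true(all(diag(M) == 0))
    }
  }
})

test_that("disjoint squares are isolated but valid, with a warning", {
  polys <- list(
    a = cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
    b = cbind(x = c(5, 6, 6, 5), y = c(5, 5, 6, 6)))
  lat <- area_lattice(c("a", "b"), c(0.5, 5.5), c(0.5, 5.5),
                      population = 10, polygons = polys)
  expect_warning(w <- build_contiguity(lat, "queen"), "isolated")
  expect_equal(lengths(w$neighbors), c(0L, 0L))
  expect_identical(weights_matrix(w), t(weights_matrix(w)))
})

test_that("contiguity requires valid polygons and names the offender", {
  lat <- grid3()
  polys <- attr(lat, "polygons")
  polys[["g02.02"]] <- NULL
  attr(lat, "polygons") <- polys
  expect_error(build_contiguity(lat), "g02\\.02")
  attr(lat, "polygons") <- NULL
  expect_error(build_contiguity(lat), "no polygons")
})

test_that("row standardization sums rows to one, keeps isolates at zero, idempotent", {
  lat <- grid3()
  w <- build_contiguity(lat, "rook")
  ws <- row_standardize(w)
  expect_equal(unname(rowSums(weights_matrix(ws))), rep(1, 9), tolerance = 1e-12)
  center <- which(lengths(w$neighbors) == 4)
  expect_equal(ws$weights[[center]], rep(0.25, 4))
  # isolated rows stay all-zero, no NaN
  iso <- spatial_weights(c("a", "b", "c"), list(2L, 1L, integer(0)))
  iso_s <- row_standardize(iso)
  expect_identical(iso_s$weights[[3]], numeric(0))
  expect_false(anyNA(unlist(iso_s$weights)))
  # idempotence
  expect_equal(row_standardize(ws)$weights, ws$weights)
})

test_that("GAL round trip preserves neighbor sets exactly; errors on bad files", {
  lat <- grid3()
  w <- build_contiguity(lat, "queen")
  path <- withr::local_tempfile(fileext = ".gal")
  write_gal(w, path)
  w2 <- read_gal(path)
  expect_identical(w2$ids, w$ids)
  expect_identical(w2$neighbors, w$neighbors)
  # a 2-area pair
  p2 <- withr::local_tempfile()
  writeLines(c("2", "a 1", "b", "b 1", "a"), p2)
  wp <- read_gal(p2)
  expect_equal(lengths(wp$neighbors), c(1L, 1L))
  # unknown neighbor id
  p3 <- withr::local_tempfile()
  writeLines(c("2", "a 1", "zz", "b 0"), p3)
  expect_error(read_gal(p3), "unknown ids.*zz")
})

test_that("GAL and polygon-derived adjacency agree on grid lattices", {
  lat <- grid_lattice(4, 5)
  w <- build_contiguity(lat, "rook")
  path <- withr::local_tempfile(fileext = ".gal")
  write_gal(w, path)
  expect_identical(read_gal(path)$neighbors, w$neighbors)
})

test_that("GeoJSON round trip preserves ids, populations and adjacency", {
  lat <- grid_lattice(3, 4, population = c(100, 200))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(lat, path)
  lat2 <- read_geojson(path)
  expect_identical(lat2$area_id, lat$area_id)
  expect_equal(lat2$population, lat$population)
  expect_equal(lat2$centroid_x, lat$centroid_x)
  expect_equal(lat2$centroid_y, lat$centroid_y)
  expect_identical(build_contiguity(lat2, "queen")$neighbors,
                   build_contiguity(lat, "queen")$neighbors)
})

test_that("area table reader validates ids and counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(area_id = c("a", "b"), population = c(100, 300),
                       observed = c(2, 6), road_density = c(1, 2)),
            path, row.names = FALSE)
  at <- read_area_table(path)
  expect_equal(at$table$observed, c(2, 6))
  expect_null(at$lattice)

  write.csv(data.frame(area_id = c("a", "a"), population = 1, observed = 1),
            path, row.names = FALSE)
  expect_error(read_area_table(path), "duplicate")
  write.csv(data.frame(area_id = c("a", "b"), population = 1,
                       observed = c(1, -1)), path, row.names = FALSE)
  expect_error(read_area_table(path), "negative.*observed.*b")
})

test_that("write_results round-trips a results table", {
  tab <- data.frame(area_id = c("a", "b"), sr = c(1.23456789, 0.5),
                    stringsAsFactors = FALSE)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_results(tab, csv)
  expect_equal(read.csv(csv, stringsAsFactors = FALSE), tab)
  js <- withr::local_tempfile(fileext = ".json")
  write_results(tab, js)
  got <- jsonlite::fromJSON(js)
  expect_equal(got$sr, tab$sr)
})

test_that("lattice validation rejects duplicates and negatives", {
  expect_error(area_lattice(c("a", "a"), 0, 0, 1), "duplicate")
  expect_error(area_lattice(c("a", ""), 0, 0, 1), "non-empty")
  expect_error(area_lattice("a", 0, 0, population = -5), "population")
})
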
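# Areal data model: lattices of areal units and their spatial weights.

#' Construct an areal lattice
#'
#' An `area_lattice` holds the spatial backbone shared by every stage of the
#' pipeline: one row per areal unit with a unique identifier, a planar
#' centroid (projected coordinates, metres assumed; no geodesic math is
#' done), a resident population and an area measure.  Ring polygons are
#' optional and only required when contiguity weights are to be derived
#' from geometry.
#'
#' @param area_id character vector of unique, non-empty identifiers.
#' @param centroid_x,centroid_y numeric planar centroid coordinates. May be
#'   `NA` if no distance-based operation (scan statistics) will be used.
#' @param population non-negative resident counts.
#' @param area_size positive area measures (used e.g. for road density =
#'   road length / area). Defaults to 1.
#' @param polygons optional named list (names = `area_id`) of two-column
#'   numeric matrices, each an open ring (first vertex not repeated).
#' @return A data frame of class `area_lattice` with the polygons stored in
#'   the `"polygons"` attribute.
#' @examples
#' lat <- grid_lattice(3, 3)
#' nrow(lat)
#' @export
area_lattice <- function(area_id, centroid_x = NA_real_, centroid_y = NA_real_,
                         population = 0, area_size = 1, polygons = NULL) {
  area_id <- as.character(area_id)
  n <- length(area_id)
  df <- data.frame(
    area_id = area_id,
    centroid_x = rep_len(as.numeric(centroid_x), n),
    centroid_y = rep_len(as.numeric(centroid_y), n),
    population = rep_len(as.numeric(population), n),
    area_size = rep_len(as.numeric(area_size), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(polygons)) {
    if (is.null(names(polygons)) || !all(area_id %in% names(polygons))) {
      stop("`polygons` must be a named list covering every area_id")
    }
    polygons <- polygons[area_id]
  }
  attr(df, "polygons") <- polygons
  class(df) <- c("area_lattice", "data.frame")
  validate_lattice(df)
}

validate_lattice <- function(lattice) {
  ids <- lattice$area_id
  if (anyNA(ids) || any(!nzchar(ids))) stop("area_id must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate area_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(lattice$population < 0, na.rm = TRUE)) stop("population must be >= 0")
  if (any(lattice$area_size <= 0, na.rm = TRUE)) stop("area_size must be > 0")
  lattice
}

#' Regular grid lattice of unit squares
#'
#' Builds an `nrow x ncol` lattice of unit-square areas with polygons and
#' centroids; cells listed in `drop` are omitted (useful for irregular-ish
#' layouts).  Cell `(r, c)` occupies `[c-1, c] x [r-1, r]` and is labelled
#' `gRR.CC`.
#'
#' @param nrow,ncol grid dimensions.
#' @param drop character vector of cell ids to omit.
#' @param population populations recycled over the retained cells.
#' @return an [area_lattice()].
#' @export
grid_lattice <- function(nrow, ncol, drop = character(), population = 1000) {
  ids <- character(0); cx <- cy <- numeric(0); polys <- list()
  for (r in seq_len(nrow)) {
    for (cc in seq_len(ncol)) {
      id <- sprintf("g%02d.%02d", r, cc)
      if (id %in% drop) next
      ids <- c(ids, id)
      cx <- c(cx, cc - 0.5); cy <- c(cy, r - 0.5)
      polys[[id]] <- cbind(
        x = c(cc - 1, cc, cc, cc - 1),
        y = c(r - 1, r - 1, r, r)
      )
    }
  }
  area_lattice(ids, cx, cy, population = population, area_size = 1,
               polygons = polys)
}

# ---- spatial weights ------------------------------------------------------

new_spatial_weights <- function(ids, neighbors, weights, style) {
  stopifnot(length(neighbors) == length(ids), length(weights) == length(ids))
  w <- list(ids = ids, neighbors = neighbors, weights = weights, style = style)
  class(w) <- "spatial_weights"
  w
}

#' Construct spatial weights from neighbor lists
#'
#' @param ids character area identifiers.
#' @param neighbors list (one entry per area) of integer indices into `ids`.
#' @param weights optional list of numeric weights matching `neighbors`;
#'   defaults to binary (all 1).
#' @param style `"B"` for binary, `"W"` for row-standardized.
#' @return object of class `spatial_weights`.
#' @export
spatial_weights <- function(ids, neighbors, weights = NULL, style = "B") {
  ids <- as.character(ids)
  neighbors <- lapply(neighbors, as.integer)
  if (is.null(weights)) weights <- lapply(neighbors, function(nb) rep(1, length(nb)))
  for (i in seq_along(neighbors)) {
    nb <- neighbors[[i]]
    if (any(nb == i)) stop("self-neighbor (w_ii != 0) at area ", ids[i])
    if (any(nb < 1 | nb > length(ids))) stop("neighbor index out of range at ", ids[i])
    if (length(weights[[i]]) != length(nb)) stop("weights/neighbors length mismatch")
  }
  w <- new_spatial_weights(ids, neighbors, weights, style)
  if (style == "B") {
    M <- weights_matrix(w)
    if (!isTRUE(all.equal(M, t(M)))) stop("binary weights must be symmetric")
  }
  w
}

#' @export
print.spatial_weights <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("spatial_weights: %d areas, style %s, avg links %.2f, %d isolated\n",
              length(x$ids), x$style, mean(deg), sum(deg == 0)))
  invisible(x)
}

#' Dense weights matrix
#'
#' @param w a `spatial_weights` object.
#' @return an `n x n` numeric matrix with `dimnames` set to the area ids.
#' @export
weights_matrix <- function(w) {
  n <- length(w$ids)
  M <- matrix(0, n, n, dimnames = list(w$ids, w$ids))
  for (i in seq_len(n)) M[i, w$neighbors[[i]]] <- w$weights[[i]]
  M
}

#' Row-standardize spatial weights
#'
#' Each non-isolated row is rescaled to sum to one; isolated rows stay
#' all-zero (no `NaN`).  Idempotent.
#'
#' @param w a `spatial_weights` object.
#' @return a `spatial_weights` object with `style = "W"`.
#' @export
row_standardize <- function(w) {
  weights <- lapply(w$weights, function(wi) {
    s <- sum(wi)
    if (s > 0) wi / s else wi
  })
  new_spatial_weights(w$ids, w$neighbors, weights, "W")
}

#' Contiguity weights from polygon geometry
#'
#' Derives binary symmetric adjacency from ring polygons: `queen` links any
#' two areas sharing at least one boundary vertex, `rook` requires a shared
#' edge of positive length.  Shared boundaries must share ring vertices
#' (true for lattices built by this package; T-junction geometries are out
#' of scope).  Isolated areas are retained with empty rows and reported via
#' a warning.
#'
#' @param lattice an [area_lattice()] carrying polygons.
#' @param rule `"queen"` (default) or `"rook"`.
#' @return binary `spatial_weights`.
#' @export
build_contiguity <- function(lattice, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  polys <- attr(lattice, "polygons")
  ids <- lattice$area_id
  n <- length(ids)
  if (is.null(polys)) stop("lattice has no polygons; cannot build contiguity")
  keysets <- vector("list", n)
  for (i in seq_len(n)) {
    p <- polys[[ids[i]]]
    if (is.null(p) || !is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop("missing or invalid polygon for area ", ids[i])
    }
    vk <- sprintf("%.6f_%.6f", p[, 1], p[, 2])
    if (anyDuplicated(vk)) stop("degenerate ring (repeated vertex) for area ", ids[i])
    if (rule == "queen") {
      keysets[[i]] <- vk
    } else {
      nxt <- c(vk[-1], vk[1])
      keysets[[i]] <- paste(pmin(vk, nxt), pmax(vk, nxt), sep = "|")
    }
  }
  # invert key -> areas, then mark co-occurring pairs
  key_df <- data.frame(
    key = unlist(keysets, use.names = FALSE),
    area = rep(seq_len(n), lengths(keysets))
  )
  nb <- replicate(n, integer(0), simplify = FALSE)
  sp <- split(key_df$area, key_df$key)
  for (areas in sp) {
    if (length(areas) < 2) next
    for (a in areas) nb[[a]] <- union(nb[[a]], setdiff(areas, a))
  }
  nb <- lapply(nb, sort)
  iso <- ids[lengths(nb) == 0]
  if (length(iso)) {
    warning("isolated areas (no ", rule, " neighbors): ",
            paste(iso, collapse = ", "))
  }
  spatial_weights(ids, nb, style = "B")
}

# ---- GAL interchange ------------------------------------------------------

#' Read a GAL adjacency file
#'
#' The dialect is a header line holding the number of areas, followed for
#' each area by an `"id k"` record line and a line of `k` neighbor ids
#' (empty for isolated areas).  Neighbor ids must appear as record heads.
#'
#' @param path file path.
#' @return binary `spatial_weights`.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) > 1]
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  ids <- character(n)
  raw_nb <- vector("list", n)
  pos <- 2
  for (i in seq_len(n)) {
    hd <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (length(hd) != 2) stop("malformed GAL record line: ", lines[pos])
    ids[i] <- hd[1]
    k <- as.integer(hd[2])
    if (k > 0) {
      raw_nb[[i]] <- strsplit(trimws(lines[pos + 1]), "\\s+")[[1]]
      if (length(raw_nb[[i]]) != k) stop("GAL record for ", ids[i], " promises ",
                                         k, " neighbors, found ", length(raw_nb[[i]]))
      pos <- pos + 2
    } else {
      raw_nb[[i]] <- character(0)
      pos <- pos + 1
    }
  }
  if (anyDuplicated(ids)) stop("duplicate ids in GAL file")
  unknown <- setdiff(unique(unlist(raw_nb)), ids)
  if (length(unknown)) {
    stop("GAL references unknown ids: ", paste(unknown, collapse = ", "))
  }
  nb <- lapply(raw_nb, function(v) sort(match(v, ids)))
  spatial_weights(ids, nb, style = "B")
}

#' Write a GAL adjacency file
#'
#' @param w binary `spatial_weights`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(w, path) {
  out <- as.character(length(w$ids))
  for (i in seq_along(w$ids)) {
    k <- length(w$neighbors[[i]])
    out <- c(out, paste(w$ids[i], k))
    if (k > 0) out <- c(out, paste(w$ids[w$neighbors[[i]]], collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

# ---- GeoJSON --------------------------------------------------------------

ring_centroid <- function(p) {
  # shoelace centroid of a simple ring (open; first vertex not repeated)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cross) / (6 * a), sum((y + yn) * cross) / (6 * a))
}

ring_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Read an areal polygon layer from GeoJSON
#'
#' Expects a FeatureCollection of `Polygon` features whose properties carry
#' `area_id` and optionally `population` and `area_size`.  Only the outer
#' ring is used; centroids are computed from it, and `area_size` defaults
#' to the ring area.
#'
#' @param path file path.
#' @return an [area_lattice()].
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  ids <- character(0); pop <- asz <- cx <- cy <- numeric(0); polys <- list()
  for (f in gj$features) {
    props <- f$properties
    id <- props$area_id
    if (is.null(id)) stop("feature without an area_id property")
    if (!identical(f$geometry$type, "Polygon")) {
      stop("unsupported geometry type for area ", id, ": ", f$geometry$type)
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(v) {
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))
    }))
    # drop closing vertex if present
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    ids <- c(ids, id)
    cen <- ring_centroid(ring)
    cx <- c(cx, cen[1]); cy <- c(cy, cen[2])
    pop <- c(pop, if (is.null(props$population)) 0 else as.numeric(props$population))
    asz <- c(asz, if (is.null(props$area_size)) ring_area(ring) else as.numeric(props$area_size))
    polys[[id]] <- ring
  }
  area_lattice(ids, cx, cy, pop, asz, polygons = polys)
}

#' Write an areal lattice to GeoJSON
#'
#' @param lattice an [area_lattice()] with polygons.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(lattice, path) {
  polys <- attr(lattice, "polygons")
  if (is.null(polys)) stop("lattice has no polygons to write")
  features <- lapply(seq_len(nrow(lattice)), function(i) {
    id <- lattice$area_id[i]
    ring <- polys[[id]]
    ring <- rbind(ring, ring[1, ])  # close the ring
    coords <- lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2]))
    list(
      type = "Feature",
      properties = list(area_id = id,
                        population = lattice$population[i],
                        area_size = lattice$area_size[i]),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- area tables ----------------------------------------------------------

#' Read a CSV area table
#'
#' Required columns: `area_id`, `population`, `observed`; any further
#' numeric columns are treated as covariates (e.g. `road_density`).  If
#' `centroid_x`/`centroid_y` columns are present a bare lattice (no
#' polygons) is also returned.
#'
#' @param path file path.
#' @return list with elements `table` (data frame) and `lattice`
#'   ([area_lattice()] or `NULL` when no centroid columns exist).
#' @export
read_area_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "population", "observed")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("area table missing columns: ", paste(miss, collapse = ", "))
  tab$area_id <- as.character(tab$area_id)
  validate_count_table(tab)
  lattice <- NULL
  if (all(c("centroid_x", "centroid_y") %in% names(tab))) {
    lattice <- area_lattice(tab$area_id, tab$centroid_x, tab$centroid_y,
                            tab$population,
                            if ("area_size" %in% names(tab)) tab$area_size else 1)
  }
  list(table = tab, lattice = lattice)
}

validate_count_table <- function(tab) {
  if (anyDuplicated(tab$area_id)) {
    stop("duplicate area_id: ",
         paste(unique(tab$area_id[duplicated(tab$area_id)]), collapse = ", "))
  }
  bad <- tab$area_id[is.na(tab$observed) | tab$observed < 0]
  if (length(bad)) stop("negative or missing observed counts: ", paste(bad, collapse = ", "))
  bad <- tab$area_id[is.na(tab$population) | tab$population < 0]
  if (length(bad)) stop("negative or missing population: ", paste(bad, collapse = ", "))
  if ("expected" %in% names(tab) && any(tab$expected < 0, na.rm = TRUE)) {
    stop("negative expected counts")
  }
  invisible(tab)
}

#' Write a results table to CSV or JSON
#'
#' Format is chosen from the file extension (`.json` vs anything else =
#' CSV).  `write_results` then `read.csv`/`fromJSON` round-trips exactly at
#' full double precision for CSV (written with 15 significant digits).
#'
#' @param table a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(table, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(table, path, row.names = FALSE)
  }
  invisible(path)
}
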
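#' County/tract region set
#'
#' A `region_set` bundles the two polygon layers of the study design: counties
#' and the census tracts that partition them. Geometries live in list-columns
#' of two-column coordinate matrices (closed rings not required; the first
#' vertex is implicitly repeated), in the same projected km coordinate system
#' as the rasters.
#'
#' @param counties Tibble with columns `county_id`, `geometry` (list of n x 2
#'   matrices) and optionally `area_km2` (recomputed if missing).
#' @param tracts Tibble with columns `county_id`, `tract_id`, `geometry`, and
#'   optionally `area_km2`, `population`, `low_income_count`.
#' @return An object of class `region_set`.
#' @export
region_set <- function(counties, tracts) {
  counties <- tibble::as_tibble(counties)
  tracts <- tibble::as_tibble(tracts)
  if (!all(c("county_id", "geometry") %in% names(counties)) ||
      !all(c("county_id", "tract_id", "geometry") %in% names(tracts))) {
    abort_airineq("counties need county_id+geometry; tracts need county_id+tract_id+geometry.",
                  "airineq_error_bad_regions")
  }
  if (!"area_km2" %in% names(counties)) {
    counties$area_km2 <- vapply(counties$geometry, polygon_area, numeric(1))
  }
  if (!"area_km2" %in% names(tracts)) {
    tracts$area_km2 <- vapply(tracts$geometry, polygon_area, numeric(1))
  }
  if (!"population" %in% names(tracts)) tracts$population <- NA_real_
  if (!"low_income_count" %in% names(tracts)) tracts$low_income_count <- NA_real_
  orphan <- setdiff(tracts$county_id, counties$county_id)
  if (length(orphan) > 0) {
    abort_airineq(paste0("tracts reference unknown counties: ",
                         paste(orphan, collapse = ", ")),
                  "airineq_error_orphan_tract")
  }
  if (any(counties$area_km2 <= 0) || any(tracts$area_km2 <= 0)) {
    abort_airineq("zero- or negative-area polygon in region set.",
                  "airineq_error_zero_area")
  }
  bad <- !is.na(tracts$low_income_count) & !is.na(tracts$population) &
    (tracts$low_income_count < 0 | tracts$low_income_count > tracts$population)
  if (any(bad)) {
    abort_airineq("low_income_count must lie in [0, population].",
                  "airineq_error_bad_regions")
  }
  structure(list(counties = counties, tracts = tracts), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set: %d counties, %d tracts, total area %.4g km2>\n",
              nrow(x$counties), nrow(x$tracts), sum(x$counties$area_km2)))
  invisible(x)
}

# Shoelace area; vertices in km, any ring orientation.
polygon_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# Which of the points (px, py) fall inside/on the polygon.
points_in_polygon <- function(px, py, coords) {
  sp::point.in.polygon(px, py, coords[, 1], coords[, 2]) > 0
}

#' Read county and tract polygons from GeoJSON
#'
#' Expects two GeoJSON FeatureCollections of Polygon features. County features
#' must carry a `county_id` property; tract features `county_id` and
#' `tract_id`, and may carry `population` and `low_income_count`. Coordinates
#' are taken to be projected km. Areas are recomputed from the geometry.
#'
#' @param county_path,tract_path Paths to GeoJSON files.
#' @return A [region_set()].
#' @export
read_regions <- function(county_path, tract_path) {
  counties <- read_geojson_layer(county_path, c("county_id"))
  tracts <- read_geojson_layer(tract_path,
                               c("county_id", "tract_id"),
                               optional = c("population", "low_income_count"))
  region_set(counties, tracts)
}

read_geojson_layer <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    abort_airineq(paste0("vector file not found: ", path),
                  "airineq_error_missing_file")
  }
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) {
    abort_airineq(paste0("not a GeoJSON FeatureCollection: ", path),
                  "airineq_error_bad_vector")
  }
  rows <- purrr::map(feats, function(f) {
    props <- f$properties
    miss <- setdiff(required, names(props))
    if (length(miss) > 0) {
      abort_airineq(paste0("feature missing properties: ",
                           paste(miss, collapse = ", ")),
                    "airineq_error_bad_vector")
    }
    if (!identical(f$geometry$type, "Polygon")) {
      abort_airineq("only Polygon geometries are supported.",
                    "airineq_error_bad_vector")
    }
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
    # drop a closing vertex that duplicates the first
    if (nrow(coords) > 1 && all(coords[1, ] == coords[nrow(coords), ])) {
      coords <- coords[-nrow(coords), , drop = FALSE]
    }
    out <- props[c(required, intersect(optional, names(props)))]
    out$geometry <- list(coords)
    out
  })
  tbl <- purrr::map_dfr(rows, ~ tibble::as_tibble(.x))
  tbl$geometry <- purrr::map(rows, ~ .x$geometry[[1]])
  tbl
}

#' Write a region set to GeoJSON
#'
#' @param regions A [region_set()].
#' @param county_path,tract_path Output GeoJSON paths.
#' @return `invisible(NULL)`.
#' @export
write_regions <- function(regions, county_path, tract_path) {
  stopifnot(inherits(regions, "region_set"))
  write_geojson_layer(regions$counties, county_path,
                      c("county_id", "area_km2"))
  write_geojson_layer(regions$tracts, tract_path,
                      c("county_id", "tract_id", "area_km2",
                        "population", "low_income_count"))
  invisible(NULL)
}

write_geojson_layer <- function(tbl, path, props) {
  feats <- purrr::map(seq_len(nrow(tbl)), function(i) {
    coords <- tbl$geometry[[i]]
    ring <- rbind(coords, coords[1, ])
    p <- as.list(tbl[i, intersect(props, names(tbl)), drop = FALSE])
    p <- p[!vapply(p, function(v) all(is.na(unlist(v))), logical(1))]
    list(
      type = "Feature",
      properties = p,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(k) c(ring[k, 1], ring[k, 2])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Binary spatial adjacency
#'
#' Builds the symmetric 0/1 contiguity matrix used by the spatial Gini index.
#' For polygons, rook contiguity means a shared edge (two or more shared
#' vertices); queen contiguity means at least one shared vertex. Polygon
#' inputs are assumed to form a tessellation with matching vertices, as the
#' synthetic generator produces. For grid cells use [cell_adjacency()].
#'
#' @param geoms List of polygon coordinate matrices.
#' @param rule `"rook"` or `"queen"`.
#' @return An n x n binary symmetric matrix with zero diagonal.
#' @examples
#' sq <- function(x, y) cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
#' build_adjacency(list(sq(0, 0), sq(1, 0), sq(1, 1)), "rook")
#' @export
build_adjacency <- function(geoms, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  n <- length(geoms)
  w <- matrix(0L, n, n)
  if (n < 2) return(w)
  keys <- lapply(geoms, function(g) {
    paste(round(g[, 1], 9), round(g[, 2], 9), sep = ",")
  })
  need <- if (rule == "rook") 2L else 1L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (length(intersect(keys[[i]], keys[[j]])) >= need) {
        w[i, j] <- w[j, i] <- 1L
      }
    }
  }
  w
}

#' Grid-cell contiguity matrix
#'
#' Adjacency over the cells of an `nr x nc` grid in column-major cell order
#' (the order of `as.vector()` on the value matrix).
#'
#' @param nr,nc Grid dimensions.
#' @param rule `"rook"` (shared edge) or `"queen"` (edge or corner).
#' @return An `(nr*nc) x (nr*nc)` binary symmetric matrix, zero diagonal.
#' @export
cell_adjacency <- function(nr, nc, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  n <- nr * nc
  idx <- function(r, c) (c - 1L) * nr + r
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (rule == "queen") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  w <- matrix(0L, n, n)
  for (o in offs) {
    r <- rep(seq_len(nr), times = nc)
    cc <- rep(seq_len(nc), each = nr)
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    a <- idx(r[ok], cc[ok]); b <- idx(r2[ok], c2[ok])
    w[cbind(a, b)] <- 1L
    w[cbind(b, a)] <- 1L
  }
  w
}

#' Assign grid cells to counties
#'
#' Zonal assignment: a cell belongs to the county whose polygon contains its
#' center (ties broken by county order; cells outside every county get `NA`).
#'
#' @param grid A [grid_field()].
#' @param regions A [region_set()].
#' @return Integer vector over cells (column-major, matching `as.vector()` of
#'   the value matrix) giving the row index into `regions$counties`.
#' @export
assign_cells <- function(grid, regions) {
  cells <- grid_cells(grid)
  n <- nrow(cells)
  out <- rep(NA_integer_, n)
  for (i in seq_len(nrow(regions$counties))) {
    g <- regions$counties$geometry[[i]]
    bb <- apply(g, 2, range)
    cand <- which(is.na(out) &
                    cells$x >= bb[1, 1] & cells$x <= bb[2, 1] &
                    cells$y >= bb[1, 2] & cells$y <= bb[2, 2])
    if (length(cand) == 0) next
    inside <- points_in_polygon(cells$x[cand], cells$y[cand], g)
    out[cand[inside]] <- i
  }
  out
}
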
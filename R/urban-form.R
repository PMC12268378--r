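#' Local coefficient of POI concentration
#'
#' `LC = 1/2 sum_i |k_i - 1/N|` where `k_i` is tract i's share of the
#' county's POIs. 0 for a perfectly even distribution, `(N-1)/N` when all
#' POIs sit in one tract.
#'
#' @param poi_shares Vector of tract POI proportions summing to 1.
#' @return A value in `[0, (N-1)/N]`.
#' @examples
#' local_coefficient(c(0.5, 0.3, 0.2, 0))  # 0.30
#' @export
local_coefficient <- function(poi_shares) {
  if (abs(sum(poi_shares) - 1) > 1e-9) {
    abort_airineq("poi_shares must sum to 1.", "airineq_error_bad_shares")
  }
  n <- length(poi_shares)
  sum(abs(poi_shares - 1 / n)) / 2
}

#' Spatial separation value of a POI distribution
#'
#' The quadratic form `V = k' D k` of the POI share vector against the
#' tract-centroid distance matrix: small when mass is concentrated, large
#' when it is split across mutually distant tracts.
#'
#' @param poi_shares Vector of tract POI proportions.
#' @param D Symmetric non-negative distance matrix (km), zero diagonal.
#' @return Separation value (km).
#' @export
separation_value <- function(poi_shares, D) {
  check_distance_matrix(D, length(poi_shares))
  as.numeric(poi_shares %*% D %*% poi_shares)
}

check_distance_matrix <- function(D, n = NULL) {
  if (!is.matrix(D) || nrow(D) != ncol(D) ||
      any(abs(D - t(D)) > 1e-9) || any(diag(D) != 0) || any(D < 0)) {
    abort_airineq("D must be symmetric, non-negative, zero-diagonal.",
                  "airineq_error_bad_distance")
  }
  if (!is.null(n) && nrow(D) != n) {
    abort_airineq("D not conformable with shares.",
                  "airineq_error_bad_distance")
  }
  invisible(TRUE)
}

#' Maximum separation value over the share simplex
#'
#' Maximizes `k' D k` over probability vectors `k`. For 12 or fewer tracts
#' the maximum is found exactly: every Karush-Kuhn-Tucker point lies on some
#' face of the simplex and solves `D_S k = c 1` on its support, so all
#' supports are enumerated; vertices contribute 0. Above 12 tracts,
#' multi-start projected gradient ascent is used (starting from the best
#' two-point split, the uniform vector, and random points). The result is
#' always at least `max_ij D_ij / 2`, the best two-point split.
#'
#' @param D Distance matrix as in [separation_value()].
#' @return The maximal separation value.
#' @export
vmax <- function(D) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (n == 1) return(0)
  best <- max(D) / 2   # two-point split on the farthest pair
  if (n <= 12) {
    for (size in 2:n) {
      subs <- utils::combn(n, size, simplify = FALSE)
      for (S in subs) {
        x <- tryCatch(solve(D[S, S, drop = FALSE], rep(1, size)),
                      error = function(e) NULL)
        if (is.null(x) || any(!is.finite(x)) || any(x <= 0)) next
        x <- x / sum(x)
        val <- as.numeric(x %*% D[S, S] %*% x)
        if (val > best) best <- val
      }
    }
    return(best)
  }
  # projected gradient ascent with deterministic multi-starts: the uniform
  # vector plus two-point splits on the ten farthest pairs
  starts <- list(rep(1 / n, n))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[ut], decreasing = TRUE)
  for (k in seq_len(min(10, nrow(ut)))) {
    two <- numeric(n)
    two[ut[ord[k], ]] <- 0.5
    starts <- c(starts, list(two))
  }
  for (x0 in starts) {
    x <- x0
    step <- 0.5 / max(D)
    for (it in 1:500) {
      g <- 2 * as.numeric(D %*% x)
      x_new <- project_simplex(x + step * g)
      if (sum(abs(x_new - x)) < 1e-10) break
      x <- x_new
    }
    val <- as.numeric(x %*% D %*% x)
    if (val > best) best <- val
  }
  best
}

# Euclidean projection onto the probability simplex (sort-and-threshold).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Urban centrality index per county
#'
#' Counts POIs per tract (point-in-polygon), forms shares, and composes
#' `LC` (unevenness), `V` (separation), `Vmax`, `PI = 1 - V / Vmax` and
#' `UCI = LC * PI`. Counties without POIs get `NA` components and a flag;
#' single-tract counties get `PI = 1` by convention (with `Vmax = 0`).
#' Identical tract distance matrices across counties (as with a regular
#' synthetic subdivision) share one `Vmax` evaluation.
#'
#' @param poi Tibble of POI points with columns `x`, `y` (km).
#' @param regions A [region_set()].
#' @return Tibble: `county_id`, `n_poi`, `LC`, `V`, `Vmax`, `PI`, `UCI`,
#'   `undefined`.
#' @export
uci_table <- function(poi, regions) {
  vmax_cache <- new.env(parent = emptyenv())
  out <- purrr::map_dfr(seq_len(nrow(regions$counties)), function(i) {
    cid <- regions$counties$county_id[i]
    tr <- dplyr::filter(regions$tracts, .data$county_id == cid)
    counts <- count_points_in_polygons(poi$x, poi$y, tr$geometry)
    n_poi <- sum(counts)
    base <- tibble::tibble(county_id = cid, n_poi = n_poi)
    if (n_poi == 0) {
      return(dplyr::mutate(base, LC = NA_real_, V = NA_real_,
                           Vmax = NA_real_, PI = NA_real_, UCI = NA_real_,
                           undefined = TRUE))
    }
    shares <- counts / n_poi
    cent <- t(vapply(tr$geometry, polygon_centroid, numeric(2)))
    D <- as.matrix(stats::dist(cent))
    dimnames(D) <- NULL
    lc <- local_coefficient(shares)
    v <- separation_value(shares, D)
    if (nrow(D) == 1) {
      vm <- 0; pi_val <- 1
    } else {
      key <- digest_matrix(D)
      vm <- vmax_cache[[key]] %||% (vmax_cache[[key]] <- vmax(D))
      pi_val <- 1 - v / vm
    }
    dplyr::mutate(base, LC = lc, V = v, Vmax = vm, PI = pi_val,
                  UCI = lc * pi_val, undefined = FALSE)
  })
  if (any(out$undefined)) {
    rlang::warn(paste0("UCI undefined (no POIs) for: ",
                       paste(out$county_id[out$undefined], collapse = ", ")),
                class = "airineq_warn_undefined_uci")
  }
  out
}

digest_matrix <- function(m) {
  paste(round(as.vector(m), 6), collapse = ",")
}

count_points_in_polygons <- function(px, py, geoms) {
  vapply(geoms, function(g) {
    bb <- apply(g, 2, range)
    cand <- px >= bb[1, 1] & px <= bb[2, 1] & py >= bb[1, 2] & py <= bb[2, 2]
    if (!any(cand)) return(0L)
    sum(points_in_polygon(px[cand], py[cand], g))
  }, integer(1))
}

#' Per-county POI, road and population densities
#'
#' Counts (POIs by point-in-polygon, road segments and population as given)
#' divided by county area in km2.
#'
#' @param regions A [region_set()].
#' @param poi Tibble of POI points (`x`, `y`).
#' @param roads Tibble with `county_id`, `road_segments`.
#' @param pop Population [grid_field()].
#' @return Tibble: `county_id`, `poi_density`, `road_density`, `pop_density`.
#' @export
density_table <- function(regions, poi, roads, pop) {
  cty <- regions$counties
  n_poi <- count_points_in_polygons(poi$x, poi$y, cty$geometry)
  cty_pop <- aggregate_to_polygons(pop, cty$geometry)
  tibble::tibble(county_id = cty$county_id,
                 poi_density = n_poi / cty$area_km2,
                 pop_density = cty_pop / cty$area_km2) |>
    dplyr::left_join(roads, by = "county_id") |>
    dplyr::mutate(road_density = .data$road_segments / cty$area_km2) |>
    dplyr::select("county_id", "poi_density", "road_density", "pop_density")
}

#' Fuzzy-sum conversion pressure index
#'
#' Probabilistic-OR combination `1 - (1 - hm2030) * (1 - dsi)` of the
#' projected human-modification and development-suitability layers: 0 means
#' no conversion pressure, 1 the maximum.
#'
#' @param hm2030,dsi Values in `[0, 1]` (vectorized).
#' @return Values in `[0, 1]`.
#' @examples
#' fuzzy_sum_cpi(0.5, 0.5)  # 0.75
#' @export
fuzzy_sum_cpi <- function(hm2030, dsi) {
  if (any(hm2030 < 0 | hm2030 > 1 | dsi < 0 | dsi > 1)) {
    abort_airineq("fuzzy_sum_cpi inputs must lie in [0, 1].",
                  "airineq_error_bad_values")
  }
  1 - (1 - hm2030) * (1 - dsi)
}

#' Assemble the urban-form indicator block
#'
#' Joins [density_table()] and [uci_table()] into one per-county tibble.
#'
#' @param province A [simulate_province()] result (or compatible list with
#'   `regions`, `poi`, `roads`, `population`).
#' @return Tibble: `county_id`, `poi_density`, `road_density`, `pop_density`,
#'   `UCI`.
#' @export
urban_form_table <- function(province) {
  dens <- density_table(province$regions, province$poi, province$roads,
                        province$population)
  uci <- uci_table(province$poi, province$regions)
  dplyr::left_join(dens, dplyr::select(uci, "county_id", "UCI"),
                   by = "county_id")
}
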
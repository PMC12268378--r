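#' Configuration for the synthetic province generator
#'
#' The generator emulates the statistical structure of a provincial study
#' region: a rectangular lattice of square counties, each regularly subdivided
#' into tracts; spatially autocorrelated log-normal pollutant surfaces whose
#' within-county variability is controlled independently of the county mean;
#' a heavy-tailed population surface with tunable monocentricity; tract-level
#' income allocations with tunable segregation; clustered points of interest;
#' and per-county socio-economic / environmental covariates with planted
#' linear effects on log county-mean concentration.
#'
#' Defaults describe a 10 x 10 county province of 8 km squares at 1-km cells
#' with 9 tracts per county, pollutant base levels 21 / 33 / 54 ug/m3 for
#' PM1 / PM2.5 / PM10, and planted effects of population density (+0.3),
#' mean annual temperature (+0.3) and NDVI (-0.3) on log exposure.
#'
#' @param n_counties_x,n_counties_y Counties along each axis.
#' @param county_size_km County edge length (km); must be an integer multiple
#'   of `cell_size_km`.
#' @param cell_size_km Raster cell size (km).
#' @param tracts_per_county Tracts per county (laid out as a near-square grid).
#' @param seed Integer master seed; every stream derives its own sub-seed.
#' @param spatial_range_km Exponential-covariance range of the shared
#'   concentration random field.
#' @param population_lognormal_mu,population_lognormal_sigma Log-normal
#'   parameters of per-cell population marks.
#' @param segregation_level In `[0, 1]`: 0 = proportional income allocation
#'   across tracts, 1 = low-income population packed into the fewest tracts.
#' @param centrality_level In `[0, 1]`: weight of the clustered (county
#'   center) component for both population density and POI placement.
#' @param effect_sizes Named numeric vector of planted effects (per standard
#'   deviation of the covariate) on log county-mean concentration. Valid
#'   names: `pop_density`, `GDP`, `CPI`, `MAT`, `MAP`, `NDVI`, `SAP`, `VC`.
#' @param noise_sd SD of the county-level log-concentration noise.
#' @param pollutant_levels Named base means (ug/m3) for `PM1`, `PM2.5`, `PM10`.
#' @param within_sd_min,within_sd_max Per-county within-county log-scale SD
#'   is drawn uniformly from this interval, independently of the county mean
#'   level, so exposure level and spatial inequality decouple by design.
#' @param poi_per_1000 Expected POIs per 1000 residents.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_counties_x = 10, n_counties_y = 10,
                             county_size_km = 8, cell_size_km = 1,
                             tracts_per_county = 9, seed = 1,
                             spatial_range_km = 10,
                             population_lognormal_mu = 8.4,
                             population_lognormal_sigma = 1,
                             segregation_level = 0.3,
                             centrality_level = 0.5,
                             effect_sizes = c(pop_density = 0.3,
                                              MAT = 0.3, NDVI = -0.3),
                             noise_sd = 0.1,
                             pollutant_levels = c(PM1 = 21, PM2.5 = 33,
                                                  PM10 = 54),
                             within_sd_min = 0.05, within_sd_max = 0.35,
                             poi_per_1000 = 0.4) {
  k <- county_size_km / cell_size_km
  if (abs(k - round(k)) > 1e-9) {
    abort_airineq("county_size_km must be an integer multiple of cell_size_km.",
                  "airineq_error_bad_config")
  }
  if (segregation_level < 0 || segregation_level > 1 ||
      centrality_level < 0 || centrality_level > 1) {
    abort_airineq("segregation_level and centrality_level must lie in [0, 1].",
                  "airineq_error_bad_config")
  }
  valid <- c("pop_density", "GDP", "CPI", "MAT", "MAP", "NDVI", "SAP", "VC")
  if (length(effect_sizes) > 0) {
    bad <- setdiff(names(effect_sizes), valid)
    if (length(bad) > 0) {
      abort_airineq(paste0("unknown indicator in effect_sizes: ",
                           paste(bad, collapse = ", ")),
                    "airineq_error_bad_effect")
    }
  }
  fields <- names(formals(synthetic_config))
  structure(mget(fields, environment()), class = "synthetic_config")
}

# Derived sub-seed per stream: adding a stream never perturbs the others.
stream_seed <- function(config, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (config$seed * 10007L + h * 97L) %% 2147483587L
}

# Standard-normal random field over the county-center lattice (row-major
# county order), spatially autocorrelated with an exponential range of a few
# county widths: regional structure (urbanized coast vs rural inland,
# latitudinal climate gradients) varies smoothly across counties.
county_level_field <- function(config, range_factor = 2.5) {
  simulate_grf(config$n_counties_y, config$n_counties_x,
               config$county_size_km,
               range_factor * config$county_size_km)
}

# Two independent county-level latent factors, fixed by the master seed:
# F1 = development density (drives population level, centrality,
# temperature), F2 = economic activity & segregation (drives GDP, CPI, road
# supply, income segregation, and within-county concentration dispersion).
# Both are spatially smooth across counties, as urbanization and economic
# geography are in a real province.
county_factors <- function(config) {
  withr::with_seed(stream_seed(config, "factors"), {
    F1 <- as.vector(t(county_level_field(config)))
    F2 <- as.vector(t(county_level_field(config)))
    matrix(c(F1, F2), ncol = 2, dimnames = list(NULL, c("F1", "F2")))
  })
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

config_dims <- function(config) {
  k <- as.integer(round(config$county_size_km / config$cell_size_km))
  list(k = k,
       nr = config$n_counties_y * k,
       nc = config$n_counties_x * k)
}

#' County and tract polygons for a synthetic config
#'
#' Counties are squares on a lattice (ids `C001`, `C002`, ... row-major from
#' the north-west); tracts subdivide each county into a near-square grid
#' (`C001_T01`, ...). The grid origin is `(0, H)` so that raster and polygons
#' share one frame.
#'
#' @param config A [synthetic_config()].
#' @return A [region_set()].
#' @export
make_regions <- function(config) {
  s <- config$county_size_km
  H <- config$n_counties_y * s
  rect <- function(x0, y0, w, h) {
    cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
  }
  tr <- floor(sqrt(config$tracts_per_county))
  while (config$tracts_per_county %% tr != 0) tr <- tr - 1
  tc <- config$tracts_per_county / tr

  counties <- list(); tracts <- list()
  id <- 0
  for (iy in seq_len(config$n_counties_y)) {
    for (ix in seq_len(config$n_counties_x)) {
      id <- id + 1
      cid <- sprintf("C%03d", id)
      x0 <- (ix - 1) * s
      y0 <- H - iy * s
      counties[[id]] <- tibble::tibble(county_id = cid,
                                       geometry = list(rect(x0, y0, s, s)))
      tid <- 0
      tw <- s / tc; th <- s / tr
      for (ty in seq_len(tr)) {
        for (tx in seq_len(tc)) {
          tid <- tid + 1
          tracts[[length(tracts) + 1]] <- tibble::tibble(
            county_id = cid,
            tract_id = sprintf("%s_T%02d", cid, tid),
            geometry = list(rect(x0 + (tx - 1) * tw,
                                 y0 + s - ty * th, tw, th))
          )
        }
      }
    }
  }
  region_set(dplyr::bind_rows(counties), dplyr::bind_rows(tracts))
}

# Stationary unit-variance Gaussian random field with exponential covariance
# exp(-h / range). Exact Cholesky for small grids, circulant embedding (FFT)
# otherwise; negative embedding eigenvalues are clamped at zero.
simulate_grf <- function(nr, nc, cell_size_km, range_km) {
  if (range_km <= cell_size_km * 1e-6) {
    return(matrix(stats::rnorm(nr * nc), nr, nc))
  }
  if (nr * nc <= 1024) {
    xs <- (rep(seq_len(nc), each = nr) - 1) * cell_size_km
    ys <- (rep(seq_len(nr), times = nc) - 1) * cell_size_km
    d <- sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2)
    S <- exp(-d / range_km)
    L <- chol(S + diag(1e-10, nrow(S)))
    return(matrix(as.vector(crossprod(L, stats::rnorm(nr * nc))), nr, nc))
  }
  m1 <- stats::nextn(2 * nr, 2)
  m2 <- stats::nextn(2 * nc, 2)
  wrap <- function(i, m) pmin(i, m - i)
  d1 <- wrap(0:(m1 - 1), m1) * cell_size_km
  d2 <- wrap(0:(m2 - 1), m2) * cell_size_km
  covmat <- exp(-sqrt(outer(d1^2, d2^2, "+")) / range_km)
  lam <- Re(stats::fft(covmat))
  lam[lam < 0] <- 0
  eps <- matrix(complex(real = stats::rnorm(m1 * m2),
                        imaginary = stats::rnorm(m1 * m2)), m1, m2)
  f <- stats::fft(sqrt(lam / (m1 * m2)) * eps)
  Re(f)[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' Simulate a pollutant concentration surface
#'
#' All three pollutants share one spatially autocorrelated standard field
#' `Z` (seeded independently of the other streams) and one per-county
#' within-county log-scale SD `s_c ~ U(within_sd_min, within_sd_max)`; the
#' pollutant surface is `level_p * exp(s_c * Z - s_c^2 / 2)`, so cell-wise
#' ordering PM1 < PM2.5 < PM10 is preserved exactly and county mean level and
#' within-county dispersion are controlled independently.
#'
#' @param config A [synthetic_config()].
#' @param pollutant One of `"PM1"`, `"PM2.5"`, `"PM10"`.
#' @return A [grid_field()].
#' @export
simulate_concentration <- function(config, pollutant = c("PM1", "PM2.5", "PM10")) {
  if (!pollutant[1] %in% c("PM1", "PM2.5", "PM10")) {
    abort_airineq(paste0("invalid pollutant label: ", pollutant[1]),
                  "airineq_error_bad_pollutant")
  }
  pollutant <- pollutant[1]
  dims <- config_dims(config)
  Z <- withr::with_seed(stream_seed(config, "grf"),
                        simulate_grf(dims$nr, dims$nc, config$cell_size_km,
                                     config$spatial_range_km))
  ncty <- config$n_counties_x * config$n_counties_y
  F2 <- county_factors(config)[, "F2"]
  s_c <- withr::with_seed(stream_seed(config, "within_sd"), {
    z <- 0.7 * F2 + sqrt(1 - 0.7^2) * stats::rnorm(ncty)
    mid <- (config$within_sd_min + config$within_sd_max) / 2
    half <- (config$within_sd_max - config$within_sd_min) / 2
    pmin(pmax(mid + half * z, config$within_sd_min), config$within_sd_max)
  })
  smat <- county_expand(s_c, config)
  level <- config$pollutant_levels[[pollutant]]
  vals <- level * exp(smat * Z - smat^2 / 2)
  grid_field(vals, cell_size_km = config$cell_size_km,
             origin = c(0, dims$nr * config$cell_size_km), label = pollutant)
}

# Bilinear interpolation of a per-county vector to the cell grid: cell
# values interpolate between the four nearest county centers, so county
# level effects vary smoothly (real concentration surfaces carry no
# administrative-boundary discontinuities, and a sharp per-county step
# would bleed into neighbouring counties' within-county roughness through
# the decay kernel).
county_expand_smooth <- function(v, config) {
  dims <- config_dims(config)
  Eta <- matrix(v, config$n_counties_y, config$n_counties_x, byrow = TRUE)
  interp_mat <- function(n_cells, n_cty, k) {
    pos <- (seq_len(n_cells) - 0.5) / k + 0.5  # county-center index space
    i0 <- pmin(pmax(floor(pos), 1), n_cty - 1)
    if (n_cty == 1) {
      return(matrix(1, n_cells, 1))
    }
    w <- pmin(pmax(pos - i0, 0), 1)
    M <- matrix(0, n_cells, n_cty)
    M[cbind(seq_len(n_cells), i0)] <- 1 - w
    M[cbind(seq_len(n_cells), i0 + 1)] <- M[cbind(seq_len(n_cells), i0 + 1)] + w
    M
  }
  R <- interp_mat(dims$nr, config$n_counties_y, dims$k)
  C <- interp_mat(dims$nc, config$n_counties_x, dims$k)
  R %*% Eta %*% t(C)
}

# Expand a per-county vector (row-major county order, as make_regions ids)
# to the full cell grid.
county_expand <- function(v, config) {
  dims <- config_dims(config)
  k <- dims$k
  cty_row <- (seq_len(dims$nr) - 1) %/% k       # 0-based county row per cell row
  cty_col <- (seq_len(dims$nc) - 1) %/% k
  idx <- outer(cty_row, cty_col, function(r, c) r * config$n_counties_x + c + 1)
  matrix(v[idx], dims$nr, dims$nc)
}

#' Simulate the population surface
#'
#' Per-cell log-normal marks multiplied by a within-county density kernel: a
#' uniform component plus a Gaussian bump at the county center whose weight
#' is `centrality_level`, so higher centrality concentrates population.
#'
#' @param config A [synthetic_config()].
#' @return A [grid_field()] labelled `"population"`.
#' @export
simulate_population <- function(config) {
  dims <- config_dims(config)
  F1 <- county_factors(config)[, "F1"]
  withr::with_seed(stream_seed(config, "population"), {
    marks <- matrix(stats::rlnorm(dims$nr * dims$nc,
                                  config$population_lognormal_mu,
                                  config$population_lognormal_sigma),
                    dims$nr, dims$nc)
    k <- dims$k
    # distance of each within-county cell to the county center, in cells
    off <- (seq_len(k) - 0.5) - k / 2
    d2 <- outer(off^2, off^2, "+")
    bump <- exp(-d2 / (2 * (k / 4)^2))
    bump <- bump / mean(bump)
    cmat <- county_centrality(config, F1)
    rowk <- ((seq_len(dims$nr) - 1) %% k) + 1
    colk <- ((seq_len(dims$nc) - 1) %% k) + 1
    cgrid <- county_expand(cmat, config)
    kern <- (1 - cgrid) + cgrid * bump[rowk, colk]
    vals <- marks * kern * county_expand(exp(0.5 * F1), config)
    grid_field(vals, cell_size_km = config$cell_size_km,
               origin = c(0, dims$nr * config$cell_size_km),
               label = "population")
  })
}

# Per-county centrality: scales the configured level by the development
# factor, so centrality_level = 0 stays exactly 0 everywhere.
county_centrality <- function(config, F1) {
  clamp01(config$centrality_level * (1 + 0.25 * F1))
}

#' Fill tract populations and low-income counts
#'
#' Tract populations aggregate the population surface; each county's
#' low-income share (about one half, since "low income" means below the
#' regional median) is spread over tracts as a mixture: proportional
#' allocation with weight `1 - segregation_level` and an extreme packing of
#' the low-income population into the fewest tracts with weight
#' `segregation_level`. Counts are real-valued so that `segregation_level = 0`
#' yields an exactly proportional allocation (downstream DI of 0).
#'
#' @param config A [synthetic_config()].
#' @param regions A [region_set()] from [make_regions()].
#' @param pop Optional population [grid_field()]; simulated if missing.
#' @return `regions` with `population` and `low_income_count` filled.
#' @export
simulate_tracts_income <- function(config, regions, pop = NULL) {
  if (is.null(pop)) pop <- simulate_population(config)
  tr <- regions$tracts
  tr$population <- aggregate_to_polygons(pop, tr$geometry)
  withr::with_seed(stream_seed(config, "income"), {
    ncty <- nrow(regions$counties)
    q_c <- stats::rbeta(ncty, 8, 8)   # county low-income share, centered on 1/2
    names(q_c) <- regions$counties$county_id
    F2 <- county_factors(config)[, "F2"]
    s_c <- clamp01(config$segregation_level * (1 + 0.5 * F2))
    names(s_c) <- regions$counties$county_id
    tr <- tr |>
      dplyr::group_by(.data$county_id) |>
      dplyr::group_modify(function(df, key) {
        q <- q_c[[key$county_id[1]]]
        s <- s_c[[key$county_id[1]]]
        Q <- df$population
        L <- q * sum(Q)
        # extreme packing: fill largest tracts first
        ord <- order(Q, decreasing = TRUE)
        packed <- numeric(nrow(df))
        left <- L
        for (i in ord) {
          take <- min(Q[i], left)
          packed[i] <- take
          left <- left - take
          if (left <= 0) break
        }
        df$low_income_count <- pmin((1 - s) * q * Q + s * packed, Q)
        df
      }) |>
      dplyr::ungroup()
  })
  region_set(regions$counties, tr[, names(regions$tracts)])
}

# Sum of grid values over each polygon (cell-center rule).
aggregate_to_polygons <- function(grid, geoms) {
  cells <- grid_cells(grid)
  out <- numeric(length(geoms))
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    bb <- apply(g, 2, range)
    cand <- cells$x >= bb[1, 1] & cells$x <= bb[2, 1] &
      cells$y >= bb[1, 2] & cells$y <= bb[2, 2]
    if (!any(cand)) next
    inside <- points_in_polygon(cells$x[cand], cells$y[cand], g)
    out[i] <- sum(cells$value[cand][inside], na.rm = TRUE)
  }
  out
}

#' Simulate POIs and road-segment counts
#'
#' POI counts per county are Poisson with mean proportional to county
#' population; locations are a mixture of a uniform component and a Gaussian
#' cluster at the county center with weight `centrality_level`. Road segment
#' counts are proportional to population with log-normal noise.
#'
#' @param config A [synthetic_config()].
#' @param regions A [region_set()].
#' @param pop Optional population [grid_field()]; simulated if missing.
#' @return A list with `poi` (tibble: `x`, `y`, `category`, `county_id`) and
#'   `roads` (tibble: `county_id`, `road_segments`).
#' @export
simulate_poi_roads <- function(config, regions, pop = NULL) {
  if (is.null(pop)) pop <- simulate_population(config)
  cty <- regions$counties
  cty_pop <- aggregate_to_polygons(pop, cty$geometry)
  cats <- c("restaurant", "school", "grocery", "gas_station", "pharmacy",
            "bank", "hospital", "park", "shopping_center", "church")
  fac <- county_factors(config)
  cent <- county_centrality(config, fac[, "F1"])
  withr::with_seed(stream_seed(config, "poi"), {
    # per-capita POI supply varies across counties, so POI density is a
    # noisy, not duplicate, copy of population density
    supply <- stats::rlnorm(nrow(cty), 0, 0.35)
    lambda <- config$poi_per_1000 * cty_pop * supply / 1000
    n_poi <- stats::rpois(length(lambda), lambda)
    poi <- purrr::map_dfr(seq_len(nrow(cty)), function(i) {
      n <- n_poi[i]
      if (n == 0) return(NULL)
      g <- cty$geometry[[i]]
      bb <- apply(g, 2, range)
      ctr <- polygon_centroid(g)
      s <- config$county_size_km
      clustered <- stats::runif(n) < cent[i]
      x <- ifelse(clustered,
                  pmin(pmax(stats::rnorm(n, ctr[1], s / 10), bb[1, 1]), bb[2, 1]),
                  stats::runif(n, bb[1, 1], bb[2, 1]))
      y <- ifelse(clustered,
                  pmin(pmax(stats::rnorm(n, ctr[2], s / 10), bb[1, 2]), bb[2, 2]),
                  stats::runif(n, bb[1, 2], bb[2, 2]))
      tibble::tibble(x = x, y = y,
                     category = sample(cats, n, replace = TRUE),
                     county_id = cty$county_id[i])
    })
    roads <- tibble::tibble(
      county_id = cty$county_id,
      road_segments = round(0.02 * cty_pop * exp(0.3 * fac[, "F2"]) *
                              stats::rlnorm(nrow(cty), 0, 0.2))
    )
    list(poi = poi, roads = roads)
  })
}

#' Simulate per-county covariates
#'
#' Draws the environmental and economic covariates with field-typical means
#' and spreads: CPI as the fuzzy sum of Beta-distributed human-modification
#' and development-suitability layers, MAT (deg C), MAP (mm), NDVI, SAP (hPa),
#' VC (m2/s) as Gaussian draws, and GDP (CNY) proportional to population with
#' log-normal per-capita noise.
#'
#' @param config A [synthetic_config()].
#' @param regions A [region_set()].
#' @param pop Optional population [grid_field()]; simulated if missing.
#' @return Tibble with one row per county: `county_id`, `GDP`, `CPI`, `MAT`,
#'   `MAP`, `NDVI`, `SAP`, `VC`.
#' @export
simulate_covariates <- function(config, regions, pop = NULL) {
  if (is.null(pop)) pop <- simulate_population(config)
  cty_pop <- aggregate_to_polygons(pop, regions$counties$geometry)
  n <- nrow(regions$counties)
  fac <- county_factors(config)
  withr::with_seed(stream_seed(config, "covariates"), {
    # environmental surfaces are spatially smooth (latitudinal temperature,
    # south-north pressure, regional precipitation and vegetation belts)
    smooth <- function() as.vector(t(county_level_field(config)))
    hm <- stats::plogis(-0.5 + 0.8 * fac[, "F2"] + 0.6 * stats::rnorm(n))
    dsi <- stats::plogis(-0.5 + 0.8 * fac[, "F2"] + 0.6 * stats::rnorm(n))
    tibble::tibble(
      county_id = regions$counties$county_id,
      GDP = cty_pop * exp(0.4 * fac[, "F2"]) *
        stats::rlnorm(n, log(7e4), 0.4),
      CPI = fuzzy_sum_cpi(hm, dsi),
      MAT = 19 + 2 * (0.7 * fac[, "F1"] + sqrt(1 - 0.49) * smooth()),
      MAP = 1400 + 250 * smooth(),
      NDVI = pmin(pmax(0.65 + 0.05 * smooth(), 0), 1),
      SAP = 1000 + 8 * smooth(),
      VC = pmax(3.3 + 0.3 * smooth(), 0.5)
    )
  })
}

#' Tilt concentration fields by planted covariate effects
#'
#' Computes a per-county log-level effect `eta_c = sum_k beta_k * z_k +
#' eps_c` (`z_k` the z-scored covariate, log scale for `pop_density` and
#' `GDP`; `eps_c ~ N(0, noise_sd)`) and multiplies the field by
#' `exp(eta)` interpolated smoothly between county centers, so that log
#' county-mean concentration tracks the planted linear effects without
#' introducing artificial concentration jumps at county borders.
#'
#' @param conc A concentration [grid_field()].
#' @param covars Covariate tibble from [simulate_covariates()].
#' @param config A [synthetic_config()].
#' @param regions A [region_set()].
#' @param pop Population [grid_field()] (needed when `pop_density` has a
#'   planted effect).
#' @return The tilted [grid_field()].
#' @export
tilt_concentration <- function(conc, covars, config, regions, pop = NULL) {
  es <- config$effect_sizes
  dims <- config_dims(config)
  ncty <- nrow(regions$counties)
  eta <- numeric(ncty)
  if (length(es) > 0) {
    if ("pop_density" %in% names(es)) {
      if (is.null(pop)) pop <- simulate_population(config)
      pd <- aggregate_to_polygons(pop, regions$counties$geometry) /
        regions$counties$area_km2
      eta <- eta + es[["pop_density"]] * as.numeric(scale(log(pd)))
    }
    for (nm in setdiff(names(es), "pop_density")) {
      v <- covars[[nm]]
      if (nm == "GDP") v <- log(v)
      eta <- eta + es[[nm]] * as.numeric(scale(v))
    }
  }
  eps <- withr::with_seed(stream_seed(config, "tilt_noise"),
                          stats::rnorm(ncty, 0, config$noise_sd))
  fac <- exp(county_expand_smooth(eta + eps, config))
  grid_field(conc$values * fac, cell_size_km = conc$cell_size_km,
             origin = conc$origin, nodata = conc$nodata, label = conc$label)
}

#' Generate a complete synthetic province
#'
#' Orchestrates all `simulate_*` streams: regions, population, covariates,
#' the three pollutant surfaces (tilted by the planted covariate effects),
#' tract income allocations, POIs and road counts. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_province` with elements `config`,
#'   `regions`, `population`, `covariates`, `conc` (named list of three
#'   [grid_field()]s), `poi`, `roads`.
#' @export
simulate_province <- function(config = synthetic_config()) {
  regions <- make_regions(config)
  pop <- simulate_population(config)
  covars <- simulate_covariates(config, regions, pop)
  conc <- lapply(stats::setNames(nm = c("PM1", "PM2.5", "PM10")), function(p) {
    tilt_concentration(simulate_concentration(config, p),
                       covars, config, regions, pop)
  })
  regions <- simulate_tracts_income(config, regions, pop)
  pr <- simulate_poi_roads(config, regions, pop)
  structure(list(config = config, regions = regions, population = pop,
                 covariates = covars, conc = conc,
                 poi = pr$poi, roads = pr$roads),
            class = "synthetic_province")
}

#' @export
print.synthetic_province <- function(x, ...) {
  cat(sprintf("<synthetic_province: %d counties, %d tracts, %d POIs, seed %d>\n",
              nrow(x$regions$counties), nrow(x$regions$tracts),
              nrow(x$poi), x$config$seed))
  invisible(x)
}

#' Write a synthetic province to disk
#'
#' Rasters as ESRI ASCII grids, polygons as GeoJSON, tables as CSV.
#'
#' @param province A [simulate_province()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_province <- function(province, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(province$conc)) {
    write_grid(province$conc[[p]],
               file.path(dir, paste0("conc_", gsub("\\.", "", p), ".asc")))
  }
  write_grid(province$population, file.path(dir, "population.asc"))
  write_regions(province$regions,
                file.path(dir, "counties.geojson"),
                file.path(dir, "tracts.geojson"))
  utils::write.csv(province$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(province$poi, file.path(dir, "poi.csv"), row.names = FALSE)
  utils::write.csv(province$roads, file.path(dir, "roads.csv"),
                   row.names = FALSE)
  invisible(dir)
}
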
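test_that("every simulation stream is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 5)
  a <- simulate_province(cfg)
  b <- simulate_province(cfg)
  expect_identical(a$conc$`PM2.5`$values, b$conc$`PM2.5`$values)
  expect_identical(a$population$values, b$population$values)
  expect_identical(a$poi, b$poi)
  expect_identical(a$roads, b$roads)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$regions$tracts$low_income_count,
                   b$regions$tracts$low_income_count)
})

test_that("pollutant fields preserve the PM1 < PM2.5 < PM10 ordering cell-wise", {
  cfg <- tiny_config(seed = 3)
  pr <- simulate_province(cfg)
  expect_true(all(pr$conc$PM1$values < pr$conc$`PM2.5`$values))
  expect_true(all(pr$conc$`PM2.5`$values < pr$conc$PM10$values))
})

test_that("zero autocorrelation range gives white noise", {
  cfg <- synthetic_config(n_counties_x = 10, n_counties_y = 10,
                          county_size_km = 10, spatial_range_km = 0,
                          seed = 9, within_sd_min = 0.3, within_sd_max = 0.3,
                          effect_sizes = c())
  gf <- simulate_concentration(cfg, "PM2.5")
  v <- log(gf$values)
  r_lag1 <- stats::cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  expect_lt(abs(r_lag1), 0.1)
})

test_that("the field's correlogram matches the exponential covariance model", {
  # range 10 km on a 100 x 100 grid: correlation at lag 10 should be near
  # exp(-1); within-county scaling cancels in per-county standardization,
  # so use a single 100 km county to read the raw field
  cfg <- synthetic_config(n_counties_x = 1, n_counties_y = 1,
                          county_size_km = 100, spatial_range_km = 10,
                          seed = 21, within_sd_min = 0.2,
                          within_sd_max = 0.2, effect_sizes = c())
  gf <- simulate_concentration(cfg, "PM1")
  z <- log(gf$values)
  lag <- 10
  r <- stats::cor(as.vector(z[, seq_len(100 - lag)]),
                  as.vector(z[, seq_len(100 - lag) + lag]))
  expect_lt(abs(r - exp(-1)), 0.15)
})

test_that("population surface centrality raises within-county dispersion", {
  # compare the density kernels directly on the default county size: same
  # seed, only the centrality dial moves
  cv <- function(level) {
    cfg <- synthetic_config(seed = 8, centrality_level = level,
                            n_counties_x = 4, n_counties_y = 4)
    pop <- simulate_population(cfg)
    regions <- make_regions(cfg)
    cc <- assign_cells(pop, regions)
    v <- as.vector(pop$values)
    mean(tapply(v, cc, function(x) stats::sd(x) / mean(x)))
  }
  expect_lt(cv(0), cv(1))
})

test_that("degenerate population marks collapse to exp(mu)", {
  # sigma = 0 makes every mark exp(mu); with a flat kernel the surface is
  # then constant within each county (the county-level development factor
  # remains as a county-wise multiplier of exp(mu))
  cfg <- tiny_config(seed = 2, population_lognormal_sigma = 0,
                     centrality_level = 0)
  pop <- simulate_population(cfg)
  regions <- make_regions(cfg)
  cc <- assign_cells(pop, regions)
  v <- as.vector(pop$values)
  within_sd <- tapply(v, cc, stats::sd)
  expect_true(all(within_sd < 1e-8))
  county_mult <- tapply(v, cc, mean) / exp(cfg$population_lognormal_mu)
  expect_gt(min(county_mult), 0)
  expect_equal(stats::median(log(county_mult)), 0, tolerance = 1)
})

test_that("total synthetic population is positive and seed-stable", {
  cfg <- tiny_config(seed = 13)
  t1 <- sum(simulate_population(cfg)$values)
  t2 <- sum(simulate_population(cfg)$values)
  expect_gt(t1, 0)
  expect_identical(t1, t2)
})

test_that("segregation level drives the dissimilarity index monotonically", {
  mean_di <- function(s, seed) {
    cfg <- tiny_config(seed = seed, segregation_level = s)
    regions <- simulate_tracts_income(cfg, make_regions(cfg))
    mean(segregation_table(regions)$DI, na.rm = TRUE)
  }
  d0 <- mean_di(0, 31)
  d5 <- mean_di(0.5, 31)
  d1 <- mean_di(1, 31)
  expect_equal(d0, 0, tolerance = 1e-12)
  expect_gt(d5, d0)
  expect_lt(d5, d1)
})

test_that("full segregation packs the low-income population into fewest tracts", {
  cfg <- tiny_config(seed = 17, segregation_level = 1)
  regions <- simulate_tracts_income(cfg, make_regions(cfg))
  # the factor-scaled county segregation level is clamped at 1, so at least
  # one county is fully packed; its DI must equal the packed-limit value
  # 1 - L/Q implied by the index formula with Q = total population
  tr <- dplyr::group_by(regions$tracts, county_id)
  packed <- dplyr::summarise(
    tr,
    n_mixed = sum(low_income_count > 1e-9 &
                    low_income_count < population - 1e-9),
    di = dissimilarity_index(low_income_count, population),
    di_limit = 1 - sum(low_income_count) / sum(population)
  )
  fully_packed <- packed[packed$n_mixed <= 1, ]
  expect_gt(nrow(fully_packed), 0)
  strict <- fully_packed[fully_packed$n_mixed == 0, ]
  if (nrow(strict) > 0) {
    expect_equal(strict$di, strict$di_limit, tolerance = 1e-9)
  }
})

test_that("POI placement is uniform at zero centrality and seed-stable", {
  cfg <- tiny_config(seed = 23, centrality_level = 0, poi_per_1000 = 3)
  regions <- make_regions(cfg)
  a <- simulate_poi_roads(cfg, regions)
  b <- simulate_poi_roads(cfg, regions)
  expect_identical(a$poi, b$poi)
  # uniform placement within counties: tract counts proportional to area
  # (all tracts equal area here), chi-square-style check per county
  poi <- a$poi
  tr <- regions$tracts
  for (cid in unique(poi$county_id)) {
    pts <- poi[poi$county_id == cid, ]
    if (nrow(pts) < 40) next
    g <- tr$geometry[tr$county_id == cid]
    k <- vapply(g, function(gg) {
      sum(sp::point.in.polygon(pts$x, pts$y, gg[, 1], gg[, 2]) > 0)
    }, numeric(1))
    expect_gt(suppressWarnings(stats::chisq.test(k)$p.value), 1e-4)
  }
})

test_that("null effect sizes leave county exposure uncorrelated with covariates", {
  # both the exposure surface and the environmental covariates are smooth
  # spatial fields, so a single realization can show sizable chance
  # correlation (the effective sample is far below the county count);
  # the null claim is about the average over realizations
  r_abs <- sapply(41:50, function(sd) {
    cfg <- synthetic_config(seed = sd, effect_sizes = c(), noise_sd = 0.1)
    regions <- make_regions(cfg)
    pop <- simulate_population(cfg)
    covars <- simulate_covariates(cfg, regions, pop)
    conc <- tilt_concentration(simulate_concentration(cfg, "PM2.5"),
                               covars, cfg, regions, pop)
    cc <- assign_cells(conc, regions)
    m <- tapply(as.vector(conc$values), cc, mean)
    vapply(c("MAT", "MAP", "NDVI", "SAP", "VC"),
           function(nm) abs(stats::cor(log(m), covars[[nm]])), numeric(1))
  })
  expect_true(all(rowMeans(r_abs) < 0.2))
})

test_that("unknown indicator names in effect_sizes are rejected", {
  expect_error(synthetic_config(effect_sizes = c(banana = 1)),
               class = "airineq_error_bad_effect")
})

test_that("county size must be a multiple of the cell size", {
  expect_error(synthetic_config(county_size_km = 5, cell_size_km = 2),
               class = "airineq_error_bad_config")
})
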
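make_blocks <- function(seed = 50) {
  cfg <- tiny_config(seed = seed)
  pr <- simulate_province(cfg)
  list(exposure = exposure_table(pr),
       sgi = sgi_table(pr),
       seg = segregation_table(pr$regions),
       urban = urban_form_table(pr),
       covars = pr$covariates)
}

test_that("indicator assembly preserves complete county sets", {
  b <- make_blocks()
  tbl <- assemble_indicators(b$exposure, b$sgi, b$seg, b$urban, b$covars)
  expect_equal(nrow(tbl), 9)
  expect_true(all(stats::complete.cases(tbl)))
  expect_named(tbl, c("county_id", "APE_combined", "SGI_combined",
                      "road_density", "poi_density", "UCI", "pop_density",
                      "GDP", "income_segregation", "CPI", "MAT", "MAP",
                      "NDVI", "SAP", "VC"))
})

test_that("counties lost to undefined metrics are dropped and named", {
  b <- make_blocks()
  b$sgi$SGI_combined[4] <- NA
  expect_message(
    tbl <- assemble_indicators(b$exposure, b$sgi, b$seg, b$urban, b$covars),
    "C004"
  )
  expect_equal(nrow(tbl), 8)
  expect_false("C004" %in% tbl$county_id)
  empty <- b$exposure[0, ]
  expect_error(assemble_indicators(empty, b$sgi, b$seg, b$urban, b$covars),
               class = "airineq_error_empty_join")
})

test_that("log transform hits exactly the named large-scale columns", {
  b <- make_blocks()
  tbl <- assemble_indicators(b$exposure, b$sgi, b$seg, b$urban, b$covars)
  tbl$GDP <- rep(exp(1), nrow(tbl))
  out <- log_transform(tbl)
  expect_equal(out$GDP, rep(1, nrow(tbl)))
  expect_equal(out$MAT, tbl$MAT)            # untouched
  expect_equal(out$CPI, tbl$CPI)            # untouched
  expect_equal(out$poi_density, log(tbl$poi_density))
  # zeros get the documented half-minimum offset, with a warning
  tbl$poi_density[2] <- 0
  expect_warning(out2 <- log_transform(tbl),
                 class = "airineq_warn_log_offset")
  eps <- min(tbl$poi_density[tbl$poi_density > 0]) / 2
  expect_equal(out2$poi_density, log(tbl$poi_density + eps))
})

test_that("bivariate OLS recovers exact fits and matches the closed form", {
  df <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  fit <- bivariate_ols(df, "x", "y")
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  withr::with_seed(64, {
    x <- rnorm(100)
    y <- x + rnorm(100)
  })
  fit2 <- bivariate_ols(tibble::tibble(x = x, y = y), "x", "y")
  # textbook normal equations evaluated by hand
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  resid <- y - b0 - b1 * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(resid^2) / 98 / sum((x - mean(x))^2))
  expect_equal(fit2$slope, b1, tolerance = 1e-12)
  expect_equal(fit2$intercept, b0, tolerance = 1e-12)
  expect_equal(fit2$r_squared, r2, tolerance = 1e-12)
  expect_equal(unname(fit2$ci["upper"] - fit2$ci["lower"]),
               2 * stats::qt(0.95, 98) * se, tolerance = 1e-10)
  expect_true(fit2$ci["lower"] <= fit2$slope && fit2$slope <= fit2$ci["upper"])
})

test_that("OLS slope and R2 are invariant to shifting the predictor", {
  withr::with_seed(9, df <- tibble::tibble(x = rnorm(40), y = rnorm(40)))
  f1 <- bivariate_ols(df, "x", "y")
  df$x <- df$x + 100
  f2 <- bivariate_ols(df, "x", "y")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-9)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-9)
  df$x <- df$x * 0
  expect_error(bivariate_ols(df, "x", "y"),
               class = "airineq_error_constant_x")
})

test_that("null predictors are calibrated: R2 small, p roughly uniform", {
  withr::with_seed(202, {
    big <- tibble::tibble(x = rnorm(1000), y = rnorm(1000))
    expect_lt(bivariate_ols(big, "x", "y")$r_squared, 0.01)
    pvals <- vapply(1:200, function(i) {
      d <- tibble::tibble(x = rnorm(30), y = rnorm(30))
      bivariate_ols(d, "x", "y")$p_value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
  expect_lt(abs(mean(pvals < 0.1) - 0.1), 0.07)
})

fake_table <- function(x, county_id = sprintf("C%03d", seq_len(nrow(x)))) {
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- airineq:::indicator_columns()
  out$county_id <- county_id
  out$APE_combined <- 0
  out$SGI_combined <- 0
  out
}

test_that("PCA recovers a planted common factor and conserves variance", {
  withr::with_seed(88, {
    f <- rnorm(300)
    x <- sapply(1:12, function(j) f + 0.3 * rnorm(300))
  })
  pc <- run_pca(fake_table(x))
  expect_gt(pc$explained_variance_ratio[1], 0.8)
  expect_equal(sum(pc$explained_variance_ratio), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$explained_variance_ratio) < 1e-12))
  # scores centered, components orthonormal
  expect_true(all(abs(colMeans(pc$scores)) < 1e-10))
  expect_equal(crossprod(pc$loadings), diag(12), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: dominant loading of each component is positive
  expect_true(all(apply(pc$loadings, 2, function(l) l[which.max(abs(l))]) > 0))
})

test_that("isotropic noise spreads variance evenly across components", {
  withr::with_seed(123, x <- matrix(rnorm(2000 * 12), 2000, 12))
  pc <- run_pca(fake_table(x))
  expect_true(all(abs(pc$explained_variance_ratio - 1 / 12) < 0.05))
})

test_that("PCA ratios are invariant to county order", {
  withr::with_seed(31, x <- matrix(rnorm(60 * 12), 60, 12))
  tbl <- fake_table(x)
  p1 <- run_pca(tbl)
  perm <- withr::with_seed(32, sample(60))
  p2 <- run_pca(tbl[perm, ])
  expect_equal(p1$explained_variance_ratio, p2$explained_variance_ratio,
               tolerance = 1e-10)
})

test_that("component regressions see planted alignment with PC scores", {
  withr::with_seed(77, {
    f <- rnorm(200)
    x <- sapply(1:12, function(j) f + 0.5 * rnorm(200))
  })
  tbl <- fake_table(x)
  pc <- run_pca(tbl)
  tbl$APE_combined <- 3 * pc$scores[, "PC1"]
  tbl$SGI_combined <- stats::rnorm(200)
  fits <- component_regressions(pc, tbl)
  r2 <- function(xx, yy) fits$r.squared[fits$x == xx & fits$y == yy]
  expect_gt(r2("PC1", "APE_combined"), 0.99)
  expect_lt(r2("PC2", "APE_combined"), 0.1)
  # consistent row permutation leaves the fits unchanged
  perm <- withr::with_seed(5, sample(200))
  pc2 <- pc
  pc2$scores <- pc$scores[perm, ]
  pc2$county_id <- pc$county_id[perm]
  fits2 <- component_regressions(pc2, tbl[perm, ])
  expect_equal(fits$r.squared, fits2$r.squared, tolerance = 1e-10)
})

test_that("driver regressions produce one tidy row per indicator and target", {
  b <- make_blocks()
  tbl <- log_transform(
    assemble_indicators(b$exposure, b$sgi, b$seg, b$urban, b$covars)
  )
  fits <- driver_regressions(tbl)
  expect_equal(nrow(fits), 24)
  expect_true(all(fits$r.squared >= 0 & fits$r.squared <= 1))
  expect_true(all(fits$conf.low <= fits$slope & fits$slope <= fits$conf.high))
})
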
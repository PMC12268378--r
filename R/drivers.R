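#' Assemble the per-county indicator table
#'
#' Inner-joins the exposure, inequality, segregation, urban-form and
#' covariate blocks on `county_id` into the canonical 14-column analysis
#' table (combined APE and SGI plus the 12 urban / socio-economic /
#' environmental indicators). Counties with any undefined metric are dropped
#' and named in a message.
#'
#' @param exposure [exposure_table()] output.
#' @param sgi [sgi_table()] output.
#' @param seg [segregation_table()] output.
#' @param urban [urban_form_table()] output.
#' @param covars Covariate tibble (`county_id`, `GDP`, `CPI`, `MAT`, `MAP`,
#'   `NDVI`, `SAP`, `VC`).
#' @return Tibble with columns `county_id`, `APE_combined`, `SGI_combined`,
#'   `road_density`, `poi_density`, `UCI`, `pop_density`, `GDP`,
#'   `income_segregation`, `CPI`, `MAT`, `MAP`, `NDVI`, `SAP`, `VC`.
#' @export
assemble_indicators <- function(exposure, sgi, seg, urban, covars) {
  tbl <- exposure |>
    dplyr::select("county_id", "APE_combined") |>
    dplyr::inner_join(dplyr::select(sgi, "county_id", "SGI_combined"),
                      by = "county_id") |>
    dplyr::inner_join(dplyr::rename(seg, income_segregation = "DI"),
                      by = "county_id") |>
    dplyr::inner_join(urban, by = "county_id") |>
    dplyr::inner_join(covars, by = "county_id") |>
    dplyr::select("county_id", "APE_combined", "SGI_combined",
                  "road_density", "poi_density", "UCI", "pop_density",
                  "GDP", "income_segregation", "CPI", "MAT", "MAP",
                  "NDVI", "SAP", "VC")
  if (nrow(tbl) == 0) {
    abort_airineq("assemble_indicators: empty join.",
                  "airineq_error_empty_join")
  }
  keep <- stats::complete.cases(tbl)
  if (any(!keep)) {
    message("dropping counties with undefined metrics: ",
            paste(tbl$county_id[!keep], collapse = ", "))
  }
  tbl[keep, ]
}

#' Indicator columns treated as indicators in driver analyses
#' @keywords internal
indicator_columns <- function() {
  c("road_density", "poi_density", "UCI", "pop_density", "GDP",
    "income_segregation", "CPI", "MAT", "MAP", "NDVI", "SAP", "VC")
}

log_transform_columns <- function() {
  c("GDP", "poi_density", "pop_density", "MAP", "SAP", "VC")
}

#' Log-transform the large-scale indicator columns
#'
#' Applies the natural log to the columns whose values span orders of
#' magnitude: GDP, POI density, population density, MAP, SAP and VC. Columns
#' containing zeros are shifted by half their smallest positive value before
#' the log, with a warning.
#'
#' @param table An [assemble_indicators()] tibble.
#' @param columns Columns to transform.
#' @return The tibble with those columns replaced by their logs.
#' @export
log_transform <- function(table, columns = log_transform_columns()) {
  for (cn in intersect(columns, names(table))) {
    v <- table[[cn]]
    if (any(v < 0, na.rm = TRUE)) {
      abort_airineq(paste0("log_transform: negative values in ", cn),
                    "airineq_error_bad_values")
    }
    if (any(v == 0, na.rm = TRUE)) {
      eps <- min(v[v > 0], na.rm = TRUE) / 2
      rlang::warn(paste0("zeros in ", cn, "; using log(x + ",
                         format(eps), ")"),
                  class = "airineq_warn_log_offset")
      v <- v + eps
    }
    table[[cn]] <- log(v)
  }
  attr(table, "log_transformed") <- TRUE
  table
}

#' Bivariate OLS of an outcome on one indicator
#'
#' Least-squares fit of `y ~ x` with the slope's two-sided p-value and a
#' 90% confidence interval, as used to screen drivers of exposure and of
#' spatial inequality one indicator at a time.
#'
#' @param data Data frame holding both columns.
#' @param x,y Column names (character).
#' @param conf_level Confidence level for the slope interval (default 0.90).
#' @return An object of class `airineq_ols` (wrapping the `lm` fit) with
#'   elements `slope`, `intercept`, `r_squared`, `p_value`, `ci`.
#' @export
bivariate_ols <- function(data, x, y, conf_level = 0.90) {
  xv <- data[[x]]; yv <- data[[y]]
  if (length(xv) < 3) {
    abort_airineq("bivariate_ols needs n >= 3.", "airineq_error_too_few")
  }
  if (stats::sd(xv) == 0) {
    abort_airineq(paste0("bivariate_ols: constant predictor ", x),
                  "airineq_error_constant_x")
  }
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  ci <- stats::confint(fit, "xv", level = conf_level)
  structure(
    list(x = x, y = y, fit = fit, n = length(xv),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients["xv", "Pr(>|t|)"],
         ci = c(lower = ci[1], upper = ci[2]),
         conf_level = conf_level),
    class = "airineq_ols"
  )
}

#' @export
print.airineq_ols <- function(x, ...) {
  cat(sprintf("<OLS %s ~ %s: slope %.4g [%.4g, %.4g] (%d%% CI), R2 %.3f, p %.3g>\n",
              x$y, x$x, x$slope, x$ci[1], x$ci[2],
              round(100 * x$conf_level), x$r_squared, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy airineq_ols
#' @export
tidy.airineq_ols <- function(x, ...) {
  obj <- x
  tibble::tibble(y = obj$y, x = obj$x, term = c("intercept", "slope"),
                 estimate = c(obj$intercept, obj$slope),
                 conf.low = c(NA_real_, unname(obj$ci[1])),
                 conf.high = c(NA_real_, unname(obj$ci[2])))
}

#' @method glance airineq_ols
#' @export
glance.airineq_ols <- function(x, ...) {
  obj <- x
  tibble::tibble(y = obj$y, x = obj$x, slope = obj$slope,
                 r.squared = obj$r_squared, p.value = obj$p_value,
                 conf.low = unname(obj$ci[1]), conf.high = unname(obj$ci[2]),
                 nobs = obj$n)
}

#' All bivariate driver regressions
#'
#' Fits each of the 12 indicators against `APE_combined` and `SGI_combined`.
#'
#' @param table A log-transformed indicator tibble (see [log_transform()]).
#' @param targets Outcome columns.
#' @return A tidy tibble with one row per (target, indicator) fit.
#' @export
driver_regressions <- function(table,
                               targets = c("APE_combined", "SGI_combined")) {
  purrr::map_dfr(targets, function(tg) {
    purrr::map_dfr(indicator_columns(), function(ind) {
      glance(bivariate_ols(table, ind, tg))
    })
  })
}

#' Standardized PCA of the 12 indicators
#'
#' Z-scores the indicator columns (exposure and inequality excluded) and
#' eigen-decomposes their correlation matrix. Sign convention: within each
#' component the largest-magnitude loading is positive.
#'
#' @param table Indicator tibble (log-transform applied upstream).
#' @return An object of class `airineq_pca` with `loadings` (12 x p),
#'   `explained_variance_ratio`, `scores` (county x p) and `county_id`.
#' @export
run_pca <- function(table) {
  cols <- indicator_columns()
  x <- as.matrix(table[, cols])
  if (nrow(x) < 2) {
    abort_airineq("run_pca needs at least 2 counties.",
                  "airineq_error_too_few")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(
    list(loadings = rot,
         explained_variance_ratio = pc$sdev^2 / sum(pc$sdev^2),
         scores = scores,
         county_id = table$county_id),
    class = "airineq_pca"
  )
}

#' @export
print.airineq_pca <- function(x, ...) {
  r <- x$explained_variance_ratio
  cat(sprintf("<PCA of %d indicators: PC1 %.1f%%, PC2 %.1f%% of variance>\n",
              nrow(x$loadings), 100 * r[1], 100 * r[2]))
  invisible(x)
}

#' @method tidy airineq_pca
#' @export
tidy.airineq_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "indicator") |>
    tidyr::pivot_longer(-"indicator", names_to = "component",
                        values_to = "loading")
}

#' @method glance airineq_pca
#' @export
glance.airineq_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$loadings),
                 explained_variance_ratio = x$explained_variance_ratio)
}

#' Regress exposure and inequality on the leading components
#'
#' Bivariate OLS of `APE_combined` and `SGI_combined` on the PC1 and PC2
#' scores, the test of whether development-density and
#' segregation-type components drive exposure level and spatial inequality
#' respectively.
#'
#' @param pca A [run_pca()] object.
#' @param table The indicator tibble the PCA was fit on (same row order).
#' @param components Components to use.
#' @return A tidy tibble of the four fits (glance columns).
#' @export
component_regressions <- function(pca, table,
                                  components = c("PC1", "PC2")) {
  stopifnot(identical(pca$county_id, table$county_id))
  df <- dplyr::bind_cols(
    table[, c("APE_combined", "SGI_combined")],
    tibble::as_tibble(pca$scores[, components, drop = FALSE])
  )
  purrr::map_dfr(c("APE_combined", "SGI_combined"), function(tg) {
    purrr::map_dfr(components, function(pc) {
      glance(bivariate_ols(df, pc, tg))
    })
  })
}
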
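#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis with defaults matching the
#' study conventions: a 1-km decay buffer with a uniform kernel, rook
#' contiguity, concentration-valued SGI, natural-log transform of the
#' large-scale columns, EBIC graphical lasso with gamma 0.5 over a
#' 100-point penalty path, and 100 bootstrap replicates.
#'
#' @param seed Global seed; also seeds the synthetic province.
#' @param synthetic A [synthetic_config()] (its seed is overridden by
#'   `seed`), or `NULL` to read inputs from `input_dir`.
#' @param input_dir Directory holding `conc_PM1.asc`, `conc_PM25.asc`,
#'   `conc_PM10.asc`, `population.asc`, `counties.geojson`,
#'   `tracts.geojson`, `covariates.csv`, `poi.csv`, `roads.csv` (the layout
#'   [write_province()] emits). Ignored when `synthetic` is given.
#' @param buffer_km,kernel Decay adjustment settings.
#' @param adjacency `"rook"` or `"queen"`.
#' @param sgi_x `"concentration"` or `"pop_weighted"`.
#' @param gamma,n_lambda,lambda_min_ratio Network selection settings.
#' @param bootstrap_B Bootstrap replicates (0 disables the bootstrap stage).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, synthetic = synthetic_config(seed = seed),
                       input_dir = NULL, buffer_km = 1,
                       kernel = "uniform", adjacency = "rook",
                       sgi_x = "concentration", gamma = 0.5,
                       n_lambda = 100, lambda_min_ratio = 0.01,
                       bootstrap_B = 0) {
  if (!is.null(synthetic)) synthetic$seed <- seed
  structure(list(seed = seed, synthetic = synthetic, input_dir = input_dir,
                 buffer_km = buffer_km, kernel = kernel,
                 adjacency = adjacency, sgi_x = sgi_x, gamma = gamma,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 bootstrap_B = bootstrap_B),
            class = "run_config")
}

read_province <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      abort_airineq(paste0("geodata_io: missing input ", p),
                    "airineq_error_missing_file")
    }
    p
  }
  conc <- list(
    PM1 = read_grid(need("conc_PM1.asc"), "PM1"),
    `PM2.5` = read_grid(need("conc_PM25.asc"), "PM2.5"),
    PM10 = read_grid(need("conc_PM10.asc"), "PM10")
  )
  pop <- read_grid(need("population.asc"), "population")
  regions <- read_regions(need("counties.geojson"), need("tracts.geojson"))
  covars <- tibble::as_tibble(utils::read.csv(need("covariates.csv")))
  poi <- tibble::as_tibble(utils::read.csv(need("poi.csv")))
  roads <- tibble::as_tibble(utils::read.csv(need("roads.csv")))
  list(conc = conc, population = pop, regions = regions,
       covariates = covars, poi = poi, roads = roads)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> exposure -> inequality -> urban form ->
#' drivers -> network. Stage outputs are returned and, when `out_dir` is
#' given, written as CSV together with a JSON run manifest (config, seed,
#' package version, per-stage row counts). Identical config and seed yield
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_result` with `province`, `exposure`,
#'   `sgi`, `segregation`, `urban_form`, `indicators` (log-transformed),
#'   `driver_fits`, `pca`, `component_fits`, `networks` (APE and SGI),
#'   `network_metrics`, `bootstrap` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[airineq] ", sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort_airineq(paste0("stage '", name, "' failed: ",
                           conditionMessage(e)),
                    "airineq_error_stage", parent = e)
    })
    say("%-12s %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  province <- stage("simulate", {
    if (!is.null(config$synthetic)) {
      simulate_province(config$synthetic)
    } else if (!is.null(config$input_dir)) {
      read_province(config$input_dir)
    } else {
      abort_airineq("run_pipeline: neither synthetic config nor input_dir.",
                    "airineq_error_bad_config")
    }
  })
  exposure <- stage("exposure",
                    exposure_table(province, config$buffer_km, config$kernel))
  sgi <- stage("inequality",
               sgi_table(province, config$buffer_km, config$kernel,
                         config$adjacency, config$sgi_x))
  seg <- segregation_table(province$regions)
  urban <- stage("urbanform", urban_form_table(province))
  indicators <- stage("drivers", {
    assemble_indicators(exposure, sgi, seg, urban, province$covariates) |>
      log_transform()
  })
  driver_fits <- driver_regressions(indicators)
  pca <- run_pca(indicators)
  component_fits <- component_regressions(pca, indicators)
  networks <- stage("network", list(
    APE = fit_network(indicators, "APE_combined", config$gamma,
                      config$n_lambda, config$lambda_min_ratio),
    SGI = fit_network(indicators, "SGI_combined", config$gamma,
                      config$n_lambda, config$lambda_min_ratio)
  ))
  metrics <- list(APE = network_metrics(networks$APE),
                  SGI = network_metrics(networks$SGI))
  boot <- NULL
  if (config$bootstrap_B >= 100) {
    boot <- stage("bootstrap", list(
      APE = bootstrap_network(indicators, "APE_combined",
                              B = config$bootstrap_B, seed = config$seed,
                              gamma = config$gamma,
                              n_lambda = config$n_lambda,
                              lambda_min_ratio = config$lambda_min_ratio),
      SGI = bootstrap_network(indicators, "SGI_combined",
                              B = config$bootstrap_B, seed = config$seed,
                              gamma = config$gamma,
                              n_lambda = config$n_lambda,
                              lambda_min_ratio = config$lambda_min_ratio)
    ))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("airineq")),
    seed = config$seed,
    config = config[setdiff(names(config), "synthetic")],
    synthetic = if (!is.null(config$synthetic)) {
      lapply(unclass(config$synthetic), function(v) {
        if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
      })
    },
    stages = list(
      simulate = nrow(province$regions$counties),
      exposure = nrow(exposure), inequality = nrow(sgi),
      urbanform = nrow(urban), drivers = nrow(indicators),
      network = length(networks)
    )
  )

  result <- structure(
    list(province = province, exposure = exposure, sgi = sgi,
         segregation = seg, urban_form = urban, indicators = indicators,
         driver_fits = driver_fits, pca = pca,
         component_fits = component_fits, networks = networks,
         network_metrics = metrics, bootstrap = boot, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d counties, seed %d>\n",
              nrow(x$indicators), x$manifest$seed))
  cat(sprintf("  mean APE %.2f, mean SGI %.4f; APE net %d links, SGI net %d links\n",
              mean(x$exposure$APE_combined, na.rm = TRUE),
              mean(x$sgi$SGI_combined, na.rm = TRUE),
              glance(x$networks$APE)$n_links,
              glance(x$networks$SGI)$n_links))
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(result$exposure, "exposure.csv")
  wcsv(result$sgi, "sgi.csv")
  wcsv(result$segregation, "segregation.csv")
  wcsv(result$urban_form, "urban_form.csv")
  wcsv(result$indicators, "indicators.csv")
  wcsv(result$driver_fits, "driver_ols.csv")
  wcsv(tidy(result$pca), "pca_loadings.csv")
  wcsv(glance(result$pca), "pca_variance.csv")
  wcsv(result$component_fits, "component_ols.csv")
  for (tg in names(result$networks)) {
    wcsv(tidy(result$networks[[tg]]),
         paste0("network_edges_", tolower(tg), ".csv"))
    wcsv(result$network_metrics[[tg]],
         paste0("network_metrics_", tolower(tg), ".csv"))
  }
  if (!is.null(result$bootstrap)) {
    for (tg in names(result$bootstrap)) {
      wcsv(result$bootstrap[[tg]]$edge_frequency,
           paste0("bootstrap_edges_", tolower(tg), ".csv"))
      wcsv(result$bootstrap[[tg]]$centrality_stability,
           paste0("bootstrap_stability_", tolower(tg), ".csv"))
    }
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
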
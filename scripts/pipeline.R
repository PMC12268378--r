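#!/usr/bin/env Rscript
# Command-line front end for the county-level air-pollution exposure and
# inequality pipeline. Thin wrapper over the airineq package functions.
#
# Usage:
#   Rscript scripts/pipeline.R <subcommand> [options]
#
# Subcommands:
#   simulate    write a synthetic province (rasters, GeoJSON, CSV) to --out-dir
#   exposure    per-county decay-adjusted population-weighted exposure (APE)
#   inequality  per-county spatial Gini (SGI) and income-segregation (DI)
#   urbanform   POI / road / population densities and UCI components
#   drivers     bivariate OLS screen, PCA, component regressions
#   network     EBIC-glasso partial-correlation networks (+ bootstrap)
#   all         the full pipeline with manifest
#
# Global options: --config FILE (flat key=value), --seed INT, --out-dir DIR,
# --in-dir DIR (read a province written by `simulate` instead of simulating).

suppressPackageStartupMessages({
  library(airineq)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) {
  stop("usage: pipeline.R <simulate|exposure|inequality|urbanform|drivers|network|all> [options]",
       call. = FALSE)
}
cmd <- argv[1]
rest <- argv[-1]

opt_val <- function(flag, default = NULL) {
  i <- which(rest == flag)
  if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
}

# flat key = value config file; CLI flags take precedence
read_config_file <- function(path) {
  if (is.null(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    out[[trimws(p[1])]] <- v
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

file_cfg <- read_config_file(opt_val("--config"))
seed <- as.integer(opt_val("--seed", file_cfg$seed %||% 1))
out_dir <- opt_val("--out-dir", file_cfg$out_dir %||% "airineq_out")
in_dir <- opt_val("--in-dir", file_cfg$in_dir)

syn_fields <- names(formals(synthetic_config))
syn_args <- file_cfg[intersect(names(file_cfg), syn_fields)]
syn_args$seed <- seed
syn <- do.call(synthetic_config, syn_args)

cfg <- run_config(
  seed = seed,
  synthetic = if (is.null(in_dir)) syn else NULL,
  input_dir = in_dir,
  buffer_km = as.numeric(opt_val("--buffer-km", file_cfg$buffer_km %||% 1)),
  kernel = opt_val("--kernel", file_cfg$kernel %||% "uniform"),
  adjacency = opt_val("--adjacency", file_cfg$adjacency %||% "rook"),
  sgi_x = opt_val("--sgi-x", file_cfg$sgi_x %||% "concentration"),
  gamma = as.numeric(opt_val("--gamma", file_cfg$gamma %||% 0.5)),
  n_lambda = as.integer(opt_val("--n-lambda", file_cfg$n_lambda %||% 100)),
  bootstrap_B = as.integer(opt_val("--bootstrap-B",
                                   file_cfg$bootstrap_B %||% 0))
)

dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                        row.names = FALSE)

if (cmd == "simulate") {
  write_province(simulate_province(syn), out_dir)
  message("province written to ", out_dir)
} else if (cmd == "all") {
  run_pipeline(cfg, out_dir = out_dir)
  message("pipeline outputs written to ", out_dir)
} else if (cmd %in% c("exposure", "inequality", "urbanform", "drivers",
                      "network")) {
  province <- if (!is.null(in_dir)) airineq:::read_province(in_dir) else
    simulate_province(syn)
  if (cmd == "exposure") {
    wcsv(exposure_table(province, cfg$buffer_km, cfg$kernel), "exposure.csv")
  } else if (cmd == "inequality") {
    wcsv(sgi_table(province, cfg$buffer_km, cfg$kernel, cfg$adjacency,
                   cfg$sgi_x), "sgi.csv")
    wcsv(segregation_table(province$regions), "segregation.csv")
  } else if (cmd == "urbanform") {
    wcsv(uci_table(province$poi, province$regions), "uci_components.csv")
    wcsv(density_table(province$regions, province$poi, province$roads,
                       province$population), "densities.csv")
  } else {
    tbl <- log_transform(assemble_indicators(
      exposure_table(province, cfg$buffer_km, cfg$kernel),
      sgi_table(province, cfg$buffer_km, cfg$kernel, cfg$adjacency,
                cfg$sgi_x),
      segregation_table(province$regions),
      urban_form_table(province),
      province$covariates
    ))
    if (cmd == "drivers") {
      wcsv(driver_regressions(tbl), "driver_ols.csv")
      pca <- run_pca(tbl)
      wcsv(generics::tidy(pca), "pca_loadings.csv")
      wcsv(generics::glance(pca), "pca_variance.csv")
      wcsv(component_regressions(pca, tbl), "component_ols.csv")
    } else {
      for (tg in c("APE_combined", "SGI_combined")) {
        net <- fit_network(tbl, tg, cfg$gamma, cfg$n_lambda)
        tag <- tolower(sub("_combined", "", tg))
        wcsv(generics::tidy(net), paste0("network_edges_", tag, ".csv"))
        wcsv(network_metrics(net), paste0("network_metrics_", tag, ".csv"))
        if (cfg$bootstrap_B >= 100) {
          bt <- bootstrap_network(tbl, tg, B = cfg$bootstrap_B, seed = seed,
                                  gamma = cfg$gamma,
                                  n_lambda = cfg$n_lambda)
          wcsv(bt$edge_frequency, paste0("bootstrap_edges_", tag, ".csv"))
          wcsv(bt$centrality_stability,
               paste0("bootstrap_stability_", tag, ".csv"))
        }
      }
    }
  }
  message(cmd, " outputs written to ", out_dir)
} else {
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
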
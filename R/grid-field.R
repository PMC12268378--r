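#' Gridded raster field
#'
#' A `grid_field` is the package's raster container: a rectangular matrix of
#' cell values (pollutant concentration in ug/m3, or population counts) on a
#' square grid in a projected, equal-area coordinate system measured in km.
#' Rows run north to south from the upper-left origin; missing cells are
#' stored as `NA` internally and written out with the `nodata` sentinel.
#'
#' @param values Numeric matrix of cell values. `NA` marks nodata cells.
#' @param cell_size_km Positive cell edge length in km.
#' @param origin Length-2 numeric, `(x, y)` of the upper-left corner in
#'   projected km.
#' @param nodata Sentinel value used when the field is written to disk.
#' @param label Field label, e.g. `"PM2.5"` or `"population"`.
#'
#' @return An object of class `grid_field`.
#' @examples
#' gf <- grid_field(matrix(5, 10, 10), cell_size_km = 1, label = "PM2.5")
#' gf
#' @export
grid_field <- function(values, cell_size_km = 1, origin = c(0, 0),
                       nodata = -9999, label = "field") {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0) {
    abort_airineq("`values` must be a non-empty numeric matrix.",
                  "airineq_error_bad_grid")
  }
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      !is.finite(cell_size_km) || cell_size_km <= 0) {
    abort_airineq("`cell_size_km` must be a single positive number.",
                  "airineq_error_bad_grid")
  }
  if (any(values[!is.na(values)] < 0)) {
    abort_airineq("grid_field values must be non-negative (concentration or population).",
                  "airineq_error_bad_grid")
  }
  structure(
    list(values = unname(values),
         cell_size_km = as.numeric(cell_size_km),
         origin = as.numeric(origin),
         nodata = nodata,
         label = as.character(label)),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_field '%s': %d x %d cells of %g km, %d nodata>\n",
              x$label, nrow(v), ncol(v), x$cell_size_km, sum(is.na(v))))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], origin (%.4g, %.4g)\n",
              rng[1], rng[2], x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.grid_field <- function(x) dim(x$values)

#' Cell-center coordinates of a grid field
#'
#' @param grid A [grid_field()].
#' @return A tibble with one row per cell: `row`, `col`, `x`, `y` (km,
#'   cell centers) and `value`.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_field"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  cs <- grid$cell_size_km
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = grid$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * cs,
    y = grid$origin[2] - (rep(seq_len(nr), times = nc) - 0.5) * cs,
    value = as.vector(v)
  )
}

abort_airineq <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "airineq_error"), ...)
}

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Reads the plain-text ESRI ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows of values,
#' north first). Coordinates are taken to be in a projected equal-area CRS
#' measured in km; the package performs no reprojection.
#'
#' @param path Path to an `.asc` file.
#' @param label Label to attach to the returned field.
#' @return A [grid_field()]; nodata cells are `NA`.
#' @export
read_grid <- function(path, label = "field") {
  if (!file.exists(path)) {
    abort_airineq(paste0("raster file not found: ", path),
                  "airineq_error_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr))) {
    abort_airineq(paste0("not a parseable ASCII grid header: ", path),
                  "airineq_error_bad_raster")
  }
  nc <- hdr$ncols; nr <- hdr$nrows
  nodata <- hdr$nodata_value %||% -9999
  body <- paste(lines[-seq_len(n_hdr)], collapse = " ")
  vals <- scan(text = body, what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    if (length(vals) %% (nr * nc) == 0 && length(vals) > nr * nc) {
      abort_airineq(paste0("multi-band raster not supported: ", path),
                    "airineq_error_multiband")
    }
    abort_airineq(sprintf("raster body has %d values, expected %d (%s)",
                          length(vals), nr * nc, path),
                  "airineq_error_bad_raster")
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  grid_field(m, cell_size_km = hdr$cellsize,
             origin = c(xll, yll + nr * hdr$cellsize),
             nodata = nodata, label = label)
}

#' Write a grid field to an ESRI ASCII grid file
#'
#' @param grid A [grid_field()].
#' @param path Output path (`.asc`).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "grid_field"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nr * grid$cell_size_km),
    sprintf("cellsize %.10g", grid$cell_size_km),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  v[is.na(v)] <- grid$nodata
  rows <- apply(v, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
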
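#' Spatial Gini index
#'
#' `SGI = sum_i sum_j w_ij |x_i - x_j| / (2 N^2 xbar)`: a Gini-type
#' inequality statistic whose numerator runs only over spatially adjacent
#' pairs (binary weights), so it contrasts the observed distribution with a
#' hypothetical spatially equal one. With complete weights (all ones off the
#' diagonal) it reduces to the classical Gini coefficient. Values near 0
#' indicate an equal distribution.
#'
#' @param x Non-negative value vector over the spatial sub-units.
#' @param w Binary symmetric adjacency matrix, zero diagonal, conformable
#'   with `x` (see [build_adjacency()] / [cell_adjacency()]).
#' @return A single dimensionless value.
#' @examples
#' w <- cell_adjacency(1, 4)  # path graph
#' spatial_gini(c(0, 0, 10, 10), w)  # 0.125
#' @export
spatial_gini <- function(x, w) {
  if (any(x < 0)) {
    abort_airineq("spatial_gini: x must be non-negative.",
                  "airineq_error_bad_values")
  }
  n <- length(x)
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n) {
    abort_airineq("spatial_gini: w must be an n x n matrix.",
                  "airineq_error_bad_weights")
  }
  xbar <- mean(x)
  if (xbar <= 0) {
    abort_airineq("spatial_gini undefined: mean(x) is zero.",
                  "airineq_error_zero_mean")
  }
  sum(w * abs(outer(x, x, "-"))) / (2 * n^2 * xbar)
}

# SGI over the cells of one county's sub-grid without materializing W:
# sums |differences| over rook (and, for queen, diagonal) neighbour pairs.
sgi_grid <- function(v, rule = "rook") {
  n <- sum(!is.na(v))
  if (n <= 1) return(0)
  xbar <- mean(v, na.rm = TRUE)
  if (xbar <= 0) return(NA_real_)
  total <- 0
  offs <- list(c(1, 0), c(0, 1))
  if (rule == "queen") offs <- c(offs, list(c(1, 1), c(1, -1)))
  nr <- nrow(v); nc <- ncol(v)
  for (o in offs) {
    rlo <- max(1, 1 - o[1]); rhi <- min(nr, nr - o[1])
    clo <- max(1, 1 - o[2]); chi <- min(nc, nc - o[2])
    if (rlo > rhi || clo > chi) next
    r1 <- rlo:rhi; c1 <- clo:chi
    d <- abs(v[r1, c1, drop = FALSE] -
               v[r1 + o[1], c1 + o[2], drop = FALSE])
    total <- total + sum(d, na.rm = TRUE)
  }
  2 * total / (2 * n^2 * xbar)   # the double sum counts each unordered pair twice
}

#' Within-county spatial Gini of a concentration surface
#'
#' For each county the sub-units are its raster cells, adjacency is rook
#' (shared edge) or queen (edge or corner) contiguity on the cell grid, and
#' the statistic is [spatial_gini()]. One-cell counties get SGI 0. With
#' `x = "pop_weighted"` the cell value is `P_i * C_i` (inequality of
#' exposure rather than of concentration).
#'
#' @param conc_decayed Concentration [grid_field()].
#' @param regions A [region_set()].
#' @param rule `"rook"` or `"queen"`.
#' @param x `"concentration"` (default) or `"pop_weighted"`.
#' @param pop Population [grid_field()] (required for `"pop_weighted"`).
#' @param cell_county Optional precomputed [assign_cells()] result.
#' @return Tibble: `county_id`, `sgi`.
#' @export
county_sgi <- function(conc_decayed, regions, rule = c("rook", "queen"),
                       x = c("concentration", "pop_weighted"), pop = NULL,
                       cell_county = NULL) {
  rule <- match.arg(rule); x <- match.arg(x)
  v <- conc_decayed$values
  if (x == "pop_weighted") {
    if (is.null(pop)) {
      abort_airineq("pop_weighted SGI needs a population field.",
                    "airineq_error_bad_values")
    }
    check_same_geometry(conc_decayed, pop)
    v <- v * pop$values
  }
  if (is.null(cell_county)) cell_county <- assign_cells(conc_decayed, regions)
  cm <- matrix(cell_county, nrow(v), ncol(v))
  n <- nrow(regions$counties)
  sgi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- which(cm == i, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    rs <- range(sel[, 1]); cs <- range(sel[, 2])
    sub <- v[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
    mask <- cm[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE] == i
    sub[!mask] <- NA_real_
    if (all(is.na(sub))) next   # all-nodata county
    sgi[i] <- sgi_grid(sub, rule)
  }
  if (anyNA(sgi)) {
    rlang::warn(paste0("SGI undefined for: ",
                       paste(regions$counties$county_id[is.na(sgi)],
                             collapse = ", ")),
                class = "airineq_warn_undefined_sgi")
  }
  tibble::tibble(county_id = regions$counties$county_id, sgi = sgi)
}

#' Per-county SGI table for all pollutants
#'
#' @param province A [simulate_province()] result (or compatible list).
#' @param buffer_km,kernel Decay adjustment settings (match the exposure
#'   stage).
#' @param rule Adjacency rule.
#' @param x Cell value choice, as in [county_sgi()].
#' @return Tibble: `county_id`, `SGI_PM1`, `SGI_PM25`, `SGI_PM10`,
#'   `SGI_combined`.
#' @export
sgi_table <- function(province, buffer_km = 1, kernel = "uniform",
                      rule = c("rook", "queen"),
                      x = c("concentration", "pop_weighted")) {
  rule <- match.arg(rule); x <- match.arg(x)
  regions <- province$regions
  cell_county <- assign_cells(province$population, regions)
  dec <- lapply(province$conc, decay_adjust, buffer_km = buffer_km,
                kernel = kernel)
  comb <- combine_pollutants(dec$PM1, dec$`PM2.5`, dec$PM10)
  sg <- function(g) county_sgi(g, regions, rule, x, pop = province$population,
                               cell_county = cell_county)$sgi
  tibble::tibble(
    county_id = regions$counties$county_id,
    SGI_PM1 = sg(dec$PM1),
    SGI_PM25 = sg(dec$`PM2.5`),
    SGI_PM10 = sg(dec$PM10),
    SGI_combined = sg(comb)
  )
}

#' Dissimilarity index of income segregation
#'
#' `DI = 1/2 sum_i |P_i / P - Q_i / Q|` over the tracts of one county,
#' where `P_i` is the tract's low-income population (`P` the county total)
#' and `Q_i` the tract's total population (`Q` the county total). 0 means
#' every tract holds the county-wide low-income share.
#'
#' @param low_income Per-tract low-income counts.
#' @param total Per-tract total populations.
#' @return A single value in `[0, 1]`, or `NA` (with a warning) when the
#'   county has no low-income individuals.
#' @examples
#' dissimilarity_index(c(30, 10), c(50, 50))  # 0.25
#' @export
dissimilarity_index <- function(low_income, total) {
  if (length(low_income) != length(total)) {
    abort_airineq("low_income and total must have equal length.",
                  "airineq_error_bad_values")
  }
  P <- sum(low_income); Q <- sum(total)
  if (Q <= 0) {
    abort_airineq("dissimilarity_index: county has no population.",
                  "airineq_error_zero_mean")
  }
  if (P <= 0) {
    rlang::warn("DI undefined: no low-income individuals in county.",
                class = "airineq_warn_undefined_di")
    return(NA_real_)
  }
  sum(abs(low_income / P - total / Q)) / 2
}

#' Per-county income segregation table
#'
#' @param regions A [region_set()] with tract `population` and
#'   `low_income_count` filled.
#' @return Tibble: `county_id`, `DI`.
#' @export
segregation_table <- function(regions) {
  regions$tracts |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(DI = dissimilarity_index(.data$low_income_count,
                                              .data$population),
                     .groups = "drop")
}
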
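# Independent oracles and small fixtures shared across tests.

# Classical Gini by brute-force double loop.
classical_gini <- function(x) {
  n <- length(x)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

# Dense grid search for max k' D k over the simplex (3 or 4 tracts).
grid_search_vmax <- function(D, step = 0.01) {
  n <- nrow(D)
  stopifnot(n %in% c(2, 3, 4))
  gr <- seq(0, 1, by = step)
  best <- 0
  if (n == 2) {
    for (a in gr) {
      x <- c(a, 1 - a)
      best <- max(best, as.numeric(x %*% D %*% x))
    }
  } else if (n == 3) {
    for (a in gr) for (b in gr[gr <= 1 - a + 1e-12]) {
      x <- c(a, b, 1 - a - b)
      best <- max(best, as.numeric(x %*% D %*% x))
    }
  } else {
    for (a in gr) for (b in gr[gr <= 1 - a + 1e-12]) {
      for (cc in gr[gr <= 1 - a - b + 1e-12]) {
        x <- c(a, b, cc, 1 - a - b - cc)
        best <- max(best, as.numeric(x %*% D %*% x))
      }
    }
  }
  best
}

# Random distance matrix from points in the plane.
rand_distance_matrix <- function(n) {
  pts <- matrix(stats::runif(2 * n, 0, 10), n, 2)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- NULL
  D
}

# Small, cheap synthetic province shared by several tests.
tiny_config <- function(seed = 42, ...) {
  synthetic_config(n_counties_x = 3, n_counties_y = 3, county_size_km = 4,
                   cell_size_km = 1, tracts_per_county = 4, seed = seed, ...)
}

# A single square county [0,n]x[0,n] with one tract covering it.
one_county_regions <- function(n = 2) {
  sq <- cbind(c(0, n, n, 0), c(0, 0, n, n))
  region_set(
    tibble::tibble(county_id = "C001", geometry = list(sq)),
    tibble::tibble(county_id = "C001", tract_id = "C001_T01",
                   geometry = list(sq))
  )
}

# Indicator-shaped table drawn from a given 13x13 correlation matrix, so
# network routines can be exercised with known structure.
mvn_indicator_table <- function(n, sigma, seed = 1) {
  cols <- c("APE_combined", "road_density", "poi_density", "UCI",
            "pop_density", "GDP", "income_segregation", "CPI", "MAT",
            "MAP", "NDVI", "SAP", "VC")
  p <- ncol(sigma)
  stopifnot(p == 13)
  withr::with_seed(seed, {
    L <- chol(sigma)
    x <- matrix(stats::rnorm(n * p), n, p) %*% L
    sgi <- stats::rnorm(n)
  })
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- cols
  out$SGI_combined <- sgi
  out$county_id <- sprintf("C%03d", seq_len(n))
  out
}

# Vectorized simplex grid evaluation of k' D k for 4 tracts.
simplex_grid_values <- function(D, pts) {
  keep <- rowSums(pts) <= 1 + 1e-12 & pts[, 1] >= 0 & pts[, 2] >= 0 &
    pts[, 3] >= 0
  pts <- pts[keep, , drop = FALSE]
  X <- cbind(pts, 1 - rowSums(pts))
  vals <- rowSums((X %*% D) * X)
  list(X = X, vals = vals)
}

# Two-stage dense grid search for max k' D k on the 4-tract simplex:
# coarse sweep then local refinement around the coarse argmax, giving
# accuracy well below 1e-4 for distance matrices of modest magnitude.
refined_grid_vmax <- function(D, coarse = 0.02, fine = 5e-4, radius = 0.03) {
  gr <- seq(0, 1, by = coarse)
  pts <- as.matrix(expand.grid(a = gr, b = gr, c = gr))
  stage1 <- simplex_grid_values(D, pts)
  x0 <- stage1$X[which.max(stage1$vals), 1:3]
  loc <- lapply(1:3, function(i) {
    seq(max(0, x0[i] - radius), min(1, x0[i] + radius), by = fine)
  })
  pts2 <- as.matrix(expand.grid(a = loc[[1]], b = loc[[2]], c = loc[[3]]))
  stage2 <- simplex_grid_values(D, pts2)
  max(max(stage1$vals), max(stage2$vals))
}
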
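# Gaussian graphical model estimation: L1-penalized precision ("graphical
# lasso") solved by block coordinate descent (Friedman-style), with the
# regularization level selected by the extended Bayesian information
# criterion (EBIC).

# One glasso fit at penalty lambda. S is a correlation matrix; only
# off-diagonal entries are penalized. Returns W (= estimated covariance),
# Theta (precision) and the per-column lasso coefficients (for warm starts).
glasso_fit <- function(S, lambda, B_init = NULL, tol = 1e-4,
                       max_sweeps = 1000) {
  p <- nrow(S)
  if (is.null(B_init)) B_init <- matrix(0, p - 1, p)
  fit <- glasso_fit_cpp(S, lambda, B_init, tol, max_sweeps)
  if (!fit$converged) {
    rlang::warn(sprintf("glasso did not converge at lambda = %.4g", lambda),
                class = "airineq_warn_glasso_convergence")
  }
  fit
}

pcor_from_theta <- function(Theta) {
  d <- sqrt(diag(Theta))
  P <- -Theta / tcrossprod(d)
  diag(P) <- 0
  P
}

#' Graphical-lasso path with EBIC model selection
#'
#' Fits the L1-penalized Gaussian precision matrix at each penalty on
#' `lambda_path`, scores each fit with the extended Bayesian information
#' criterion `EBIC = -2 loglik + E log(n) + 4 E gamma log(p)` (`E` = number
#' of off-diagonal edges), and returns the partial-correlation network of
#' the EBIC-minimizing penalty. `gamma = 0` recovers the ordinary BIC;
#' larger `gamma` prefers sparser graphs.
#'
#' @param corr Correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite).
#' @param lambda_path Descending positive penalties.
#' @param gamma EBIC hyperparameter (conventional default 0.5).
#' @param n Sample size behind `corr`.
#' @param labels Optional node labels.
#' @return An object of class `pc_network`: `labels`, `pcor` (symmetric,
#'   zero diagonal; exact zeros where the selected precision is zero),
#'   `theta`, `lambda_path`, `ebic`, `n_edges`, `lambda_selected`, `gamma`,
#'   `n`.
#' @export
glasso_path <- function(corr, lambda_path, gamma = 0.5, n,
                        labels = colnames(corr)) {
  p <- nrow(corr)
  if (any(abs(diag(corr) - 1) > 1e-8) || any(abs(corr - t(corr)) > 1e-8)) {
    abort_airineq("corr must be symmetric with unit diagonal.",
                  "airineq_error_bad_corr")
  }
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort_airineq("corr is not positive semi-definite.",
                  "airineq_error_not_psd")
  }
  if (n <= p) {
    rlang::warn("sample size does not exceed the variable count.",
                class = "airineq_warn_small_n")
  }
  if (is.unsorted(rev(lambda_path))) {
    lambda_path <- sort(lambda_path, decreasing = TRUE)
  }
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  ebic <- numeric(length(lambda_path))
  n_edges <- integer(length(lambda_path))
  fits <- vector("list", length(lambda_path))
  B <- NULL
  for (i in seq_along(lambda_path)) {
    fit <- glasso_fit(corr, lambda_path[i], B_init = B)
    B <- fit$B   # warm start down the path
    Theta <- fit$Theta
    Th0 <- zero_structural(Theta, fit$B)
    E <- sum(Th0[upper.tri(Th0)] != 0)
    ll <- (n / 2) * (determinant(Theta, logarithm = TRUE)$modulus -
                       sum(corr * Theta))
    ebic[i] <- -2 * as.numeric(ll) + E * log(n) + 4 * E * gamma * log(p)
    n_edges[i] <- E
    fits[[i]] <- list(Theta = Theta, Theta_structural = Th0)
  }
  sel <- which.min(ebic)
  Theta_sel <- fits[[sel]]$Theta_structural
  pc <- pcor_from_theta(fits[[sel]]$Theta)
  pc[Theta_sel == 0] <- 0   # structural zeros are exact zeros
  dimnames(pc) <- list(labels, labels)
  structure(
    list(labels = labels, pcor = pc, theta = fits[[sel]]$Theta,
         lambda_path = lambda_path, ebic = ebic, n_edges = n_edges,
         lambda_selected = lambda_path[sel], gamma = gamma, n = n),
    class = "pc_network"
  )
}

# Edge structure: off-diagonal zero wherever the lasso coefficient is zero.
zero_structural <- function(Theta, B) {
  p <- nrow(Theta)
  Z <- Theta
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    Z[idx, j][B[, j] == 0] <- 0
  }
  Z <- (abs(Z) + t(abs(Z))) / 2   # symmetrize: edge present if either nonzero
  Z
}

#' @export
print.pc_network <- function(x, ...) {
  E <- sum(x$pcor[upper.tri(x$pcor)] != 0)
  cat(sprintf("<pc_network: %d nodes, %d edges, lambda %.4g (EBIC gamma %.2g)>\n",
              length(x$labels), E, x$lambda_selected, x$gamma))
  invisible(x)
}

#' @method tidy pc_network
#' @export
tidy.pc_network <- function(x, ...) {
  ut <- which(upper.tri(x$pcor), arr.ind = TRUE)
  tibble::tibble(from = x$labels[ut[, 1]], to = x$labels[ut[, 2]],
                 weight = x$pcor[ut]) |>
    dplyr::filter(.data$weight != 0)
}

#' @method glance pc_network
#' @export
glance.pc_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$labels),
                 n_links = sum(x$pcor[upper.tri(x$pcor)] != 0),
                 lambda_selected = x$lambda_selected,
                 gamma = x$gamma, n = x$n)
}

#' Fit the partial-correlation network for one target
#'
#' Builds the Pearson correlation matrix of the standardized 13 analysis
#' columns (the chosen target plus the 12 indicators; log transforms are
#' expected to have been applied upstream), lays a log-spaced penalty path
#' from `lambda_max` (the smallest penalty yielding the empty graph, i.e.
#' the largest absolute off-diagonal correlation) down to
#' `lambda_max * lambda_min_ratio`, and runs [glasso_path()].
#'
#' @param table Indicator tibble from [assemble_indicators()] +
#'   [log_transform()].
#' @param target `"APE_combined"` or `"SGI_combined"`.
#' @param gamma EBIC hyperparameter.
#' @param n_lambda Path length.
#' @param lambda_min_ratio Ratio of smallest to largest penalty.
#' @return A `pc_network`.
#' @export
fit_network <- function(table, target = c("APE_combined", "SGI_combined"),
                        gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01) {
  target <- match.arg(target)
  cols <- c(target, indicator_columns())
  x <- scale(as.matrix(table[, cols]))
  S <- stats::cor(x)
  lmax <- max(abs(S[upper.tri(S)]))
  path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  glasso_path(S, path, gamma = gamma, n = nrow(x), labels = cols)
}

#' Node centrality metrics of a partial-correlation network
#'
#' Strength is the sum of absolute incident edge weights; expected influence
#' keeps the signs.
#'
#' @param net A `pc_network`.
#' @return Tibble: `node`, `strength`, `expected_influence`; the edge count
#'   is in attribute `n_links`.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "pc_network"))
  out <- tibble::tibble(
    node = net$labels,
    strength = unname(colSums(abs(net$pcor))),
    expected_influence = unname(colSums(net$pcor))
  )
  attr(out, "n_links") <- sum(net$pcor[upper.tri(net$pcor)] != 0)
  out
}

#' Bootstrap stability of a fitted network
#'
#' Two resampling exercises, both deterministic given `seed`:
#' case-resampling with replacement (`B` replicates) yielding per-edge
#' inclusion frequencies, and case-dropping at the given proportions
#' (`ceiling(B / length(drop_proportions))` replicates each) yielding the
#' correlation of each replicate's strength vector with the full-sample one.
#' Replicates with a degenerate (constant) column are redrawn, up to 10
#' extra attempts each.
#'
#' @param table Indicator tibble (log-transformed).
#' @param target `"APE_combined"` or `"SGI_combined"`.
#' @param B Replicate count (at least 100).
#' @param seed Integer seed.
#' @param gamma,n_lambda,lambda_min_ratio Passed to [fit_network()].
#' @param drop_proportions Case-dropping proportions.
#' @return An object of class `network_bootstrap`: `B`, `edge_frequency`
#'   (tibble `from`, `to`, `frequency`, `mean_weight`),
#'   `centrality_stability` (tibble `drop_proportion`, `mean_cor`), and the
#'   full-sample `network`.
#' @export
bootstrap_network <- function(table, target = c("APE_combined", "SGI_combined"),
                              B = 100, seed = 1, gamma = 0.5, n_lambda = 100,
                              lambda_min_ratio = 0.01,
                              drop_proportions = c(0.1, 0.2, 0.3)) {
  target <- match.arg(target)
  if (B < 100) {
    abort_airineq("bootstrap_network needs B >= 100.",
                  "airineq_error_too_few")
  }
  full <- fit_network(table, target, gamma, n_lambda, lambda_min_ratio)
  p <- length(full$labels)
  ut <- upper.tri(full$pcor)
  n <- nrow(table)
  full_strength <- colSums(abs(full$pcor))

  draw_fit <- function(m, replace = TRUE) {
    # sample m rows; redraw on degenerate columns
    for (attempt in 1:11) {
      rows <- sample.int(n, m, replace = replace)
      sub <- table[rows, ]
      sds <- vapply(sub[, c(target, indicator_columns())], stats::sd,
                    numeric(1))
      if (all(sds > 0)) {
        return(fit_network(sub, target, gamma, n_lambda, lambda_min_ratio))
      }
    }
    rlang::warn("degenerate bootstrap replicate retained after 10 redraws.",
                class = "airineq_warn_degenerate_replicate")
    fit_network(sub, target, gamma, n_lambda, lambda_min_ratio)
  }

  withr::with_seed(seed, {
    freq <- matrix(0, p, p)
    wsum <- matrix(0, p, p)
    for (b in seq_len(B)) {
      net_b <- draw_fit(n)
      freq <- freq + (net_b$pcor != 0)
      wsum <- wsum + net_b$pcor
    }
    stab <- purrr::map_dfr(drop_proportions, function(q) {
      reps <- ceiling(B / length(drop_proportions))
      cors <- vapply(seq_len(reps), function(b) {
        m <- max(p + 2, round((1 - q) * n))
        net_b <- draw_fit(m, replace = FALSE)
        suppressWarnings(stats::cor(colSums(abs(net_b$pcor)), full_strength))
      }, numeric(1))
      tibble::tibble(drop_proportion = q,
                     mean_cor = mean(cors, na.rm = TRUE))
    })
  })
  idx <- which(ut, arr.ind = TRUE)
  structure(
    list(B = B,
         edge_frequency = tibble::tibble(
           from = full$labels[idx[, 1]], to = full$labels[idx[, 2]],
           frequency = freq[ut] / B, mean_weight = wsum[ut] / B),
         centrality_stability = stab,
         network = full),
    class = "network_bootstrap"
  )
}

#' @export
print.network_bootstrap <- function(x, ...) {
  cat(sprintf("<network_bootstrap: B = %d, %d candidate edges, mean stability %.2f>\n",
              x$B, nrow(x$edge_frequency),
              mean(x$centrality_stability$mean_cor)))
  invisible(x)
}
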
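test_that("an identity correlation selects the empty graph", {
  S <- diag(6)
  path <- exp(seq(log(0.5), log(0.005), length.out = 40))
  net <- glasso_path(S, path, gamma = 0.5, n = 1000)
  expect_equal(sum(net$pcor != 0), 0)
  expect_equal(glance(net)$n_links, 0)
})

test_that("EBIC at the empty graph equals the diagonal-model deviance", {
  # for a correlation input the empty-graph precision is the identity, so
  # -2 loglik = -n (log det I - tr(S I)) = n * p, with zero penalty terms
  withr::with_seed(10, {
    x <- matrix(rnorm(200 * 5), 200, 5)
  })
  S <- stats::cor(x)
  lmax <- max(abs(S[upper.tri(S)]))
  net <- glasso_path(S, c(lmax * 1.01), gamma = 0.5, n = 200)
  expect_equal(net$n_edges[1], 0L)
  expect_equal(net$ebic[1], 200 * 5, tolerance = 1e-6)
})

test_that("the lambda -> 0 limit matches direct precision-matrix inversion", {
  withr::with_seed(40, {
    for (p in 4:6) {
      A <- matrix(rnorm(p * p, sd = 0.3), p, p)
      S <- stats::cov2cor(diag(p) + crossprod(A))
      fit <- airineq:::glasso_fit(S, 1e-8)
      Theta_ref <- solve(S)
      expect_equal(fit$Theta, Theta_ref, tolerance = 1e-3,
                   ignore_attr = TRUE)
      pc_ref <- -Theta_ref / tcrossprod(sqrt(diag(Theta_ref)))
      diag(pc_ref) <- 0
      pc <- airineq:::pcor_from_theta(fit$Theta)
      expect_equal(pc, pc_ref, tolerance = 1e-3, ignore_attr = TRUE)
    }
  })
})

test_that("chain-graph simulations recover edges and exclude shortcuts", {
  # 5-node chain precision. Two signal regimes: a strong chain checks that
  # every true edge is detected; a weak chain checks that the two absent
  # "shortcut" pairs are excluded (with strong edges, EBIC tolerates weak
  # spurious partial correlations that absorb the lasso shrinkage bias --
  # the sparsistency regime is the weak-signal one).
  run_chain <- function(wgt, n_seeds = 20) {
    Omega <- diag(5)
    for (i in 1:4) Omega[i, i + 1] <- Omega[i + 1, i] <- -wgt
    L <- chol(stats::cov2cor(solve(Omega)))
    chain <- 0; excluded <- 0
    for (sd in seq_len(n_seeds)) {
      x <- withr::with_seed(1000 + sd,
                            matrix(stats::rnorm(500 * 5), 500, 5) %*% L)
      S <- stats::cor(x)
      lmax <- max(abs(S[upper.tri(S)]))
      path <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 50))
      net <- glasso_path(S, path, gamma = 0.5, n = 500)
      if (all(sapply(1:4, function(i) net$pcor[i, i + 1] != 0))) {
        chain <- chain + 1
      }
      if (net$pcor[1, 3] == 0 && net$pcor[2, 4] == 0) excluded <- excluded + 1
    }
    c(chain = chain / n_seeds, excluded = excluded / n_seeds)
  }
  strong <- run_chain(0.4)
  expect_gte(strong[["chain"]], 0.95)
  weak <- run_chain(0.15)
  expect_gte(weak[["excluded"]], 0.8)
})

test_that("gamma = 0 is BIC and larger gamma never adds edges", {
  withr::with_seed(61, {
    f <- rnorm(120)
    x <- sapply(1:6, function(j) f + rnorm(120))
  })
  S <- stats::cor(x)
  lmax <- max(abs(S[upper.tri(S)]))
  path <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 40))
  edges_at <- function(g) {
    net <- glasso_path(S, path, gamma = g, n = 120)
    sum(net$pcor[upper.tri(net$pcor)] != 0)
  }
  e <- vapply(c(0, 0.25, 0.5, 1), edges_at, numeric(1))
  expect_true(all(diff(e) <= 0))
  # gamma = 0: EBIC reduces to -2 loglik + E log n exactly
  net0 <- glasso_path(S, path, gamma = 0, n = 120)
  expect_false(any(is.na(net0$ebic)))
})

test_that("partial correlations are bounded and edge counts shrink with lambda", {
  withr::with_seed(73, {
    f <- rnorm(150)
    x <- sapply(1:8, function(j) 0.7 * f + rnorm(150))
  })
  S <- stats::cor(x)
  lmax <- max(abs(S[upper.tri(S)]))
  path <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 30))
  net <- glasso_path(S, path, gamma = 0.5, n = 150)
  expect_true(all(net$pcor > -1 & net$pcor < 1))
  expect_true(all(diag(net$pcor) == 0))
  expect_identical(net$pcor, t(net$pcor))
  # path is descending in lambda; edge counts should broadly increase
  expect_lte(net$n_edges[1], net$n_edges[length(net$n_edges)])
})

test_that("fitted networks are deterministic and order-invariant", {
  tbl <- mvn_indicator_table(120, diag(13), seed = 3)
  n1 <- fit_network(tbl, "APE_combined")
  n2 <- fit_network(tbl, "APE_combined")
  expect_identical(n1$pcor, n2$pcor)
  perm <- withr::with_seed(4, sample(120))
  n3 <- fit_network(tbl[perm, ], "APE_combined")
  expect_equal(n1$pcor, n3$pcor, tolerance = 1e-12)
})

test_that("network metrics equal brute-force row sums", {
  Sig <- diag(13)
  Sig[1, 5] <- Sig[5, 1] <- 0.6   # APE_combined -- pop_density
  Sig[9, 11] <- Sig[11, 9] <- -0.4
  tbl <- mvn_indicator_table(250, Sig, seed = 8)
  net <- fit_network(tbl, "APE_combined")
  m <- network_metrics(net)
  for (i in seq_along(net$labels)) {
    s_ref <- 0; e_ref <- 0
    for (j in seq_along(net$labels)) {
      s_ref <- s_ref + abs(net$pcor[i, j])
      e_ref <- e_ref + net$pcor[i, j]
    }
    expect_equal(m$strength[i], s_ref, tolerance = 1e-12)
    expect_equal(m$expected_influence[i], e_ref, tolerance = 1e-12)
  }
  expect_true(all(m$strength >= abs(m$expected_influence) - 1e-12))
  expect_lte(attr(m, "n_links"), 13 * 12 / 2)
  # empty network: all zeros
  empty <- fit_network(mvn_indicator_table(500, diag(13), seed = 12),
                       "APE_combined")
  me <- network_metrics(empty)
  expect_true(all(me$strength == 0))
  expect_equal(attr(me, "n_links"), 0L)
})

test_that("non-PSD and malformed correlation inputs are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(glasso_path(bad, 0.1, gamma = 0.5, n = 100),
               class = "airineq_error_not_psd")
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(glasso_path(asym, 0.1, gamma = 0.5, n = 100),
               class = "airineq_error_bad_corr")
})

test_that("bootstrap is seed-deterministic and finds planted edges", {
  Sig <- diag(13)
  Sig[1, 5] <- Sig[5, 1] <- 0.5   # APE_combined -- pop_density planted
  tbl <- mvn_indicator_table(300, Sig, seed = 21)
  b1 <- bootstrap_network(tbl, "APE_combined", B = 100, seed = 99,
                          n_lambda = 40)
  b2 <- bootstrap_network(tbl, "APE_combined", B = 100, seed = 99,
                          n_lambda = 40)
  expect_identical(b1$edge_frequency, b2$edge_frequency)
  expect_identical(b1$centrality_stability, b2$centrality_stability)
  ef <- b1$edge_frequency
  planted <- ef$frequency[ef$from == "APE_combined" & ef$to == "pop_density"]
  expect_gte(planted, 0.9)
  expect_true(all(ef$frequency >= 0 & ef$frequency <= 1))
  # planted edge is hit more often than the average null edge
  null_mean <- mean(ef$frequency[!(ef$from == "APE_combined" &
                                     ef$to == "pop_density")])
  expect_gt(planted, null_mean)
  expect_error(bootstrap_network(tbl, "APE_combined", B = 50, seed = 1),
               class = "airineq_error_too_few")
})
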
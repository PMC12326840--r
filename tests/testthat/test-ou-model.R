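test_that("OU covariance matches the closed form on a two-tip tree", {
  tree <- nwk("(A:1,B:1);")
  v <- ou_covariance(alpha = 0.5, sigma = 1, tree)
  expect_equal(unname(diag(v)), rep(1 - exp(-1), 2))  # sigma^2/(2a)(1-e^-2aT)
  ## MRCA at the root: no shared history, zero covariance
  expect_equal(v["A", "B"], 0)
  expect_true(isSymmetric(v))
})

test_that("star phylogenies have diagonal OU covariance", {
  star <- nwk("(A:2,B:2,C:2,D:2);")
  v <- ou_covariance(1.3, 0.7, star)
  expect_equal(unname(v - diag(diag(v))), matrix(0, 4, 4))
})

test_that("the Brownian-motion covariance is the alpha -> 0 limit", {
  tree <- simulate_tree(5, height_myr = 80, seed = 9)
  sigma <- 1.4
  v_ou <- ou_covariance(1e-6, sigma, tree)
  v_bm <- sigma^2 * shared_time_matrix(tree)
  expect_equal(v_ou, v_bm, tolerance = 1e-4)
})

test_that("covariance is positive-definite across the default lattice", {
  tree <- simulate_tree(7, height_myr = 100, seed = 31)
  g <- ou_grid(n = 12)
  for (a in g$alpha) {
    v <- ou_covariance(a, 2, tree)
    expect_no_error(chol(v))
  }
  expect_error(ou_covariance(0, 1, tree), "alpha")
})

test_that("design matrix rows always sum to one and hit both limits", {
  tree <- simulate_tree(6, height_myr = 100, seed = 4)
  c0 <- ou_design(0, tree)
  expect_equal(unname(c0[, "ancestral"]), rep(1, 6))
  expect_equal(unname(c0[, "optimum"]), rep(0, 6))
  expect_equal(unname(rowSums(ou_design(0.737, tree))), rep(1, 6))
  expect_equal(unname(ou_design(5, tree)[, "optimum"]), rep(1, 6),
               tolerance = 1e-6)
})

test_that("GLS reduces to OLS under identity covariance and interpolates exactly", {
  set.seed(8)
  C <- cbind(a = runif(9), b = rnorm(9))   # well-conditioned design
  y <- rnorm(9)
  th <- gls_theta(C, diag(9), y)
  expect_equal(as.numeric(th), unname(lm.fit(C, y)$coefficients),
               tolerance = 1e-10)
  expect_false(attr(th, "degenerate"))
  ## exact interpolation
  y2 <- drop(C %*% c(3, 7))
  expect_equal(as.numeric(gls_theta(C, diag(9), y2)), c(3, 7), tolerance = 1e-8)
})

test_that("GLS on a three-tip case matches hand-solved normal equations", {
  ## V and C built by hand; normal equations solved with the analytic
  ## 2x2 inverse as an independent route
  V <- matrix(c(2, 1, 0,
                1, 2, 0,
                0, 0, 3), 3, 3)
  C <- cbind(c(1, 0.5, 0), c(0, 0.5, 1))
  y <- c(4, 5, 9)
  Vi <- solve(V)
  G <- t(C) %*% Vi %*% C
  b <- t(C) %*% Vi %*% y
  det_g <- G[1, 1] * G[2, 2] - G[1, 2] * G[2, 1]
  theta_hand <- c(G[2, 2] * b[1] - G[1, 2] * b[2],
                  -G[2, 1] * b[1] + G[1, 1] * b[2]) / det_g
  expect_equal(as.numeric(gls_theta(C, V, y)), theta_hand, tolerance = 1e-10)
})

test_that("ultrametric trees make the normal matrix rank-1: minimum-norm theta", {
  tree <- simulate_tree(5, height_myr = 100, seed = 2)
  C <- ou_design(2, tree)
  V <- ou_covariance(2, 1.5, tree)
  y <- rnorm(5, 6)
  expect_warning(th <- gls_theta(C, V, y), "minimum-norm")
  expect_true(attr(th, "degenerate"))
  ## the fitted mean is the GLS mean of y on the constant vector
  Vi <- solve(V)
  mu_gls <- sum(Vi %*% y) / sum(Vi)
  expect_equal(unname(drop(C %*% th)), rep(mu_gls, 5), tolerance = 1e-8)
})

test_that("log-determinant scales as 2 n log c when sigma is scaled by c", {
  tree <- simulate_tree(6, height_myr = 100, seed = 13)
  c_ <- 2.7
  ld <- function(sg) 2 * sum(log(diag(chol(ou_covariance(0.8, sg, tree)))))
  expect_equal(ld(1.1 * c_), ld(1.1) + 2 * 6 * log(c_), tolerance = 1e-8)
})

test_that("log-likelihood is invariant under consistent tip relabeling", {
  tree <- simulate_tree(6, height_myr = 100, seed = 5)
  y <- setNames(rnorm(6, 6), tree$tip.label)
  ll <- ou_loglik(1.2, 1.8, tree, y)
  perm <- sample(6)
  ll_p <- ou_loglik(1.2, 1.8, tree, y[perm])   # names carry the mapping
  expect_equal(as.numeric(ll), as.numeric(ll_p))
  ## and agrees with an explicit permutation of V, C and y
  V <- ou_covariance(1.2, 1.8, tree)
  C <- ou_design(1.2, tree)
  r <- y - drop(C %*% suppressWarnings(gls_theta(C, V, y)))
  ll_direct <- -0.5 * (6 * log(2 * pi) + determinant(V)$modulus[1] +
                         drop(r %*% solve(V, r)))
  expect_equal(as.numeric(ll), ll_direct, tolerance = 1e-8)
})

test_that("BM likelihood oracle agrees with the OU fit at tiny alpha", {
  tree <- simulate_tree(5, height_myr = 60, seed = 77)
  sigma <- 1.3
  y <- setNames(c(5, 7, 6, 8, 5), tree$tip.label)
  ## independent BM log-likelihood: GLS mean on ones, covariance sigma^2 S
  S <- shared_time_matrix(tree)
  Vb <- sigma^2 * S
  Vi <- solve(Vb)
  mu <- sum(Vi %*% y[rownames(S)]) / sum(Vi)
  r <- y[rownames(S)] - mu
  ll_bm <- -0.5 * (5 * log(2 * pi) + determinant(Vb)$modulus[1] +
                     drop(r %*% Vi %*% r))
  ll_ou <- ou_loglik(1e-6, sigma, tree, y)
  expect_equal(as.numeric(ll_ou), ll_bm, tolerance = 1e-3)
})

test_that("lattice fit attains the maximum and matches the direct likelihood", {
  tree <- simulate_tree(6, height_myr = 100, seed = 19)
  cfg <- sim_config(seed = 19, n_species = 6, tree = tree, n_blocks = 5,
                    theta_scale = "constant")
  y <- simulate_traits(cfg, tree)[3, ]
  g <- ou_grid(n = 25)
  fit <- grid_fit(y, tree, grid = g)
  expect_equal(fit$loglik, max(fit$surface, na.rm = TRUE))
  ## dual route: factorised lattice value vs direct ou_loglik
  expect_equal(fit$loglik,
               as.numeric(ou_loglik(fit$alpha, fit$sigma, tree, y)),
               tolerance = 1e-8)
  ## every surface entry matches the direct computation at spot-checked points
  for (idx in list(c(1, 1), c(13, 20), c(25, 3))) {
    expect_equal(fit$surface[idx[1], idx[2]],
                 as.numeric(ou_loglik(g$alpha[idx[1]], g$sigma[idx[2]],
                                      tree, y)),
                 tolerance = 1e-8)
  }
})

test_that("classification splits drift from selection at the alpha threshold", {
  fits <- data.frame(block_id = sprintf("b%d", 1:5),
                     alpha = c(0.01, 5.2, 5.2, 5.2, 3),
                     sigma = c(0.5, 2.11, 2.11, 1, 1),
                     loglik = rep(-10, 5))
  cl <- classify_blocks(list(fits = fits))
  expect_equal(cl$n_drift, 1L)
  expect_equal(cl$pct_selection, 80)
  expect_equal(cl$modal_alpha, 5.2)
  expect_equal(cl$modal_sigma, 2.11)
})
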
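## Ornstein-Uhlenbeck model of TAD-number evolution along a phylogeny.
##
## The trait X_t follows dX_t = -alpha (X_t - theta) dt + sigma dB_t. On an
## ultrametric tree of height T the tip covariance is
##
##   V_ij = sigma^2/(2 alpha) * exp(-alpha t_ij) * (1 - exp(-2 alpha t_ra))
##
## with t_ij the time separating tips i and j (patristic distance) and t_ra
## the time from the root to their most recent common ancestor. The expected
## tip values are C %*% theta with C_i1 = exp(-alpha t_ia),
## C_i2 = 1 - exp(-alpha t_ia), t_ia the root-to-tip time, and
## theta = (ancestral state, optimum). theta is profiled out at each grid
## point by generalised least squares; (alpha, sigma) are fitted by
## maximising the Gaussian log-likelihood on a lattice.
##
## Note on identifiability: on an ultrametric tree every t_ia equals the
## tree height, so the two columns of C are proportional and C'V^-1 C is
## rank 1 for every alpha. Only the scalar mean mu = C_i. %*% theta is
## identified; gls_theta() returns the minimum-norm theta and flags the fit
## degenerate. The likelihood, which depends on theta only through C theta,
## is unaffected.

#' OU tip covariance matrix on a phylogeny
#'
#' Evaluates `V_ij = sigma^2/(2 alpha) exp(-alpha t_ij)
#' (1 - exp(-2 alpha t_ra))` for every tip pair, where `t_ij` is the time
#' separating the two tips and `t_ra` the root-to-MRCA time. The diagonal is
#' `sigma^2/(2 alpha) (1 - exp(-2 alpha T))` with `T` the tree height. As
#' `alpha -> 0` the matrix tends to the Brownian-motion covariance
#' `sigma^2 * t_(root->MRCA)`.
#'
#' @param alpha Selection strength (1/Myr), > 0.
#' @param sigma Drift intensity (trait units / sqrt(Myr)), > 0.
#' @param tree A validated ultrametric `phylo`.
#' @return Symmetric positive-definite matrix with tip-label dimnames.
#' @export
ou_covariance <- function(alpha, sigma, tree) {
  assert_that(alpha > 0, "alpha must be > 0")
  assert_that(sigma > 0, "sigma must be > 0")
  s <- shared_time_matrix(tree)
  depths <- diag(s)
  tij <- outer(depths, rep(1, length(depths))) +
    outer(rep(1, length(depths)), depths) - 2 * s
  v <- sigma^2 / (2 * alpha) * exp(-alpha * tij) * (1 - exp(-2 * alpha * s))
  dimnames(v) <- dimnames(s)
  v
}

#' OU design matrix
#'
#' `C_i1 = exp(-alpha t_ia)`, `C_i2 = 1 - exp(-alpha t_ia)` with `t_ia` the
#' root-to-tip time of tip i: the weights with which the ancestral state and
#' the optimum enter the expected tip value. Rows sum to 1 for every alpha.
#'
#' @param alpha Selection strength (1/Myr), >= 0.
#' @param tree A validated ultrametric `phylo`.
#' @return n x 2 matrix with rownames = tip labels and columns
#'   `c("ancestral", "optimum")`.
#' @export
ou_design <- function(alpha, tree) {
  assert_that(alpha >= 0, "alpha must be >= 0")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  w <- exp(-alpha * depths)
  m <- cbind(ancestral = w, optimum = 1 - w)
  rownames(m) <- tree$tip.label
  m
}

#' Generalised least squares estimate of the OU mean parameters
#'
#' Solves `theta = (C' V^-1 C)^-1 C' V^-1 y`, the GLS minimiser of
#' `(y - C theta)' V^-1 (y - C theta)`. When the normal matrix is (near)
#' singular — on ultrametric trees the columns of C are always proportional —
#' the minimum-norm solution among the GLS minimisers is returned via the
#' SVD pseudoinverse, a warning is raised, and the result carries
#' `attr(, "degenerate") = TRUE`.
#'
#' @param C Design matrix (n x p), see [ou_design()].
#' @param V Positive-definite covariance (n x n), see [ou_covariance()].
#' @param y Trait vector of length n.
#' @return Numeric vector theta of length p with attribute `degenerate`.
#' @export
gls_theta <- function(C, V, y) {
  R <- chol(V)
  Ci <- backsolve(R, forwardsolve(t(R), C))   # V^-1 C
  G <- crossprod(C, Ci)
  b <- crossprod(Ci, y)
  degenerate <- rcond(G) < 1e-10
  if (degenerate) {
    warning("normal matrix C'V^-1C is singular; returning minimum-norm theta",
            call. = FALSE)
    sv <- svd(G)
    pos <- sv$d > max(sv$d) * 1e-12
    theta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  } else {
    theta <- solve(G, b)
  }
  theta <- drop(theta)
  names(theta) <- colnames(C)
  attr(theta, "degenerate") <- degenerate
  theta
}

#' Profile log-likelihood of an OU parameter pair
#'
#' Multivariate-normal log-density of the tip traits with mean `C theta`
#' (theta profiled out by [gls_theta()]) and covariance `V`:
#' `-1/2 [n log 2 pi + log|V| + (y - C theta)' V^-1 (y - C theta)]`, in nats.
#'
#' @inheritParams ou_covariance
#' @param y Trait vector named by (or ordered as) the tree's tip labels.
#' @return Log-likelihood (nats) with attributes `theta` and `degenerate`.
#' @export
ou_loglik <- function(alpha, sigma, tree, y) {
  n <- length(tree$tip.label)
  assert_that(length(y) == n, "trait vector length != number of tips")
  if (!is.null(names(y))) y <- y[tree$tip.label]
  V <- ou_covariance(alpha, sigma, tree)
  C <- ou_design(alpha, tree)
  theta <- suppressWarnings(gls_theta(C, V, y))
  r <- y - drop(C %*% theta)
  R <- chol(V)
  z <- forwardsolve(t(R), r)
  ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
  attr(ll, "theta") <- theta
  attr(ll, "degenerate") <- attr(theta, "degenerate")
  ll
}

#' Construct an OU parameter grid
#'
#' @param min,max Grid range for both alpha and sigma (defaults 0.01 and 10).
#' @param n Number of lattice points per axis (default 100).
#' @param scale `"linear"` (default) or `"log"` spacing.
#' @return List with numeric vectors `alpha` and `sigma`.
#' @export
ou_grid <- function(min = 0.01, max = 10, n = 100, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  assert_that(min > 0 && max > min, "need 0 < min < max")
  g <- switch(scale,
              linear = seq(min, max, length.out = n),
              log = exp(seq(log(min), log(max), length.out = n)))
  list(alpha = g, sigma = g, scale = scale)
}

#' Grid-search OU fit for a matrix of block traits
#'
#' Fits the OU model independently to every block (row of `traits`) by
#' maximising the profile log-likelihood over the (alpha, sigma) lattice.
#' The likelihood factorises over sigma: with `V = sigma^2 M(alpha)`, the GLS
#' mean and the quadratic form depend on alpha only, so each alpha requires
#' one Cholesky of `M` shared by all blocks, and the sigma axis is evaluated
#' in closed form. Ties on the lattice are broken toward the smallest alpha,
#' then the smallest sigma.
#'
#' Only blocks with a trait value for every tip are fitted; rows with
#' missing values are an error (filter first, complete-case, as the analyses
#' that restrict to a fully covered clade do).
#'
#' @param traits Numeric matrix, blocks x species; column names must match
#'   the tree's tip labels.
#' @param tree A validated ultrametric `phylo`.
#' @param grid An [ou_grid()] (default: linear 100 x 100 on \[0.01, 10\]).
#' @return An object of class `ou_grid_fit`: `fits` (data frame per block:
#'   `block_id`, `alpha`, `sigma`, `theta_ancestral`, `theta_optimum`,
#'   `loglik`, `degenerate`), `alpha_grid`, `sigma_grid`,
#'   `cumulative_loglik` (alpha x sigma matrix summed over blocks), and
#'   `n_tips`.
#' @export
fit_ou_grid <- function(traits, tree, grid = ou_grid()) {
  traits <- as.matrix(traits)
  assert_that(!anyNA(traits),
              "traits contain NA: OU fitting is complete-case, filter blocks first")
  assert_that(!is.null(colnames(traits)) &&
                setequal(colnames(traits), tree$tip.label),
              "trait columns must match tree tip labels")
  traits <- traits[, tree$tip.label, drop = FALSE]
  n <- ncol(traits)
  B <- nrow(traits)
  Y <- t(traits)                                   # n x B
  s <- shared_time_matrix(tree)
  depths <- diag(s)
  tij <- outer(depths, rep(1, n)) + outer(rep(1, n), depths) - 2 * s

  alphas <- grid$alpha
  sigmas <- grid$sigma
  const <- n * log(2 * pi)
  best_ll <- rep(-Inf, B)
  best_ai <- rep(NA_integer_, B)
  best_si <- rep(NA_integer_, B)
  best_mu <- rep(NA_real_, B)
  cum <- matrix(0, length(alphas), length(sigmas),
                dimnames = list(alpha = NULL, sigma = NULL))
  for (ai in seq_along(alphas)) {
    a <- alphas[ai]
    M <- exp(-a * tij) * (1 - exp(-2 * a * s)) / (2 * a)
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) {
      tv_log(sprintf("alpha = %g: covariance not PD, lattice column skipped",
                     a), stage = "oufit")
      cum[ai, ] <- NA_real_
      next
    }
    logdetM <- 2 * sum(log(diag(R)))
    Mi <- chol2inv(R)
    wi <- rowSums(Mi)                              # M^-1 1
    denom <- sum(wi)                               # 1' M^-1 1
    mu <- drop(crossprod(wi, Y)) / denom           # GLS mean per block
    Resid <- Y - matrix(mu, n, B, byrow = TRUE)
    q <- colSums(Resid * (Mi %*% Resid))           # (y-mu)' M^-1 (y-mu)
    for (si in seq_along(sigmas)) {
      sg <- sigmas[si]
      ll <- -0.5 * (const + 2 * n * log(sg) + logdetM + q / sg^2)
      cum[ai, si] <- sum(ll)
      upd <- ll > best_ll                          # strict: ties keep the
      if (any(upd)) {                              # earlier (smaller) point
        best_ll[upd] <- ll[upd]
        best_ai[upd] <- ai
        best_si[upd] <- si
        best_mu[upd] <- mu[upd]
      }
    }
  }
  unfit <- is.na(best_ai)
  if (any(unfit))
    tv_log(sprintf("%d block(s) unfittable (no finite lattice point)",
                   sum(unfit)), stage = "oufit")
  ## minimum-norm theta from the fitted scalar mean (see file header)
  a_hat <- alphas[best_ai]
  c1 <- exp(-a_hat * max(depths))
  c2 <- 1 - c1
  nrm <- c1^2 + c2^2
  fits <- data.frame(
    block_id = rownames(traits) %||% as.character(seq_len(B)),
    alpha = a_hat, sigma = sigmas[best_si],
    theta_ancestral = c1 * best_mu / nrm,
    theta_optimum = c2 * best_mu / nrm,
    mu = best_mu, loglik = best_ll, degenerate = TRUE,
    stringsAsFactors = FALSE)
  fits$loglik[unfit] <- NA_real_
  structure(list(fits = fits, alpha_grid = alphas, sigma_grid = sigmas,
                 cumulative_loglik = cum, n_tips = n, scale = grid$scale),
            class = "ou_grid_fit")
}

#' @export
print.ou_grid_fit <- function(x, ...) {
  cat(sprintf("<ou_grid_fit: %d blocks, %d x %d %s grid, median alpha %.3g>\n",
              nrow(x$fits), length(x$alpha_grid), length(x$sigma_grid),
              x$scale, stats::median(x$fits$alpha, na.rm = TRUE)))
  invisible(x)
}

#' Grid-search OU fit for a single block
#'
#' Single-block convenience wrapper around [fit_ou_grid()] that returns the
#' fitted parameters together with the full likelihood surface over the
#' lattice (useful for inspecting ridges and near-ties).
#'
#' @param y Named trait vector (names = tip labels).
#' @param tree A validated ultrametric `phylo`.
#' @inheritParams fit_ou_grid
#' @return List of class `ou_fit`: `alpha`, `sigma`, `theta`
#'   (ancestral/optimum), `loglik`, `degenerate`, `surface` (alpha x sigma
#'   log-likelihood matrix), `alpha_grid`, `sigma_grid`.
#' @export
grid_fit <- function(y, tree, grid = ou_grid()) {
  m <- matrix(y[tree$tip.label], nrow = 1,
              dimnames = list("block", tree$tip.label))
  gf <- fit_ou_grid(m, tree, grid = grid)
  f <- gf$fits[1L, ]
  structure(list(alpha = f$alpha, sigma = f$sigma,
                 theta = c(ancestral = f$theta_ancestral,
                           optimum = f$theta_optimum),
                 loglik = f$loglik, degenerate = f$degenerate,
                 surface = gf$cumulative_loglik,
                 alpha_grid = gf$alpha_grid, sigma_grid = gf$sigma_grid),
            class = "ou_fit")
}

#' Classify blocks into selection vs drift regimes
#'
#' Blocks whose fitted alpha sits at or below `alpha_threshold` (the grid
#' floor by default) are indistinguishable from Brownian drift; the rest show
#' mean reversion consistent with stabilising selection on TAD number. Also
#' reports the modal (alpha, sigma) combination across blocks.
#'
#' @param fit An `ou_grid_fit`.
#' @param alpha_threshold Drift threshold on fitted alpha (default 0.01, the
#'   default grid floor).
#' @return List of class `ou_classification`: `n_blocks`, `n_drift`,
#'   `n_selection`, `pct_drift`, `pct_selection`, `modal_alpha`,
#'   `modal_sigma`, `modal_count`, `alpha_threshold`.
#' @export
classify_blocks <- function(fit, alpha_threshold = 0.01) {
  f <- fit$fits[!is.na(fit$fits$loglik), ]
  assert_that(nrow(f) >= 1L, "no fitted blocks")
  drift <- f$alpha <= alpha_threshold
  combo <- paste(f$alpha, f$sigma, sep = "|")
  tab <- sort(table(combo), decreasing = TRUE)
  modal <- as.numeric(strsplit(names(tab)[1L], "|", fixed = TRUE)[[1L]])
  structure(list(n_blocks = nrow(f), n_drift = sum(drift),
                 n_selection = sum(!drift),
                 pct_drift = 100 * mean(drift),
                 pct_selection = 100 * mean(!drift),
                 modal_alpha = modal[1L], modal_sigma = modal[2L],
                 modal_count = as.integer(tab[1L]),
                 alpha_threshold = alpha_threshold),
            class = "ou_classification")
}

#' @export
print.ou_classification <- function(x, ...) {
  cat(sprintf(paste0("<ou_classification: %d blocks, %.2f%% selection / ",
                     "%.2f%% drift (alpha <= %g); modal (alpha, sigma) = ",
                     "(%.3g, %.3g)>\n"),
              x$n_blocks, x$pct_selection, x$pct_drift, x$alpha_threshold,
              x$modal_alpha, x$modal_sigma))
  invisible(x)
}
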
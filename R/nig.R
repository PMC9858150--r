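#' Normal-inverse-gamma parameter set
#'
#' Container for the hyperparameters of a p-variate normal-inverse-gamma
#' (NIG) law for a regression coefficient vector `theta` and error variance
#' `sigma2`: `sigma2 ~ IG(a, b)` and `theta | sigma2 ~ N_p(m, sigma2 * V)`.
#' The same structure describes a prior (`m0, V0, a0, b0`) or the posterior
#' it induces.
#'
#' @param m numeric location vector (length p).
#' @param V symmetric positive-definite p x p scale matrix.
#' @param a shape parameter, `a > 0`.
#' @param b rate parameter, `b > 0` (units of variance times shape).
#'
#' @return An object of class `"nig"`: a list with elements `m`, `V`, `a`,
#'   `b`, `p` and the upper Cholesky factor `V_chol` of `V`.
#' @examples
#' nig_prior(m = c(0, 0), V = diag(2), a = 3, b = 2)
#' @export
nig_prior <- function(m, V, a, b) {
  m <- as.numeric(m)
  p <- length(m)
  V <- as.matrix(V)
  if (p > 0L && (nrow(V) != p || ncol(V) != p))
    stop("V must be a ", p, " x ", p, " matrix", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("shape 'a' must be a positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("rate 'b' must be a positive number", call. = FALSE)
  if (p > 0L) {
    if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V))))
      stop("V must be symmetric", call. = FALSE)
    Vc <- .chol_pd(V, "scale matrix V")
  } else {
    V <- matrix(0, 0, 0)
    Vc <- matrix(0, 0, 0)
  }
  structure(list(m = m, V = .sym(V), V_chol = Vc, a = a, b = b, p = p),
            class = "nig")
}

#' Default weakly-informative prior
#'
#' The reference prior used throughout the simulation studies and the
#' worked real-data examples: `m0 = 0`, `V0 = I_p`, `a0 = 3`, `b0 = 2`.
#'
#' @param p number of regression coefficients.
#' @return A `"nig"` object.
#' @export
default_prior <- function(p) nig_prior(rep(0, p), diag(p), 3, 2)

#' @export
print.nig <- function(x, ...) {
  cat(sprintf("Normal-inverse-gamma parameters (p = %d)\n", x$p))
  cat("  m:", format(x$m, digits = 4), "\n")
  cat("  a:", format(x$a, digits = 6), "  b:", format(x$b, digits = 6), "\n")
  invisible(x)
}

.check_data <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite (no missing values)", call. = FALSE)
  if (nrow(X) != length(y))
    stop("nrow(X) must equal length(y)", call. = FALSE)
  if (nrow(X) < 1L || ncol(X) < 1L)
    stop("need n >= 1 observations and p >= 1 columns", call. = FALSE)
  list(X = X, y = y)
}

#' Conjugate posterior update for the normal linear model
#'
#' Combines a normal-inverse-gamma prior with the Gaussian likelihood of
#' `y = X theta + eps`, `eps ~ N_n(0, sigma2 I)`, giving the posterior
#' NIG parameters
#' \deqn{V^* = (V_0^{-1} + X'X)^{-1}, \quad m^* = V^*(V_0^{-1} m_0 + X'y),}
#' \deqn{a_1 = a_0 + n/2, \quad
#'       b_1 = b_0 + (m_0'V_0^{-1}m_0 + y'y - m^{*\prime}V^{*-1}m^*)/2.}
#'
#' @param prior a `"nig"` object with `p` matching `ncol(X)`.
#' @param X numeric design matrix (n x p).
#' @param y numeric response vector (length n).
#' @return A `"nig"` object holding the posterior parameters.
#' @examples
#' nig_update(nig_prior(0, 1, 3, 2), X = cbind(rep(1, 3)), y = 1:3)
#' @export
nig_update <- function(prior, X, y) {
  stopifnot(inherits(prior, "nig"))
  d <- .check_data(X, y)
  X <- d$X; y <- d$y
  n <- nrow(X)
  if (ncol(X) != prior$p)
    stop("ncol(X) must match the prior dimension p = ", prior$p, call. = FALSE)
  V0inv_m0 <- .chol_solve(prior$V_chol, prior$m)
  prec <- .sym(chol2inv(prior$V_chol) + crossprod(X))
  Rprec <- .chol_pd(prec, "posterior precision")
  mstar <- drop(.chol_solve(Rprec, V0inv_m0 + crossprod(X, y)))
  Vstar <- .sym(chol2inv(Rprec))
  a1 <- prior$a + n / 2
  # m*' V*^{-1} m* = m*' (V0^{-1} m0 + X'y) since V*^{-1} m* is that vector
  quad_star <- sum(mstar * (V0inv_m0 + crossprod(X, y)))
  b1 <- prior$b + (sum(prior$m * V0inv_m0) + sum(y^2) - quad_star) / 2
  stopifnot(b1 > 0)
  nig_prior(mstar, Vstar, a1, b1)
}

#' Condition a normal-inverse-gamma law on its last r coefficients
#'
#' For `theta = (theta1, theta2)` with `theta2` the LAST `r` coordinates,
#' returns the s-variate NIG law of `(theta1, sigma2) | theta2`:
#' location `m1 + V12 V22^{-1} (theta2 - m2)`, scale the Schur complement
#' `V11 - V12 V22^{-1} V21`, shape `a + r/2`, and rate
#' `b + (theta2 - m2)' V22^{-1} (theta2 - m2) / 2`. With `s = 0` (all
#' coefficients conditioned) the location/scale are empty and only the
#' updated shape/rate remain.
#'
#' @param params a `"nig"` object of dimension `p = s + r`.
#' @param r size of the conditioned (tested) block, `1 <= r <= p`.
#' @param theta2 value of the last `r` coordinates (default all zero).
#' @return A `"nig"` object of dimension `s = p - r`.
#' @export
nig_condition <- function(params, r, theta2 = rep(0, r)) {
  stopifnot(inherits(params, "nig"))
  p <- params$p
  if (!.is_count(r) || r > p)
    stop("r must be an integer in 1..p", call. = FALSE)
  r <- as.integer(r)
  s <- p - r
  theta2 <- as.numeric(theta2)
  if (length(theta2) != r) stop("theta2 must have length r = ", r, call. = FALSE)
  i1 <- seq_len(s)
  i2 <- s + seq_len(r)
  V22 <- params$V[i2, i2, drop = FALSE]
  R22 <- tryCatch(.chol_pd(V22, "V22 block"),
                  error = function(e) stop("V22 block numerically singular",
                                           call. = FALSE))
  dev <- theta2 - params$m[i2]
  q <- sum(.quad_inv(R22, dev))
  a_new <- params$a + r / 2
  b_new <- params$b + q / 2
  if (s == 0L) {
    out <- nig_prior(numeric(0), matrix(0, 0, 0), a_new, b_new)
    return(out)
  }
  V12 <- params$V[i1, i2, drop = FALSE]
  W <- t(.chol_solve(R22, t(V12)))            # V12 V22^{-1}
  m_cond <- params$m[i1] + drop(W %*% dev)
  V_cond <- .sym(params$V[i1, i1, drop = FALSE] - W %*% t(V12))
  nig_prior(m_cond, V_cond, a_new, b_new)
}

#' Normal-inverse-gamma log density
#'
#' Normalized joint log density of `(theta, sigma2)` under a NIG law:
#' the inverse-gamma density of `sigma2` times the `N_p(m, sigma2 V)`
#' density of `theta`. The exponent of `sigma2` is `-(a + p/2 + 1)`.
#'
#' @param theta numeric vector of length p, or an M x p matrix of points.
#' @param sigma2 positive scalar, or vector of length M.
#' @param params a `"nig"` object.
#' @param log if `TRUE` (default) return the log density.
#' @return Numeric vector of (log) density values.
#' @export
dnig <- function(theta, sigma2, params, log = TRUE) {
  stopifnot(inherits(params, "nig"))
  p <- params$p
  theta <- if (p == 0L) matrix(0, length(sigma2), 0) else
    if (is.matrix(theta)) theta else matrix(theta, ncol = p, byrow = FALSE,
                                            nrow = length(theta) / p)
  if (ncol(theta) != p) stop("theta must have p = ", p, " columns", call. = FALSE)
  sigma2 <- as.numeric(sigma2)
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("sigma2 must be positive and finite", call. = FALSE)
  if (nrow(theta) != length(sigma2))
    stop("theta rows and sigma2 length must agree", call. = FALSE)
  a <- params$a; b <- params$b
  K <- a * base::log(b) - lgamma(a) - (p / 2) * base::log(2 * pi) -
    (if (p > 0L) 0.5 * .logdet_chol(params$V_chol) else 0)
  q <- if (p > 0L) .quad_inv(params$V_chol, t(theta) - params$m) else
    rep(0, length(sigma2))
  ll <- K - (a + p / 2 + 1) * base::log(sigma2) - b / sigma2 - q / (2 * sigma2)
  if (log) ll else exp(ll)
}

#' Sample from a normal-inverse-gamma law
#'
#' Draws `sigma2 ~ IG(a, b)` then `theta | sigma2 ~ N_p(m, sigma2 V)`.
#'
#' @param n number of draws.
#' @param params a `"nig"` object.
#' @param seed optional integer seed (draws are identical for equal seeds).
#' @return A list with `theta` (n x p matrix) and `sigma2` (length-n vector).
#' @export
rnig <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "nig"), .is_count(n))
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- params$p
  sigma2 <- 1 / stats::rgamma(n, shape = params$a, rate = params$b)
  if (p == 0L) return(list(theta = matrix(0, n, 0), sigma2 = sigma2))
  Z <- matrix(stats::rnorm(n * p), nrow = p)
  theta <- t(params$m + t(params$V_chol) %*% Z * rep(sqrt(sigma2), each = p))
  list(theta = theta, sigma2 = sigma2)
}

#' Ordinary least squares estimate
#'
#' Solves the normal equations `(X'X) theta = X'y` by QR decomposition.
#'
#' @param X design matrix (n x p), full column rank.
#' @param y response vector.
#' @return Coefficient vector of length p.
#' @export
ols_fit <- function(X, y) {
  d <- .check_data(X, y)
  qrx <- qr(d$X)
  if (qrx$rank < ncol(d$X))
    stop("design matrix is rank deficient: X'X is singular", call. = FALSE)
  drop(qr.coef(qrx, d$y))
}

# Permute columns of a design/prior so that the tested coefficients come
# last (the block-conditioning convention). Returns permuted X, prior and
# the permutation used.
.move_tested_last <- function(X, prior, test_idx) {
  p <- ncol(X)
  test_idx <- sort(unique(as.integer(test_idx)))
  if (length(test_idx) < 1L || any(test_idx < 1L | test_idx > p))
    stop("tested indices must be in 1..p", call. = FALSE)
  keep <- setdiff(seq_len(p), test_idx)
  perm <- c(keep, test_idx)
  list(X = X[, perm, drop = FALSE],
       prior = nig_prior(prior$m[perm], prior$V[perm, perm, drop = FALSE],
                         prior$a, prior$b),
       perm = perm, r = length(test_idx))
}
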
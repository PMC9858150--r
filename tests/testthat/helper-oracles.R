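# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own code paths: densities are recomputed from scratch
# with dnorm/dgamma and integrals evaluated by adaptive quadrature.

# inverse-gamma density, coded independently of the package
ig_dens <- function(s2, a, b) s2^(-(a + 1)) * exp(-b / s2) * b^a / gamma(a)

# NIG joint density (p = 1) coded independently: IG(s2; a, b) * N(th; m, s2 V)
nig_dens_1d <- function(th, s2, m, V, a, b) {
  ig_dens(s2, a, b) * dnorm(th, m, sqrt(s2 * V))
}

# prior predictive density at y (n = 1, p = 1, design value x) by nested
# adaptive quadrature of the full hierarchy; under H the whole coefficient
# is pinned at zero and only sigma2 is integrated (conditional prior).
quad_predictive_a_1d <- function(y, x, m, V, a, b) {
  integrate(function(s2v) sapply(s2v, function(s2) {
    inner <- integrate(function(th) dnorm(y, x * th, sqrt(s2)) *
                         dnorm(th, m, sqrt(s2 * V)), -Inf, Inf,
                       rel.tol = 1e-10)$value
    inner * ig_dens(s2, a, b)
  }), 0, Inf, rel.tol = 1e-10)$value
}

quad_predictive_h_s0_1d <- function(y, aH, bH) {
  integrate(function(s2v) sapply(s2v, function(s2)
    dnorm(y, 0, sqrt(s2)) * ig_dens(s2, aH, bH)),
    0, Inf, rel.tol = 1e-10)$value
}

# semi-analytic e-value oracle for p = 1 posteriors: given sigma2 the
# tangential-set condition log f(theta, s2) > c is a quadratic constraint
# |theta - m| < sqrt(2 V s2 t(s2)), whose normal probability is
# 2 Phi(sqrt(2 t)) - 1; one adaptive integral over sigma2 remains. The
# integration range is clipped to extreme inverse-gamma quantiles so the
# adaptive rule cannot step over the (possibly narrow) high-density region.
quad_evalue_1d <- function(m, V, a, b, log_sup) {
  K <- a * log(b) - lgamma(a) - 0.5 * log(2 * pi) - 0.5 * log(V)
  t_margin <- function(s2) K - log_sup - (a + 3 / 2) * log(s2) - b / s2
  # t_margin is unimodal in sigma2 (single stationary point at b/(a+3/2));
  # bracket its positivity interval by root finding so the quadrature is
  # confined to where the integrand is nonzero
  s2_peak <- b / (a + 3 / 2)
  if (t_margin(s2_peak) <= 0) return(1)     # empty tangential set
  lo <- uniroot(t_margin, c(s2_peak * 1e-8, s2_peak), tol = 1e-14)$root
  hi <- uniroot(t_margin, c(s2_peak, s2_peak * 1e8), tol = 1e-14)$root
  tangent_prob <- integrate(function(s2v) sapply(s2v, function(s2) {
    t <- t_margin(s2)
    if (t <= 0) return(0)
    (2 * pnorm(sqrt(2 * t)) - 1) * ig_dens(s2, a, b)
  }), lo, hi, rel.tol = 1e-11, subdivisions = 2000L)$value
  1 - tangent_prob
}

# independent multivariate normal log pdf (factorization checks)
mvtnorm_logpdf <- function(x, mu, S) {
  k <- length(x)
  -0.5 * (k * log(2 * pi) + determinant(S)$modulus[1] +
            drop(t(x - mu) %*% solve(S, x - mu)))
}

# capital-P P-value oracle for n = 1 by dense Simpson quadrature of
# 1[log BF(y) <= log BF(y0)] fH(y) over a wide y grid
quad_pvalue_1d <- function(model, y0, half_width = 400, n_grid = 400001) {
  fh <- predictive_h(model); fa <- predictive_a(model)
  lbf0 <- log_bf(model, y0)
  ys <- seq(-half_width, half_width, length.out = n_grid)
  h <- ys[2] - ys[1]
  Y <- matrix(ys, nrow = 1)
  fh_d <- dmvt_spec(fh, Y, log = FALSE)
  ind <- (dmvt_spec(fh, Y) - dmvt_spec(fa, Y)) <= lbf0
  w <- rep(c(2, 4), length.out = n_grid); w[1] <- 1; w[n_grid] <- 1
  sum(w * fh_d * ind) * h / 3
}

# small random regression fixture
make_reg_data <- function(n = 25, p = 3, seed = 1, theta = NULL, sigma = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  if (is.null(theta)) theta <- rnorm(p)
  y <- drop(X %*% theta) + rnorm(n, sd = sigma)
  list(X = X, y = y, theta = theta)
}
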
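#' Sharp-null hypothesis model for regression coefficients
#'
#' Bundles a fixed design matrix `X`, a normal-inverse-gamma prior and the
#' size `r` of the tested block for the hypothesis pair
#' `H: theta2 = 0` vs `A: theta2 != 0`, where `theta2` holds the LAST `r`
#' regression coefficients (use [fbst()] / [pvalue_test()] on a fitted
#' model, or `.move_tested_last()` internals, to test arbitrary index sets).
#' The parameter-space dimensionality is `d = p + 1` (coefficients plus the
#' error variance).
#'
#' @param X numeric design matrix (n x p).
#' @param prior a `"nig"` prior of dimension p; default [default_prior()].
#' @param r number of tested coefficients (last r columns), `1 <= r <= p`.
#' @return An object of class `"hyp_model"`.
#' @examples
#' hypothesis_model(X = matrix(1, 10, 1), r = 1)  # intercept-only, d = 2
#' @export
hypothesis_model <- function(X, prior = NULL, r = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  p <- ncol(X)
  if (is.null(prior)) prior <- default_prior(p)
  stopifnot(inherits(prior, "nig"))
  if (prior$p != p) stop("prior dimension must match ncol(X)", call. = FALSE)
  if (!.is_count(r) || r > p) stop("r must be an integer in 1..p", call. = FALSE)
  structure(list(X = X, prior = prior, r = as.integer(r), s = p - as.integer(r),
                 n = nrow(X), p = p, d = p + 1L),
            class = "hyp_model")
}

#' @export
print.hyp_model <- function(x, ...) {
  cat(sprintf("Hypothesis model: n = %d, p = %d (d = %d), testing last %d coefficient(s) = 0\n",
              x$n, x$p, x$d, x$r))
  invisible(x)
}

#' Prior predictive density of the data under the null hypothesis
#'
#' Under `H: theta2 = 0` the data are marginally n-variate Student-t with
#' `df = 2 a_0 + r`, location `X_1 m_0^{1.2}(0)` and scale
#' `(b_H / a_H) (I_n + X_1 V_0^{11.2} X_1')`, where `X_1` is the first `s`
#' columns of `X`, `(m_0^{1.2}(0), V_0^{11.2}, a_H, b_H)` is the prior
#' conditioned on `theta2 = 0` (see [nig_condition()]). When `s = 0` the
#' location is zero and the scale is `(b_H / a_H) I_n`.
#'
#' @param model a [hypothesis_model()].
#' @return An [mvt_spec()] with structured scale.
#' @export
predictive_h <- function(model) {
  stopifnot(inherits(model, "hyp_model"))
  cond <- nig_condition(model$prior, model$r, rep(0, model$r))
  X1 <- model$X[, seq_len(model$s), drop = FALSE]
  loc <- if (model$s > 0L) drop(X1 %*% cond$m) else rep(0, model$n)
  mvt_spec(df = 2 * cond$a, loc = loc, c = cond$b / cond$a,
           U = X1, W = cond$V)
}

#' Prior predictive density of the data under the alternative
#'
#' Marginally `y ~ t_n(2 a_0; X m_0, (b_0 / a_0)(I_n + X V_0 X'))`.
#'
#' @param model a [hypothesis_model()].
#' @return An [mvt_spec()] with structured scale.
#' @export
predictive_a <- function(model) {
  stopifnot(inherits(model, "hyp_model"))
  pr <- model$prior
  mvt_spec(df = 2 * pr$a, loc = drop(model$X %*% pr$m), c = pr$b / pr$a,
           U = model$X, W = pr$V)
}

#' Log Bayes factor of the sharp null against the alternative
#'
#' `log BF(y) = log f_H(y) - log f_A(y)`, the log ratio of the two prior
#' predictive densities. The test `phi*` rejects H when `BF(y) <= b/a`.
#'
#' @param model a [hypothesis_model()].
#' @param y response vector (length n) or n x M matrix of datasets.
#' @return Numeric vector of log Bayes factors.
#' @export
log_bf <- function(model, y) {
  dmvt_spec(predictive_h(model), y) - dmvt_spec(predictive_a(model), y)
}

#' Simulate datasets from the prior predictive under H or A
#'
#' Hierarchical sampling. Under H (`sample_under_h`): `theta2 = 0`;
#' with `scheme = "sigma-first"` (default) `sigma2 ~ IG(a_H, b_H)` and
#' `theta1 | sigma2 ~ N(m_0^{1.2}(0), sigma2 V_0^{11.2})`; with
#' `scheme = "theta-first"` `theta1` is drawn from its marginal Student-t and
#' `sigma2 | theta` from its inverse-gamma conditional. The two schemes are
#' factorizations of the same joint law. Finally
#' `y | theta, sigma2 ~ N_n(X theta, sigma2 I)`. Under A
#' (`sample_under_a`): `sigma2 ~ IG(a_0, b_0)`,
#' `theta | sigma2 ~ N_p(m_0, sigma2 V_0)`, then the same likelihood draw.
#'
#' @param model a [hypothesis_model()].
#' @param n_sim number of replicate datasets.
#' @param seed optional integer seed.
#' @param scheme factorization used under H (see Details).
#' @return A list with `y` (n x n_sim matrix), `theta` (n_sim x p matrix of
#'   latent coefficients) and `sigma2` (length n_sim).
#' @export
sample_under_h <- function(model, n_sim, seed = NULL,
                           scheme = c("sigma-first", "theta-first")) {
  stopifnot(inherits(model, "hyp_model"), .is_count(n_sim))
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- model$s; r <- model$r; n <- model$n
  cond <- nig_condition(model$prior, r, rep(0, r))
  if (scheme == "sigma-first") {
    draws <- rnig(n_sim, cond)
    theta1 <- draws$theta
    sigma2 <- draws$sigma2
  } else {
    # theta1 marginal t_{2 aH}(m0^{1.2}, (bH/aH) V0^{11.2}), then sigma2 given theta
    if (s > 0L) {
      tspec <- mvt_spec(df = 2 * cond$a, loc = cond$m,
                        scale = (cond$b / cond$a) * cond$V)
      theta1 <- t(rmvt_spec(n_sim, tspec))
      dev <- t(theta1) - cond$m
      q <- .quad_inv(cond$V_chol, dev)
      sigma2 <- 1 / stats::rgamma(n_sim, shape = cond$a + s / 2,
                                  rate = cond$b + q / 2)
    } else {
      theta1 <- matrix(0, n_sim, 0)
      sigma2 <- 1 / stats::rgamma(n_sim, shape = cond$a, rate = cond$b)
    }
  }
  theta <- cbind(theta1, matrix(0, n_sim, r))
  X1 <- model$X[, seq_len(s), drop = FALSE]
  mu <- if (s > 0L) X1 %*% t(theta1) else matrix(0, n, n_sim)
  Y <- mu + matrix(stats::rnorm(n * n_sim), n, n_sim) *
    rep(sqrt(sigma2), each = n)
  list(y = Y, theta = theta, sigma2 = sigma2)
}

#' @rdname sample_under_h
#' @export
sample_under_a <- function(model, n_sim, seed = NULL) {
  stopifnot(inherits(model, "hyp_model"), .is_count(n_sim))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- model$n
  draws <- rnig(n_sim, model$prior)
  mu <- model$X %*% t(draws$theta)
  Y <- mu + matrix(stats::rnorm(n * n_sim), n, n_sim) *
    rep(sqrt(draws$sigma2), each = n)
  list(y = Y, theta = draws$theta, sigma2 = draws$sigma2)
}
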
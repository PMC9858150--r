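#' Bayesian linear regression with a normal-inverse-gamma prior
#'
#' Fits the normal linear model `y = X theta + eps`,
#' `eps ~ N_n(0, sigma2 I)`, by exact conjugate updating of a
#' normal-inverse-gamma prior on `(theta, sigma2)`. The posterior is again
#' normal-inverse-gamma with parameters given in [nig_update()].
#'
#' @param formula,data model formula and data frame (an intercept is included
#'   unless removed in the formula).
#' @param prior a `"nig"` prior of matching dimension, or `NULL` for
#'   [default_prior()] (`m0 = 0`, `V0 = I`, `a0 = 3`, `b0 = 2`).
#' @param x,y alternatively, a design matrix and response for
#'   `blm_fit()` (no formula processing, no intercept added).
#' @param ... unused.
#' @return An object of class `"blm"` with components `X`, `y`, `prior`,
#'   `posterior` (both `"nig"`), `coefficients` (posterior mean of `theta`),
#'   `sigma2_mean` (posterior mean of `sigma2`, `b1 / (a1 - 1)`), and the
#'   usual `call`/`terms` bookkeeping.
#' @examples
#' d <- data.frame(x = rnorm(20))
#' d$y <- 1 + 0.5 * d$x + rnorm(20)
#' fit <- blm(y ~ x, d)
#' coef(fit)
#' @export
blm <- function(formula, data, prior = NULL, ...) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  fit <- blm_fit(X, y, prior)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' @rdname blm
#' @export
blm_fit <- function(x, y, prior = NULL) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(prior)) prior <- default_prior(ncol(X))
  post <- nig_update(prior, X, y)
  coefs <- stats::setNames(post$m, colnames(X))
  structure(list(X = X, y = as.numeric(y), prior = prior, posterior = post,
                 coefficients = coefs,
                 sigma2_mean = post$b / (post$a - 1),
                 n = nrow(X), p = ncol(X), call = sys.call()),
            class = "blm")
}

#' @export
print.blm <- function(x, ...) {
  cat("Bayesian linear model (normal-inverse-gamma conjugate)\n")
  cat(sprintf("  n = %d, p = %d\n", x$n, x$p))
  cat("  Posterior mean coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.blm <- function(object, ...) object$coefficients

#' @export
fitted.blm <- function(object, ...) drop(object$X %*% object$coefficients)

#' @export
residuals.blm <- function(object, ...) object$y - fitted(object)

#' Posterior covariance of the coefficients
#'
#' `Var(theta | y) = E(sigma2 | y) * V* = (b1 / (a1 - 1)) V*` (finite for
#' `a1 > 1`).
#' @param object a `"blm"` fit.
#' @param ... unused.
#' @export
vcov.blm <- function(object, ...) {
  object$sigma2_mean * object$posterior$V
}

#' @export
summary.blm <- function(object, ...) {
  po <- object$posterior
  sd_theta <- sqrt(diag(object$sigma2_mean * po$V))
  tab <- cbind(`Post. mean` = object$coefficients,
               `Post. sd` = sd_theta,
               `OLS` = tryCatch(ols_fit(object$X, object$y),
                                error = function(e) rep(NA_real_, object$p)))
  structure(list(coefficients = tab, posterior = po, n = object$n,
                 p = object$p, sigma2_mean = object$sigma2_mean,
                 call = object$call),
            class = "summary.blm")
}

#' @export
print.summary.blm <- function(x, ...) {
  cat("Bayesian linear model, NIG posterior", sprintf(
    "(a1 = %.2f, b1 = %.4g)\n", x$posterior$a, x$posterior$b))
  print(round(x$coefficients, 4))
  cat(sprintf("Posterior mean of sigma2: %.4g\n", x$sigma2_mean))
  invisible(x)
}

#' Draw from the joint posterior of a fitted model
#'
#' @param object a `"blm"` fit.
#' @param nsim number of posterior draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with one row per draw: the coefficient draws and
#'   `sigma2`.
#' @export
simulate.blm <- function(object, nsim = 1, seed = NULL, ...) {
  dr <- rnig(nsim, object$posterior, seed = seed)
  out <- as.data.frame(dr$theta)
  names(out) <- names(object$coefficients)
  out$sigma2 <- dr$sigma2
  out
}

#' Posterior predictive distribution at new design points
#'
#' The posterior predictive of `y_new` at design `Xnew` is multivariate
#' Student-t with `df = 2 a_1`, location `Xnew m*` and scale
#' `(b_1 / a_1)(I + Xnew V* Xnew')`.
#'
#' @param object a `"blm"` fit.
#' @param newdata data frame (formula fits) or design matrix.
#' @param interval if `"predictive"`, adds equal-tailed `level` predictive
#'   bounds from the marginal Student-t.
#' @param level coverage for the interval.
#' @param ... unused.
#' @return Vector of predictive means, or a matrix with `fit`, `lwr`, `upr`.
#' @export
predict.blm <- function(object, newdata = NULL,
                        interval = c("none", "predictive"), level = 0.95, ...) {
  interval <- match.arg(interval)
  Xn <- if (is.null(newdata)) object$X
  else if (is.matrix(newdata)) newdata
  else stats::model.matrix(stats::delete.response(object$terms),
                           stats::model.frame(stats::delete.response(object$terms), newdata))
  po <- object$posterior
  mu <- drop(Xn %*% po$m)
  if (interval == "none") return(mu)
  scale_diag <- (po$b / po$a) * (1 + rowSums((Xn %*% po$V) * Xn))
  tq <- stats::qt(1 - (1 - level) / 2, df = 2 * po$a)
  half <- tq * sqrt(scale_diag)
  cbind(fit = mu, lwr = mu - half, upr = mu + half)
}

#' Residual diagnostic plot
#'
#' Plots residuals (about the posterior mean fit) against fitted values.
#' @param x a `"blm"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.blm <- function(x, ...) {
  graphics::plot(fitted(x), residuals(x),
                 xlab = "Fitted values (posterior mean)",
                 ylab = "Residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
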
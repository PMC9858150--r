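#' Supremum of the posterior density over the null set
#'
#' For the sharp null `H: theta2 = 0`, the posterior restricted to H is
#' maximized at `theta1_hat = m*^{1.2}(0)` (the posterior location
#' conditioned on `theta2 = 0`) and
#' `sigma2_hat = b' / (a' + 1 + s/2)`, where `(a', b')` are the shape/rate
#' of the conditioned posterior, i.e.
#' `sigma2_hat = (b_1 + m*_2' (V*_{22})^{-1} m*_2 / 2) / (a_1 + r/2 + 1 + s/2)`.
#'
#' @param post posterior `"nig"` object (from [nig_update()]).
#' @param r number of tested (last) coefficients.
#' @return A list of class `"sup_h"`: `theta1_hat`, `sigma2_hat`,
#'   `log_density` (posterior log density at the constrained maximizer).
#' @export
sup_under_h <- function(post, r) {
  stopifnot(inherits(post, "nig"))
  s <- post$p - r
  cond <- nig_condition(post, r, rep(0, r))
  sigma2_hat <- cond$b / (cond$a + 1 + s / 2)
  theta_hat <- c(cond$m, rep(0, r))
  ld <- dnig(theta_hat, sigma2_hat, post)
  structure(list(theta1_hat = cond$m, sigma2_hat = sigma2_hat,
                 log_density = as.numeric(ld)),
            class = "sup_h")
}

# Vectorized e-value core. Given the posterior (a1, b1, chol(V*)), the
# posterior log density at the constrained supremum, and M, draw M posterior
# samples and return 1 - frac(log posterior density STRICTLY above the sup).
# Draws are generated in standardized form, so the density at a draw is
# K - (a1 + p/2 + 1) log s2 - b1/s2 - z'z/2 with z the standard-normal
# innovations -- no solves needed.
.evalue_core <- function(a1, b1, V_chol, log_sup, M) {
  p <- ncol(V_chol)
  K <- a1 * base::log(b1) - lgamma(a1) - (p / 2) * base::log(2 * pi) -
    0.5 * .logdet_chol(V_chol)
  sigma2 <- 1 / stats::rgamma(M, shape = a1, rate = b1)
  q <- if (p > 0L) colSums(matrix(stats::rnorm(p * M), p, M)^2) else rep(0, M)
  ld <- K - (a1 + p / 2 + 1) * base::log(sigma2) - b1 / sigma2 - q / 2
  1 - mean(ld > log_sup)
}

#' Monte Carlo e-value of the FBST
#'
#' Evidence in favor of the sharp null `H: theta2 = 0`: one minus the
#' posterior probability of the tangential set (the points whose posterior
#' density strictly exceeds the supremum of the posterior density over H),
#' estimated from `M` posterior draws. Small e-values discredit H.
#'
#' @param post posterior `"nig"` object.
#' @param r number of tested (last) coefficients.
#' @param M Monte Carlo sample size (default 1000).
#' @param seed optional integer seed; identical seeds give identical results.
#' @return An object of class `"evalue"`: list with `evalue`, `mc_se`
#'   (binomial standard error `sqrt(ev (1 - ev) / M)`), `M`, `seed`, and the
#'   `"sup_h"` object used.
#' @export
evalue <- function(post, r, M = 1000, seed = NULL) {
  stopifnot(inherits(post, "nig"), .is_count(M))
  if (!is.null(seed)) set.seed(as.integer(seed))
  sup <- sup_under_h(post, r)
  ev <- .evalue_core(post$a, post$b, post$V_chol, sup$log_density, M)
  structure(list(evalue = ev, mc_se = sqrt(ev * (1 - ev) / M),
                 M = as.integer(M), seed = seed, sup = sup),
            class = "evalue")
}

#' @export
print.evalue <- function(x, ...) {
  cat(sprintf("FBST e-value: %.4f (MC se %.4f, M = %d)\n",
              x$evalue, x$mc_se, x$M))
  invisible(x)
}

#' FBST decision rule
#'
#' The test `phi_e` rejects H when the e-value does not exceed the cutoff:
#' `reject  <=>  ev <= kstar` (inclusive at the boundary).
#'
#' @param ev an `"evalue"` object or a numeric e-value in `[0, 1]`.
#' @param kstar cutoff in `[0, 1]` (see [adaptive_cutoff()]).
#' @return Logical: `TRUE` to reject H.
#' @export
fbst_decision <- function(ev, kstar) {
  e <- if (inherits(ev, "evalue")) ev$evalue else as.numeric(ev)
  stopifnot(is.finite(e), is.finite(kstar))
  e <= kstar
}

#' Full Bayesian significance test on a fitted model
#'
#' Tests the sharp null that the selected coefficients are all zero, by
#' computing the FBST e-value from the posterior of a [blm()] fit. The
#' selected columns are internally permuted to the last block (prior rows
#' and columns are permuted consistently), under which the posterior is
#' equivariant.
#'
#' @param fit a [blm()] object.
#' @param test coefficients to test jointly: integer indices or names
#'   (default: all coefficients except an `"(Intercept)"` column, or all
#'   coefficients if that is the only one).
#' @param M Monte Carlo sample size for the e-value.
#' @param kstar optional e-value cutoff; if supplied the decision is
#'   reported against it.
#' @param seed optional integer seed.
#' @return An object of class `"fbst_test"`.
#' @export
fbst <- function(fit, test = NULL, M = 1000, kstar = NULL, seed = NULL) {
  stopifnot(inherits(fit, "blm"))
  idx <- .resolve_test_idx(fit, test)
  pm <- .move_tested_last(fit$X, fit$prior, idx)
  post <- nig_update(pm$prior, pm$X, fit$y)
  ev <- evalue(post, pm$r, M = M, seed = seed)
  structure(list(evalue = ev$evalue, mc_se = ev$mc_se, M = ev$M,
                 seed = seed, tested = colnames(fit$X)[idx], index = idx,
                 kstar = kstar,
                 reject = if (is.null(kstar)) NA else fbst_decision(ev, kstar)),
            class = "fbst_test")
}

#' @export
print.fbst_test <- function(x, ...) {
  cat("Full Bayesian significance test (FBST)\n")
  cat("  H: ", paste(x$tested, collapse = ", "), " = 0\n", sep = "")
  cat(sprintf("  e-value: %.4f (MC se %.4f, M = %d)\n", x$evalue, x$mc_se, x$M))
  if (!is.null(x$kstar))
    cat(sprintf("  cutoff k*: %.4f -> %s H\n", x$kstar,
                if (isTRUE(x$reject)) "reject" else "accept"))
  invisible(x)
}

.resolve_test_idx <- function(fit, test) {
  nm <- colnames(fit$X)
  if (is.null(test)) {
    idx <- which(nm != "(Intercept)")
    if (length(idx) == 0L) idx <- seq_along(nm)
  } else if (is.character(test)) {
    idx <- match(test, nm)
    if (anyNA(idx)) stop("unknown coefficient name(s): ",
                         paste(test[is.na(idx)], collapse = ", "), call. = FALSE)
  } else idx <- as.integer(test)
  idx
}
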
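#' Monte Carlo e-value error curves under the two predictive densities
#'
#' Draws `M_outer` datasets from the prior predictive under H and `M_outer`
#' under A (design held fixed), computes each dataset's posterior and FBST
#' e-value with `M_inner` posterior draws, and returns the two e-value
#' samples together with the induced averaged error-probability step
#' functions
#' `alpha(k) = frac(ev_H <= k)` (type I) and
#' `beta(k)  = frac(ev_A >  k)` (type II).
#'
#' The master `seed` is split into independent sub-streams for the H data,
#' the A data, and the per-dataset inner e-value draws, so results are a
#' pure function of `(model, M_outer, M_inner, seed)`.
#'
#' @param model a [hypothesis_model()].
#' @param M_outer number of replicate datasets per hypothesis.
#' @param M_inner posterior draws per e-value.
#' @param seed integer master seed.
#' @return An object of class `"error_curve"`: sorted `ev_H`, `ev_A`, plus
#'   the inputs.
#' @export
error_curves <- function(model, M_outer = 1000, M_inner = 1000, seed = NULL) {
  stopifnot(inherits(model, "hyp_model"), .is_count(M_outer), .is_count(M_inner))
  seeds <- if (is.null(seed)) NULL else .split_seed(seed, 4)
  YH <- sample_under_h(model, M_outer, seed = seeds[1])$y
  YA <- sample_under_a(model, M_outer, seed = seeds[2])$y
  ev_H <- .evalues_fixed_design(model, YH, M_inner, seed = seeds[3])
  ev_A <- .evalues_fixed_design(model, YA, M_inner, seed = seeds[4])
  structure(list(ev_H = sort(ev_H), ev_A = sort(ev_A),
                 M_outer = as.integer(M_outer), M_inner = as.integer(M_inner),
                 seed = seed, n = model$n, d = model$d, r = model$r),
            class = "error_curve")
}

# Batch e-values for many datasets sharing one design. The posterior scale
# V* and shape a1 are common to all datasets; only m* and b1 vary with y.
# The constrained-supremum log density uses the identity
# (theta_hat - m*)' V*^{-1} (theta_hat - m*) = m*_2' (V*_22)^{-1} m*_2.
.evalues_fixed_design <- function(model, Y, M_inner, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  X <- model$X; prior <- model$prior
  n <- nrow(X); p <- ncol(X); r <- model$r; s <- model$s
  prec <- .sym(chol2inv(prior$V_chol) + crossprod(X))
  Rprec <- .chol_pd(prec, "posterior precision")
  Vstar <- .sym(chol2inv(Rprec))
  Vc <- .chol_pd(Vstar, "V*")
  a1 <- prior$a + n / 2
  V0inv_m0 <- .chol_solve(prior$V_chol, prior$m)
  c0 <- sum(prior$m * V0inv_m0)
  B <- V0inv_m0 + crossprod(X, Y)              # p x M: V*^{-1} m* per dataset
  Mstar <- .chol_solve(Rprec, B)               # p x M posterior locations
  b1 <- prior$b + (c0 + colSums(Y^2) - colSums(Mstar * B)) / 2
  i2 <- s + seq_len(r)
  R22 <- .chol_pd(Vstar[i2, i2, drop = FALSE], "V*22")
  q_sup <- .quad_inv(R22, Mstar[i2, , drop = FALSE])   # m*2' V*22^{-1} m*2
  s2_hat <- (b1 + q_sup / 2) / (a1 + r / 2 + 1 + s / 2)
  logdet_half <- 0.5 * .logdet_chol(Vc)
  K <- a1 * base::log(b1) - lgamma(a1) - (p / 2) * base::log(2 * pi) - logdet_half
  log_sup <- K - (a1 + p / 2 + 1) * base::log(s2_hat) - b1 / s2_hat -
    q_sup / (2 * s2_hat)
  M <- ncol(Y)
  ev <- numeric(M)
  for (j in seq_len(M)) {
    sigma2 <- 1 / stats::rgamma(M_inner, shape = a1, rate = b1[j])
    qz <- colSums(matrix(stats::rnorm(p * M_inner), p, M_inner)^2)
    ld <- K[j] - (a1 + p / 2 + 1) * base::log(sigma2) - b1[j] / sigma2 - qz / 2
    ev[j] <- 1 - mean(ld > log_sup[j])
  }
  ev
}

#' Averaged error probabilities at a cutoff
#'
#' Step functions induced by an [error_curves()] object:
#' `alpha_hat(k)` is the fraction of null-predictive e-values at or below
#' `k` (averaged type-I error of the FBST test with cutoff `k`);
#' `beta_hat(k)` is the fraction of alternative-predictive e-values above
#' `k` (averaged type-II error).
#'
#' @param curve an `"error_curve"` object.
#' @param k cutoff value(s) in `[0, 1]`.
#' @return Numeric vector of error probabilities.
#' @export
alpha_hat <- function(curve, k) {
  stopifnot(inherits(curve, "error_curve"))
  vapply(k, function(kk) mean(curve$ev_H <= kk), numeric(1))
}

#' @rdname alpha_hat
#' @export
beta_hat <- function(curve, k) {
  stopifnot(inherits(curve, "error_curve"))
  vapply(k, function(kk) mean(curve$ev_A > kk), numeric(1))
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf("FBST error curves: n = %d, d = %d, M_outer = %d, M_inner = %d\n",
              x$n, x$d, x$M_outer, x$M_inner))
  invisible(x)
}

#' Plot averaged error probabilities against the cutoff
#'
#' Draws `alpha(k)`, `beta(k)` and their weighted sum as functions of the
#' e-value cutoff `k`.
#' @param x an `"error_curve"` object.
#' @param a,b error weights.
#' @param ... passed to [graphics::plot()].
#' @export
plot.error_curve <- function(x, a = 1, b = 1, ...) {
  k <- sort(unique(c(0, x$ev_H, x$ev_A, 1)))
  al <- alpha_hat(x, k); be <- beta_hat(x, k)
  graphics::plot(k, a * al + b * be, type = "s", ylim = c(0, max(a + b, 1)),
                 xlab = "cutoff k", ylab = "averaged error probability", ...)
  graphics::lines(k, al, type = "s", lty = 2)
  graphics::lines(k, be, type = "s", lty = 3)
  graphics::legend("top", legend = c("a*alpha + b*beta", "alpha", "beta"),
                   lty = 1:3, bty = "n")
  invisible(x)
}

#' Adaptive e-value cutoff k*
#'
#' Minimizes `a * alpha(k) + b * beta(k)` exactly over the finite candidate
#' set `{0} U ev_H U ev_A` (the Monte Carlo objective is piecewise constant
#' with jumps only at sample e-values); ties are broken by the smallest `k`.
#'
#' @param curve an [error_curves()] object.
#' @param a,b positive weights on the type-I and type-II averaged errors.
#' @return A list of class `"kstar"`: `kstar`, `alpha` (= `alpha_hat(kstar)`),
#'   `beta`, `objective`, binomial standard errors `se_alpha`, `se_beta`, and
#'   the Monte Carlo sizes.
#' @export
find_kstar <- function(curve, a = 1, b = 1) {
  stopifnot(inherits(curve, "error_curve"), a > 0, b > 0)
  cand <- sort(unique(c(0, curve$ev_H, curve$ev_A)))
  MH <- length(curve$ev_H); MA <- length(curve$ev_A)
  # counts via findInterval on the sorted samples (ev <= k and ev > k)
  nH <- findInterval(cand, curve$ev_H)          # ev_H <= k
  nA <- MA - findInterval(cand, curve$ev_A)     # ev_A >  k
  obj <- a * nH / MH + b * nA / MA
  best <- which(obj <= min(obj) + 1e-12)[1]
  al <- nH[best] / MH; be <- nA[best] / MA
  structure(list(kstar = cand[best], alpha = al, beta = be,
                 objective = obj[best],
                 se_alpha = sqrt(al * (1 - al) / MH),
                 se_beta = sqrt(be * (1 - be) / MA),
                 a = a, b = b, M_outer = curve$M_outer,
                 M_inner = curve$M_inner, seed = curve$seed),
            class = "kstar")
}

#' @export
print.kstar <- function(x, ...) {
  cat(sprintf("Adaptive e-value cutoff k* = %.4f (alpha = %.4f, beta = %.4f)\n",
              x$kstar, x$alpha, x$beta))
  invisible(x)
}

#' Adaptive cutoff for a hypothesis model or fitted model (one call)
#'
#' Convenience wrapper: [error_curves()] followed by [find_kstar()]. Accepts
#' either a [hypothesis_model()] or a [blm()] fit together with the tested
#' coefficients (as in [fbst()]), in which case the fit's design and prior
#' are used with the tested columns permuted last.
#'
#' @param model a `"hyp_model"` or a `"blm"` fit.
#' @param test for a `"blm"` fit: coefficients defining the sharp null (see
#'   [fbst()]); ignored for a `"hyp_model"`.
#' @inheritParams error_curves
#' @inheritParams find_kstar
#' @return A `"kstar"` object.
#' @export
adaptive_cutoff <- function(model, test = NULL, M_outer = 1000,
                            M_inner = 1000, a = 1, b = 1, seed = NULL) {
  if (inherits(model, "blm")) {
    idx <- .resolve_test_idx(model, test)
    pm <- .move_tested_last(model$X, model$prior, idx)
    model <- hypothesis_model(pm$X, pm$prior, r = pm$r)
  }
  find_kstar(error_curves(model, M_outer, M_inner, seed), a = a, b = b)
}

#' Capital-P P-value of the Bayes-factor test
#'
#' The P-value at observed data `y0` is the probability, under the null
#' prior predictive `f_H`, that the Bayes factor is at most `BF(y0)`:
#' the integral of `f_H` over `{y : BF(y) <= BF(y0)}`, estimated by Monte
#' Carlo with `M` draws from `f_H`.
#'
#' @param model a [hypothesis_model()].
#' @param y0 observed response vector (length n).
#' @param M number of predictive draws.
#' @param seed optional integer seed.
#' @return A list of class `"pvalue"`: `pvalue`, `mc_se`, `log_bf0`, `M`.
#' @export
pvalue <- function(model, y0, M = 1000, seed = NULL) {
  stopifnot(inherits(model, "hyp_model"), .is_count(M))
  y0 <- as.numeric(y0)
  if (length(y0) != model$n) stop("y0 must have length n = ", model$n,
                                  call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fh <- predictive_h(model); fa <- predictive_a(model)
  lbf0 <- as.numeric(dmvt_spec(fh, y0) - dmvt_spec(fa, y0))
  Y <- sample_under_h(model, M)$y
  lbf <- dmvt_spec(fh, Y) - dmvt_spec(fa, Y)
  pv <- mean(lbf <= lbf0)
  structure(list(pvalue = pv, mc_se = sqrt(pv * (1 - pv) / M),
                 log_bf0 = lbf0, M = as.integer(M), seed = seed),
            class = "pvalue")
}

#' @export
print.pvalue <- function(x, ...) {
  cat(sprintf("P-value: %.4f (MC se %.4f, M = %d; log BF(y0) = %.3f)\n",
              x$pvalue, x$mc_se, x$M, x$log_bf0))
  invisible(x)
}

#' Optimal averaged error probabilities of the Bayes-factor test
#'
#' The generalized Neyman-Pearson optimal test `phi*` rejects H when
#' `BF(y) <= b/a`. Its averaged error probabilities are
#' `alpha* = P_{f_H}(BF <= b/a)` and `beta* = P_{f_A}(BF > b/a)`, estimated
#' with `M` Monte Carlo draws from each predictive. `alpha*` is the adaptive
#' significance level against which the P-value is compared.
#'
#' @param model a [hypothesis_model()].
#' @param a,b positive error weights (only `b/a` matters).
#' @param M Monte Carlo draws per hypothesis.
#' @param seed optional integer master seed.
#' @return A list of class `"optimal_rates"`: `alpha_star`, `beta_star`,
#'   `objective` (`a*alpha + b*beta`), binomial standard errors, `M`.
#' @export
optimal_error_rates <- function(model, a = 1, b = 1, M = 1000, seed = NULL) {
  stopifnot(inherits(model, "hyp_model"), .is_count(M), a > 0, b > 0)
  seeds <- if (is.null(seed)) NULL else .split_seed(seed, 2)
  fh <- predictive_h(model); fa <- predictive_a(model)
  thr <- base::log(b / a)
  YH <- sample_under_h(model, M, seed = seeds[1])$y
  lbf_H <- dmvt_spec(fh, YH) - dmvt_spec(fa, YH)
  YA <- sample_under_a(model, M, seed = seeds[2])$y
  lbf_A <- dmvt_spec(fh, YA) - dmvt_spec(fa, YA)
  al <- mean(lbf_H <= thr)
  be <- mean(lbf_A > thr)
  structure(list(alpha_star = al, beta_star = be,
                 objective = a * al + b * be,
                 se_alpha = sqrt(al * (1 - al) / M),
                 se_beta = sqrt(be * (1 - be) / M),
                 a = a, b = b, M = as.integer(M), seed = seed),
            class = "optimal_rates")
}

#' @export
print.optimal_rates <- function(x, ...) {
  cat(sprintf("Optimal averaged errors: alpha* = %.4f, beta* = %.4f (M = %d)\n",
              x$alpha_star, x$beta_star, x$M))
  invisible(x)
}

#' P-value decision rule
#'
#' The test rejects H when the P-value is STRICTLY below the adaptive
#' significance level `alpha*`.
#'
#' @param pv a `"pvalue"` object or numeric P-value.
#' @param alpha_star adaptive significance level (see
#'   [optimal_error_rates()]).
#' @return Logical: `TRUE` to reject H.
#' @export
pvalue_decision <- function(pv, alpha_star) {
  p <- if (inherits(pv, "pvalue")) pv$pvalue else as.numeric(pv)
  stopifnot(is.finite(p), is.finite(alpha_star))
  p < alpha_star
}

#' Bayes-factor significance test on a fitted model
#'
#' Computes the capital-P P-value for the sharp null that the selected
#' coefficients are zero, together with the adaptive significance level
#' `alpha*` and the resulting decision.
#'
#' @inheritParams fbst
#' @param a,b error weights.
#' @param M Monte Carlo draws (used both for the P-value and for `alpha*`).
#' @return An object of class `"pvalue_test"`.
#' @export
pvalue_test <- function(fit, test = NULL, a = 1, b = 1, M = 1000, seed = NULL) {
  stopifnot(inherits(fit, "blm"))
  idx <- .resolve_test_idx(fit, test)
  pm <- .move_tested_last(fit$X, fit$prior, idx)
  model <- hypothesis_model(pm$X, pm$prior, r = pm$r)
  seeds <- if (is.null(seed)) NULL else .split_seed(seed, 2)
  pv <- pvalue(model, fit$y, M = M, seed = seeds[1])
  opt <- optimal_error_rates(model, a = a, b = b, M = M, seed = seeds[2])
  structure(list(pvalue = pv$pvalue, mc_se = pv$mc_se,
                 alpha_star = opt$alpha_star, beta_star = opt$beta_star,
                 log_bf0 = pv$log_bf0, M = as.integer(M), seed = seed,
                 tested = colnames(fit$X)[idx], index = idx,
                 reject = pvalue_decision(pv$pvalue, opt$alpha_star)),
            class = "pvalue_test")
}

#' @export
print.pvalue_test <- function(x, ...) {
  cat("Bayes-factor significance test (capital-P P-value)\n")
  cat("  H: ", paste(x$tested, collapse = ", "), " = 0\n", sep = "")
  cat(sprintf("  P-value: %.4f, adaptive alpha*: %.4f -> %s H\n",
              x$pvalue, x$alpha_star,
              if (x$reject) "reject" else "accept"))
  invisible(x)
}
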
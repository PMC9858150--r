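#' Multivariate Student-t specification
#'
#' Describes an n-variate Student-t density with `df` degrees of freedom,
#' location `loc` and scale matrix `Sigma`. The scale can be given either
#' in full (`scale =`), or in the structured form
#' `Sigma = c * (I_n + U W U')` (`c`, `U`, `W`) that the prior predictive
#' densities of the conjugate linear model take; the structured form is
#' evaluated with the Woodbury identity and the matrix determinant lemma so
#' the cost is O(n q^2) for a rank-q update rather than O(n^3).
#'
#' @param df degrees of freedom (> 0).
#' @param loc location vector (length n).
#' @param scale optional full n x n symmetric positive-definite scale matrix.
#' @param c,U,W optional structured scale: positive scalar `c`, n x q matrix
#'   `U`, and q x q symmetric positive-definite `W` (`q = 0` allowed, giving
#'   `Sigma = c I_n`).
#' @return An object of class `"mvt_spec"`.
#' @export
mvt_spec <- function(df, loc, scale = NULL, c = NULL, U = NULL, W = NULL) {
  loc <- as.numeric(loc)
  n <- length(loc)
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df <= 0)
    stop("df must be a positive number", call. = FALSE)
  if (!is.null(scale)) {
    scale <- .sym(as.matrix(scale))
    if (nrow(scale) != n) stop("scale dimension must match loc", call. = FALSE)
    R <- .chol_pd(scale, "scale matrix")
    obj <- list(df = df, loc = loc, n = n, form = "full",
                scale = scale, scale_chol = R)
  } else {
    if (is.null(c)) stop("either 'scale' or ('c','U','W') must be given",
                         call. = FALSE)
    if (!is.numeric(c) || length(c) != 1L || c <= 0)
      stop("'c' must be a positive scalar", call. = FALSE)
    U <- if (is.null(U)) matrix(0, n, 0) else as.matrix(U)
    q <- ncol(U)
    W <- if (is.null(W) || q == 0L) matrix(0, q, q) else .sym(as.matrix(W))
    if (nrow(U) != n || nrow(W) != q || ncol(W) != q)
      stop("inconsistent structured-scale dimensions", call. = FALSE)
    if (q > 0L) {
      Wc <- .chol_pd(W, "W")
      # (I + U W U')^{-1} = I - U (W^{-1} + U'U)^{-1} U'   (Woodbury)
      Winv <- chol2inv(Wc)
      M <- .sym(Winv + crossprod(U))
      Mc <- .chol_pd(M, "Woodbury core")
      # log|I + U W U'| = log|W| + log|W^{-1} + U'U|
      logdet_core <- .logdet_chol(Wc) + .logdet_chol(Mc)
    } else {
      Wc <- W; Mc <- matrix(0, 0, 0); logdet_core <- 0
    }
    obj <- list(df = df, loc = loc, n = n, form = "lowrank",
                c = c, U = U, W = W, W_chol = Wc, core_chol = Mc,
                logdet = n * base::log(c) + logdet_core)
  }
  structure(obj, class = "mvt_spec")
}

# quadratic form z' Sigma^{-1} z for columns of Z (n x M)
.mvt_quad <- function(spec, Z) {
  if (spec$form == "full") {
    .quad_inv(spec$scale_chol, Z)
  } else {
    base_q <- colSums(Z^2)
    if (ncol(spec$U) > 0L) {
      UZ <- crossprod(spec$U, Z)
      base_q <- base_q - .quad_inv(spec$core_chol, UZ)
    }
    base_q / spec$c
  }
}

.mvt_logdet <- function(spec) {
  if (spec$form == "full") .logdet_chol(spec$scale_chol) else spec$logdet
}

#' Multivariate Student-t log density
#'
#' @param spec an [mvt_spec()] object.
#' @param y numeric vector of length n, or an n x M matrix of column vectors.
#' @param log if `TRUE` (default) return log densities.
#' @return Numeric vector of length M.
#' @export
dmvt_spec <- function(spec, y, log = TRUE) {
  stopifnot(inherits(spec, "mvt_spec"))
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (nrow(Y) != spec$n) stop("y must have length/rows n = ", spec$n,
                              call. = FALSE)
  nu <- spec$df; n <- spec$n
  q <- .mvt_quad(spec, Y - spec$loc)
  ll <- lgamma((nu + n) / 2) - lgamma(nu / 2) - (n / 2) * base::log(nu * pi) -
    0.5 * .mvt_logdet(spec) - ((nu + n) / 2) * log1p(q / nu)
  if (log) ll else exp(ll)
}

#' Sample from a multivariate Student-t specification
#'
#' Uses the scale-mixture representation: `g ~ df / chi^2_df`, then
#' `y = loc + sqrt(g) * L z` with `Sigma = L L'`.
#'
#' @param n number of draws.
#' @param spec an [mvt_spec()] object.
#' @param seed optional integer seed.
#' @return An `spec$n` x `n` matrix; each column is one draw.
#' @export
rmvt_spec <- function(n, spec, seed = NULL) {
  stopifnot(inherits(spec, "mvt_spec"), .is_count(n))
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- spec$df / stats::rchisq(n, df = spec$df)
  Z <- matrix(stats::rnorm(spec$n * n), nrow = spec$n)
  if (spec$form == "full") {
    E <- t(spec$scale_chol) %*% Z
  } else {
    E <- Z
    if (ncol(spec$U) > 0L) {
      Wh <- matrix(stats::rnorm(ncol(spec$U) * n), nrow = ncol(spec$U))
      E <- E + spec$U %*% (t(spec$W_chol) %*% Wh)
    }
    E <- sqrt(spec$c) * E
  }
  spec$loc + E * rep(sqrt(g), each = spec$n)
}

#' @export
print.mvt_spec <- function(x, ...) {
  cat(sprintf("%d-variate Student-t: df = %g, %s scale\n", x$n, x$df, x$form))
  invisible(x)
}
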
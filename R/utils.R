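# internal helpers: linear algebra and seed management

# symmetrize before factorizing; guards against drift from repeated updates
.sym <- function(A) (A + t(A)) / 2

# Cholesky with a package-level error message; A must be symmetric PD
.chol_pd <- function(A, what = "matrix") {
  A <- .sym(as.matrix(A))
  R <- tryCatch(chol(A), error = function(e) {
    stop(sprintf("%s is not positive definite (Cholesky failed): %s",
                 what, conditionMessage(e)), call. = FALSE)
  })
  R
}

# log|A| from an upper-triangular Cholesky factor R (A = R'R)
.logdet_chol <- function(R) 2 * sum(log(diag(R)))

# solve A x = b given chol factor R of A
.chol_solve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

# quadratic form x' A^{-1} x (columns of x) given chol factor R of A
.quad_inv <- function(R, x) {
  x <- as.matrix(x)
  z <- backsolve(R, x, transpose = TRUE)
  colSums(z^2)
}

# Split one master seed into n reproducible sub-seeds (31-bit, R-safe).
# Every exported stochastic function takes a single seed and derives the
# streams it needs through this rule, so runs are exactly reproducible.
.split_seed <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

.is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
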
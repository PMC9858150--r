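#' Design matrix generator for the simulation study
#'
#' Builds the fixed design used by the simulation scenarios: a column of
#' ones followed by `d - 2` independent standard-normal covariate columns,
#' where `d = p + 1` is the parameter-space dimensionality (coefficients
#' plus variance). `d = 2` gives the intercept-only design `X = 1_n`.
#'
#' @param n number of observations.
#' @param d parameter-space dimensionality (`d >= 2`).
#' @param seed optional integer seed (the design is seed-deterministic).
#' @return An `n x (d - 1)` design matrix.
#' @export
generate_design <- function(n, d, seed = NULL) {
  stopifnot(.is_count(n), .is_count(d), d >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- d - 1L
  X <- cbind(rep(1, n),
             if (p > 1L) matrix(stats::rnorm(n * (p - 1L)), n, p - 1L))
  colnames(X) <- c("(Intercept)",
                   if (p > 1L) paste0("x", seq_len(p - 1L)))
  X
}

# Build the scenario hypothesis model for a (n, d) grid cell: design from
# generate_design (fixed across replicates), default priors, tested block =
# last coefficient for d > 2 (r = 1, s = d - 2), or the intercept itself for
# the intercept-only model d = 2 (r = 1, s = 0).
.scenario_model <- function(n, d, seed) {
  X <- generate_design(n, d, seed = seed)
  hypothesis_model(X, prior = default_prior(d - 1L), r = 1L)
}

#' Adaptive-cutoff table over a scenario grid
#'
#' For each `(n, d)` pair: generate the design once (held fixed across
#' replicates), build the sharp-null model testing the last coefficient,
#' estimate the e-value error curves and the adaptive cutoff `k*` that
#' minimizes `a * alpha + b * beta`. Scenario failures are recorded as `NA`
#' rows rather than aborting the grid.
#'
#' @param n,d equal-length vectors (or scalars, recycled) of sample sizes
#'   and parameter-space dimensionalities.
#' @param M_outer,M_inner Monte Carlo sizes (replicate datasets per
#'   hypothesis; posterior draws per e-value).
#' @param a,b error weights.
#' @param seed integer master seed; sub-seeds are derived per scenario.
#' @return A data frame of class `"kstar_table"` with columns `n`, `d`,
#'   `kstar`, `alpha_e`, `beta_e`, `se_alpha`, `se_beta`, `seed`.
#' @export
kstar_table <- function(n, d, M_outer = 1000, M_inner = 1000,
                        a = 1, b = 1, seed = 1) {
  grid <- data.frame(n = as.integer(n), d = as.integer(d))
  seeds <- .split_seed(seed, 2L * nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    out <- data.frame(n = grid$n[i], d = grid$d[i], kstar = NA_real_,
                      alpha_e = NA_real_, beta_e = NA_real_,
                      se_alpha = NA_real_, se_beta = NA_real_,
                      seed = seeds[2 * i])
    res <- tryCatch({
      model <- .scenario_model(grid$n[i], grid$d[i], seed = seeds[2 * i - 1])
      ks <- find_kstar(error_curves(model, M_outer, M_inner,
                                    seed = seeds[2 * i]), a = a, b = b)
      out$kstar <- ks$kstar; out$alpha_e <- ks$alpha; out$beta_e <- ks$beta
      out$se_alpha <- ks$se_alpha; out$se_beta <- ks$se_beta
      out
    }, error = function(e) {
      warning(sprintf("scenario (n=%d, d=%d) failed: %s",
                      grid$n[i], grid$d[i], conditionMessage(e)), call. = FALSE)
      out
    })
    res
  })
  res <- do.call(rbind, rows)
  class(res) <- c("kstar_table", "data.frame")
  res
}

#' Adaptive significance-level table over a scenario grid
#'
#' Same scenario loop as [kstar_table()], but computing the optimal averaged
#' error probabilities of the Bayes-factor test: `alpha* = P_H(BF <= b/a)`
#' and `beta* = P_A(BF > b/a)`.
#'
#' @inheritParams kstar_table
#' @param M Monte Carlo draws per hypothesis.
#' @return A data frame with columns `n`, `d`, `alpha_star`, `beta_star`,
#'   `se_alpha`, `se_beta`, `seed`.
#' @export
alphastar_table <- function(n, d, M = 1000, a = 1, b = 1, seed = 1) {
  grid <- data.frame(n = as.integer(n), d = as.integer(d))
  seeds <- .split_seed(seed, 2L * nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    out <- data.frame(n = grid$n[i], d = grid$d[i], alpha_star = NA_real_,
                      beta_star = NA_real_, se_alpha = NA_real_,
                      se_beta = NA_real_, seed = seeds[2 * i])
    tryCatch({
      model <- .scenario_model(grid$n[i], grid$d[i], seed = seeds[2 * i - 1])
      opt <- optimal_error_rates(model, a = a, b = b, M = M,
                                 seed = seeds[2 * i])
      out$alpha_star <- opt$alpha_star; out$beta_star <- opt$beta_star
      out$se_alpha <- opt$se_alpha; out$se_beta <- opt$se_beta
      out
    }, error = function(e) {
      warning(sprintf("scenario (n=%d, d=%d) failed: %s",
                      grid$n[i], grid$d[i], conditionMessage(e)), call. = FALSE)
      out
    })
  })
  res <- do.call(rbind, rows)
  class(res) <- c("alphastar_table", "data.frame")
  res
}
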
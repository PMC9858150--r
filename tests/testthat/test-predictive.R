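test_that("structured and full scale forms of the t density agree", {
  set.seed(31)
  n <- 6; q <- 2
  U <- matrix(rnorm(n * q), n, q)
  W <- crossprod(matrix(rnorm(q * q), q)) + diag(q)
  cc <- 0.7; loc <- rnorm(n)
  s_low <- mvt_spec(df = 7, loc = loc, c = cc, U = U, W = W)
  s_full <- mvt_spec(df = 7, loc = loc, scale = cc * (diag(n) + U %*% W %*% t(U)))
  Y <- matrix(rnorm(n * 5), n, 5)
  expect_equal(dmvt_spec(s_low, Y), dmvt_spec(s_full, Y), tolerance = 1e-10)
})

test_that("t density has the normal limit, unit mass, and t marginals", {
  # df -> Inf limit
  s <- mvt_spec(df = 1e6, loc = 0, scale = matrix(1))
  for (y in c(0, 1, 2))
    expect_equal(as.numeric(dmvt_spec(s, y)), dnorm(y, log = TRUE),
                 tolerance = 1e-3)
  # normalization at n = 1, df = 6
  s6 <- mvt_spec(df = 6, loc = 0.5, scale = matrix(2))
  I <- integrate(function(y) dmvt_spec(s6, matrix(y, 1), log = FALSE),
                 -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(I, 1, tolerance = 1e-6)
  # scaled 1-D t: matches dt after standardization
  expect_equal(as.numeric(dmvt_spec(s6, 1.3, log = FALSE)),
               dt((1.3 - 0.5) / sqrt(2), df = 6) / sqrt(2), tolerance = 1e-12)
  # marginal of component 1 of a correlated bivariate t is 1-D t (quadrature)
  S <- matrix(c(2, 0.8, 0.8, 1.5), 2)
  s2d <- mvt_spec(df = 5, loc = c(0.2, -0.1), scale = S)
  marg <- integrate(function(y2v) sapply(y2v, function(y2)
    dmvt_spec(s2d, c(0.9, y2), log = FALSE)), -Inf, Inf, rel.tol = 1e-10)$value
  s1d <- mvt_spec(df = 5, loc = 0.2, scale = matrix(S[1, 1]))
  expect_equal(marg, as.numeric(dmvt_spec(s1d, 0.9, log = FALSE)),
               tolerance = 1e-6)
})

test_that("null predictive has the stated df, location and scale", {
  # m0 = 0, V0 = I: zero location, bH = b0, scale (b0/aH)(I + X1 X1')
  set.seed(32)
  X <- cbind(1, matrix(rnorm(8 * 2), 8, 2))
  model <- hypothesis_model(X, default_prior(3), r = 1)
  fh <- predictive_h(model)
  expect_equal(fh$df, 2 * 3 + 1)
  expect_equal(fh$loc, rep(0, 8))
  X1 <- X[, 1:2]
  full <- mvt_spec(df = 7, loc = rep(0, 8),
                   scale = (2 / 3.5) * (diag(8) + tcrossprod(X1)))
  y <- rnorm(8)
  expect_equal(as.numeric(dmvt_spec(fh, y)), as.numeric(dmvt_spec(full, y)),
               tolerance = 1e-10)

  # reference prior, intercept-only: fA = t_n(2 a0; 0, (b0/a0)(I + 1 1'))
  mA <- hypothesis_model(matrix(1, 4, 1), r = 1)
  fa <- predictive_a(mA)
  expect_equal(fa$df, 6)
  expect_equal(fa$loc, rep(0, 4))
  fullA <- mvt_spec(df = 6, loc = rep(0, 4),
                    scale = (2 / 3) * (diag(4) + matrix(1, 4, 4)))
  y4 <- c(0.3, -1, 0.5, 2)
  expect_equal(as.numeric(dmvt_spec(fa, y4)), as.numeric(dmvt_spec(fullA, y4)),
               tolerance = 1e-10)
})

test_that("both predictive densities match nested quadrature at n = 1, p = 1", {
  pr <- nig_prior(0.3, 1.5, 3, 2)
  X <- matrix(2, 1, 1)
  model <- hypothesis_model(X, pr, r = 1)      # s = 0 under H
  fh <- predictive_h(model); fa <- predictive_a(model)
  cond <- nig_condition(pr, 1, 0)
  for (y in c(-1.5, 0.7, 3)) {
    expect_equal(as.numeric(dmvt_spec(fh, y, log = FALSE)),
                 quad_predictive_h_s0_1d(y, cond$a, cond$b), tolerance = 1e-6)
    expect_equal(as.numeric(dmvt_spec(fa, y, log = FALSE)),
                 quad_predictive_a_1d(y, 2, 0.3, 1.5, 3, 2), tolerance = 1e-6)
    expect_equal(as.numeric(log_bf(model, y)),
                 log(quad_predictive_h_s0_1d(y, cond$a, cond$b) /
                       quad_predictive_a_1d(y, 2, 0.3, 1.5, 3, 2)),
                 tolerance = 1e-6)
  }
})

test_that("null predictive with free coefficients matches a 2-level quadrature", {
  # n = 1, p = 2, s = 1: integrate theta1 and sigma2 numerically
  pr <- nig_prior(c(0.4, 0), matrix(c(1.2, 0.3, 0.3, 0.9), 2), 3, 2)
  X <- matrix(c(1, -0.7), 1, 2)
  model <- hypothesis_model(X, pr, r = 1)
  cond <- nig_condition(pr, 1, 0)
  y <- 0.9
  q <- integrate(function(s2v) sapply(s2v, function(s2) {
    inner <- integrate(function(t1) dnorm(y, X[1, 1] * t1, sqrt(s2)) *
                         dnorm(t1, cond$m, sqrt(s2 * cond$V[1, 1])),
                       -Inf, Inf, rel.tol = 1e-10)$value
    inner * ig_dens(s2, cond$a, cond$b)
  }), 0, Inf, rel.tol = 1e-10)$value
  expect_equal(as.numeric(dmvt_spec(predictive_h(model), y, log = FALSE)), q,
               tolerance = 1e-6)
})

test_that("predictive densities integrate to one (n = 1 and n = 2)", {
  model <- hypothesis_model(generate_design(2, 3, seed = 33),
                            default_prior(2), r = 1)
  for (spec in list(predictive_h(model), predictive_a(model))) {
    I2 <- integrate(function(y1v) sapply(y1v, function(y1)
      integrate(function(y2) dmvt_spec(spec, rbind(y1, y2), log = FALSE),
                -Inf, Inf, rel.tol = 1e-9)$value),
      -Inf, Inf, rel.tol = 1e-9)$value
    expect_equal(I2, 1, tolerance = 1e-4)
  }
  m1 <- hypothesis_model(matrix(1.5, 1, 1), nig_prior(0.2, 2, 3, 2), r = 1)
  for (spec in list(predictive_h(m1), predictive_a(m1))) {
    I1 <- integrate(function(y) dmvt_spec(spec, matrix(y, 1), log = FALSE),
                    -Inf, Inf, rel.tol = 1e-9)$value
    expect_equal(I1, 1, tolerance = 1e-4)
  }
})

test_that("Monte Carlo average of the likelihood recovers the predictive density", {
  # (1/M) sum N_n(y | X theta_j, s2_j I) over prior draws -> f_A(y)
  set.seed(34)
  X <- generate_design(2, 3, seed = 35)
  pr <- default_prior(2)
  model <- hypothesis_model(X, pr, r = 1)
  y <- c(0.5, -1.2)
  dr <- rnig(200000, pr, seed = 36)
  mu <- X %*% t(dr$theta)
  dens <- dnorm(y[1], mu[1, ], sqrt(dr$sigma2)) *
    dnorm(y[2], mu[2, ], sqrt(dr$sigma2))
  mc <- mean(dens)
  cf <- as.numeric(dmvt_spec(predictive_a(model), y, log = FALSE))
  expect_lt(abs(mc - cf) / cf, 0.05)
})

test_that("hierarchical samplers are consistent with the closed-form predictives", {
  X <- generate_design(5, 3, seed = 37)
  model <- hypothesis_model(X, default_prior(2), r = 1)
  sh <- sample_under_h(model, 5000, seed = 38)
  expect_true(all(sh$theta[, 2] == 0))           # tested block pinned at 0
  # first coordinate of y vs draws from the Student-t mixture representation
  yh_ref <- rmvt_spec(5000, predictive_h(model), seed = 39)[1, ]
  expect_gt(ks.test(sh$y[1, ], yh_ref)$p.value, 0.01)
  # sigma2-first and theta-first factorizations agree in distribution
  sh2 <- sample_under_h(model, 5000, seed = 40, scheme = "theta-first")
  expect_gt(ks.test(sh$sigma2, sh2$sigma2)$p.value, 0.01)
  expect_gt(ks.test(sh$y[1, ], sh2$y[1, ])$p.value, 0.01)

  sa <- sample_under_a(model, 5000, seed = 41)
  ya_ref <- rmvt_spec(5000, predictive_a(model), seed = 42)[1, ]
  expect_gt(ks.test(sa$y[1, ], ya_ref)$p.value, 0.01)
  # determinism and the law of total expectation E(y) = X m0 = 0 here
  sa2 <- sample_under_a(model, 5000, seed = 41)
  expect_identical(sa$y, sa2$y)
  big <- sample_under_a(model, 50000, seed = 43)
  se <- sd(big$y[1, ]) / sqrt(50000)
  expect_lt(abs(mean(big$y[1, ]) - 0), 3 * se)
})

test_that("Bayes factor is invariant to joint row permutations", {
  set.seed(44)
  X <- generate_design(9, 4, seed = 45)
  model <- hypothesis_model(X, default_prior(3), r = 1)
  y <- rnorm(9)
  perm <- sample(9)
  model_p <- hypothesis_model(X[perm, ], default_prior(3), r = 1)
  expect_equal(as.numeric(log_bf(model, y)),
               as.numeric(log_bf(model_p, y[perm])), tolerance = 1e-10)
})

test_that("the sampling distribution of BF under fH is probability-integral uniform", {
  model <- hypothesis_model(matrix(1, 8, 1), r = 1)
  Y <- sample_under_h(model, 2000, seed = 46)$y
  lbf <- log_bf(model, Y)
  u <- (rank(lbf) - 0.5) / length(lbf)   # F(BF) via the empirical CDF
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})
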
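# fbstlm

Bayesian significance testing for linear-regression coefficients with
**adaptive decision thresholds**.

## The problem

In the normal linear model with unknown variance,

```
y = X θ + ε,   ε ~ N_n(0, σ² I_n),
```

deciding which coefficients matter is usually done by comparing a p-value
with a fixed level such as 0.05. But p-values — and their Bayesian
counterpart in the FBST, the e-value — shrink toward zero as the sample
size grows, so with thousands of observations a fixed threshold rejects
almost every sharp null `H: θ₂ = 0`. fbstlm is for analysts who want
coefficient tests whose thresholds *adapt to the sample size n and the
parameter-space dimensionality d = p + 1*, keeping both decision error
probabilities under control instead of fixing one and letting the other
vanish.

## What it computes

Under the conjugate normal-inverse-gamma prior
`σ² ~ IG(a₀, b₀)`, `θ | σ² ~ N_p(m₀, σ² V₀)`, the package provides exact
conjugate inference (`blm()`) and two tests of `H: θ₂ = 0`:

* **FBST e-value** (`fbst()`, `evalue()`): `ev = 1 − P(ξ ∈ T_y | y)`, the
  posterior probability outside the highest-posterior-density region
  tangent to the null set. The constrained supremum of the posterior over
  H is closed form; the e-value is estimated from posterior Monte Carlo
  draws. The test rejects when `ev ≤ k*`.
* **Capital-P P-value** (`pvalue_test()`, `pvalue()`): both hypotheses
  induce closed-form multivariate Student-t prior predictive densities
  `f_H`, `f_A`; with Bayes factor `BF(y) = f_H(y)/f_A(y)`, the P-value at
  observed `y₀` is `P_{f_H}(BF(Y) ≤ BF(y₀))`. The test rejects when
  `P < α*`.

The adaptive thresholds are found by Monte Carlo under the two predictive
densities:

* `adaptive_cutoff()` minimizes `a·α(k) + b·β(k)` over e-value cutoffs,
  where `α(k)`/`β(k)` are the averaged type-I/type-II error probabilities
  of the FBST test with cutoff `k` — giving `k*(n, d)`;
* `optimal_error_rates()` computes `α* = P_{f_H}(BF ≤ b/a)` and
  `β* = P_{f_A}(BF > b/a)`, the optimal averaged error probabilities of
  the Bayes-factor test (generalized Neyman-Pearson lemma).

`kstar_table()` / `alphastar_table()` run scenario grids over `(n, d)`,
`generate_design()` builds the scenario designs, `test_coefficients()`
produces a per-coefficient report (OLS and Bayes estimates, classical
p-value, e-value vs `k*`, P-value vs `α*`, and all three decisions), and a
command-line interface (`exec/fbstlm`, subcommands
`fit | evalue | pvalue | kstar | test-coef | simulate`) wraps the same
functions for CSV workflows.

## Worked example

Median home value in the Boston housing data (MASS) on nine tract-level
covariates, with the reference prior `m₀ = 0, V₀ = I, a₀ = 3, b₀ = 2`:

```r
library(fbstlm)
library(MASS)
covars <- c("crim", "zn", "indus", "rm", "age", "dis", "tax", "ptratio", "black")
X <- cbind(`(Intercept)` = 1, as.matrix(Boston[, covars]))
fit <- blm_fit(X, Boston$medv)
summary(fit)
#> Bayesian linear model, NIG posterior (a1 = 256.00, b1 = 7415)
#>             Post. mean Post. sd     OLS
#> (Intercept)     1.2035   3.3597  1.7035
#> crim           -0.1244   0.0354 -0.1244
#> zn              0.0362   0.0155  0.0359
#> indus          -0.1473   0.0640 -0.1489
#> rm              6.7336   0.3458  6.7165
#> age            -0.0648   0.0132 -0.0655
#> dis            -1.3091   0.2127 -1.3198
#> tax            -0.0030   0.0025 -0.0030
#> ptratio        -0.7528   0.1286 -0.7652
#> black           0.0147   0.0029  0.0145
#> Posterior mean of sigma2: 29.08
```

Is the property-tax coefficient null? The classical p-value is 0.2324, so
the fixed-level test accepts. The adaptive Bayesian tests agree, each
against its own calibrated threshold (`n = 506`, `d = 11`):

```r
fbst(fit, test = "tax", M = 10000, seed = 1)
#> Full Bayesian significance test (FBST)
#>   H: tax = 0
#>   e-value: 0.9998 (MC se 0.0001, M = 10000)
adaptive_cutoff(fit, test = "tax", seed = 1)
#> Adaptive e-value cutoff k* = 0.0260 (alpha = 0.0000, beta = 0.0030)
pvalue_test(fit, test = "tax", M = 10000, seed = 1)
#> Bayes-factor significance test (capital-P P-value)
#>   H: tax = 0
#>   P-value: 0.0240, adaptive alpha*: 0.0001 -> accept H
```

The e-value 0.9998 is far above `k* = 0.026` and the P-value 0.024 is above
`α* = 0.0001`: both tests accept the null, at thresholds that would be
absurd as fixed levels but are the error-optimal cutoffs for this n and d.
Note how small `α*` is at `n = 506` — a fixed 0.05 level would spend far
more type-I error than necessary here.

The same decisions for every coefficient at once:

```r
test_coefficients(fit, M = 10000, seed = 1)
```

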
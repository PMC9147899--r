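test_that("Richards curve hits its stated landmark values", {
  p2 <- richards_params(A = 1000, x_i = 0, d = 2)
  expect_equal(eval_richards(0, p2), 500)              # A/2 at d = 2
  expect_equal(eval_ln_richards(0, p2), log(500))
  pg <- richards_params(A = 1000, x_i = 0, d = 1 + 1e-12)
  expect_equal(eval_richards(0, pg), 1000 / exp(1))    # A/e in the d -> 1 limit
  # asymptotes
  expect_equal(eval_richards(60, p2), 1000, tolerance = 1e-12)
  expect_lt(eval_richards(-60, p2), 1e-20)
})

test_that("log Richards matches the logistic closed form at d = 2", {
  p <- richards_params(A = 1e4, k = 1.3, x_i = -2, d = 2)
  x <- seq(-12, 8, length.out = 2000)
  oracle <- log(1e4) - log1p(exp(-1.3 * (x + 2)))
  expect_lt(max(abs(eval_ln_richards(x, p) - oracle)), 1e-12)
})

test_that("log Richards matches the Gompertz closed form as d -> 1", {
  p <- richards_params(A = 1e4, x_i = -2, d = 1 + 1e-9)
  x <- seq(-12, 8, length.out = 2000)
  oracle <- log(1e4) - exp(-(x + 2))          # ln(A exp(-e^{-k(x-x_i)}))
  expect_lt(max(abs(eval_ln_richards(x, p) - oracle)), 1e-6)
})

test_that("deep-tail evaluation switches to the exact linear asymptote", {
  p <- richards_params(A = 1, x_i = 0, d = 1.5)
  x <- c(-800, -1200)
  expected <- (log(0.5) - x) / (1 - 1.5)  # slope k/(d-1) = 2
  expect_equal(eval_ln_richards(x, p), expected)
  expect_true(all(is.finite(eval_ln_richards(seq(-2000, 0, by = 10), p))))
})

test_that("limiting slope formula agrees with a finite-difference oracle", {
  expect_identical(limiting_slope(1, 2), 1)
  expect_identical(limiting_slope(2, 1.5), 4)
  expect_equal(limiting_slope(1, 1.01), 100)
  for (prm in list(c(1, 2), c(1, 1.01), c(2, 1.4))) {
    k <- prm[1]; d <- prm[2]
    p <- richards_params(A = 10, k = k, x_i = 0, d = d)
    h <- 1e-2
    num <- (eval_ln_richards(-30 + h, p) - eval_ln_richards(-30 - h, p)) / (2 * h)
    expect_equal(num, limiting_slope(k, d), tolerance = 1e-6)
  }
  expect_error(limiting_slope(1, 1), "'d'")
})

test_that("numerical inflection of R(x) sits at x_i (50 random draws)", {
  set.seed(42)
  h <- 1e-4
  for (i in 1:50) {
    p <- richards_params(A = exp(runif(1, 0, 10)), x_i = runif(1, -15, -5),
                         d = runif(1, 1.05, 2), k = 1)
    d2 <- function(x)
      (eval_richards(x + h, p) - 2 * eval_richards(x, p) +
         eval_richards(x - h, p)) / h^2
    # second derivative changes sign within 1e-3 of x_i
    expect_gt(d2(p$x_i - 1e-3), 0)
    expect_lt(d2(p$x_i + 1e-3), 0)
  }
})

test_that("2D model has the stated limits, ordering and monotonicity", {
  q <- twodim_params(C = 1e6, B = 20, m = 1.2, x_i = -10, d = 1.7)
  # logistic factor -> 1 at large x
  expect_equal(eval_ln_r2(50, 300, q), log(1e6) - 1.2 * log(320),
               tolerance = 1e-12)
  # ordered dilution curves (Fig-2-style): less diluted sits higher
  x <- seq(-13, -8, length.out = 20)
  v100 <- eval_ln_r2(x, 100, q)
  v300 <- eval_ln_r2(x, 300, q)
  v900 <- eval_ln_r2(x, 900, q)
  expect_true(all(v100 > v300) && all(v300 > v900))
  # strictly increasing in x
  expect_true(all(diff(v100) > 0))
  expect_error(eval_ln_r2(-10, 0.5, q), "z")
  # B -> 0, m = 1: dilution by a factor e shifts ln signal by -1
  qb <- twodim_params(C = 1, B = 1e-12, m = 1, x_i = -10, d = 1.7)
  expect_equal(eval_ln_r2(-10, exp(1), qb) - eval_ln_r2(-10, 1, qb), -1,
               tolerance = 1e-9)
})

test_that("activity-coefficient curves are normalized, monotone and amplitude-free", {
  expect_equal(activity_coefficient_curve(-10, x_i = -10, d = 2)$gamma,
               0.5)                                   # gamma(x_i) at d = 2
  ac <- activity_coefficient_curve(seq(-15, 0, length.out = 200),
                                   x_i = -10, d = 2)
  expect_equal(max(ac$gamma), 1, tolerance = 1e-4)    # -> 1 as x -> +inf
  expect_true(all(ac$gamma > 0 & ac$gamma <= 1))
  expect_equal(ac$limiting_index, 1)
  set.seed(7)
  for (i in 1:100) {
    xi <- runif(1, -14, -6); d <- runif(1, 1.01, 2)
    g <- activity_coefficient_curve(seq(xi - 8, xi + 8, length.out = 1000),
                                    xi, d)$gamma
    expect_true(all(diff(g) > 0))
  }
  # concentration invariance: gamma is R(x)/A for any A
  x <- seq(-14, -6, length.out = 50)
  g1 <- eval_richards(x, richards_params(A = 1, x_i = -10, d = 1.6))
  g2 <- eval_richards(x, richards_params(A = 1e6, x_i = -10, d = 1.6)) / 1e6
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(activity_coefficient_curve(x, -10, 1.6)$gamma, g1)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(richards_params(A = -1, x_i = 0, d = 1.5), "'A'")
  expect_error(richards_params(A = 1, x_i = 0, d = 1), "'d'")
  expect_error(twodim_params(C = 1, B = 0, m = 1, x_i = 0, d = 1.5), "'B'")
  expect_error(activity_coefficient_curve(0, x_i = 0, d = 0.9), "'d'")
})
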
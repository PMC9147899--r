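test_that("initial guesses are sane, deterministic and fail loudly", {
  g <- grid_2d()
  init <- initial_guess(g, "r2_2d")
  # finite SSE, better than a flat model
  f0 <- eval_ln_r2(g$x, g$z, twodim_params(C = init[["C"]], B = init[["B"]],
                                           m = init[["m"]], x_i = init[["x_i"]],
                                           d = init[["d"]]))
  sse_init <- sum((g$ln_signal - f0)^2)
  sse_flat <- sum((g$ln_signal - mean(g$ln_signal))^2)
  expect_true(is.finite(sse_init))
  expect_lt(sse_init, sse_flat)
  # permutation determinism
  expect_identical(init, initial_guess(g[sample(nrow(g)), ], "r2_2d"))
  # one dilution cannot support the 2D model
  expect_error(initial_guess(g[g$z == 100, ], "r2_2d"),
               "insufficient data: 1 dilutions")
})

test_that("1D fit recovers noiseless Richards parameters to 1e-6", {
  truth <- richards_params(A = 1e4, k = 1, x_i = -10.5, d = 1.6)
  fit <- fit_richards_1d(curve_1d(truth))
  expect_true(fit$converged)
  for (nm in c("A", "x_i", "d"))
    expect_equal(fit$coef[[nm]], truth[[nm]], tolerance = 1e-6)
})

test_that("free-k fit of binding-equation data returns the forced rate k = 1", {
  bc <- binding_curve()
  fit <- fit_richards_1d(bc[, c("x", "ln_signal")], fix_k = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$coef[["k"]], 1, tolerance = 1e-3)
})

test_that("degenerate flat input does not crash and is flagged", {
  df <- data.frame(x = seq(-12, -9, length.out = 6), ln_signal = 5)
  fit <- fit_richards_1d(df)
  expect_s3_class(fit, "microspot_fit")
  expect_true(!fit$converged || fit$flags$xi_out_of_range ||
                fit$flags$d_near_lower || fit$flags$d_near_upper ||
                fit$sse < 1e-20)
})

test_that("2D fit recovers noiseless surface parameters to 1e-6", {
  q <- truth_2d()
  fit <- fit_r2_2d(grid_2d(q))
  expect_true(fit$converged)
  for (nm in c("C", "B", "m", "x_i", "d"))
    expect_equal(fit$coef[[nm]], q[[nm]], tolerance = 1e-6)
  expect_false(fit$flags$xi_out_of_range)
})

test_that("Gauss-Newton optimum matches a dense grid-search oracle", {
  set.seed(21)
  x <- seq(-13, -8, length.out = 9)
  truth <- richards_params(A = 5e3, x_i = -10.2, d = 1.5)
  y <- eval_ln_richards(x, truth) + rnorm(9, 0, 0.1)
  fit <- fit_richards_1d(data.frame(x = x, ln_signal = y))
  oracle <- grid_search_sse_1d(x, y, xi_range = c(-12, -9))
  expect_lte(fit$sse, oracle * (1 + 1e-4))
})

test_that("well-conditioned fits are basin-stable over perturbed starts", {
  set.seed(5)
  q <- truth_2d()
  g <- grid_2d(q)
  g$ln_signal <- g$ln_signal + rnorm(nrow(g), 0, 0.05)
  ref <- fit_r2_2d(g)
  init0 <- initial_guess(g, "r2_2d")
  for (i in 1:10) {
    init <- init0 * exp(rnorm(5, 0, 0.15))
    init["d"] <- min(max(init[["d"]], 1.05), 1.95)
    init["x_i"] <- init0[["x_i"]] + rnorm(1, 0, 0.4)
    fit <- fit_r2_2d(g, init = init)
    expect_equal(fit$sse, ref$sse, tolerance = 1e-6)
  }
})

test_that("(x_i, d) are invariant to a uniform rescaling of raw intensities", {
  lay <- default_layout()
  spots <- simulate_experiment(lay, truth_2d(), seed = 8, noise_sigma = 0.1)
  f1 <- fit_r2_2d(suppressMessages(aggregate_replicates(spots)))
  spots$rfi <- spots$rfi * 37
  f2 <- fit_r2_2d(suppressMessages(aggregate_replicates(spots)))
  expect_equal(f2$coef[["x_i"]], f1$coef[["x_i"]], tolerance = 1e-6)
  expect_equal(f2$coef[["d"]], f1$coef[["d"]], tolerance = 1e-6)
  expect_equal(log(f2$coef[["C"]]) - log(f1$coef[["C"]]), log(37),
               tolerance = 1e-6)
})

test_that("x_i outside the measured range raises the reliability flag", {
  q <- truth_2d(x_i = -7)  # above max printed x (~ -8.5)
  g <- grid_2d(q)
  fit <- fit_r2_2d(g)
  expect_true(fit$flags$xi_out_of_range)
})

test_that("median parameter recovery over 50 noisy replicates is within 0.1", {
  lay <- default_layout()
  q <- truth_2d()
  err_xi <- err_d <- numeric(50)
  for (i in 1:50) {
    spots <- simulate_experiment(lay, q, seed = 1000 + i, noise_sigma = 0.1)
    fit <- fit_r2_2d(suppressMessages(aggregate_replicates(spots)))
    err_xi[i] <- abs(fit$coef[["x_i"]] - q$x_i)
    err_d[i] <- abs(fit$coef[["d"]] - q$d)
  }
  expect_lte(median(err_xi), 0.1)
  expect_lte(median(err_d), 0.1)
})

test_that("nls reproduces the 2D optimum on a noisy fixture (independent oracle)", {
  set.seed(31)
  g <- grid_2d()
  g$ln_signal <- g$ln_signal + rnorm(nrow(g), 0, 0.08)
  ours <- fit_r2_2d(g)
  nf <- nls(ln_signal ~ lnC - exp(lnm) * log(exp(lnB) + z) +
              log1p((d - 1) * exp(-(x - xi))) / (1 - d),
            data = g,
            start = list(lnC = log(5e6), lnB = log(50), lnm = 0,
                         xi = -10.5, d = 1.6),
            control = nls.control(maxiter = 200))
  expect_equal(ours$sse, sum(resid(nf)^2), tolerance = 1e-6)
  expect_equal(ours$coef[["x_i"]], coef(nf)[["xi"]], tolerance = 1e-4)
})
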
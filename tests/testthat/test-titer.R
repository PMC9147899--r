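# binding-model fixture in the Ab << KD regime: signal is an exact
# logistic of -ln z with midpoint titer z* = D * ab0 * ag / kd at the
# half-saturation point (u = 1), so titers scale linearly with density.
titer_spots <- function(noise = 0, seed = 1,
                        dilutions = 100 * 3^(0:5)) {
  lay <- array_layout(antigen_concs = 2e-4 * 0.5^(0:6), n_replicates = 5,
                      dilutions = dilutions)
  p <- binding_model_params(ab_conc = 1e-7, kd = 1e-9, d_const = 1e6,
                            alpha = 1e10, noise_sigma = noise)
  simulate_experiment(lay, p, seed = seed)
}

test_that("midpoint titer matches its analytic value on noiseless data", {
  spots <- titer_spots()
  tbl <- aggregate_replicates(spots)
  p <- list(ab = 1e-7, kd = 1e-9, D = 1e6)
  for (ag in c(2e-4, 5e-5)) {
    cur <- tbl[!tbl$excluded & abs(tbl$x - log(ag)) < 1e-9, ]
    mt <- midpoint_titer(cur$z, exp(cur$ln_signal))
    expect_true(mt$defined)
    # signal(z) = const / (1 + z kd / (ab (1 + D ag))): exact logistic in
    # ln z whose half-plateau dilution is ab (1 + D ag) / kd
    zstar <- p$ab * (1 + p$D * ag) / p$kd
    expect_equal(mt$value, zstar, tolerance = 0.01)
  }
})

test_that("midpoint titer brackets an exact halving between tested dilutions", {
  z <- c(100, 200, 400, 800, 1600)
  sig <- 1000 / (1 + z / 300)  # half of plateau 1000 at exactly z = 300
  mt <- midpoint_titer(z, sig)
  expect_true(mt$defined)
  expect_gt(mt$value, 200)
  expect_lt(mt$value, 400)
  expect_equal(mt$value, 300, tolerance = 0.01)
})

test_that("undefined midpoint titers carry reasons", {
  expect_match(midpoint_titer(c(100, 300, 900, 2700), rep(0, 4))$reason,
               "no signal")
  expect_match(midpoint_titer(c(100, 300, 900, 2700), c(1, 2, 3, 4))$reason,
               "not decreasing")
  expect_match(midpoint_titer(c(100, 300), c(2, 1))$reason, ">= 4")
})

test_that("endpoint titer interpolates a constructed threshold crossing", {
  z <- c(100, 300, 900, 2700)
  sig <- c(80, 40, 10, 2)
  et <- endpoint_titer(z, sig, background_mean = 0, background_sd = 5, c = 3)
  expect_true(et$defined)
  expect_gt(et$value, 300)
  expect_lt(et$value, 900)
  # all above threshold: right-censored at max tested dilution
  et2 <- endpoint_titer(z, sig, background_mean = 0, background_sd = 0.1)
  expect_true(et2$censored)
  expect_equal(et2$value, 2700)
  # nothing above threshold
  expect_match(endpoint_titer(z, sig, 0, background_sd = 50)$reason,
               "no signal above threshold")
  # threshold monotonicity: looser threshold, larger titer
  e0 <- endpoint_titer(z, sig, 0, background_sd = 5, c = 0)
  expect_gte(e0$value, et$value)
})

test_that("titers increase with antigen density while the 2D fit shape does not", {
  spots <- titer_spots(noise = 0.05, seed = 17)
  titers <- titer_vs_density(spots)
  expect_identical(nrow(titers), 6L)  # background density excluded
  mt <- titers$midpoint_titer[order(titers$conc)]
  expect_true(all(titers$midpoint_defined))
  expect_true(all(diff(mt) > 0))     # strictly increasing with density
  expect_gt(max(mt) / min(mt), 4)    # strong density dependence
  et <- titers$endpoint_titer[order(titers$conc)]
  expect_true(all(diff(et[titers$endpoint_defined[order(titers$conc)]]) >= 0))

  # paired run: the 2D fit of the same spots gives one density-independent
  # (x_i, d); refitting on disjoint density subsets moves x_i by far less
  # than the titers move
  tbl <- suppressMessages(aggregate_replicates(spots))
  # two 4-density windows (high vs low; they overlap in the middle two)
  top <- tbl[tbl$excluded | tbl$x >= log(2.5e-5) - 1e-9, ]
  bot <- tbl[tbl$excluded | tbl$x <= log(5e-5) + 1e-9, ]
  f_top <- fit_r2_2d(top)
  f_bot <- fit_r2_2d(bot)
  expect_lt(abs(f_top$coef[["x_i"]] - f_bot$coef[["x_i"]]), 0.5)
  expect_gt(max(mt) / min(mt), 2 * exp(abs(f_top$coef[["x_i"]] -
                                             f_bot$coef[["x_i"]])))
})

test_that("midpoint titer is scale-invariant; endpoint titer is not", {
  z <- c(100, 300, 900, 2700, 8100)
  sig <- 1000 / (1 + z / 500)
  m1 <- midpoint_titer(z, sig)$value
  m2 <- midpoint_titer(z, sig * 10)$value
  expect_equal(m1, m2, tolerance = 1e-6)
  e1 <- endpoint_titer(z, sig, 0, background_sd = 20)$value
  e2 <- endpoint_titer(z, sig * 10, 0, background_sd = 20)$value
  expect_gt(e2, e1)
})

test_that("titers scale with a uniform rescaling of the dilution axis", {
  z <- c(100, 300, 900, 2700, 8100)
  sig <- 1000 / (1 + z / 500)
  expect_equal(midpoint_titer(z * 3, sig)$value,
               3 * midpoint_titer(z, sig)$value, tolerance = 1e-6)
  expect_equal(endpoint_titer(z * 3, sig, 0, background_sd = 20)$value,
               3 * endpoint_titer(z, sig, 0, background_sd = 20)$value,
               tolerance = 1e-6)
})
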
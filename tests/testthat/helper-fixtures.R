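# Shared fixtures: ground truths and small generators used across tests.

truth_2d <- function(C = 5e6, B = 50, m = 1, x_i = -10.5, d = 1.6) {
  twodim_params(C = C, B = B, m = m, x_i = x_i, d = d)
}

# noiseless log-signal grid straight from the 2D model (no spot level)
grid_2d <- function(q = truth_2d(),
                    x = log(2e-4 * 0.5^(0:5)),
                    z = 100 * 3^(0:4)) {
  g <- expand.grid(x = x, z = z)
  g$ln_signal <- eval_ln_r2(g$x, g$z, q)
  g
}

# noiseless 1D Richards curve
curve_1d <- function(p = richards_params(A = 1e4, x_i = -10.5, d = 1.6),
                     x = seq(-14, -7, length.out = 15)) {
  data.frame(x = x, ln_signal = eval_ln_richards(x, p))
}

# log-signal generated from the equilibrium binding model (Eq.-(1)-type),
# pure logistic of x with rate 1; midpoint at ln((kd+ab)/(D*ab))
binding_curve <- function(ab = 1e-8, kd = 1e-8, d_const = 1e6,
                          alpha = 1e10, beta = 1, n = 60, span = 8) {
  xmid <- log((kd + ab) / (d_const * ab))
  x <- seq(xmid - span, xmid + span, length.out = n)
  cplx <- bound_complex_concentration(exp(x), ab, kd, d_const)
  data.frame(x = x, ln_signal = log(detection_transform(cplx, alpha, beta)),
             xmid = xmid)
}

# brute-force oracle for the 1D NLS optimum at k = 1: dense grid over
# (x_i, d), lnA solved in closed form (it enters the model additively)
grid_search_sse_1d <- function(x, y, xi_range, n_xi = 80, n_d = 60) {
  xis <- seq(xi_range[1], xi_range[2], length.out = n_xi)
  ds <- seq(1.001, 1.999, length.out = n_d)
  best <- Inf
  for (d in ds) {
    for (xi in xis) {
      g <- eval_ln_richards(x, richards_params(A = 1, x_i = xi, d = d))
      lnA <- mean(y - g)
      sse <- sum((y - g - lnA)^2)
      if (sse < best) best <- sse
    }
  }
  best
}
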
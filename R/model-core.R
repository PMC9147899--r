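# Core curve definitions. All evaluation goes through .ln_richards_core(),
# which owns the numerically stable branches:
#   - Gompertz limit when |d - 1| < 1e-6 (avoids 1/(1-d) cancellation),
#   - linear asymptote when the exponent exceeds 700 (exp() would overflow),
#   - log1p() form otherwise.

.gompertz_eps <- 1e-6
.exp_overflow <- 700

# ln R(x) for A = 1; t = k * (x - x_i) may be any real vector
.ln_richards_core <- function(t, d) {
  out <- numeric(length(t))
  if (abs(d - 1) < .gompertz_eps) {
    # Gompertz limit: ln R = -exp(-t)
    mt <- -t
    big <- mt > .exp_overflow
    out[big] <- -Inf
    out[!big] <- -exp(mt[!big])
    return(out)
  }
  big <- (-t) > .exp_overflow
  # linear asymptote: (1/(1-d)) * (ln(d-1) - t) = s*t/k*... slope k/(d-1) in x
  out[big] <- (log(d - 1) - t[big]) / (1 - d)
  tt <- t[!big]
  out[!big] <- log1p((d - 1) * exp(-tt)) / (1 - d)
  out
}

#' Evaluate the Richards growth curve
#'
#' \deqn{R(x) = A (1 + (d-1) e^{-k(x - x_i)})^{1/(1-d)}}
#' At \code{d = 2} this is the logistic curve with \eqn{R(x_i) = A/2};
#' as \code{d} approaches 1 it converges to the Gompertz curve with
#' \eqn{R(x_i) = A/e}. Values of \code{d} within \code{1e-6} of 1 are
#' evaluated through the Gompertz closed form.
#'
#' @param x numeric vector: natural log of molar antigen concentration.
#' @param p a [richards_params()] object.
#' @return numeric vector of signal values in \code{(0, A)}.
#' @seealso [eval_ln_richards()] for the log form used in fitting.
#' @export
eval_richards <- function(x, p) {
  stopifnot(inherits(p, "richards_params"))
  exp(eval_ln_richards(x, p))
}

#' Evaluate the log of the Richards curve
#'
#' \deqn{\ln R(x) = \ln A + \frac{1}{1-d}\ln(1 + (d-1) e^{-k(x - x_i)})}
#' computed via \code{log1p} with overflow-safe branches, so the linear
#' asymptote of slope \eqn{k/(d-1)} at \eqn{x \to -\infty} is exact.
#'
#' @inheritParams eval_richards
#' @return numeric vector of log signal values.
#' @export
eval_ln_richards <- function(x, p) {
  stopifnot(inherits(p, "richards_params"), is.numeric(x))
  log(p$A) + .ln_richards_core(p$k * (x - p$x_i), p$d)
}

#' Evaluate the log of the two-dimensional antigen-by-dilution model
#'
#' \deqn{\ln R_2(x, z) = \ln C - m \ln(B + z) +
#'       \frac{1}{1-d}\ln(1 + (d-1) e^{-(x - x_i)})}
#' The growth rate along \code{x} is fixed at 1 (forced by the binding
#' equilibrium model). \code{z} is the serum fold-dilution (1:100 gives
#' \code{z = 100}); the effective upper limit \eqn{A(z) = C (B+z)^{-m}}
#' is strictly decreasing in \code{z}.
#'
#' @param x numeric vector: natural log of molar antigen concentration.
#' @param z numeric vector of fold-dilutions, all \code{>= 1}; recycled
#'   against \code{x}.
#' @param q a [twodim_params()] object.
#' @return numeric vector of log signal values.
#' @export
eval_ln_r2 <- function(x, z, q) {
  stopifnot(inherits(q, "twodim_params"), is.numeric(x), is.numeric(z))
  if (any(z < 1)) stop("fold-dilutions 'z' must all be >= 1")
  n <- max(length(x), length(z))
  x <- rep_len(x, n)
  z <- rep_len(z, n)
  log(q$C) - q$m * log(q$B + z) + .ln_richards_core(x - q$x_i, q$d)
}

#' Thermodynamic activity-coefficient curve of serum antibody
#'
#' The concentration-normalized binding curve
#' \eqn{\gamma_{Ab}(x) = R(x)/A \in (0, 1]}: the Richards curve with the
#' amplitude divided out. It depends only on \code{(k, x_i, d)}, never on
#' the amplitude or fluorescence scale, so curves from different samples,
#' isotypes or laboratories are directly overlayable.
#'
#' @param x_grid numeric vector of ln molar antigen concentrations.
#' @param x_i inflection point (ln M).
#' @param d asymmetry parameter, \code{d > 1}.
#' @param k growth rate, default 1.
#' @return An object of class \code{"activity_curve"}: list with
#'   \code{x_grid}, \code{gamma}, \code{x_i}, \code{d}, \code{k} and
#'   \code{limiting_index = d - 1} (the unitless index the asymmetry
#'   parameter ties to the limiting activity coefficient at infinite
#'   antigen dilution).
#' @export
activity_coefficient_curve <- function(x_grid, x_i, d, k = 1) {
  stopifnot(is.numeric(x_grid), all(is.finite(x_grid)))
  if (!is.finite(d) || d <= 1) stop("'d' must be > 1")
  if (!is.finite(k) || k <= 0) stop("'k' must be > 0")
  if (!is.finite(x_i)) stop("'x_i' must be finite")
  gamma <- exp(.ln_richards_core(k * (x_grid - x_i), d))
  structure(list(x_grid = x_grid, gamma = gamma, x_i = x_i, d = d, k = k,
                 limiting_index = d - 1),
            class = "activity_curve")
}

#' @export
print.activity_curve <- function(x, ...) {
  cat(sprintf(
    "Activity-coefficient curve: x_i = %g, d = %g (limiting index d-1 = %g)\n",
    x$x_i, x$d, x$limiting_index))
  cat(sprintf("  %d grid points, gamma in [%.4g, %.4g]\n",
              length(x$x_grid), min(x$gamma), max(x$gamma)))
  invisible(x)
}

#' @export
as.data.frame.activity_curve <- function(x, ...) {
  data.frame(x = x$x_grid, gamma = x$gamma)
}

#' Limiting slope of the log Richards curve at infinite antigen dilution
#'
#' As \eqn{x \to -\infty} the log Richards curve becomes linear with slope
#' \eqn{s = k/(d - 1)}. At \code{k = 1} the slope grows from 1 (logistic,
#' \code{d = 2}) to infinity (Gompertz limit); it characterizes binding in
#' the infinite-dilution state where antigen contacts antibody only.
#'
#' @param k growth rate (> 0).
#' @param d asymmetry parameter (> 1).
#' @return the slope \code{k / (d - 1)}.
#' @examples
#' limiting_slope(1, 2)   # 1
#' limiting_slope(1, 1.5) # 2
#' @export
limiting_slope <- function(k, d) {
  if (!is.numeric(k) || !is.numeric(d)) stop("'k' and 'd' must be numeric")
  if (any(d <= 1)) stop("'d' must be > 1")
  if (any(k <= 0)) stop("'k' must be > 0")
  k / (d - 1)
}
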
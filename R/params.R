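#' Parameters of a single Richards (generalized logistic) titration curve
#'
#' Container for the four parameters of the Richards growth curve
#' \deqn{R(x) = A (1 + (d-1) e^{-k(x - x_i)})^{1/(1-d)}}
#' used to model log-signal versus log molar antigen concentration
#' \eqn{x = \ln[Ag]}.
#'
#' @param A upper asymptote, in signal units (> 0). Proportional to the
#'   total concentration of antibody binding sites in the sample.
#' @param k growth rate (> 0). The binding equilibrium model forces
#'   \code{k = 1}; a free \code{k} is retained as a diagnostic.
#' @param x_i inflection point on the \eqn{\ln} molar antigen axis
#'   (unitless "lnKD"). Lower values mean stronger binding.
#' @param d asymmetry parameter. \code{d = 2} gives the logistic curve,
#'   \code{d -> 1} the Gompertz limit; fits constrain \eqn{d \in (1, 2]}.
#'   Evaluation is defined for any \code{d > 1}.
#' @return An object of class \code{"richards_params"}.
#' @examples
#' p <- richards_params(A = 1e4, x_i = -10.5, d = 1.6)
#' eval_richards(-10.5, p)
#' @export
richards_params <- function(A, x_i, d, k = 1) {
  stopifnot(is.numeric(A), is.numeric(k), is.numeric(x_i), is.numeric(d),
            length(A) == 1L, length(k) == 1L, length(x_i) == 1L,
            length(d) == 1L)
  if (!is.finite(A) || A <= 0) stop("'A' must be finite and > 0")
  if (!is.finite(k) || k <= 0) stop("'k' must be finite and > 0")
  if (!is.finite(x_i)) stop("'x_i' must be finite")
  if (!is.finite(d) || d <= 1) stop("'d' must be finite and > 1")
  structure(list(A = A, k = k, x_i = x_i, d = d),
            class = "richards_params")
}

#' @export
print.richards_params <- function(x, ...) {
  cat("Richards curve parameters\n")
  cat(sprintf("  A   = %g (upper asymptote)\n", x$A))
  cat(sprintf("  k   = %g (growth rate)\n", x$k))
  cat(sprintf("  x_i = %g (inflection, ln M)\n", x$x_i))
  cat(sprintf("  d   = %g (asymmetry; limiting slope k/(d-1) = %g)\n",
              x$d, x$k / (x$d - 1)))
  invisible(x)
}

#' Parameters of the two-dimensional antigen-by-dilution product model
#'
#' Container for the five parameters of the product of two generalized
#' logistic functions
#' \deqn{R_2(x, z) = C (B + z)^{-m} (1 + (d-1) e^{-(x - x_i)})^{1/(1-d)}}
#' where \eqn{x = \ln[Ag]} and \eqn{z \ge 1} is the serum fold-dilution.
#' The growth rate along \code{x} is fixed at 1 by the binding model; the
#' dilution factor \eqn{C (B+z)^{-m}} is the upper limit \eqn{A(z)} of the
#' antigen titration curve at dilution \code{z} and is the exponential of a
#' second generalized logistic function of \eqn{-\ln z}.
#'
#' @param C scale, in signal units (> 0).
#' @param B dilution offset, same units as \code{z} (> 0).
#' @param m dilution exponent (> 0).
#' @param x_i inflection point on the \eqn{\ln} molar antigen axis.
#' @param d asymmetry parameter, \eqn{d \in (1, 2]} for fits.
#' @return An object of class \code{"twodim_params"}.
#' @examples
#' q <- twodim_params(C = 5e6, B = 50, m = 1, x_i = -10.5, d = 1.6)
#' eval_ln_r2(-10, 100, q)
#' @export
twodim_params <- function(C, B, m, x_i, d) {
  stopifnot(is.numeric(C), is.numeric(B), is.numeric(m), is.numeric(x_i),
            is.numeric(d), length(C) == 1L, length(B) == 1L,
            length(m) == 1L, length(x_i) == 1L, length(d) == 1L)
  if (!is.finite(C) || C <= 0) stop("'C' must be finite and > 0")
  if (!is.finite(B) || B <= 0) stop("'B' must be finite and > 0")
  if (!is.finite(m) || m <= 0) stop("'m' must be finite and > 0")
  if (!is.finite(x_i)) stop("'x_i' must be finite")
  if (!is.finite(d) || d <= 1) stop("'d' must be finite and > 1")
  structure(list(C = C, B = B, m = m, x_i = x_i, d = d),
            class = "twodim_params")
}

#' @export
print.twodim_params <- function(x, ...) {
  cat("Two-dimensional titration model parameters\n")
  cat(sprintf("  C   = %g, B = %g, m = %g (dilution factor C*(B+z)^-m)\n",
              x$C, x$B, x$m))
  cat(sprintf("  x_i = %g (inflection, ln M)\n", x$x_i))
  cat(sprintf("  d   = %g (asymmetry)\n", x$d))
  invisible(x)
}

#' Ground-truth physical parameters for the binding-model simulator
#'
#' Describes one detection channel of a simulated microspot experiment:
#' equilibrium formation of antibody-antigen complexes with
#' surface-inhibition constant \code{d_const}, a log-log linear detection
#' transform, and multiplicative (lognormal) measurement noise.
#'
#' @param ab_conc total antibody concentration in the undiluted sample (M).
#' @param kd equilibrium dissociation constant (M).
#' @param d_const inhibition constant \eqn{D} of the complex-formation
#'   equation (1/M); the bound-complex concentration saturates at
#'   \eqn{1/D} as antigen density grows.
#' @param alpha detection scale: signal units per \eqn{M^\beta}.
#' @param beta detection log-log slope (default 1, linear detection).
#' @param noise_sigma standard deviation of the log-signal noise
#'   (unitless, >= 0).
#' @return An object of class \code{"binding_model_params"}.
#' @export
binding_model_params <- function(ab_conc, kd, d_const, alpha = 1e10,
                                 beta = 1, noise_sigma = 0) {
  stopifnot(is.numeric(ab_conc), is.numeric(kd), is.numeric(d_const),
            is.numeric(alpha), is.numeric(beta), is.numeric(noise_sigma))
  if (ab_conc <= 0) stop("'ab_conc' must be > 0")
  if (kd <= 0) stop("'kd' must be > 0")
  if (d_const <= 0) stop("'d_const' must be > 0")
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(list(ab_conc = ab_conc, kd = kd, d_const = d_const,
                 alpha = alpha, beta = beta, noise_sigma = noise_sigma),
            class = "binding_model_params")
}

#' @export
print.binding_model_params <- function(x, ...) {
  cat("Binding-model simulator parameters\n")
  cat(sprintf("  [Ab] = %g M, KD = %g M, D = %g 1/M\n",
              x$ab_conc, x$kd, x$d_const))
  cat(sprintf("  detection: RFI = %g * [AbAg]^%g; ln-noise sd = %g\n",
              x$alpha, x$beta, x$noise_sigma))
  invisible(x)
}
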
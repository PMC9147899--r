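#' Equilibrium concentration of antibody-antigen complexes
#'
#' The surface binding model with self-inhibition:
#' \deqn{[AbAg] = \frac{[Ab][Ag]}{K_D + [Ab] + D [Ab][Ag]}}
#' where a bound antibody inhibits nearby free antigen from engaging other
#' antibodies (constant \code{D > 0}, 1/M). At fixed \code{[Ab]} this is a
#' logistic function of \eqn{\ln[Ag]} with growth rate 1, midpoint at
#' \eqn{[Ag] = (K_D + [Ab])/(D [Ab])} and saturation level \eqn{1/D}.
#'
#' @param ag antigen concentration (M), vector, >= 0.
#' @param ab free antibody concentration (M), >= 0.
#' @param kd equilibrium dissociation constant (M), > 0.
#' @param d_const inhibition constant D (1/M), > 0.
#' @return complex concentration (M), in \code{[0, 1/d_const)}.
#' @export
bound_complex_concentration <- function(ag, ab, kd, d_const) {
  stopifnot(is.numeric(ag), is.numeric(ab), is.numeric(kd),
            is.numeric(d_const))
  if (any(ag < 0) || any(ab < 0)) stop("'ag' and 'ab' must be >= 0")
  if (kd <= 0) stop("'kd' must be > 0")
  if (d_const <= 0) stop("'d_const' must be > 0")
  if (kd + max(ab) <= 0) stop("'kd' + 'ab' must be > 0")
  ab * ag / (kd + ab + d_const * ab * ag)
}

#' Fluorescence detection transform
#'
#' Maps bound-complex concentration to relative fluorescence intensity:
#' \code{RFI = alpha * conc^beta}, i.e. log RFI is affine in log
#' concentration with slope \code{beta} (log-log linear detection).
#'
#' @param complex_conc complex concentration (M), vector, >= 0.
#' @param alpha detection scale (> 0).
#' @param beta log-log slope (default 1).
#' @return RFI vector in signal units.
#' @export
detection_transform <- function(complex_conc, alpha = 1e10, beta = 1) {
  stopifnot(is.numeric(complex_conc))
  if (any(complex_conc < 0)) stop("'complex_conc' must be >= 0")
  if (alpha <= 0) stop("'alpha' must be > 0")
  alpha * complex_conc^beta
}

# expected noise-free specific signal for one channel's truth object
.expected_signal <- function(truth, conc, z) {
  if (inherits(truth, "binding_model_params")) {
    ab <- truth$ab_conc / z
    detection_transform(
      bound_complex_concentration(conc, ab, truth$kd, truth$d_const),
      truth$alpha, truth$beta)
  } else if (inherits(truth, "twodim_params")) {
    exp(eval_ln_r2(log(conc), z, truth))
  } else {
    stop("truth must be binding_model_params or twodim_params")
  }
}

.truth_noise_sigma <- function(truth, noise_sigma) {
  if (!is.null(noise_sigma)) return(noise_sigma)
  if (inherits(truth, "binding_model_params")) truth$noise_sigma else 0
}

#' Simulate a spot-level microspot titration experiment
#'
#' Generates per-spot RFI records for every (antigen concentration,
#' replicate, serum dilution, channel) cell of a layout. The per-channel
#' truth is either a [binding_model_params()] object (signal from the
#' equilibrium complex-formation model, antibody diluted ideally as
#' \code{ab_conc / z}) or a [twodim_params()] object (signal directly from
#' the two-dimensional product model).
#'
#' The lowest-concentration spots carry serum-specific background only
#' (no specific binding); by default the background level per dilution is
#' pegged to the expected specific signal at that lowest concentration, so
#' that the downstream background subtraction is exactly self-consistent
#' on noiseless data. Noise is multiplicative lognormal on the total spot
#' intensity: \code{RFI = (signal + background) * exp(eps)},
#' \code{eps ~ N(0, noise_sigma^2)}, giving constant variance on the log
#' scale.
#'
#' @param layout an [array_layout()].
#' @param params one truth object, or a named list with one truth object
#'   per layout channel.
#' @param seed integer seed; mandatory, no hidden RNG state is used.
#' @param background optional background level override: a single number
#'   (signal units, applied at every dilution) or \code{NULL} for the
#'   default pegging described above.
#' @param noise_sigma optional override of the log-signal noise sd (needed
#'   when the truth is a \code{twodim_params}, which carries no noise
#'   field); default takes \code{noise_sigma} from the truth object or 0.
#' @return A \code{spot_table} data frame with columns \code{block}
#'   (dilution index), \code{row} (replicate), \code{column} (concentration
#'   rank, 1 = highest), \code{id}, \code{conc} (M), \code{replicate},
#'   \code{dilution} (fold), \code{channel}, \code{rfi}.
#' @export
simulate_experiment <- function(layout, params, seed, background = NULL,
                                noise_sigma = NULL) {
  stopifnot(inherits(layout, "array_layout"))
  if (missing(seed)) stop("'seed' is mandatory")
  if (inherits(params, "binding_model_params") ||
      inherits(params, "twodim_params")) {
    params <- stats::setNames(rep(list(params), length(layout$channels)),
                              layout$channels)
  }
  if (!all(layout$channels %in% names(params)))
    stop("'params' must name every layout channel")

  concs <- layout$antigen_concs
  zs <- layout$dilutions
  reps <- seq_len(layout$n_replicates)
  conc_min <- min(concs)

  grid <- expand.grid(replicate = reps,
                      column = seq_along(concs),
                      block = seq_along(zs),
                      channel = layout$channels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$conc <- concs[grid$column]
  grid$dilution <- zs[grid$block]
  grid$row <- grid$replicate
  grid$id <- sprintf("Ag%02d", grid$column)

  set.seed(as.integer(seed))
  rfi <- numeric(nrow(grid))
  for (ch in layout$channels) {
    truth <- params[[ch]]
    sigma <- .truth_noise_sigma(truth, noise_sigma)
    sel <- grid$channel == ch
    spec <- .expected_signal(truth, grid$conc[sel], grid$dilution[sel])
    # background spots: lowest concentration carries background only
    spec[grid$conc[sel] == conc_min] <- 0
    if (is.null(background)) {
      bg <- .expected_signal(truth, conc_min, grid$dilution[sel])
    } else {
      bg <- background
    }
    eps <- stats::rnorm(sum(sel), 0, sigma)
    rfi[sel] <- (spec + bg) * exp(eps)
  }
  grid$rfi <- rfi
  out <- grid[, c("block", "row", "column", "id", "conc", "replicate",
                  "dilution", "channel", "rfi")]
  class(out) <- c("spot_table", "data.frame")
  attr(out, "layout") <- layout
  out
}
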
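# Conventional serum-titration endpoints, computed per antigen density.
# These are the quantities the two-dimensional fit is designed to replace:
# both depend on the printed antigen density, unlike (x_i, d).

.titer_result <- function(value = NA_real_, defined = FALSE,
                          reason = NA_character_, extrapolated = FALSE,
                          censored = FALSE, rule = NA_character_,
                          diagnostics = NULL) {
  structure(list(value = value, defined = defined, reason = reason,
                 extrapolated = extrapolated, censored = censored,
                 rule = rule, diagnostics = diagnostics),
            class = "titer_estimate")
}

#' @export
print.titer_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("titer z* = %.4g%s%s\n", x$value,
                if (x$extrapolated) " (extrapolated)" else "",
                if (x$censored) " (right-censored)" else ""))
  } else {
    cat(sprintf("titer undefined: %s\n", x$reason))
  }
  if (!is.na(x$rule)) cat("  rule:", x$rule, "\n")
  invisible(x)
}

#' Mid-point titer of a dilution curve
#'
#' Fits a three-parameter logistic (lower asymptote pinned at 0, since
#' signals are background-subtracted upstream) to signal versus
#' \eqn{-\ln z} and returns the fold-dilution at which the fitted signal
#' is half the fitted plateau. A mid-point outside the tested dilution
#' range is flagged as extrapolated.
#'
#' @param z fold-dilutions (>= 1), at least 4.
#' @param signal background-subtracted signals (linear scale), decreasing
#'   in \code{z} overall.
#' @return a \code{titer_estimate}: \code{value} (the titer \eqn{z^*}),
#'   \code{defined}, \code{reason} when undefined, \code{extrapolated}
#'   flag and the logistic fit diagnostics.
#' @export
midpoint_titer <- function(z, signal) {
  stopifnot(is.numeric(z), is.numeric(signal), length(z) == length(signal))
  ok <- is.finite(z) & is.finite(signal)
  z <- z[ok]; signal <- signal[ok]
  if (length(z) < 4)
    return(.titer_result(reason = sprintf("need >= 4 dilutions, have %d",
                                          length(z))))
  if (any(z < 1)) stop("fold-dilutions must be >= 1")
  if (max(signal) <= 0)
    return(.titer_result(reason = "no signal"))
  o <- order(z)
  z <- z[o]; signal <- signal[o]
  if (signal[1] <= signal[length(signal)] || diff(range(signal)) == 0)
    return(.titer_result(reason = "signal not decreasing with dilution"))
  u <- -log(z)
  fit <- tryCatch(
    stats::nls(signal ~ SSlogis(u, Asym, xmid, scal),
               data = data.frame(u = u, signal = signal),
               # scaleOffset keeps convergence well-defined on (near)
               # zero-residual curves such as noiseless simulations
               control = stats::nls.control(maxiter = 100, scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit))
    return(.titer_result(reason = "logistic fit failure"))
  cf <- stats::coef(fit)
  if (cf[["Asym"]] <= 0)
    return(.titer_result(reason = "fitted plateau not positive"))
  zstar <- exp(-cf[["xmid"]])
  .titer_result(value = zstar, defined = TRUE,
                extrapolated = zstar < min(z) || zstar > max(z),
                rule = "half of fitted plateau, logistic in -ln z, lower asymptote 0",
                diagnostics = as.list(cf))
}

#' End-point titer of a dilution curve
#'
#' The highest fold-dilution whose signal exceeds
#' \code{background_mean + c * background_sd}, log-linearly interpolated
#' to the threshold crossing between adjacent tested dilutions. If even
#' the highest tested dilution is above threshold the result is the
#' maximal tested dilution with a right-censoring flag.
#'
#' @inheritParams midpoint_titer
#' @param background_mean,background_sd background statistics on the same
#'   scale as \code{signal} (for background-subtracted signals the mean is
#'   0 and the sd comes from the background spot replicates).
#' @param c threshold multiplier (default 3).
#' @return a \code{titer_estimate} with the threshold rule recorded.
#' @export
endpoint_titer <- function(z, signal, background_mean = 0, background_sd,
                           c = 3) {
  stopifnot(is.numeric(z), is.numeric(signal), length(z) == length(signal))
  if (missing(background_sd) || !is.finite(background_sd) || background_sd < 0)
    stop("'background_sd' must be a finite non-negative number")
  ok <- is.finite(z) & is.finite(signal)
  z <- z[ok]; signal <- signal[ok]
  if (!length(z)) return(.titer_result(reason = "no data"))
  if (any(z < 1)) stop("fold-dilutions must be >= 1")
  thr <- background_mean + c * background_sd
  rule <- sprintf("background mean + %g * SD = %.4g, log-linear interpolation",
                  c, thr)
  o <- order(z)
  z <- z[o]; signal <- signal[o]
  above <- signal > thr
  if (!any(above))
    return(.titer_result(reason = "no signal above threshold", rule = rule))
  i <- max(which(above))
  if (i == length(z))
    return(.titer_result(value = z[i], defined = TRUE, censored = TRUE,
                         rule = rule))
  # interpolate in ln z between the last above-threshold point and the next
  lz <- log(z[i]) + (signal[i] - thr) / (signal[i] - signal[i + 1]) *
    (log(z[i + 1]) - log(z[i]))
  .titer_result(value = exp(lz), defined = TRUE, rule = rule)
}

#' Conventional titers as a function of antigen density
#'
#' Computes mid-point and end-point titers separately for every printed
#' antigen density (the lowest, background density excluded) and channel.
#' On data generated from the equilibrium binding model both titer types
#' increase with antigen density, while the inflection point and asymmetry
#' of the two-dimensional fit of the same data do not depend on which
#' densities are used - the contrast that motivates curve-shape-based
#' quantitation.
#'
#' @param spots a \code{spot_table}; replicate aggregation and background
#'   subtraction are applied internally (see [aggregate_replicates()]).
#' @param c end-point threshold multiplier (default 3).
#' @return data frame with one row per (antigen concentration, channel):
#'   the two titers, definedness reasons, censoring/extrapolation flags and
#'   the threshold rule used.
#' @export
titer_vs_density <- function(spots, c = 3) {
  stopifnot(is.data.frame(spots))
  tbl <- suppressMessages(aggregate_replicates(spots))
  bg <- attr(tbl, "background")
  fit_rows <- tbl[!tbl$excluded, , drop = FALSE]
  concs <- sort(unique(exp(fit_rows$x)), decreasing = TRUE)
  if (length(concs) < 2)
    stop(sprintf("need >= 2 antigen densities with dilution curves, have %d",
                 length(concs)))
  out <- NULL
  for (ch in unique(fit_rows$channel)) {
    # pooled background-spot scatter for this channel (subtracted scale)
    bsd <- bg$bg_sd[bg$channel == ch]
    bsd <- if (all(is.na(bsd))) 0 else stats::median(bsd, na.rm = TRUE)
    for (cc in concs) {
      cur <- fit_rows[fit_rows$channel == ch &
                        abs(fit_rows$x - log(cc)) < 1e-12, , drop = FALSE]
      sig <- exp(cur$ln_signal)
      mt <- midpoint_titer(cur$z, sig)
      et <- endpoint_titer(cur$z, sig, background_mean = 0,
                           background_sd = bsd, c = c)
      out <- rbind(out, data.frame(
        conc = cc, channel = ch,
        midpoint_titer = mt$value, midpoint_defined = mt$defined,
        midpoint_reason = mt$reason, midpoint_extrapolated = mt$extrapolated,
        endpoint_titer = et$value, endpoint_defined = et$defined,
        endpoint_reason = et$reason, endpoint_censored = et$censored,
        threshold_rule = et$rule, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
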
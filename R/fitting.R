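# Nonlinear least-squares fitting of the 1D Richards model and the 2D
# product model on the log-signal scale.
#
# Constrained parameters are reparameterized so unconstrained Gauss-Newton
# steps cannot leave the domain:
#   d = 1 + plogis(eta)   (d in (1, 2))
#   A = exp(lnA), k = exp(lnk), C = exp(lnC), B = exp(lnB), m = exp(lnm)

# logistic part shared by both models, with analytic derivatives.
# Returns g = (1/(1-d)) log1p((d-1) e^{-k(x - x_i)}) and partials wrt
# x_i, k (natural) and d (natural), handling overflow and the d -> 1 limit.
.logistic_part <- function(x, x_i, d, k = 1) {
  t <- k * (x - x_i)
  n <- length(t)
  a <- d - 1
  g <- dg_xi <- dg_k <- dg_d <- numeric(n)
  if (a < .gompertz_eps) {
    E <- exp(pmin(-t, .exp_overflow))
    g <- -E
    dg_xi <- -k * E
    dg_k <- (x - x_i) * E
    dg_d <- E^2 / 2
  } else {
    big <- (-t) > .exp_overflow
    if (any(big)) {
      tb <- t[big]
      g[big] <- -(log(a) - tb) / a
      dg_xi[big] <- -k / a
      dg_k[big] <- (x[big] - x_i) / a
      dg_d[big] <- (-1 + log(a) - tb) / a^2
    }
    if (any(!big)) {
      E <- exp(-t[!big])
      u <- a * E
      L <- log1p(u)
      w <- E / (1 + u)
      g[!big] <- -L / a
      dg_xi[!big] <- -k * w
      dg_k[!big] <- (x[!big] - x_i) * w
      dg_d[!big] <- (-a * w + L) / a^2
    }
  }
  list(g = g, dg_xi = dg_xi, dg_k = dg_k, dg_d = dg_d)
}

.d_from_eta <- function(eta) 1 + stats::plogis(eta)
.eta_from_d <- function(d) stats::qlogis(pmin(pmax(d - 1, 1e-12), 1 - 1e-12))

# model closures -------------------------------------------------------------

.model_r1d <- function(x, fix_k) {
  # theta: (lnA, x_i, eta) or (lnA, lnk, x_i, eta)
  function(theta) {
    if (fix_k) {
      lnA <- theta[1]; k <- 1; x_i <- theta[2]; eta <- theta[3]
    } else {
      lnA <- theta[1]; k <- exp(theta[2]); x_i <- theta[3]; eta <- theta[4]
    }
    sig <- stats::plogis(eta)
    d <- 1 + sig
    lp <- .logistic_part(x, x_i, d, k)
    f <- lnA + lp$g
    d_eta <- lp$dg_d * sig * (1 - sig)
    J <- if (fix_k) {
      cbind(lnA = 1, x_i = lp$dg_xi, eta = d_eta)
    } else {
      cbind(lnA = 1, lnk = lp$dg_k * k, x_i = lp$dg_xi, eta = d_eta)
    }
    list(f = f, J = J)
  }
}

.model_r2d <- function(x, z) {
  # theta: (lnC, lnB, lnm, x_i, eta)
  function(theta) {
    lnC <- theta[1]; B <- exp(theta[2]); m <- exp(theta[3])
    x_i <- theta[4]; eta <- theta[5]
    sig <- stats::plogis(eta)
    d <- 1 + sig
    lp <- .logistic_part(x, x_i, d, k = 1)
    lBz <- log(B + z)
    f <- lnC - m * lBz + lp$g
    J <- cbind(lnC = 1,
               lnB = -m * B / (B + z),
               lnm = -m * lBz,
               x_i = lp$dg_xi,
               eta = lp$dg_d * sig * (1 - sig))
    list(f = f, J = J)
  }
}

# ---------------------------------------------------------------------------

.fit_frame <- function(tbl, channel = NULL) {
  if (!is.null(tbl$excluded) || !is.null(tbl$channel)) {
    if (!is.null(channel)) {
      tbl <- tbl[tbl$channel == channel, , drop = FALSE]
    } else if (!is.null(tbl$channel) && length(unique(tbl$channel)) > 1) {
      stop("table has multiple channels; pass 'channel' (channels are fitted independently)")
    }
    if (!is.null(tbl$excluded))
      tbl <- tbl[!tbl$excluded, , drop = FALSE]
  }
  tbl <- tbl[is.finite(tbl$ln_signal), , drop = FALSE]
  tbl
}

#' Deterministic starting values for the titration models
#'
#' For the 1D Richards model: \code{x_i} starts at the antigen
#' concentration where the log signal crosses the middle of its observed
#' range, \code{d} at 1.5 and \code{ln A} just above the maximal signal.
#' For the 2D model the \code{x_i} start comes from the least-diluted
#' curve, \code{m} starts at 1, \code{B} at the smallest dilution and
#' \code{C} so that the model matches the maximal observed signal.
#'
#' @param tbl a \code{binding_table} (or data frame with \code{x},
#'   \code{ln_signal} and, for the 2D model, \code{z}).
#' @param model_kind \code{"richards_1d"} or \code{"r2_2d"}.
#' @param channel channel to use when the table has several.
#' @return named numeric vector of natural-scale starting values.
#' @export
initial_guess <- function(tbl, model_kind = c("richards_1d", "r2_2d"),
                          channel = NULL) {
  model_kind <- match.arg(model_kind)
  df <- .fit_frame(tbl, channel)
  df <- df[order(df$x), , drop = FALSE]
  n_x <- length(unique(df$x))
  if (model_kind == "richards_1d") {
    if (n_x < 4)
      stop(sprintf("insufficient data: %d distinct antigen concentrations with finite signal (need >= 4)",
                   n_x))
    xi0 <- .half_range_x(df$x, df$ln_signal)
    c(A = exp(max(df$ln_signal) + 0.2), k = 1, x_i = xi0, d = 1.5)
  } else {
    if (is.null(df$z)) stop("2D model needs a dilution column 'z'")
    n_z <- length(unique(df$z))
    if (n_z < 2 || n_x < 4)
      stop(sprintf("insufficient data: %d dilutions (need >= 2), %d antigen concentrations (need >= 4)",
                   n_z, n_x))
    z0 <- min(df$z)
    low <- df[df$z == z0, , drop = FALSE]
    xi0 <- .half_range_x(low$x, low$ln_signal)
    m0 <- 1
    B0 <- z0
    lnC0 <- max(low$ln_signal) + 0.2 + m0 * log(B0 + z0)
    c(C = exp(lnC0), B = B0, m = m0, x_i = xi0, d = 1.5)
  }
}

# x where ln_signal crosses the middle of its range (linear interpolation)
.half_range_x <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (diff(range(y)) < 1e-12) return(stats::median(x))
  target <- (min(y) + max(y)) / 2
  above <- which(y >= target)
  i <- above[1]
  if (i == 1) return(x[1])
  x[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
}

.new_fit <- function(model_kind, coef, theta, gn, df, k_fixed, flags) {
  est <- if (model_kind == "richards_1d") {
    richards_params(A = coef[["A"]], k = coef[["k"]], x_i = coef[["x_i"]],
                    d = coef[["d"]])
  } else {
    twodim_params(C = coef[["C"]], B = coef[["B"]], m = coef[["m"]],
                  x_i = coef[["x_i"]], d = coef[["d"]])
  }
  structure(list(model_kind = model_kind, estimates = est,
                 coef = coef, theta = theta, k_fixed = k_fixed,
                 sse = gn$sse, n_obs = nrow(df),
                 converged = gn$converged, n_iter = gn$n_iter,
                 damped = gn$damped, gradient_norm = gn$gradient_norm,
                 residuals = gn$residuals, fitted = gn$fitted,
                 flags = flags, data = df, ci = NULL, level = NULL),
            class = "microspot_fit")
}

#' Fit the 1D Richards model to one antigen titration curve
#'
#' Minimizes \eqn{\sum (\ln signal - \ln R(x))^2} over the curve
#' parameters by Gauss-Newton with step-halving, with \code{d}
#' constrained to (1, 2) through an internal logistic reparameterization.
#' \code{k} is fixed at 1 by default (the value forced by the binding
#' equilibrium model); \code{fix_k = FALSE} frees it as a diagnostic.
#'
#' @param curve data frame with columns \code{x} (ln molar antigen
#'   concentration) and \code{ln_signal}; a \code{binding_table} restricted
#'   to one dilution/channel also works (excluded rows are ignored).
#' @param fix_k keep the growth rate at 1 (default TRUE).
#' @param init optional named vector of natural-scale starting values
#'   (\code{A}, \code{k}, \code{x_i}, \code{d}); default [initial_guess()].
#' @param control optional list: \code{maxit} (200), \code{tol} (1e-10
#'   relative SSE change), \code{max_halvings} (30).
#' @return A \code{microspot_fit} object; \code{converged = FALSE} flags
#'   non-convergence, never a silent bad result.
#' @export
fit_richards_1d <- function(curve, fix_k = TRUE, init = NULL,
                            control = list()) {
  df <- .fit_frame(curve)
  n_x <- length(unique(df$x))
  need <- if (fix_k) 4 else 5
  if (n_x < need)
    stop(sprintf("insufficient data: %d distinct antigen concentrations with finite signal (need >= %d)",
                 n_x, need))
  if (is.null(init)) init <- initial_guess(df, "richards_1d")
  if (is.na(init["k"])) init["k"] <- 1
  theta0 <- if (fix_k) {
    c(log(init[["A"]]), init[["x_i"]], .eta_from_d(init[["d"]]))
  } else {
    c(log(init[["A"]]), log(init[["k"]]), init[["x_i"]],
      .eta_from_d(init[["d"]]))
  }
  model <- .model_r1d(df$x, fix_k)
  gn <- .gn_fit(theta0, df$ln_signal, model, control = control)
  th <- gn$theta
  coef <- if (fix_k) {
    c(A = exp(th[1]), k = 1, x_i = th[2], d = .d_from_eta(th[3]))
  } else {
    c(A = exp(th[1]), k = exp(th[2]), x_i = th[3], d = .d_from_eta(th[4]))
  }
  flags <- list(
    xi_out_of_range = coef[["x_i"]] < min(df$x) || coef[["x_i"]] > max(df$x),
    d_near_lower = coef[["d"]] < 1 + 1e-4,
    d_near_upper = coef[["d"]] > 2 - 1e-4)
  .new_fit("richards_1d", coef, th, gn, df, k_fixed = fix_k, flags = flags)
}

#' Fit the two-dimensional antigen-by-dilution product model
#'
#' Minimizes \eqn{\sum (\ln signal - \ln R_2(x, z))^2} over all
#' (concentration, dilution) cells of one channel, with a single shared
#' \code{(x_i, d)} across dilutions. The inflection point is only
#' meaningful inside the measured concentration range; an estimate outside
#' \code{[min x, max x]} raises the \code{xi_out_of_range} flag.
#'
#' @param tbl a \code{binding_table} (from [aggregate_replicates()]) or a
#'   data frame with columns \code{x}, \code{z}, \code{ln_signal}.
#' @param channel channel to fit when the table carries several (channels
#'   are always fitted independently).
#' @param init optional named vector (\code{C}, \code{B}, \code{m},
#'   \code{x_i}, \code{d}) of starting values.
#' @param control see [fit_richards_1d()].
#' @return A \code{microspot_fit} object.
#' @export
fit_r2_2d <- function(tbl, channel = NULL, init = NULL, control = list()) {
  df <- .fit_frame(tbl, channel)
  n_x <- length(unique(df$x))
  n_z <- length(unique(df$z))
  if (n_z < 2 || n_x < 4)
    stop(sprintf("insufficient data: %d dilutions (need >= 2), %d antigen concentrations (need >= 4)",
                 n_z, n_x))
  if (is.null(init)) init <- initial_guess(df, "r2_2d")
  theta0 <- c(log(init[["C"]]), log(init[["B"]]), log(init[["m"]]),
              init[["x_i"]], .eta_from_d(init[["d"]]))
  model <- .model_r2d(df$x, df$z)
  gn <- .gn_fit(theta0, df$ln_signal, model, control = control)
  th <- gn$theta
  coef <- c(C = exp(th[1]), B = exp(th[2]), m = exp(th[3]),
            x_i = th[4], d = .d_from_eta(th[5]))
  flags <- list(
    xi_out_of_range = coef[["x_i"]] < min(df$x) || coef[["x_i"]] > max(df$x),
    d_near_lower = coef[["d"]] < 1 + 1e-4,
    d_near_upper = coef[["d"]] > 2 - 1e-4)
  .new_fit("r2_2d", coef, th, gn, df, k_fixed = TRUE, flags = flags)
}

#' @export
print.microspot_fit <- function(x, ...) {
  cat(sprintf("Microspot titration fit (%s)%s\n", x$model_kind,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  cat("  estimates:", paste(sprintf("%s = %.6g", names(x$coef), x$coef),
                            collapse = ", "), "\n")
  cat(sprintf("  SSE = %.6g on %d observations; %d iterations%s\n",
              x$sse, x$n_obs, x$n_iter,
              if (x$damped) " (Levenberg damping used)" else ""))
  if (isTRUE(x$flags$xi_out_of_range))
    cat("  warning: x_i outside the measured concentration range; not reliable\n")
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% profile-likelihood confidence intervals:\n",
                100 * x$level))
    print(x$ci, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a fit to a JSON-ready list
#'
#' @param fit a \code{microspot_fit}.
#' @return a plain list (estimates, flags, SSE, diagnostics, CIs) suitable
#'   for \code{jsonlite::write_json(..., auto_unbox = TRUE)}.
#' @export
fit_as_list <- function(fit) {
  stopifnot(inherits(fit, "microspot_fit"))
  out <- list(model_kind = fit$model_kind,
              estimates = as.list(fit$coef),
              k_fixed = fit$k_fixed,
              sse = fit$sse, n_obs = fit$n_obs,
              converged = fit$converged, n_iter = fit$n_iter,
              damped = fit$damped,
              gradient_norm = fit$gradient_norm,
              flags = fit$flags)
  if (!is.null(fit$ci)) {
    out$ci_level <- fit$level
    out$ci <- fit$ci
  }
  out
}
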
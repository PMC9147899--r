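# Internal Gauss-Newton least-squares engine with step-halving line search
# and Levenberg damping on rank-deficient normal equations.
#
# model(theta) must return list(f = fitted vector, J = Jacobian d f / d theta)
# on the (unconstrained) transformed parameter scale.

.gn_control <- function(control = list()) {
  def <- list(maxit = 200L, tol = 1e-10, max_halvings = 30L,
              sse_floor = 1e-28, grad_tol = 1e-8)
  def[names(control)] <- control
  def
}

.gn_fit <- function(theta, y, model, fixed = NULL, control = list()) {
  ctl <- .gn_control(control)
  np <- length(theta)
  if (is.null(fixed)) fixed <- rep(FALSE, np)
  if (all(fixed)) {
    m <- model(theta)
    r <- y - m$f
    return(list(theta = theta, sse = sum(r^2), converged = TRUE,
                n_iter = 0L, damped = FALSE, gradient_norm = 0,
                residuals = r, fitted = m$f))
  }
  damped <- FALSE
  m <- model(theta)
  r <- y - m$f
  sse <- sum(r^2)
  if (!is.finite(sse)) stop("initial parameters give non-finite residuals")
  converged <- FALSE
  gradient_norm <- NA_real_
  iter <- 0L
  while (iter < ctl$maxit) {
    iter <- iter + 1L
    J <- m$J[, !fixed, drop = FALSE]
    gradient_norm <- sqrt(sum(crossprod(J, r)^2))
    delta <- tryCatch(qr.coef(qr(J), r), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      # Levenberg damping: inflate the normal-equation diagonal until solvable
      JtJ <- crossprod(J)
      g <- crossprod(J, r)
      lambda <- 1e-8 * max(mean(diag(JtJ)), 1e-300)
      delta <- NULL
      for (i in 1:30) {
        delta <- tryCatch(solve(JtJ + lambda * diag(ncol(JtJ)), g),
                          error = function(e) NULL)
        if (!is.null(delta) && all(is.finite(delta))) break
        lambda <- lambda * 10
        delta <- NULL
      }
      if (is.null(delta)) break
      delta <- drop(delta)
      damped <- TRUE
    }
    # step-halving line search
    alpha <- 1
    accepted <- FALSE
    for (h in seq_len(ctl$max_halvings)) {
      cand <- theta
      cand[!fixed] <- theta[!fixed] + alpha * delta
      mc <- tryCatch(model(cand), error = function(e) NULL)
      if (!is.null(mc)) {
        rc <- y - mc$f
        ssec <- sum(rc^2)
        if (is.finite(ssec) && ssec < sse) {
          accepted <- TRUE
          theta <- cand
          m <- mc
          r <- rc
          rel <- (sse - ssec) / max(sse, 1e-300)
          sse <- ssec
          if (rel < ctl$tol || sse < ctl$sse_floor) converged <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      # no descent direction left: at a (possibly flat) minimum
      converged <- gradient_norm <= ctl$grad_tol * max(1, sse) ||
        sse < ctl$sse_floor || gradient_norm < 1e-6
      break
    }
    if (converged) break
  }
  J <- m$J[, !fixed, drop = FALSE]
  gradient_norm <- sqrt(sum(crossprod(J, r)^2))
  list(theta = theta, sse = sse, converged = converged, n_iter = iter,
       damped = damped, gradient_norm = gradient_norm,
       residuals = r, fitted = m$f)
}
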
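# Small damped Newton solver for square nonlinear systems, used by the
# layer-equilibrium polish and the coexistence solvers.  The Jacobian is
# formed by forward differences; a simple backtracking line search enforces
# a decrease of the residual norm.

mf_newton <- function(fn, x0, tol = 1e-11, maxit = 200, fd_h = 1e-7) {
  x <- x0
  n <- length(x0)
  fx <- fn(x)
  if (any(!is.finite(fx)))
    return(list(x = x, residual = Inf, iterations = 0L, converged = FALSE))
  for (it in seq_len(maxit)) {
    nrm <- sqrt(sum(fx^2))
    if (nrm < tol)
      return(list(x = x, residual = nrm, iterations = it - 1L,
                  converged = TRUE))
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- fd_h * max(1, abs(x[j]))
      xp <- x
      xp[j] <- x[j] + h
      fp <- fn(xp)
      if (any(!is.finite(fp))) {   # step off the domain: difference backwards
        xp[j] <- x[j] - h
        fp <- fn(xp)
        h <- -h
      }
      J[, j] <- (fp - fx) / h
    }
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx))
      return(list(x = x, residual = nrm, iterations = it, converged = FALSE))
    lambda <- 1
    repeat {
      xn <- x + lambda * dx
      fnew <- tryCatch(fn(xn), error = function(e) rep(NA_real_, n))
      if (all(is.finite(fnew)) &&
          sqrt(sum(fnew^2)) <= nrm * (1 - 0.25 * lambda) + 1e-15) {
        x <- xn
        fx <- fnew
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-13)
        return(list(x = x, residual = nrm, iterations = it,
                    converged = FALSE))
    }
  }
  list(x = x, residual = sqrt(sum(fx^2)), iterations = maxit,
       converged = sqrt(sum(fx^2)) < tol)
}

# Least-squares |slope| of log(y) on log(x); shared by the layer and
# single-chain exponent fitters.
loglog_slope <- function(x, y, min_points = 5) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]
  y <- y[keep]
  if (length(x) < min_points)
    fg_domain_error(sprintf("need at least %d positive points for a log-log fit",
                            min_points))
  if (diff(range(log(y))) < 1e-12)
    fg_domain_error("degenerate (constant) curve: scaling exponent undefined")
  fit <- stats::lm(log(y) ~ log(x))
  abs(unname(stats::coef(fit)[2]))
}
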
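# Implicit single-step time integration (generalized trapezoidal rule).
#
# The same theta-scheme is used by the full closed-loop solver (with chord
# Newton and finite-difference Jacobian reuse) and, through the generic
# routine below, by small verification problems with closed-form solutions.

#' Generalized trapezoidal integration of an ODE system
#'
#' Advances dy/dt = f(t, y) on the supplied time grid with the theta scheme
#' y1 = y0 + dt ((1-theta) f(t0,y0) + theta f(t1,y1)); theta = 0.5 is the
#' (second-order) trapezoidal rule. The implicit stage is solved by Newton
#' iteration with a finite-difference Jacobian.
#'
#' @param f function(t, y) returning dy/dt.
#' @param y0 initial state vector.
#' @param times strictly increasing time grid (first entry = initial time).
#' @param theta implicitness parameter in (0, 1].
#' @param atol,rtol Newton convergence tolerances.
#' @param max_newton Newton iteration cap per step.
#' @return Matrix (length(times) x length(y0)) of states, one row per time.
#' @export
trap_integrate <- function(f, y0, times, theta = 0.5,
                           atol = 1e-8, rtol = 1e-6, max_newton = 20) {
  stopifnot(theta > 0, theta <= 1, length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0
  y <- y0
  for (k in seq_len(length(times) - 1)) {
    t0 <- times[k]; t1 <- times[k + 1]; dt <- t1 - t0
    f0 <- f(t0, y)
    y1 <- y + dt * f0   # explicit predictor
    for (it in seq_len(max_newton)) {
      f1 <- f(t1, y1)
      g <- y1 - y - dt * ((1 - theta) * f0 + theta * f1)
      if (!all(is.finite(g))) stop("non-finite state at t = ", t1)
      J <- diag(n) - dt * theta * fd_jacobian(f, t1, y1, f1)
      dy <- solve(J, -g)
      y1 <- y1 + dy
      if (max(abs(dy) / (atol + rtol * abs(y1))) < 1) break
    }
    y <- y1
    out[k + 1, ] <- y
  }
  out
}

fd_jacobian <- function(f, t, y, fy = NULL, eps = 1e-7) {
  if (is.null(fy)) fy <- f(t, y)
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(y[j]), 1)
    yp <- y; yp[j] <- yp[j] + h
    J[, j] <- (f(t, yp) - fy) / h
  }
  J
}

#' Discharge of an isolated Windkessel compartment
#'
#' Integrates the RC discharge dP/dt = -(P - Pref) / (Rd C) from P0 with the
#' package's implicit theta scheme; the closed form is
#' P(t) = Pref + (P0 - Pref) exp(-t / (Rd C)).
#'
#' @param C compliance (cm5/dyn).
#' @param Rd distal resistance (dyn.s/cm5).
#' @param P0 initial pressure (dyn/cm2).
#' @param times time grid (s).
#' @param Pref reference pressure.
#' @param ... passed to [trap_integrate()].
#' @return Vector of pressures on `times`.
#' @export
windkessel_discharge <- function(C, Rd, P0, times, Pref = 0, ...) {
  stopifnot(C > 0, Rd > 0)
  drop(trap_integrate(function(t, y) -(y - Pref) / (Rd * C), P0, times, ...))
}
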
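#' Adaptive Dormand-Prince RK45 integration
#'
#' Minimal embedded Runge-Kutta 5(4) solver (Dormand-Prince coefficients)
#' with proportional step-size control and dense sampling by 4th-order
#' Hermite-free re-integration to the requested output times.  Implemented
#' in the package because no ODE solver is available among its dependencies;
#' accuracy is checked in the test suite by tolerance-halving convergence.
#'
#' @param f function(t, y) returning dy/dt (numeric vector).
#' @param y0 numeric initial state.
#' @param times numeric vector of strictly increasing output times; the first
#'   element is the initial time.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param max_steps safety cap on accepted+rejected steps.
#' @return matrix `length(times) x length(y0)` of states at `times`.
#' @keywords internal
ode_rk45 <- function(f, y0, times, rtol = 1e-6, atol = 1e-9,
                     max_steps = 1e6) {
  # Dormand-Prince 5(4) tableau
  c2 <- 1 / 5; c3 <- 3 / 10; c4 <- 4 / 5; c5 <- 8 / 9
  a21 <- 1 / 5
  a31 <- 3 / 40; a32 <- 9 / 40
  a41 <- 44 / 45; a42 <- -56 / 15; a43 <- 32 / 9
  a51 <- 19372 / 6561; a52 <- -25360 / 2187; a53 <- 64448 / 6561
  a54 <- -212 / 729
  a61 <- 9017 / 3168; a62 <- -355 / 33; a63 <- 46732 / 5247
  a64 <- 49 / 176; a65 <- -5103 / 18656
  b1 <- 35 / 384; b3 <- 500 / 1113; b4 <- 125 / 192
  b5 <- -2187 / 6784; b6 <- 11 / 84
  # 4th-order embedded weights
  e1 <- 5179 / 57600; e3 <- 7571 / 16695; e4 <- 393 / 640
  e5 <- -92097 / 339200; e6 <- 187 / 2100; e7 <- 1 / 40

  t <- times[1]
  y <- as.numeric(y0)
  n <- length(y)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y
  next_out <- 2L
  t_end <- times[length(times)]
  h <- (t_end - t) / 100
  k1 <- f(t, y)
  steps <- 0L
  while (t < t_end && next_out <= length(times)) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop(sprintf(
        "ODE integration failed: step limit %d reached at t=%g (h=%g)",
        max_steps, t, h))
    # land exactly on the next requested output time
    h <- min(h, times[next_out] - t)
    k2 <- f(t + c2 * h, y + h * a21 * k1)
    k3 <- f(t + c3 * h, y + h * (a31 * k1 + a32 * k2))
    k4 <- f(t + c4 * h, y + h * (a41 * k1 + a42 * k2 + a43 * k3))
    k5 <- f(t + c5 * h, y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
    k6 <- f(t + h, y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 +
                              a65 * k5))
    y5 <- y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
    k7 <- f(t + h, y5)
    y4 <- y + h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err))
      stop(sprintf("ODE integration failed: non-finite error at t=%g", t))
    if (err <= 1) {
      t <- t + h
      y <- y5
      k1 <- k7  # FSAL
      while (next_out <= length(times) && abs(times[next_out] - t) < 1e-12) {
        out[next_out, ] <- y
        next_out <- next_out + 1L
      }
    }
    fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
    h <- h * fac
  }
  if (next_out <= length(times))
    stop("ODE integration failed: did not reach final output time")
  out
}
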
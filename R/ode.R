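# Adaptive Dormand-Prince RK45 integrator. Used by simulate() to integrate
# power-law dynamics in log-concentration space, which preserves positivity
# of the trajectories by construction.

DP_A <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
DP_C <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
DP_B5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
DP_B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200, 187 / 2100, 1 / 40)

# L-stable two-stage Rosenbrock scheme (order 2 with embedded order-1 error
# estimate) for the stiff systems that arise when reactions sit very close to
# equilibrium (kinetic orders of magnitude theta/(1-theta)). `jac` returns the
# Jacobian of f at (t, y).
ode_ros2 <- function(f, jac, y0, t_grid, rtol = 1e-6, atol = 1e-9) {
  gam <- 1 + 1 / sqrt(2)
  t_grid <- sort(unique(as.numeric(t_grid)))
  nvar <- length(y0)
  out <- matrix(NA_real_, length(t_grid), nvar)
  t <- t_grid[1]; y <- as.numeric(y0)
  out[1, ] <- y
  if (length(t_grid) == 1L) return(list(t = t_grid, y = out))
  h <- max((t_grid[length(t_grid)] - t) / 100, 1e-8)
  gi <- 2L; nstep <- 0L
  feval <- function(t, y) tryCatch(f(t, y), error = function(e) rep(NaN, nvar))
  while (gi <= length(t_grid)) {
    if (nstep > 2e5) stop_pf("ODE integration failed: step limit at t = %g", t)
    h_try <- min(h, t_grid[gi] - t)
    J <- tryCatch(jac(t, y), error = function(e) NULL)
    ok <- !is.null(J) && all(is.finite(J))
    if (ok) {
      W <- diag(nvar) - gam * h_try * J
      f0 <- feval(t, y)
      k1 <- tryCatch(solve(W, f0), error = function(e) rep(NaN, nvar))
      f1 <- feval(t + h_try, y + h_try * k1)
      k2 <- tryCatch(solve(W, f1 - 2 * k1), error = function(e) rep(NaN, nvar))
      y2 <- y + h_try * (1.5 * k1 + 0.5 * k2)
      y1 <- y + h_try * k1
      sc <- atol + rtol * pmax(abs(y), abs(y2))
      err <- sqrt(mean(((y2 - y1) / sc)^2))
    } else err <- NaN
    if (!is.finite(err)) {
      h <- h_try / 10
      if (h < 1e-14) stop_pf("ODE integration failed near t = %g", t)
      nstep <- nstep + 1L
      next
    }
    if (err <= 1) {
      t <- t + h_try; y <- y2
      if (abs(t - t_grid[gi]) < 1e-12 * max(1, abs(t_grid[gi]))) {
        out[gi, ] <- y
        gi <- gi + 1L
      }
    }
    fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.5)))
    h <- max(h_try * fac, 1e-14)
    nstep <- nstep + 1L
  }
  list(t = t_grid, y = out)
}

ode_rk45 <- function(f, y0, t_grid, rtol = 1e-8, atol = 1e-10, h_init = NULL) {
  t_grid <- sort(unique(as.numeric(t_grid)))
  stopifnot(length(t_grid) >= 1)
  nvar <- length(y0)
  out <- matrix(NA_real_, length(t_grid), nvar)
  t <- t_grid[1]
  y <- as.numeric(y0)
  out[1, ] <- y
  if (length(t_grid) == 1L) return(list(t = t_grid, y = out))
  h <- h_init %||% max((t_grid[length(t_grid)] - t) / 1000, 1e-8)
  gi <- 2L
  k <- matrix(0, 7, nvar)
  nstep <- 0L
  while (gi <= length(t_grid)) {
    if (nstep > 5e5) stop_pf("ODE integration failed: step limit at t = %g", t)
    t_target <- t_grid[gi]
    h_try <- min(h, t_target - t)
    # a failed rate evaluation (overshoot in a stiff step) rejects the step
    feval <- function(t, y) tryCatch(f(t, y), error = function(e) rep(NaN, nvar))
    k[1, ] <- feval(t, y)
    for (s in 1:6) {
      ys <- y + h_try * as.numeric(matrix(DP_A[[s]], 1) %*% k[seq_along(DP_A[[s]]), , drop = FALSE])
      k[s + 1, ] <- feval(t + DP_C[s] * h_try, ys)
    }
    y5 <- y + h_try * as.numeric(matrix(DP_B5, 1) %*% k)
    y4 <- y + h_try * as.numeric(matrix(DP_B4, 1) %*% k)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) {
      h <- h_try / 10
      if (h < 1e-14) stop_pf("ODE integration failed: non-finite derivative at t = %g", t)
      nstep <- nstep + 1L
      next
    }
    if (err <= 1) {
      t <- t + h_try
      y <- y5
      if (abs(t - t_target) < 1e-12 * max(1, abs(t_target))) {
        out[gi, ] <- y
        gi <- gi + 1L
      }
    }
    fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
    h <- max(h_try * fac, 1e-14)
    nstep <- nstep + 1L
  }
  list(t = t_grid, y = out)
}
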
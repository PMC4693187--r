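# Power-law (S-system / GMA) dynamic models built on top of a network and a
# reference steady state. Total kinetic orders are assembled as
# g = g^k - s * theta/(1-theta) for stoichiometric participants (modifier
# orders are purely kinetic), rate constants follow from the reference state,
# and steady states of S-systems are solved exactly as linear systems in
# log-concentrations. Stability is assessed on the log-space Jacobian, whose
# verdict coincides with the linear-space one (similarity through a positive
# diagonal).

#' Build a power-law model
#'
#' @param net A `metabolic_network`.
#' @param reference A [reference_state()] (defaults to the network's). Must
#'   satisfy the mass-action-quotient identity for every reaction with
#'   theta > 0.
#' @param kinetic_parts Named list reaction id -> named numeric of kinetic
#'   parts g^k covering all stoichiometric participants and modifiers
#'   (defaults to the network's kinetics block).
#' @param theta,keq Named numerics per reaction (defaults from the kinetics
#'   block, then 0 / 1).
#' @return A `power_law_model`.
#' @export
build_model <- function(net, reference = net$reference,
                        kinetic_parts = NULL, theta = NULL, keq = NULL) {
  if (is.null(reference)) stop_pf("build_model needs a reference state")
  kin <- net$kinetics
  kinetic_parts <- kinetic_parts %||% kin$kinetic_parts
  if (is.null(kinetic_parts)) stop_pf("build_model needs kinetic parts")
  rids <- reaction_ids(net)
  th <- stats::setNames(rep(0, length(rids)), rids)
  kq <- stats::setNames(rep(1, length(rids)), rids)
  if (!is.null(kin$theta)) th[names(kin$theta)] <- kin$theta
  if (!is.null(kin$keq)) kq[names(kin$keq)] <- kin$keq
  if (!is.null(theta)) { theta <- as_named_num(as.list(theta)); th[names(theta)] <- theta }
  if (!is.null(keq)) { keq <- as_named_num(as.list(keq)); kq[names(keq)] <- keq }
  if (any(th < 0 | th >= 1)) stop_pf("theta must lie in [0, 1)")
  # mass-action-quotient consistency for reactions at finite distance
  ref_chk <- reference
  ref_chk$theta <- th; ref_chk$keq <- kq
  check_reference_state(net, ref_chk)

  rates <- list()
  for (r in net$reactions) {
    kp <- kinetic_parts[[r$id]]
    need <- c(names(r$stoich), names(r$modifiers))
    missing_kp <- setdiff(need, names(kp))
    if (length(missing_kp) > 0L) stop_pf("reaction '%s': missing kinetic part for %s",
                                         r$id, paste(missing_kp, collapse = ", "))
    tc <- if (th[[r$id]] > 0) th[[r$id]] / (1 - th[[r$id]]) else 0
    orders <- stats::setNames(numeric(length(need)), need)
    for (j in names(r$stoich)) orders[j] <- kp[[j]] - r$stoich[[j]] * tc
    for (j in names(r$modifiers)) orders[j] <- kp[[j]]
    rates[[r$id]] <- list(orders = orders, kinetic_parts = kp[need],
                          theta = th[[r$id]], keq = kq[[r$id]])
  }
  la <- rate_log_constants(reference, lapply(rates, `[[`, "orders"))
  for (rid in names(rates)) {
    rates[[rid]]$log_alpha <- la[[rid]]
    rates[[rid]]$alpha <- exp(la[[rid]])
  }
  model <- structure(list(
    dependent_ids = dependent_ids(net),
    independent_ids = independent_ids(net),
    reaction_ids = rids,
    rates = rates,
    stoich = stoichiometric_matrix(net, rows = "dependent"),
    reference = reference
  ), class = "power_law_model")
  # invariant: reference reproduction
  v0 <- evaluate_rates(model, reference$concentrations)
  ref_v <- reference$fluxes[rids]
  rel <- abs(v0 - ref_v) / pmax(abs(ref_v), 1e-300)
  if (any(rel > 1e-9)) stop_pf("internal error: reference fluxes not reproduced")
  model
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("power_law_model: %d dependent, %d independent, %d reactions\n",
              length(x$dependent_ids), length(x$independent_ids), length(x$reaction_ids)))
  invisible(x)
}

#' Rate constants from a reference state
#'
#' `ln alpha_i = ln v0_i - sum_j g_ij ln x0_j`, so that evaluating each power
#' law at the reference reproduces the reference flux exactly.
#'
#' @param reference A [reference_state()] with positive fluxes and
#'   concentrations.
#' @param orders Named list reaction id -> named numeric of total orders.
#' @return Named numeric of rate constants alpha.
#' @export
rate_constants <- function(reference, orders) {
  exp(rate_log_constants(reference, orders))
}

# same, in log space (rate constants can overflow doubles near equilibrium)
rate_log_constants <- function(reference, orders) {
  v0 <- reference$fluxes; x0 <- reference$concentrations
  if (any(v0 <= 0)) stop_pf("reference fluxes must be positive")
  if (any(x0 <= 0)) stop_pf("reference concentrations must be positive")
  out <- stats::setNames(rep(NA_real_, length(orders)), names(orders))
  for (rid in names(orders)) {
    g <- orders[[rid]]
    xs <- x0[names(g)]
    if (anyNA(xs)) stop_pf("reaction '%s': reference concentration missing", rid)
    if (is.na(v0[rid])) stop_pf("reaction '%s': reference flux missing", rid)
    out[rid] <- log(v0[[rid]]) - sum(g * log(xs))
  }
  out
}

# log rate constant of a rate entry (backward compatible with plain alpha)
log_alpha_of <- function(r) r$log_alpha %||% log(r$alpha)

#' Evaluate all power-law rates at a concentration vector
#'
#' @param model A `power_law_model`.
#' @param x Named concentrations covering every metabolite with an order.
#' @return Named numeric of rates.
#' @export
evaluate_rates <- function(model, x) {
  vapply(model$reaction_ids, function(rid) {
    r <- model$rates[[rid]]
    xs <- x[names(r$orders)]
    if (anyNA(xs)) stop_pf("evaluate_rates: concentration missing for %s",
                           paste(names(r$orders)[is.na(xs)], collapse = ", "))
    exp(log_alpha_of(r) + sum(r$orders * log(xs)))
  }, numeric(1))
}

# one production and one consumption reaction per dependent variable?
s_system_structure <- function(model) {
  S <- model$stoich
  prod_r <- cons_r <- character(nrow(S))
  for (k in seq_len(nrow(S))) {
    pos <- which(S[k, ] > 0); neg <- which(S[k, ] < 0)
    if (length(pos) != 1L || length(neg) != 1L) return(NULL)
    prod_r[k] <- colnames(S)[pos]; cons_r[k] <- colnames(S)[neg]
  }
  list(prod = prod_r, cons = cons_r)
}

independent_reference <- function(model, independent_values = NULL) {
  iv <- model$reference$concentrations[model$independent_ids]
  if (!is.null(independent_values)) {
    ov <- as_named_num(as.list(independent_values))
    iv[names(ov)] <- ov
  }
  iv
}

# the log-linear steady-state system A y_dep = b for an S-system
s_system_linear <- function(model, independent_values = NULL) {
  ss <- s_system_structure(model)
  if (is.null(ss)) return(NULL)
  dep <- model$dependent_ids
  iv <- independent_reference(model, independent_values)
  yi <- log(iv)
  n <- length(dep)
  A <- matrix(0, n, n, dimnames = list(dep, dep))
  b <- numeric(n)
  S <- model$stoich
  for (k in seq_len(n)) {
    p <- ss$prod[k]; co <- ss$cons[k]
    gp <- model$rates[[p]]$orders; gc <- model$rates[[co]]$orders
    cp <- S[k, p]; cc <- -S[k, co]
    gpd <- gp[names(gp) %in% dep]; gcd <- gc[names(gc) %in% dep]
    if (length(gpd) > 0) A[k, names(gpd)] <- A[k, names(gpd)] + gpd
    if (length(gcd) > 0) A[k, names(gcd)] <- A[k, names(gcd)] - gcd
    bi <- log(cc) + log_alpha_of(model$rates[[co]]) - log(cp) - log_alpha_of(model$rates[[p]])
    gpi <- gp[names(gp) %in% model$independent_ids]
    gci <- gc[names(gc) %in% model$independent_ids]
    if (length(gci) > 0) bi <- bi + sum(gci * yi[names(gci)])
    if (length(gpi) > 0) bi <- bi - sum(gpi * yi[names(gpi)])
    b[k] <- bi
  }
  list(A = A, b = b, prod = ss$prod, cons = ss$cons, yi = yi)
}

#' Steady state of a power-law model
#'
#' Exact log-linear solve for S-systems (one net production and one net
#' consumption term per dependent variable); otherwise a damped Newton
#' iteration on the mass balance, converging to `||xdot||_inf <= 1e-10`.
#'
#' @param model A `power_law_model`.
#' @param independent_values Optional named overrides of the clamped
#'   (independent) concentrations.
#' @return Named numeric of dependent steady-state concentrations.
#' @export
steady_state <- function(model, independent_values = NULL) {
  lin <- s_system_linear(model, independent_values)
  if (!is.null(lin)) {
    qrA <- qr(lin$A)
    if (qrA$rank < nrow(lin$A)) stop_pf("singular log-linear system: steady state undetermined")
    y <- solve(qrA, lin$b)
    return(stats::setNames(exp(as.numeric(y)), model$dependent_ids))
  }
  steady_state_newton(model, independent_values)
}

steady_state_newton <- function(model, independent_values = NULL, tol = 1e-10) {
  dep <- model$dependent_ids
  iv <- independent_reference(model, independent_values)
  y <- log(model$reference$concentrations[dep])
  S <- model$stoich
  fx <- function(y) {
    x <- c(stats::setNames(exp(y), dep), iv)
    as.numeric(S %*% evaluate_rates(model, x))
  }
  jac <- function(y) {
    x <- c(stats::setNames(exp(y), dep), iv)
    v <- evaluate_rates(model, x)
    G <- order_matrix(model, dep)
    S %*% (v * G)
  }
  for (it in seq_len(200)) {
    f <- fx(y)
    if (max(abs(f)) <= tol) return(stats::setNames(exp(as.numeric(y)), dep))
    J <- jac(y)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) stop_pf("singular Jacobian in steady-state iteration")
    lam <- 1
    repeat {
      y_new <- y + lam * step
      f_new <- tryCatch(fx(y_new), error = function(e) rep(Inf, length(f)))
      if (max(abs(f_new)) < max(abs(f)) || lam < 1e-6) break
      lam <- lam / 2
    }
    y <- y + lam * step
  }
  stop_pf("steady-state iteration did not converge (||xdot||_inf = %.3g)", max(abs(fx(y))))
}

# matrix of total orders g_ij, reactions x chosen metabolite columns
order_matrix <- function(model, cols) {
  G <- matrix(0, length(model$reaction_ids), length(cols),
              dimnames = list(model$reaction_ids, cols))
  for (rid in model$reaction_ids) {
    g <- model$rates[[rid]]$orders
    g <- g[names(g) %in% cols]
    if (length(g) > 0) G[rid, names(g)] <- g
  }
  G
}

#' Simulate a power-law model
#'
#' Integrates the dependent concentrations in log space (positivity preserved
#' by construction) with an adaptive Dormand-Prince RK45 scheme.
#'
#' @param model A `power_law_model`.
#' @param x0 Named positive initial concentrations of the dependent variables.
#' @param t_grid Output time grid (first entry is the initial time).
#' @param independent_values Optional clamped-concentration overrides.
#' @param rtol,atol Integration tolerances.
#' @return data.frame with column `time` and one column per dependent variable.
#' @export
simulate_model <- function(model, x0, t_grid, independent_values = NULL,
                           rtol = 1e-8, atol = 1e-10,
                           method = c("auto", "rk45", "rosenbrock")) {
  method <- match.arg(method)
  dep <- model$dependent_ids
  x0 <- as_named_num(as.list(x0))[dep]
  if (anyNA(x0) || any(x0 <= 0)) stop_pf("x0 must give a positive value for every dependent variable")
  iv <- independent_reference(model, independent_values)
  S <- model$stoich
  f <- function(t, y) {
    x <- c(stats::setNames(exp(y), dep), iv)
    v <- evaluate_rates(model, x)
    as.numeric(S %*% v) / exp(y)
  }
  if (method == "auto") {
    gmax <- max(vapply(model$rates, function(r) max(abs(r$orders)), numeric(1)))
    method <- if (gmax > 20) "rosenbrock" else "rk45"
  }
  sol <- if (method == "rosenbrock") {
    G <- order_matrix(model, dep)
    jac <- function(t, y) {
      x <- c(stats::setNames(exp(y), dep), iv)
      v <- evaluate_rates(model, x)
      fy <- as.numeric(S %*% v) / exp(y)
      (S %*% (v * G)) / exp(y) - diag(fy, length(dep))
    }
    ode_ros2(f, jac, log(x0), t_grid, rtol = max(rtol, 1e-7), atol = max(atol, 1e-9))
  } else {
    ode_rk45(f, log(x0), t_grid, rtol = rtol, atol = atol)
  }
  out <- as.data.frame(exp(sol$y))
  names(out) <- dep
  cbind(data.frame(time = sol$t), out)
}

#' Logarithmic gains with respect to an independent variable
#'
#' For S-systems the gains follow from the log-linear steady-state solve; flux
#' gains are included. `method = "numeric"` re-solves the steady state at
#' perturbed clamps (central differences) and is the cross-check.
#'
#' @param model A `power_law_model`.
#' @param independent_id Independent metabolite id.
#' @param independent_values Optional clamp overrides.
#' @param method `"analytic"` or `"numeric"`.
#' @return Named numeric of gains `L(target, x_indep)` for every dependent
#'   variable (`x_<id>`) and every flux (`v_<id>`).
#' @export
log_gains <- function(model, independent_id, independent_values = NULL,
                      method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (!(independent_id %in% model$independent_ids)) stop_pf("'%s' is not an independent variable", independent_id)
  dep <- model$dependent_ids
  if (method == "numeric") {
    h <- 1e-6
    iv <- independent_reference(model, independent_values)
    up <- iv; up[independent_id] <- iv[independent_id] * exp(h)
    dn <- iv; dn[independent_id] <- iv[independent_id] * exp(-h)
    xu <- steady_state(model, up); xd <- steady_state(model, dn)
    Lx <- (log(xu) - log(xd)) / (2 * h)
    vu <- evaluate_rates(model, c(xu, up)); vd <- evaluate_rates(model, c(xd, dn))
    Lv <- (log(vu) - log(vd)) / (2 * h)
    return(c(stats::setNames(Lx, paste0("x_", dep)),
             stats::setNames(Lv, paste0("v_", model$reaction_ids))))
  }
  lin <- s_system_linear(model, independent_values)
  if (is.null(lin)) return(log_gains(model, independent_id, independent_values, "numeric"))
  # d b / d y_indep
  d <- numeric(length(dep))
  for (k in seq_along(dep)) {
    gp <- model$rates[[lin$prod[k]]]$orders
    gc <- model$rates[[lin$cons[k]]]$orders
    d[k] <- gv(gc, independent_id) - gv(gp, independent_id)
  }
  qrA <- qr(lin$A)
  if (qrA$rank < nrow(lin$A)) stop_pf("singular log-linear system")
  Lx <- as.numeric(solve(qrA, d))
  names(Lx) <- dep
  Lv <- vapply(model$reaction_ids, function(rid) {
    g <- model$rates[[rid]]$orders
    gv(g, independent_id) + sum(vapply(dep, function(j) gv(g, j) * Lx[j], numeric(1)))
  }, numeric(1))
  c(stats::setNames(Lx, paste0("x_", dep)), stats::setNames(Lv, paste0("v_", model$reaction_ids)))
}

#' Parametric sensitivities with respect to a rate constant
#'
#' `S(x_j, alpha_i)` and `S(v_m, alpha_i)` from the log-linear solve
#' (S-systems), with a finite-difference fallback/cross-check.
#'
#' @param model A `power_law_model`.
#' @param reaction_id Reaction whose rate constant alpha is perturbed.
#' @param independent_values Optional clamp overrides.
#' @param method `"analytic"` or `"numeric"`.
#' @return Named numeric over `x_<dep>` and `v_<reaction>` targets.
#' @export
parameter_sensitivities <- function(model, reaction_id, independent_values = NULL,
                                    method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (!(reaction_id %in% model$reaction_ids)) stop_pf("unknown reaction id '%s'", reaction_id)
  dep <- model$dependent_ids
  if (method == "numeric") {
    h <- 1e-6
    perturb <- function(f) {
      m2 <- model
      m2$rates[[reaction_id]]$log_alpha <- log_alpha_of(model$rates[[reaction_id]]) + f * h
      m2$rates[[reaction_id]]$alpha <- exp(m2$rates[[reaction_id]]$log_alpha)
      x <- steady_state(m2, independent_values)
      iv <- independent_reference(m2, independent_values)
      list(x = x, v = evaluate_rates(m2, c(x, iv)))
    }
    up <- perturb(1); dn <- perturb(-1)
    Sx <- (log(up$x) - log(dn$x)) / (2 * h)
    Sv <- (log(up$v) - log(dn$v)) / (2 * h)
    return(c(stats::setNames(Sx, paste0("x_", dep)),
             stats::setNames(Sv, paste0("v_", model$reaction_ids))))
  }
  lin <- s_system_linear(model, independent_values)
  if (is.null(lin)) return(parameter_sensitivities(model, reaction_id, independent_values, "numeric"))
  d <- as.numeric(lin$cons == reaction_id) - as.numeric(lin$prod == reaction_id)
  qrA <- qr(lin$A)
  if (qrA$rank < nrow(lin$A)) stop_pf("singular log-linear system")
  Sx <- as.numeric(solve(qrA, d))
  names(Sx) <- dep
  Sv <- vapply(model$reaction_ids, function(rid) {
    g <- model$rates[[rid]]$orders
    as.numeric(rid == reaction_id) + sum(vapply(dep, function(j) gv(g, j) * Sx[j], numeric(1)))
  }, numeric(1))
  c(stats::setNames(Sx, paste0("x_", dep)), stats::setNames(Sv, paste0("v_", model$reaction_ids)))
}

# log-space Jacobian at a steady state
log_jacobian <- function(model, x_dep, independent_values = NULL) {
  dep <- model$dependent_ids
  iv <- independent_reference(model, independent_values)
  x <- c(x_dep[dep], iv)
  v <- evaluate_rates(model, x)
  G <- order_matrix(model, dep)
  J <- (model$stoich %*% (v * G)) / x_dep[dep]
  dimnames(J) <- list(dep, dep)
  J
}

#' Stability of the steady state
#'
#' Eigenvalues of the log-space Jacobian; for up to three dependent variables
#' the Routh-Hurwitz determinant conditions are evaluated as well and compared
#' with the eigenvalue verdict.
#'
#' @param model A `power_law_model`.
#' @param independent_values Optional clamp overrides.
#' @return List with `eigenvalues`, `stable`, and (n <= 3) `routh_hurwitz`
#'   (logical verdict) plus `rh_agrees`.
#' @export
stability <- function(model, independent_values = NULL) {
  x <- steady_state(model, independent_values)
  J <- log_jacobian(model, x, independent_values)
  ev <- eigen(J, only.values = TRUE)$values
  stable <- all(Re(ev) < 0)
  out <- list(eigenvalues = ev, stable = stable)
  n <- nrow(J)
  if (n <= 3) {
    a <- charpoly_coeffs(J)  # lambda^n + a1 l^{n-1} + ... + an
    rh <- switch(n,
                 a[1] > 0,
                 a[1] > 0 && a[2] > 0,
                 a[1] > 0 && a[3] > 0 && a[1] * a[2] > a[3])
    out$routh_hurwitz <- rh
    out$rh_agrees <- identical(rh, stable) || any(abs(Re(ev)) < 1e-10)
  }
  out
}

charpoly_coeffs <- function(J) {
  n <- nrow(J)
  tr1 <- sum(diag(J))
  if (n == 1L) return(-tr1)
  if (n == 2L) return(c(-tr1, det(J)))
  tr2 <- sum(diag(J %*% J))
  a1 <- -tr1
  a2 <- (tr1^2 - tr2) / 2
  a3 <- -det(J)
  c(a1, a2, a3)
}

#' Critical feedback strength (stability margin)
#'
#' Scans the magnitude of a designated negative modifier order upward,
#' re-deriving the rate constants from the fixed reference state at each
#' magnitude (so the reference remains the steady state), and locates the
#' point where the leading eigenvalue's real part crosses zero by bisection.
#'
#' @param model A `power_law_model`.
#' @param reaction_id Reaction carrying the feedback modifier.
#' @param metabolite_id The modifier metabolite.
#' @param cap Magnitudes above `cap` are reported as `Inf` (default 1e6).
#' @param rel_tol Relative bisection tolerance (default 1e-6).
#' @return Positive critical magnitude, or `Inf` if no crossing below `cap`.
#' @export
feedback_stability_margin <- function(model, reaction_id, metabolite_id,
                                      cap = 1e6, rel_tol = 1e-6) {
  r <- model$rates[[reaction_id]]
  if (is.null(r)) stop_pf("unknown reaction id '%s'", reaction_id)
  if (!(metabolite_id %in% names(r$orders))) stop_pf("'%s' carries no order for '%s'", reaction_id, metabolite_id)
  if (!(metabolite_id %in% names(r$kinetic_parts)) || r$kinetic_parts[[metabolite_id]] > 0) {
    stop_pf("designated order must be a negative (feedback) modifier order")
  }
  lead_re <- function(m) {
    m2 <- set_feedback_magnitude(model, reaction_id, metabolite_id, m)
    x <- steady_state(m2)
    J <- log_jacobian(m2, x)
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  if (lead_re(0) >= 0) stop_pf("model is unstable already at feedback magnitude 0")
  lo <- 0; hi <- 1
  while (lead_re(hi) < 0) {
    lo <- hi; hi <- hi * 2
    if (hi > cap) return(Inf)
  }
  while ((hi - lo) > rel_tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (lead_re(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# rebuild the model with the designated feedback order set to -magnitude,
# keeping the reference state (alphas re-derived)
set_feedback_magnitude <- function(model, reaction_id, metabolite_id, magnitude) {
  m2 <- model
  m2$rates[[reaction_id]]$orders[[metabolite_id]] <- -magnitude
  m2$rates[[reaction_id]]$kinetic_parts[[metabolite_id]] <- -magnitude
  la <- rate_log_constants(model$reference, lapply(m2$rates, `[[`, "orders"))
  for (rid in names(m2$rates)) {
    m2$rates[[rid]]$log_alpha <- la[[rid]]
    m2$rates[[rid]]$alpha <- exp(la[[rid]])
  }
  m2
}
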
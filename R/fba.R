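# Flux balance analysis in the primal (maximize an objective flux) and swapped
# (minimize an uptake flux at a guaranteed objective floor) formulations. Both
# explore the same steady-state polytope S_dep v = 0, vL <= v <= vU; the
# optimum of the first problem lies inside the feasible region of the second,
# which is what makes trade-off curves from the two formulations coincide.

flux_state <- function(fluxes, objective_value, status, formulation) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, formulation = formulation),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("flux_state [%s]: status %s, objective %.6g\n",
              x$formulation, x$status, x$objective_value))
  invisible(x)
}

fba_bounds <- function(net, extra_bounds = NULL) {
  lb <- vapply(net$reactions, `[[`, numeric(1), "flux_lb")
  ub <- vapply(net$reactions, `[[`, numeric(1), "flux_ub")
  names(lb) <- names(ub) <- reaction_ids(net)
  if (!is.null(extra_bounds)) {
    for (rid in names(extra_bounds)) {
      if (!(rid %in% names(lb))) stop_pf("unknown reaction id '%s' in extra_bounds", rid)
      b <- extra_bounds[[rid]]
      lb[rid] <- max(lb[rid], b[1]); ub[rid] <- min(ub[rid], b[2])
    }
  }
  list(lb = lb, ub = ub)
}

#' Maximize a flux subject to steady state and bounds
#'
#' @param net A `metabolic_network`.
#' @param objective_id Reaction to maximize (defaults to the network's
#'   `objective_id`).
#' @param extra_bounds Optional named list of `c(lb, ub)` overrides, intersected
#'   with the declared bounds.
#' @param tie_break `"none"` (default) or `"l1"`: among alternate optima pick
#'   one minimizing the total absolute flux, making degenerate solutions
#'   deterministic.
#' @return A `flux_state` with status `optimal`, `infeasible` or `unbounded`;
#'   unbounded problems are reported, never truncated.
#' @export
maximize_flux <- function(net, objective_id = net$objective_id,
                          extra_bounds = NULL, tie_break = c("none", "l1")) {
  tie_break <- match.arg(tie_break)
  if (is.null(objective_id)) stop_pf("no objective reaction given")
  rids <- reaction_ids(net)
  if (!(objective_id %in% rids)) stop_pf("unknown reaction id '%s'", objective_id)
  S <- stoichiometric_matrix(net, rows = "dependent")
  bb <- fba_bounds(net, extra_bounds)
  n <- length(rids)
  obj <- as.numeric(rids == objective_id)
  sol <- lp_solve(obj, "max", A_eq = S, b_eq = rep(0, nrow(S)), lb = bb$lb, ub = bb$ub)
  if (sol$status != "optimal") {
    return(flux_state(stats::setNames(rep(NA_real_, n), rids), sol$objective_value,
                      sol$status, "max_objective"))
  }
  v <- sol$x
  if (tie_break == "l1") {
    # min sum t, t >= |v|, objective pinned at its optimum
    obj2 <- c(rep(0, n), rep(1, n))
    Aeq2 <- cbind(S, matrix(0, nrow(S), n))
    Aeq2 <- rbind(Aeq2, c(obj, rep(0, n)))
    beq2 <- c(rep(0, nrow(S)), sol$objective_value)
    Ale <- rbind(cbind(diag(n), -diag(n)), cbind(-diag(n), -diag(n)))
    sol2 <- lp_solve(obj2, "min", A_eq = Aeq2, b_eq = beq2,
                     A_le = Ale, b_le = rep(0, 2 * n),
                     lb = c(bb$lb, rep(0, n)), ub = c(bb$ub, rep(Inf, n)))
    if (sol2$status == "optimal") v <- sol2$x[seq_len(n)]
  }
  flux_state(stats::setNames(v, rids), sol$objective_value, "optimal", "max_objective")
}

#' Minimize an uptake flux at a guaranteed objective floor
#'
#' The swapped formulation: minimize `v_uptake` subject to steady state, bounds
#' and `v_objective >= objective_floor`.
#'
#' @param net A `metabolic_network`.
#' @param uptake_id Reaction whose flux is minimized.
#' @param objective_floor Required minimum for the objective flux (finite).
#' @param objective_id Objective reaction (defaults to the network's).
#' @param extra_bounds As in [maximize_flux()].
#' @return A `flux_state`; `objective_value` is the minimized uptake flux.
#' @export
minimize_uptake <- function(net, uptake_id = net$uptake_id, objective_floor,
                            objective_id = net$objective_id, extra_bounds = NULL) {
  if (is.null(uptake_id)) stop_pf("no uptake reaction given")
  if (!is.finite(objective_floor)) stop_pf("objective_floor must be finite")
  rids <- reaction_ids(net)
  for (id in c(uptake_id, objective_id)) {
    if (!(id %in% rids)) stop_pf("unknown reaction id '%s'", id)
  }
  S <- stoichiometric_matrix(net, rows = "dependent")
  bb <- fba_bounds(net, extra_bounds)
  n <- length(rids)
  obj <- as.numeric(rids == uptake_id)
  floor_row <- -as.numeric(rids == objective_id)
  sol <- lp_solve(obj, "min", A_eq = S, b_eq = rep(0, nrow(S)),
                  A_le = matrix(floor_row, 1), b_le = -objective_floor,
                  lb = bb$lb, ub = bb$ub)
  if (sol$status != "optimal") {
    return(flux_state(stats::setNames(rep(NA_real_, n), rids), NA_real_,
                      sol$status, "min_uptake"))
  }
  flux_state(stats::setNames(sol$x, rids), sol$objective_value, "optimal", "min_uptake")
}

#' Uptake/objective trade-off curve
#'
#' First pass: maximize the objective at each uptake cap. Second pass: minimize
#' the uptake at each achieved objective. The two passes trace the same curve.
#'
#' @param net A `metabolic_network`.
#' @param uptake_id,objective_id Reaction ids.
#' @param grid Ascending vector of uptake caps.
#' @return data.frame with columns `cap`, `objective` (max pass), `uptake`
#'   (min pass) and `status`.
#' @export
tradeoff_curve <- function(net, uptake_id = net$uptake_id,
                           objective_id = net$objective_id, grid) {
  if (is.unsorted(grid)) stop_pf("grid must be sorted ascending")
  rows <- lapply(grid, function(cap) {
    fs <- maximize_flux(net, objective_id,
                        extra_bounds = stats::setNames(list(c(-Inf, cap)), uptake_id))
    if (fs$status != "optimal") {
      return(data.frame(cap = cap, objective = NA_real_, uptake = NA_real_,
                        status = fs$status))
    }
    ms <- minimize_uptake(net, uptake_id, objective_floor = fs$objective_value,
                          objective_id = objective_id,
                          extra_bounds = stats::setNames(list(c(-Inf, cap)), uptake_id))
    data.frame(cap = cap, objective = fs$objective_value,
               uptake = ms$objective_value, status = "optimal")
  })
  do.call(rbind, rows)
}

#' Yields relative to an uptake flux
#'
#' @param flux_state An optimal `flux_state`.
#' @param uptake_id Reaction id whose flux normalizes the others.
#' @return Named numeric `Y_k = v_k / v_uptake`.
#' @export
yields <- function(flux_state, uptake_id) {
  stopifnot(inherits(flux_state, "flux_state"))
  vin <- flux_state$fluxes[[uptake_id]]
  if (is.na(vin) || vin == 0) stop_pf("uptake flux is zero (or undefined); yields undefined")
  flux_state$fluxes / vin
}
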
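# Thermodynamic feasibility analysis: the linear inequalities
# g = g0 + RT * S^T y <= 0 over log-concentrations y, explored by linear
# programming: admissible ranges per metabolite and reaction, the Max-min
# Driving Force, and dG sweeps over a chosen metabolite. Concentrations are in
# mol/L and logarithms are natural throughout; water/proton activity is
# assumed absorbed into g0.

#' Thermodynamic data for a network
#'
#' @param net A `metabolic_network` whose reactions carry `dg0` where needed.
#' @param dg0 Optional named override of standard free energies (kJ/mol).
#' @param temperature Kelvin; `rt` is derived as R*T with R = 8.314e-3
#'   kJ/(mol K).
#' @param fixed_conc Named numeric of clamped concentrations (mol/L); these
#'   metabolites get `y` fixed at `log(conc)`. Defaults to clamping every
#'   independent metabolite at its reference concentration when the network
#'   carries a reference state.
#' @return `thermo_data` with `dg0`, `temperature`, `rt`, `y_lb`, `y_ub`,
#'   `fixed_y`.
#' @export
thermo_data <- function(net, dg0 = NULL, temperature = net$temperature %||% 298.15,
                        fixed_conc = NULL) {
  rids <- reaction_ids(net)
  g0 <- stats::setNames(vapply(net$reactions, `[[`, numeric(1), "dg0"), rids)
  if (!is.null(dg0)) {
    ov <- as_named_num(as.list(dg0))
    bad <- setdiff(names(ov), rids)
    if (length(bad) > 0L) stop_pf("dg0 given for unknown reaction(s): %s", paste(bad, collapse = ", "))
    g0[names(ov)] <- ov
  }
  mids <- metabolite_ids(net)
  y_lb <- stats::setNames(log(vapply(net$metabolites, `[[`, numeric(1), "conc_lb")), mids)
  y_ub <- stats::setNames(log(vapply(net$metabolites, `[[`, numeric(1), "conc_ub")), mids)
  if (is.null(fixed_conc) && !is.null(net$reference)) {
    iid <- independent_ids(net)
    fixed_conc <- net$reference$concentrations[intersect(iid, names(net$reference$concentrations))]
  }
  fixed_y <- if (is.null(fixed_conc) || length(fixed_conc) == 0) {
    stats::setNames(numeric(0), character(0))
  } else {
    fc <- as_named_num(as.list(fixed_conc))
    if (any(fc <= 0)) stop_pf("fixed concentrations must be positive")
    log(fc)
  }
  structure(list(dg0 = g0, temperature = temperature,
                 rt = rt_constant(temperature),
                 y_lb = y_lb, y_ub = y_ub, fixed_y = fixed_y),
            class = "thermo_data")
}

# effective per-metabolite y bounds after clamping
tfa_boxes <- function(thermo, net) {
  mids <- metabolite_ids(net)
  lb <- thermo$y_lb[mids]; ub <- thermo$y_ub[mids]
  fy <- thermo$fixed_y
  clamped <- intersect(names(fy), mids)
  lb[clamped] <- fy[clamped]; ub[clamped] <- fy[clamped]
  list(lb = lb, ub = ub)
}

#' Reaction Gibbs energies at given log-concentrations
#'
#' @param thermo A [thermo_data()].
#' @param net The network.
#' @param y Named numeric of log-concentrations (ln mol/L) covering every
#'   metabolite appearing in a stoichiometry.
#' @return Named numeric, reaction id -> dG (kJ/mol).
#' @export
reaction_gibbs <- function(thermo, net, y) {
  rids <- reaction_ids(net)
  out <- stats::setNames(rep(NA_real_, length(rids)), rids)
  for (r in net$reactions) {
    if (is.na(thermo$dg0[[r$id]])) stop_pf("missing dg0 for reaction '%s'", r$id)
    ys <- y[names(r$stoich)]
    if (anyNA(ys)) stop_pf("missing log-concentration for metabolite(s): %s",
                           paste(names(r$stoich)[is.na(ys)], collapse = ", "))
    out[r$id] <- thermo$dg0[[r$id]] + thermo$rt * sum(r$stoich * ys)
  }
  out
}

# rows of the directed constraint system: a %*% y <= b encodes g_i <= 0
# (forward) or g_i >= 0 (reverse)
direction_rows <- function(thermo, net, directions) {
  mids <- metabolite_ids(net)
  rows <- list(); rhs <- numeric(0); which_r <- character(0)
  for (r in net$reactions) {
    dir <- directions[[r$id]] %||% "off"
    if (dir == "off") next
    if (is.na(thermo$dg0[[r$id]])) stop_pf("missing dg0 for directed reaction '%s'", r$id)
    a <- stats::setNames(numeric(length(mids)), mids)
    a[names(r$stoich)] <- thermo$rt * r$stoich
    if (dir == "forward") {
      rows[[length(rows) + 1L]] <- a; rhs <- c(rhs, -thermo$dg0[[r$id]])
    } else if (dir == "reverse") {
      rows[[length(rows) + 1L]] <- -a; rhs <- c(rhs, thermo$dg0[[r$id]])
    } else stop_pf("direction for '%s' must be forward/reverse/off", r$id)
    which_r <- c(which_r, r$id)
  }
  list(A = if (length(rows) > 0) do.call(rbind, rows) else matrix(0, 0, length(mids)),
       b = rhs, reactions = which_r)
}

#' Directions from an FBA solution
#'
#' @param flux_state A `flux_state`.
#' @param tol Fluxes with magnitude below `tol` are "off".
#' @return Named character vector forward/reverse/off.
#' @export
directions_from_fluxes <- function(flux_state, tol = 1e-9) {
  v <- flux_state$fluxes
  out <- ifelse(v > tol, "forward", ifelse(v < -tol, "reverse", "off"))
  stats::setNames(out, names(v))
}

#' Admissible ranges of log-concentrations and reaction Gibbs energies
#'
#' Each bound is a linear-programming optimum subject to the directed
#' feasibility inequalities and the concentration box.
#'
#' @param thermo A [thermo_data()].
#' @param net The network.
#' @param directions Named map reaction id -> forward/reverse/off (e.g. from
#'   [directions_from_fluxes()]); missing entries are "off".
#' @return List with `status` and data.frames `metabolites` (`id`, `y_min`,
#'   `y_max`, `conc_min`, `conc_max`) and `reactions` (`id`, `g_min`, `g_max`).
#' @export
variable_ranges <- function(thermo, net, directions = list()) {
  mids <- metabolite_ids(net)
  bx <- tfa_boxes(thermo, net)
  dr <- direction_rows(thermo, net, directions)
  nv <- length(mids)
  run <- function(obj, dirn) lp_solve(obj, dirn, A_le = dr$A, b_le = dr$b, lb = bx$lb, ub = bx$ub)
  # feasibility probe
  probe <- run(rep(0, nv), "min")
  if (probe$status != "optimal") {
    return(list(status = "infeasible", metabolites = NULL, reactions = NULL))
  }
  ymin <- ymax <- stats::setNames(rep(NA_real_, nv), mids)
  for (j in seq_len(nv)) {
    e <- as.numeric(seq_len(nv) == j)
    ymin[j] <- run(e, "min")$objective_value
    ymax[j] <- run(e, "max")$objective_value
  }
  rids <- reaction_ids(net)
  gmin <- gmax <- stats::setNames(rep(NA_real_, length(rids)), rids)
  for (r in net$reactions) {
    if (is.na(thermo$dg0[[r$id]])) next
    a <- stats::setNames(numeric(nv), mids)
    a[names(r$stoich)] <- thermo$rt * r$stoich
    gmin[r$id] <- thermo$dg0[[r$id]] + run(a, "min")$objective_value
    gmax[r$id] <- thermo$dg0[[r$id]] + run(a, "max")$objective_value
  }
  list(status = "feasible",
       metabolites = data.frame(id = mids, y_min = unname(ymin), y_max = unname(ymax),
                                conc_min = exp(unname(ymin)), conc_max = exp(unname(ymax))),
       reactions = data.frame(id = rids, g_min = unname(gmin), g_max = unname(gmax)))
}

#' Max-min Driving Force
#'
#' Minimizes B subject to `g_i <= B` for every directed reaction (sign-flipped
#' for reverse), the feasibility inequalities and the concentration box, i.e.
#' maximizes the magnitude of the least negative driving force. Reactions
#' directed "off" impose no constraint.
#'
#' @inheritParams variable_ranges
#' @return `thermo_state`: optimizing `y` (named), `g` (named, all reactions
#'   with dg0), `B` (kJ/mol), `status` (`feasible` iff B <= 0 within 1e-9).
#' @export
max_min_driving_force <- function(thermo, net, directions = list()) {
  mids <- metabolite_ids(net)
  bx <- tfa_boxes(thermo, net)
  dr <- direction_rows(thermo, net, directions)
  if (nrow(dr$A) == 0L) stop_pf("no directed reactions: MDF undefined")
  nv <- length(mids)
  # variables: y (nv) then B
  A <- cbind(dr$A, -1)
  sol <- lp_solve(c(rep(0, nv), 1), "min", A_le = A, b_le = dr$b,
                  lb = c(bx$lb, -Inf), ub = c(bx$ub, Inf))
  if (sol$status != "optimal") {
    return(structure(list(y = NULL, g = NULL, B = NA_real_, status = "infeasible"),
                     class = "thermo_state"))
  }
  y <- stats::setNames(sol$x[seq_len(nv)], mids)
  g <- tryCatch(reaction_gibbs(thermo, net, y), error = function(e) NULL)
  B <- sol$objective_value
  structure(list(y = y, g = g, B = B,
                 status = if (B <= 1e-9) "feasible" else "infeasible"),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("thermo_state: %s, B = %.4f kJ/mol\n", x$status, x$B))
  invisible(x)
}

#' Gibbs-energy sweep over one metabolite
#'
#' All other concentrations are held fixed; one row per grid point. Reactions
#' not involving the swept metabolite have constant dG across rows.
#'
#' @param thermo A [thermo_data()].
#' @param net The network.
#' @param metabolite_id Swept metabolite.
#' @param grid Concentrations (mol/L) to sweep.
#' @param conc Named numeric of the fixed concentrations for every other
#'   metabolite; defaults to the clamps in `thermo` plus the network's
#'   reference concentrations.
#' @param directions Directions used for the reported minimal driving force B
#'   (default: all reactions with dg0 forward).
#' @return data.frame with columns `conc`, one `dG_<reaction>` per reaction
#'   carrying a dg0, and `B` (the largest directed dG at that concentration).
#' @export
dg_sweep <- function(thermo, net, metabolite_id, grid, conc = NULL, directions = NULL) {
  mids <- metabolite_ids(net)
  if (!(metabolite_id %in% mids)) stop_pf("unknown metabolite id '%s'", metabolite_id)
  base <- stats::setNames(rep(NA_real_, length(mids)), mids)
  if (!is.null(net$reference)) {
    rc <- net$reference$concentrations
    base[intersect(names(rc), mids)] <- rc[intersect(names(rc), mids)]
  }
  if (length(thermo$fixed_y) > 0) {
    base[intersect(names(thermo$fixed_y), mids)] <- exp(thermo$fixed_y[intersect(names(thermo$fixed_y), mids)])
  }
  if (!is.null(conc)) {
    cc <- as_named_num(as.list(conc))
    base[names(cc)] <- cc
  }
  m <- get_metabolite(net, metabolite_id)
  if (any(grid < m$conc_lb | grid > m$conc_ub)) {
    warning(sprintf("sweep values outside declared bounds for '%s'", metabolite_id), call. = FALSE)
  }
  with_dg0 <- rids_with_dg0(thermo, net)
  if (is.null(directions)) {
    directions <- stats::setNames(as.list(rep("forward", length(with_dg0))), with_dg0)
  }
  rows <- lapply(grid, function(cv) {
    x <- base; x[metabolite_id] <- cv
    if (anyNA(x[unique(unlist(lapply(net$reactions, function(r) names(r$stoich))))])) {
      stop_pf("dg_sweep: concentrations missing for some stoichiometric participants")
    }
    g <- reaction_gibbs(thermo, net, log(x))
    gdir <- vapply(with_dg0, function(rid) {
      d <- directions[[rid]] %||% "off"
      if (d == "forward") g[[rid]] else if (d == "reverse") -g[[rid]] else NA_real_
    }, numeric(1))
    out <- c(conc = cv, stats::setNames(g[with_dg0], paste0("dG_", with_dg0)),
             B = if (all(is.na(gdir))) NA_real_ else max(gdir, na.rm = TRUE))
    as.data.frame(as.list(out))
  })
  do.call(rbind, rows)
}

rids_with_dg0 <- function(thermo, net) {
  rids <- reaction_ids(net)
  rids[!is.na(thermo$dg0[rids])]
}
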
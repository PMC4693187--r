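# Mathematically controlled comparison: alternative regulatory designs are
# compared under internal equivalence (all parameters outside the changed
# reactions identical) and external equivalence (matched observable behavior:
# fluxes, selected concentrations, log gains). The theta-equivalence map
# builds, from a fully irreversible reference pathway, the family of models
# whose second reaction sits at an arbitrary distance to equilibrium while
# carrying the same flux and end-product level.

#' Internal-equivalence specification
#'
#' Enumerates the free parameters of an alternative design: everything outside
#' the changed reactions is frozen.
#'
#' @param model The reference `power_law_model`.
#' @param changed Character vector of changed reaction ids.
#' @return `equivalence_spec` with `changed_reaction_ids` and
#'   `free_parameters` (data.frame reaction/parameter).
#' @export
internal_equivalence <- function(model, changed) {
  if (length(model$reaction_ids) == 0L) stop_pf("empty model")
  bad <- setdiff(changed, model$reaction_ids)
  if (length(bad) > 0L) stop_pf("changed reactions not in model: %s", paste(bad, collapse = ", "))
  rows <- list()
  for (rid in changed) {
    r <- model$rates[[rid]]
    rows[[length(rows) + 1L]] <- data.frame(reaction = rid, parameter = "theta")
    for (met in names(r$kinetic_parts)) {
      rows[[length(rows) + 1L]] <- data.frame(reaction = rid, parameter = paste0("gk_", met))
    }
    rows[[length(rows) + 1L]] <- data.frame(reaction = rid, parameter = "alpha")
  }
  structure(list(changed_reaction_ids = changed,
                 free_parameters = if (length(rows) > 0) do.call(rbind, rows) else
                   data.frame(reaction = character(0), parameter = character(0))),
            class = "equivalence_spec")
}

#' Check two models for internal equivalence
#'
#' @param spec An [internal_equivalence()] specification.
#' @param reference,alternative `power_law_model`s over the same reactions.
#' @return Invisibly TRUE; stops listing every parameter that differs outside
#'   the changed reactions.
#' @export
check_internal_equivalence <- function(spec, reference, alternative) {
  viol <- character(0)
  for (rid in setdiff(reference$reaction_ids, spec$changed_reaction_ids)) {
    a <- reference$rates[[rid]]; b <- alternative$rates[[rid]]
    if (is.null(b)) { viol <- c(viol, sprintf("reaction '%s' missing in alternative", rid)); next }
    if (abs(log_alpha_of(a) - log_alpha_of(b)) > 1e-12) viol <- c(viol, sprintf("alpha of '%s' differs", rid))
    if (abs(a$theta - b$theta) > 1e-12) viol <- c(viol, sprintf("theta of '%s' differs", rid))
    for (met in union(names(a$orders), names(b$orders))) {
      if (abs(gv(a$orders, met) - gv(b$orders, met)) > 1e-12) {
        viol <- c(viol, sprintf("order (%s, %s) differs", rid, met))
      }
    }
  }
  if (length(viol) > 0L) stop_pf("internal equivalence violated:\n- %s", paste(viol, collapse = "\n- "))
  invisible(TRUE)
}

# case-2 interior reaction structure: one dependent substrate, one dependent
# product, downstream consumer depending only on the product
interior_structure <- function(model, reaction_id) {
  r <- model$rates[[reaction_id]]
  if (is.null(r)) stop_pf("unknown reaction id '%s'", reaction_id)
  S <- model$stoich
  col <- S[, reaction_id]
  sub <- rownames(S)[col < 0]; prod_m <- rownames(S)[col > 0]
  if (length(sub) != 1L || length(prod_m) != 1L) stop_pf("'%s' is not a 1:1 interior reaction", reaction_id)
  down <- colnames(S)[S[prod_m, ] < 0]
  if (length(down) != 1L) stop_pf("product '%s' needs a unique downstream consumer", prod_m)
  list(substrate = sub, product = prod_m, downstream = down)
}

#' Thermodynamic-consistency constraints for an interior reaction
#'
#' For a reaction at distance theta with equilibrium constant keq, the steady
#' state can only satisfy the mass-action-quotient identity if (i) the
#' downstream order on the product equals the sum of the reaction's kinetic
#' parts and (ii) the rate constants obey
#' `ln alpha = ln alpha_down + (g^k_sub + theta/(1-theta)) * ln(keq*theta)`.
#'
#' @param model A `power_law_model`.
#' @param reaction_id Interior reaction id (e.g. "v2" of the 3-step chain).
#' @return List with the two constraint targets and actual values, plus
#'   `satisfied`. With theta = 0 the constraints degenerate to the
#'   irreversible case and only the structure is reported.
#' @export
thermo_consistency <- function(model, reaction_id) {
  st <- interior_structure(model, reaction_id)
  r <- model$rates[[reaction_id]]
  rd <- model$rates[[st$downstream]]
  g_down <- gv(rd$orders, st$product)
  gk_sub <- gv(r$kinetic_parts, st$substrate)
  gk_prod <- gv(r$kinetic_parts, st$product)
  if (r$theta == 0) {
    return(list(reaction_id = reaction_id, downstream_id = st$downstream,
                theta = 0, keq = r$keq, degenerate = TRUE,
                kinetic_sum_target = g_down, kinetic_sum_actual = gk_sub + gk_prod,
                satisfied = NA))
  }
  t_c <- r$theta / (1 - r$theta)
  la_target <- log_alpha_of(rd) + (gk_sub + t_c) * log(r$keq * r$theta)
  list(reaction_id = reaction_id, downstream_id = st$downstream,
       theta = r$theta, keq = r$keq, degenerate = FALSE,
       kinetic_sum_target = g_down, kinetic_sum_actual = gk_sub + gk_prod,
       log_alpha_target = la_target, log_alpha_actual = log_alpha_of(r),
       satisfied = abs(g_down - (gk_sub + gk_prod)) < 1e-9 &&
         abs(la_target - log_alpha_of(r)) < 1e-9)
}

#' Gain-transfer factor of the theta family
#'
#' The factor `g21 / (g32 - g22)` relating the log gains of a theta-family
#' member to those of its irreversible reference, evaluated from the model's
#' total orders. Under the thermodynamic-consistency constraints it equals 1.
#'
#' @param model A `power_law_model`.
#' @param reaction_id Interior reaction id.
#' @return Numeric scalar.
#' @export
gain_transfer_factor <- function(model, reaction_id) {
  st <- interior_structure(model, reaction_id)
  r <- model$rates[[reaction_id]]
  rd <- model$rates[[st$downstream]]
  g21 <- gv(r$orders, st$substrate)
  g22 <- gv(r$orders, st$product)
  g32 <- gv(rd$orders, st$product)
  g21 / (g32 - g22)
}

#' Theta-equivalent variant of an irreversible reference pathway
#'
#' Starting from a network whose designated interior reaction is fully
#' irreversible (theta = 0), builds the member of the theta family at the
#' requested distance to equilibrium and equilibrium constant: the rate
#' constant is scaled by `(theta/keq)^(-theta/(1-theta))`, the substrate
#' kinetic part follows from the consistency constraint on the rate constants
#' and the product kinetic part from the downstream order. Flux and end-product
#' steady state are preserved exactly; the substrate steady state shifts to
#' `x_product / (theta*keq)`.
#'
#' @param net Network (with kinetics and reference) of the irreversible
#'   reference, e.g. from [make_unbranched_pathway()].
#' @param theta Target distance to equilibrium in (0, 1).
#' @param keq Apparent equilibrium constant of the changed reaction;
#'   `theta * keq` must differ from 1 (otherwise the constraint system is
#'   degenerate).
#' @param reaction_id Changed reaction (default "v2").
#' @return List with `parameters` (named: alpha, gk_substrate, gk_product,
#'   alpha_multiplier), `network` (modified) and `model` (built
#'   `power_law_model`).
#' @export
theta_equivalence <- function(net, theta, keq, reaction_id = "v2") {
  if (!(theta > 0 && theta < 1)) stop_pf("theta must lie in (0, 1)")
  ref_model <- build_model(net)
  if (ref_model$rates[[reaction_id]]$theta != 0) stop_pf("reference reaction '%s' must be irreversible (theta = 0)", reaction_id)
  st <- interior_structure(ref_model, reaction_id)
  if (abs(log(keq * theta)) < 1e-12) stop_pf("theta*keq = 1 is degenerate (substrate and product coincide)")
  t_c <- theta / (1 - theta)
  la2_irr <- log_alpha_of(ref_model$rates[[reaction_id]])
  la_down <- log_alpha_of(ref_model$rates[[st$downstream]])
  g_down <- gv(ref_model$rates[[st$downstream]]$orders, st$product)
  log_multiplier <- -t_c * log(theta / keq)
  la2_hat <- la2_irr + log_multiplier
  gk_sub <- (la2_hat - la_down) / log(keq * theta) - t_c
  gk_prod <- g_down - gk_sub

  net2 <- net
  kp <- net2$kinetics$kinetic_parts[[reaction_id]]
  kp[st$substrate] <- gk_sub
  kp[st$product] <- gk_prod
  net2$kinetics$kinetic_parts[[reaction_id]] <- kp
  net2$kinetics$theta[reaction_id] <- theta
  net2$kinetics$keq[reaction_id] <- keq
  conc <- net2$reference$concentrations
  conc[st$substrate] <- conc[st$product] / (theta * keq)
  net2$reference$concentrations <- conc
  net2$reference$theta[reaction_id] <- theta
  net2$reference$keq[reaction_id] <- keq
  model <- build_model(net2)
  list(parameters = c(alpha = unname(model$rates[[reaction_id]]$alpha),
                      log_alpha = unname(model$rates[[reaction_id]]$log_alpha),
                      gk_substrate = gk_sub, gk_product = gk_prod,
                      alpha_multiplier = exp(log_multiplier),
                      log_alpha_multiplier = log_multiplier),
       network = net2, model = model)
}

#' External equivalence: match observable behavior by adjusting rate constants
#'
#' Solves for the rate constants of the changed reactions so that the matched
#' properties (steady-state fluxes, concentrations or log gains) of the
#' alternative coincide with the reference. Conditions may be redundant (the
#' solve is least-squares); inconsistent or over-determined sets are rejected.
#'
#' @param reference Reference `power_law_model`.
#' @param alternative Alternative `power_law_model` (internally equivalent
#'   outside the changed reactions).
#' @param free Character vector of reaction ids whose alpha may move.
#' @param matched List of conditions, each `list(type, id, ...)` with type
#'   `"flux"` (reaction id), `"conc"` (metabolite id) or
#'   `"log_gain"` (`target`, `independent`).
#' @return List with `model` (solved alternative), `alpha` (named solved rate
#'   constants) and `residual` (max absolute matched-property mismatch).
#' @export
external_equivalence <- function(reference, alternative, free, matched) {
  if (length(matched) > length(free)) stop_pf("over-determined: %d conditions, %d free parameters",
                                              length(matched), length(free))
  prop <- function(model, cond) {
    switch(cond$type,
           flux = {
             x <- steady_state(model)
             iv <- independent_reference(model)
             log(evaluate_rates(model, c(x, iv))[[cond$id]])
           },
           conc = log(steady_state(model)[[cond$id]]),
           log_gain = log_gains(model, cond$independent)[[cond$target]],
           stop_pf("unknown matched property type '%s'", cond$type))
  }
  target <- vapply(matched, function(cond) prop(reference, cond), numeric(1))
  apply_alpha <- function(model, la) {
    for (i in seq_along(free)) {
      model$rates[[free[i]]]$log_alpha <- la[i]
      model$rates[[free[i]]]$alpha <- exp(la[i])
    }
    model
  }
  resid <- function(la) {
    m <- apply_alpha(alternative, la)
    vapply(matched, function(cond) prop(m, cond), numeric(1)) - target
  }
  la <- vapply(free, function(rid) log_alpha_of(alternative$rates[[rid]]), numeric(1))
  if (length(matched) > 0L) {
    for (it in 1:100) {
      f <- resid(la)
      if (max(abs(f)) < 1e-12) break
      h <- 1e-6
      J <- matrix(0, length(f), length(la))
      for (j in seq_along(la)) {
        lp <- la; lp[j] <- la[j] + h
        J[, j] <- (resid(lp) - f) / h
      }
      step <- tryCatch(qr.solve(J, -f), error = function(e) NULL)
      if (is.null(step)) stop_pf("matched conditions are inconsistent (singular solve)")
      la <- la + step
    }
    f <- resid(la)
    if (max(abs(f)) > 1e-8) stop_pf("matched conditions could not be satisfied (residual %.3g)", max(abs(f)))
  }
  solved <- apply_alpha(alternative, la)
  list(model = solved, alpha = stats::setNames(exp(la), free),
       residual = if (length(matched) > 0) max(abs(resid(la))) else 0)
}

#' Compare systemic properties of two models
#'
#' @param reference,alternative `power_law_model`s, each solvable at its own
#'   steady state.
#' @param properties Named list of functions `power_law_model -> numeric`.
#' @param better Optional named character ("smaller"/"larger") giving the
#'   criterion per property; without it the verdict is "equal"/"differs".
#' @return data.frame: property, reference, alternative, difference, ratio,
#'   verdict.
#' @export
compare_models <- function(reference, alternative, properties, better = NULL) {
  rows <- lapply(names(properties), function(pn) {
    pr <- properties[[pn]](reference)
    pa <- properties[[pn]](alternative)
    verdict <- if (!is.null(better) && pn %in% names(better)) {
      crit <- better[[pn]]
      if (abs(pa - pr) < 1e-9) "equal"
      else if ((crit == "smaller") == (abs(pa) < abs(pr))) "better" else "worse"
    } else if (isTRUE(abs(pa - pr) < 1e-9)) "equal" else "differs"
    data.frame(property = pn, reference = pr, alternative = pa,
               difference = pa - pr,
               ratio = if (pr != 0) pa / pr else NA_real_,
               verdict = verdict)
  })
  do.call(rbind, rows)
}

#' Sweep economic-versus-responsive pathway designs
#'
#' Builds a grid of unbranched-pathway designs over theta profiles and
#' feedback strengths, reporting for each: the steady-state flux, the
#' responsiveness gain |L(x_n, demand)|, the total minimal enzyme needed to
#' carry the flux (sum over steps of flux / (kcat (1-theta))), and the
#' feedback stability margin.
#'
#' @param n Pathway length (default 3).
#' @param theta_profiles Named list of theta vectors (length n+1).
#' @param feedback_strengths Numeric vector of feedback magnitudes (>= 0).
#' @param keq Equilibrium constant used for near-equilibrium steps.
#' @param kcat Common catalytic constant for the enzyme-cost proxy.
#' @param flux Pathway flux at the reference state.
#' @return data.frame with one row per (profile, feedback) design.
#' @export
design_sweep <- function(n = 3,
                         theta_profiles = list(economic = rep(0, n + 1),
                                               responsive = c(0, rep(0.99, n - 1), 0)),
                         feedback_strengths = c(0, 0.5, 2),
                         keq = 10, kcat = 10, flux = 1) {
  rows <- list()
  for (pn in names(theta_profiles)) {
    th <- rep_len(theta_profiles[[pn]], n + 1)
    for (fb in feedback_strengths) {
      fx <- make_unbranched_pathway(n, feedback_order = -fb, theta = th,
                                    keq = rep(keq, n + 1))
      model <- build_model(fx$network)
      end_id <- paste0("X", n); demand_id <- paste0("X", n + 1)
      gains <- log_gains(model, demand_id)
      resp <- abs(gains[[paste0("x_", end_id)]])
      cost <- sum(vapply(seq_len(n + 1), function(i) {
        thi <- th[i]
        dg <- if (thi > 0) dg_from_theta(thi) else -Inf
        min_enzyme(flux, kcat, dg)
      }, numeric(1)))
      margin <- tryCatch(feedback_stability_margin(model, "v1", end_id),
                         error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        profile = pn, feedback = fb, flux = flux,
        responsiveness = resp, enzyme_cost = cost, margin = margin)
    }
  }
  do.call(rbind, rows)
}
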
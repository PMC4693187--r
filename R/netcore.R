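# Network data model: metabolites with a dependent/independent split, reactions
# with signed stoichiometry, flux bounds and regulatory modifiers, plus a
# reference steady state carrying fluxes, concentrations, distances to
# equilibrium (theta) and apparent equilibrium constants.

DEFAULT_CONC_LB <- 1e-7   # mol/L, conventional lower bound on metabolite levels
DEFAULT_CONC_UB <- 1e-2   # mol/L, conventional upper bound

#' Declare a metabolite
#'
#' @param id Short identifier, unique within a network.
#' @param role `"dependent"` (gets a differential equation) or `"independent"`
#'   (clamped by the environment).
#' @param name Free-text name.
#' @param conc_lb,conc_ub Concentration bounds in mol/L; both must be positive
#'   so that log-concentrations exist.
#' @return A `pf_metabolite` list.
#' @export
metabolite <- function(id, role = c("dependent", "independent"), name = id,
                       conc_lb = DEFAULT_CONC_LB, conc_ub = DEFAULT_CONC_UB) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) stop_pf("metabolite id must be a non-empty string")
  if (!(conc_lb > 0)) stop_pf("metabolite '%s': conc_lb must be > 0", id)
  if (!(conc_ub > conc_lb)) stop_pf("metabolite '%s': conc_ub must exceed conc_lb", id)
  structure(list(id = id, name = name, role = role,
                 conc_lb = conc_lb, conc_ub = conc_ub),
            class = "pf_metabolite")
}

#' Declare a reaction
#'
#' @param id Short identifier.
#' @param stoich Named numeric: metabolite id -> signed stoichiometric
#'   coefficient (negative substrates, positive products). Zero entries are
#'   dropped.
#' @param flux_lb,flux_ub Flux bounds (may be infinite).
#' @param dg0 Standard Gibbs free energy in kJ/mol, or NA.
#' @param modifiers Named numeric: metabolite id -> regulatory sign (+1
#'   activator, -1 inhibitor). Modifier metabolites must not appear in `stoich`.
#' @return A `pf_reaction` list.
#' @export
reaction <- function(id, stoich, flux_lb = 0, flux_ub = Inf, dg0 = NA_real_,
                     modifiers = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) stop_pf("reaction id must be a non-empty string")
  stoich <- as_named_num(as.list(stoich))
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L) stop_pf("reaction '%s': stoichiometry is empty", id)
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) stop_pf("reaction '%s': stoich must be named", id)
  if (flux_lb > flux_ub) stop_pf("reaction '%s': flux_lb exceeds flux_ub", id)
  modifiers <- if (is.null(modifiers)) stats::setNames(numeric(0), character(0)) else as_named_num(as.list(modifiers))
  if (length(intersect(names(modifiers), names(stoich))) > 0L) {
    stop_pf("reaction '%s': modifiers overlap stoichiometric participants (%s)",
            id, paste(intersect(names(modifiers), names(stoich)), collapse = ", "))
  }
  structure(list(id = id, stoich = stoich, flux_lb = flux_lb, flux_ub = flux_ub,
                 dg0 = as.numeric(dg0), modifiers = modifiers),
            class = "pf_reaction")
}

#' Assemble a metabolic network
#'
#' @param metabolites List of [metabolite()] objects (declaration order is the
#'   row order of the stoichiometric matrix).
#' @param reactions List of [reaction()] objects (column order).
#' @param objective_id,uptake_id Optional reaction ids used by the flux module.
#' @param reference Optional [reference_state()].
#' @param kinetics Optional kinetics block: list with `kinetic_parts` (named
#'   list reaction id -> named numeric of per-metabolite kinetic parts),
#'   `theta` and `keq` (named numerics over reaction ids).
#' @param temperature Temperature in Kelvin (default 298.15).
#' @return A validated `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, objective_id = NULL,
                              uptake_id = NULL, reference = NULL,
                              kinetics = NULL, temperature = 298.15) {
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        objective_id = objective_id, uptake_id = uptake_id,
                        reference = reference, kinetics = kinetics,
                        temperature = temperature),
                   class = "metabolic_network")
  validate_network(net)
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d metabolites (%d dependent), %d reactions\n",
              length(x$metabolites), sum(metabolite_roles(x) == "dependent"),
              length(x$reactions)))
  invisible(x)
}

metabolite_ids <- function(net) vapply(net$metabolites, `[[`, character(1), "id")
reaction_ids <- function(net) vapply(net$reactions, `[[`, character(1), "id")
metabolite_roles <- function(net) vapply(net$metabolites, `[[`, character(1), "role")
dependent_ids <- function(net) metabolite_ids(net)[metabolite_roles(net) == "dependent"]
independent_ids <- function(net) metabolite_ids(net)[metabolite_roles(net) == "independent"]

get_reaction <- function(net, id) {
  i <- match(id, reaction_ids(net))
  if (is.na(i)) stop_pf("unknown reaction id '%s'", id)
  net$reactions[[i]]
}

get_metabolite <- function(net, id) {
  i <- match(id, metabolite_ids(net))
  if (is.na(i)) stop_pf("unknown metabolite id '%s'", id)
  net$metabolites[[i]]
}

#' Validate a network, reporting every violated invariant
#'
#' @param net A `metabolic_network`.
#' @return Invisibly TRUE; otherwise stops with all violations enumerated.
#' @export
validate_network <- function(net) {
  errs <- character(0)
  mids <- metabolite_ids(net)
  rids <- reaction_ids(net)
  if (anyDuplicated(mids)) errs <- c(errs, sprintf("duplicate metabolite ids: %s", paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  if (anyDuplicated(rids)) errs <- c(errs, sprintf("duplicate reaction ids: %s", paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  for (r in net$reactions) {
    bad <- setdiff(c(names(r$stoich), names(r$modifiers)), mids)
    if (length(bad) > 0L) errs <- c(errs, sprintf("reaction '%s' references undeclared metabolite(s): %s", r$id, paste(bad, collapse = ", ")))
    if (r$flux_lb > r$flux_ub) errs <- c(errs, sprintf("reaction '%s': flux_lb > flux_ub", r$id))
  }
  for (m in net$metabolites) {
    if (!(m$conc_lb > 0) || !(m$conc_ub > m$conc_lb)) {
      errs <- c(errs, sprintf("metabolite '%s': need 0 < conc_lb < conc_ub", m$id))
    }
  }
  if (!is.null(net$objective_id) && !(net$objective_id %in% rids)) errs <- c(errs, sprintf("objective_id '%s' is not a reaction", net$objective_id))
  if (!is.null(net$uptake_id) && !(net$uptake_id %in% rids)) errs <- c(errs, sprintf("uptake_id '%s' is not a reaction", net$uptake_id))
  if (!is.null(net$reference)) {
    ref_errs <- tryCatch({ check_reference_state(net, net$reference); character(0) },
                         error = function(e) conditionMessage(e))
    errs <- c(errs, ref_errs)
  }
  if (length(errs) > 0L) stop_pf("invalid network:\n- %s", paste(errs, collapse = "\n- "))
  invisible(TRUE)
}

#' Reference steady state
#'
#' @param fluxes Named numeric, reaction id -> reference flux magnitude.
#' @param concentrations Named numeric, metabolite id -> reference
#'   concentration (mol/L), all positive.
#' @param theta Named numeric, reaction id -> distance to equilibrium in
#'   `[0, 1)`.
#' @param keq Named numeric, reaction id -> apparent equilibrium constant.
#' @return A `reference_state`.
#' @export
reference_state <- function(fluxes, concentrations, theta = NULL, keq = NULL) {
  fluxes <- as_named_num(as.list(fluxes))
  concentrations <- as_named_num(as.list(concentrations))
  theta <- if (is.null(theta)) stats::setNames(numeric(0), character(0)) else as_named_num(as.list(theta))
  keq <- if (is.null(keq)) stats::setNames(numeric(0), character(0)) else as_named_num(as.list(keq))
  if (any(concentrations <= 0)) stop_pf("reference concentrations must be positive")
  if (any(theta < 0 | theta >= 1)) stop_pf("theta must lie in [0, 1)")
  structure(list(fluxes = fluxes, concentrations = concentrations,
                 theta = theta, keq = keq),
            class = "reference_state")
}

# Mass-action-quotient consistency of a reference state: for every reaction
# with theta > 0 and a keq entry, prod_j x_j^{s_ij} must equal theta_i * keq_i.
check_reference_state <- function(net, ref, tol = 1e-9) {
  errs <- character(0)
  for (r in net$reactions) {
    th <- unname(ref$theta[r$id]); kq <- unname(ref$keq[r$id])
    if (is.na(th) || is.na(kq) || th <= 0) next
    xs <- ref$concentrations[names(r$stoich)]
    if (anyNA(xs)) { errs <- c(errs, sprintf("reaction '%s': reference concentration missing", r$id)); next }
    q <- prod(xs^r$stoich)
    if (abs(q - th * kq) > tol * max(abs(th * kq), 1e-300)) {
      errs <- c(errs, sprintf("reaction '%s': mass-action quotient %.12g != theta*keq = %.12g", r$id, q, th * kq))
    }
  }
  if (length(errs) > 0L) stop_pf("%s", paste(errs, collapse = "\n- "))
  invisible(TRUE)
}

#' Stoichiometric matrix
#'
#' Rows follow metabolite declaration order, columns reaction order.
#'
#' @param net A `metabolic_network`.
#' @param rows `"dependent"` (drop independent-metabolite rows) or `"all"`.
#' @return Numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(net, rows = c("dependent", "all")) {
  rows <- match.arg(rows)
  mids <- metabolite_ids(net)
  rids <- reaction_ids(net)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (j in seq_along(net$reactions)) {
    st <- net$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  if (rows == "dependent") S <- S[metabolite_roles(net) == "dependent", , drop = FALSE]
  S
}

## ---------------------------------------------------------------------------
## JSON model I/O. Schema (top level): metabolites, reactions, objective_id,
## uptake_id, reference_state, thermodynamics, kinetics. Water/proton activity
## is assumed absorbed into dg0 and is not represented as a metabolite.

#' Save a network (with any attached reference state / kinetics) to JSON
#'
#' @param net A `metabolic_network`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
save_network <- function(net, path) {
  num <- function(x) ifelse(is.finite(x), x, ifelse(x > 0, "Inf", "-Inf"))
  doc <- list(
    metabolites = lapply(net$metabolites, function(m) {
      list(id = m$id, name = m$name, role = m$role, conc_lb = m$conc_lb, conc_ub = m$conc_ub)
    }),
    reactions = lapply(net$reactions, function(r) {
      out <- list(id = r$id, stoich = as.list(r$stoich),
                  flux_lb = num(r$flux_lb), flux_ub = num(r$flux_ub))
      if (!is.na(r$dg0)) out$dg0 <- r$dg0
      if (length(r$modifiers) > 0) out$modifiers <- as.list(r$modifiers)
      out
    }),
    temperature = net$temperature
  )
  if (!is.null(net$objective_id)) doc$objective_id <- net$objective_id
  if (!is.null(net$uptake_id)) doc$uptake_id <- net$uptake_id
  if (!is.null(net$reference)) {
    doc$reference_state <- list(fluxes = as.list(net$reference$fluxes),
                                concentrations = as.list(net$reference$concentrations),
                                theta = as.list(net$reference$theta),
                                keq = as.list(net$reference$keq))
  }
  if (!is.null(net$kinetics)) {
    doc$kinetics <- list(kinetic_parts = lapply(net$kinetics$kinetic_parts, as.list),
                         theta = as.list(net$kinetics$theta),
                         keq = as.list(net$kinetics$keq))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a network from JSON (or minimal SBML)
#'
#' The JSON schema is the one written by [save_network()]. SBML import reads
#' stoichiometry, boundary-condition flags and flux bounds only.
#'
#' @param path File path.
#' @param format `"json"` or `"sbml"`.
#' @return A validated `metabolic_network`.
#' @export
load_network <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_pf("model file not found: %s", path)
  if (format == "sbml") return(load_sbml(path))
  doc <- jsonlite::read_json(path)
  for (key in c("metabolites", "reactions")) {
    if (is.null(doc[[key]])) stop_pf("schema violation: missing top-level key '%s'", key)
  }
  fin <- function(x, default) {
    if (is.null(x)) return(default)
    if (identical(x, "Inf")) return(Inf)
    if (identical(x, "-Inf")) return(-Inf)
    as.numeric(x)
  }
  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop_pf("schema violation: metabolite without 'id'")
    metabolite(id = m$id, role = m$role %||% "dependent", name = m$name %||% m$id,
               conc_lb = fin(m$conc_lb, DEFAULT_CONC_LB), conc_ub = fin(m$conc_ub, DEFAULT_CONC_UB))
  })
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop_pf("schema violation: reaction without 'id'")
    if (is.null(r$stoich)) stop_pf("schema violation: reaction '%s' without 'stoich'", r$id)
    reaction(id = r$id, stoich = r$stoich,
             flux_lb = fin(r$flux_lb, 0), flux_ub = fin(r$flux_ub, Inf),
             dg0 = fin(r$dg0, NA_real_), modifiers = r$modifiers)
  })
  ref <- NULL
  if (!is.null(doc$reference_state)) {
    rs <- doc$reference_state
    ref <- reference_state(fluxes = rs$fluxes, concentrations = rs$concentrations,
                           theta = rs$theta, keq = rs$keq)
  }
  kin <- NULL
  if (!is.null(doc$kinetics)) {
    kin <- list(kinetic_parts = lapply(doc$kinetics$kinetic_parts, as_named_num),
                theta = as_named_num(doc$kinetics$theta),
                keq = as_named_num(doc$kinetics$keq))
  }
  metabolic_network(mets, rxns,
                    objective_id = doc$objective_id, uptake_id = doc$uptake_id,
                    reference = ref, kinetics = kin,
                    temperature = fin(doc$temperature, 298.15))
}

load_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) stop_pf("SBML import requires the 'xml2' package")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  attr_or <- function(node, name, default) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- lapply(sp, function(s) {
    bc <- identical(xml2::xml_attr(s, "boundaryCondition"), "true")
    id <- xml2::xml_attr(s, "id")
    metabolite(id = id, role = if (bc) "independent" else "dependent",
               name = attr_or(s, "name", id))
  })
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx, function(r) {
    stoich <- numeric(0)
    for (ref in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      v <- as.numeric(attr_or(ref, "stoichiometry", "1"))
      stoich[xml2::xml_attr(ref, "species")] <- -v
    }
    for (ref in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      v <- as.numeric(attr_or(ref, "stoichiometry", "1"))
      id <- xml2::xml_attr(ref, "species")
      prev <- if (id %in% names(stoich)) stoich[[id]] else 0
      stoich[id] <- prev + v
    }
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb <- -Inf; ub <- Inf
    for (p in xml2::xml_find_all(r, ".//kineticLaw//parameter")) {
      pid <- xml2::xml_attr(p, "id")
      if (identical(pid, "LOWER_BOUND")) lb <- as.numeric(xml2::xml_attr(p, "value"))
      if (identical(pid, "UPPER_BOUND")) ub <- as.numeric(xml2::xml_attr(p, "value"))
    }
    if (!rev && !is.finite(lb)) lb <- 0
    reaction(id = xml2::xml_attr(r, "id"), stoich = stoich, flux_lb = lb, flux_ub = ub)
  })
  metabolic_network(mets, rxns)
}

## ---------------------------------------------------------------------------
## Fixture generators

#' Unbranched pathway fixture with end-product inhibition
#'
#' Emits the pathway X0 -> X1 -> ... -> Xn -> (demand), with X0 and the demand
#' variable X(n+1) independent. Reaction 1 carries the end product Xn as an
#' inhibitory modifier with kinetic order `feedback_order`; the demand reaction
#' carries X(n+1) as a multiplicative modifier with order +1. The reference
#' state is constructed so that the mass-action quotient of every reaction with
#' theta > 0 equals theta*keq exactly, anchoring concentrations at 1 where the
#' constraints leave freedom, with all reference fluxes equal (steady state).
#'
#' @param n Number of dependent metabolites (pathway length), >= 1.
#' @param feedback_order Kinetic order (<= 0) of the end product on reaction 1.
#' @param theta Distances to equilibrium per reaction, recycled to length n+1
#'   (the demand step is conventionally irreversible).
#' @param keq Apparent equilibrium constants per reaction, recycled likewise.
#' @param kinetic_parts Optional named list (reaction id -> named numeric) of
#'   kinetic parts g^k; defaults to 0.5 on each substrate and 0 on each product.
#' @param flux Common reference flux (default 1, arbitrary units).
#' @param conc_lb,conc_ub Declared concentration bounds for the fixture. The
#'   fixture works in arbitrary concentration units anchored at 1, so the
#'   default box is (1e-6, 1e6) rather than the physiological mol/L box.
#' @return List with elements `network` and `reference`.
#' @export
make_unbranched_pathway <- function(n, feedback_order = -0.5, theta = 0,
                                    keq = 1, kinetic_parts = NULL, flux = 1,
                                    conc_lb = 1e-6, conc_ub = 1e6) {
  stopifnot(n >= 1)
  if (feedback_order > 0) stop_pf("feedback_order must be <= 0")
  nr <- n + 1L
  theta <- rep_len(as.numeric(theta), nr)
  keq <- rep_len(as.numeric(keq), nr)
  if (any(theta < 0 | theta >= 1)) stop_pf("theta must lie in [0, 1)")
  mids <- paste0("X", 0:(n + 1))
  rids <- paste0("v", seq_len(nr))
  mets <- lapply(0:(n + 1), function(i) {
    metabolite(mids[i + 1], role = if (i == 0 || i == n + 1) "independent" else "dependent",
               conc_lb = conc_lb, conc_ub = conc_ub)
  })
  rxns <- vector("list", nr)
  kparts <- list()
  for (i in seq_len(nr)) {
    sub <- mids[i]; prod_m <- if (i <= n) mids[i + 1] else NULL
    st <- stats::setNames(-1, sub)
    if (!is.null(prod_m)) st[prod_m] <- 1
    mods <- NULL
    kp <- stats::setNames(0.5, sub)
    if (!is.null(prod_m)) kp[prod_m] <- 0
    if (i == 1L && n >= 2) {
      # end-product inhibition; order 0 keeps the loop structurally present
      mods <- stats::setNames(-1, mids[n + 1])
      kp[mids[n + 1]] <- feedback_order
    }
    if (i == nr) {  # demand: multiplied by the independent demand variable
      mods <- stats::setNames(+1, mids[n + 2])
      kp[mids[n + 2]] <- 1
    }
    rxns[[i]] <- reaction(rids[i], stoich = st, flux_lb = 0, flux_ub = Inf, modifiers = mods)
    kparts[[rids[i]]] <- kp
  }
  if (!is.null(kinetic_parts)) {
    for (rid in names(kinetic_parts)) {
      kp <- as_named_num(as.list(kinetic_parts[[rid]]))
      kparts[[rid]][names(kp)] <- kp
    }
  }
  # reference concentrations: anchored at 1; a positive theta on step i pins
  # x_i / x_{i-1} = theta_i * keq_i (for i <= n).
  conc <- stats::setNames(rep(1, n + 2), mids)
  for (i in seq_len(n)) {
    if (theta[i] > 0) conc[mids[i + 1]] <- conc[mids[i]] * theta[i] * keq[i]
  }
  bad <- names(conc)[conc < conc_lb | conc > conc_ub]
  if (length(bad) > 0L) stop_pf("theta/keq force concentration(s) outside declared bounds: %s", paste(bad, collapse = ", "))
  ref <- reference_state(fluxes = stats::setNames(rep(flux, nr), rids),
                         concentrations = conc,
                         theta = stats::setNames(theta, rids),
                         keq = stats::setNames(keq, rids))
  net <- metabolic_network(mets, rxns, objective_id = rids[nr], uptake_id = rids[1],
                           reference = ref,
                           kinetics = list(kinetic_parts = kparts,
                                           theta = stats::setNames(theta, rids),
                                           keq = stats::setNames(keq, rids)))
  list(network = net, reference = ref)
}

#' Ammonia-assimilation network (GDH versus GS/GOGAT)
#'
#' GDH:   AKG + NH3 + NADPH -> GLU + NADP
#' GS:    GLU + NH3 + ATP   -> GLN + ADP + Pi
#' GOGAT: GLN + AKG + NADPH -> 2 GLU + NADP
#'
#' GLU and GLN are dependent; NH3, AKG and the cofactor pairs are clamped
#' (independent). The stoichiometric sum GS + GOGAT - GDH is ATP hydrolysis.
#'
#' @param dg0 Named numeric with entries GDH, GS, GOGAT (kJ/mol). Defaults are
#'   the shipped synthetic values (see `ammonia_defaults()`).
#' @param conc Named numeric of clamped concentrations (mol/L) for the
#'   independent metabolites; defaults from `ammonia_defaults()`.
#' @param exchanges If TRUE, adds exchange/supply reactions and a biomass-proxy
#'   demand (GLU + ATP -> ) so the network is closed for flux balance analysis
#'   with NH3 uptake capped at 10 and ATP synthesis capped at 10.
#' @return A `metabolic_network`.
#' @export
make_ammonia_network <- function(dg0 = NULL, conc = NULL, exchanges = FALSE) {
  def <- ammonia_defaults()
  dg0 <- if (is.null(dg0)) def$dg0 else as_named_num(as.list(dg0))
  conc <- if (is.null(conc)) def$conc else {
    cc <- def$conc; ov <- as_named_num(as.list(conc)); cc[names(ov)] <- ov; cc
  }
  missing_dg <- setdiff(c("GDH", "GS", "GOGAT"), names(dg0))
  if (length(missing_dg) > 0L) stop_pf("missing dg0 entr%s for: %s",
                                       if (length(missing_dg) > 1) "ies" else "y",
                                       paste(missing_dg, collapse = ", "))
  dep <- c("GLU", "GLN")
  indep <- c("NH3", "AKG", "NADPH", "NADP", "ATP", "ADP", "Pi")
  bounds_ub <- c(GLU = 1e-2, GLN = 1e-2, NH3 = 1e-2, AKG = 1e-2, NADPH = 1e-2,
                 NADP = 1e-2, ATP = 1e-2, ADP = 1e-2, Pi = 1e-2)
  mets <- c(
    lapply(dep, function(id) metabolite(id, role = "dependent")),
    lapply(indep, function(id) metabolite(id, role = "independent"))
  )
  rxns <- list(
    reaction("GDH", c(AKG = -1, NH3 = -1, NADPH = -1, GLU = 1, NADP = 1),
             dg0 = dg0[["GDH"]]),
    reaction("GS", c(GLU = -1, NH3 = -1, ATP = -1, GLN = 1, ADP = 1, Pi = 1),
             dg0 = dg0[["GS"]]),
    reaction("GOGAT", c(GLN = -1, AKG = -1, NADPH = -1, GLU = 2, NADP = 1),
             dg0 = dg0[["GOGAT"]])
  )
  objective_id <- NULL; uptake_id <- NULL
  if (exchanges) {
    # close the network: everything becomes dependent, supplies are explicit
    mets <- lapply(c(dep, indep), function(id) metabolite(id, role = "dependent"))
    rxns <- c(rxns, list(
      reaction("vin_nh3", c(NH3 = 1), flux_lb = 0, flux_ub = 10),
      reaction("vin_akg", c(AKG = 1)),
      reaction("vregen_nadph", c(NADP = -1, NADPH = 1)),
      reaction("vatp_syn", c(ADP = -1, Pi = -1, ATP = 1), flux_lb = 0, flux_ub = 10),
      reaction("vbio", c(GLU = -1, ATP = -1, ADP = 1, Pi = 1))
    ))
    objective_id <- "vbio"; uptake_id <- "vin_nh3"
  }
  ref <- reference_state(fluxes = stats::setNames(rep(1, length(rxns)),
                                                  vapply(rxns, `[[`, character(1), "id")),
                         concentrations = conc[c(dep, indep)])
  metabolic_network(mets, rxns, objective_id = objective_id, uptake_id = uptake_id,
                    reference = ref)
}

#' Shipped synthetic thermodynamic defaults for the ammonia case
#'
#' These values are synthetic stand-ins (the literature-derived values used in
#' the original analysis are not redistributable); they are chosen so that the
#' qualitative structure of the case study exists: GDH becomes infeasible at
#' low NH3 while GS/GOGAT stays feasible.
#'
#' @return List with `dg0` (kJ/mol) and `conc` (mol/L) named vectors.
#' @export
ammonia_defaults <- function() {
  path <- system.file("extdata", "ammonia_thermo.json", package = "pathforge")
  if (nzchar(path) && file.exists(path)) {
    doc <- jsonlite::read_json(path)
    return(list(dg0 = as_named_num(doc$dg0), conc = as_named_num(doc$conc)))
  }
  list(dg0 = c(GDH = -30, GS = -25, GOGAT = -40),
       conc = c(GLU = 1e-3, GLN = 1e-3, NH3 = 1e-3, AKG = 1e-2, NADPH = 1e-4,
                NADP = 1e-4, ATP = 5e-3, ADP = 5e-4, Pi = 5e-3))
}
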
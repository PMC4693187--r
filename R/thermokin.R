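# Scalar maps between reaction Gibbs energy and kinetics: the distance to
# equilibrium theta = exp(dG/RT), the thermodynamic factor (1 - theta) that
# scales an enzyme's maximal rate, the theta/(1-theta) contribution to kinetic
# orders, and the decomposition of a kinetic order into kinetic and
# thermodynamic parts.

#' Distance to equilibrium
#'
#' `theta = exp(dg / rt)`; 0 means fully irreversible, 1 equilibrium.
#'
#' @param dg Reaction Gibbs energy, kJ/mol.
#' @param rt Thermal energy R*T, kJ/mol (default at 298.15 K).
#' @return Dimensionless theta; in (0, 1) for dg < 0.
#' @export
theta_from_dg <- function(dg, rt = rt_constant()) {
  stopifnot(rt > 0)
  exp(dg / rt)
}

#' Gibbs energy from a distance to equilibrium
#'
#' Inverse of [theta_from_dg()].
#'
#' @param theta Distance to equilibrium in (0, 1].
#' @inheritParams theta_from_dg
#' @return dg in kJ/mol.
#' @export
dg_from_theta <- function(theta, rt = rt_constant()) {
  stopifnot(rt > 0)
  if (any(theta <= 0)) stop_pf("theta must be positive (theta = 0 maps to dg = -Inf)")
  rt * log(theta)
}

#' Thermodynamic factor 1 - theta
#'
#' The fraction of an enzyme's maximal rate available as net forward flux.
#'
#' @param dg Reaction Gibbs energy, kJ/mol; must be <= 0 (forward feasible).
#' @inheritParams theta_from_dg
#' @return Value in `[0, 1)`: 0 at equilibrium, -> 1 far from it.
#' @export
thermodynamic_factor <- function(dg, rt = rt_constant()) {
  if (any(dg > 0)) stop_pf("dg must be <= 0 for a forward-operating reaction")
  1 - exp(dg / rt)
}

#' Gibbs energy at which a fraction of Vmax is available
#'
#' Returns the dg at which `1 - theta` equals `fraction`; e.g. fraction 0.95
#' gives the dG at which the enzyme reaches 95% of its maximal rate.
#'
#' @param fraction Target fraction of Vmax, in (0, 1).
#' @inheritParams theta_from_dg
#' @return dg in kJ/mol (monotone decreasing in `fraction`).
#' @export
dg_at_fraction <- function(fraction, rt = rt_constant()) {
  if (any(fraction <= 0 | fraction >= 1)) stop_pf("fraction must lie in (0, 1)")
  rt * log(1 - fraction)
}

#' Thermodynamic contribution theta / (1 - theta) to a kinetic order
#'
#' Diverges as dg -> 0- (reaction approaching equilibrium).
#'
#' @param dg Reaction Gibbs energy, kJ/mol; must be strictly negative.
#' @inheritParams theta_from_dg
#' @return Non-negative dimensionless contribution.
#' @export
thermo_contribution <- function(dg, rt = rt_constant()) {
  if (any(dg >= 0)) stop_pf("dg must be < 0 (contribution diverges at equilibrium)")
  th <- exp(dg / rt)
  th / (1 - th)
}

#' Decompose a kinetic order into kinetic and thermodynamic parts
#'
#' The total order is `g = g_k - s * theta/(1-theta)`: the bounded kinetic part
#' plus a thermodynamic part whose sign opposes the stoichiometric coefficient
#' (substrates s < 0 gain, products s > 0 lose).
#'
#' @param kinetic_part Kinetic part g^k (log-log slope of the non-thermodynamic
#'   factors of the rate).
#' @param s Signed stoichiometric coefficient of the metabolite.
#' @param dg Reaction Gibbs energy, kJ/mol, < 0 (use `theta = 0` semantics via
#'   `dg = -Inf`).
#' @inheritParams theta_from_dg
#' @return List of class `order_decomposition` with `kinetic_part`,
#'   `thermo_part`, `total`, `s`, `theta`.
#' @export
kinetic_order <- function(kinetic_part, s, dg, rt = rt_constant()) {
  if (identical(dg, -Inf)) {
    tc <- 0; th <- 0
  } else {
    tc <- thermo_contribution(dg, rt)
    th <- exp(dg / rt)
  }
  if (abs(kinetic_part) > 4) {
    warning("kinetic part magnitude exceeds 4 (beyond the usual allosteric range)", call. = FALSE)
  }
  structure(list(kinetic_part = kinetic_part, thermo_part = -s * tc,
                 total = kinetic_part - s * tc, s = s, theta = th),
            class = "order_decomposition")
}

#' Enzyme specification
#'
#' @param kcat Forward catalytic constant (1/s), > 0.
#' @param et Total enzyme concentration (same units as the model's
#'   concentrations, or copies/cell), >= 0.
#' @return `enzyme_spec` with derived `vmax = kcat * et`.
#' @export
enzyme_spec <- function(kcat, et) {
  if (!(kcat > 0)) stop_pf("kcat must be positive")
  if (et < 0) stop_pf("et must be non-negative")
  structure(list(kcat = kcat, et = et, vmax = kcat * et), class = "enzyme_spec")
}

#' Effective maximal rate at a given driving force
#'
#' `kcat * et * (1 - theta)`: the ceiling on net forward flux for an enzyme
#' operating at Gibbs energy `dg`.
#'
#' @param enzyme An [enzyme_spec()].
#' @param dg Reaction Gibbs energy, kJ/mol, <= 0.
#' @inheritParams theta_from_dg
#' @return Rate in the units of `vmax`.
#' @export
effective_vmax <- function(enzyme, dg, rt = rt_constant()) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  enzyme$vmax * thermodynamic_factor(dg, rt)
}

#' Minimal enzyme needed to sustain a flux
#'
#' `flux / (kcat * (1 - theta))`; diverges as the reaction approaches
#' equilibrium.
#'
#' @param flux Required net flux, > 0.
#' @param kcat Forward catalytic constant, > 0.
#' @param dg Reaction Gibbs energy, kJ/mol, < 0 (use `-Inf` for the
#'   irreversible minimum `flux / kcat`).
#' @inheritParams theta_from_dg
#' @return Enzyme concentration in the units implied by `flux` and `kcat`.
#' @export
min_enzyme <- function(flux, kcat, dg, rt = rt_constant()) {
  if (!(flux > 0)) stop_pf("flux must be positive")
  if (!(kcat > 0)) stop_pf("kcat must be positive")
  if (!identical(dg, -Inf) && dg >= 0) stop_pf("dg must be < 0")
  fac <- if (identical(dg, -Inf)) 1 else thermodynamic_factor(dg, rt)
  flux / (kcat * fac)
}

#' Numerical elasticity (log-log slope) of a black-box rate law
#'
#' Central-difference estimate of d ln v / d ln x_j at `x0`. Serves as the
#' independent oracle against which the analytic order decomposition is
#' validated.
#'
#' @param rate_fn Function taking a concentration vector and returning a
#'   positive rate.
#' @param x0 Concentration vector (positive).
#' @param j Index of the metabolite to perturb.
#' @param rel_step Relative log-space step (default 1e-6).
#' @return Estimated elasticity (dimensionless).
#' @export
elasticity_oracle <- function(rate_fn, x0, j, rel_step = 1e-6) {
  v0 <- rate_fn(x0)
  if (!is.finite(v0) || v0 <= 0) stop_pf("rate_fn must be positive at x0")
  h <- rel_step
  xp <- x0; xp[j] <- x0[j] * exp(h)
  xm <- x0; xm[j] <- x0[j] * exp(-h)
  (log(rate_fn(xp)) - log(rate_fn(xm))) / (2 * h)
}
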
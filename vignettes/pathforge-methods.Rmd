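---
title: "Methods: from flux polytopes to thermodynamically consistent dynamic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from flux polytopes to thermodynamically consistent dynamic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathforge)
```

`pathforge` chains three modeling layers that consume progressively more
information about a metabolic network: stoichiometry (flux balance analysis),
standard free energies and concentration bounds (thermodynamic feasibility),
and a reference steady state plus kinetic orders (power-law dynamics). This
vignette documents the models, the assumptions behind them, the tunable
parameters, and the numerical and design choices that a user or reviewer
would want to audit.

## The network model and its units

A network is a list of metabolites and reactions. Metabolites are either
*dependent* (they receive a differential equation) or *independent* (clamped
by the environment: nutrients, demands, cofactor pools held constant by the
rest of metabolism). Reactions carry signed stoichiometries (negative
substrates, positive products), flux bounds, an optional standard free energy
ΔG° in kJ/mol, and regulatory *modifiers* — metabolites that affect the rate
without entering the mass balance, e.g. an allosteric end-product inhibitor.

One unit system is used throughout: concentrations in mol/L, energies in
kJ/mol, natural logarithms, and `RT = 8.314e-3 * T` kJ/mol (2.4788 at
298.15 K). Mixing kJ with kcal or ln with log10 is a classic source of silent
thermodynamic errors; a single convention removes the failure mode. The
default concentration box is 1e-7 to 1e-2 mol/L (0.1 µM to 10 mM), the
conventional physiological range; every metabolite can override it.
Water and proton activities are not represented as metabolites — their
contribution is assumed absorbed into ΔG°, the standard practice when ΔG°
values are supplied by the user.

## Flux balance analysis: two formulations of one question

`maximize_flux()` solves the familiar problem: maximize an objective flux
subject to `S_dep v = 0` and bounds, with an uptake cap preventing the trivial
unbounded solution. `minimize_uptake()` swaps the objective and the
constraint: minimize the uptake subject to the objective staying above a
floor. The two formulations trace the same trade-off curve — the optimum of
the first lies in the feasible set of the second — but they tell different
biological stories (transport-limited growth versus regulated flux at a set
growth rate). `tradeoff_curve()` runs both passes and the test suite asserts
their agreement to 1e-6 on every fixture.

FBA optima are famously degenerate. We report one optimum and offer a
deterministic tie-break (`tie_break = "l1"`: among optima, minimize the total
absolute flux), which is off by default because it changes the reported
distribution, not the objective. Solutions where the uptake bound is
arbitrary should be read as yield vectors (`yields()`), not rates.

No LP solver package ships in the supported environment, so the package
carries a small dense two-phase simplex (`lp_solve()`) with Bland's rule,
validated against brute-force vertex enumeration on every random fixture in
the test suite. Problems here have tens of variables; a textbook tableau is
fully adequate and completely deterministic.

## Thermodynamic feasibility and the Max-min Driving Force

Feasible concentration states satisfy `g = g0 + RT·Sᵀy ≤ 0` for every
forward-operating reaction (sign flipped for reverse, no constraint for
zero-flux reactions — a reaction that carries no flux imposes no driving-force
requirement). `variable_ranges()` reports per-metabolite and per-reaction
admissible intervals as LP optima; `max_min_driving_force()` finds the
concentration assignment minimizing B in `g_i ≤ B`, i.e. pushing the least
negative ΔG as far from equilibrium as possible. For an unbranched chain with
free interior metabolites the optimum equalizes all ΔG — the interior
metabolite splits the overall driving force — which the tests assert to
1e-6 kJ/mol and cross-check against a grid-search oracle.

The MDF is the thermodynamic face of enzyme economics: the closer a reaction
runs to equilibrium, the larger the fraction of its enzyme catalyzing the
reverse direction. `thermodynamic_factor()` (`1 − θ` with `θ = exp(ΔG/RT)`),
`effective_vmax()`, `min_enzyme()` and `dg_at_fraction()` quantify this: at
`ΔG = RT·ln(0.05) ≈ −7.4` kJ/mol an enzyme reaches 95% of its maximal rate;
at −1.7 kJ/mol only half.

## Power-law models with a thermodynamic backbone

Around a reference steady state, every rate is represented as a power law
`v_i = α_i ∏ x_j^{g_ij}`. The kinetic order `g_ij` (the elasticity) splits
into a bounded kinetic part and an unbounded thermodynamic part,

`g_ij = g^k_ij − s_ij · θ_i/(1−θ_i)`,

so substrates of a near-equilibrium reaction acquire huge positive orders and
products huge negative ones. The kinetic parts aggregate saturation and
regulation; they lie in [0, 1] for hyperbolic kinetics and up to the Hill
coefficient for allosteric enzymes (magnitudes above 4 trigger a validation
warning, not an error — the bound is advisory). The decomposition is
validated against a central-difference elasticity oracle on reversible
mass-action and reversible Michaelis–Menten laws (1000 random draws, 1e-6
relative, θ capped at 0.95 to keep the oracle's finite differences
well-conditioned).

Rate constants follow from the reference state
(`ln α = ln v₀ − Σ g ln x₀`) and are carried in log space internally: near
equilibrium the θ-equivalent rate constant grows like
`(θ/Keq)^{−θ/(1−θ)}` and overflows doubles long before the model itself
becomes ill-defined.

A reference state must satisfy the mass-action-quotient identity
`∏ x₀^{s} = θ·Keq` for every reaction with θ > 0 (checked to 1e-9 relative);
`build_model()` refuses inconsistent inputs. Steady states of S-systems (one
net production and one net consumption term per dependent variable) are
solved exactly as linear systems in log-concentrations; branched (GMA) models
fall back to a damped Newton iteration converging to `‖ẋ‖∞ ≤ 1e-10`.
Logarithmic gains and parametric sensitivities come from the same linear
solve and are cross-checked against finite-difference re-solution at 1e-8.

Stability is judged on the log-space Jacobian
`J = diag(1/x*) S_dep diag(v*) G`, which is similar to the linear-space
Jacobian through a positive diagonal and therefore shares its verdict, while
being better conditioned for the near-equilibrium orders this package
specializes in. For up to three dependent variables the Routh–Hurwitz
determinant conditions are evaluated and compared with the eigenvalues.

**Stability margin.** The critical magnitude of a designated feedback order
is found by scanning the magnitude upward and bisecting the leading
eigenvalue's zero crossing to 1e-6 relative, with magnitudes above 1e6
reported as infinite. Two conventions were open here: (a) hold the rate
constants fixed and let the steady state drift as the feedback strengthens,
or (b) re-derive the rate constants from the fixed reference state so the
operating point is preserved. We chose (b): it compares like with like (the
same steady state under different regulatory gain) and is the convention
under which the known limit results hold (a single-variable loop is stable at
any strength; margins shrink as homologous pathways grow). A closed-form
margin expression exists in principle but the operational eigenvalue
definition is formalism-independent and testable; an independent
simulation-divergence oracle agrees with it to 1e-3 in the tests.

## Thermodynamic shortening

When a reaction stays close to equilibrium its substrate and product are
locked near their equilibrium ratio, and the meaningful variable is their
pool. `reduce_model()`:

1. partitions reactions by `θ ≥ threshold` (default 0.99 — at that distance
   the thermodynamic contribution `θ/(1−θ) ≥ 99` dwarfs any kinetic part);
2. builds an integer pooling matrix `C` from the left null space of the
   equilibrated stoichiometric block, rows normalized to smallest positive
   integers and ordered lexicographically by support, so pools read as
   literal sums (`p = x1 + x2`);
3. picks bound metabolites by reverse declaration order (later pathway
   members first) keeping the bound block invertible — any invertible split
   is valid, a canonical one makes results reproducible;
4. eliminates them through `ln x_b = F ln x_f + ln γ` with
   `F = −(Sᵀ_eq,b)⁻¹ Sᵀ_eq,f`, `ln γ = (Sᵀ_eq,b)⁻¹ ln Keq`;
5. rewrites each remaining rate over pools using the equilibrium shares
   `x_j = (γ_j / W) p`, `W = Σ c_k γ_k` — for a two-member pool this is the
   familiar `ᾱ = α (Keq/(1+Keq))^g` construction.

The re-expression is an exact power law only when each bound metabolite loads
on its pool's free metabolite with exponent 1 (true for 1:1 interconversion
chains); other stoichiometries make the pool a posynomial and the function
raises an error rather than silently linearizing. Metabolites that act as
distant modifiers elsewhere are rewritten through the same elimination map.
Because the generalized pool construction has no printed closed form beyond
the two-member case, it is validated against simulation: pooled trajectories
of the full model agree with the reduced model within 1% at θ = 0.999, and
steady states, gains and sensitivities converge monotonically over
θ ∈ {0.9, 0.99, 0.999}.

Shortening is not merely bookkeeping: removing a fast intermediate widens the
feedback stability margin (to infinity for the worked 3-step case, since the
2-variable reduced loop adds damping with feedback strength instead of phase
lag). The same margin widening appears when rate constants are spread over a
wide range — *kinetic* shortening — asserted in the tests on two concrete
length-4 parameterizations.

## Controlled comparison and the θ family

To compare regulatory designs fairly, alternatives must be internally
equivalent (all parameters outside the changed reactions byte-identical) and
externally equivalent (matched fluxes, end-product levels, or gains).
`theta_equivalence()` constructs the family of pathways whose interior
reaction sits at distance θ with equilibrium constant Keq while carrying the
same flux and end-product steady state as the irreversible reference. Two
consistency constraints tie the parameters: the downstream order must equal
the sum of the reaction's kinetic parts, and the rate constants must satisfy
`ln α₂ = ln α₃ + (g^k₂₁ + θ/(1−θ))·ln(Keq·θ)`. Deriving this relation from
the steady-state balance produces a **plus** sign on the second term where
one printed source shows a minus; the plus sign is the one under which the
steady state actually satisfies the quotient identity and the flux is
invariant, both asserted numerically to 1e-9 in the tests, so that is what
the package implements. The point `θ·Keq = 1` is genuinely degenerate (the
substrate and product concentrations coincide and one degree of freedom
disappears); the constructor rejects it.

Under these constraints the factor `g₂₁/(g₃₂ − g₂₂)` relating the family's
log gains to the irreversible reference equals exactly 1 — every member is
indistinguishable from outside — while the sensitivity to the equilibrated
enzyme's rate constant vanishes as θ → 1: the enzyme disappears from the
systemic behavior, which is precisely why the shortened model can drop it.
In `external_equivalence()` the matched conditions may be redundant (matching
the end product of a chain matches its flux for free); the solve is
least-squares with a residual check, and sets with more conditions than free
parameters are rejected.

`design_sweep()` places designs in a performance space: "economic" designs
(far from equilibrium, weak feedback) carry a given flux with the least
enzyme; "responsive" designs (irreversible committed step, downstream
near-equilibrium steps, strong feedback) buy a wide stability margin — hence
headroom for strong feedback — at a higher enzyme cost. Neither dominates;
they are ends of a trade-off.

## The fixture generators as a stated world

`make_unbranched_pathway(n)` emits the canonical chain X0 → X1 → … → Xn →
demand, with X0 and the demand multiplier clamped, end-product inhibition on
the first step, kinetic parts 0.5 on substrates (mid-saturation hyperbolic
kinetics) and 0 on products, reference fluxes 1 and concentrations anchored
at 1 in arbitrary units (the declared box is widened to 1e-6–1e6 for this
dimensionless fixture; the physiological mol/L box applies to the ammonia
case). Where θ > 0 pins a concentration ratio, the anchor propagates through
`x_i = x_{i−1}·θ·Keq`. These defaults are the conditions the case studies
state; they are not tuned.

`make_ammonia_network()` builds GDH (AKG + NH3 + NADPH → GLU + NADP), GS
(GLU + NH3 + ATP → GLN + ADP + Pi) and GOGAT (GLN + AKG + NADPH → 2 GLU +
NADP); the stoichiometric sum GS + GOGAT − GDH is exactly one ATP hydrolysis.
The shipped ΔG° values (−30, −25, −40 kJ/mol) and cofactor concentrations are
**synthetic** stand-ins of literature-like magnitude — the original analysis
used supplementary values that are not redistributable — chosen once so the
qualitative structure exists: at low NH3, GDH is thermodynamically blocked
while GS/GOGAT still runs; at high NH3, GDH is the cheaper route. Green tests
on this fixture establish the structure of the analysis, not the numerical
ΔG of real E. coli enzymes.

What the generators do not emulate: measurement noise, enzyme-level
regulation, crowding, non-ideal activities (all activities are
concentrations), and genome-scale network context.

## Numerical choices

* LP: internal two-phase simplex, Bland's rule, pivot tolerance 1e-9,
  deterministic; unboundedness and infeasibility are reported, never patched.
* ODE: Dormand–Prince RK45 for ordinary models; an L-stable two-stage
  Rosenbrock scheme with the analytic log-space Jacobian when any kinetic
  order exceeds 20 in magnitude (near-equilibrium models are stiff with rate
  ratios of order θ/(1−θ)). Integration is in log-concentrations, which
  preserves positivity by construction; a failed rate evaluation inside a
  trial step rejects the step rather than aborting.
* Pool matrices: double-precision reduced row echelon form with
  rationalization to smallest integers (denominators up to 1e4) — exact for
  the small integer stoichiometries this package targets.
* Steady-state tolerances: 1e-10 on `‖ẋ‖∞` (Newton fallback), 1e-9 relative
  on reference reproduction, 1e-8 on analytic-versus-numeric
  gain/sensitivity agreement.

## Known limitations

* Genome-scale models load (JSON, minimal SBML) and solve, but the package is
  tuned for small, interpretable networks; no loopless FBA, flux variability,
  or thermodynamic sampling.
* ΔG° estimation (group contribution, Legendre transforms for pH/ionic
  strength) is out of scope; ΔG° values are user inputs.
* The reduced model requires unit equilibrium exponents per pool (see above).
* The exact log-linear solve covers S-systems; branched models use the
  Newton fallback and numeric sensitivities.
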
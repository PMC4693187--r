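test_that("build_model assembles orders per the kinetic/thermodynamic split", {
  # fully irreversible symmetric fixture: product orders vanish
  m0 <- build_model(fixture_symmetric()$network)
  expect_equal(unname(m0$rates$v2$orders[c("X1", "X2")]), c(0.5, 0))
  expect_equal(unname(m0$rates$v1$orders[["X3"]]), -0.5)
  # reaction 2 at theta = 0.5: substrate gains +1, product loses 1
  fx <- make_unbranched_pathway(3, theta = c(0, 0.5, 0, 0), keq = c(1, 2, 1, 1))
  m <- build_model(fx$network)
  expect_equal(m$rates$v2$orders[["X1"]], 0.5 + 1, tolerance = 1e-12)
  expect_equal(m$rates$v2$orders[["X2"]], 0 - 1, tolerance = 1e-12)
  # modifier orders equal their kinetic part
  expect_equal(m$rates$v1$orders[["X3"]], m$rates$v1$kinetic_parts[["X3"]])
  # mismatched reference errors (mass-action-quotient guard)
  bad <- fx$network
  bad$reference$concentrations["X2"] <- 5
  expect_error(build_model(bad), "quotient")
  # missing kinetic part errors
  fx2 <- fixture_symmetric()
  fx2$network$kinetics$kinetic_parts$v2 <- fx2$network$kinetics$kinetic_parts$v2["X1"]
  expect_error(build_model(fx2$network), "missing kinetic part")
})

test_that("rate constants invert the power law at the reference state", {
  ref <- reference_state(fluxes = c(r = 1), concentrations = c(A = 1))
  expect_equal(unname(rate_constants(ref, list(r = c(A = 0.5)))), 1)
  ref2 <- reference_state(fluxes = c(r = 2), concentrations = c(A = 4))
  expect_equal(unname(rate_constants(ref2, list(r = c(A = 0.5)))), 1, tolerance = 1e-12)
  # round trip on random fixtures
  set.seed(3)
  for (i in 1:20) {
    fx <- make_unbranched_pathway(3, theta = c(0, runif(1, 0, 0.9), 0, 0),
                                  keq = 10^runif(4, -0.5, 0.5))
    m <- build_model(fx$network)
    v0 <- evaluate_rates(m, fx$reference$concentrations)
    expect_equal(unname(v0), unname(fx$reference$fluxes[m$reaction_ids]),
                 tolerance = 1e-9)
  }
  expect_error(rate_constants(reference_state(c(r = 1), c(A = 1)),
                              list(r = c(B = 1))), "missing")
})

test_that("steady states solve the log-linear system and match ODE integration", {
  m <- build_model(fixture_symmetric()$network)
  expect_equal(unname(steady_state(m)), c(1, 1, 1), tolerance = 1e-12)
  # clamp X0 = 2: closed-form log gain of x3 is g10/(g43 - g13) = 0.5/1 = 0.5
  x <- steady_state(m, independent_values = c(X0 = 2))
  expect_equal(x[["X3"]], 2^0.5, tolerance = 1e-10)
  # with g1,0 = 1 and demand g4,3 = 0.5, feedback -0.5: L(x3, x0) = 1, so x3 = 2
  fx <- make_unbranched_pathway(3, kinetic_parts = list(v1 = c(X0 = 1)))
  m2 <- build_model(fx$network)
  x2 <- steady_state(m2, independent_values = c(X0 = 2))
  expect_equal(x2[["X3"]], 2, tolerance = 1e-10)
  # long-time integration lands on the same state
  m3 <- build_model(make_unbranched_pathway(3, theta = c(0, 0.6, 0, 0), keq = c(1, 3, 1, 1))$network)
  xs <- steady_state(m3, independent_values = c(X0 = 1.5))
  tr <- simulate_model(m3, xs * c(1.4, 0.7, 1.2), c(0, 200),
                       independent_values = c(X0 = 1.5))
  expect_equal(as.numeric(tr[2, -1]), unname(xs), tolerance = 1e-6)
})

test_that("the Newton fallback handles branched (GMA) models", {
  # branched consumption of A: not an S-system
  net <- metabolic_network(
    list(metabolite("S0", role = "independent"), metabolite("A")),
    list(reaction("in1", c(S0 = -1, A = 1)),
         reaction("outA", c(A = -1)),
         reaction("outB", c(A = -1))),
    reference = reference_state(fluxes = c(in1 = 2, outA = 1, outB = 1),
                                concentrations = c(S0 = 1, A = 1)),
    kinetics = list(kinetic_parts = list(in1 = c(S0 = 0.5, A = 0),
                                         outA = c(A = 0.7), outB = c(A = 0.3))))
  m <- build_model(net)
  expect_null(pathforge:::s_system_structure(m))
  xs <- steady_state(m)
  expect_equal(xs[["A"]], 1, tolerance = 1e-9)
  xs2 <- steady_state(m, independent_values = c(S0 = 2))
  v <- evaluate_rates(m, c(xs2, S0 = 2))
  expect_lt(abs(v[["in1"]] - v[["outA"]] - v[["outB"]]), 1e-9)
})

test_that("trajectories stay flat at steady state and decay when stable", {
  m <- build_model(fixture_symmetric()$network)
  xs <- steady_state(m)
  tr <- simulate_model(m, xs, seq(0, 100, 25))
  drift <- abs(as.matrix(tr[, -1]) - matrix(xs, nrow(tr), 3, byrow = TRUE))
  expect_lt(max(drift), 1e-8)
  # stable model: perturbation decays
  tr2 <- simulate_model(m, xs * 1.1, seq(0, 50, 5))
  dev <- apply(abs(as.matrix(tr2[, -1]) - matrix(xs, nrow(tr2), 3, byrow = TRUE)), 1, max)
  expect_lt(dev[length(dev)], 1e-3 * dev[1])
  expect_error(simulate_model(m, c(X1 = -1, X2 = 1, X3 = 1), c(0, 1)), "positive")
})

test_that("analytic gains and sensitivities match numerical re-solution", {
  fx <- make_unbranched_pathway(3, theta = c(0, 0.4, 0, 0), keq = c(1, 4, 1, 1))
  m <- build_model(fx$network)
  for (iid in c("X0", "X4")) {
    expect_equal(log_gains(m, iid), log_gains(m, iid, method = "numeric"),
                 tolerance = 1e-8)
  }
  for (rid in c("v1", "v2", "v4")) {
    expect_equal(parameter_sensitivities(m, rid),
                 parameter_sensitivities(m, rid, method = "numeric"),
                 tolerance = 1e-8)
  }
  # closed form: L(x3, x0) = g10/(g43 - g13)
  g <- m$rates
  L_closed <- g$v1$orders[["X0"]] / (g$v4$orders[["X3"]] - g$v1$orders[["X3"]])
  expect_equal(log_gains(m, "X0")[["x_X3"]], L_closed, tolerance = 1e-10)
  # no-feedback chain: gain of x3 with respect to demand is negative
  m0 <- build_model(make_unbranched_pathway(3, feedback_order = 0)$network)
  expect_lt(log_gains(m0, "X4")[["x_X3"]], 0)
  # independent variable absent from all rates has zero gains
  fx5 <- make_unbranched_pathway(3)
  fx5$network$metabolites[[6]] <- metabolite("Z", role = "independent")
  fx5$network$reference$concentrations["Z"] <- 1
  m5 <- build_model(fx5$network)
  expect_true(all(abs(log_gains(m5, "Z")) < 1e-12))
})

test_that("flux sensitivities respect homogeneity on the unbranched chain", {
  m <- build_model(fixture_symmetric()$network)
  # uniform alpha scaling multiplies every flux: sum over reactions of the
  # pathway-flux sensitivities equals 1
  tot <- Reduce(`+`, lapply(m$reaction_ids,
                            function(rid) parameter_sensitivities(m, rid)[["v_v4"]]))
  expect_equal(tot, 1, tolerance = 1e-9)
  # sensitivity to alpha2 vanishes as reaction 2 approaches equilibrium
  s_vals <- vapply(c(0.9, 0.99, 0.999), function(th) {
    mm <- theta_equivalence(make_unbranched_pathway(3, feedback_order = -0.25)$network,
                            th, 20)$model
    abs(parameter_sensitivities(mm, "v2")[["x_X1"]])
  }, numeric(1))
  expect_true(all(diff(s_vals) < 0))
  expect_lt(s_vals[3], 1e-2)
})

test_that("stability verdicts: eigenvalues and Routh-Hurwitz agree", {
  # irreversible chain without feedback: triangular Jacobian, stable
  m0 <- build_model(make_unbranched_pathway(3, feedback_order = 0)$network)
  st0 <- stability(m0)
  expect_true(st0$stable)
  expect_true(st0$rh_agrees)
  # strong feedback destabilizes
  m50 <- build_model(make_unbranched_pathway(3, feedback_order = -50)$network)
  expect_false(stability(m50)$stable)
  # random fixtures: criterion equivalence
  set.seed(11)
  for (i in 1:60) {
    fb <- -10^runif(1, -1, 1.8)
    kp <- runif(3, 0.2, 1.5)
    fx <- make_unbranched_pathway(3, feedback_order = fb,
                                  kinetic_parts = list(v2 = c(X1 = kp[1]),
                                                       v3 = c(X2 = kp[2]),
                                                       v4 = c(X3 = kp[3])))
    st <- stability(build_model(fx$network))
    expect_true(st$rh_agrees, info = paste("draw", i))
  }
})

test_that("feedback stability margins behave as the theory prescribes", {
  # single dependent variable: negative 1-D Jacobian for any feedback
  net1 <- metabolic_network(
    list(metabolite("S0", role = "independent"), metabolite("A"),
         metabolite("D", role = "independent")),
    list(reaction("vin", c(S0 = -1, A = 1), modifiers = c(D = -1)),
         reaction("vout", c(A = -1))),
    reference = reference_state(fluxes = c(vin = 1, vout = 1),
                                concentrations = c(S0 = 1, A = 1, D = 1)),
    kinetics = list(kinetic_parts = list(vin = c(S0 = 0.5, A = 0, D = -0.5),
                                         vout = c(A = 0.5))))
  # feedback through the dependent variable itself: product inhibition on vin
  net1$kinetics$kinetic_parts$vin["A"] <- -0.5
  m1 <- build_model(net1)
  expect_identical(feedback_stability_margin(m1, "vin", "A"), Inf)
  # 3-step fixture: finite margin, agreeing with the simulation oracle
  m3 <- build_model(fixture_symmetric(-0.5)$network)
  marg <- feedback_stability_margin(m3, "v1", "X3")
  expect_true(is.finite(marg) && marg > 0.5)
  sim_marg <- oracle_margin_sim(m3, "v1", "X3", hi = 2 * marg, tol = 5e-4)
  expect_equal(marg, sim_marg, tolerance = 1e-3)
  # margins shrink as homologous pathways grow longer
  margins <- vapply(2:4, function(n) {
    m <- build_model(make_unbranched_pathway(n, feedback_order = -0.5)$network)
    feedback_stability_margin(m, "v1", paste0("X", n))
  }, numeric(1))
  expect_true(margins[1] >= margins[2] && margins[2] >= margins[3])
  # kinetic shortening: spreading rate constants widens the margin (n = 4)
  even <- build_model(make_unbranched_pathway(4, feedback_order = -0.5)$network)
  spread_fx <- make_unbranched_pathway(4, feedback_order = -0.5)
  spread_fx$reference$fluxes[] <- 1
  # spread enzyme speeds: scale reference concentrations to stagger alphas
  spread_fx$network$reference$concentrations[c("X1", "X2", "X3", "X4")] <-
    c(10, 0.1, 10, 0.1)
  spread <- build_model(spread_fx$network)
  m_even <- feedback_stability_margin(even, "v1", "X4")
  m_spread <- feedback_stability_margin(spread, "v1", "X4")
  expect_gt(m_spread, m_even)
  # unstable at zero feedback is rejected
  expect_error(feedback_stability_margin(m1, "vin", "S0"), "feedback")
})

test_that("perturbations beyond the margin grow instead of decaying", {
  m3 <- build_model(fixture_symmetric(-0.5)$network)
  marg <- feedback_stability_margin(m3, "v1", "X3")
  above <- pathforge:::set_feedback_magnitude(m3, "v1", "X3", marg * 1.3)
  xs <- steady_state(above)
  tr <- simulate_model(above, xs * (1 + 1e-3), seq(0, 80, 20))
  dev <- apply(abs(as.matrix(tr[, -1]) - matrix(xs, nrow(tr), 3, byrow = TRUE)) /
                 matrix(xs, nrow(tr), 3, byrow = TRUE), 1, max)
  expect_gt(dev[length(dev)], dev[1])
})
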
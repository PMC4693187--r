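test_that("internal equivalence enumerates exactly the changed reaction's freedom", {
  m <- build_model(make_unbranched_pathway(3, feedback_order = -0.25)$network)
  spec <- internal_equivalence(m, "v2")
  fp <- paste(spec$free_parameters$reaction, spec$free_parameters$parameter)
  expect_setequal(fp, c("v2 theta", "v2 gk_X1", "v2 gk_X2", "v2 alpha"))
  spec0 <- internal_equivalence(m, character(0))
  expect_equal(nrow(spec0$free_parameters), 0)
  expect_error(internal_equivalence(m, "v9"), "v9")
  # altering a frozen parameter is reported by name
  m2 <- m
  m2$rates$v3$alpha <- 2; m2$rates$v3$log_alpha <- log(2)
  expect_error(check_internal_equivalence(spec, m, m2), "v3")
  # equivalent models pass
  expect_true(check_internal_equivalence(spec, m, m))
})

test_that("thermodynamic consistency ties kinetic parts and rate constants", {
  fam_net <- make_unbranched_pathway(3, feedback_order = -0.25)$network
  te <- theta_equivalence(fam_net, 0.5, 10)
  tc <- thermo_consistency(te$model, "v2")
  expect_false(tc$degenerate)
  expect_true(tc$satisfied)
  # downstream order equals the sum of the kinetic parts
  expect_equal(tc$kinetic_sum_actual, tc$kinetic_sum_target, tolerance = 1e-12)
  expect_equal(te$parameters[["gk_substrate"]] + te$parameters[["gk_product"]],
               0.5, tolerance = 1e-12)   # downstream order of the fixture
  # theta = 0 degenerates to the irreversible case
  tc0 <- thermo_consistency(build_model(fam_net), "v2")
  expect_true(tc0$degenerate)
  # contrapositive: a rate constant violating the consistency constraint
  # yields a steady state that breaks the mass-action-quotient identity
  m_bad <- te$model
  m_bad$rates$v2$log_alpha <- m_bad$rates$v2$log_alpha + 0.3
  m_bad$rates$v2$alpha <- exp(m_bad$rates$v2$log_alpha)
  expect_false(thermo_consistency(m_bad, "v2")$satisfied)
  x_bad <- steady_state(m_bad)
  q <- x_bad[["X2"]] / x_bad[["X1"]]
  expect_gt(abs(q - 0.5 * 10), 1e-3)
})

test_that("the gain-transfer factor equals one under the consistency constraints", {
  base <- make_unbranched_pathway(3, feedback_order = -0.25)$network
  set.seed(19)
  vals <- replicate(100, {
    th <- runif(1, 0.05, 0.95)
    kq <- 10^runif(1, 0.2, 1.5)
    if (abs(th * kq - 1) < 0.05) return(NA_real_)
    gain_transfer_factor(theta_equivalence(base, th, kq)$model, "v2")
  })
  vals <- vals[!is.na(vals)]
  expect_gt(length(vals), 50)
  expect_true(all(abs(vals - 1) < 1e-12))
})

test_that("theta equivalence preserves flux and end-product state across the family", {
  base <- make_unbranched_pathway(3, feedback_order = -0.25)$network
  ref <- build_model(base)
  x_ref <- steady_state(ref)
  v_ref <- evaluate_rates(ref, c(x_ref, pathforge:::independent_reference(ref)))
  for (th in c(0.1, 0.5, 0.9)) {
    te <- theta_equivalence(base, th, 20)
    x <- steady_state(te$model)
    v <- evaluate_rates(te$model, c(x, pathforge:::independent_reference(te$model)))
    expect_equal(v[["v2"]], v_ref[["v2"]], tolerance = 1e-9)
    expect_equal(x[["X3"]], x_ref[["X3"]], tolerance = 1e-9)
    # the steady state satisfies the mass-action-quotient identity
    expect_equal(x[["X2"]] / x[["X1"]], th * 20, tolerance = 1e-9)
  }
  # closed-form multiplier at keq = 10, theta = 0.5: (0.05)^{-1} = 20
  te <- theta_equivalence(base, 0.5, 10)
  expect_equal(unname(te$parameters[["alpha_multiplier"]]), 20, tolerance = 1e-12)
  # irreversible limit: multiplier -> 1
  te_small <- theta_equivalence(base, 1e-4, 10)
  expect_equal(unname(te_small$parameters[["alpha_multiplier"]]), 1, tolerance = 1e-2)
  expect_error(theta_equivalence(base, 1.2, 10), "theta")
  expect_error(theta_equivalence(base, 0.1, 10), "degenerate")
})

test_that("external equivalence solves the no-feedback comparison analytically expected way", {
  base <- make_unbranched_pathway(3, feedback_order = -0.25)
  ref <- build_model(base$network)
  nofb_net <- base$network
  nofb_net$kinetics$kinetic_parts$v1["X3"] <- 0
  alt <- build_model(nofb_net)
  # move the operating point away from 1 so the solve is non-trivial
  ref$reference$concentrations["X0"] <- 2
  alt$reference$concentrations["X0"] <- 2
  eq <- external_equivalence(ref, alt, free = "v1",
                             matched = list(list(type = "conc", id = "X3")))
  expect_lt(eq$residual, 1e-9)
  x3 <- steady_state(ref)[["X3"]]
  # matching x3 matches the pathway flux for free (demand depends on x3 only)
  v_ref <- evaluate_rates(ref, c(steady_state(ref), pathforge:::independent_reference(ref)))
  v_alt <- evaluate_rates(eq$model, c(steady_state(eq$model),
                                      pathforge:::independent_reference(eq$model)))
  expect_equal(v_alt[["v4"]], v_ref[["v4"]], tolerance = 1e-9)
  # matching flux and x3 fixes alpha1_hat = alpha1 * x3^{g1,3}
  expect_equal(unname(eq$alpha[["v1"]] / ref$rates$v1$alpha), x3^(-0.25),
               tolerance = 1e-8)
  # empty matched set keeps the template parameters
  eq0 <- external_equivalence(ref, alt, free = "v1", matched = list())
  expect_equal(unname(eq0$alpha[["v1"]]), alt$rates$v1$alpha)
  # over-determined sets are rejected
  expect_error(external_equivalence(ref, alt, free = "v1",
                                    matched = list(list(type = "conc", id = "X1"),
                                                   list(type = "conc", id = "X2"),
                                                   list(type = "conc", id = "X3"))),
               "over-determined")
})

test_that("controlled comparison: feedback buys robustness at equal flux", {
  base <- make_unbranched_pathway(3, feedback_order = -0.5)
  ref <- build_model(base$network)
  nofb_net <- base$network
  nofb_net$kinetics$kinetic_parts$v1["X3"] <- 0
  alt0 <- build_model(nofb_net)
  eq <- external_equivalence(ref, alt0, free = "v1",
                             matched = list(list(type = "conc", id = "X3")))
  rep <- compare_models(
    ref, eq$model,
    properties = list(
      flux = function(m) {
        x <- steady_state(m)
        evaluate_rates(m, c(x, pathforge:::independent_reference(m)))[["v4"]]
      },
      S_x3_a1 = function(m) parameter_sensitivities(m, "v1")[["x_X3"]]),
    better = c(S_x3_a1 = "smaller"))
  expect_equal(rep$reference[rep$property == "flux"],
               rep$alternative[rep$property == "flux"], tolerance = 1e-9)
  s_ref <- abs(rep$reference[rep$property == "S_x3_a1"])
  s_alt <- abs(rep$alternative[rep$property == "S_x3_a1"])
  expect_lt(s_ref, s_alt)           # feedback system is more robust
  expect_equal(rep$verdict[rep$property == "S_x3_a1"], "worse")
  # log gains with respect to the clamped ends coincide across the theta family
  fam_net <- make_unbranched_pathway(3, feedback_order = -0.25)$network
  L <- vapply(c(0.2, 0.6, 0.9), function(th) {
    log_gains(theta_equivalence(fam_net, th, 20)$model, "X0")[["x_X3"]]
  }, numeric(1))
  expect_lt(max(L) - min(L), 1e-9)
})

test_that("design sweep separates economic and responsive archetypes", {
  sw <- design_sweep(n = 3, feedback_strengths = c(0, 2), keq = 50)
  eco <- sw[sw$profile == "economic" & sw$feedback == 0, ]
  resp <- sw[sw$profile == "responsive" & sw$feedback == 2, ]
  # economic design carries the flux with the least enzyme
  expect_equal(eco$enzyme_cost, min(sw$enzyme_cost), tolerance = 1e-12)
  # near-equilibrium design has at least the margin of the irreversible one
  for (fb in unique(sw$feedback)) {
    m_resp <- sw$margin[sw$profile == "responsive" & sw$feedback == fb]
    m_eco <- sw$margin[sw$profile == "economic" & sw$feedback == fb]
    expect_gte(m_resp, m_eco)
  }
  # neither archetype dominates the other on (cost, margin-weighted response)
  expect_gt(resp$enzyme_cost, eco$enzyme_cost)
  expect_gt(resp$margin, eco$margin)
})
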
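theta_family <- function(feedback = -0.25, keq = 10) {
  base <- make_unbranched_pathway(3, feedback_order = feedback)
  function(th) theta_equivalence(base$network, th, keq)$model
}

test_that("reaction partition by proximity to equilibrium is deterministic", {
  fx <- make_unbranched_pathway(3, theta = c(0, 0.999, 0, 0), keq = c(1, 2, 1, 1))
  m <- build_model(fx$network)
  p <- partition_reactions(m, 0.99)
  expect_equal(p$eq_ids, "v2")
  expect_setequal(p$irr_ids, c("v1", "v3", "v4"))
  p0 <- partition_reactions(m, 0)
  expect_setequal(p0$eq_ids, m$reaction_ids)
  expect_error(partition_reactions(m, 1), "theta_threshold")
})

test_that("pooling matrix is an integer left-null-space basis with sum pools", {
  # one equilibrated step x1 <-> x2: pool x1 + x2 plus the untouched x3
  Seq <- matrix(c(-1, 1, 0), 3, 1, dimnames = list(c("x1", "x2", "x3"), "r2"))
  C <- pool_matrix(Seq)
  expect_equal(unname(C), rbind(c(1, 1, 0), c(0, 0, 1)))
  expect_equal(rownames(C), c("pool_x1_x2", "x3"))
  expect_true(all(C %*% Seq == 0))
  # empty equilibrium set: identity
  C0 <- pool_matrix(matrix(0, 2, 0, dimnames = list(c("a", "b"), NULL)))
  expect_equal(unname(C0), diag(2))
  # random chain-with-stoichiometry cases: C Seq = 0 and rank condition
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:5, 1)
    k <- sample(1:(n - 1), 1)
    Seq <- matrix(0, n, k, dimnames = list(paste0("m", 1:n), paste0("e", 1:k)))
    for (j in 1:k) {
      Seq[j, j] <- -sample(1:2, 1)
      Seq[j + 1, j] <- sample(1:2, 1)
    }
    C <- pool_matrix(Seq)
    expect_lt(max(abs(C %*% Seq)), 1e-12)
    expect_equal(nrow(C) + qr(Seq)$rank, n)
    expect_true(all(C >= 0))
  }
})

test_that("free/bound split takes later metabolites first and stays invertible", {
  Seq <- matrix(c(-1, 1), 2, 1, dimnames = list(c("x1", "x2"), "r"))
  sp <- split_metabolites(Seq)
  expect_equal(sp$bound_ids, "x2")
  expect_equal(sp$free_ids, "x1")
  Seq2 <- matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
                 dimnames = list(c("x1", "x2", "x3"), c("r1", "r2")))
  sp2 <- split_metabolites(Seq2)
  expect_equal(sp2$bound_ids, c("x2", "x3"))
  sp0 <- split_metabolites(matrix(0, 2, 0, dimnames = list(c("a", "b"), NULL)))
  expect_equal(sp0$bound_ids, character(0))
})

test_that("bound elimination reproduces the equilibrium map", {
  Seq <- matrix(c(-1, 1), 2, 1, dimnames = list(c("x1", "x2"), "r"))
  sp <- split_metabolites(Seq)
  el <- eliminate_bound(Seq, sp, keq = 3)
  expect_equal(unname(el$f_matrix[1, 1]), 1)
  expect_equal(unname(el$gamma[["x2"]]), 3)          # x2 = Keq * x1
  el1 <- eliminate_bound(Seq, sp, keq = 1)
  expect_equal(unname(el1$gamma[["x2"]]), 1)
  # two-constraint chain: substitution satisfies the constraints on a grid
  Seq2 <- matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
                 dimnames = list(c("x1", "x2", "x3"), c("r1", "r2")))
  sp2 <- split_metabolites(Seq2)
  el2 <- eliminate_bound(Seq2, sp2, keq = c(2, 5))
  for (xf in c(0.1, 1, 7)) {
    lxb <- el2$f_matrix %*% log(xf) + log(el2$gamma)
    lx <- c(x1 = log(xf), lxb[, 1])
    resid <- t(Seq2) %*% lx[rownames(Seq2)] - log(c(2, 5))
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("model reduction reproduces the worked pooled chain", {
  # reaction 2 equilibrated with keq = 1 and g3,2 = 1: alpha3_bar = alpha3 / 2
  fx <- make_unbranched_pathway(3, theta = c(0, 0.999, 0, 0), keq = c(1, 1, 1, 1),
                                kinetic_parts = list(v3 = c(X2 = 1)))
  m <- build_model(fx$network)
  rr <- reduce_model(m, 0.99)
  expect_equal(rr$reduced$rates$v3$alpha, m$rates$v3$alpha / 2, tolerance = 1e-12)
  expect_equal(rownames(rr$reduction$c), c("pool_X1_X2", "X3"))
  expect_lt(max(abs(rr$reduction$c %*% rr$reduction$seq)), 1e-12)
  # rank condition
  expect_equal(nrow(rr$reduction$c) + qr(rr$reduction$seq)$rank,
               length(m$dependent_ids))
  # threshold excluding every reaction: reduction is the identity
  rr0 <- reduce_model(m, 0.9999)
  expect_identical(rr0$reduced, m)
  # steady-state pools of the full model converge to the reduced model
  fam <- theta_family()
  red <- reduce_model(fam(0.999), 0.99)$reduced
  pr <- steady_state(red)[[grep("pool", red$dependent_ids, value = TRUE)]]
  errs <- vapply(c(0.9, 0.99, 0.999), function(th) {
    x <- steady_state(fam(th))
    abs((x[["X1"]] + x[["X2"]]) - pr)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("steady-state pathway flux is preserved by the reduction", {
  fam <- theta_family()
  red <- reduce_model(fam(0.999), 0.99)$reduced
  xr <- steady_state(red)
  vr <- evaluate_rates(red, c(xr, pathforge:::independent_reference(red)))
  for (th in c(0.9, 0.99, 0.999)) {
    m <- fam(th)
    x <- steady_state(m)
    v <- evaluate_rates(m, c(x, pathforge:::independent_reference(m)))
    expect_equal(unname(v[["v4"]]), unname(vr[["v4"]]), tolerance = 1e-6)
  }
})

test_that("limit_check tabulates convergence of systemic properties", {
  fam <- theta_family()
  red <- reduce_model(fam(0.999), 0.99)$reduced
  grid <- c(0.9, 0.99, 0.999)
  # end-product steady state
  t1 <- limit_check(fam, function(m) steady_state(m)[["X3"]], grid, red)
  expect_true(all(t1$abs_error < 1e-9))   # preserved exactly by construction
  # log gain toward the supply
  t2 <- limit_check(fam, function(m) log_gains(m, "X0")[["x_X3"]], grid, red)
  expect_true(attr(t2, "monotone"))
  expect_lt(t2$abs_error[3], 1e-9)
  # sensitivity to the equilibrated enzyme converges to zero
  t3 <- limit_check(fam, function(m) {
    if ("v2" %in% m$reaction_ids) parameter_sensitivities(m, "v2")[["x_X1"]] else 0
  }, grid, 0)
  expect_true(attr(t3, "monotone"))
  expect_lt(t3$abs_error[3], 2e-3)
})

test_that("shortening inflates the stability margin to infinity", {
  fam <- theta_family(feedback = -0.5)
  full <- fam(0.99)
  red <- reduce_model(full, 0.99)$reduced
  m_full <- feedback_stability_margin(full, "v1", "X3")
  expect_true(is.finite(m_full))
  expect_identical(feedback_stability_margin(red, "v1", "X3"), Inf)
})

test_that("pooled trajectories of full and reduced models agree near equilibrium", {
  fam <- theta_family()
  full <- fam(0.999)
  red <- reduce_model(full, 0.99)$reduced
  pid <- grep("pool", red$dependent_ids, value = TRUE)
  x0 <- steady_state(full) * c(1.3, 1.3, 0.8)
  tg <- seq(0, 20, 1)
  tr_f <- simulate_model(full, x0, tg, rtol = 1e-6)
  tr_r <- simulate_model(red, stats::setNames(c(x0[["X1"]] + x0[["X2"]], x0[["X3"]]),
                                              c(pid, "X3")), tg)
  p_f <- tr_f$X1 + tr_f$X2
  rel <- abs(p_f - tr_r[[pid]]) / tr_r[[pid]]
  expect_lt(max(rel[tg > 1]), 0.01)
})
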
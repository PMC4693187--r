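# Independent oracles used across the suite. These deliberately avoid the
# code paths they validate: the LP oracle enumerates polytope vertices, the
# MDF oracle does a grid search, and the margin oracle detects divergence in
# simulated trajectories.

# Brute-force LP oracle: maximize obj over {S v = 0, lb <= v <= ub} by
# enumerating basic solutions (every choice of n - rank(S) active bounds).
oracle_lp_vertex <- function(S, lb, ub, obj) {
  n <- ncol(S)
  r <- qr(S)$rank
  nf <- n - r
  best <- -Inf
  best_v <- NULL
  fix_sets <- if (nf == 0) list(integer(0)) else
    utils::combn(n, nf, simplify = FALSE)
  for (fx in fix_sets) {
    sides <- expand.grid(rep(list(c(1, 2)), length(fx)))
    if (nrow(sides) == 0) sides <- data.frame(row.names = 1)
    for (si in seq_len(nrow(sides))) {
      v <- rep(NA_real_, n)
      okfix <- TRUE
      for (i in seq_along(fx)) {
        b <- if (sides[si, i] == 1) lb[fx[i]] else ub[fx[i]]
        if (!is.finite(b)) { okfix <- FALSE; break }
        v[fx[i]] <- b
      }
      if (!okfix) next
      free <- setdiff(seq_len(n), fx)
      if (length(free) > 0) {
        A <- S[, free, drop = FALSE]
        rhs <- if (length(fx) > 0) -S[, fx, drop = FALSE] %*% v[fx] else matrix(0, nrow(S), 1)
        sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        res <- A %*% sol - rhs
        if (max(abs(res)) > 1e-8) next
        v[free] <- sol
      }
      if (anyNA(v) || any(!is.finite(v))) next
      if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
      val <- sum(obj * v)
      if (val > best + 1e-12) { best <- val; best_v <- v }
    }
  }
  list(value = best, v = best_v)
}

# random bounded flux network with <= 6 reactions (chain plus random branches)
random_flux_network <- function(seed) {
  set.seed(seed)
  n_met <- sample(1:3, 1)
  mids <- paste0("M", seq_len(n_met))
  mets <- lapply(mids, metabolite)
  rxns <- list()
  # uptake into M1, demand out of each metabolite, random interconversions
  rxns[[1]] <- reaction("up", stats::setNames(1, "M1"), 0, round(runif(1, 1, 10), 1))
  k <- 2L
  for (i in seq_len(n_met)) {
    rxns[[k]] <- reaction(paste0("out", i), stats::setNames(-1, mids[i]), 0,
                          round(runif(1, 1, 10), 1))
    k <- k + 1L
  }
  n_extra <- min(6 - length(rxns), sample(0:2, 1))
  for (e in seq_len(n_extra)) {
    if (n_met < 2) break
    ij <- sample(n_met, 2)
    rxns[[k]] <- reaction(paste0("c", e),
                          stats::setNames(c(-1, 1), mids[ij]),
                          round(-runif(1, 0, 2), 1), round(runif(1, 1, 5), 1))
    k <- k + 1L
  }
  metabolic_network(mets, rxns, objective_id = "out1", uptake_id = "up")
}

# grid-search oracle for the max-min driving force over the free metabolites
oracle_mdf_grid <- function(thermo, net, directions, free_ids, n_grid = 60) {
  mids <- pathforge:::metabolite_ids(net)
  bx <- pathforge:::tfa_boxes(thermo, net)
  grids <- lapply(free_ids, function(id) seq(bx$lb[[id]], bx$ub[[id]], length.out = n_grid))
  names(grids) <- free_ids
  combos <- expand.grid(grids)
  y0 <- (bx$lb + bx$ub) / 2
  clamped <- setdiff(mids, free_ids)
  y0[clamped] <- bx$lb[clamped]  # clamped: lb == ub
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    y <- y0
    y[free_ids] <- as.numeric(combos[i, ])
    g <- reaction_gibbs(thermo, net, y)
    vals <- vapply(names(directions), function(rid) {
      if (directions[[rid]] == "forward") g[[rid]]
      else if (directions[[rid]] == "reverse") -g[[rid]] else NA_real_
    }, numeric(1))
    B <- max(vals, na.rm = TRUE)
    if (B < best) best <- B
  }
  best
}

# simulation-based stability-margin oracle: smallest feedback magnitude whose
# small perturbation fails to decay
oracle_margin_sim <- function(model, reaction_id, metabolite_id,
                              lo = 0, hi = 512, tol = 1e-4) {
  # compare the oscillation envelope over two late windows: growth between
  # them flags instability (robust to oscillatory transients near the margin)
  diverges <- function(m) {
    m2 <- pathforge:::set_feedback_magnitude(model, reaction_id, metabolite_id, m)
    xs <- steady_state(m2)
    x0 <- xs * (1 + 1e-3)
    tg <- seq(0, 200, length.out = 201)
    tr <- simulate_model(m2, x0, tg, rtol = 1e-9, atol = 1e-12)
    dev <- abs(as.matrix(tr[, -1]) - matrix(xs, nrow(tr), length(xs), byrow = TRUE)) /
      matrix(xs, nrow(tr), length(xs), byrow = TRUE)
    env <- apply(dev, 1, max)
    w1 <- max(env[tg >= 50 & tg <= 100])
    w2 <- max(env[tg >= 150 & tg <= 200])
    w2 > w1
  }
  if (diverges(lo + 1e-9)) stop("unstable at zero feedback")
  while (!diverges(hi)) {
    lo <- hi; hi <- 2 * hi
    if (hi > 1e5) return(Inf)
  }
  while ((hi - lo) > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (diverges(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# reversible uni-uni Michaelis-Menten rate with Haldane-consistent parameters
make_rev_mm <- function(vf, ks, kp, keq) {
  vr <- vf * kp / (ks * keq)
  function(x) {
    s <- x[1]; p <- x[2]
    (vf * s / ks - vr * p / kp) / (1 + s / ks + p / kp)
  }
}

# canonical 3-step pathway fixtures
fixture_symmetric <- function(feedback = -0.5) {
  make_unbranched_pathway(3, feedback_order = feedback)
}
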
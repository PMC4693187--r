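# Thermodynamic shortening: reactions operating close to equilibrium are
# removed from the dynamics by pooling the metabolites they connect. The
# pooling matrix C is an integer basis of the left null space of the
# near-equilibrium stoichiometric block Seq, so pool dynamics reduce to
# pdot = C * Sirr * virr; bound metabolites are eliminated through the
# equilibrium constraints log(xb) = F log(xf) + log(gamma).

#' Partition reactions by proximity to equilibrium
#'
#' @param model A `power_law_model` (each rate carries its theta).
#' @param theta_threshold Reactions with `theta >= theta_threshold` are
#'   treated as equilibrated; must lie in `[0, 1)`.
#' @return List with `eq_ids` and `irr_ids`.
#' @export
partition_reactions <- function(model, theta_threshold) {
  if (!(theta_threshold >= 0 && theta_threshold < 1)) stop_pf("theta_threshold must lie in [0, 1)")
  th <- vapply(model$rates, `[[`, numeric(1), "theta")
  eq <- names(th)[th >= theta_threshold]
  list(eq_ids = eq, irr_ids = setdiff(model$reaction_ids, eq))
}

# reduced row echelon form over doubles with rationalization-friendly pivots
rref <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  m <- nrow(M); n <- ncol(M)
  piv_cols <- integer(0)
  r <- 1L
  for (cidx in seq_len(n)) {
    if (r > m) break
    p <- which.max(abs(M[r:m, cidx])) + r - 1L
    if (abs(M[p, cidx]) < tol) next
    if (p != r) M[c(p, r), ] <- M[c(r, p), ]
    M[r, ] <- M[r, ] / M[r, cidx]
    for (k in seq_len(m)) if (k != r && abs(M[k, cidx]) > 0) {
      M[k, ] <- M[k, ] - M[k, cidx] * M[r, ]
    }
    piv_cols <- c(piv_cols, cidx)
    r <- r + 1L
  }
  list(M = M, piv_cols = piv_cols, rank = length(piv_cols))
}

# smallest-integer scaling of a rational-valued vector
to_smallest_integers <- function(v, max_den = 10000L, tol = 1e-8) {
  den <- 1L
  for (x in v) {
    if (abs(x - round(x)) < tol) next
    found <- FALSE
    for (d in 2:max_den) {
      if (abs(x * d - round(x * d)) < tol * d) { den <- den * d / gcd_int(den, d); found <- TRUE; break }
    }
    if (!found) stop_pf("cannot rationalize null-space entry %.12g", x)
  }
  iv <- round(v * den)
  g <- Reduce(gcd_int, abs(iv[iv != 0]))
  if (is.null(g) || g == 0) return(iv)
  iv <- iv / g
  i1 <- which(iv != 0)[1]
  if (!is.na(i1) && iv[i1] < 0) iv <- -iv
  iv
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Integer pooling matrix from the left null space of Seq
#'
#' Rows are normalized to smallest positive integers and ordered
#' lexicographically by support, so pools read as literal metabolite sums.
#'
#' @param seq Stoichiometric submatrix of the near-equilibrium reactions
#'   (dependent metabolites x eq reactions; dimnames used for pool names).
#' @return Integer matrix C (pools x metabolites) with `C %*% seq = 0`.
#' @export
pool_matrix <- function(seq) {
  seq <- as.matrix(seq)
  n_met <- nrow(seq)
  mids <- rownames(seq) %||% paste0("m", seq_len(n_met))
  if (ncol(seq) == 0L) {
    C <- diag(n_met)
    dimnames(C) <- list(mids, mids)
    return(C)
  }
  rr <- rref(t(seq))  # null space of t(seq) = left null space of seq
  free_cols <- setdiff(seq_len(n_met), rr$piv_cols)
  if (length(free_cols) == 0L) stop_pf("left null space of seq is zero-dimensional: no pools possible")
  basis <- lapply(free_cols, function(fc) {
    v <- numeric(n_met)
    v[fc] <- 1
    for (i in seq_along(rr$piv_cols)) v[rr$piv_cols[i]] <- -rr$M[i, fc]
    to_smallest_integers(v)
  })
  C <- do.call(rbind, basis)
  if (any(C < 0)) stop_pf("pooling matrix has negative entries; pools must be sums of concentrations")
  ord <- order(apply(C, 1, function(r) {
    s <- which(r != 0)
    sum(2^(n_met - s))  # lexicographic by support position
  }), decreasing = TRUE)
  C <- C[ord, , drop = FALSE]
  colnames(C) <- mids
  rownames(C) <- apply(C, 1, function(r) {
    s <- which(r != 0)
    if (length(s) == 1L && r[s] == 1) mids[s] else paste0("pool_", paste(mids[s], collapse = "_"))
  })
  C
}

#' Split metabolites into free and bound sets
#'
#' The bound set has as many members as equilibrium constraints and is chosen
#' by reverse declaration order (later pathway members bound first), greedily
#' keeping the bound block invertible.
#'
#' @param seq Near-equilibrium stoichiometric submatrix (metabolites x
#'   reactions) with row names.
#' @return List with `free_ids` and `bound_ids`.
#' @export
split_metabolites <- function(seq) {
  seq <- as.matrix(seq)
  mids <- rownames(seq) %||% paste0("m", seq_len(nrow(seq)))
  n_eq <- ncol(seq)
  if (n_eq == 0L) return(list(free_ids = mids, bound_ids = character(0)))
  if (qr(seq)$rank < n_eq) stop_pf("equilibrium constraints are not independent (seq lacks full column rank)")
  Tt <- t(seq)  # n_eq x n_met
  bound <- integer(0)
  for (j in rev(seq_len(nrow(seq)))) {
    cand <- c(bound, j)
    if (qr(Tt[, cand, drop = FALSE])$rank == length(cand)) bound <- cand
    if (length(bound) == n_eq) break
  }
  if (length(bound) < n_eq) stop_pf("no invertible bound split exists")
  bound <- sort(bound)
  list(free_ids = mids[setdiff(seq_len(nrow(seq)), bound)], bound_ids = mids[bound])
}

#' Eliminate bound metabolites through the equilibrium constraints
#'
#' Solves `log(keq) = Seq^T log(x)` for the bound block:
#' `log(xb) = F log(xf) + log(gamma)` with `F = -(Seq_b^T)^{-1} Seq_f^T` and
#' `log(gamma) = (Seq_b^T)^{-1} log(keq)`.
#'
#' @param seq Near-equilibrium stoichiometric submatrix with row names.
#' @param split Output of [split_metabolites()].
#' @param keq Equilibrium constants of the eq reactions (column order of
#'   `seq`).
#' @return List with `gamma` (named over bound metabolites) and `f_matrix`
#'   (bound x free).
#' @export
eliminate_bound <- function(seq, split, keq) {
  seq <- as.matrix(seq)
  Sb <- seq[split$bound_ids, , drop = FALSE]
  Sf <- seq[split$free_ids, , drop = FALSE]
  SbT <- t(Sb)
  if (abs(det(SbT)) < 1e-12) stop_pf("bound block is singular")
  inv <- solve(SbT)
  Fm <- -inv %*% t(Sf)
  lg <- inv %*% log(as.numeric(keq))
  gamma <- stats::setNames(exp(as.numeric(lg)), split$bound_ids)
  dimnames(Fm) <- list(split$bound_ids, split$free_ids)
  list(gamma = gamma, f_matrix = Fm)
}

#' Thermodynamic shortening of a power-law model
#'
#' Pools metabolites connected by near-equilibrium reactions and emits the
#' reduced power-law model over pools. Every metabolite j inside a nontrivial
#' pool is re-expressed through its equilibrium share,
#' `x_j = (gamma_j / W) p` with `W = sum_k c_k gamma_k` (for the two-member
#' pool this is the `(Keq/(1+Keq))^g` construction). The re-expression is a
#' power law only when each bound metabolite depends on its pool's free
#' metabolite with exponent 1; other cases raise an error.
#'
#' @param model A `power_law_model`.
#' @param theta_threshold Near-equilibrium cutoff (default 0.99).
#' @return List with `reduction` (a `pool_reduction`) and `reduced` (the
#'   reduced `power_law_model`). With an empty equilibrium set the reduced
#'   model is the input model.
#' @export
reduce_model <- function(model, theta_threshold = 0.99) {
  part <- partition_reactions(model, theta_threshold)
  dep <- model$dependent_ids
  S <- model$stoich
  Seq <- S[, part$eq_ids, drop = FALSE]
  Sirr <- S[, part$irr_ids, drop = FALSE]
  if (length(part$eq_ids) == 0L) {
    red <- structure(list(eq_reaction_ids = character(0), irr_reaction_ids = part$irr_ids,
                          seq = Seq, sirr = Sirr, c = diag(length(dep)),
                          free_ids = dep, bound_ids = character(0),
                          f_matrix = NULL, gamma = NULL, reduced = model),
                     class = "pool_reduction")
    return(list(reduction = red, reduced = model))
  }
  C <- pool_matrix(Seq)
  split <- split_metabolites(Seq)
  keq_eq <- vapply(part$eq_ids, function(rid) model$rates[[rid]]$keq, numeric(1))
  el <- eliminate_bound(Seq, split, keq_eq)

  # per-metabolite equilibrium multiplier gamma (1 for free), pool membership
  gamma_all <- stats::setNames(rep(1, length(dep)), dep)
  gamma_all[names(el$gamma)] <- el$gamma
  # verify power-law representability: each bound metabolite must load on
  # exactly one free metabolite with exponent 1
  for (b in split$bound_ids) {
    row <- el$f_matrix[b, , drop = TRUE]
    nz <- which(abs(row) > 1e-12)
    if (length(nz) != 1L || abs(row[nz] - 1) > 1e-12) {
      stop_pf("bound metabolite '%s' has non-unit equilibrium exponents; pool is not a power law", b)
    }
  }
  pool_of <- stats::setNames(rep(NA_character_, length(dep)), dep)
  for (pid in rownames(C)) {
    sup <- colnames(C)[C[pid, ] != 0]
    pool_of[sup] <- pid
  }
  if (anyNA(pool_of)) stop_pf("metabolite(s) not covered by any pool: %s",
                              paste(dep[is.na(pool_of)], collapse = ", "))
  W <- stats::setNames(vapply(rownames(C), function(pid) {
    sup <- colnames(C)[C[pid, ] != 0]
    sum(C[pid, sup] * gamma_all[sup])
  }, numeric(1)), rownames(C))

  # reduced rates over pools
  pool_ids <- rownames(C)
  red_stoich <- C %*% Sirr
  rates <- list()
  for (rid in part$irr_ids) {
    r <- model$rates[[rid]]
    orders <- stats::setNames(numeric(0), character(0))
    kparts <- stats::setNames(numeric(0), character(0))
    lalpha <- log_alpha_of(r)
    for (j in names(r$orders)) {
      gj <- r$orders[[j]]
      if (j %in% dep) {
        pid <- pool_of[[j]]
        # equilibrium share: x_j = (gamma_j / W) * p
        share <- gamma_all[[j]] / W[[pid]]
        lalpha <- lalpha + gj * log(share)
        orders[pid] <- gv(orders, pid) + gj
        kparts[pid] <- gv(kparts, pid) + gv(r$kinetic_parts, j)
      } else {
        orders[j] <- gj
        kparts[j] <- gv(r$kinetic_parts, j)
      }
    }
    rates[[rid]] <- list(alpha = exp(lalpha), log_alpha = lalpha,
                         orders = orders, kinetic_parts = kparts,
                         theta = r$theta, keq = r$keq)
  }

  # reference over pools: project the reference onto the equilibrium manifold
  x0 <- model$reference$concentrations
  p0 <- stats::setNames(as.numeric(C %*% x0[dep]), pool_ids)
  iv <- x0[model$independent_ids]
  reduced <- structure(list(
    dependent_ids = pool_ids,
    independent_ids = model$independent_ids,
    reaction_ids = part$irr_ids,
    rates = rates,
    stoich = red_stoich,
    reference = NULL
  ), class = "power_law_model")
  v0 <- evaluate_rates(reduced, c(p0, iv))
  reduced$reference <- reference_state(fluxes = v0, concentrations = c(p0, iv),
                                       theta = vapply(rates, `[[`, numeric(1), "theta"),
                                       keq = vapply(rates, `[[`, numeric(1), "keq"))

  reduction <- structure(list(
    eq_reaction_ids = part$eq_ids, irr_reaction_ids = part$irr_ids,
    seq = Seq, sirr = Sirr, c = C,
    free_ids = split$free_ids, bound_ids = split$bound_ids,
    f_matrix = el$f_matrix, gamma = el$gamma, reduced = reduced
  ), class = "pool_reduction")
  list(reduction = reduction, reduced = reduced)
}

#' @export
print.pool_reduction <- function(x, ...) {
  cat(sprintf("pool_reduction: %d eq / %d irr reactions, pools: %s\n",
              length(x$eq_reaction_ids), length(x$irr_reaction_ids),
              paste(rownames(x$c), collapse = ", ")))
  invisible(x)
}

#' Convergence of a systemic property toward its shortened-model value
#'
#' Evaluates `property_fn` on the full model produced by `model_family(theta)`
#' for every grid value and on `reduced_model`, tabulating the absolute error
#' `|S(theta) - S_bar|`.
#'
#' @param model_family Function theta -> `power_law_model`.
#' @param property_fn Function `power_law_model` -> numeric scalar.
#' @param theta_grid Increasing theta values approaching 1.
#' @param reduced_model The shortened model (or a fixed target value).
#' @return data.frame with `theta`, `value`, `reduced_value`, `abs_error` and
#'   an attribute `monotone` flagging monotone non-increasing error.
#' @export
limit_check <- function(model_family, property_fn, theta_grid, reduced_model) {
  sbar <- if (inherits(reduced_model, "power_law_model")) property_fn(reduced_model) else as.numeric(reduced_model)
  vals <- vapply(theta_grid, function(th) property_fn(model_family(th)), numeric(1))
  err <- abs(vals - sbar)
  out <- data.frame(theta = theta_grid, value = vals, reduced_value = sbar, abs_error = err)
  attr(out, "monotone") <- all(diff(err) <= 1e-12 + 1e-6 * err[-length(err)])
  out
}
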
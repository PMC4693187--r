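# Dense two-phase simplex for the small LPs arising in flux balance and
# thermodynamic feasibility problems. No LP backend is assumed; problem sizes
# here are tens of variables at most, so a textbook tableau with Bland's rule
# is adequate and fully deterministic.

#' Solve a small dense linear program
#'
#' Minimizes or maximizes `objective %*% x` subject to `A_eq x = b_eq`,
#' `A_le x <= b_le` and box bounds `lb <= x <= ub` (entries may be infinite).
#'
#' @param objective Numeric objective coefficient vector.
#' @param direction `"max"` or `"min"`.
#' @param A_eq,b_eq Equality constraints (matrix / vector, or NULL).
#' @param A_le,b_le Inequality (<=) constraints (matrix / vector, or NULL).
#' @param lb,ub Box bounds, recycled to the number of variables.
#' @param tol Feasibility/pivot tolerance.
#' @return List with `status` ("optimal", "infeasible", "unbounded"),
#'   `x` (solution vector, NA unless optimal) and `objective_value`.
#' @export
lp_solve <- function(objective, direction = c("max", "min"),
                     A_eq = NULL, b_eq = NULL,
                     A_le = NULL, b_le = NULL,
                     lb = -Inf, ub = Inf, tol = 1e-9) {
  direction <- match.arg(direction)
  n <- length(objective)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  if (any(lb > ub)) return(list(status = "infeasible", x = rep(NA_real_, n), objective_value = NA_real_))
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric(0) }
  if (is.null(A_le)) { A_le <- matrix(0, 0, n); b_le <- numeric(0) }
  A_eq <- matrix(as.numeric(A_eq), ncol = n); b_eq <- as.numeric(b_eq)
  A_le <- matrix(as.numeric(A_le), ncol = n); b_le <- as.numeric(b_le)

  cvec <- if (direction == "max") -objective else objective

  # Variable substitution to z >= 0:
  #   finite lb:            x = lb + z
  #   lb=-Inf, finite ub:   x = ub - z
  #   both infinite:        x = z+ - z-
  # map: each original var -> list(cols, signs, shift)
  cols <- list(); shift <- numeric(n)
  zsign <- list()
  next_col <- 0L
  extra_ub <- list()  # rows z_col <= val
  for (i in seq_len(n)) {
    if (is.finite(lb[i])) {
      next_col <- next_col + 1L
      cols[[i]] <- next_col; zsign[[i]] <- 1; shift[i] <- lb[i]
      if (is.finite(ub[i])) extra_ub[[length(extra_ub) + 1L]] <- c(next_col, ub[i] - lb[i])
    } else if (is.finite(ub[i])) {
      next_col <- next_col + 1L
      cols[[i]] <- next_col; zsign[[i]] <- -1; shift[i] <- ub[i]
    } else {
      cols[[i]] <- c(next_col + 1L, next_col + 2L); zsign[[i]] <- c(1, -1); shift[i] <- 0
      next_col <- next_col + 2L
    }
  }
  nz <- next_col

  expand_row <- function(row) {
    out <- numeric(nz)
    for (i in seq_len(n)) out[cols[[i]]] <- out[cols[[i]]] + row[i] * zsign[[i]]
    out
  }

  rows <- list(); rhs <- numeric(0); type <- character(0)
  for (k in seq_len(nrow(A_eq))) {
    rows[[length(rows) + 1L]] <- expand_row(A_eq[k, ])
    rhs <- c(rhs, b_eq[k] - sum(A_eq[k, ] * shift)); type <- c(type, "eq")
  }
  for (k in seq_len(nrow(A_le))) {
    rows[[length(rows) + 1L]] <- expand_row(A_le[k, ])
    rhs <- c(rhs, b_le[k] - sum(A_le[k, ] * shift)); type <- c(type, "le")
  }
  for (e in extra_ub) {
    r <- numeric(nz); r[e[1]] <- 1
    rows[[length(rows) + 1L]] <- r; rhs <- c(rhs, e[2]); type <- c(type, "le")
  }
  m <- length(rows)
  cz <- numeric(nz)
  for (i in seq_len(n)) cz[cols[[i]]] <- cz[cols[[i]]] + cvec[i] * zsign[[i]]
  const_term <- sum(cvec * shift)

  if (m == 0L) {
    # unconstrained over z >= 0
    if (any(cz < -tol)) {
      return(list(status = "unbounded", x = rep(NA_real_, n), objective_value = if (direction == "max") Inf else -Inf))
    }
    z <- numeric(nz)
    x <- vapply(seq_len(n), function(i) shift[i] + sum(zsign[[i]] * z[cols[[i]]]), numeric(1))
    obj <- sum(objective * x)
    return(list(status = "optimal", x = x, objective_value = obj))
  }

  A <- do.call(rbind, rows)
  b <- rhs
  # slacks for <= rows
  n_sl <- sum(type == "le")
  S <- matrix(0, m, n_sl)
  j <- 0L
  slack_col_of_row <- rep(NA_integer_, m)
  for (k in seq_len(m)) if (type[k] == "le") { j <- j + 1L; S[k, j] <- 1; slack_col_of_row[k] <- nz + j }
  A <- cbind(A, S)
  ctot <- c(cz, rep(0, n_sl))
  # normalize rhs >= 0
  for (k in seq_len(m)) if (b[k] < 0) { A[k, ] <- -A[k, ]; b[k] <- -b[k] }
  ntot <- ncol(A)
  # initial basis: usable slack (+1 after sign flip) else artificial
  basis <- rep(NA_integer_, m)
  art_cols <- integer(0)
  for (k in seq_len(m)) {
    sc <- slack_col_of_row[k]
    if (!is.na(sc) && A[k, sc] > 0.5) basis[k] <- sc
  }
  for (k in seq_len(m)) if (is.na(basis[k])) {
    A <- cbind(A, as.numeric(seq_len(m) == k))
    art_cols <- c(art_cols, ncol(A))
    basis[k] <- ncol(A)
  }
  n_all <- ncol(A)

  run_simplex <- function(A, b, cost, basis, tol) {
    m <- nrow(A); n_all <- ncol(A)
    # canonicalize cost row
    red <- cost - as.numeric(matrix(cost[basis], 1) %*% A)
    obj <- -sum(cost[basis] * b)
    it <- 0L; itmax <- 20000L
    repeat {
      it <- it + 1L
      if (it > itmax) stop_pf("simplex iteration limit reached")
      enter <- which(red < -tol)
      if (length(enter) == 0L) return(list(status = "optimal", A = A, b = b, basis = basis, red = red))
      e <- enter[1L]  # Bland
      col <- A[, e]
      pos <- which(col > tol)
      if (length(pos) == 0L) return(list(status = "unbounded", A = A, b = b, basis = basis, red = red))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      l <- cand[which.min(basis[cand])]  # Bland tie-break
      piv <- A[l, e]
      A[l, ] <- A[l, ] / piv; b[l] <- b[l] / piv
      for (k in seq_len(m)) if (k != l && abs(A[k, e]) > 0) {
        f <- A[k, e]; A[k, ] <- A[k, ] - f * A[l, ]; b[k] <- b[k] - f * b[l]
      }
      f <- red[e]; red <- red - f * A[l, ]
      basis[l] <- e
    }
  }

  # Phase 1
  if (length(art_cols) > 0L) {
    c1 <- rep(0, n_all); c1[art_cols] <- 1
    r1 <- run_simplex(A, b, c1, basis, tol)
    if (r1$status != "optimal") stop_pf("phase-1 simplex failed")
    A <- r1$A; b <- r1$b; basis <- r1$basis
    if (sum(b[basis %in% art_cols]) > 1e-7) {
      return(list(status = "infeasible", x = rep(NA_real_, n), objective_value = NA_real_))
    }
    # drive remaining artificials out of the basis
    for (k in seq_len(nrow(A))) {
      if (basis[k] %in% art_cols) {
        nonart <- setdiff(seq_len(ntot), integer(0))
        piv_candidates <- which(abs(A[k, seq_len(ntot)]) > tol)
        if (length(piv_candidates) > 0L) {
          e <- piv_candidates[1L]
          piv <- A[k, e]
          A[k, ] <- A[k, ] / piv; b[k] <- b[k] / piv
          for (kk in seq_len(nrow(A))) if (kk != k && abs(A[kk, e]) > 0) {
            f <- A[kk, e]; A[kk, ] <- A[kk, ] - f * A[k, ]; b[kk] <- b[kk] - f * b[k]
          }
          basis[k] <- e
        }
        # else: redundant row, keep artificial basic at zero (harmless)
      }
    }
    # drop artificial columns from pricing by fixing their cost high? simpler:
    # forbid re-entering by zeroing their columns
    A[, art_cols] <- 0
  }

  c2 <- c(ctot, rep(0, n_all - ntot))
  r2 <- run_simplex(A, b, c2, basis, tol)
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective_value = if (direction == "max") Inf else -Inf))
  }
  z <- numeric(n_all)
  z[r2$basis] <- r2$b
  zv <- z[seq_len(nz)]
  x <- vapply(seq_len(n), function(i) shift[i] + sum(zsign[[i]] * zv[cols[[i]]]), numeric(1))
  list(status = "optimal", x = x, objective_value = sum(objective * x))
}
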
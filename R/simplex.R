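# Dense two-phase primal simplex with Bland's rule.
#
# This is the package's default LP backend. RBA problems at desk scale are
# tiny (tens of rows/columns) but are solved tens of thousands of times
# during bisection, screens and ensembles, and the solver contract needs
# explicit infeasible/unbounded statuses plus row duals. The implementation
# follows the textbook tableau method: variables with finite lower bounds
# are shifted, free variables are split into positive and negative parts,
# finite upper bounds become extra rows; phase 1 minimizes the sum of
# artificial variables, phase 2 the actual objective. Bland's least-index
# rule guarantees termination on degenerate problems.
#
# Interface (internal): simplex_solve(A, relations, b, lower, upper,
# objective, sense) -> list(status, x, value, duals, iterations) where
# status is one of "optimal", "infeasible", "unbounded",
# "tolerance_failure". x and duals are in the caller's original space.

SIMPLEX_PIVOT_TOL <- 1e-9
SIMPLEX_FEAS_TOL <- 1e-9 # phase-1 residual per equilibrated row
SIMPLEX_MAX_ITER <- 20000L

simplex_solve <- function(A, relations, b, lower, upper, objective,
                          sense = c("min", "max")) {
  sense <- match.arg(sense)
  m0 <- nrow(A); n0 <- ncol(A)
  stopifnot(length(relations) == m0, length(b) == m0,
            length(lower) == n0, length(upper) == n0,
            length(objective) == n0)

  # ---- reduce to: optimize c'x, Ax rel b, x >= 0 --------------------------
  shift <- ifelse(is.finite(lower), lower, 0)
  const_obj <- sum(objective * shift)
  b <- b - as.numeric(A %*% shift)
  upper_sh <- upper - shift

  free <- !is.finite(lower)
  # columns: originals (shifted), then negative parts of free variables
  Afull <- cbind(A, -A[, free, drop = FALSE])
  cfull <- c(objective, -objective[free])
  neg_of <- which(free)

  # finite upper bounds become rows x_j <= u_j
  ub_rows <- which(is.finite(upper_sh))
  if (length(ub_rows)) {
    extra <- matrix(0, length(ub_rows), ncol(Afull))
    for (i in seq_along(ub_rows)) extra[i, ub_rows[i]] <- 1
    Afull <- rbind(Afull, extra)
    relations <- c(relations, rep("<=", length(ub_rows)))
    b <- c(b, upper_sh[ub_rows])
  }

  cmin <- if (sense == "max") -cfull else cfull
  res <- simplex_core(Afull, relations, b, cmin)

  if (res$status %in% c("optimal")) {
    x <- res$x[seq_len(n0)]
    if (any(free)) x[neg_of] <- x[neg_of] - res$x[n0 + seq_along(neg_of)]
    x <- x + shift
    value <- sum(objective * x)
    duals <- res$duals[seq_len(m0)]
    if (sense == "max") duals <- -duals
    list(status = "optimal", x = x, value = value, duals = duals,
         iterations = res$iterations)
  } else {
    list(status = res$status, x = rep(NA_real_, n0), value = NA_real_,
         duals = rep(NA_real_, m0), iterations = res$iterations)
  }
}

# Core tableau method for: min c'x  s.t.  A x rel b, x >= 0.
simplex_core <- function(A, relations, b, cvec) {
  m <- nrow(A); n <- ncol(A)

  # row equilibration: models mix coefficients over many orders of magnitude
  # (dilution terms ~ mu * precursor costs vs. unit stoichiometries), which
  # would make absolute pivot/feasibility tolerances meaningless
  rscale <- pmax(apply(abs(A), 1L, max), abs(b), 1e-300)
  A <- A / rscale
  b <- b / rscale

  # normalize to b >= 0
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    relations[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[relations[flip]]
  }

  # slack (<=: +1, basic), surplus (>=: -1), artificials (>= and =)
  n_slack <- sum(relations == "<=")
  n_surp <- sum(relations == ">=")
  n_art <- sum(relations != "<=")
  ncols <- n + n_slack + n_surp + n_art
  T <- matrix(0, m, ncols + 1L)
  T[, seq_len(n)] <- A
  T[, ncols + 1L] <- b
  basis <- integer(m)
  slack_col <- integer(m); art_col <- integer(m) # unit column of each row
  js <- n; ja <- n + n_slack + n_surp
  for (i in seq_len(m)) {
    if (relations[i] == "<=") {
      js <- js + 1L; T[i, js] <- 1; basis[i] <- js; slack_col[i] <- js
    } else if (relations[i] == ">=") {
      js <- js + 1L; T[i, js] <- -1; slack_col[i] <- js
      ja <- ja + 1L; T[i, ja] <- 1; basis[i] <- ja; art_col[i] <- ja
    } else {
      ja <- ja + 1L; T[i, ja] <- 1; basis[i] <- ja; art_col[i] <- ja
    }
  }
  art_set <- art_col[art_col > 0L]
  A0 <- T[, seq_len(ncols), drop = FALSE] # pristine copy for the final solve
  b0 <- b
  total_iter <- 0L

  run_phase <- function(T, basis, cost, allowed) {
    # cost: vector over columns; allowed: logical, may enter basis
    iter <- 0L
    repeat {
      cb <- cost[basis]
      y <- crossprod(T[, seq_len(ncols), drop = FALSE], cb)  # cb' T
      red <- cost[seq_len(ncols)] - as.numeric(y)
      cand <- which(allowed & red < -SIMPLEX_PIVOT_TOL)
      if (length(cand) == 0L) {
        return(list(T = T, basis = basis, status = "optimal", iterations = iter))
      }
      q <- cand[1L]  # Bland: least index
      col <- T[, q]
      pos <- which(col > SIMPLEX_PIVOT_TOL)
      if (length(pos) == 0L) {
        return(list(T = T, basis = basis, status = "unbounded", iterations = iter))
      }
      ratio <- T[pos, ncols + 1L] / col[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + 1e-12 * (1 + rmin)]
      r <- tie[which.min(basis[tie])]  # Bland tie-break: least basis index
      # pivot on (r, q)
      T[r, ] <- T[r, ] / T[r, q]
      other <- setdiff(seq_len(m), r)
      T[other, ] <- T[other, ] - outer(T[other, q], T[r, ])
      basis[r] <- q
      iter <- iter + 1L
      if (iter > SIMPLEX_MAX_ITER) {
        return(list(T = T, basis = basis, status = "tolerance_failure",
                    iterations = iter))
      }
    }
  }

  allowed <- rep(TRUE, ncols)

  if (n_art > 0L) {
    cost1 <- numeric(ncols); cost1[art_set] <- 1
    ph1 <- run_phase(T, basis, cost1, allowed)
    total_iter <- total_iter + ph1$iterations
    if (ph1$status != "optimal") {
      return(list(status = if (ph1$status == "unbounded") "tolerance_failure"
                  else ph1$status,
                  x = NULL, duals = NULL, iterations = total_iter))
    }
    T <- ph1$T; basis <- ph1$basis
    if (sum(T[basis %in% art_set, ncols + 1L]) > SIMPLEX_FEAS_TOL ||
        sum(cost1[basis] * T[, ncols + 1L]) > SIMPLEX_FEAS_TOL) {
      return(list(status = "infeasible", x = NULL, duals = NULL,
                  iterations = total_iter))
    }
    # drive remaining artificials out of the basis where possible
    for (i in which(basis %in% art_set)) {
      row <- T[i, seq_len(ncols)]
      cand <- which(abs(row) > SIMPLEX_PIVOT_TOL & !(seq_len(ncols) %in% art_set))
      if (length(cand)) {
        q <- cand[1L]
        T[i, ] <- T[i, ] / T[i, q]
        other <- setdiff(seq_len(m), i)
        T[other, ] <- T[other, ] - outer(T[other, q], T[i, ])
        basis[i] <- q
      }
      # else: redundant row; its artificial stays basic at value 0
    }
    allowed[art_set] <- FALSE
  }

  cost2 <- c(cvec, numeric(ncols - n))
  ph2 <- run_phase(T, basis, cost2, allowed)
  total_iter <- total_iter + ph2$iterations
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = NULL, duals = NULL,
                iterations = total_iter))
  }
  T <- ph2$T; basis <- ph2$basis

  # recompute the basic solution and duals from the pristine basis matrix:
  # one clean solve instead of the tableau's accumulated pivot roundoff
  x <- numeric(ncols)
  B <- A0[, basis, drop = FALSE]
  xb <- tryCatch(solve(B, b0), error = function(e) NULL)
  if (is.null(xb) || any(xb < -SIMPLEX_FEAS_TOL * 10)) {
    xb <- T[, ncols + 1L] # singular/degenerate fallback: tableau values
  }
  x[basis] <- xb
  duals <- tryCatch(as.numeric(solve(t(B), cost2[basis])),
                    error = function(e) rep(NA_real_, m))
  duals[flip] <- -duals[flip]
  duals <- duals / rscale # undo row equilibration
  list(status = "optimal", x = x[seq_len(n)], duals = duals,
       iterations = total_iter)
}
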
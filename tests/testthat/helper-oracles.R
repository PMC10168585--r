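# Closed-form optima of the toy models, used as independent oracles.

mu_self_closed <- function(k_enzyme, k_process, n_enzyme = 1, n_process = 1) {
  1 / (n_enzyme / k_enzyme + n_process / k_process)
}

mu_pinned_closed <- function(k_enzyme, k_process, n_enzyme = 1, n_process = 1,
                             n_housekeeping = 1, c0 = 0.2, density = 1) {
  (1 - n_housekeeping * c0 / density) *
    mu_self_closed(k_enzyme, k_process, n_enzyme, n_process)
}

mu_mm_closed <- function(conc, vmax = 2, km = 0.1, k_process = 2, c0 = 0.2,
                         density = 1) {
  k_imp <- vmax * conc / (km + conc)
  if (k_imp == 0) return(0)
  (1 - c0 / density) / (1 / k_imp + 1 / k_process)
}

# Proteome cost per unit precursor in the overflow toy, and its mu_max.
mu_overflow_closed <- function(conc, vmax = 4, km = 1, yield_resp = 2,
                               k_resp = 1, yield_ferm = 1, k_ferm = 4,
                               k_process = 2, c0 = 0.2, density = 1) {
  kt <- vmax * conc / (km + conc)
  if (kt == 0) return(0)
  q <- min((1 / yield_resp) * (1 / kt + 1 / k_resp),
           (1 / yield_ferm) * (1 / kt + 1 / k_ferm))
  (1 - c0 / density) / (q + 1 / k_process)
}

# Dense-grid feasibility scan: the largest feasible mu on an n-point grid
# over [0, hi]. Independent of the bisection path.
grid_mu_max <- function(model, medium = rba_medium(), n = 400, hi = 2) {
  grid <- seq(0, hi, length.out = n)
  feas <- vapply(grid, function(mu) is_feasible(model, mu, medium), logical(1))
  if (!any(feas)) return(NA_real_)
  max(grid[feas])
}

# Feasibility prefix check: TRUE iff feasibility on the grid is monotone
# (feasible below some mu*, infeasible above).
feasibility_is_prefix <- function(model, medium = rba_medium(), n = 50,
                                  hi = 2) {
  grid <- seq(0, hi, length.out = n)
  feas <- vapply(grid, function(mu) is_feasible(model, mu, medium), logical(1))
  all(diff(feas) <= 0)
}

# Brute-force LP oracle by enumeration of basic solutions: every vertex of
# {x : Ax rel b, lower <= x <= upper} lies at the intersection of n active
# constraints (rows at equality or bounds). Enumerate all such square
# systems, keep feasible solutions, return the best objective value.
# Exponential, fine for the tiny problems it is used on; completely
# independent of the simplex implementation.
enumerate_lp_value <- function(problem) {
  d <- lp_to_dense(problem)
  n <- ncol(d$A)
  rows <- rbind(d$A, diag(n), diag(n))
  vals <- c(d$b, d$lower, d$upper)
  keep <- is.finite(vals)
  rows <- rows[keep, , drop = FALSE]
  vals <- vals[keep]
  best <- NA_real_
  better <- if (d$sense == "max") function(a, b) is.na(b) || a > b
            else function(a, b) is.na(b) || a < b
  feasible <- function(x) {
    lhs <- as.numeric(d$A %*% x)
    all(abs(lhs[d$relations == "="] - d$b[d$relations == "="]) < 1e-7,
        lhs[d$relations == "<="] <= d$b[d$relations == "<="] + 1e-7,
        lhs[d$relations == ">="] >= d$b[d$relations == ">="] - 1e-7,
        x >= d$lower - 1e-7, x <= d$upper + 1e-7)
  }
  for (combo in utils::combn(nrow(rows), n, simplify = FALSE)) {
    M <- rows[combo, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- solve(M, vals[combo])
    if (feasible(x)) {
      v <- sum(d$objective * x)
      if (better(v, best)) best <- v
    }
  }
  best
}

# All five toy generators under default parameters, with a medium saturating
# the external nutrient where import is medium-dependent.
toy_zoo <- function() {
  list(
    self_replicator = list(model = make_self_replicator(),
                           medium = rba_medium()),
    pinned_replicator = list(model = make_pinned_replicator(),
                             medium = rba_medium()),
    mm_importer = list(model = make_mm_importer(),
                       medium = rba_medium(c(nutrient_ext = 10))),
    overflow_branch = list(model = make_overflow_branch(),
                           medium = rba_medium(c(nutrient_ext = 10))),
    secretion = list(model = make_secretion(), medium = rba_medium())
  )
}
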
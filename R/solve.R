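#' Solve an assembled RBA linear program
#'
#' Runs the package's LP backend (a dense two-phase simplex) on a problem
#' built by [build_lp()] and maps the primal solution back onto reaction
#' fluxes and catalyst concentrations. Primal feasibility is re-checked
#' independently of the backend: any constraint violated by more than
#' `feas_tol` turns the status into `"tolerance_failure"`.
#'
#' @param problem an [build_lp()] result.
#' @param feas_tol feasibility tolerance of the independent re-check
#'   (default `1e-8`), applied to each row's residual scaled by the
#'   magnitude of the terms producing it (backward-error style), so rows of
#'   any magnitude are checked equally sharply.
#' @return An object of class `rba_solution` with fields `mu`, `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"` or `"tolerance_failure"`),
#'   `objective_value`, `fluxes`, `enzyme_concentrations`,
#'   `machine_concentrations`, `target_concentrations` and `duals` (named by
#'   constraint row). Use [tidy()][generics::tidy] / `glance()` for tabular
#'   views.
#' @export
solve_lp <- function(problem, feas_tol = 1e-8) {
  stopifnot(inherits(problem, "rba_lp"))
  d <- lp_to_dense(problem)
  res <- simplex_solve(d$A, d$relations, d$b, d$lower, d$upper,
                       d$objective, d$sense)
  status <- res$status
  x <- res$x
  if (status == "optimal") {
    viol <- constraint_violation(d, x)
    if (viol > feas_tol) status <- "tolerance_failure"
  }
  new_solution(problem, status, x, res$value, res$duals)
}

# Largest scaled (backward-error style) constraint violation: each row's
# residual is measured relative to the magnitude of the terms producing it,
# so the check is meaningful for rows of any scale.
constraint_violation <- function(dense, x) {
  lhs <- as.numeric(dense$A %*% x)
  v <- numeric(length(lhs))
  eq <- dense$relations == "="
  le <- dense$relations == "<="
  ge <- dense$relations == ">="
  v[eq] <- abs(lhs[eq] - dense$b[eq])
  v[le] <- pmax(0, lhs[le] - dense$b[le])
  v[ge] <- pmax(0, dense$b[ge] - lhs[ge])
  scale <- 1 + abs(dense$b) + as.numeric(abs(dense$A) %*% abs(x))
  vb <- pmax(0, dense$lower - x, x - dense$upper) / (1 + abs(x))
  max(0, v / scale, vb)
}

new_solution <- function(problem, status, x, value, duals) {
  vars <- problem$variables
  pick <- function(kind) {
    sel <- vars$kind == kind
    stats::setNames(x[sel], vars$id[sel])
  }
  structure(list(
    mu = problem$mu,
    status = status,
    objective_value = if (identical(status, "optimal")) value else NA_real_,
    fluxes = pick("flux"),
    enzyme_concentrations = pick("enzyme"),
    machine_concentrations = pick("machine"),
    target_concentrations = pick("conc"),
    fixed_concentrations = problem$fixed_concentrations,
    duals = if (identical(status, "optimal")) {
      stats::setNames(duals, rownames(problem$A))
    } else {
      stats::setNames(numeric(0), character(0))
    }
  ), class = "rba_solution")
}

#' @export
print.rba_solution <- function(x, ...) {
  cat("<rba_solution> status = ", x$status, ", mu = ",
      format(x$mu, digits = 8), "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective: ", format(x$objective_value, digits = 8), "\n", sep = "")
    cat("  fluxes: ", paste0(names(x$fluxes), " = ",
                             format(x$fluxes, digits = 6), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Is the all-zero point of this LP trivially feasible? True for fully
# homogeneous models (no target with a nonzero evaluated value), where LP
# feasibility alone cannot define a maximal growth rate.
zero_point_feasible <- function(problem) {
  ok_eq <- problem$relation != "=" | abs(problem$rhs) == 0
  ok_le <- problem$relation != "<=" | problem$rhs >= 0
  ok_ge <- problem$relation != ">=" | problem$rhs <= 0
  all(ok_eq & ok_le & ok_ge) && all(problem$variables$lower <= 0)
}

# Objective selecting the total (unweighted) catalyst concentration.
total_concentration_objective <- function(problem) {
  vars <- problem$variables
  sel <- vars$kind %in% c("enzyme", "machine", "conc")
  stats::setNames(rep(1, sum(sel)), vars$name[sel])
}

#' Test feasibility of a balanced-growth state at a given growth rate
#'
#' A growth rate `mu` is feasible when the model admits a non-trivial
#' balanced-growth state. For models with inhomogeneous target constraints
#' this is plain LP feasibility. For fully homogeneous models (no targets
#' with nonzero value) the all-zero state satisfies every constraint at any
#' `mu`, so feasibility is instead defined as the existence of a state with
#' positive total catalyst mass: the total concentration is maximized and
#' the optimum compared against zero. This is what makes the maximal growth
#' rate a well-defined, finite quantity for every model.
#'
#' @param model a valid [rba_model()].
#' @param mu growth rate, `>= 0`.
#' @param medium an [rba_medium()].
#' @return `TRUE` or `FALSE`.
#' @export
is_feasible <- function(model, mu, medium = rba_medium()) {
  lp <- build_lp(model, mu, medium)
  if (zero_point_feasible(lp)) {
    lp$objective <- numeric(ncol(lp$A))
    names(lp$objective) <- colnames(lp$A)
    obj <- total_concentration_objective(lp)
    lp$objective[names(obj)] <- obj
    lp$sense <- "max"
    sol <- solve_lp(lp)
    sol$status == "optimal" && sol$objective_value > 1e-9
  } else {
    sol <- solve_lp(lp)
    sol$status == "optimal"
  }
}

#' Maximal feasible growth rate by bisection
#'
#' The LP coefficients depend on the growth rate, so the maximal growth rate
#' cannot be found by a single LP solve. Instead, feasibility is
#' monotone: below some `mu*` the constraint set admits a balanced-growth
#' state, above it does not. `maximize_growth()` brackets `mu*` by doubling
#' from `bisection_tol` and bisects until the bracket's relative width falls
#' below `settings$bisection_tol`, then reports the state at the *last
#' feasible* growth rate (conservative: the returned state always exists).
#'
#' Among the typically degenerate optima at `mu*`, a parsimonious state is
#' selected by default: total enzyme plus machine concentration is
#' minimized (for fully homogeneous models, where that minimum is the
#' trivial zero state, the density-saturated state of maximal total
#' concentration is reported instead). Set `parsimonious = FALSE` to return
#' the solver's arbitrary feasible point.
#'
#' @param model a valid [rba_model()].
#' @param medium an [rba_medium()].
#' @param settings an [analysis_settings()].
#' @param parsimonious select the minimal-concentration optimum?
#' @return An `rba_solution` whose `mu` is the maximal feasible growth rate.
#'   If the model is infeasible even at `mu = 0` the status is
#'   `"infeasible"` with `mu = 0`. A model still feasible at
#'   `settings$mu_scan_max` raises an error (unbounded growth indicates a
#'   model pathology such as a missing density constraint).
#' @examples
#' toy <- make_self_replicator(k_enzyme = 2, k_process = 2)
#' sol <- maximize_growth(toy)
#' sol$mu  # closed form: 1 / (1/2 + 1/2) = 1
#' @export
maximize_growth <- function(model, medium = rba_medium(),
                            settings = analysis_settings(),
                            parsimonious = TRUE) {
  stopifnot(inherits(model, "rba_model"))
  tol <- settings$bisection_tol
  if (!is_feasible(model, 0, medium)) {
    lp <- build_lp(model, 0, medium)
    return(new_solution(lp, "infeasible", rep(NA_real_, ncol(lp$A)),
                        NA_real_, NULL))
  }
  lo <- 0
  hi <- NA_real_
  mu <- tol
  while (mu <= settings$mu_scan_max) {
    if (is_feasible(model, mu, medium)) {
      lo <- mu
      mu <- mu * 2
    } else {
      hi <- mu
      break
    }
  }
  if (is.na(hi)) {
    if (is_feasible(model, settings$mu_scan_max, medium)) {
      stop("model is still feasible at mu_scan_max = ", settings$mu_scan_max,
           ": unbounded growth indicates a model pathology", call. = FALSE)
    }
    hi <- settings$mu_scan_max
  }
  while (hi - lo > tol * max(lo, tol)) {
    mid <- (lo + hi) / 2
    if (is_feasible(model, mid, medium)) lo <- mid else hi <- mid
  }
  solve_state_at(model, lo, medium, parsimonious = parsimonious)
}

# Solve for a reportable state at a fixed mu, choosing among degenerate
# optima: minimize total concentration (or maximize it for homogeneous
# models, where the minimum is the trivial zero state).
solve_state_at <- function(model, mu, medium, parsimonious = TRUE) {
  lp <- build_lp(model, mu, medium)
  obj <- total_concentration_objective(lp)
  full <- numeric(ncol(lp$A)); names(full) <- colnames(lp$A)
  full[names(obj)] <- obj
  if (parsimonious) {
    lp$objective <- full
    lp$sense <- if (zero_point_feasible(lp)) "max" else "min"
  }
  sol <- solve_lp(lp)
  sol$mu <- mu
  sol
}

#' Optimize a linear side objective at a fixed growth rate
#'
#' At sub-maximal growth rates the feasible set has slack, and secondary
#' objectives -- maximal production of a compound, minimal machinery
#' investment -- can be optimized over it.
#'
#' @param model a valid [rba_model()].
#' @param mu fixed growth rate (must not exceed the maximal feasible growth
#'   rate, else the returned status is `"infeasible"`).
#' @param medium an [rba_medium()].
#' @param objective named numeric vector of objective coefficients; names
#'   are variable names (`flux:<id>`, `enzyme:<id>`, `machine:<id>`) or bare
#'   component ids when unambiguous.
#' @param sense `"max"` or `"min"`.
#' @return An `rba_solution`.
#' @examples
#' toy <- make_pinned_replicator()
#' optimize_at_growth(toy, mu = 0.4,
#'                    objective = c("machine:translation" = 1))$objective_value
#' @export
optimize_at_growth <- function(model, mu, medium = rba_medium(), objective,
                               sense = "max") {
  lp <- build_lp(model, mu, medium, objective = objective, sense = sense)
  solve_lp(lp)
}
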
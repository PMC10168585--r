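simple_lp <- function(A, rel, b, obj, sense = "max",
                      lower = rep(0, ncol(A)), upper = rep(Inf, ncol(A))) {
  rbakit:::simplex_solve(A, rel, b, lower, upper, obj, sense)
}

test_that("the simplex backend reports optimal/infeasible/unbounded", {
  r <- simple_lp(matrix(1, 1, 1), "<=", 3, 1)
  expect_equal(r$status, "optimal")
  expect_equal(r$value, 3)

  r <- simple_lp(matrix(1, 2, 1), c("<=", ">="), c(-1, 0), 1)
  expect_equal(r$status, "infeasible")

  r <- simple_lp(matrix(1, 1, 1), ">=", 1, 1)
  expect_equal(r$status, "unbounded")

  # free variable, equality row, finite upper bound: min x1 = 2 - max x2 = -1
  r <- simple_lp(matrix(c(1, 1), 1, 2), "=", 2, c(1, 0), sense = "min",
                 lower = c(-Inf, 0), upper = c(Inf, 3))
  expect_equal(r$status, "optimal")
  expect_equal(r$value, -1, tolerance = 1e-9)
  expect_equal(r$x, c(-1, 3), tolerance = 1e-9)
})

test_that("simplex agrees with exhaustive vertex enumeration on random LPs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:4, 1); m <- sample(2:5, 1)
    A <- matrix(stats::rnorm(m * n), m, n)
    x0 <- stats::runif(n)
    b <- as.numeric(A %*% x0) + stats::runif(m, 0.1, 1) # feasible by design
    A <- rbind(A, rep(1, n)) # boundedness: sum x <= 10
    b <- c(b, 10)
    obj <- stats::rnorm(n)
    mine <- simple_lp(A, rep("<=", m + 1), b, obj)
    fake <- structure(list(mu = 0, variables = data.frame(
      name = paste0("x", 1:n), kind = "flux", id = paste0("x", 1:n),
      lower = rep(0, n), upper = rep(Inf, n)),
      A = A, relation = rep("<=", m + 1), rhs = b,
      block = rep("target", m + 1),
      objective = stats::setNames(obj, paste0("x", 1:n)), sense = "max"),
      class = "rba_lp")
    expect_equal(mine$status, "optimal")
    expect_equal(mine$value, enumerate_lp_value(fake), tolerance = 1e-8)
  }
})

test_that("solve_lp matches the enumeration oracle on an RBA problem", {
  lp <- build_lp(make_pinned_replicator(), 0.4,
                 objective = c("machine:translation" = 1), sense = "max")
  expect_equal(solve_lp(lp)$objective_value, enumerate_lp_value(lp),
               tolerance = 1e-8)
  lp$sense <- "min"
  expect_equal(solve_lp(lp)$objective_value, enumerate_lp_value(lp),
               tolerance = 1e-8)
})

test_that("solved states are re-verified feasible independently", {
  lp <- build_lp(make_self_replicator(), 0.5)
  lp$objective <- stats::setNames(rep(1, ncol(lp$A)), colnames(lp$A))
  lp$sense <- "min"
  sol <- solve_lp(lp)
  expect_equal(sol$status, "optimal")
  d <- lp_to_dense(lp)
  x <- c(sol$fluxes, sol$enzyme_concentrations, sol$machine_concentrations)
  expect_lt(rbakit:::constraint_violation(d, x), 1e-8)
  # duals are reported per constraint row
  expect_equal(names(sol$duals), rownames(lp$A))
})

test_that("feasibility thresholds bracket the closed-form mu_max", {
  toy <- make_self_replicator(2, 2)
  expect_true(is_feasible(toy, 0))
  expect_true(is_feasible(toy, 0.99))
  expect_false(is_feasible(toy, 1.01))

  pin <- make_pinned_replicator()
  expect_true(is_feasible(pin, 0.79))
  expect_false(is_feasible(pin, 0.81))
})

test_that("bisection recovers closed-form growth rates", {
  expect_equal(maximize_growth(make_self_replicator(2, 2))$mu, 1,
               tolerance = 2e-6)
  expect_equal(maximize_growth(make_self_replicator(2, 6))$mu, 1.5,
               tolerance = 2e-6)
  sol <- maximize_growth(make_pinned_replicator())
  expect_equal(sol$mu, 0.8, tolerance = 2e-6)
  # the optimum itself: E = M = 0.4, density row tight (0.4 + 0.4 + 0.2 = 1)
  expect_equal(unname(sol$enzyme_concentrations), 0.4, tolerance = 1e-4)
  expect_equal(unname(sol$machine_concentrations), 0.4, tolerance = 1e-4)
})

test_that("mu_max is independent of density capacity for homogeneous models", {
  for (D in c(0.5, 1, 2)) {
    expect_equal(maximize_growth(make_self_replicator(2, 6, density = D))$mu,
                 1.5, tolerance = 2e-6)
  }
})

test_that("scaling all efficiencies scales mu_max proportionally", {
  pin <- make_pinned_replicator()
  ref <- maximize_growth(pin)$mu
  for (lambda in c(0.5, 3)) {
    scaled <- scale_efficiency(scale_efficiency(pin, "E_uptake", lambda),
                               "translation", lambda)
    expect_equal(maximize_growth(scaled)$mu, lambda * ref,
                 tolerance = 1e-5 * lambda * ref)
  }
})

test_that("bisection agrees with a dense feasibility-grid oracle", {
  for (toy in toy_zoo()) {
    mu_bis <- maximize_growth(toy$model, toy$medium)$mu
    mu_grid <- grid_mu_max(toy$model, toy$medium, n = 400, hi = 2)
    expect_equal(mu_bis, mu_grid, tolerance = 2 / 400 / mu_grid)
  }
})

test_that("side objectives at fixed growth match hand-derived LP solutions", {
  pin <- make_pinned_replicator()
  # at mu = 0.4: max M = 0.6 (density-limited), min M = 1/15 (capacity-limited)
  expect_equal(
    optimize_at_growth(pin, 0.4, objective = c("machine:translation" = 1))$objective_value,
    0.6, tolerance = 1e-8)
  expect_equal(
    optimize_at_growth(pin, 0.4, objective = c("machine:translation" = 1),
                       sense = "min")$objective_value,
    1 / 15, tolerance = 1e-8)
  # zero objective: any feasible point, status optimal
  z <- optimize_at_growth(pin, 0.4, objective = c("machine:translation" = 0))
  expect_equal(z$status, "optimal")
  # above mu_max: infeasible
  expect_equal(
    optimize_at_growth(pin, 0.9, objective = c("machine:translation" = 1))$status,
    "infeasible")
})

test_that("growth beyond the scan cap is flagged as a model pathology", {
  # mu_max = 100 with these efficiencies, far above mu_scan_max = 10
  fast <- scale_efficiency(scale_efficiency(make_self_replicator(),
                                            "E_uptake", 100),
                           "translation", 100)
  expect_error(maximize_growth(fast), "mu_scan_max")
})
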
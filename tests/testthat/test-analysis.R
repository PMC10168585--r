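test_that("medium screens trace the Monod curve of the importer toy", {
  mm <- make_mm_importer()
  concs <- c(0, 0.05, 0.1, 1, 10, 100)
  sc <- medium_screen(mm, "nutrient_ext", concs)
  expect_equal(nrow(sc), length(concs))
  expect_equal(sc$concentration, concs) # order preserved
  # closed form at every grid point, including mu_max = 8/15 at c = km
  for (i in seq_along(concs)) {
    expect_equal(sc$mu_max[i], mu_mm_closed(concs[i]), tolerance = 1e-4)
  }
  expect_equal(sc$mu_max[3], 8 / 15, tolerance = 1e-5)
  expect_true(all(diff(sc$mu_max) >= -1e-9)) # monotone non-decreasing
  expect_lt(sc$mu_max[1], 1e-6)             # no import, no growth
  # saturation approaches the pinned-replicator ceiling 0.8
  expect_lt(sc$mu_max[length(concs)], 0.8)
  expect_gt(sc$mu_max[length(concs)], 0.79)
})

test_that("failed screen points are recorded while the screen continues", {
  # boost both catalysts so that growth exceeds the scan cap at high (but
  # not at low) nutrient: the failing point is recorded, the screen finishes
  turbo <- scale_efficiency(scale_efficiency(make_mm_importer(),
                                             "E_uptake", 100),
                            "translation", 100)
  sc <- medium_screen(turbo, "nutrient_ext", c(0.001, 1))
  expect_equal(sc$status[1], "optimal")
  expect_match(sc$status[2], "mu_scan_max")
  expect_true(is.na(sc$mu_max[2]))
})

test_that("minimum substrate concentration inverts the Monod curve", {
  mm <- make_mm_importer()
  expect_equal(find_min_substrate(mm, "nutrient_ext", 8 / 15), 0.1,
               tolerance = 1e-4)
  expect_equal(find_min_substrate(mm, "nutrient_ext", 0), 0)
  # mu = 0.8 is the supremum, approached only as c -> infinity
  expect_error(find_min_substrate(mm, "nutrient_ext", 0.8), "unreachable")
})

test_that("parameter screens reproduce closed forms and are monotone", {
  toy <- make_self_replicator(2, 2)
  ps <- parameter_screen(toy, "translation", factors = c(0.5, 1, 2))
  expect_equal(ps$mu_max, c(2 / 3, 1, 4 / 3), tolerance = 1e-4)
  ps2 <- parameter_screen(make_mm_importer(), "E_uptake",
                          factors = 10^seq(-2, 2, length.out = 9),
                          medium = rba_medium(c(nutrient_ext = 0.1)))
  expect_true(all(diff(ps2$mu_max) >= -1e-9))
})

test_that("local sensitivities match analytic control coefficients", {
  pin <- make_pinned_replicator() # kE = kR = 2: control split evenly
  rep <- local_sensitivities(pin)
  expect_equal(rep$sensitivity[rep$parameter == "translation"], 0.5,
               tolerance = 1e-4)
  expect_equal(rep$sensitivity[rep$parameter == "E_uptake"], 0.5,
               tolerance = 1e-4)
  expect_equal(sum(rep$sensitivity), 1, tolerance = 1e-4)

  # asymmetric case: s(kR) = (nR/kR) / (nE/kE + nR/kR)
  asym <- make_pinned_replicator(k_enzyme = 2, k_process = 6)
  rep2 <- local_sensitivities(asym)
  expect_equal(rep2$sensitivity[rep2$parameter == "translation"],
               (1 / 6) / (1 / 2 + 1 / 6), tolerance = 1e-4)
})

test_that("an enzyme carrying no optimal flux has zero sensitivity", {
  ov <- make_overflow_branch()
  med <- rba_medium(c(nutrient_ext = 20)) # deep overflow regime
  rep <- local_sensitivities(ov, med)
  expect_equal(rep$sensitivity[rep$parameter == "E_respiration"], 0)
  expect_gt(rep$sensitivity[rep$parameter == "E_overflow"], 0)
  expect_gt(rep$sensitivity[rep$parameter == "translation"], 0)
})

test_that("ensembles are seed-reproducible and degenerate as sigma -> 0", {
  pin <- make_pinned_replicator()
  s <- analysis_settings(ensemble_n = 8, seed = 7)
  e1 <- sample_ensemble(pin, settings = s)
  e2 <- sample_ensemble(pin, settings = s)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  e3 <- sample_ensemble(pin, settings = analysis_settings(ensemble_n = 8,
                                                          seed = 8))
  expect_false(identical(e1$factor_E_uptake, e3$factor_E_uptake))
  expect_equal(nrow(e1), 8L)

  tiny <- sample_ensemble(pin, settings = analysis_settings(
    ensemble_n = 5, ensemble_sigma = 1e-12, seed = 1))
  expect_true(all(abs(tiny$mu_max - 0.8) < 1e-5))
})

test_that("RVA brackets the optimum and collapses at maximal growth", {
  pin <- make_pinned_replicator()
  r <- variability_analysis(pin, 0.4)
  expect_true(all(r$min <= r$max + 1e-8))
  opt <- rbakit:::solve_state_at(pin, 0.4, rba_medium())
  vals <- c(opt$fluxes, opt$enzyme_concentrations, opt$machine_concentrations)
  expect_true(all(r$min - 1e-8 <= vals & vals <= r$max + 1e-8))

  m <- variability_analysis(pin, 0.8, variable_ids = "machine:translation")
  expect_equal(m$min, 0.4, tolerance = 1e-6)
  expect_equal(m$max, 0.4, tolerance = 1e-6)

  inf <- variability_analysis(pin, 0.9)
  expect_true(all(inf$status_min == "infeasible"))
  expect_true(all(is.na(inf$min)))
})

test_that("unbounded RVA directions are reported, not raised", {
  # two spontaneous reversible reactions with identical stoichiometry form a
  # thermodynamically unconstrained loop: their fluxes cancel pairwise, so
  # either flux alone is unbounded in both directions
  loopy <- make_self_replicator()
  loopy$reactions$R_leak_a <- rba_reaction("R_leak_a",
                                           c(precursor = -1, nutrient_ext = 1),
                                           reversible = TRUE)
  loopy$reactions$R_leak_b <- rba_reaction("R_leak_b",
                                           c(precursor = -1, nutrient_ext = 1),
                                           reversible = TRUE)
  r <- variability_analysis(loopy, 0, variable_ids = "flux:R_leak_a")
  expect_equal(r$status_max, "unbounded")
  expect_equal(r$status_min, "unbounded")
})

test_that("RVA over growth emits the growth/flexibility trade-off", {
  pin <- make_pinned_replicator()
  rg <- rva_over_growth(pin, variable_ids = "machine:translation",
                        fractions = c(0.5, 0.75, 1))
  expect_equal(rg$min[1], 1 / 15, tolerance = 1e-5)
  expect_equal(rg$max[1], 0.6, tolerance = 1e-5)
  expect_equal(rg$min[3], 0.4, tolerance = 1e-4)
  expect_equal(rg$max[3], 0.4, tolerance = 1e-4)
  widths <- rg$max - rg$min
  expect_true(all(diff(widths) <= 1e-8)) # range shrinks towards mu_max
  # the fraction-1 range contains the growth-optimal state
  opt <- maximize_growth(pin)
  expect_gte(opt$machine_concentrations[["translation"]], rg$min[3] - 1e-6)
  expect_lte(opt$machine_concentrations[["translation"]], rg$max[3] + 1e-6)
})

test_that("epsilon-constraint fronts hit their endpoints and decrease", {
  sec <- make_secretion(second_product = TRUE)
  obj_a <- c("flux:R_product" = 1)
  obj_b <- c("flux:R_product_2" = 1)
  pf <- pareto_front(sec, 0.4, objective_a = obj_a, objective_b = obj_b,
                     settings = analysis_settings(pareto_points = 11))
  free_a <- optimize_at_growth(sec, 0.4, objective = obj_a)$objective_value
  expect_equal(pf$value_a[1], free_a, tolerance = 1e-8)
  expect_true(all(diff(pf$value_a) <= 1e-8))
  b_max <- optimize_at_growth(sec, 0.4, objective = obj_b)$objective_value
  expect_equal(max(pf$b_level), b_max, tolerance = 1e-8)
  # two identical sinks sharing one budget: the front is a straight line
  line <- free_a * (1 - pf$b_level / b_max)
  expect_equal(pf$value_a, line, tolerance = 1e-6)
})

test_that("front points agree with a feasibility-bisection oracle", {
  sec <- make_secretion(second_product = TRUE)
  obj_a <- c("flux:R_product" = 1)
  obj_b <- c("flux:R_product_2" = 1)
  pf <- pareto_front(sec, 0.4, objective_a = obj_a, objective_b = obj_b,
                     settings = analysis_settings(pareto_points = 5))
  lp <- build_lp(sec, 0.4)
  a_vec <- rbakit:::full_objective(lp, obj_a)
  b_vec <- rbakit:::full_objective(lp, obj_b)
  demand_feasible <- function(a, b) {
    p <- lp
    p$A <- rbind(p$A, demand_a = a_vec, demand_b = b_vec)
    p$relation <- c(p$relation, ">=", ">=")
    p$rhs <- c(p$rhs, a, b)
    p$block <- c(p$block, "target", "target")
    solve_lp(p)$status == "optimal"
  }
  for (i in seq_len(nrow(pf))) {
    lo <- 0; hi <- 1
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (demand_feasible(mid, pf$b_level[i])) lo <- mid else hi <- mid
    }
    expect_equal(pf$value_a[i], lo, tolerance = 1e-6)
  }
})

test_that("production trades off against fitness and matches direct solves", {
  sec <- make_secretion()
  td <- production_tradeoff(sec, product_reaction = "R_product",
                            fitness_fractions = c(0.25, 0.5, 0.75, 1))
  expect_true(all(diff(td$production) <= 1e-8))
  expect_equal(td$production[4], 0, tolerance = 1e-6) # no slack at mu_max
  direct <- optimize_at_growth(sec, td$mu[2],
                               objective = c("flux:R_product" = 1))
  expect_equal(td$production[2], direct$objective_value, tolerance = 1e-9)
  # closed form at f = 0.5 (mu = 0.4): kV * [D(1 - mu) - c0] / (1 + kV/kE)
  expect_equal(td$production[2], (1 * (1 - 0.4) - 0.2) / (1 + 1 / 2),
               tolerance = 1e-5)
})
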
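test_that("every generator output validates cleanly", {
  for (toy in toy_zoo()) {
    expect_equal(nrow(validate_model(toy$model)), 0L)
  }
  expect_equal(nrow(validate_model(make_secretion(second_product = TRUE))), 0L)
})

test_that("randomized self-replicators reproduce the closed form", {
  set.seed(101)
  wide <- analysis_settings(mu_scan_max = 1000)
  for (i in 1:20) {
    p <- exp(stats::runif(4, log(0.1), log(10))) # kE, kR, nE, nR log-uniform
    m <- make_self_replicator(p[1], p[2], p[3], p[4])
    mu <- mu_self_closed(p[1], p[2], p[3], p[4])
    expect_equal(maximize_growth(m, settings = wide)$mu, mu, tolerance = 2e-6)
  }
})

test_that("randomized pinned replicators reproduce the closed form", {
  set.seed(102)
  wide <- analysis_settings(mu_scan_max = 1000)
  for (i in 1:20) {
    p <- exp(stats::runif(4, log(0.1), log(10)))
    D <- exp(stats::runif(1, log(0.5), log(5)))
    nH <- exp(stats::runif(1, log(0.1), log(10)))
    c0 <- stats::runif(1, 0, 0.9) * D / nH
    m <- make_pinned_replicator(p[1], p[2], p[3], p[4], nH, c0, D)
    mu <- mu_pinned_closed(p[1], p[2], p[3], p[4], nH, c0, D)
    expect_equal(maximize_growth(m, settings = wide)$mu, mu, tolerance = 2e-6)
  }
})

test_that("pinned replicator limits behave as documented", {
  # c0 = 0 reduces to the self-replicator
  expect_equal(maximize_growth(make_pinned_replicator(conc_housekeeping = 0))$mu,
               1, tolerance = 2e-6)
  # c0 -> D: growth collapses
  expect_lt(maximize_growth(make_pinned_replicator(conc_housekeeping = 0.99))$mu,
            0.011)
  # c0 >= D is structurally infeasible and rejected at build time
  expect_error(make_pinned_replicator(conc_housekeeping = 1), "infeasible")
})

test_that("the importer toy has a saturating, strictly increasing Monod curve", {
  mm <- make_mm_importer()
  concs <- c(0.02, 0.1, 0.5, 2, 20)
  mus <- vapply(concs, function(cc)
    maximize_growth(mm, rba_medium(c(nutrient_ext = cc)))$mu, numeric(1))
  expect_true(all(diff(mus) > 0))
  for (i in seq_along(concs)) {
    expect_equal(mus[i], mu_mm_closed(concs[i]), tolerance = 1e-4)
  }
  expect_lt(maximize_growth(mm, rba_medium(c(nutrient_ext = 0)))$mu, 1e-6)
})

test_that("the overflow toy switches pathways at the predicted concentration", {
  ov <- make_overflow_branch()
  c_star <- attr(ov, "switch_concentration")
  expect_equal(c_star, 1) # defaults were chosen to switch at 1 mM

  below <- maximize_growth(ov, rba_medium(c(nutrient_ext = 0.5 * c_star)))
  above <- maximize_growth(ov, rba_medium(c(nutrient_ext = 2 * c_star)))
  expect_lt(below$fluxes[["R_overflow"]], 1e-8)  # respiration only
  expect_gt(above$fluxes[["R_overflow"]], 1e-3)  # overflow active
  expect_lt(above$fluxes[["R_respiration"]], 1e-8)
  # growth matches the min-cost closed form on both sides
  expect_equal(below$mu, mu_overflow_closed(0.5 * c_star), tolerance = 1e-4)
  expect_equal(above$mu, mu_overflow_closed(2 * c_star), tolerance = 1e-4)

  # knocking out the overflow branch abolishes secretion everywhere
  no_ovf <- knock_out(ov, "E_overflow")
  for (cc in c(0.5, 1, 5)) {
    s <- maximize_growth(no_ovf, rba_medium(c(nutrient_ext = cc)))
    expect_lt(abs(s$fluxes[["R_overflow"]]), 1e-9)
  }
  # parameters that never favour overflow are rejected with a diagnostic
  expect_error(make_overflow_branch(yield_ferm = 1, k_ferm = 1.5), "never switch")
})

test_that("at the switch point both pathway configurations are feasible", {
  ov <- make_overflow_branch()
  med <- rba_medium(c(nutrient_ext = attr(ov, "switch_concentration")))
  mu_max <- maximize_growth(ov, med)$mu
  r <- variability_analysis(ov, 0.999 * mu_max, med,
                            variable_ids = c("flux:R_respiration",
                                             "flux:R_overflow"))
  # wide ranges at near-maximal growth: the configuration is flexible
  expect_gt(r$max[1] - r$min[1], 0.1 * r$max[1])
  expect_gt(r$max[2] - r$min[2], 0.1 * r$max[2])
  # away from the switch the same ranges are narrow
  med_far <- rba_medium(c(nutrient_ext = 0.2))
  mu_far <- maximize_growth(ov, med_far)$mu
  r_far <- variability_analysis(ov, 0.999 * mu_far, med_far,
                                variable_ids = c("flux:R_respiration",
                                                 "flux:R_overflow"))
  expect_lt(r_far$max[2] - r_far$min[2], r$max[2] - r$min[2])
})

test_that("the secretion toy gives production only below maximal growth", {
  sec <- make_secretion()
  mu_max <- maximize_growth(sec)$mu
  at <- function(f) optimize_at_growth(sec, f * mu_max,
                                       objective = c("flux:R_product" = 1))
  expect_equal(at(1)$objective_value, 0, tolerance = 1e-6)
  expect_gt(at(0.5)$objective_value, 0.1)
  # near-linear trade-off at high fitness (exactly linear for this toy)
  f <- c(0.7, 0.8, 0.9, 1)
  prod <- vapply(f, function(ff) at(ff)$objective_value, numeric(1))
  slopes <- diff(prod) / diff(f)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-4)
})
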
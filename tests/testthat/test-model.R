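test_that("valid toy models produce no diagnostics", {
  for (toy in toy_zoo()) {
    expect_equal(nrow(validate_model(toy$model)), 0L)
  }
})

test_that("broken references and invariant violations are each diagnosed", {
  m <- make_self_replicator()

  broken <- m
  broken$enzymes$E_uptake$composition <- c(no_such_protein = 1)
  d <- validate_model(broken)
  expect_equal(nrow(d), 1L)
  expect_equal(d$id, "E_uptake")
  expect_match(d$message, "no_such_protein")

  neg <- m
  neg$compartments$cytosol$density_capacity <- pf_constant(1)
  neg$compartments$cytosol$density_capacity$value <- -1 # bypass constructor
  d <- validate_model(neg)
  expect_equal(nrow(d), 1L)
  expect_equal(d$id, "cytosol")

  orphan <- m
  orphan$reactions$R_uptake$enzyme <- NULL
  d <- validate_model(orphan)
  expect_true(any(d$id == "E_uptake" & grepl("exactly one reaction", d$message)))

  dup <- m
  dup$metabolites[["E_uptake"]] <- rba_metabolite("E_uptake")
  expect_true(any(validate_model(dup)$message == "duplicate identifier"))
})

test_that("knockout zeroes efficiencies and leaves the input untouched", {
  mm <- make_mm_importer()
  before <- mm
  dead <- knock_out(mm, "E_uptake")
  expect_identical(mm, before) # copy-on-write
  expect_equal(evaluate_parameter(dead$enzymes$E_uptake$forward_efficiency, 1,
                                  rba_medium(c(nutrient_ext = 10))), 0)
  # no precursor influx: only mu = 0 remains feasible
  sol <- maximize_growth(dead, rba_medium(c(nutrient_ext = 10)))
  expect_lt(sol$mu, 2e-6)
  expect_false(is_feasible(dead, 0.01, rba_medium(c(nutrient_ext = 10))))

  expect_identical(knock_out(mm, character()), mm)
  expect_error(knock_out(mm, "no_such"), "no_such")
})

test_that("knocking out one branch leaves the single-pathway closed form", {
  ov <- make_overflow_branch()
  med <- rba_medium(c(nutrient_ext = 10))
  only_resp <- knock_out(ov, "E_overflow")
  kt <- 4 * 10 / (1 + 10)
  q_resp <- (1 / 2) * (1 / kt + 1 / 1)
  expect_equal(maximize_growth(only_resp, med)$mu,
               0.8 / (q_resp + 1 / 2), tolerance = 1e-5)
})

test_that("efficiency scaling composes and inverts exactly", {
  toy <- make_self_replicator(k_enzyme = 2, k_process = 2)
  expect_equal(maximize_growth(scale_efficiency(toy, "translation", 1))$mu,
               1, tolerance = 1e-5)
  # closed form: scaling kR by 2 gives 1/(1/2 + 1/4) = 4/3
  expect_equal(maximize_growth(scale_efficiency(toy, "translation", 2))$mu,
               4 / 3, tolerance = 1e-5)
  # endpoints of the conventional screening range are accepted
  expect_s3_class(scale_efficiency(toy, "E_uptake", 0.01), "rba_model")
  expect_s3_class(scale_efficiency(toy, "E_uptake", 100), "rba_model")

  # round trip: scale by f then 1/f agrees on a (mu, medium) grid
  mm <- make_mm_importer()
  round_trip <- scale_efficiency(scale_efficiency(mm, "E_uptake", 3.7),
                                 "E_uptake", 1 / 3.7)
  for (mu in c(0, 0.3, 1)) {
    for (conc in c(0.01, 0.1, 10)) {
      med <- rba_medium(c(nutrient_ext = conc))
      expect_equal(
        evaluate_parameter(round_trip$enzymes$E_uptake$forward_efficiency,
                           mu, med),
        evaluate_parameter(mm$enzymes$E_uptake$forward_efficiency, mu, med),
        tolerance = 1e-12)
    }
  }
})

test_that("imposed targets append, collide on ids, and bind as expected", {
  pin <- make_pinned_replicator()
  sol <- maximize_growth(pin)

  # a flux bound at the optimal flux is inactive: mu_max unchanged
  capped <- impose_target(
    pin, rba_target("cap_uptake", "flux_le", "R_uptake",
                    sol$fluxes[["R_uptake"]]))
  expect_equal(maximize_growth(capped)$mu, sol$mu, tolerance = 1e-4)

  # the corresponding equality pins the whole state: still solvable at the
  # optimal growth rate, but no growth rate below it remains feasible
  pinned_flux <- impose_target(
    pin, rba_target("fix_uptake", "flux_eq", "R_uptake",
                    sol$fluxes[["R_uptake"]]))
  at_opt <- optimize_at_growth(pinned_flux, sol$mu,
                               objective = c("flux:R_uptake" = 0))
  expect_equal(at_opt$status, "optimal")
  expect_false(is_feasible(pinned_flux, 0.5 * sol$mu))

  # contradictory target: more machine than the compartment can hold
  stuffed <- impose_target(
    pin, rba_target("too_much", "concentration_ge", "translation", 2))
  out <- maximize_growth(stuffed)
  expect_equal(out$status, "infeasible")
  expect_equal(out$mu, 0)

  # the housekeeping target itself produces the pinned closed form
  self <- make_self_replicator()
  expect_error(impose_target(pin, pin$targets$housekeeping_level), "already")
  expect_error(
    impose_target(self, rba_target("bad", "concentration_eq", "nutrient_ext", 1)),
    "external")
})
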
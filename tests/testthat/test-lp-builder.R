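test_that("row blocks and counts match the model structure", {
  toy <- make_self_replicator()
  lp <- build_lp(toy, mu = 1)
  # 1 internal metabolite + 1 catalysed reaction + 1 process + 1 compartment
  expect_equal(as.integer(table(lp$block)[c("mass_balance", "capacity",
                                            "process_capacity", "density")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(nrow(lp$A), 4L)
  expect_equal(ncol(lp$A), 3L) # flux, enzyme, machine
  d <- lp_to_dense(lp)
  expect_equal(dim(d$A), c(4L, 3L))

  pin <- make_pinned_replicator()
  lp2 <- build_lp(pin, mu = 0.4)
  # substituted concentration target: no extra variable, no target row
  expect_equal(nrow(lp2$A), 4L)
  expect_equal(ncol(lp2$A), 3L)
  # ... but it appears in the mass-balance RHS (dilution demand mu*c0)
  expect_equal(lp2$rhs[lp2$block == "mass_balance"], 0.4 * 0.2)
})

test_that("dilution terms vanish at mu = 0", {
  lp <- build_lp(make_pinned_replicator(), mu = 0)
  mb <- lp$A[lp$block == "mass_balance", , drop = FALSE]
  conc_cols <- lp$variables$kind != "flux"
  expect_true(all(mb[, conc_cols] == 0))
  expect_true(all(lp$rhs[lp$block == "mass_balance"] == 0))
})

test_that("a knocked-out enzyme's capacity row forces zero flux", {
  dead <- knock_out(make_self_replicator(), "E_uptake")
  lp <- build_lp(dead, mu = 0.5)
  row <- lp$A["capacity_fwd__R_uptake", ]
  expect_equal(unname(row["flux:R_uptake"]), 1)
  expect_equal(unname(row["enzyme:E_uptake"]), 0) # k = 0
  expect_equal(lp$rhs[rownames(lp$A) == "capacity_fwd__R_uptake"], 0)
})

test_that("all evaluated coefficients are finite on every toy", {
  for (toy in toy_zoo()) {
    for (mu in c(0, 0.5, 5)) {
      lp <- build_lp(toy$model, mu, toy$medium)
      expect_true(all(is.finite(lp$A)))
      expect_true(all(is.finite(lp$rhs)))
    }
  }
})

test_that("declaration order changes columns but not the optimum", {
  sec <- make_secretion(second_product = TRUE)
  permuted <- sec
  permuted$reactions <- rev(permuted$reactions)
  permuted$enzymes <- rev(permuted$enzymes)
  obj <- c("flux:R_product" = 1)
  a <- optimize_at_growth(sec, 0.4, objective = obj)
  b <- optimize_at_growth(permuted, 0.4, objective = obj)
  expect_false(identical(colnames(build_lp(sec, 0.4)$A),
                         colnames(build_lp(permuted, 0.4)$A)))
  expect_equal(a$objective_value, b$objective_value, tolerance = 1e-9)
})

test_that("shrinking a feasible state stays feasible below the density bound", {
  # homogeneous model: density is the only inhomogeneous row, and it relaxes
  toy <- make_self_replicator()
  lp <- build_lp(toy, mu = 0.5)
  sol <- rbakit:::solve_state_at(toy, 0.5, rba_medium())
  x <- c(sol$fluxes, sol$enzyme_concentrations, sol$machine_concentrations)
  d <- lp_to_dense(lp)
  for (alpha in c(1, 0.5, 0.1, 0)) {
    expect_lt(rbakit:::constraint_violation(d, alpha * x), 1e-8)
  }
})

test_that("feasibility over a mu grid is a prefix on every toy", {
  for (toy in toy_zoo()) {
    expect_true(feasibility_is_prefix(toy$model, toy$medium, n = 50, hi = 2))
  }
})

test_that("the LP block dump round-trips through CSV", {
  lp <- build_lp(make_pinned_replicator(), 0.4)
  path <- withr::local_tempfile(fileext = ".csv")
  dump_lp_csv(lp, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$row, rownames(lp$A))
  expect_equal(as.matrix(back[, colnames(lp$A)]), lp$A, ignore_attr = TRUE)
})
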
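#' Medium screens and Monod curves
#'
#' Computes the maximal growth rate and the optimal exchange/internal fluxes
#' along a grid of concentrations of one external metabolite -- the Monod
#' curve of the model, with the medium-dependent flux pattern (e.g.
#' respiration/overflow switching) alongside.
#'
#' @param model a valid [rba_model()].
#' @param metabolite id of the external metabolite to screen.
#' @param concentrations numeric vector of concentrations (mM, `>= 0`).
#' @param medium base [rba_medium()]; the screened entry is overridden per
#'   grid point.
#' @param settings an [analysis_settings()].
#' @param fluxes reaction ids whose optimal fluxes to record (default: all).
#' @return A tibble of class `rba_screen` with one row per concentration:
#'   `concentration`, `mu_max`, `status`, and one `flux_<reaction>` column
#'   per recorded reaction. Failures at single grid points are recorded in
#'   `status`; the screen continues.
#' @examples
#' monod <- medium_screen(make_mm_importer(), "nutrient_ext",
#'                        c(0.01, 0.1, 1, 10))
#' @export
medium_screen <- function(model, metabolite, concentrations,
                          medium = rba_medium(),
                          settings = analysis_settings(),
                          fluxes = NULL) {
  stopifnot(metabolite %in% external_ids(model), all(concentrations >= 0))
  if (is.null(fluxes)) fluxes <- names(model$reactions)
  rows <- purrr::map(concentrations, function(conc) {
    med <- medium_set(medium, stats::setNames(conc, metabolite))
    screen_point(model, med, settings, fluxes,
                 tibble::tibble(concentration = conc))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rba_screen", class(out)),
            axis = "concentration", axis_label = paste0(metabolite, " (mM)"))
}

# One mu_max evaluation wrapped against per-point failure.
screen_point <- function(model, medium, settings, fluxes, lead) {
  res <- tryCatch(maximize_growth(model, medium, settings),
                  error = function(e) e)
  if (inherits(res, "error")) {
    row <- dplyr::mutate(lead, mu_max = NA_real_,
                         status = conditionMessage(res))
    fl <- rep(NA_real_, length(fluxes))
  } else {
    row <- dplyr::mutate(lead, mu_max = res$mu, status = res$status)
    fl <- res$fluxes[fluxes]
    if (res$status != "optimal") fl <- rep(NA_real_, length(fluxes))
  }
  names(fl) <- paste0("flux_", fluxes)
  dplyr::bind_cols(row, tibble::as_tibble_row(fl))
}

#' Minimum substrate concentration sustaining a target growth rate
#'
#' Inverts the Monod curve by bisection over the concentration of a limiting
#' substrate: the smallest concentration at which `mu_target` is feasible
#' (chemostat-style question).
#'
#' @inheritParams medium_screen
#' @param mu_target the growth rate to reach.
#' @param conc_max upper end of the concentration bracket (default `1e6`
#'   mM); if `mu_target` is not reachable even there, an error reports the
#'   saturated maximal growth rate.
#' @return The minimal concentration (scalar).
#' @export
find_min_substrate <- function(model, metabolite, mu_target,
                               medium = rba_medium(),
                               settings = analysis_settings(),
                               conc_max = 1e6) {
  stopifnot(metabolite %in% external_ids(model), mu_target >= 0)
  if (mu_target == 0) return(0)
  feas_at <- function(conc) {
    is_feasible(model, mu_target,
                medium_set(medium, stats::setNames(conc, metabolite)))
  }
  if (!feas_at(conc_max)) {
    sat <- maximize_growth(
      model, medium_set(medium, stats::setNames(conc_max, metabolite)),
      settings)
    stop("growth rate ", mu_target, " is unreachable: maximal growth rate ",
         "at saturating concentration (", conc_max, " mM) is ",
         format(sat$mu, digits = 8), call. = FALSE)
  }
  lo <- 0; hi <- conc_max
  while (hi - lo > settings$bisection_tol * max(hi, settings$bisection_tol)) {
    mid <- (lo + hi) / 2
    if (feas_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Parameter screens
#'
#' Scales one catalyst's efficiency function by each factor in turn and
#' recomputes the maximal growth rate -- e.g. the classic
#' ribosome-efficiency screen. The default grid spans factors 0.01 to 100
#' logarithmically.
#'
#' @inheritParams medium_screen
#' @param catalyst_id enzyme or process id whose efficiency is scaled.
#' @param factors positive scaling factors.
#' @return A tibble of class `rba_screen` with columns `factor`, `mu_max`,
#'   `status` and recorded fluxes.
#' @export
parameter_screen <- function(model, catalyst_id,
                             factors = 10^seq(-2, 2, length.out = 25),
                             medium = rba_medium(),
                             settings = analysis_settings(),
                             fluxes = NULL) {
  stopifnot(all(factors > 0))
  if (is.null(fluxes)) fluxes <- names(model$reactions)
  rows <- purrr::map(factors, function(f) {
    edited <- scale_efficiency(model, catalyst_id, f)
    screen_point(edited, medium, settings, fluxes,
                 tibble::tibble(factor = f))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rba_screen", class(out)),
            axis = "factor",
            axis_label = paste0("efficiency scaling of ", catalyst_id))
}

#' Local growth-rate sensitivities to catalyst efficiencies
#'
#' Scaled sensitivities `d ln(mu_max) / d ln(k_app)`: the relative change of
#' the maximal growth rate caused by a relative change in one catalyst's
#' efficiency. Estimated by a symmetric finite difference in log space with
#' half-step `settings$fd_step` (default `ln(1.01)`); the inner growth
#' bisections are run at a tenfold tighter tolerance than
#' `settings$bisection_tol` so the difference quotient is not dominated by
#' bisection error. Absolute sensitivities below `1e-6` are reported as
#' exactly 0 ("no control").
#'
#' For models with constant efficiencies and no flux targets, the maximal
#' growth rate is homogeneous of degree one in the full efficiency vector,
#' so the sensitivities sum to 1 -- a built-in consistency check.
#'
#' @inheritParams medium_screen
#' @param parameter_ids catalyst (enzyme or process) ids; default: all.
#' @return A tibble of class `rba_sensitivity` with columns `parameter`,
#'   `sensitivity` and `mu_ref` (reference maximal growth rate).
#' @export
local_sensitivities <- function(model, medium = rba_medium(),
                                parameter_ids = NULL,
                                settings = analysis_settings()) {
  if (is.null(parameter_ids)) parameter_ids <- catalyst_ids(model)
  inner <- settings
  inner$bisection_tol <- settings$bisection_tol / 10
  ref <- maximize_growth(model, medium, inner, parsimonious = FALSE)
  if (ref$status != "optimal" || ref$mu <= 0) {
    stop("reference state is infeasible or has zero growth (status ",
         ref$status, ", mu = ", ref$mu, ")", call. = FALSE)
  }
  delta <- settings$fd_step
  sens <- purrr::map_dbl(parameter_ids, function(id) {
    up <- maximize_growth(scale_efficiency(model, id, exp(delta)),
                          medium, inner, parsimonious = FALSE)$mu
    dn <- maximize_growth(scale_efficiency(model, id, exp(-delta)),
                          medium, inner, parsimonious = FALSE)$mu
    if (up <= 0 || dn <= 0) return(NA_real_)
    (log(up) - log(dn)) / (2 * delta)
  })
  sens[!is.na(sens) & abs(sens) < 1e-6] <- 0
  out <- tibble::tibble(parameter = parameter_ids, sensitivity = sens,
                        mu_ref = ref$mu)
  structure(out, class = c("rba_sensitivity", class(out)))
}

# Evaluate code with a local, restorable RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Global sensitivity analysis by ensemble sampling
#'
#' Draws an ensemble of `settings$ensemble_n` perturbed models: every enzyme
#' efficiency is multiplied by its own random factor `x` with
#' `ln(x) ~ Normal(0, settings$ensemble_sigma)` (default `sigma = ln(1.1)`,
#' about 10 percent uncertainty). Process-machine efficiencies are left
#' unperturbed unless `include_processes = TRUE`. For each sampled model the
#' maximal growth rate and the optimal fluxes are recorded. The result is
#' bitwise reproducible from `settings$seed`.
#'
#' Near a metabolic switch point (e.g. the respiration/overflow transition)
#' the flux distributions of such an ensemble are bimodal: small efficiency
#' perturbations tip the optimum from one strategy to the other.
#'
#' @inheritParams medium_screen
#' @param include_processes also perturb process-machine efficiencies?
#' @return A tibble of class `rba_ensemble` with one row per sample:
#'   `sample`, `mu_max`, `status`, recorded `flux_*` columns and the applied
#'   `factor_<catalyst>` columns. Attributes `seed` and `sigma` record the
#'   sampling conditions. Infeasible samples are recorded, not fatal.
#' @export
sample_ensemble <- function(model, medium = rba_medium(),
                            settings = analysis_settings(),
                            fluxes = NULL, include_processes = FALSE) {
  ids <- names(model$enzymes)
  if (include_processes) ids <- c(ids, names(model$processes))
  if (is.null(fluxes)) fluxes <- names(model$reactions)
  n <- settings$ensemble_n
  factors <- with_local_seed(settings$seed, {
    matrix(exp(stats::rnorm(n * length(ids), 0, settings$ensemble_sigma)),
           nrow = n, dimnames = list(NULL, ids))
  })
  rows <- purrr::map(seq_len(n), function(i) {
    edited <- model
    for (id in ids) edited <- scale_efficiency(edited, id, factors[i, id])
    row <- screen_point(edited, medium, settings, fluxes,
                        tibble::tibble(sample = i))
    fac <- stats::setNames(as.numeric(factors[i, ]), paste0("factor_", ids))
    dplyr::bind_cols(row, tibble::as_tibble_row(fac))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rba_ensemble", class(out)),
            seed = settings$seed, sigma = settings$ensemble_sigma)
}

#' Resource Variability Analysis (RVA)
#'
#' The RBA analogue of Flux Variability Analysis: at a fixed (usually
#' sub-maximal) growth rate, each requested variable is minimized and
#' maximized over the feasible set. Wide ranges indicate flexibility of the
#' cell configuration (or prediction uncertainty); at the maximal growth
#' rate the feasible region typically collapses to a single point.
#'
#' @inheritParams medium_screen
#' @param mu fixed growth rate.
#' @param variable_ids variables to range over: full names
#'   (`flux:<reaction>`, `enzyme:<id>`, `machine:<process>`) or bare ids.
#'   Default: all variables.
#' @return A tibble of class `rba_rva` with columns `variable`, `min`,
#'   `max`, `status_min`, `status_max`. An infeasible `mu` yields
#'   `"infeasible"` statuses and `NA` bounds; an unbounded direction is
#'   reported as status `"unbounded"`, not an error.
#' @examples
#' variability_analysis(make_pinned_replicator(), mu = 0.4,
#'                      variable_ids = "machine:translation")
#' @export
variability_analysis <- function(model, mu, medium = rba_medium(),
                                 variable_ids = NULL,
                                 settings = analysis_settings()) {
  lp <- build_lp(model, mu, medium)
  all_vars <- lp$variables$name
  if (is.null(variable_ids)) variable_ids <- all_vars
  idx <- resolve_variable_names(all_vars, variable_ids)
  rows <- purrr::map(seq_along(idx), function(i) {
    vn <- all_vars[idx[i]]
    one <- function(sense) {
      p <- lp
      p$objective <- stats::setNames(numeric(length(all_vars)), all_vars)
      p$objective[vn] <- 1
      p$sense <- sense
      solve_lp(p)
    }
    lo <- one("min"); hi <- one("max")
    tibble::tibble(
      variable = variable_ids[i],
      min = if (lo$status == "optimal") lo$objective_value else NA_real_,
      max = if (hi$status == "optimal") hi$objective_value else NA_real_,
      status_min = lo$status, status_max = hi$status
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(dplyr::mutate(out, mu = mu, .before = 1),
            class = c("rba_rva", class(out)))
}

#' RVA as a function of growth rate
#'
#' Computes the maximal growth rate once, then runs
#' [variability_analysis()] at each requested fraction of it -- the
#' trade-off curves between growth and feasible variable ranges (upper
#' curves are Pareto fronts when the variable is a maximization objective).
#'
#' @inheritParams variability_analysis
#' @param fractions fractions of the maximal growth rate, in `(0, 1]`.
#' @return A tibble of class `rba_rva` with columns `fraction`, `mu`,
#'   `variable`, `min`, `max`, `status_min`, `status_max`.
#' @export
rva_over_growth <- function(model, medium = rba_medium(),
                            variable_ids = NULL,
                            fractions = seq(0.5, 1, by = 0.1),
                            settings = analysis_settings()) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  mu_max <- maximize_growth(model, medium, settings)$mu
  rows <- purrr::map(fractions, function(f) {
    r <- variability_analysis(model, f * mu_max, medium, variable_ids, settings)
    dplyr::mutate(r, fraction = f, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rba_rva", class(out)), mu_max = mu_max)
}

# Build a full-length objective vector from a named spec.
full_objective <- function(lp, objective) {
  all_vars <- lp$variables$name
  idx <- resolve_variable_names(all_vars, names(objective))
  v <- stats::setNames(numeric(length(all_vars)), all_vars)
  v[idx] <- as.numeric(objective)
  v
}

#' Pareto fronts between two objectives at fixed growth
#'
#' Epsilon-constraint sweep at a fixed, sub-maximal growth rate: objective B
#' is first maximized alone (`b_max`); then, for `settings$pareto_points`
#' levels `b` spanning `[0, b_max]`, objective A is maximized subject to
#' `B >= b`. The resulting front is non-increasing in `b`.
#'
#' @inheritParams variability_analysis
#' @param objective_a,objective_b named numeric vectors defining the two
#'   linear objectives (both maximized); names as in [optimize_at_growth()].
#' @param log_grid space the `b` levels logarithmically instead of linearly
#'   (the smallest level is then `b_max / 1000`).
#' @return A tibble of class `rba_pareto` with columns `b_level`, `value_a`
#'   and `status`.
#' @export
pareto_front <- function(model, mu, medium = rba_medium(),
                         objective_a, objective_b,
                         settings = analysis_settings(), log_grid = FALSE) {
  lp <- build_lp(model, mu, medium)
  obj_a <- full_objective(lp, objective_a)
  obj_b <- full_objective(lp, objective_b)

  solve_with <- function(obj, sense = "max", extra_row = NULL) {
    p <- lp
    p$objective <- obj
    p$sense <- sense
    if (!is.null(extra_row)) {
      p$A <- rbind(p$A, pareto_epsilon = extra_row$coef)
      p$relation <- c(p$relation, extra_row$rel)
      p$rhs <- c(p$rhs, extra_row$rhs)
      p$block <- c(p$block, "target")
    }
    solve_lp(p)
  }

  sb <- solve_with(obj_b)
  if (sb$status == "unbounded") {
    stop("objective B is unbounded at mu = ", mu, call. = FALSE)
  }
  if (sb$status != "optimal") {
    stop("no feasible state at mu = ", mu, " (status ", sb$status, ")",
         call. = FALSE)
  }
  b_max <- sb$objective_value
  levels <- if (log_grid && b_max > 0) {
    exp(seq(log(b_max / 1000), log(b_max), length.out = settings$pareto_points))
  } else {
    seq(0, b_max, length.out = settings$pareto_points)
  }
  rows <- purrr::map(levels, function(b) {
    sa <- solve_with(obj_a, extra_row = list(coef = obj_b, rel = ">=", rhs = b))
    if (sa$status == "unbounded") {
      stop("objective A is unbounded at mu = ", mu, call. = FALSE)
    }
    tibble::tibble(b_level = b,
                   value_a = if (sa$status == "optimal") sa$objective_value
                             else NA_real_,
                   status = sa$status)
  })
  out <- dplyr::bind_rows(rows)
  structure(dplyr::mutate(out, mu = mu, .before = 1),
            class = c("rba_pareto", class(out)))
}

#' Growth/production trade-off curves
#'
#' For each fitness fraction `f`, maximizes the flux of a product reaction
#' at growth rate `f * mu_max` -- the classic "production vs. fitness"
#' curve of strain design. At `f = 1` production is typically zero: the
#' growth-optimal state has no slack.
#'
#' @inheritParams medium_screen
#' @param product_reaction reaction id whose flux is the production
#'   objective.
#' @param fitness_fractions fractions of the maximal growth rate, `(0, 1]`.
#' @return A tibble of class `rba_tradeoff` with columns `fraction`, `mu`,
#'   `production`, `status`.
#' @export
production_tradeoff <- function(model, medium = rba_medium(),
                                product_reaction,
                                fitness_fractions = seq(0.1, 1, by = 0.1),
                                settings = analysis_settings()) {
  stopifnot(product_reaction %in% names(model$reactions),
            all(fitness_fractions > 0), all(fitness_fractions <= 1))
  mu_max <- maximize_growth(model, medium, settings)$mu
  obj <- stats::setNames(1, paste0("flux:", product_reaction))
  rows <- purrr::map(fitness_fractions, function(f) {
    s <- optimize_at_growth(model, f * mu_max, medium, objective = obj)
    tibble::tibble(fraction = f, mu = f * mu_max,
                   production = if (s$status == "optimal") s$objective_value
                                else NA_real_,
                   status = s$status)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rba_tradeoff", class(out)), mu_max = mu_max)
}
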
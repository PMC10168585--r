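#' Assemble the growth-rate-parametric linear program
#'
#' At a fixed growth rate `mu` and growth medium, an RBA model defines a
#' linear program in the metabolic fluxes `nu_j` (one per reaction), the
#' enzyme concentrations `E_j` and the process-machine concentrations `M_p`.
#' Five row blocks are generated, with every parameter function evaluated at
#' `(mu, medium)`:
#'
#' 1. `mass_balance` -- one equality per *internal* metabolite: net
#'    production by fluxes equals the dilution-by-growth demand
#'    `mu * sum_i a_mi * c_i` for synthesizing all catalysts (and all
#'    concentration-targeted macromolecules), where `a_mi` is the precursor
#'    cost of species `i` in metabolite `m`. This is the balanced-growth
#'    condition: every component is reproduced at the rate at which growth
#'    dilutes it.
#' 2. `capacity` -- per catalysed reaction, `nu_j <= k_fwd * E_j`, and
#'    additionally `-nu_j <= k_bwd * E_j` if reversible: a flux needs enzyme
#'    to carry it.
#' 3. `process_capacity` -- per process `p`: the total synthesis workload
#'    `mu * sum_i d_ip * c_i` over the process's products may not exceed the
#'    machine capacity `k_p * M_p`.
#' 4. `density` -- per compartment: total weighted macromolecule
#'    concentration is bounded by the compartment's density capacity.
#' 5. `target` -- rows for flux targets and for concentration targets on
#'    species that have their own LP variable.
#'
#' Concentration-equality targets on macromolecules without an LP variable
#' are substituted as constants into blocks 1, 3 and 4 (fewer variables,
#' identical polytope). Dilution of small internal metabolites is *not*
#' modelled: metabolite pools are treated as steady-state intermediates. A
#' concentration target on an internal metabolite therefore only adds the
#' dilution demand `mu * c_target` of the maintained pool to its
#' mass-balance row.
#'
#' @param model a valid [rba_model()].
#' @param mu growth rate (per hour), `>= 0`.
#' @param medium an [rba_medium()].
#' @param objective named numeric vector of objective coefficients over
#'   variable names (see Details for naming), or `NULL` for a pure
#'   feasibility problem.
#' @param sense `"max"` or `"min"`.
#' @details Variables are named `flux:<reaction>`, `enzyme:<enzyme>`,
#'   `machine:<process>` and `conc:<macromolecule>` (the latter only for
#'   inequality concentration targets on species that are not part of any
#'   catalyst). Objective and analysis functions accept either these full
#'   names or bare component ids when unambiguous.
#' @return An object of class `rba_lp`: the dense coefficient matrix plus
#'   row/variable metadata. See [lp_to_dense()] for the plain matrix form.
#' @export
build_lp <- function(model, mu, medium = rba_medium(), objective = NULL,
                     sense = "max") {
  stopifnot(inherits(model, "rba_model"), is.numeric(mu), length(mu) == 1L,
            mu >= 0)
  ev <- function(fn) evaluate_parameter(fn, mu, medium)
  mm_tab <- model$macromolecules
  weights <- vapply(mm_tab, `[[`, numeric(1), "weight")
  compartment_of <- vapply(mm_tab, `[[`, character(1), "compartment")

  internals <- internal_ids(model)
  cat_ids <- catalyst_ids(model)

  # --- variables -----------------------------------------------------------
  var_name <- character(); var_kind <- character(); var_id <- character()
  lower <- numeric(); upper <- numeric()
  add_var <- function(kind, id, lo) {
    var_name <<- c(var_name, paste0(kind, ":", id))
    var_kind <<- c(var_kind, kind); var_id <<- c(var_id, id)
    lower <<- c(lower, lo); upper <<- c(upper, Inf)
  }
  for (rx in model$reactions) {
    add_var("flux", rx$id, if (rx$reversible) -Inf else 0)
  }
  for (en in model$enzymes) add_var("enzyme", en$id, 0)
  for (pr in model$processes) add_var("machine", pr$id, 0)

  # classify targets
  fixed_conc <- stats::setNames(numeric(0), character(0)) # macromolecule -> conc
  met_demand <- stats::setNames(numeric(0), character(0)) # metabolite -> conc
  var_targets <- list()  # rows on existing or dedicated variables
  flux_targets <- list()
  for (tg in model$targets) {
    val <- ev(tg$value)
    if (tg$kind %in% c("flux_eq", "flux_ge", "flux_le")) {
      flux_targets[[length(flux_targets) + 1L]] <- list(tg = tg, value = val)
    } else if (tg$subject %in% cat_ids) {
      kind <- if (tg$subject %in% names(model$enzymes)) "enzyme" else "machine"
      var_targets[[length(var_targets) + 1L]] <-
        list(tg = tg, value = val, var = paste0(kind, ":", tg$subject))
    } else if (tg$subject %in% internals) {
      add <- stats::setNames(val, tg$subject)
      met_demand <- c(met_demand, add)
    } else if (tg$kind == "concentration_eq") {
      fixed_conc[tg$subject] <- val
    } else { # concentration_ge on a plain macromolecule: own variable
      vn <- paste0("conc:", tg$subject)
      if (!vn %in% var_name) add_var("conc", tg$subject, 0)
      var_targets[[length(var_targets) + 1L]] <-
        list(tg = tg, value = val, var = vn)
    }
  }

  nv <- length(var_name)
  # macromolecule composition of each concentration variable
  composition_of <- vector("list", nv)
  for (k in seq_len(nv)) {
    composition_of[[k]] <- switch(var_kind[k],
      enzyme = model$enzymes[[var_id[k]]]$composition,
      machine = model$processes[[var_id[k]]]$machine_composition,
      conc = stats::setNames(1, var_id[k]),
      NULL)
  }

  # precursor cost a_m per concentration variable: metabolite -> amount
  precursor_of <- lapply(composition_of, function(comp) {
    if (is.null(comp)) return(NULL)
    out <- stats::setNames(numeric(0), character(0))
    for (i in seq_along(comp)) {
      pc <- mm_tab[[names(comp)[i]]]$precursor_cost * comp[[i]]
      for (m in names(pc)) out[m] <- (if (m %in% names(out)) out[[m]] else 0) + pc[[m]]
    }
    out
  })

  # --- rows ----------------------------------------------------------------
  rows <- list(); row_name <- character(); row_block <- character()
  relation <- character(); rhs <- numeric()
  add_row <- function(name, block, coefs, rel, b) {
    r <- numeric(nv)
    if (length(coefs)) {
      idx <- match(names(coefs), var_name)
      r[idx] <- as.numeric(coefs)
    }
    rows[[length(rows) + 1L]] <<- r
    row_name <<- c(row_name, name); row_block <<- c(row_block, block)
    relation <<- c(relation, rel); rhs <<- c(rhs, b)
  }

  # (1) mass balance
  for (m in internals) {
    coefs <- stats::setNames(numeric(0), character(0))
    for (rx in model$reactions) {
      s <- rx$stoichiometry
      if (m %in% names(s)) coefs[paste0("flux:", rx$id)] <- s[[m]]
    }
    if (mu > 0) {
      for (k in seq_len(nv)) {
        a <- precursor_of[[k]]
        if (!is.null(a) && m %in% names(a)) {
          coefs[var_name[k]] <-
            (if (var_name[k] %in% names(coefs)) coefs[[var_name[k]]] else 0) -
            mu * a[[m]]
        }
      }
    }
    b <- 0
    for (mm in names(fixed_conc)) {
      pc <- mm_tab[[mm]]$precursor_cost
      if (m %in% names(pc)) b <- b + mu * pc[[m]] * fixed_conc[[mm]]
    }
    if (m %in% names(met_demand)) b <- b + mu * met_demand[[m]]
    add_row(paste0("mass_balance__", m), "mass_balance", coefs, "=", b)
  }

  # (2) catalytic capacity
  for (rx in model$reactions) {
    if (is.null(rx$enzyme)) next
    en <- model$enzymes[[rx$enzyme]]
    kf <- ev(en$forward_efficiency)
    add_row(paste0("capacity_fwd__", rx$id), "capacity",
            stats::setNames(c(1, -kf),
                            c(paste0("flux:", rx$id), paste0("enzyme:", en$id))),
            "<=", 0)
    if (rx$reversible) {
      kb <- ev(en$backward_efficiency)
      add_row(paste0("capacity_bwd__", rx$id), "capacity",
              stats::setNames(c(-1, -kb),
                              c(paste0("flux:", rx$id), paste0("enzyme:", en$id))),
              "<=", 0)
    }
  }

  # (3) process capacity
  for (pr in model$processes) {
    demand_of <- function(mm) {
      if (!is.null(pr$demand_per_unit) && mm %in% names(pr$demand_per_unit)) {
        pr$demand_per_unit[[mm]]
      } else {
        weights[[mm]]
      }
    }
    coefs <- stats::setNames(-ev(pr$efficiency), paste0("machine:", pr$id))
    if (mu > 0) {
      for (k in seq_len(nv)) {
        comp <- composition_of[[k]]
        if (is.null(comp)) next
        load <- 0
        for (mm in intersect(names(comp), pr$products)) {
          load <- load + comp[[mm]] * demand_of(mm)
        }
        if (load != 0) {
          coefs[var_name[k]] <-
            (if (var_name[k] %in% names(coefs)) coefs[[var_name[k]]] else 0) +
            mu * load
        }
      }
    }
    b <- 0
    for (mm in intersect(names(fixed_conc), pr$products)) {
      b <- b - mu * demand_of(mm) * fixed_conc[[mm]]
    }
    add_row(paste0("process_capacity__", pr$id), "process_capacity",
            coefs, "<=", b)
  }

  # (4) compartment density
  for (cp in model$compartments) {
    coefs <- stats::setNames(numeric(0), character(0))
    for (k in seq_len(nv)) {
      comp <- composition_of[[k]]
      if (is.null(comp)) next
      w <- 0
      for (mm in names(comp)) {
        if (compartment_of[[mm]] == cp$id) w <- w + comp[[mm]] * weights[[mm]]
      }
      if (w != 0) coefs[var_name[k]] <- w
    }
    b <- ev(cp$density_capacity)
    for (mm in names(fixed_conc)) {
      if (compartment_of[[mm]] == cp$id) {
        b <- b - weights[[mm]] * fixed_conc[[mm]]
      }
    }
    add_row(paste0("density__", cp$id), "density", coefs, "<=", b)
  }

  # (5) target rows
  rel_of <- function(kind) switch(kind,
    concentration_eq = "=", concentration_ge = ">=",
    flux_eq = "=", flux_ge = ">=", flux_le = "<=")
  for (ft in flux_targets) {
    add_row(paste0("target__", ft$tg$id), "target",
            stats::setNames(1, paste0("flux:", ft$tg$subject)),
            rel_of(ft$tg$kind), ft$value)
  }
  for (vt in var_targets) {
    add_row(paste0("target__", vt$tg$id), "target",
            stats::setNames(1, vt$var), rel_of(vt$tg$kind), vt$value)
  }

  A <- do.call(rbind, c(rows, list(matrix(0, 0, nv))))
  dimnames(A) <- list(row_name, var_name)
  if (any(!is.finite(A)) || any(!is.finite(rhs))) {
    stop("non-finite coefficient in assembled LP", call. = FALSE)
  }

  obj <- numeric(nv)
  names(obj) <- var_name
  if (!is.null(objective)) {
    idx <- resolve_variable_names(var_name, names(objective))
    obj[idx] <- as.numeric(objective)
  }

  structure(list(
    mu = mu, medium = medium,
    variables = data.frame(name = var_name, kind = var_kind, id = var_id,
                           lower = lower, upper = upper,
                           stringsAsFactors = FALSE),
    fixed_concentrations = fixed_conc,
    A = A, relation = relation, rhs = rhs, block = row_block,
    objective = if (is.null(objective)) NULL else obj,
    sense = match.arg(sense, c("max", "min"))
  ), class = "rba_lp")
}

# Map user-facing variable references (full "kind:id" names or bare ids) to
# positions in var_name; errors on unknown or ambiguous references.
resolve_variable_names <- function(var_name, refs) {
  idx <- match(refs, var_name)
  bare_ids <- sub("^[a-z]+:", "", var_name)
  for (i in which(is.na(idx))) {
    hit <- which(bare_ids == refs[i])
    if (length(hit) == 0L) {
      stop("unknown variable '", refs[i], "'", call. = FALSE)
    }
    if (length(hit) > 1L) {
      stop("ambiguous variable '", refs[i], "': matches ",
           paste(var_name[hit], collapse = ", "), call. = FALSE)
    }
    idx[i] <- hit
  }
  idx
}

#' @export
print.rba_lp <- function(x, ...) {
  cat("<rba_lp> mu = ", x$mu, ": ", nrow(x$A), " rows x ", ncol(x$A),
      " variables\n", sep = "")
  print(table(x$block))
  invisible(x)
}

#' Extract the plain matrix form of an assembled LP
#'
#' Deterministic ordering: variables in model declaration order, rows in
#' block order (`mass_balance`, `capacity`, `process_capacity`, `density`,
#' `target`).
#'
#' @param problem an [build_lp()] result.
#' @return A list with entries `A` (dense named matrix), `relations`
#'   (`"="`, `"<="`, `">="` per row), `b`, `lower`, `upper` (variable
#'   bounds), `objective` (numeric vector, zero if none was set) and `sense`.
#' @export
lp_to_dense <- function(problem) {
  stopifnot(inherits(problem, "rba_lp"))
  list(
    A = problem$A,
    relations = problem$relation,
    b = problem$rhs,
    lower = problem$variables$lower,
    upper = problem$variables$upper,
    objective = if (is.null(problem$objective)) {
      stats::setNames(numeric(ncol(problem$A)), colnames(problem$A))
    } else {
      problem$objective
    },
    sense = problem$sense
  )
}

#' Dump the LP blocks as CSV for inspection
#'
#' Writes the coefficient matrix with named rows and columns, together with
#' the relation and right-hand side of each row, to a CSV file.
#'
#' @param problem an [build_lp()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
dump_lp_csv <- function(problem, path) {
  stopifnot(inherits(problem, "rba_lp"))
  d <- tibble::as_tibble(problem$A, rownames = "row")
  d <- dplyr::mutate(d, block = problem$block, relation = problem$relation,
                     rhs = problem$rhs)
  readr::write_csv(d, path)
  invisible(path)
}
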
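#' Components of a Resource Balance Analysis model
#'
#' An RBA model describes the production and consumption processes of a whole
#' cell: metabolic reactions and the enzymes catalysing them, macromolecular
#' processes (translation, folding, transport) and the machines carrying them
#' out, the compartments whose limited space bounds total macromolecule
#' concentrations, and empirical target constraints. These constructors build
#' the individual components; [rba_model()] assembles them.
#'
#' Units convention (documented, not enforced): concentrations in mmol per
#' gram dry weight, fluxes in mmol/gDW/h, time in hours, macromolecule
#' weights in amino-acid equivalents, medium concentrations in mM.
#'
#' @param id component identifier (unique across the whole model).
#' @param density_capacity maximum weighted macromolecule concentration the
#'   compartment can hold (a parameter function of the growth rate, or a
#'   number for a constant capacity).
#' @param external is the metabolite a boundary species whose concentration
#'   is fixed by the growth [rba_medium()]? External metabolites carry no
#'   mass-balance constraint.
#' @param weight density weight of one macromolecule unit (e.g. amino-acid
#'   chain length); contributes `weight * concentration` to its
#'   compartment's density constraint.
#' @param compartment id of the compartment housing the macromolecule.
#' @param precursor_cost named numeric vector, internal metabolite id ->
#'   amount consumed per macromolecule unit synthesized.
#' @param producing_process id of the process whose machinery synthesizes
#'   this macromolecule, or `NULL`.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param reversible can the reaction carry negative flux?
#' @param enzyme id of the catalysing enzyme, or `NULL` for a spontaneous
#'   reaction.
#' @param composition,machine_composition named numeric vector, macromolecule
#'   id -> copy number per catalyst unit.
#' @param forward_efficiency,backward_efficiency apparent catalytic
#'   efficiency k_app (flux per unit enzyme concentration); parameter
#'   functions or numbers. `backward_efficiency` is required iff the
#'   catalysed reaction is reversible.
#' @param efficiency process-machine efficiency k_p (processing capacity per
#'   machine unit per hour).
#' @param products macromolecule ids synthesized by the process.
#' @param demand_per_unit named numeric vector, product macromolecule id ->
#'   machine capacity consumed per unit synthesized. Defaults to each
#'   product's weight.
#' @param kind target kind: `"concentration_eq"`, `"concentration_ge"`
#'   (subject: macromolecule, enzyme, process machine or internal
#'   metabolite), or `"flux_eq"`, `"flux_ge"`, `"flux_le"` (subject: a
#'   reaction).
#' @param subject id the target constrains.
#' @param value target value (parameter function or number).
#' @return A component object of class `rba_compartment`, `rba_metabolite`,
#'   `rba_macromolecule`, `rba_reaction`, `rba_enzyme`, `rba_process` or
#'   `rba_target`.
#' @name model-components
NULL

as_parameter <- function(x, what = "parameter") {
  if (inherits(x, "rba_parameter")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(pf_constant(x))
  stop(what, " must be a parameter function or a single number")
}

check_id <- function(id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("id must be a non-empty string")
  }
  id
}

named_numeric <- function(x, what) {
  x <- unlist(x)
  if (length(x) == 0L) return(stats::setNames(numeric(), character()))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " must be a named numeric vector")
  }
  stats::setNames(as.numeric(x), names(x))
}

#' @rdname model-components
#' @export
rba_compartment <- function(id, density_capacity) {
  structure(list(id = check_id(id),
                 density_capacity = as_parameter(density_capacity, "density_capacity")),
            class = "rba_compartment")
}

#' @rdname model-components
#' @export
rba_metabolite <- function(id, external = FALSE) {
  structure(list(id = check_id(id), external = isTRUE(external)),
            class = "rba_metabolite")
}

#' @rdname model-components
#' @export
rba_macromolecule <- function(id, weight, compartment, precursor_cost,
                              producing_process = NULL) {
  structure(list(
    id = check_id(id), weight = as.numeric(weight), compartment = compartment,
    precursor_cost = named_numeric(precursor_cost, "precursor_cost"),
    producing_process = producing_process
  ), class = "rba_macromolecule")
}

#' @rdname model-components
#' @export
rba_reaction <- function(id, stoichiometry, reversible = FALSE, enzyme = NULL) {
  structure(list(
    id = check_id(id),
    stoichiometry = named_numeric(stoichiometry, "stoichiometry"),
    reversible = isTRUE(reversible), enzyme = enzyme
  ), class = "rba_reaction")
}

#' @rdname model-components
#' @export
rba_enzyme <- function(id, composition, forward_efficiency,
                       backward_efficiency = NULL) {
  structure(list(
    id = check_id(id),
    composition = named_numeric(composition, "composition"),
    forward_efficiency = as_parameter(forward_efficiency, "forward_efficiency"),
    backward_efficiency = if (!is.null(backward_efficiency))
      as_parameter(backward_efficiency, "backward_efficiency")
  ), class = "rba_enzyme")
}

#' @rdname model-components
#' @export
rba_process <- function(id, machine_composition, efficiency, products,
                        demand_per_unit = NULL) {
  structure(list(
    id = check_id(id),
    machine_composition = named_numeric(machine_composition, "machine_composition"),
    efficiency = as_parameter(efficiency, "efficiency"),
    products = as.character(products),
    demand_per_unit = if (!is.null(demand_per_unit))
      named_numeric(demand_per_unit, "demand_per_unit")
  ), class = "rba_process")
}

#' @rdname model-components
#' @export
rba_target <- function(id, kind, subject, value) {
  kinds <- c("concentration_eq", "concentration_ge",
             "flux_eq", "flux_ge", "flux_le")
  if (!kind %in% kinds) {
    stop("target kind must be one of ", paste(kinds, collapse = ", "))
  }
  structure(list(id = check_id(id), kind = kind, subject = subject,
                 value = as_parameter(value, "target value")),
            class = "rba_target")
}

named_by_id <- function(xs) {
  if (length(xs) == 0L) return(stats::setNames(list(), character()))
  stats::setNames(xs, vapply(xs, `[[`, character(1), "id"))
}

#' Assemble an RBA model
#'
#' @param name model name (free text).
#' @param compartments,metabolites,macromolecules,reactions,enzymes,processes,targets
#'   lists of the corresponding components (see [model-components]).
#' @return An object of class `rba_model`. Use [validate_model()] to check
#'   cross-references and invariants.
#' @seealso [make_self_replicator()] and friends for ready-made small models.
#' @export
rba_model <- function(name, compartments = list(), metabolites = list(),
                      macromolecules = list(), reactions = list(),
                      enzymes = list(), processes = list(), targets = list()) {
  structure(list(
    name = name,
    compartments = named_by_id(compartments),
    metabolites = named_by_id(metabolites),
    macromolecules = named_by_id(macromolecules),
    reactions = named_by_id(reactions),
    enzymes = named_by_id(enzymes),
    processes = named_by_id(processes),
    targets = named_by_id(targets)
  ), class = "rba_model")
}

#' @export
print.rba_model <- function(x, ...) {
  cat("<rba_model> ", x$name, "\n", sep = "")
  for (coll in c("compartments", "metabolites", "macromolecules", "reactions",
                 "enzymes", "processes", "targets")) {
    cat("  ", coll, ": ", length(x[[coll]]), "\n", sep = "")
  }
  invisible(x)
}

external_ids <- function(model) {
  ids <- names(model$metabolites)
  ids[vapply(model$metabolites, `[[`, logical(1), "external")]
}

internal_ids <- function(model) {
  setdiff(names(model$metabolites), external_ids(model))
}

# Is the subject of a concentration target a species with its own LP
# variable (enzyme or process machine)?
catalyst_ids <- function(model) c(names(model$enzymes), names(model$processes))

# Evaluate fn on a mu grid, using a probe medium that defines every external
# metabolite the function references at several concentrations; returns TRUE
# if all values are finite and >= 0.
parameter_nonnegative <- function(fn, mu_max = 10) {
  args <- parameter_arguments(fn)
  conc_grid <- c(0, 0.01, 1, 1e6)
  mus <- c(0, 0.1, 1, mu_max)
  for (conc in conc_grid) {
    med <- rba_medium(stats::setNames(rep(conc, length(args)), args))
    for (mu in mus) {
      v <- tryCatch(evaluate_parameter(fn, mu, med), error = function(e) NA_real_)
      if (is.na(v) || !is.finite(v) || v < 0) return(FALSE)
    }
  }
  TRUE
}

#' Validate an RBA model
#'
#' Checks all structural invariants -- resolvable cross-references, unique
#' identifiers, positive weights, well-formed parameter functions -- and
#' returns diagnostics rather than raising errors, so that partially built
#' models can be inspected.
#'
#' @param model an [rba_model()].
#' @return A tibble with columns `component` (collection), `id` (offending
#'   component) and `message` (the violated rule). Zero rows iff the model is
#'   valid.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "rba_model"))
  bad <- list()
  flag <- function(component, id, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      component = component, id = id, message = message)
  }

  if (length(model$compartments) == 0L) {
    flag("model", model$name, "model must declare at least one compartment")
  }
  all_ids <- c(names(model$compartments), names(model$metabolites),
               names(model$macromolecules), names(model$reactions),
               names(model$enzymes), names(model$processes),
               names(model$targets))
  dup <- unique(all_ids[duplicated(all_ids)])
  for (d in dup) flag("model", d, "duplicate identifier")

  internals <- internal_ids(model)

  for (cp in model$compartments) {
    if (!parameter_nonnegative(cp$density_capacity)) {
      flag("compartment", cp$id,
           "density_capacity must evaluate finite and >= 0 for all mu >= 0")
    }
  }

  for (mm in model$macromolecules) {
    if (!is.finite(mm$weight) || mm$weight <= 0) {
      flag("macromolecule", mm$id, "weight must be > 0")
    }
    if (!mm$compartment %in% names(model$compartments)) {
      flag("macromolecule", mm$id,
           paste0("unknown compartment '", mm$compartment, "'"))
    }
    miss <- setdiff(names(mm$precursor_cost), internals)
    for (m in miss) {
      flag("macromolecule", mm$id,
           paste0("precursor_cost references '", m,
                  "', which is not an internal metabolite"))
    }
    if (any(mm$precursor_cost <= 0)) {
      flag("macromolecule", mm$id, "precursor_cost entries must be > 0")
    }
    if (!is.null(mm$producing_process)) {
      pp <- model$processes[[mm$producing_process]]
      if (is.null(pp)) {
        flag("macromolecule", mm$id,
             paste0("unknown producing_process '", mm$producing_process, "'"))
      } else if (!mm$id %in% pp$products) {
        flag("macromolecule", mm$id,
             paste0("producing_process '", pp$id,
                    "' does not list it among its products"))
      }
    }
  }

  enzyme_use <- table(unlist(lapply(model$reactions, `[[`, "enzyme")))
  for (rx in model$reactions) {
    if (length(rx$stoichiometry) == 0L) {
      flag("reaction", rx$id, "stoichiometry must be non-empty")
    }
    miss <- setdiff(names(rx$stoichiometry), names(model$metabolites))
    for (m in miss) {
      flag("reaction", rx$id, paste0("unknown metabolite '", m, "'"))
    }
    if (!is.null(rx$enzyme) && !rx$enzyme %in% names(model$enzymes)) {
      flag("reaction", rx$id, paste0("unknown enzyme '", rx$enzyme, "'"))
    }
  }

  for (en in model$enzymes) {
    miss <- setdiff(names(en$composition), names(model$macromolecules))
    for (m in miss) {
      flag("enzyme", en$id, paste0("unknown macromolecule '", m, "'"))
    }
    n_use <- if (en$id %in% names(enzyme_use)) enzyme_use[[en$id]] else 0L
    if (n_use != 1L) {
      flag("enzyme", en$id,
           paste0("must be referenced by exactly one reaction (found ", n_use, ")"))
    } else {
      rx <- Filter(function(r) identical(r$enzyme, en$id), model$reactions)[[1]]
      if (rx$reversible && is.null(en$backward_efficiency)) {
        flag("enzyme", en$id,
             "catalyses a reversible reaction but has no backward_efficiency")
      }
      if (!rx$reversible && !is.null(en$backward_efficiency)) {
        flag("enzyme", en$id,
             "has a backward_efficiency but its reaction is irreversible")
      }
    }
    if (!parameter_nonnegative(en$forward_efficiency)) {
      flag("enzyme", en$id, "forward_efficiency must evaluate finite and >= 0")
    }
    if (!is.null(en$backward_efficiency) &&
        !parameter_nonnegative(en$backward_efficiency)) {
      flag("enzyme", en$id, "backward_efficiency must evaluate finite and >= 0")
    }
  }

  for (pr in model$processes) {
    miss <- setdiff(names(pr$machine_composition), names(model$macromolecules))
    for (m in miss) {
      flag("process", pr$id, paste0("unknown macromolecule '", m, "'"))
    }
    miss <- setdiff(pr$products, names(model$macromolecules))
    for (m in miss) {
      flag("process", pr$id, paste0("unknown product macromolecule '", m, "'"))
    }
    if (!is.null(pr$demand_per_unit)) {
      extra <- setdiff(names(pr$demand_per_unit), pr$products)
      for (m in extra) {
        flag("process", pr$id,
             paste0("demand_per_unit key '", m, "' is not among the products"))
      }
    }
    if (!parameter_nonnegative(pr$efficiency)) {
      flag("process", pr$id, "efficiency must evaluate finite and >= 0")
    }
  }

  conc_subjects <- c(names(model$macromolecules), internals, catalyst_ids(model))
  for (tg in model$targets) {
    if (tg$kind %in% c("concentration_eq", "concentration_ge")) {
      if (tg$subject %in% external_ids(model)) {
        flag("target", tg$id,
             "concentration targets on external metabolites are invalid")
      } else if (!tg$subject %in% conc_subjects) {
        flag("target", tg$id, paste0("unknown concentration subject '",
                                     tg$subject, "'"))
      }
    } else {
      if (!tg$subject %in% names(model$reactions)) {
        flag("target", tg$id, paste0("unknown reaction '", tg$subject, "'"))
      }
    }
    if (!parameter_nonnegative(tg$value)) {
      flag("target", tg$id, "target value must evaluate finite and >= 0")
    }
  }

  if (length(bad) == 0L) {
    tibble::tibble(component = character(), id = character(),
                   message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

stop_if_invalid <- function(model) {
  d <- validate_model(model)
  if (nrow(d) > 0L) {
    stop("invalid RBA model:\n",
         paste0("  [", d$component, " ", d$id, "] ", d$message, collapse = "\n"),
         call. = FALSE)
  }
  invisible(model)
}
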
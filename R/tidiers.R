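#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solved cell state
#'
#' @param x an `rba_solution`.
#' @param ... unused.
#' @return One row per state variable: `kind` (`flux`, `enzyme`, `machine`,
#'   `target_concentration`), `id`, `value`.
#' @method tidy rba_solution
#' @export
tidy.rba_solution <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(kind = "flux", id = names(x$fluxes),
                   value = unname(x$fluxes)),
    tibble::tibble(kind = "enzyme", id = names(x$enzyme_concentrations),
                   value = unname(x$enzyme_concentrations)),
    tibble::tibble(kind = "machine", id = names(x$machine_concentrations),
                   value = unname(x$machine_concentrations)),
    tibble::tibble(kind = "target_concentration",
                   id = c(names(x$target_concentrations),
                          names(x$fixed_concentrations)),
                   value = c(unname(x$target_concentrations),
                             unname(x$fixed_concentrations)))
  )
}

#' One-row summary of a solved cell state
#'
#' @param x an `rba_solution`.
#' @param ... unused.
#' @method glance rba_solution
#' @export
glance.rba_solution <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, status = x$status, objective_value = x$objective_value,
    n_fluxes = length(x$fluxes),
    n_enzymes = length(x$enzyme_concentrations),
    n_machines = length(x$machine_concentrations)
  )
}

#' Plot methods for analysis results
#'
#' `autoplot()` methods give quick default visualizations: Monod or
#' parameter-screen curves (`rba_screen`), growth-rate histograms
#' (`rba_ensemble`), sensitivity bar charts (`rba_sensitivity`), feasible
#' ranges versus growth (`rba_rva`), Pareto fronts (`rba_pareto`) and
#' production/fitness trade-offs (`rba_tradeoff`).
#'
#' @param object an analysis result.
#' @param ... unused.
#' @return A ggplot object.
#' @name rba-autoplot
NULL

#' @rdname rba-autoplot
#' @method autoplot rba_screen
#' @export
autoplot.rba_screen <- function(object, ...) {
  axis <- attr(object, "axis")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[axis]], y = .data$mu_max)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "axis_label"),
                  y = expression(mu[max] ~ (h^-1)))
  vals <- object[[axis]]
  if (all(vals > 0) && max(vals) / max(min(vals), 1e-12) > 50) {
    p <- p + ggplot2::scale_x_log10()
  }
  p
}

#' @rdname rba-autoplot
#' @method autoplot rba_ensemble
#' @export
autoplot.rba_ensemble <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mu_max)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(x = expression(mu[max] ~ (h^-1)), y = "models")
}

#' @rdname rba-autoplot
#' @method autoplot rba_sensitivity
#' @export
autoplot.rba_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$parameter,
                                                  .data$sensitivity),
                               y = .data$sensitivity)) +
    ggplot2::geom_col() + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = expression(d * ln(mu[max]) / d * ln(k[app])))
}

#' @rdname rba-autoplot
#' @method autoplot rba_rva
#' @export
autoplot.rba_rva <- function(object, ...) {
  xvar <- if ("fraction" %in% names(object)) "fraction" else "mu"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$max)) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = if (xvar == "fraction") "relative fitness" else
                    expression(mu ~ (h^-1)),
                  y = "feasible range")
}

#' @rdname rba-autoplot
#' @method autoplot rba_pareto
#' @export
autoplot.rba_pareto <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$b_level, y = .data$value_a)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "objective B level", y = "maximal objective A")
}

#' @rdname rba-autoplot
#' @method autoplot rba_tradeoff
#' @export
autoplot.rba_tradeoff <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fraction, y = .data$production)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "relative fitness (mu / mu_max)", y = "production flux")
}
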
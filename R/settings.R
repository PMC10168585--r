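#' Numerical settings shared by all analyses
#'
#' @param bisection_tol relative tolerance on the growth rate in all
#'   bisections (growth maximization, minimum-substrate inference).
#' @param fd_step half-step `delta` of the symmetric log-space finite
#'   difference used for local sensitivities; default `ln(1.01)`, i.e.
#'   parameters perturbed by +/- 1 percent.
#' @param ensemble_sigma standard deviation of `ln(x)` for the random
#'   efficiency-scaling factors of [sample_ensemble()]; default `ln(1.1)`
#'   (about 10 percent parameter uncertainty).
#' @param ensemble_n number of models in the sampled ensemble.
#' @param seed RNG seed used by stochastic analyses.
#' @param mu_scan_max upper cap of the growth-rate bracket (per hour); a
#'   model still feasible here is flagged as pathological.
#' @param pareto_points number of epsilon-constraint levels per Pareto front.
#' @return An object of class `rba_settings`.
#' @export
analysis_settings <- function(bisection_tol = 1e-6,
                              fd_step = log(1.01),
                              ensemble_sigma = log(1.1),
                              ensemble_n = 1000L,
                              seed = 42L,
                              mu_scan_max = 10,
                              pareto_points = 20L) {
  stopifnot(bisection_tol > 0, fd_step > 0, ensemble_sigma >= 0,
            ensemble_n >= 1, mu_scan_max > 0, pareto_points >= 2)
  structure(list(
    bisection_tol = bisection_tol, fd_step = fd_step,
    ensemble_sigma = ensemble_sigma, ensemble_n = as.integer(ensemble_n),
    seed = as.integer(seed), mu_scan_max = mu_scan_max,
    pareto_points = as.integer(pareto_points)
  ), class = "rba_settings")
}
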
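#' Self-replicator toy models with closed-form optima
#'
#' Small RBA models whose maximal growth rates (and, for some, whole optimal
#' states) are known in closed form. They are the package's test and demo
#' substrate: every algorithm in the package can be validated against them
#' at desk scale, without a genome-scale model.
#'
#' All generators share a single compartment (`cytosol`), an external
#' nutrient (`nutrient_ext`), an internal `precursor` pool, a transport /
#' uptake reaction `R_uptake` catalysed by enzyme `E_uptake`, and a
#' `translation` process whose machine (`ribosome`, built from
#' `ribosome_protein`) synthesizes every protein. Proteins cost their own
#' weight in precursor and load the translation machinery with their weight.
#'
#' **`make_self_replicator()`** -- the minimal cell: enzyme and ribosome
#' reproduce themselves. Closed form:
#' \deqn{\mu_{max} = \frac{1}{n_E/k_E + n_R/k_R}}
#' independent of the density capacity `D` (the model is homogeneous: states
#' scale freely below the density bound).
#'
#' **`make_pinned_replicator()`** -- adds a `housekeeping_protein` with a
#' fixed concentration target `c0` (growth-independent maintenance
#' proteome). The target pins the state's scale, and the density constraint
#' becomes limiting:
#' \deqn{\mu_{max} = \frac{1 - n_H c_0 / D}{n_E/k_E + n_R/k_R}}
#' At the optimum with symmetric parameters `k_E = k_R = 2`, `n = 1`,
#' `c0 = 0.2`, `D = 1`: `E = M = 0.4` and the density row is tight
#' (`0.4 + 0.4 + 0.2 = 1`). The optimum is unique, so Resource Variability
#' Analysis collapses to a point at `mu_max`.
#'
#' **`make_mm_importer()`** -- a pinned replicator whose uptake enzyme has
#' Michaelis-Menten efficiency `vmax * c / (km + c)` in the external
#' nutrient concentration `c`. Gives a Monod curve:
#' \deqn{\mu_{max}(c) = \frac{1 - c_0/D}{\frac{km + c}{vmax\, c} + 1/k_R}}
#'
#' **`make_overflow_branch()`** -- Michaelis-Menten import feeding two
#' alternative precursor-producing pathways: `R_respiration` (high yield
#' `yield_resp`, low efficiency `k_resp`) and `R_overflow` (low yield
#' `yield_ferm`, high efficiency `k_ferm`, secreting `byproduct_ext`). At
#' low external nutrient the import enzyme is expensive, substrate yield
#' dominates and the high-yield pathway wins; at high nutrient the
#' proteome cost of catalysis dominates and the cell switches to the
#' low-yield, fast pathway with byproduct secretion. The switch happens
#' where the proteome costs per unit precursor are equal, at import
#' efficiency
#' \deqn{k_T^* = \frac{1/y_H - 1/y_L}{1/(y_L k_L) - 1/(y_H k_H)}}
#' i.e. at nutrient concentration `c* = km * kT* / (vmax - kT*)` (defaults:
#' `c* = 1`). A parameter set for which the low-yield pathway never becomes
#' cheaper (`yield_resp * k_resp >= yield_ferm * k_ferm`) cannot switch and
#' is rejected.
#'
#' **`make_secretion()`** -- a pinned replicator plus a product-synthesis
#' reaction `R_product` (precursor -> external product, enzyme `E_product`,
#' efficiency `k_product`). At the maximal growth rate all resources go to
#' growth and production is zero; at sub-maximal growth the slack can be
#' redirected, giving growth/production trade-off curves. With
#' `second_product = TRUE` a second, independent sink (`R_product_2`) is
#' added, so that production-vs-production Pareto fronts at fixed growth
#' are exactly linear (the two sinks compete for one shared resource
#' budget).
#'
#' @param k_enzyme,k_process forward efficiency of the uptake enzyme and
#'   efficiency of the translation machine (per hour).
#' @param n_enzyme,n_process,n_housekeeping protein weights (amino-acid
#'   equivalents) of the uptake enzyme, ribosome and housekeeping protein.
#' @param density density capacity `D` of the cytosol.
#' @param conc_housekeeping fixed concentration target `c0` of the
#'   housekeeping protein; must satisfy `n_housekeeping * c0 < density`.
#' @param vmax,km Michaelis-Menten parameters of the import efficiency.
#' @param yield_resp,k_resp,yield_ferm,k_ferm yield (precursor per nutrient)
#'   and catalytic efficiency of the respiration-like and overflow-like
#'   pathways.
#' @param k_product efficiency of the product-synthesis enzyme.
#' @param second_product add a second product sink?
#' @return A validated [rba_model()].
#' @examples
#' maximize_growth(make_self_replicator(2, 6))$mu  # 1 / (1/2 + 1/6) = 1.5
#' @name toy-models
NULL

toy_core <- function(k_process, n_enzyme, n_process, density,
                     uptake_efficiency, extra = list()) {
  proteins <- c(list(
    rba_macromolecule("enzyme_protein", weight = n_enzyme,
                      compartment = "cytosol",
                      precursor_cost = c(precursor = n_enzyme),
                      producing_process = "translation"),
    rba_macromolecule("ribosome_protein", weight = n_process,
                      compartment = "cytosol",
                      precursor_cost = c(precursor = n_process),
                      producing_process = "translation")
  ), extra$macromolecules %||% list())
  rba_model(
    name = extra$name %||% "self_replicator",
    compartments = list(rba_compartment("cytosol", density)),
    metabolites = c(list(
      rba_metabolite("nutrient_ext", external = TRUE),
      rba_metabolite("precursor")
    ), extra$metabolites %||% list()),
    macromolecules = proteins,
    reactions = c(list(
      rba_reaction("R_uptake", c(nutrient_ext = -1, precursor = 1),
                   enzyme = "E_uptake")
    ), extra$reactions %||% list()),
    enzymes = c(list(
      rba_enzyme("E_uptake", c(enzyme_protein = 1), uptake_efficiency)
    ), extra$enzymes %||% list()),
    processes = list(
      rba_process("translation",
                  machine_composition = c(ribosome_protein = 1),
                  efficiency = k_process,
                  products = vapply(proteins, `[[`, character(1), "id"))
    ),
    targets = extra$targets %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname toy-models
#' @export
make_self_replicator <- function(k_enzyme = 2, k_process = 2, n_enzyme = 1,
                                 n_process = 1, density = 1) {
  stopifnot(k_enzyme > 0, k_process > 0, n_enzyme > 0, n_process > 0,
            density > 0)
  m <- toy_core(k_process, n_enzyme, n_process, density,
                uptake_efficiency = k_enzyme)
  stop_if_invalid(m)
}

housekeeping_extra <- function(n_housekeeping, conc_housekeeping) {
  list(
    macromolecules = list(
      rba_macromolecule("housekeeping_protein", weight = n_housekeeping,
                        compartment = "cytosol",
                        precursor_cost = c(precursor = n_housekeeping),
                        producing_process = "translation")
    ),
    targets = list(
      rba_target("housekeeping_level", "concentration_eq",
                 "housekeeping_protein", conc_housekeeping)
    )
  )
}

#' @rdname toy-models
#' @export
make_pinned_replicator <- function(k_enzyme = 2, k_process = 2, n_enzyme = 1,
                                   n_process = 1, n_housekeeping = 1,
                                   conc_housekeeping = 0.2, density = 1) {
  stopifnot(k_enzyme > 0, k_process > 0, n_enzyme > 0, n_process > 0,
            n_housekeeping > 0, conc_housekeeping >= 0, density > 0)
  if (n_housekeeping * conc_housekeeping >= density) {
    stop("structurally infeasible: the housekeeping target alone ",
         "(n_housekeeping * conc_housekeeping = ",
         n_housekeeping * conc_housekeeping,
         ") fills the density capacity ", density, call. = FALSE)
  }
  extra <- housekeeping_extra(n_housekeeping, conc_housekeeping)
  extra$name <- "pinned_replicator"
  m <- toy_core(k_process, n_enzyme, n_process, density,
                uptake_efficiency = k_enzyme, extra = extra)
  stop_if_invalid(m)
}

#' @rdname toy-models
#' @export
make_mm_importer <- function(vmax = 2, km = 0.1, k_process = 2,
                             conc_housekeeping = 0.2, density = 1) {
  stopifnot(vmax > 0, km > 0, k_process > 0, conc_housekeeping >= 0,
            density > 0, conc_housekeeping < density)
  extra <- housekeeping_extra(1, conc_housekeeping)
  extra$name <- "mm_importer"
  m <- toy_core(k_process, n_enzyme = 1, n_process = 1, density,
                uptake_efficiency = pf_michaelis_menten(vmax, km, "nutrient_ext"),
                extra = extra)
  stop_if_invalid(m)
}

#' @rdname toy-models
#' @export
make_overflow_branch <- function(vmax = 4, km = 1,
                                 yield_resp = 2, k_resp = 1,
                                 yield_ferm = 1, k_ferm = 4,
                                 k_process = 2, conc_housekeeping = 0.2,
                                 density = 1) {
  stopifnot(vmax > 0, km > 0, yield_resp > 0, k_resp > 0, yield_ferm > 0,
            k_ferm > 0, k_process > 0, conc_housekeeping >= 0, density > 0)
  if (yield_resp <= yield_ferm) {
    stop("the respiration-like pathway must have the higher yield ",
         "(yield_resp > yield_ferm)", call. = FALSE)
  }
  if (yield_resp * k_resp >= yield_ferm * k_ferm) {
    stop("these parameters never switch to overflow: at saturating import ",
         "the high-yield pathway is still cheaper ",
         "(yield_resp * k_resp >= yield_ferm * k_ferm)", call. = FALSE)
  }
  kt_star <- (1 / yield_resp - 1 / yield_ferm) /
    (1 / (yield_ferm * k_ferm) - 1 / (yield_resp * k_resp))
  if (kt_star >= vmax) {
    stop("switch point unreachable: required import efficiency ", kt_star,
         " exceeds vmax = ", vmax, call. = FALSE)
  }

  protein <- function(id) {
    rba_macromolecule(id, weight = 1, compartment = "cytosol",
                      precursor_cost = c(precursor = 1),
                      producing_process = "translation")
  }
  extra <- list(
    name = "overflow_branch",
    metabolites = list(
      rba_metabolite("sugar"),
      rba_metabolite("byproduct_ext", external = TRUE)
    ),
    macromolecules = c(
      list(protein("respiration_protein"), protein("overflow_protein")),
      housekeeping_extra(1, conc_housekeeping)$macromolecules
    ),
    reactions = list(
      rba_reaction("R_respiration",
                   c(sugar = -1, precursor = yield_resp),
                   enzyme = "E_respiration"),
      rba_reaction("R_overflow",
                   c(sugar = -1, precursor = yield_ferm, byproduct_ext = 1),
                   enzyme = "E_overflow")
    ),
    enzymes = list(
      rba_enzyme("E_respiration", c(respiration_protein = 1), k_resp),
      rba_enzyme("E_overflow", c(overflow_protein = 1), k_ferm)
    ),
    targets = housekeeping_extra(1, conc_housekeeping)$targets
  )
  m <- toy_core(k_process, n_enzyme = 1, n_process = 1, density,
                uptake_efficiency = pf_michaelis_menten(vmax, km, "nutrient_ext"),
                extra = extra)
  # import makes sugar, pathways consume it
  m$reactions$R_uptake$stoichiometry <- c(nutrient_ext = -1, sugar = 1)
  attr(m, "switch_concentration") <- km * kt_star / (vmax - kt_star)
  stop_if_invalid(m)
}

#' @rdname toy-models
#' @export
make_secretion <- function(k_enzyme = 2, k_process = 2, k_product = 1,
                           conc_housekeeping = 0.2, density = 1,
                           second_product = FALSE) {
  stopifnot(k_enzyme > 0, k_process > 0, k_product > 0,
            conc_housekeeping >= 0, density > 0, conc_housekeeping < density)
  protein <- function(id) {
    rba_macromolecule(id, weight = 1, compartment = "cytosol",
                      precursor_cost = c(precursor = 1),
                      producing_process = "translation")
  }
  extra <- housekeeping_extra(1, conc_housekeeping)
  extra$name <- "secretion"
  extra$metabolites <- list(rba_metabolite("product_ext", external = TRUE))
  extra$macromolecules <- c(extra$macromolecules, list(protein("product_protein")))
  extra$reactions <- list(
    rba_reaction("R_product", c(precursor = -1, product_ext = 1),
                 enzyme = "E_product")
  )
  extra$enzymes <- list(
    rba_enzyme("E_product", c(product_protein = 1), k_product)
  )
  if (second_product) {
    extra$metabolites <- c(extra$metabolites,
                           list(rba_metabolite("product2_ext", external = TRUE)))
    extra$macromolecules <- c(extra$macromolecules,
                              list(protein("product2_protein")))
    extra$reactions <- c(extra$reactions, list(
      rba_reaction("R_product_2", c(precursor = -1, product2_ext = 1),
                   enzyme = "E_product_2")
    ))
    extra$enzymes <- c(extra$enzymes, list(
      rba_enzyme("E_product_2", c(product2_protein = 1), k_product)
    ))
  }
  m <- toy_core(k_process, n_enzyme = 1, n_process = 1, density,
                uptake_efficiency = k_enzyme, extra = extra)
  stop_if_invalid(m)
}
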
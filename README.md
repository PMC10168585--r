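# rbakit

Resource Balance Analysis (RBA) in R: build, edit, solve and analyse
whole-cell resource-allocation models.

## The problem

Constraint-based metabolic models (FBA) predict fluxes but assume a fixed
biomass recipe and ignore what catalysis costs. RBA closes that loop: every
flux needs enzyme, every enzyme needs to be translated by ribosomes,
ribosomes need to translate themselves too, and everything dilutes as the
cell grows. A cell state is a vector of metabolic fluxes `v_j`, enzyme
concentrations `E_j` and macromolecular-machine concentrations `M_p`
satisfying four families of constraints at growth rate `mu`:

* **mass balance** (balanced growth): for each internal metabolite `m`,
  `sum_j S_mj v_j = mu * sum_i a_mi c_i` — net production covers the
  dilution-by-growth demand of all macromolecular components `i` with
  precursor costs `a_mi`;
* **catalytic capacity**: `v_j <= k_app,j E_j` (and the reverse bound for
  reversible reactions);
* **process capacity**: for each process `p` (e.g. translation),
  `mu * sum_i d_ip c_i <= k_p M_p` — the synthesis workload may not exceed
  machine capacity;
* **density**: `sum_i w_i c_i <= D_c` per compartment — limited cellular
  space;

plus empirical **target** constraints (known concentrations or fluxes).
All of this is linear *at fixed `mu`*, but the coefficients depend on `mu`
(and on the medium, through transporter efficiencies), so the maximal
growth rate is found by bisection on the feasibility of this
growth-rate-parametric linear program. Above some `mu*` no balanced-growth
state exists; `mu*` is the predicted growth rate and the state at `mu*` the
predicted phenotype (fluxes plus quantitative proteome).

The package is aimed at systems/synthetic biologists who want to script RBA
workflows: growth maximization, Monod curves and medium screens, parameter
screens, local sensitivities `d ln(mu_max)/d ln(k_app)`, global
(ensemble) sensitivity sampling, Resource Variability Analysis (RVA — the
RBA analogue of FVA), epsilon-constraint Pareto fronts, and
growth-vs-production trade-off curves. Models are directories of
SBtab-flavoured TSV tables; solutions export to CSV/SBtab and to Escher and
Proteomaps data files. A family of small self-replicator models with
closed-form optima serves for testing, teaching and demos.

## Worked example

The pinned self-replicator has one uptake enzyme (`k_E = 2 /h`), a
translation machine (`k_R = 2 /h`), a housekeeping protein pinned at
concentration 0.2 and a density capacity of 1. Its maximal growth rate is
known in closed form: `mu_max = (1 - 0.2/1) / (1/2 + 1/2) = 0.8`.

```r
library(rbakit)

toy <- make_pinned_replicator()   # kE = kR = 2, c0 = 0.2, D = 1
sol <- maximize_growth(toy)
sol
#> <rba_solution> status = optimal, mu = 0.79999995
#>   objective: 0.79999999
#>   fluxes: R_uptake = 0.8

tidy(sol)
#> # A tibble: 4 × 3
#>   kind                 id                   value
#>   <chr>                <chr>                <dbl>
#> 1 flux                 R_uptake             0.800
#> 2 enzyme               E_uptake             0.400
#> 3 machine              translation          0.400
#> 4 target_concentration housekeeping_protein 0.2
```

At the optimum the density constraint is tight (0.4 + 0.4 + 0.2 = 1):
enzyme and ribosome each claim 40% of the cell's space, and the uptake flux
0.8 exactly covers dilution of the whole proteome at `mu = 0.8`. Below the
maximal growth rate the cell has slack; RVA quantifies it:

```r
variability_analysis(toy, mu = 0.4, variable_ids = "machine:translation")
#> # A tibble: 1 × 6
#>      mu variable               min   max status_min status_max
#>   <dbl> <chr>                <dbl> <dbl> <chr>      <chr>
#> 1   0.4 machine:translation 0.0667 0.600 optimal    optimal
```

At half-maximal growth the ribosome concentration can range from 1/15 to
0.6; at `mu = 0.8` the range collapses to the single point 0.4 — the
growth-optimal state is unique. Sensitivities confirm the symmetric design:

```r
local_sensitivities(toy)
#> # A tibble: 2 × 3
#>   parameter   sensitivity mu_ref
#>   <chr>             <dbl>  <dbl>
#> 1 E_uptake          0.500  0.800
#> 2 translation       0.500  0.800
```

Each `autoplot()`-able analysis has a tibble result: try
`autoplot(medium_screen(make_mm_importer(), "nutrient_ext", 10^seq(-3, 2, 0.25)))`
for a Monod curve, or `sample_ensemble()` on `make_overflow_branch()` at
its switch concentration for a bimodal flux distribution. A command-line
interface (`exec/rbakit`: `solve`, `monod`, `screen`, `sens`, `sample`,
`rva`, `pareto`, `tradeoff`, `model`) wraps the same functions for shell
pipelines.

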
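---
title: "Resource Balance Analysis with rbakit: model, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource Balance Analysis with rbakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbakit)
```

## The model

Resource Balance Analysis (RBA) predicts growth-optimal cell states under
the assumption that cells allocate their limited resources — precursors,
catalytic capacity, and physical space — efficiently. A state consists of
metabolic fluxes $\nu_j$, enzyme concentrations $E_j$ and process-machine
concentrations $M_p$ (ribosomes, chaperones, transport machinery). At a
given growth rate $\mu$ and medium, the state must satisfy:

1. **Mass balance / balanced growth.** For every internal metabolite $m$:
   $\sum_j S_{mj}\nu_j = \mu \sum_i a_{mi} c_i$, where $c_i$ runs over all
   macromolecular components and $a_{mi}$ is the precursor cost of one unit
   of $i$. In balanced exponential growth every component is diluted at
   rate $\mu c_i$ and must be resynthesized at exactly that rate.
2. **Catalytic capacity.** $\nu_j \le k^{+}_{\mathrm{app},j} E_j$, and
   $-\nu_j \le k^{-}_{\mathrm{app},j} E_j$ for reversible reactions. The
   apparent catalytic efficiency $k_\mathrm{app}$ is flux per unit enzyme.
3. **Process capacity.** For each process $p$:
   $\mu \sum_i d_{ip} c_i \le k_p M_p$ — the synthesis workload of all
   products of $p$ (by default, their weight in amino-acid equivalents)
   must fit into the machinery's capacity.
4. **Density.** Per compartment $c$: $\sum_{i \in c} w_i c_i \le D_c$ —
   macromolecules occupy space, and space is finite.

plus **target constraints** encoding empirical knowledge (fixed or bounded
concentrations and fluxes). All constraints are linear in
$(\nu, E, M)$ at fixed $\mu$, but the coefficients depend on $\mu$; the
model is a growth-rate-parametric linear program.

Parameters ($k_\mathrm{app}$, $k_p$, $D_c$, target values) are *parameter
functions* of $\mu$ and of one external metabolite concentration. The
vocabulary is deliberately small: `constant`, `linear_bounded` (affine in
$\mu$, clipped), `michaelis_menten` (in one medium concentration), and
`product` of other functions. These cover constant kcats,
growth-rate-dependent machine efficiencies, medium-dependent transporter
efficiencies, and multiplicative scaling edits; other shapes can often be
approximated by products of these.

### Units

Concentrations are mmol (or machine units) per gram dry weight, fluxes per
hour, weights in amino-acid equivalents, medium concentrations in mM. The
package documents but does not enforce these; only ratios matter to the
mathematics.

## Feasibility and the maximal growth rate

Feasibility of the constraint set is monotone in $\mu$ for these models:
raising $\mu$ tightens every dilution and workload term, so states exist
below some $\mu^{*}$ and not above. `maximize_growth()` brackets $\mu^{*}$
(doubling from `bisection_tol`) and bisects until the bracket's relative
width is below `bisection_tol` (default $10^{-6}$), returning the state at
the **last feasible** $\mu$ — conservative, so the reported state always
exists. Monotone feasibility is an assumption: imposed *equality* flux
targets can make the feasible $\mu$-set a single point, which bisection
from zero correctly reports as infeasible rather than discovering.

One subtlety deserves spelling out. For a model with no nonzero target
constraint, every constraint except density is homogeneous, so the all-zero
state (no enzymes, no ribosomes, no fluxes) is feasible at *any* growth
rate and plain LP feasibility would never become infeasible. What we mean
by "the model grows at rate $\mu$" is the existence of a *non-trivial*
balanced-growth state. `is_feasible()` therefore checks, for fully
homogeneous models, whether the maximal total catalyst mass at $\mu$ is
positive; models with nonzero targets are checked by ordinary LP
feasibility (the targets already pin the scale). Both notions coincide
whenever both apply, and the closed-form optima of the toy models are
recovered exactly under this definition.

At $\mu^{*}$ the optimum is typically unique, but at degenerate optima the
raw feasible point returned by a solver is arbitrary. For reproducibility
`maximize_growth()` applies a parsimonious tie-break by default: it
minimizes the total enzyme-plus-machine concentration at the reported
$\mu$ (for fully homogeneous models, whose minimum is the trivial zero
state, it instead reports the density-saturated state of maximal total
concentration). `parsimonious = FALSE` disables this.

## The LP backend

The package ships its own dense two-phase primal simplex
(`R/simplex.R`). RBA problems at desk scale are tiny (tens of rows and
columns) but are solved tens of thousands of times per analysis, and the
solver contract needs explicit `infeasible` and `unbounded` statuses plus
row duals. Numerical choices, all visible in the code:

* **Row equilibration.** Model rows mix coefficients across many orders of
  magnitude ($\mu \times$ precursor costs vs. unit stoichiometries); every
  row is scaled by its largest absolute entry before solving so that the
  pivot and feasibility tolerances ($10^{-9}$) are meaningful for rows of
  any scale.
* **Bland's rule** for entering and leaving variables: slower than
  steepest-edge but cycle-free on the degenerate problems that RVA and
  Pareto sweeps produce.
* **Clean final solve.** The returned basic solution and duals are
  recomputed from the pristine basis matrix (`solve(B, b)`) rather than
  read off the accumulated tableau, removing pivot roundoff.
* **Independent feasibility re-check.** Every `optimal` solution is
  re-verified against the original constraints with a scaled
  (backward-error) tolerance of $10^{-8}$ per row; violations downgrade
  the status to `tolerance_failure` instead of silently passing solver
  output through.

In the test suite the simplex is cross-checked against an exhaustive
enumeration of basic solutions (vertex enumeration), an oracle that shares
no code with the solver.

## Analyses

* **Medium screens / Monod curves** (`medium_screen`,
  `find_min_substrate`): $\mu_{max}$ and optimal fluxes along a
  concentration grid of one external metabolite; the inverse question
  (minimum substrate sustaining a target growth rate) is answered by
  bisection over concentration.
* **Parameter screens** (`parameter_screen`): one catalyst's efficiency is
  scaled by factors spanning 0.01–100 (log-spaced by default) and
  $\mu_{max}$ recomputed per factor.
* **Local sensitivities** (`local_sensitivities`): scaled sensitivities
  $\mathrm{d}\ln\mu_{max}/\mathrm{d}\ln k_\mathrm{app}$ by a symmetric
  finite difference in log space with half-step $\delta = \ln(1.01)$.
  A finite difference over bisection results is preferred over dual-based
  formulas because duals are unreliable exactly where sensitivities are
  most interesting (degenerate optima at metabolic switch points). The
  inner bisections run at `bisection_tol/10` so that the difference
  quotient's error ($\approx$ tolerance$/\delta$) stays an order of
  magnitude below the quantity itself; $|s| < 10^{-6}$ is reported as
  exactly 0, which is also the operational definition of an enzyme
  "without control". For constant-efficiency models without flux targets,
  $\mu_{max}$ is homogeneous of degree 1 in the efficiency vector, so
  sensitivities must sum to 1 — a built-in consistency check used
  throughout the tests.
* **Ensemble sampling** (`sample_ensemble`): each enzyme efficiency is
  multiplied by its own random factor $x$, $\ln x \sim
  \mathcal{N}(0, \sigma)$ with $\sigma = \ln(1.1)$ and $n = 1000$ models
  by default — about 10% multiplicative parameter uncertainty. Process
  machines are left unperturbed by default (`include_processes = TRUE`
  widens the scope). Sampling is bitwise reproducible from the seed; the
  RNG state of the session is saved and restored.
* **RVA** (`variability_analysis`, `rva_over_growth`): min and max of each
  variable at fixed $\mu$ (two LP solves per variable); over a grid of
  fractions of $\mu_{max}$ this yields growth-vs-flexibility trade-off
  curves whose upper edges are Pareto fronts.
* **Pareto fronts** (`pareto_front`): $\varepsilon$-constraint sweep at
  fixed $\mu$ — maximize objective B alone, then maximize A subject to
  $B \ge b$ for `pareto_points` (default 20) linearly spaced levels
  $b \in [0, b_{max}]$ (a log grid is available by flag). Endpoints
  coincide with the single-objective optima by construction.
* **Production trade-offs** (`production_tradeoff`): maximal product flux
  at fractions of $\mu_{max}$ — the strain designer's
  production-vs-fitness curve.

## The toy-model family

Genome-scale RBA models are external artifacts; the package instead ships
generators for five small models whose behaviour is known in closed form,
used as the test substrate and in all examples:

| generator | behaviour | closed form |
|---|---|---|
| `make_self_replicator` | minimal self-replicating cell | $\mu_{max} = (n_E/k_E + n_R/k_R)^{-1}$ |
| `make_pinned_replicator` | + housekeeping protein target $c_0$ | $\mu_{max} = (1 - n_H c_0/D)\,(n_E/k_E + n_R/k_R)^{-1}$ |
| `make_mm_importer` | Michaelis–Menten import, Monod curve | $\mu_{max}(c)$ saturating in $c$ |
| `make_overflow_branch` | high-yield/slow vs low-yield/fast pathways | switch at $k_T^\ast$ where proteome costs per precursor are equal |
| `make_secretion` | product sink(s) competing with growth | production linear in $\mu_{max} - \mu$ |

The defaults are chosen for readable arithmetic, not biological realism:
unit weights, $k_E = k_R = 2\,h^{-1}$, $c_0 = 0.2$, $D = 1$, and overflow
parameters ($v_{max} = 4$, $k_m = 1$, yields 2 vs 1, efficiencies 1 vs 4)
that place the respiration/overflow switch at exactly 1 mM. What the toys
emulate is the *structure* of whole-cell RBA models — self-replication,
pinned maintenance proteome, medium-dependent transport, pathway choice,
production burden. What they do not emulate: genome-scale degeneracy,
compartment multiplicity (membranes), reversible fluxes in the optimal
state, and realistic parameter magnitudes. Tests passing on the toys
validate the algorithms, not the biology of any particular organism.

Closed forms are re-derived in the test suite by independent dense
$\mu$-grid feasibility scans, so the analytic formulas and the builders
cannot silently drift apart. Randomized variants draw parameters
log-uniformly from $[0.1, 10]$ to exercise numerical conditioning.

## Design choices where the design was open

* **Knockouts set efficiencies to zero** rather than deleting components:
  the LP keeps its shape across edits, which keeps screens comparable row
  by row. Edits are copy-on-write (ordinary R semantics), so branching a
  model is free.
* **Reversible fluxes are single free variables** with two capacity rows,
  not split non-negative pairs: half the variables, same polytope.
* **Concentration-equality targets are substituted as constants** into
  mass-balance, process and density rows instead of being kept as pinned
  variables. Inequality concentration targets on species without a
  variable get a dedicated one; targets on enzymes or machines constrain
  the existing variable.
* **Metabolite dilution is not modelled**: internal metabolite pools are
  steady-state intermediates, and only an explicit concentration target on
  a metabolite adds its dilution demand $\mu c$ to the balance. Whether to
  include $\mu c$ terms for free metabolite pools is a genuine modelling
  choice; excluding them keeps the toy closed forms exact and is stated
  here rather than guessed at silently.
* **Spontaneous reactions** (no enzyme) get no capacity rows, only their
  reversibility bounds.
* **Tabular archive format**: one SBtab-style TSV per component collection
  with a named-parameter table, `id:coefficient` lists for compositions,
  and a `form(name=value,...)` grammar for parameter functions. Floats are
  written in the shortest representation that parses back bit-identically,
  so archives and exports are stable under round-trips and diffs.

## Problem sizes and runtimes

All bundled analyses run on models with 3–8 LP variables. The test suite
uses 100 random draws per replicator family for closed-form recovery, a
$10^4$-point dense grid for the bisection oracle, the full $n = 1000$
ensemble at the overflow switch, 50-point grids for feasibility-prefix
properties, and $50 \times 50$ demand grids for Pareto-efficiency
verification; the whole suite completes in a few minutes on a single core.

## Known limitations

* Only linear RBA: no thermodynamic constraints, integer decisions, or
  nonlinear kinetics beyond the fixed parameter-function vocabulary.
* The bisection contract assumes monotone feasibility in $\mu$ (see
  above); pathological target combinations violating it are reported
  infeasible rather than searched exhaustively.
* The dense simplex is deliberately simple; genome-scale models (thousands
  of variables) would need a sparse industrial LP backend behind the same
  `solve_lp()` contract.
* The importer for the XML dialect used by other RBA software is out of
  scope; the tabular archive is the native format.
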
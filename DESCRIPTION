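Package: rbakit
Title: Resource Balance Analysis Models, Growth Optimization and
    Resource Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, edit and analyse Resource Balance Analysis (RBA) cell
    models: whole-cell resource-allocation models formulated as
    growth-rate-parametric linear programs coupling metabolic fluxes to the
    concentrations of the enzymes and macromolecular machines that sustain
    them. Computes maximal feasible growth rates by bisection, growth-optimal
    cell states, Monod curves and medium screens, parameter screens, local
    and global (ensemble) parameter sensitivities, Resource Variability
    Analysis (RVA) and epsilon-constraint Pareto fronts. Models are read from
    and written to an SBtab-flavoured tabular format; solutions export to
    CSV/SBtab and to Escher and Proteomaps data files. A family of small
    self-replicator models with closed-form optima is included for testing
    and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
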
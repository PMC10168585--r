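#' Read and write RBA model archives
#'
#' The native on-disk format is a directory of SBtab-flavoured TSV files,
#' one per component collection, plus a JSON manifest:
#'
#' ```
#' <path>/manifest.json
#' <path>/compartments.tsv   metabolites.tsv   macromolecules.tsv
#' <path>/reactions.tsv      enzymes.tsv       processes.tsv
#' <path>/targets.tsv        parameters.tsv
#' ```
#'
#' Each table starts with a `!!SBtab` declaration line
#' (`TableID`, `TableType`) followed by `!`-prefixed column headers.
#' Stoichiometries and compositions are serialized as `id:coefficient`
#' lists joined by `;`. All parameter functions live in `parameters.tsv`
#' as `form(name=value,...)` strings (see [format_parameter()] for the
#' grammar); component tables reference them by parameter id
#' `<component>__<slot>`. Numbers are written in their shortest
#' representation that round-trips exactly, so `read_model(write_model(m))`
#' reproduces `m` including every parameter value bit for bit.
#'
#' @param model a valid [rba_model()].
#' @param path directory of the archive (created by `write_model()`).
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   a validated [rba_model()] (structural problems are raised as errors
#'   naming the offending file and component).
#' @examples
#' dir <- file.path(tempdir(), "toy_archive")
#' write_model(make_pinned_replicator(), dir)
#' m2 <- read_model(dir)
#' @name model-archive
NULL

FORMAT_VERSION <- "1.0"

pairs_to_string <- function(x) {
  if (length(x) == 0L) return("")
  paste(paste0(names(x), ":", fmt_num(x)), collapse = ";")
}

string_to_pairs <- function(s, context) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(), character()))
  items <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(items, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    stop("malformed id:coefficient list in ", context, ": '", s, "'",
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 2L)))
  if (any(is.na(vals))) {
    stop("non-numeric coefficient in ", context, ": '", s, "'", call. = FALSE)
  }
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1L))
}

write_sbtab <- function(df, path, table_id, table_type = "Quantity") {
  header <- paste0("!!SBtab SBtabVersion='1.0' TableID='", table_id,
                   "' TableType='", table_type, "'")
  cols <- paste0("!", names(df))
  lines <- c(header, paste(cols, collapse = "\t"))
  if (nrow(df) > 0L) {
    body <- apply(as.matrix(df), 1L, paste, collapse = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
}

read_sbtab <- function(path) {
  if (!file.exists(path)) stop("missing archive table: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "!!SBtab")) {
    stop(path, " is not an SBtab table (missing !!SBtab declaration)",
         call. = FALSE)
  }
  cols <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  cols <- sub("^!", "", cols)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(character(), 0, length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    return(df)
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  cells <- lapply(cells, function(x) c(x, rep("", length(cols) - length(x))))
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' @rdname model-archive
#' @export
write_model <- function(model, path) {
  stop_if_invalid(model)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  params <- list() # id -> rba_parameter
  param_ref <- function(owner, slot, fn) {
    if (is.null(fn)) return("")
    id <- paste0(owner, "__", slot)
    params[[id]] <<- fn
    id
  }

  comp <- data.frame(
    ID = names(model$compartments),
    DensityCapacity = vapply(model$compartments, function(x)
      param_ref(x$id, "density_capacity", x$density_capacity), character(1)),
    stringsAsFactors = FALSE)
  met <- data.frame(
    ID = names(model$metabolites),
    IsExternal = vapply(model$metabolites, function(x)
      if (x$external) "True" else "False", character(1)),
    stringsAsFactors = FALSE)
  mac <- data.frame(
    ID = names(model$macromolecules),
    Weight = vapply(model$macromolecules, function(x) fmt_num(x$weight),
                    character(1)),
    Compartment = vapply(model$macromolecules, `[[`, character(1),
                         "compartment"),
    PrecursorCost = vapply(model$macromolecules, function(x)
      pairs_to_string(x$precursor_cost), character(1)),
    ProducingProcess = vapply(model$macromolecules, function(x)
      x$producing_process %||% "", character(1)),
    stringsAsFactors = FALSE)
  rxn <- data.frame(
    ID = names(model$reactions),
    Stoichiometry = vapply(model$reactions, function(x)
      pairs_to_string(x$stoichiometry), character(1)),
    IsReversible = vapply(model$reactions, function(x)
      if (x$reversible) "True" else "False", character(1)),
    Enzyme = vapply(model$reactions, function(x) x$enzyme %||% "",
                    character(1)),
    stringsAsFactors = FALSE)
  enz <- data.frame(
    ID = names(model$enzymes),
    Composition = vapply(model$enzymes, function(x)
      pairs_to_string(x$composition), character(1)),
    ForwardEfficiency = vapply(model$enzymes, function(x)
      param_ref(x$id, "forward_efficiency", x$forward_efficiency),
      character(1)),
    BackwardEfficiency = vapply(model$enzymes, function(x)
      param_ref(x$id, "backward_efficiency", x$backward_efficiency),
      character(1)),
    stringsAsFactors = FALSE)
  prc <- data.frame(
    ID = names(model$processes),
    MachineComposition = vapply(model$processes, function(x)
      pairs_to_string(x$machine_composition), character(1)),
    Efficiency = vapply(model$processes, function(x)
      param_ref(x$id, "efficiency", x$efficiency), character(1)),
    Products = vapply(model$processes, function(x)
      paste(x$products, collapse = ";"), character(1)),
    DemandPerUnit = vapply(model$processes, function(x)
      if (is.null(x$demand_per_unit)) "" else
        pairs_to_string(x$demand_per_unit), character(1)),
    stringsAsFactors = FALSE)
  tgt <- data.frame(
    ID = names(model$targets),
    Kind = vapply(model$targets, `[[`, character(1), "kind"),
    Subject = vapply(model$targets, `[[`, character(1), "subject"),
    Value = vapply(model$targets, function(x)
      param_ref(x$id, "value", x$value), character(1)),
    stringsAsFactors = FALSE)
  par <- data.frame(
    ID = names(params),
    Definition = vapply(params, format_parameter, character(1)),
    stringsAsFactors = FALSE)
  fix_empty <- function(df) { rownames(df) <- NULL; df }

  tables <- list(
    compartments = list(fix_empty(comp), "Compartment"),
    metabolites = list(fix_empty(met), "Compound"),
    macromolecules = list(fix_empty(mac), "Macromolecule"),
    reactions = list(fix_empty(rxn), "Reaction"),
    enzymes = list(fix_empty(enz), "Enzyme"),
    processes = list(fix_empty(prc), "Process"),
    targets = list(fix_empty(tgt), "Target"),
    parameters = list(fix_empty(par), "Parameter")
  )
  for (nm in names(tables)) {
    write_sbtab(tables[[nm]][[1]], file.path(path, paste0(nm, ".tsv")),
                table_id = nm, table_type = tables[[nm]][[2]])
  }
  jsonlite::write_json(
    list(format = "rbakit-model", format_version = FORMAT_VERSION,
         name = model$name, tables = paste0(names(tables), ".tsv")),
    file.path(path, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname model-archive
#' @export
read_model <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a model archive (no manifest.json): ", path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  if (!identical(manifest$format, "rbakit-model")) {
    stop(path, ": unknown archive format '", manifest$format, "'",
         call. = FALSE)
  }
  tab <- function(nm) read_sbtab(file.path(path, paste0(nm, ".tsv")))
  par_df <- tab("parameters")
  params <- stats::setNames(vector("list", nrow(par_df)), par_df$ID)
  for (i in seq_len(nrow(par_df))) {
    params[[i]] <- tryCatch(parse_parameter(par_df$Definition[i]),
      error = function(e) {
        stop("parameters.tsv, row ", i, " ('", par_df$ID[i], "'): ",
             conditionMessage(e), call. = FALSE)
      })
  }
  pfetch <- function(id, context) {
    if (!nzchar(id)) return(NULL)
    if (!id %in% names(params)) {
      stop(context, ": unknown parameter id '", id, "'", call. = FALSE)
    }
    params[[id]]
  }
  opt <- function(s) if (nzchar(s)) s else NULL
  num1 <- function(s, context) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(context, ": not a number: '", s, "'", call. = FALSE)
    v
  }

  comp_df <- tab("compartments")
  compartments <- purrr::map(seq_len(nrow(comp_df)), function(i) {
    rba_compartment(comp_df$ID[i],
                    pfetch(comp_df$DensityCapacity[i],
                           paste0("compartments.tsv row ", i)))
  })
  met_df <- tab("metabolites")
  metabolites <- purrr::map(seq_len(nrow(met_df)), function(i) {
    rba_metabolite(met_df$ID[i], external = met_df$IsExternal[i] == "True")
  })
  mac_df <- tab("macromolecules")
  macromolecules <- purrr::map(seq_len(nrow(mac_df)), function(i) {
    ctx <- paste0("macromolecules.tsv row ", i)
    rba_macromolecule(mac_df$ID[i],
                      weight = num1(mac_df$Weight[i], ctx),
                      compartment = mac_df$Compartment[i],
                      precursor_cost = string_to_pairs(mac_df$PrecursorCost[i], ctx),
                      producing_process = opt(mac_df$ProducingProcess[i]))
  })
  rxn_df <- tab("reactions")
  reactions <- purrr::map(seq_len(nrow(rxn_df)), function(i) {
    ctx <- paste0("reactions.tsv row ", i)
    rba_reaction(rxn_df$ID[i],
                 stoichiometry = string_to_pairs(rxn_df$Stoichiometry[i], ctx),
                 reversible = rxn_df$IsReversible[i] == "True",
                 enzyme = opt(rxn_df$Enzyme[i]))
  })
  enz_df <- tab("enzymes")
  enzymes <- purrr::map(seq_len(nrow(enz_df)), function(i) {
    ctx <- paste0("enzymes.tsv row ", i)
    rba_enzyme(enz_df$ID[i],
               composition = string_to_pairs(enz_df$Composition[i], ctx),
               forward_efficiency = pfetch(enz_df$ForwardEfficiency[i], ctx),
               backward_efficiency = pfetch(enz_df$BackwardEfficiency[i], ctx))
  })
  prc_df <- tab("processes")
  processes <- purrr::map(seq_len(nrow(prc_df)), function(i) {
    ctx <- paste0("processes.tsv row ", i)
    dpu <- string_to_pairs(prc_df$DemandPerUnit[i], ctx)
    rba_process(prc_df$ID[i],
                machine_composition = string_to_pairs(prc_df$MachineComposition[i], ctx),
                efficiency = pfetch(prc_df$Efficiency[i], ctx),
                products = strsplit(prc_df$Products[i], ";", fixed = TRUE)[[1]],
                demand_per_unit = if (length(dpu)) dpu else NULL)
  })
  tgt_df <- tab("targets")
  targets <- purrr::map(seq_len(nrow(tgt_df)), function(i) {
    ctx <- paste0("targets.tsv row ", i)
    rba_target(tgt_df$ID[i], tgt_df$Kind[i], tgt_df$Subject[i],
               pfetch(tgt_df$Value[i], ctx))
  })

  model <- rba_model(
    name = manifest$name %||% basename(path),
    compartments = compartments, metabolites = metabolites,
    macromolecules = macromolecules, reactions = reactions,
    enzymes = enzymes, processes = processes, targets = targets
  )
  d <- validate_model(model)
  if (nrow(d) > 0L) {
    stop("archive ", path, " contains an invalid model:\n",
         paste0("  [", d$component, " ", d$id, "] ", d$message,
                collapse = "\n"),
         call. = FALSE)
  }
  model
}

#' Export solutions and analysis tables
#'
#' Writes a solution or any analysis result (screen, RVA, Pareto front,
#' ensemble, sensitivities) as a tidy CSV table or as SBtab TSV. Numbers
#' are written at full precision; column order is fixed, so identical
#' inputs yield byte-identical files.
#'
#' @param x an `rba_solution` or an analysis result tibble.
#' @param path output file.
#' @param format `"csv"` or `"sbtab"`.
#' @return `path`, invisibly.
#' @export
export_results <- function(x, path, format = c("csv", "sbtab")) {
  format <- match.arg(format)
  if (inherits(x, "rba_solution")) {
    if (format == "sbtab") {
      blocks <- list(
        fluxes = tibble::tibble(Reaction = names(x$fluxes),
                                Value = fmt_num(x$fluxes)),
        enzyme_concentrations = tibble::tibble(
          Enzyme = names(x$enzyme_concentrations),
          Value = fmt_num(x$enzyme_concentrations)),
        machine_concentrations = tibble::tibble(
          Process = names(x$machine_concentrations),
          Value = fmt_num(x$machine_concentrations))
      )
      lines <- character()
      for (nm in names(blocks)) {
        df <- blocks[[nm]]
        lines <- c(lines,
                   paste0("!!SBtab SBtabVersion='1.0' TableID='", nm,
                          "' TableType='Quantity'"),
                   paste(paste0("!", names(df)), collapse = "\t"),
                   if (nrow(df)) apply(as.matrix(df), 1L, paste,
                                       collapse = "\t"))
      }
      writeLines(lines, path)
    } else {
      readr::write_csv(generics::tidy(x), path)
    }
    return(invisible(path))
  }
  df <- tibble::as_tibble(x)
  if (format == "csv") {
    readr::write_csv(df, path)
  } else {
    chr <- df
    for (j in seq_along(chr)) {
      chr[[j]] <- if (is.numeric(chr[[j]])) fmt_num(chr[[j]])
                  else as.character(chr[[j]])
    }
    write_sbtab(as.data.frame(chr), path,
                table_id = class(x)[1], table_type = "Quantity")
  }
  invisible(path)
}

#' Export fluxes as Escher reaction data
#'
#' Writes the solution's fluxes as the flat JSON object
#' (`{"reaction_id": flux, ...}`) that Escher accepts as reaction data.
#' Zero-flux reactions are included.
#'
#' @param solution an optimal `rba_solution`.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
export_escher_flux <- function(solution, path) {
  stopifnot(inherits(solution, "rba_solution"))
  if (solution$status != "optimal") {
    stop("cannot export a non-optimal solution (status ", solution$status,
         ")", call. = FALSE)
  }
  jsonlite::write_json(as.list(solution$fluxes), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export macromolecule mass shares for Proteomaps
#'
#' Computes the proteome mass share of every macromolecule in the optimal
#' state: its weight times its total concentration summed over all
#' catalysts containing it (composition-weighted) plus any fixed target
#' concentration, normalized to sum to 1. Written as the two-column TSV
#' (id, share) that Proteomaps accepts. Macromolecules with zero abundance
#' are omitted.
#'
#' @param solution an optimal `rba_solution`.
#' @param model the model the solution was computed from.
#' @param path output `.tsv` file.
#' @return A tibble (id, share), invisibly.
#' @export
export_proteomaps <- function(solution, model, path) {
  stopifnot(inherits(solution, "rba_solution"), inherits(model, "rba_model"))
  if (solution$status != "optimal") {
    stop("cannot export a non-optimal solution (status ", solution$status,
         ")", call. = FALSE)
  }
  mass <- stats::setNames(numeric(length(model$macromolecules)),
                          names(model$macromolecules))
  add <- function(comp, conc) {
    for (mm in names(comp)) {
      mass[mm] <<- mass[mm] +
        model$macromolecules[[mm]]$weight * comp[[mm]] * conc
    }
  }
  for (en in model$enzymes) {
    add(en$composition, solution$enzyme_concentrations[[en$id]])
  }
  for (pr in model$processes) {
    add(pr$machine_composition, solution$machine_concentrations[[pr$id]])
  }
  for (mm in names(solution$target_concentrations)) {
    add(stats::setNames(1, mm), solution$target_concentrations[[mm]])
  }
  for (mm in names(solution$fixed_concentrations)) {
    add(stats::setNames(1, mm), solution$fixed_concentrations[[mm]])
  }
  mass <- mass[mass > 0]
  share <- mass / sum(mass)
  writeLines(paste(names(share), fmt_num(share), sep = "\t"), path)
  invisible(tibble::tibble(id = names(share), share = unname(share)))
}
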
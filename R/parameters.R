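#' Growth-rate- and medium-dependent model parameters
#'
#' Every quantitative coefficient of an RBA model -- catalytic efficiencies
#' (apparent kcat values), process-machine efficiencies, compartment density
#' capacities and target values -- is a *parameter function*: a scalar
#' function of the growth rate \eqn{\mu} and/or of the concentration of one
#' external metabolite in the growth medium. Four functional forms are
#' supported:
#'
#' * `pf_constant(value)`: a constant, independent of \eqn{\mu} and medium.
#' * `pf_linear_bounded(intercept, slope, lower_cap, upper_cap)`:
#'   `intercept + slope * mu`, clipped to `[lower_cap, upper_cap]`. Used for
#'   growth-rate-dependent machine efficiencies and density capacities.
#' * `pf_michaelis_menten(vmax, km, metabolite)`:
#'   `vmax * c / (km + c)` where `c` is the medium concentration of the named
#'   external metabolite (in mM). Used for transporter efficiencies, and the
#'   source of Monod-type growth curves.
#' * `pf_product(...)`: the product of other parameter functions. An empty
#'   product evaluates to 1. Efficiency scaling (see [scale_efficiency()])
#'   wraps a function as `pf_product(pf_constant(factor), original)`.
#'
#' All forms must evaluate to a finite, non-negative number for
#' \eqn{\mu \ge 0} and non-negative medium concentrations.
#'
#' @param value,intercept,slope,lower_cap,upper_cap,vmax,km numeric scalars.
#' @param metabolite identifier of the external metabolite whose medium
#'   concentration is the function's argument.
#' @param ... for `pf_product()`, parameter functions to multiply.
#' @return An object of class `rba_parameter`.
#' @examples
#' kcat <- pf_constant(120)
#' evaluate_parameter(kcat, mu = 0.5)
#'
#' importer <- pf_michaelis_menten(vmax = 2, km = 0.1, metabolite = "glc_ext")
#' evaluate_parameter(importer, mu = 0.5, medium = rba_medium(c(glc_ext = 0.1)))
#' @name parameter-functions
NULL

new_parameter <- function(form, fields) {
  structure(c(list(form = form), fields), class = "rba_parameter")
}

#' @rdname parameter-functions
#' @export
pf_constant <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_parameter("constant", list(value = as.numeric(value)))
}

#' @rdname parameter-functions
#' @export
pf_linear_bounded <- function(intercept, slope, lower_cap, upper_cap) {
  stopifnot(
    is.numeric(intercept), is.numeric(slope),
    is.numeric(lower_cap), is.numeric(upper_cap),
    lower_cap <= upper_cap
  )
  new_parameter("linear_bounded", list(
    intercept = as.numeric(intercept), slope = as.numeric(slope),
    lower_cap = as.numeric(lower_cap), upper_cap = as.numeric(upper_cap)
  ))
}

#' @rdname parameter-functions
#' @export
pf_michaelis_menten <- function(vmax, km, metabolite) {
  stopifnot(is.numeric(vmax), vmax >= 0, is.numeric(km), km > 0,
            is.character(metabolite), length(metabolite) == 1L)
  new_parameter("michaelis_menten", list(
    vmax = as.numeric(vmax), km = as.numeric(km), metabolite = metabolite
  ))
}

#' @rdname parameter-functions
#' @export
pf_product <- function(...) {
  operands <- list(...)
  if (length(operands) == 1L && is.list(operands[[1]]) &&
      !inherits(operands[[1]], "rba_parameter")) {
    operands <- operands[[1]]
  }
  ok <- vapply(operands, inherits, logical(1), what = "rba_parameter")
  if (!all(ok)) stop("all operands of pf_product() must be parameter functions")
  new_parameter("product", list(operands = operands))
}

#' @export
print.rba_parameter <- function(x, ...) {
  cat("<rba_parameter> ", format_parameter(x), "\n", sep = "")
  invisible(x)
}

#' Growth medium
#'
#' A medium assigns a concentration (mM) to each external metabolite.
#' Parameter functions of Michaelis-Menten form look their argument up here.
#'
#' @param concentrations named numeric vector, external metabolite id ->
#'   concentration (>= 0). May be empty for models whose parameters do not
#'   depend on the medium.
#' @return An object of class `rba_medium` (a named numeric vector).
#' @examples
#' rba_medium(c(glc_ext = 10, o2_ext = 0.21))
#' @export
rba_medium <- function(concentrations = numeric()) {
  x <- unlist(concentrations)
  if (length(x) == 0L) x <- numeric()
  if (length(x) > 0L && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("medium concentrations must be named by external metabolite id")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("medium concentrations must be finite and >= 0")
  }
  structure(as.numeric(x), names = names(x), class = "rba_medium")
}

#' Override single entries of a medium
#'
#' @param medium an [rba_medium()].
#' @param ... `id = concentration` pairs to set or add.
#' @return The modified medium.
#' @export
medium_set <- function(medium, ...) {
  upd <- c(...)
  m <- unclass(medium)
  m[names(upd)] <- upd
  rba_medium(m)
}

#' Evaluate a parameter function
#'
#' @param fn an `rba_parameter` (see [parameter-functions]).
#' @param mu growth rate (per hour), `>= 0`.
#' @param medium an [rba_medium()]; required only when `fn` (or one of its
#'   product operands) references an external metabolite.
#' @return A finite, non-negative scalar.
#' @examples
#' evaluate_parameter(pf_linear_bounded(1, 2, 1, 4), mu = 2)  # 1 + 2*2 capped at 4
#' @export
evaluate_parameter <- function(fn, mu, medium = rba_medium()) {
  stopifnot(inherits(fn, "rba_parameter"), is.numeric(mu), mu >= 0)
  v <- switch(fn$form,
    constant = fn$value,
    linear_bounded = {
      raw <- fn$intercept + fn$slope * mu
      min(max(raw, fn$lower_cap), fn$upper_cap)
    },
    michaelis_menten = {
      conc <- unclass(medium)[fn$metabolite]
      if (is.null(conc) || length(conc) == 0L || is.na(conc)) {
        stop("medium does not define a concentration for external metabolite '",
             fn$metabolite, "'", call. = FALSE)
      }
      fn$vmax * conc / (fn$km + conc)
    },
    product = {
      prod(vapply(fn$operands, evaluate_parameter, numeric(1),
                  mu = mu, medium = medium))
    },
    stop("unknown parameter form '", fn$form, "'")
  )
  v <- unname(v)
  if (!is.finite(v) || v < 0) {
    stop("parameter function evaluated to a non-finite or negative value (",
         v, ") at mu = ", mu, call. = FALSE)
  }
  v
}

# External metabolite ids referenced anywhere inside a parameter function.
parameter_arguments <- function(fn) {
  switch(fn$form,
    michaelis_menten = fn$metabolite,
    product = unique(unlist(lapply(fn$operands, parameter_arguments))),
    character()
  )
}

# Shortest decimal representation that survives a read-back round trip.
fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- as.character(v)
    if (identical(as.numeric(s), as.numeric(v))) s else sprintf("%.17g", v)
  }, character(1))
}

#' Serialize a parameter function to its text form
#'
#' The grammar is `form(name=value, ...)` with nested forms allowed inside
#' `product(...)`: for example
#' `michaelis_menten(vmax=2,km=0.1,arg=glc_ext)` or
#' `product(constant(value=2),constant(value=3))`. [parse_parameter()] is the
#' exact inverse.
#'
#' @param fn an `rba_parameter`.
#' @return A single string.
#' @export
format_parameter <- function(fn) {
  stopifnot(inherits(fn, "rba_parameter"))
  switch(fn$form,
    constant = paste0("constant(value=", fmt_num(fn$value), ")"),
    linear_bounded = paste0(
      "linear_bounded(intercept=", fmt_num(fn$intercept),
      ",slope=", fmt_num(fn$slope),
      ",lower_cap=", fmt_num(fn$lower_cap),
      ",upper_cap=", fmt_num(fn$upper_cap), ")"
    ),
    michaelis_menten = paste0(
      "michaelis_menten(vmax=", fmt_num(fn$vmax),
      ",km=", fmt_num(fn$km),
      ",arg=", fn$metabolite, ")"
    ),
    product = paste0(
      "product(",
      paste(vapply(fn$operands, format_parameter, character(1)),
            collapse = ","),
      ")"
    )
  )
}

#' Parse the text form of a parameter function
#'
#' @param text a string produced by [format_parameter()] (see there for the
#'   grammar).
#' @return An `rba_parameter`.
#' @export
parse_parameter <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  res <- parse_parameter_at(text, 1L)
  rest <- substr(text, res$pos, nchar(text))
  if (grepl("[^[:space:]]", rest)) {
    stop("trailing characters after parameter function: '", rest, "'")
  }
  res$fn
}

# Recursive-descent parser; returns list(fn, pos) where pos is the first
# unconsumed character index.
parse_parameter_at <- function(text, pos) {
  rest <- substr(text, pos, nchar(text))
  m <- regmatches(rest, regexec("^[[:space:]]*([a-z_]+)\\(", rest))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse parameter function at: '", rest, "'")
  }
  form <- m[2]
  pos <- pos + nchar(m[1])
  if (form == "product") {
    operands <- list()
    repeat {
      rest <- substr(text, pos, nchar(text))
      if (grepl("^[[:space:]]*\\)", rest)) {
        pos <- pos + attr(regexpr("^[[:space:]]*\\)", rest), "match.length")
        break
      }
      sub <- parse_parameter_at(text, pos)
      operands[[length(operands) + 1L]] <- sub$fn
      pos <- sub$pos
      rest <- substr(text, pos, nchar(text))
      if (grepl("^[[:space:]]*,", rest)) {
        pos <- pos + attr(regexpr("^[[:space:]]*,", rest), "match.length")
      }
    }
    return(list(fn = pf_product(operands), pos = pos))
  }
  # flat key=value list up to the closing parenthesis
  rest <- substr(text, pos, nchar(text))
  close <- regexpr("\\)", rest)
  if (close < 0) stop("unterminated parameter function: '", rest, "'")
  body <- substr(rest, 1L, close - 1L)
  pos <- pos + close
  kv <- strsplit(body, ",", fixed = TRUE)[[1]]
  kv <- kv[nzchar(trimws(kv))]
  keys <- character(0); vals <- character(0)
  for (item in kv) {
    parts <- strsplit(item, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed argument '", item, "' in parameter function")
    keys <- c(keys, trimws(parts[1])); vals <- c(vals, trimws(parts[2]))
  }
  names(vals) <- keys
  num <- function(k) {
    if (!k %in% keys) stop("parameter form '", form, "' is missing argument '", k, "'")
    v <- suppressWarnings(as.numeric(vals[[k]]))
    if (is.na(v)) stop("argument '", k, "' of '", form, "' is not numeric: ", vals[[k]])
    v
  }
  fn <- switch(form,
    constant = pf_constant(num("value")),
    linear_bounded = pf_linear_bounded(num("intercept"), num("slope"),
                                       num("lower_cap"), num("upper_cap")),
    michaelis_menten = {
      if (!"arg" %in% keys) stop("michaelis_menten requires an 'arg' metabolite")
      pf_michaelis_menten(num("vmax"), num("km"), vals[["arg"]])
    },
    stop("unknown parameter form '", form, "'")
  )
  list(fn = fn, pos = pos)
}
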
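#' Model editing: knockouts, efficiency scaling, imposed targets
#'
#' All editing functions return a modified copy; the input model is never
#' changed. Knockouts replace the catalyst's efficiency function(s) by a
#' constant zero rather than removing components, so the shape of the linear
#' program stays identical across edits -- convenient for screens that
#' compare wild type and mutants row by row.
#'
#' @param model an [rba_model()].
#' @param catalyst_ids,catalyst_id enzyme or process ids.
#' @param factor positive scaling factor applied to the catalyst's
#'   efficiency function(s); the original function is wrapped as
#'   `pf_product(pf_constant(factor), original)`.
#' @param target an [rba_target()] to append.
#' @return The edited model.
#' @examples
#' toy <- make_self_replicator(k_enzyme = 2, k_process = 2)
#' faster <- scale_efficiency(toy, "translation", 2)
#' dead <- knock_out(toy, "E_uptake")
#' @name model-editing
NULL

#' @rdname model-editing
#' @export
knock_out <- function(model, catalyst_ids) {
  stopifnot(inherits(model, "rba_model"))
  for (id in catalyst_ids) {
    if (id %in% names(model$enzymes)) {
      model$enzymes[[id]]$forward_efficiency <- pf_constant(0)
      if (!is.null(model$enzymes[[id]]$backward_efficiency)) {
        model$enzymes[[id]]$backward_efficiency <- pf_constant(0)
      }
    } else if (id %in% names(model$processes)) {
      model$processes[[id]]$efficiency <- pf_constant(0)
    } else {
      stop("knock_out: '", id, "' is not an enzyme or process id", call. = FALSE)
    }
  }
  model
}

#' @rdname model-editing
#' @export
scale_efficiency <- function(model, catalyst_id, factor) {
  stopifnot(inherits(model, "rba_model"),
            is.numeric(factor), length(factor) == 1L, factor > 0)
  id <- catalyst_id
  if (id %in% names(model$enzymes)) {
    en <- model$enzymes[[id]]
    en$forward_efficiency <- pf_product(pf_constant(factor), en$forward_efficiency)
    if (!is.null(en$backward_efficiency)) {
      en$backward_efficiency <- pf_product(pf_constant(factor), en$backward_efficiency)
    }
    model$enzymes[[id]] <- en
  } else if (id %in% names(model$processes)) {
    pr <- model$processes[[id]]
    pr$efficiency <- pf_product(pf_constant(factor), pr$efficiency)
    model$processes[[id]] <- pr
  } else {
    stop("scale_efficiency: '", id, "' is not an enzyme or process id",
         call. = FALSE)
  }
  model
}

#' @rdname model-editing
#' @export
impose_target <- function(model, target) {
  stopifnot(inherits(model, "rba_model"), inherits(target, "rba_target"))
  if (target$id %in% names(model$targets)) {
    stop("impose_target: a target with id '", target$id, "' already exists",
         call. = FALSE)
  }
  probe <- model
  probe$targets[[target$id]] <- target
  d <- validate_model(probe)
  d <- d[d$component == "target" & d$id == target$id, ]
  if (nrow(d) > 0L) {
    stop("impose_target: invalid target '", target$id, "': ",
         paste(d$message, collapse = "; "), call. = FALSE)
  }
  probe
}
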
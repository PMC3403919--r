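# Typed error conditions. Every user-facing failure mode has its own class so
# callers (and tests) can dispatch on tryCatch(..., fluxmapr_<class> = ...).

fm_stop <- function(class, message, ..., call = sys.call(-1)) {
  data <- list(...)
  cond <- structure(
    class = c(paste0("fluxmapr_", class), "fluxmapr_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cond)
}

fm_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("fluxmapr_", class), "fluxmapr_warning", "warning", "condition"),
    c(list(message = message, call = NULL), list(...))
  )
  warning(cond)
}

#' @title Error classes used by fluxmapr
#' @description All errors signalled by the package carry the condition class
#'   `fluxmapr_error` plus one specific subclass, so they can be caught
#'   selectively with `tryCatch()`. The subclasses are:
#'   `malformed_equation`, `duplicate_reactant`, `template_format_error`,
#'   `cross_reference_error`, `missing_weight_error`, `io_failure`,
#'   `validation_error`, `empty_network`, `topology_conflict`,
#'   `bipartite_inference_error`, `numeric_error`, `unmapped_measurement`,
#'   `no_such_label`, `already_split`, `not_split`, `nothing_to_connect`,
#'   `layout_coverage_error`, `spec_error`, each prefixed with `fluxmapr_`.
#' @name fluxmapr-conditions
#' @keywords internal
NULL
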
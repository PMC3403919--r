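#' Validate reaction-level flux balance of a slice
#'
#' For substance fluxes (atom-weighted), a correctly entered reaction
#' conserves the traced element: the sum of all ingoing per-edge fluxes into
#' a reaction node equals the sum of all outgoing ones. A violated balance
#' almost always indicates a template entry error — a misspelled substance
#' name, a glued stoichiometry (`"2Suc"` for `"2 Suc"`), a missing factor or
#' a missing reactant. Mass-flux maps (all weights 1) are generally not
#' balanceable: any reaction whose stoichiometry-weighted substrate and
#' product counts differ is reported unbalanced there.
#'
#' Zero-flux reactions (measured 0 or unmeasured) would trivially pass
#' `0 = 0`, which would hide template errors; they get a flux-independent
#' structural check of the stoichiometry-weight sums instead, reported as
#' `structural_warning` (never as a failure).
#'
#' Validation never throws on unbalanced data; it reports.
#'
#' @param slice A [map_slice()] result.
#' @param tolerance Relative tolerance; a reaction is balanced when
#'   `|inflow - outflow| <= tolerance * max(inflow, outflow, 1)` (the floor
#'   of 1 guards the zero-flux case).
#' @return A `balance_report` with a `reactions` data frame: `label`,
#'   `inflow`, `outflow`, `residual`, `balanced`, `zero_flux`,
#'   `structural_warning`.
#' @export
validate_reactions <- function(slice, tolerance = 1e-6) {
  stopifnot(inherits(slice, "flux_map_slice"))
  net <- slice$network
  rxn <- net$nodes[net$nodes$kind == "reaction", ]
  e <- slice$edges
  inflow <- vapply(rxn$id, function(id) sum(e$flux[e$to == id]), numeric(1))
  outflow <- vapply(rxn$id, function(id) sum(e$flux[e$from == id]), numeric(1))
  zero_flux <- rxn$id %in% c(e$to[e$zero], e$from[e$zero]) |
    !(rxn$id %in% c(e$to, e$from))
  residual <- inflow - outflow
  balanced <- abs(residual) <= tolerance * pmax(inflow, outflow, 1)

  # structural atom check for zero-flux reactions: sum(s * w) per side
  lab <- stats::setNames(net$nodes$label, net$nodes$id)
  w <- slice$weights
  structural <- vapply(seq_len(nrow(rxn)), function(i) {
    if (!zero_flux[i]) return(FALSE)
    id <- rxn$id[i]
    rw <- w[lab[e$base_from[e$base_to == id]]]
    pw <- w[lab[e$base_to[e$base_from == id]]]
    if (anyNA(rw) || anyNA(pw)) return(FALSE)   # weights unknown: skip
    lhs <- sum(e$stoichiometry[e$base_to == id] * rw)
    rhs <- sum(e$stoichiometry[e$base_from == id] * pw)
    abs(lhs - rhs) > tolerance * max(lhs, rhs, 1)
  }, logical(1))

  new_balance_report(slice,
    reactions = data.frame(label = rxn$label, inflow = unname(inflow),
                           outflow = unname(outflow), residual = unname(residual),
                           balanced = unname(balanced), zero_flux = zero_flux,
                           structural_warning = structural,
                           stringsAsFactors = FALSE),
    tolerance = tolerance)
}

#' Validate metabolite-level (steady-state) flux balance of a slice
#'
#' At steady state an internal metabolite is produced exactly as fast as it
#' is consumed. Per metabolite *label* (summing over all clones created by
#' hub splitting), production is the sum of per-edge fluxes of incoming
#' edges and consumption that of outgoing edges. Boundary metabolites —
#' nutrient uptakes, excreted products, biomass sinks — legitimately violate
#' this; list them in `external_labels` to mark them exempt. Nothing is
#' auto-exempted.
#'
#' @param slice A [map_slice()] result.
#' @param external_labels Character vector of exempt metabolite labels.
#' @param tolerance Relative tolerance, as in [validate_reactions()].
#' @return A `balance_report` with a `metabolites` data frame: `label`,
#'   `production`, `consumption`, `residual`, `balanced`, `exempt`.
#' @export
validate_metabolites <- function(slice, external_labels = character(),
                                 tolerance = 1e-6) {
  stopifnot(inherits(slice, "flux_map_slice"))
  net <- slice$network
  met <- net$nodes[net$nodes$kind == "metabolite", ]
  labels <- unique(met$label)
  e <- slice$edges
  id_by_label <- split(met$id, met$label)
  production <- vapply(labels, function(l)
    sum(e$flux[e$to %in% id_by_label[[l]]]), numeric(1))
  consumption <- vapply(labels, function(l)
    sum(e$flux[e$from %in% id_by_label[[l]]]), numeric(1))
  residual <- production - consumption
  balanced <- abs(residual) <= tolerance * pmax(production, consumption, 1)
  new_balance_report(slice,
    metabolites = data.frame(label = labels, production = unname(production),
                             consumption = unname(consumption),
                             residual = unname(residual), balanced = unname(balanced),
                             exempt = labels %in% external_labels,
                             stringsAsFactors = FALSE),
    tolerance = tolerance)
}

#' Validate a slice at both levels
#'
#' Convenience wrapper running [validate_reactions()] and
#' [validate_metabolites()] and combining the two parts into one report.
#'
#' @inheritParams validate_metabolites
#' @return A `balance_report` with both `reactions` and `metabolites`.
#' @export
validate_slice <- function(slice, external_labels = character(), tolerance = 1e-6) {
  r <- validate_reactions(slice, tolerance)
  m <- validate_metabolites(slice, external_labels, tolerance)
  r$metabolites <- m$metabolites
  r
}

new_balance_report <- function(slice, reactions = NULL, metabolites = NULL,
                               tolerance) {
  structure(list(condition = slice$condition, timepoint = slice$timepoint,
                 reactions = reactions, metabolites = metabolites,
                 tolerance = tolerance),
            class = "balance_report")
}

report_failures <- function(report) {
  fr <- report$reactions
  fm <- report$metabolites
  out <- rbind(
    if (!is.null(fr) && any(!fr$balanced))
      data.frame(kind = "reaction", label = fr$label[!fr$balanced],
                 residual = fr$residual[!fr$balanced], stringsAsFactors = FALSE),
    if (!is.null(fm) && any(!fm$balanced & !fm$exempt))
      data.frame(kind = "metabolite",
                 label = fm$label[!fm$balanced & !fm$exempt],
                 residual = fm$residual[!fm$balanced & !fm$exempt],
                 stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(kind = character(), label = character(),
                      residual = numeric(), stringsAsFactors = FALSE)
  # largest absolute residual first; ties broken by label, lexicographically
  out[order(-abs(out$residual), out$label), , drop = FALSE]
}

#' Summarize a balance report
#'
#' Lists unbalanced reactions and non-exempt metabolites sorted by absolute
#' residual (descending, ties by label), plus structural warnings for
#' zero-flux reactions. The `status` follows the CLI exit-status contract:
#' 0 when everything is balanced, 3 when anything is not.
#'
#' @param report A `balance_report`.
#' @return List with `text` (character lines), `data` (a list ready for JSON
#'   serialization) and `status` (0 or 3).
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "balance_report"))
  fail <- report_failures(report)
  status <- if (nrow(fail)) 3L else 0L
  text <- c(sprintf("balance report: condition '%s', timepoint '%s' (tolerance %g)",
                    report$condition, report$timepoint, report$tolerance))
  if (nrow(fail)) {
    text <- c(text, sprintf("%d unbalanced element(s):", nrow(fail)),
              sprintf("  %-10s %-24s residual %+g", fail$kind, fail$label, fail$residual))
  } else text <- c(text, "all balanced")
  if (!is.null(report$reactions) && any(report$reactions$structural_warning)) {
    warn <- report$reactions$label[report$reactions$structural_warning]
    text <- c(text, sprintf("warning: zero-flux reaction(s) structurally unbalanced: %s",
                            paste(warn, collapse = ", ")))
  }
  data <- list(condition = report$condition, timepoint = report$timepoint,
               tolerance = report$tolerance, status = status,
               unbalanced = fail,
               reactions = report$reactions, metabolites = report$metabolites)
  list(text = text, data = data, status = status)
}

#' @export
print.balance_report <- function(x, ...) {
  cat(summarize_report(x)$text, sep = "\n")
  invisible(x)
}
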
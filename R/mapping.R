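#' Per-edge substance flux
#'
#' The flux carried by one metabolite-reaction edge: the absolute reaction
#' flux times the stoichiometric factor of the metabolite in the reaction
#' times the substance weight (traced atoms per molecule). With all weights 1
#' this degenerates to the mass flux `|v| * s`; the sign of `v` is consumed
#' by direction adaptation, not by the magnitude.
#'
#' @param v Signed reaction flux measurement.
#' @param stoichiometry Positive stoichiometric factor.
#' @param weight Nonnegative integer substance weight.
#' @return `|v| * stoichiometry * weight`.
#' @export
effective_edge_flux <- function(v, stoichiometry, weight) {
  if (any(!is.finite(v)) || any(!is.finite(stoichiometry)) || any(!is.finite(weight)))
    fm_stop("numeric_error", "non-finite input to effective_edge_flux")
  abs(v) * stoichiometry * weight
}

#' Enumerate the (condition, timepoint) slices of an experiment
#'
#' Cartesian product of the declared conditions and timepoints in template
#' declaration order, condition-major — the programmatic counterpart of the
#' interactive condition combobox and timepoint slider.
#'
#' @param experiment A [flux_experiment()].
#' @return Data frame with columns `condition`, `timepoint`.
#' @export
list_slices <- function(experiment) {
  stopifnot(inherits(experiment, "flux_experiment"))
  data.frame(condition = rep(experiment$conditions, each = length(experiment$timepoints)),
             timepoint = rep(experiment$timepoints, times = length(experiment$conditions)),
             stringsAsFactors = FALSE)
}

#' Map one (condition, timepoint) slice onto a network
#'
#' Projects the flux measurements of one condition and timepoint onto the
#' bipartite network. Every network edge is preserved: edges of reactions
#' with a nonzero measurement get the per-edge flux
#' [effective_edge_flux()] and, for negative measurements, reversed
#' orientation (reactants become products and vice versa) *within the slice
#' only* — the base network is immutable, so slices from different
#' conditions may disagree on direction. Edges of reactions measured as 0,
#' or not measured in this slice at all, are kept as dashed zero-flux edges,
#' preserving topology even for sparse flux data.
#'
#' @param network A [metabolic_network()] containing all measured reactions.
#' @param experiment A [flux_experiment()].
#' @param condition,timepoint Declared condition and timepoint names.
#' @return A `flux_map_slice`: list with the base `network`, the slice
#'   `edges` table (columns `base_from`, `base_to`, `from`, `to`,
#'   `stoichiometry`, `flux`, `zero`), `edge_flux` (named by base edge key),
#'   `zero_edges`, `reaction_flux` and `reaction_quality` (named by reaction
#'   node id; quality `NA` when absent).
#' @export
map_slice <- function(network, experiment, condition, timepoint) {
  check_network(network)
  stopifnot(inherits(experiment, "flux_experiment"))
  if (!condition %in% experiment$conditions)
    fm_stop("cross_reference_error", sprintf("undeclared condition '%s'", condition))
  if (!timepoint %in% experiment$timepoints)
    fm_stop("cross_reference_error", sprintf("undeclared timepoint '%s'", timepoint))

  m <- experiment$measurements
  m <- m[m$condition == condition & m$timepoint == timepoint, , drop = FALSE]
  rxn_nodes <- network$nodes[network$nodes$kind == "reaction", ]
  unmapped <- setdiff(m$reaction, rxn_nodes$label)
  if (length(unmapped))
    fm_stop("unmapped_measurement",
            sprintf("measured reaction(s) missing from the network: %s",
                    paste(sQuote(unmapped), collapse = ", ")),
            reactions = unmapped)

  v_of <- stats::setNames(m$value, m$reaction)
  q_of <- stats::setNames(m$quality, m$reaction)
  label_of <- stats::setNames(network$nodes$label, network$nodes$id)
  kind_of <- stats::setNames(network$nodes$kind, network$nodes$id)

  e <- network$edges
  rxn_id <- ifelse(kind_of[e$from] == "reaction", e$from, e$to)
  met_id <- ifelse(kind_of[e$from] == "reaction", e$to, e$from)
  rxn_label <- unname(label_of[rxn_id])
  met_label <- unname(label_of[met_id])
  v <- unname(v_of[rxn_label])          # NA where unmeasured
  measured <- !is.na(v) & v != 0

  w <- unname(experiment$weights[met_label])
  if (any(measured & is.na(w)))
    fm_stop("missing_weight_error",
            sprintf("no substance weight for metabolite(s): %s",
                    paste(sQuote(unique(met_label[measured & is.na(w)])), collapse = ", ")))

  flux <- numeric(nrow(e))
  flux[measured] <- effective_edge_flux(v[measured], e$stoichiometry[measured], w[measured])
  flip <- measured & v < 0
  edges <- data.frame(base_from = e$from, base_to = e$to,
                      from = ifelse(flip, e$to, e$from),
                      to = ifelse(flip, e$from, e$to),
                      stoichiometry = e$stoichiometry,
                      flux = flux, zero = !measured,
                      stringsAsFactors = FALSE)
  keys <- edge_key(e$from, e$to)
  rflux <- stats::setNames(rep(0, nrow(rxn_nodes)), rxn_nodes$id)
  hit <- rxn_nodes$label %in% names(v_of)
  rflux[rxn_nodes$id[hit]] <- v_of[rxn_nodes$label[hit]]
  rqual <- stats::setNames(rep(NA_real_, nrow(rxn_nodes)), rxn_nodes$id)
  rqual[rxn_nodes$id[hit]] <- q_of[rxn_nodes$label[hit]]

  structure(list(network = network, condition = condition, timepoint = timepoint,
                 edges = edges,
                 edge_flux = stats::setNames(flux, keys),
                 zero_edges = keys[!measured],
                 reaction_flux = rflux,
                 reaction_quality = rqual,
                 weights = experiment$weights),
            class = "flux_map_slice")
}

#' Serialize a slice as an annotated network
#'
#' Returns the slice as a [metabolic_network()] with the slice's
#' (flux-adapted) edge orientation and per-edge `flux` and `zero` edge
#' attributes plus per-reaction `flux`/`quality` node attributes, ready for
#' [write_network()].
#'
#' @param slice A [map_slice()] result.
#' @return A [metabolic_network()].
#' @export
slice_network <- function(slice) {
  stopifnot(inherits(slice, "flux_map_slice"))
  net <- slice$network
  e <- slice$edges
  edge_attrs <- net$edge_attrs
  for (i in seq_len(nrow(e)))
    edge_attrs[[edge_key(e$from[i], e$to[i])]] <-
      c(edge_attrs[[edge_key(e$from[i], e$to[i])]],
        list(flux = e$flux[i], zero = as.numeric(e$zero[i])))
  node_attrs <- net$node_attrs
  for (id in names(slice$reaction_flux)) {
    at <- node_attrs[[id]]
    at$flux <- unname(slice$reaction_flux[[id]])
    q <- slice$reaction_quality[[id]]
    if (!is.na(q)) at$quality <- unname(q)
    node_attrs[[id]] <- at
  }
  metabolic_network(net$nodes,
                    data.frame(from = e$from, to = e$to,
                               stoichiometry = e$stoichiometry,
                               stringsAsFactors = FALSE),
                    node_attrs, edge_attrs)
}

#' @export
print.flux_map_slice <- function(x, ...) {
  cat(sprintf("<flux_map_slice> condition '%s', timepoint '%s': %d edges (%d zero-flux)\n",
              x$condition, x$timepoint, nrow(x$edges), length(x$zero_edges)))
  invisible(x)
}
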
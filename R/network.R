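#' Construct a bipartite metabolic network
#'
#' A metabolic network is a directed bipartite graph with two node kinds:
#' metabolites and reactions. Edges always connect a metabolite and a
#' reaction (reactant edges metabolite -> reaction, product edges reaction ->
#' metabolite) and carry a positive stoichiometry. Metabolite nodes are
#' identified by `(label, clone_index)` — clones with index > 0 arise from
#' hub splitting (see [split_label()]); reaction labels are unique.
#'
#' @param nodes Data frame with columns `id` (opaque unique string), `kind`
#'   (`"metabolite"` or `"reaction"`), `label`, `clone_index` (integer,
#'   0 for unsplit nodes).
#' @param edges Data frame with columns `from`, `to` (node ids) and
#'   `stoichiometry` (> 0).
#' @param node_attrs,edge_attrs Named lists (by node id / by
#'   `"from->to"` edge key) of named scalar attribute lists; optional.
#' @return A `metabolic_network` object.
#' @export
metabolic_network <- function(nodes, edges, node_attrs = list(), edge_attrs = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    edges <- data.frame(from = character(), to = character(),
                        stoichiometry = numeric(), stringsAsFactors = FALSE)
  nodes$clone_index <- as.integer(nodes$clone_index)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges,
                        node_attrs = node_attrs, edge_attrs = edge_attrs),
                   class = "metabolic_network")
  check_network(net)
  net
}

edge_key <- function(from, to) paste0(from, "->", to)

check_network <- function(net) {
  n <- net$nodes; e <- net$edges
  stopifnot(all(c("id", "kind", "label", "clone_index") %in% names(n)),
            all(c("from", "to", "stoichiometry") %in% names(e)))
  if (anyDuplicated(n$id))
    fm_stop("validation_error", "duplicate node ids")
  if (!all(n$kind %in% c("metabolite", "reaction")))
    fm_stop("validation_error", "node kind must be 'metabolite' or 'reaction'")
  met <- n[n$kind == "metabolite", ]
  if (anyDuplicated(paste(met$label, met$clone_index, sep = "\x1f")))
    fm_stop("validation_error", "metabolite (label, clone_index) pairs must be unique")
  rxn <- n[n$kind == "reaction", ]
  if (anyDuplicated(rxn$label))
    fm_stop("validation_error", "reaction labels must be unique")
  if (nrow(e)) {
    if (any(!is.finite(e$stoichiometry) | e$stoichiometry <= 0))
      fm_stop("validation_error", "edge stoichiometry must be > 0")
    if (any(e$from == e$to))
      fm_stop("validation_error", "self-loops are not allowed")
    kind_of <- stats::setNames(n$kind, n$id)
    if (any(!e$from %in% n$id) || any(!e$to %in% n$id))
      fm_stop("validation_error", "edge endpoint references unknown node id")
    if (any(kind_of[e$from] == kind_of[e$to]))
      fm_stop("validation_error",
              "graph must be bipartite: every edge links a metabolite and a reaction")
    if (anyDuplicated(edge_key(e$from, e$to)))
      fm_stop("validation_error", "parallel edges (same from, to) are not allowed")
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  nm <- sum(x$nodes$kind == "metabolite")
  nr <- sum(x$nodes$kind == "reaction")
  ns <- sum(x$nodes$kind == "metabolite" & x$nodes$clone_index > 0)
  cat(sprintf("<metabolic_network> %d metabolite node%s%s, %d reaction%s, %d edges\n",
              nm, if (nm == 1) "" else "s",
              if (ns) sprintf(" (%d clones)", ns) else "",
              nr, if (nr == 1) "" else "s", nrow(x$edges)))
  invisible(x)
}

met_node_id <- function(label, clone) paste0("met:", label, ":", clone)
rxn_node_id <- function(label) paste0("rxn:", label)

#' Build the bipartite network of an experiment
#'
#' Creates one reaction node per reaction equation and one metabolite node
#' per distinct metabolite label (clone index 0), with reactant edges
#' metabolite -> reaction and product edges reaction -> metabolite, each
#' carrying its stoichiometric factor.
#'
#' @param experiment A [flux_experiment()].
#' @return A [metabolic_network()].
#' @export
network_from_experiment <- function(experiment) {
  stopifnot(inherits(experiment, "flux_experiment"))
  if (length(experiment$reactions) == 0L)
    fm_stop("empty_network", "experiment declares no reactions")
  mets <- unique(unlist(lapply(experiment$reactions, equation_labels)))
  rxns <- vapply(experiment$reactions, function(r) r$name, character(1))
  nodes <- data.frame(
    id = c(met_node_id(mets, 0L), rxn_node_id(rxns)),
    kind = rep(c("metabolite", "reaction"), c(length(mets), length(rxns))),
    label = c(mets, rxns),
    clone_index = 0L,
    stringsAsFactors = FALSE)
  el <- do.call(rbind, lapply(experiment$reactions, function(r) {
    rid <- rxn_node_id(r$name)
    rbind(
      data.frame(from = met_node_id(r$reactants$label, 0L), to = rid,
                 stoichiometry = r$reactants$stoichiometry, stringsAsFactors = FALSE),
      data.frame(from = rid, to = met_node_id(r$products$label, 0L),
                 stoichiometry = r$products$stoichiometry, stringsAsFactors = FALSE))
  }))
  metabolic_network(nodes, el)
}

# incident reactant/product label sets of a reaction node, for topology match
reaction_label_sets <- function(net, rid) {
  lab <- stats::setNames(net$nodes$label, net$nodes$id)
  list(reactants = sort(unique(lab[net$edges$from[net$edges$to == rid]])),
       products  = sort(unique(lab[net$edges$to[net$edges$from == rid]])))
}

#' Add missing template reactions to a network
#'
#' Ensures every reaction of the experiment exists in the network. Reactions
#' already present (matched case-sensitively by reaction label) are left
#' untouched after checking that their incident reactant/product label sets
#' agree with the equation; metabolite nodes are reused by label where they
#' exist. Running the merge on an already-complete network is the identity.
#'
#' @param network A [metabolic_network()].
#' @param experiment A [flux_experiment()].
#' @return The completed network with an attribute-free `report`:
#'   `list(added_reactions =, added_metabolites =)` attached as
#'   `attr(result, "merge_report")`.
#' @export
merge_missing_reactions <- function(network, experiment) {
  check_network(network)
  added_r <- character(); added_m <- character()
  nodes <- network$nodes; edges <- network$edges
  have_rxn <- nodes$label[nodes$kind == "reaction"]
  for (r in experiment$reactions) {
    if (r$name %in% have_rxn) {
      rid <- nodes$id[nodes$kind == "reaction" & nodes$label == r$name]
      net_now <- structure(list(nodes = nodes, edges = edges,
                                node_attrs = network$node_attrs,
                                edge_attrs = network$edge_attrs),
                           class = "metabolic_network")
      got <- reaction_label_sets(net_now, rid)
      want <- list(reactants = sort(unique(r$reactants$label)),
                   products = sort(unique(r$products$label)))
      if (!identical(unname(got$reactants), unname(want$reactants)) ||
          !identical(unname(got$products), unname(want$products)))
        fm_stop("topology_conflict",
                sprintf("reaction '%s' exists with different reactant/product sets", r$name),
                reaction = r$name)
      next
    }
    rid <- rxn_node_id(r$name)
    nodes <- rbind(nodes, data.frame(id = rid, kind = "reaction", label = r$name,
                                     clone_index = 0L, stringsAsFactors = FALSE))
    added_r <- c(added_r, r$name)
    for (lbl in equation_labels(r)) {
      hit <- nodes$kind == "metabolite" & nodes$label == lbl
      if (!any(hit)) {
        nodes <- rbind(nodes, data.frame(id = met_node_id(lbl, 0L), kind = "metabolite",
                                         label = lbl, clone_index = 0L,
                                         stringsAsFactors = FALSE))
        added_m <- c(added_m, lbl)
      }
    }
    # attach to the clone_index-0 node when clones exist
    mid_of <- function(lbl) {
      cand <- nodes[nodes$kind == "metabolite" & nodes$label == lbl, ]
      cand$id[which.min(cand$clone_index)]
    }
    edges <- rbind(edges,
      data.frame(from = vapply(r$reactants$label, mid_of, character(1)), to = rid,
                 stoichiometry = r$reactants$stoichiometry, stringsAsFactors = FALSE),
      data.frame(from = rid, to = vapply(r$products$label, mid_of, character(1)),
                 stoichiometry = r$products$stoichiometry, stringsAsFactors = FALSE))
  }
  out <- metabolic_network(nodes, edges, network$node_attrs, network$edge_attrs)
  attr(out, "merge_report") <- list(added_reactions = added_r,
                                    added_metabolites = added_m)
  out
}

# node degrees (total, summed over clones per label for metabolites)
label_degrees <- function(net) {
  deg <- table(c(net$edges$from, net$edges$to))
  met <- net$nodes[net$nodes$kind == "metabolite", ]
  d <- vapply(split(met$id, met$label),
              function(ids) sum(deg[ids[ids %in% names(deg)]]), numeric(1))
  d[order(-d, names(d))]
}

#' Test two networks for equality
#'
#' Structural equality up to row order: same node table (by id), same edge
#' table (by from/to), same attributes.
#'
#' @param a,b Networks.
#' @return Logical.
#' @export
networks_equal <- function(a, b) {
  na <- a$nodes[order(a$nodes$id), ]; nb <- b$nodes[order(b$nodes$id), ]
  ea <- a$edges[order(a$edges$from, a$edges$to), ]
  eb <- b$edges[order(b$edges$from, b$edges$to), ]
  rownames(na) <- rownames(nb) <- rownames(ea) <- rownames(eb) <- NULL
  sort_attrs <- function(l) if (length(l)) l[order(names(l))] else list()
  isTRUE(all.equal(na, nb)) && isTRUE(all.equal(ea, eb)) &&
    identical(sort_attrs(a$node_attrs), sort_attrs(b$node_attrs)) &&
    identical(sort_attrs(a$edge_attrs), sort_attrs(b$edge_attrs))
}
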
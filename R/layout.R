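#' Rank metabolites by degree of interconnection
#'
#' Orders metabolite labels by total degree (number of incident edges,
#' summed over clones) in descending order, ties broken lexicographically.
#' This is the node list from which hub metabolites — currency compounds
#' such as ATP or CO2 that take part in many reactions — are picked for
#' [split_label()].
#'
#' @param network A [metabolic_network()].
#' @return Data frame with columns `label` and `degree`.
#' @export
rank_by_degree <- function(network) {
  check_network(network)
  d <- label_degrees(network)
  data.frame(label = names(d), degree = as.numeric(d),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split a hub metabolite into per-reaction clones
#'
#' Replaces the (unsplit) metabolite node carrying `label` by one clone per
#' incident reaction; clone indices 1..k are assigned in ascending order of
#' reaction label. Each clone carries exactly the edges linking it to its
#' one reaction (both of them if the metabolite is simultaneously reactant
#' and product of that reaction), so the edge multiset of the network is
#' unchanged and all flux and balance semantics are invariant. A metabolite
#' incident to a single reaction is returned unchanged.
#'
#' @param network A [metabolic_network()].
#' @param label Metabolite label to split.
#' @return The network with the hub split.
#' @export
split_label <- function(network, label) {
  check_network(network)
  met <- network$nodes[network$nodes$kind == "metabolite" &
                         network$nodes$label == label, , drop = FALSE]
  if (nrow(met) == 0L)
    fm_stop("no_such_label", sprintf("no metabolite labeled '%s'", label))
  if (any(met$clone_index > 0L))
    fm_stop("already_split", sprintf("'%s' is already split", label))
  mid <- met$id
  e <- network$edges
  incident <- e$from == mid | e$to == mid
  rxn_ids <- unique(ifelse(e$from[incident] == mid, e$to[incident], e$from[incident]))
  if (length(rxn_ids) <= 1L) return(network)
  rlab <- stats::setNames(network$nodes$label, network$nodes$id)[rxn_ids]
  rxn_ids <- rxn_ids[order(rlab)]

  nodes <- network$nodes[network$nodes$id != mid, , drop = FALSE]
  clones <- data.frame(id = met_node_id(label, seq_along(rxn_ids)),
                       kind = "metabolite", label = label,
                       clone_index = seq_along(rxn_ids), stringsAsFactors = FALSE)
  nodes <- rbind(nodes, clones)

  clone_of <- stats::setNames(clones$id, rxn_ids)
  edge_attrs <- network$edge_attrs
  old_keys <- edge_key(e$from, e$to)
  e$from <- ifelse(e$from == mid, clone_of[e$to], e$from)
  e$to <- ifelse(e$to == mid, clone_of[e$from], e$to)
  new_keys <- edge_key(e$from, e$to)
  changed <- which(old_keys != new_keys & old_keys %in% names(edge_attrs))
  for (i in changed) {
    edge_attrs[[new_keys[i]]] <- edge_attrs[[old_keys[i]]]
    edge_attrs[[old_keys[i]]] <- NULL
  }
  node_attrs <- network$node_attrs
  if (!is.null(node_attrs[[mid]])) {
    for (cid in clones$id) node_attrs[[cid]] <- node_attrs[[mid]]
    node_attrs[[mid]] <- NULL
  }
  metabolic_network(nodes, e, node_attrs, edge_attrs)
}

#' Merge the clones of a split metabolite back into one node
#'
#' Inverse of [split_label()]: all clones carrying `label` are replaced by a
#' single clone-index-0 node with the union of their edges and the node
#' attributes the clones inherited at split time.
#'
#' @param network A [metabolic_network()].
#' @param label A currently split metabolite label.
#' @return The network with the label unsplit.
#' @export
unsplit_label <- function(network, label) {
  check_network(network)
  met <- network$nodes[network$nodes$kind == "metabolite" &
                         network$nodes$label == label, , drop = FALSE]
  if (nrow(met) == 0L)
    fm_stop("no_such_label", sprintf("no metabolite labeled '%s'", label))
  if (all(met$clone_index == 0L))
    fm_stop("not_split", sprintf("'%s' is not split", label))
  mid <- met_node_id(label, 0L)
  clone_ids <- met$id
  nodes <- network$nodes[!network$nodes$id %in% clone_ids, , drop = FALSE]
  nodes <- rbind(nodes, data.frame(id = mid, kind = "metabolite", label = label,
                                   clone_index = 0L, stringsAsFactors = FALSE))
  e <- network$edges
  edge_attrs <- network$edge_attrs
  old_keys <- edge_key(e$from, e$to)
  e$from[e$from %in% clone_ids] <- mid
  e$to[e$to %in% clone_ids] <- mid
  new_keys <- edge_key(e$from, e$to)
  changed <- which(old_keys != new_keys & old_keys %in% names(edge_attrs))
  for (i in changed) {
    edge_attrs[[new_keys[i]]] <- edge_attrs[[old_keys[i]]]
    edge_attrs[[old_keys[i]]] <- NULL
  }
  node_attrs <- network$node_attrs
  first <- clone_ids[which.min(met$clone_index)]
  if (!is.null(node_attrs[[first]])) node_attrs[[mid]] <- node_attrs[[first]]
  for (cid in clone_ids) node_attrs[[cid]] <- NULL
  metabolic_network(nodes, e, node_attrs, edge_attrs)
}

#' Temporarily reconnect the clones of a split metabolite
#'
#' Builds a connector overlay — one connector node plus one overlay edge per
#' clone — that visually re-links all clones sharing a label so the global
#' flux through a split hub can still be tracked. The overlay is a separate
#' object: the base network is untouched, overlays for several labels
#' coexist, they carry no flux, never enter balance validation, and are
#' omitted from standard exports. Rendering styles them distinctly (green).
#'
#' @param x A [metabolic_network()] or a `flux_map_slice`.
#' @param label A metabolite label with at least two clones.
#' @return A `connector_overlay`: list with `label`, `connector_node_id`,
#'   `member_ids`, `overlay_edges`.
#' @export
reconnect_label <- function(x, label) {
  net <- if (inherits(x, "flux_map_slice")) x$network else x
  check_network(net)
  met <- net$nodes[net$nodes$kind == "metabolite" & net$nodes$label == label, , drop = FALSE]
  if (nrow(met) < 2L)
    fm_stop("nothing_to_connect",
            sprintf("'%s' has %d clone(s); need at least 2", label, nrow(met)))
  cid <- paste0("conn:", label)
  structure(list(label = label, connector_node_id = cid,
                 member_ids = met$id,
                 overlay_edges = data.frame(from = cid, to = met$id,
                                            stringsAsFactors = FALSE)),
            class = "connector_overlay")
}

#' Drop a connector overlay
#'
#' Overlays never modify the base network, so removal is simply dropping the
#' overlay from the active list.
#'
#' @param overlays List of `connector_overlay` objects.
#' @param label Label whose overlay to drop.
#' @return The list without that overlay.
#' @export
remove_overlay <- function(overlays, label) {
  Filter(function(o) o$label != label, overlays)
}

#' Hierarchical (DOT-style) layout
#'
#' Computes layered coordinates for a network. With `engine = "dot"` (or
#' `"auto"` when Graphviz is on the `PATH`) the graph is emitted as DOT text
#' and laid out by the external `dot` engine; otherwise a deterministic
#' built-in layered layout is used: longest-path layering from source nodes
#' (back edges of cycles ignored for ranking), barycenter ordering within
#' layers, fixed tie-breaking by node id. Coordinates follow the screen
#' convention — origin top-left, y growing downward, units in points.
#'
#' @param network A [metabolic_network()].
#' @param orientation `"TB"` (layers top to bottom) or `"LR"`.
#' @param engine `"auto"`, `"dot"` or `"builtin"`.
#' @param spacing Distance between adjacent layers / neighbors, in points.
#' @return A `layout_result`: `coordinates` data frame (`id`, `x`, `y`),
#'   `bounding_box` (`width`, `height`), `engine` actually used, and
#'   `fallback` flag set when `dot` was requested but unavailable.
#' @export
layout_dot <- function(network, orientation = c("TB", "LR"),
                       engine = c("auto", "dot", "builtin"), spacing = 80) {
  orientation <- match.arg(orientation)
  engine <- match.arg(engine)
  check_network(network)
  have_dot <- nzchar(Sys.which("dot"))
  fallback <- FALSE
  if (engine == "auto") engine <- if (have_dot) "dot" else "builtin"
  else if (engine == "dot" && !have_dot) {
    fm_warn("layout_fallback", "Graphviz 'dot' not found; using built-in layered layout")
    engine <- "builtin"
    fallback <- TRUE
  }
  coords <- if (engine == "dot") layout_via_dot(network, orientation)
            else layout_layered(network, orientation, spacing)
  bb <- c(width = max(coords$x, 0) + spacing / 2,
          height = max(coords$y, 0) + spacing / 2)
  structure(list(coordinates = coords, bounding_box = bb,
                 engine = engine, fallback = fallback),
            class = "layout_result")
}

#' Emit Graphviz DOT text for a network
#'
#' @param network A [metabolic_network()].
#' @param orientation Rank direction, `"TB"` or `"LR"`.
#' @return A single DOT string.
#' @export
dot_text <- function(network, orientation = "TB") {
  q <- function(s) paste0('"', gsub('"', '\\\\"', s), '"')
  n <- network$nodes
  shapes <- ifelse(n$kind == "reaction", "box", "ellipse")
  paste(c(sprintf("digraph fluxmap {\n  rankdir=%s;", orientation),
          sprintf("  %s [label=%s, shape=%s];", q(n$id), q(n$label), shapes),
          sprintf("  %s -> %s;", q(network$edges$from), q(network$edges$to)),
          "}"), collapse = "\n")
}

layout_via_dot <- function(network, orientation) {
  src <- tempfile(fileext = ".dot"); out <- tempfile(fileext = ".txt")
  on.exit(unlink(c(src, out)), add = TRUE)
  writeLines(dot_text(network, orientation), src)
  status <- system2(Sys.which("dot"), c("-Tplain", shQuote(src)), stdout = out)
  if (!identical(status, 0L))
    fm_stop("io_failure", "Graphviz 'dot' failed")
  lines <- readLines(out)
  nd <- strsplit(grep("^node ", lines, value = TRUE), " +")
  unq <- function(s) gsub('^"|"$', "", s)
  ids <- vapply(nd, function(p) unq(p[[2]]), character(1))
  x <- vapply(nd, function(p) as.numeric(p[[3]]), numeric(1)) * 72
  y <- vapply(nd, function(p) as.numeric(p[[4]]), numeric(1)) * 72
  y <- max(y) - y + 36   # dot's y grows upward; flip to screen convention
  data.frame(id = ids, x = x + 36, y = y, stringsAsFactors = FALSE)[
    match(network$nodes$id, ids), , drop = FALSE]
}

# deterministic layered fallback: longest-path ranks on the DAG obtained by
# ignoring DFS back edges, then barycenter ordering within layers
layout_layered <- function(network, orientation, spacing) {
  ids <- sort(network$nodes$id)
  if (length(ids) == 0L)
    return(data.frame(id = character(), x = numeric(), y = numeric(),
                      stringsAsFactors = FALSE))
  e <- network$edges
  out_adj <- split(e$to, factor(e$from, levels = ids))
  # iterative DFS over all nodes in sorted order, collecting non-back edges
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 on stack, 2 done
  fwd_from <- character(); fwd_to <- character()
  for (root in ids) {
    if (state[[root]] != 0L) next
    stack <- list(list(id = root, nxt = 1L))
    state[[root]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nbrs <- sort(out_adj[[top$id]])
      if (top$nxt <= length(nbrs)) {
        stack[[length(stack)]]$nxt <- top$nxt + 1L
        v <- nbrs[[top$nxt]]
        if (state[[v]] == 0L) {
          fwd_from <- c(fwd_from, top$id); fwd_to <- c(fwd_to, v)
          state[[v]] <- 1L
          stack[[length(stack) + 1L]] <- list(id = v, nxt = 1L)
        } else if (state[[v]] == 2L) {
          fwd_from <- c(fwd_from, top$id); fwd_to <- c(fwd_to, v)  # cross/forward edge
        }                                    # state 1: back edge of a cycle — skip
      } else {
        state[[top$id]] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  # longest-path ranks via Kahn order on the forward DAG
  rank <- stats::setNames(rep(0L, length(ids)), ids)
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  tf <- table(fwd_to); indeg[names(tf)] <- as.integer(tf)
  queue <- sort(ids[indeg == 0L])
  fadj <- split(fwd_to, factor(fwd_from, levels = ids))
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]
    for (v in fadj[[u]]) {
      rank[[v]] <- max(rank[[v]], rank[[u]] + 1L)
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) queue <- sort(c(queue, v))
    }
  }
  # barycenter ordering within layers (3 deterministic sweeps)
  pos <- stats::setNames(rep(0, length(ids)), ids)
  layers <- split(ids, rank[ids])
  layers <- lapply(layers, sort)
  for (l in seq_along(layers)) pos[layers[[l]]] <- seq_along(layers[[l]])
  nbr <- split(c(e$to, e$from), c(e$from, e$to))
  for (sweep in 1:3) {
    ord <- if (sweep %% 2L) seq_along(layers) else rev(seq_along(layers))
    for (l in ord) {
      lay <- layers[[l]]
      bc <- vapply(lay, function(v) {
        nb <- nbr[[v]]
        if (is.null(nb) || !length(nb)) pos[[v]] else mean(pos[nb])
      }, numeric(1))
      lay <- lay[order(bc, lay)]
      layers[[l]] <- lay
      pos[lay] <- seq_along(lay)
    }
  }
  r <- as.numeric(rank[ids]) * spacing + spacing / 2
  p <- as.numeric(pos[ids]) * spacing
  coords <- if (orientation == "TB") data.frame(id = ids, x = p, y = r)
            else data.frame(id = ids, x = r, y = p)
  coords$id <- as.character(coords$id)
  rownames(coords) <- NULL
  coords[match(network$nodes$id, coords$id), , drop = FALSE]
}
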
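#' Read a metabolic network from SBML, GML or SIF
#'
#' SBML (Level 2/3 core subset): `listOfSpecies` become metabolite nodes,
#' `listOfReactions` reaction nodes, `speciesReference` stoichiometries the
#' edge stoichiometries (default 1 per the SBML standard); the `reversible`
#' flag is recorded as a node attribute but never used for edge direction —
#' direction comes from flux data. GML is read through igraph and expects
#' `kind`/`clone` node attributes (as written by [write_network()]); a plain
#' GML file without `kind` is classified by two-coloring with
#' reaction-likeness decided by `reaction_labels`, and fails with a
#' `bipartite_inference_error` rather than guessing. SIF uses the tab-separated
#' dialect `SOURCE<TAB>interaction<TAB>TARGET[<TAB>stoichiometry]` with
#' interaction `rp` (reactant -> reaction) or `pr` (reaction -> product);
#' missing stoichiometries default to 1 with a warning.
#'
#' @param path Input file.
#' @param format `"sbml"`, `"gml"`, `"graphml"` or `"sif"`; default guesses
#'   from the extension.
#' @param reaction_labels Optional character vector of known reaction labels,
#'   used only for bipartite inference on kind-less GML input.
#' @return A [metabolic_network()].
#' @export
read_network <- function(path, format = c("auto", "sbml", "gml", "graphml", "sif"),
                         reaction_labels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", gml = "gml",
                     graphml = "graphml", sif = "sif",
                     fm_stop("io_failure", sprintf("cannot guess network format of '%s'", path)))
  }
  if (!file.exists(path))
    fm_stop("io_failure", sprintf("cannot read network file '%s'", path))
  switch(format,
         sbml = read_sbml_network(path),
         gml = read_igraph_network(path, "gml", reaction_labels),
         graphml = read_igraph_network(path, "graphml", reaction_labels),
         sif = read_sif_network(path))
}

#' Write a metabolic network to GML or GraphML
#'
#' All node and edge attributes (including visual attributes attached by the
#' rendering step) are serialized; `read_network()` on the emitted GML or
#' GraphML file reproduces the network. Serialization goes through igraph;
#' double quotes in GML string attributes are protected as `&quot;` entities.
#'
#' @param network A [metabolic_network()].
#' @param path Output file.
#' @param format `"gml"` or `"graphml"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("auto", "gml", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), gml = "gml",
                     graphml = "graphml",
                     fm_stop("io_failure", sprintf("cannot guess network format of '%s'", path)))
  g <- network_to_igraph(network, escape_gml = (format == "gml"))
  ok <- tryCatch({ igraph::write_graph(g, path, format = format); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    fm_stop("io_failure", sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

# ---- igraph bridge -------------------------------------------------------

gml_escape <- function(x) if (is.character(x)) gsub('"', "&quot;", x, fixed = TRUE) else x
gml_unescape <- function(x) if (is.character(x)) gsub("&quot;", '"', x, fixed = TRUE) else x

network_to_igraph <- function(net, escape_gml = FALSE) {
  esc <- if (escape_gml) gml_escape else identity
  vdf <- data.frame(name = net$nodes$id,
                    nodelabel = esc(net$nodes$label),
                    kind = net$nodes$kind,
                    clone = net$nodes$clone_index,
                    stringsAsFactors = FALSE)
  # collect extra scalar node attributes into columns
  extra <- unique(unlist(lapply(net$node_attrs, names)))
  for (a in extra) {
    vals <- lapply(net$nodes$id, function(id) net$node_attrs[[id]][[a]])
    miss <- vapply(vals, is.null, logical(1))
    if (all(vapply(vals[!miss], is.numeric, logical(1)))) {
      col <- rep(NA_real_, nrow(vdf)); col[!miss] <- unlist(vals[!miss])
    } else {
      col <- rep("", nrow(vdf))
      col[!miss] <- esc(vapply(vals[!miss], function(v) as.character(v)[1], character(1)))
    }
    vdf[[a]] <- col
  }
  edf <- data.frame(from = net$edges$from, to = net$edges$to,
                    stoichiometry = net$edges$stoichiometry,
                    stringsAsFactors = FALSE)
  eextra <- unique(unlist(lapply(net$edge_attrs, names)))
  keys <- edge_key(net$edges$from, net$edges$to)
  for (a in eextra) {
    vals <- lapply(keys, function(k) net$edge_attrs[[k]][[a]])
    miss <- vapply(vals, is.null, logical(1))
    if (all(vapply(vals[!miss], is.numeric, logical(1)))) {
      col <- rep(NA_real_, nrow(edf)); col[!miss] <- unlist(vals[!miss])
    } else {
      col <- rep("", nrow(edf))
      col[!miss] <- esc(vapply(vals[!miss], function(v) as.character(v)[1], character(1)))
    }
    edf[[a]] <- col
  }
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

igraph_to_network <- function(g, unescape = FALSE) {
  une <- if (unescape) gml_unescape else identity
  va <- igraph::vertex_attr(g)
  ids <- if (!is.null(va$name)) as.character(va$name) else as.character(seq_len(igraph::vcount(g)))
  nodes <- data.frame(
    id = ids,
    kind = as.character(va$kind),
    label = une(as.character(if (!is.null(va$nodelabel)) va$nodelabel else ids)),
    clone_index = as.integer(if (!is.null(va$clone)) va$clone else 0L),
    stringsAsFactors = FALSE)
  node_attrs <- list()
  extra_v <- setdiff(names(va), c("name", "nodelabel", "kind", "clone", "id"))
  for (i in seq_along(ids)) {
    at <- list()
    for (a in extra_v) {
      v <- va[[a]][[i]]
      if (!is.null(v) && !(is.na(v)) && !(is.character(v) && !nzchar(v)))
        at[[a]] <- if (is.character(v)) une(v) else v
    }
    if (length(at)) node_attrs[[ids[[i]]]] <- at
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  ea <- igraph::edge_attr(g)
  stoich <- if (!is.null(ea$stoichiometry)) as.numeric(ea$stoichiometry)
            else rep(1, nrow(el))
  edges <- data.frame(from = el[, 1], to = el[, 2], stoichiometry = stoich,
                      stringsAsFactors = FALSE)
  edge_attrs <- list()
  extra_e <- setdiff(names(ea), "stoichiometry")
  keys <- edge_key(edges$from, edges$to)
  for (i in seq_along(keys)) {
    at <- list()
    for (a in extra_e) {
      v <- ea[[a]][[i]]
      if (!is.null(v) && !(is.na(v)) && !(is.character(v) && !nzchar(v)))
        at[[a]] <- if (is.character(v)) une(v) else v
    }
    if (length(at)) edge_attrs[[keys[[i]]]] <- at
  }
  metabolic_network(nodes, edges, node_attrs, edge_attrs)
}

read_igraph_network <- function(path, format, reaction_labels = NULL) {
  g <- tryCatch(igraph::read_graph(path, format = format),
                error = function(e)
                  fm_stop("io_failure", sprintf("cannot parse %s file '%s': %s",
                                                format, path, conditionMessage(e))))
  va <- names(igraph::vertex_attr(g))
  if (!"kind" %in% va)
    g <- infer_bipartite_kinds(g, reaction_labels, path)
  if (!"stoichiometry" %in% names(igraph::edge_attr(g)) && igraph::ecount(g) > 0) {
    fm_warn("default_stoichiometry",
            sprintf("'%s' carries no stoichiometry attribute; defaulting to 1", path))
    g <- igraph::set_edge_attr(g, "stoichiometry", value = 1)
  }
  igraph_to_network(g, unescape = (format == "gml"))
}

# classify kind-less nodes: a two-coloring must exist AND reaction-likeness
# must be decidable from supplied reaction labels; otherwise error, not guess
infer_bipartite_kinds <- function(g, reaction_labels, path) {
  bm <- tryCatch(igraph::bipartite_mapping(igraph::as_undirected(g, mode = "collapse")),
                 error = function(e) list(res = FALSE))
  if (!bm$res)
    fm_stop("bipartite_inference_error",
            sprintf("'%s' is not two-colorable: not a bipartite metabolite-reaction graph", path))
  if (is.null(reaction_labels))
    fm_stop("bipartite_inference_error",
            sprintf(paste0("'%s' carries no 'kind' node attribute; supply ",
                           "reaction_labels to classify the two-coloring"), path))
  va <- igraph::vertex_attr(g)
  labels <- as.character(if (!is.null(va$nodelabel)) va$nodelabel else va$name)
  side <- bm$type
  rxn_hits <- c(sum(labels[!side] %in% reaction_labels),
                sum(labels[side] %in% reaction_labels))
  if (all(rxn_hits == 0) || all(rxn_hits > 0))
    fm_stop("bipartite_inference_error",
            sprintf("'%s': reaction labels do not identify one side of the two-coloring", path))
  rxn_side <- rxn_hits[2] > 0
  igraph::set_vertex_attr(g, "kind",
                          value = ifelse(side == rxn_side, "reaction", "metabolite"))
}

# ---- SBML ----------------------------------------------------------------

read_sbml_network <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    fm_stop("io_failure", sprintf("cannot parse SBML '%s': %s",
                                                  path, conditionMessage(e))))
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx) == 0L)
    fm_stop("template_format_error", sprintf("SBML '%s' contains no reactions", path))
  sp_id <- xml2::xml_attr(sp, "id")
  nodes <- data.frame(id = met_node_id(sp_id, 0L), kind = "metabolite",
                      label = sp_id, clone_index = 0L, stringsAsFactors = FALSE)
  node_attrs <- list()
  sp_name <- xml2::xml_attr(sp, "name")
  for (i in seq_along(sp_id))
    if (!is.na(sp_name[i]) && nzchar(sp_name[i]))
      node_attrs[[met_node_id(sp_id[i], 0L)]] <- list(sbml_name = sp_name[i])

  edges <- NULL
  for (r in rx) {
    rid_raw <- xml2::xml_attr(r, "id")
    rid <- rxn_node_id(rid_raw)
    nodes <- rbind(nodes, data.frame(id = rid, kind = "reaction", label = rid_raw,
                                     clone_index = 0L, stringsAsFactors = FALSE))
    rev <- xml2::xml_attr(r, "reversible")
    if (!is.na(rev)) node_attrs[[rid]] <- list(reversible = rev)
    ref_stoich <- function(nd) {
      s <- xml2::xml_attr(nd, "stoichiometry")
      ifelse(is.na(s), 1, as.numeric(s))   # SBML default stoichiometry is 1
    }
    rea <- xml2::xml_find_all(r, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    pro <- xml2::xml_find_all(r, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    if (length(rea))
      edges <- rbind(edges, data.frame(
        from = met_node_id(xml2::xml_attr(rea, "species"), 0L), to = rid,
        stoichiometry = vapply(rea, ref_stoich, numeric(1)), stringsAsFactors = FALSE))
    if (length(pro))
      edges <- rbind(edges, data.frame(
        from = rid, to = met_node_id(xml2::xml_attr(pro, "species"), 0L),
        stoichiometry = vapply(pro, ref_stoich, numeric(1)), stringsAsFactors = FALSE))
  }
  used <- unique(c(edges$from, edges$to))
  miss <- setdiff(used, nodes$id)
  if (length(miss))
    fm_stop("template_format_error",
            sprintf("SBML '%s': speciesReference to undeclared species: %s",
                    path, paste(sub("^met:(.*):0$", "\\1", miss), collapse = ", ")))
  metabolic_network(nodes, if (is.null(edges)) data.frame() else edges, node_attrs)
}

# ---- SIF -----------------------------------------------------------------

read_sif_network <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    fm_stop("template_format_error", sprintf("SIF '%s' is empty", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad))
    fm_stop("template_format_error",
            sprintf("SIF '%s': line %d has fewer than 3 tab-separated fields", path, bad[1]))
  rel <- vapply(parts, `[[`, "", 2)
  if (any(!rel %in% c("rp", "pr")))
    fm_stop("template_format_error",
            sprintf("SIF '%s': unknown interaction '%s' (expected rp or pr)",
                    path, setdiff(rel, c("rp", "pr"))[1]))
  src <- trimws(vapply(parts, `[[`, "", 1))
  dst <- trimws(vapply(parts, `[[`, "", 3))
  stoich <- vapply(parts, function(x) if (length(x) >= 4L) as.numeric(x[[4]]) else NA_real_,
                   numeric(1))
  if (anyNA(stoich)) {
    fm_warn("default_stoichiometry",
            sprintf("SIF '%s': %d edge(s) without stoichiometry; defaulting to 1",
                    path, sum(is.na(stoich))))
    stoich[is.na(stoich)] <- 1
  }
  met <- ifelse(rel == "rp", src, dst)
  rxn <- ifelse(rel == "rp", dst, src)
  both <- intersect(unique(met), unique(rxn))
  if (length(both))
    fm_stop("bipartite_inference_error",
            sprintf("SIF '%s': label(s) %s appear both as metabolite and reaction",
                    path, paste(sQuote(both), collapse = ", ")))
  mets <- unique(met); rxns <- unique(rxn)
  nodes <- data.frame(
    id = c(met_node_id(mets, 0L), rxn_node_id(rxns)),
    kind = rep(c("metabolite", "reaction"), c(length(mets), length(rxns))),
    label = c(mets, rxns), clone_index = 0L, stringsAsFactors = FALSE)
  edges <- data.frame(
    from = ifelse(rel == "rp", met_node_id(src, 0L), rxn_node_id(src)),
    to   = ifelse(rel == "rp", rxn_node_id(dst), met_node_id(dst, 0L)),
    stoichiometry = stoich, stringsAsFactors = FALSE)
  metabolic_network(nodes, edges)
}
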
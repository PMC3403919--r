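# shared test helpers: independent oracles and small conveniences

# brute-force balance sums from an explicit incidence list, kept independent
# of the package's vectorized implementation
oracle_node_sums <- function(slice) {
  e <- slice$edges
  inc <- rbind(
    data.frame(node = e$from, dir = "out", flux = e$flux, stringsAsFactors = FALSE),
    data.frame(node = e$to, dir = "in", flux = e$flux, stringsAsFactors = FALSE))
  nodes <- unique(c(e$from, e$to))
  res <- data.frame(node = nodes, inflow = 0, outflow = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(inc))) {
    j <- match(inc$node[i], res$node)
    if (inc$dir[i] == "in") res$inflow[j] <- res$inflow[j] + inc$flux[i]
    else res$outflow[j] <- res$outflow[j] + inc$flux[i]
  }
  res
}

# independent two-coloring check by BFS (does not use the 'kind' column)
oracle_bipartite <- function(net) {
  ids <- net$nodes$id
  if (!nrow(net$edges)) return(TRUE)
  adj <- split(c(net$edges$to, net$edges$from), c(net$edges$from, net$edges$to))
  color <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (root in ids) {
    if (!is.na(color[[root]])) next
    color[[root]] <- 0L
    queue <- root
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.na(color[[v]])) { color[[v]] <- 1L - color[[u]]; queue <- c(queue, v) }
        else if (color[[v]] == color[[u]]) return(FALSE)
      }
    }
  }
  TRUE
}

igraph_of <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")], directed = TRUE,
                                     vertices = data.frame(name = net$nodes$id))
  igraph::set_vertex_attr(g, "label", value = net$nodes$label)
}

# isomorphism up to node-id renaming, respecting labels
networks_isomorphic <- function(a, b) {
  ga <- igraph_of(a); gb <- igraph_of(b)
  la <- as.integer(factor(igraph::vertex_attr(ga, "label"),
                          levels = sort(unique(c(a$nodes$label, b$nodes$label)))))
  lb <- as.integer(factor(igraph::vertex_attr(gb, "label"),
                          levels = sort(unique(c(a$nodes$label, b$nodes$label)))))
  igraph::isomorphic(ga, gb, method = "vf2",
                     vertex.color1 = la, vertex.color2 = lb)
}

balanced_labels_ok <- function(report, external) {
  m <- report$metabolites
  all(m$balanced[!m$label %in% external])
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")
fluxmap_cli <- function() system.file("cli", "fluxmap.R", package = "fluxmapr")

run_cli <- function(...) {
  args <- c(fluxmap_cli(), ...)
  out <- suppressWarnings(system2(rscript_bin(), shQuote(args), stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
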
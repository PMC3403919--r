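#' Visual style options for flux maps
#'
#' @param multiplicator Global edge-thickness factor: an edge carrying
#'   per-edge flux `f` is drawn `multiplicator * f` points wide (clamped
#'   below at `min_thickness`).
#' @param min_thickness Minimum stroke width in points; zero-flux edges are
#'   drawn at this width, dashed.
#' @param arrow_ratio Arrowhead width as a multiple of the line thickness;
#'   raise it to emphasize direction over magnitude.
#' @param node_style Reaction-node style: `"normal"`, `"rounded"`,
#'   `"small"` or `"invisible"` (invisible nodes still occupy their
#'   coordinate so edges route through them). Metabolite nodes are always
#'   labeled ellipses unless node attributes override them.
#' @param labels_on Draw reaction-node labels?
#' @param quality_mode `"off"` (all edges black) or `"red_graduation"`:
#'   per-reaction quality values are mapped to a black-to-red ramp applied
#'   to the reaction node and its edges. Both use cases treat quality as a
#'   badness measure (measurement uncertainty, flux variability), so larger
#'   quality means redder; set `invert_quality` for datasets where larger
#'   means better.
#' @param quality_range `c(q_low, q_high)` anchors of the ramp, or `NULL`
#'   to use the finite quality range of the slice.
#' @param invert_quality Reverse the ramp direction.
#' @param zero_dash Dash pattern `c(on, off)` in points for zero-flux edges.
#' @return A `flux_style` list.
#' @export
flux_style <- function(multiplicator = 1, min_thickness = 0.5, arrow_ratio = 1.5,
                       node_style = c("normal", "rounded", "small", "invisible"),
                       labels_on = TRUE,
                       quality_mode = c("off", "red_graduation"),
                       quality_range = NULL, invert_quality = FALSE,
                       zero_dash = c(4, 3)) {
  node_style <- match.arg(node_style)
  quality_mode <- match.arg(quality_mode)
  stopifnot(multiplicator > 0, min_thickness > 0, arrow_ratio > 0,
            length(zero_dash) == 2L, all(zero_dash > 0))
  if (!is.null(quality_range)) {
    stopifnot(length(quality_range) == 2L)
    if (!(quality_range[1] < quality_range[2]))
      fm_stop("validation_error", "quality_range must satisfy q_low < q_high")
  }
  structure(list(multiplicator = multiplicator, min_thickness = min_thickness,
                 arrow_ratio = arrow_ratio, node_style = node_style,
                 labels_on = isTRUE(labels_on), quality_mode = quality_mode,
                 quality_range = quality_range,
                 invert_quality = isTRUE(invert_quality), zero_dash = zero_dash),
            class = "flux_style")
}

#' Edge thickness for a per-edge flux
#'
#' Linear thickness map `max(min_thickness, multiplicator * f)`; zero flux
#' maps to the minimum thickness (such edges are additionally dashed).
#'
#' @param f Nonnegative per-edge flux (vectorized).
#' @param opts A [flux_style()].
#' @return Stroke width(s) in points.
#' @export
thickness_of <- function(f, opts = flux_style()) {
  if (any(!is.finite(f)))
    fm_stop("numeric_error", "non-finite flux passed to thickness_of")
  pmax(opts$min_thickness, opts$multiplicator * f)
}

#' Black-to-red quality ramp
#'
#' Linear RGB ramp used for quality color graduation: black at `q_low`,
#' pure red at `q_high`, clamped outside the range; channel values rounded
#' half-up to integers. Absent qualities (`NA`) map to black, and a
#' degenerate range (`q_low == q_high`) maps everything to black with a
#' warning.
#'
#' @param q Quality value(s).
#' @param q_low,q_high Ramp anchors, `q_low < q_high`.
#' @return Integer matrix with columns `r`, `g`, `b` (one row per `q`).
#' @export
quality_color <- function(q, q_low, q_high) {
  if (q_low == q_high) {
    fm_warn("degenerate_quality_range",
            "q_low == q_high: quality ramp degenerates to black")
    t <- rep(0, length(q))
  } else {
    if (q_low > q_high)
      fm_stop("validation_error", "quality_color requires q_low < q_high")
    t <- pmin(1, pmax(0, (q - q_low) / (q_high - q_low)))
  }
  t[is.na(t)] <- 0
  r <- as.integer(floor(255 * t + 0.5))   # round half up
  cbind(r = r, g = 0L, b = 0L)
}

rgb_hex <- function(rgb) {
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Resolve a slice into a fully styled drawable graph
#'
#' Combines a flux map slice, node coordinates and style options into
#' concrete visual attributes: per-edge stroke widths ([thickness_of()]),
#' dash flags for zero fluxes, arrowhead sizes (`arrow_ratio` times the
#' thickness), quality colors ([quality_color()] of the owning reaction,
#' inherited by its edges), reaction-node styling and green connector
#' overlays. Rendering is pure: identical inputs give identical output.
#'
#' @param slice A [map_slice()] result.
#' @param layout A [layout_dot()] result covering every node.
#' @param opts A [flux_style()].
#' @param overlays List of [reconnect_label()] overlays to draw.
#' @return A `styled_graph` with `nodes`, `edges`, `bounding_box`, `opts`
#'   and the originating `slice`.
#' @export
style_slice <- function(slice, layout, opts = flux_style(), overlays = list()) {
  stopifnot(inherits(slice, "flux_map_slice"), inherits(layout, "layout_result"))
  net <- slice$network
  co <- layout$coordinates
  idx <- match(net$nodes$id, co$id)
  if (anyNA(idx) || any(!is.finite(co$x[idx])) || any(!is.finite(co$y[idx])))
    fm_stop("layout_coverage_error", "layout does not cover every node")
  x <- co$x[idx]; y <- co$y[idx]
  xy <- stats::setNames(seq_along(net$nodes$id), net$nodes$id)

  # reaction quality -> fill color
  q <- slice$reaction_quality
  if (opts$quality_mode == "red_graduation") {
    qr <- opts$quality_range
    if (is.null(qr)) {
      fin <- q[is.finite(q)]
      qr <- if (length(fin) && min(fin) < max(fin)) range(fin) else c(0, 1)
    }
    qq <- if (opts$invert_quality) qr[1] + qr[2] - q else q
    rcol <- rgb_hex(quality_color(qq, qr[1], qr[2]))
  } else rcol <- rep("#000000", length(q))
  names(rcol) <- names(q)

  is_rxn <- net$nodes$kind == "reaction"
  shape <- ifelse(is_rxn,
                  switch(opts$node_style, rounded = "roundrect", "rect"),
                  "ellipse")
  wdt <- ifelse(is_rxn, switch(opts$node_style, small = 10, 46), 60)
  hgt <- ifelse(is_rxn, switch(opts$node_style, small = 10, 18), 26)
  fill <- ifelse(is_rxn & opts$quality_mode == "red_graduation",
                 unname(rcol[net$nodes$id]), "#ffffff")
  fill[is.na(fill)] <- "#ffffff"
  opacity <- ifelse(is_rxn & opts$node_style == "invisible", 0, 1)
  label_on <- ifelse(is_rxn, opts$labels_on & opts$node_style != "invisible", TRUE)
  # user attribute pass-through (e.g. manual fill for sink/transport nodes)
  for (i in seq_along(net$nodes$id)) {
    at <- net$node_attrs[[net$nodes$id[i]]]
    if (!is.null(at$fill)) fill[i] <- at$fill
  }
  nodes <- data.frame(id = net$nodes$id, label = net$nodes$label,
                      kind = net$nodes$kind, x = x, y = y, shape = shape,
                      width = wdt, height = hgt, fill = fill,
                      opacity = opacity, label_on = label_on,
                      overlay = FALSE, stringsAsFactors = FALSE)

  e <- slice$edges
  thick <- thickness_of(e$flux, opts)
  rxn_of <- ifelse(e$from %in% net$nodes$id[is_rxn], e$from, e$to)
  ecol <- if (opts$quality_mode == "red_graduation") unname(rcol[rxn_of])
          else rep("#000000", nrow(e))
  edges <- data.frame(from = e$from, to = e$to,
                      x1 = x[xy[e$from]], y1 = y[xy[e$from]],
                      x2 = x[xy[e$to]], y2 = y[xy[e$to]],
                      thickness = thick, color = ecol, dashed = e$zero,
                      arrow_size = opts$arrow_ratio * thick,
                      overlay = FALSE, stringsAsFactors = FALSE)

  for (ov in overlays) {
    stopifnot(inherits(ov, "connector_overlay"))
    mi <- xy[ov$member_ids]
    cx <- mean(x[mi]); cy <- mean(y[mi])
    nodes <- rbind(nodes, data.frame(
      id = ov$connector_node_id, label = ov$label, kind = "connector",
      x = cx, y = cy, shape = "ellipse", width = 16, height = 16,
      fill = "#00a000", opacity = 1, label_on = FALSE, overlay = TRUE,
      stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(
      from = ov$connector_node_id, to = ov$member_ids,
      x1 = cx, y1 = cy, x2 = x[mi], y2 = y[mi],
      thickness = 1, color = "#00a000", dashed = FALSE, arrow_size = 0,
      overlay = TRUE, stringsAsFactors = FALSE))
  }

  structure(list(nodes = nodes, edges = edges,
                 bounding_box = layout$bounding_box,
                 opts = opts, slice = slice),
            class = "styled_graph")
}

#' @export
print.styled_graph <- function(x, ...) {
  cat(sprintf("<styled_graph> %d nodes, %d edges (%d dashed, %d overlay), canvas %.0f x %.0f pt\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$dashed),
              sum(x$edges$overlay), x$bounding_box[1], x$bounding_box[2]))
  invisible(x)
}
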
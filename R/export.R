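svg_num <- function(x) sprintf("%.3f", x)   # 3-decimal lengths: byte-stable output

#' Export a styled flux map as SVG
#'
#' Deterministic, timestamp-free SVG emission: every edge is one `<line>`
#' element whose `stroke-width` equals its resolved thickness printed with
#' exactly three decimals, dashed zero-flux edges carry the configured
#' `stroke-dasharray`, arrowheads are filled triangles sized by the
#' arrowhead ratio, and node fills carry the quality colors. Re-exporting
#' identical input yields a byte-identical file.
#'
#' @param styled A [style_slice()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_svg <- function(styled, path) {
  stopifnot(inherits(styled, "styled_graph"))
  bb <- styled$bounding_box
  dash <- paste(svg_num(styled$opts$zero_dash), collapse = ",")
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            svg_num(bb[1]), svg_num(bb[2]), svg_num(bb[1]), svg_num(bb[2])))
  e <- styled$edges
  for (i in seq_len(nrow(e))) {
    out <- c(out, sprintf(
      '<line class="edge" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
      svg_num(e$x1[i]), svg_num(e$y1[i]), svg_num(e$x2[i]), svg_num(e$y2[i]),
      e$color[i], svg_num(e$thickness[i]),
      if (e$dashed[i]) sprintf(' stroke-dasharray="%s"', dash) else ""))
    if (!e$overlay[i] && e$arrow_size[i] > 0) {
      tri <- arrow_triangle(e$x1[i], e$y1[i], e$x2[i], e$y2[i], e$arrow_size[i])
      if (!is.null(tri))
        out <- c(out, sprintf('<polygon class="arrow" points="%s" fill="%s"/>',
                              paste(svg_num(t(tri)), collapse = " "), e$color[i]))
    }
  }
  n <- styled$nodes
  for (i in seq_len(nrow(n))) {
    style_extra <- if (n$opacity[i] < 1) sprintf(' opacity="%s"', svg_num(n$opacity[i])) else ""
    if (n$shape[i] == "ellipse") {
      out <- c(out, sprintf(
        '<ellipse class="node" cx="%s" cy="%s" rx="%s" ry="%s" fill="%s" stroke="#000000" stroke-width="0.500"%s/>',
        svg_num(n$x[i]), svg_num(n$y[i]), svg_num(n$width[i] / 2), svg_num(n$height[i] / 2),
        n$fill[i], style_extra))
    } else {
      rx <- if (n$shape[i] == "roundrect") ' rx="5.000"' else ""
      out <- c(out, sprintf(
        '<rect class="node" x="%s" y="%s" width="%s" height="%s"%s fill="%s" stroke="#000000" stroke-width="0.500"%s/>',
        svg_num(n$x[i] - n$width[i] / 2), svg_num(n$y[i] - n$height[i] / 2),
        svg_num(n$width[i]), svg_num(n$height[i]), rx, n$fill[i], style_extra))
    }
    if (isTRUE(n$label_on[i]))
      out <- c(out, sprintf(
        '<text class="label" x="%s" y="%s" text-anchor="middle" font-family="sans-serif" font-size="9">%s</text>',
        svg_num(n$x[i]), svg_num(n$y[i] + 3), xml_escape(n$label[i])))
  }
  out <- c(out, "</svg>")
  ok <- tryCatch({ writeLines(out, path, useBytes = TRUE); TRUE },
                 error = function(e2) e2)
  if (!isTRUE(ok))
    fm_stop("io_failure", sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

# filled triangle at the target end, width = arrow size, length 1.5 * size
arrow_triangle <- function(x1, y1, x2, y2, size) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len < 1e-9) return(NULL)
  ux <- dx / len; uy <- dy / len
  px <- -uy; py <- ux
  tipx <- x2; tipy <- y2
  bx <- tipx - 1.5 * size * ux; by <- tipy - 1.5 * size * uy
  rbind(c(tipx, tipy),
        c(bx + size / 2 * px, by + size / 2 * py),
        c(bx - size / 2 * px, by - size / 2 * py))
}

#' Export a styled flux map as PNG
#'
#' Rasterizes the same geometry as [export_svg()] on an R `png` device; the
#' raster dimensions are the SVG canvas times `dpi / 72`.
#'
#' @param styled A [style_slice()] result.
#' @param path Output path.
#' @param dpi Raster resolution (default 72: one pixel per point).
#' @return `path`, invisibly.
#' @export
export_png <- function(styled, path, dpi = 72) {
  stopifnot(inherits(styled, "styled_graph"))
  bb <- styled$bounding_box
  wpx <- max(1L, round(bb[1] * dpi / 72))
  hpx <- max(1L, round(bb[2] * dpi / 72))
  ok <- tryCatch({
    grDevices::png(path, width = wpx, height = hpx, units = "px")
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, bb[1]), ylim = c(bb[2], 0))
    e <- styled$edges
    scale <- dpi / 72
    if (nrow(e)) {
      graphics::segments(e$x1, e$y1, e$x2, e$y2, col = e$color,
                         lwd = pmax(1, e$thickness * scale),
                         lty = ifelse(e$dashed, 2, 1))
      for (i in which(!e$overlay & e$arrow_size > 0)) {
        tri <- arrow_triangle(e$x1[i], e$y1[i], e$x2[i], e$y2[i], e$arrow_size[i])
        if (!is.null(tri))
          graphics::polygon(tri[, 1], tri[, 2], col = e$color[i], border = NA)
      }
    }
    n <- styled$nodes
    vis <- n$opacity > 0
    graphics::symbols(n$x[vis], n$y[vis], rectangles = cbind(n$width[vis], n$height[vis]),
                      inches = FALSE, add = TRUE, bg = n$fill[vis], fg = "black")
    lab <- vis & n$label_on
    graphics::text(n$x[lab], n$y[lab], n$label[lab], cex = 0.6)
    TRUE
  }, error = function(er) er)
  if (!isTRUE(ok))
    fm_stop("io_failure", sprintf("cannot render PNG '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Export a styled flux map as attribute-annotated GML/GraphML
#'
#' Serializes the slice's network through [write_network()] with the
#' resolved visual attributes attached: node `x`, `y` and `fill`, edge
#' `thickness`, `dashed` and `rgb` stroke color, plus the slice's per-edge
#' `flux`. Edges keep the slice's (flux-adapted) orientation. Connector
#' overlays are omitted unless `include_overlays = TRUE`, in which case
#' connector nodes are serialized as overlay-flagged auxiliary nodes.
#'
#' @param styled A [style_slice()] result.
#' @param path Output path.
#' @param format `"gml"` or `"graphml"` (default from extension).
#' @param include_overlays Also serialize connector overlays?
#' @return `path`, invisibly.
#' @export
export_annotated <- function(styled, path, format = c("auto", "gml", "graphml"),
                             include_overlays = FALSE) {
  stopifnot(inherits(styled, "styled_graph"))
  slice <- styled$slice
  net <- slice$network
  n <- styled$nodes
  node_attrs <- net$node_attrs
  for (i in seq_len(nrow(n))) {
    if (n$overlay[i] && !include_overlays) next
    id <- n$id[i]
    at <- node_attrs[[id]]
    at$x <- n$x[i]; at$y <- n$y[i]; at$fill <- n$fill[i]
    if (n$overlay[i]) at$overlay <- 1
    node_attrs[[id]] <- at
  }
  e <- styled$edges
  se <- slice$edges
  edge_attrs <- net$edge_attrs
  edges <- data.frame(from = se$from, to = se$to, stoichiometry = se$stoichiometry,
                      stringsAsFactors = FALSE)
  base_idx <- which(!e$overlay)
  for (j in seq_along(base_idx)) {
    i <- base_idx[j]
    k <- edge_key(e$from[i], e$to[i])
    at <- edge_attrs[[k]]
    at$thickness <- e$thickness[i]
    at$dashed <- as.numeric(e$dashed[i])
    at$rgb <- e$color[i]
    at$flux <- se$flux[j]
    edge_attrs[[k]] <- at
  }
  nodes <- net$nodes
  if (include_overlays && any(n$overlay)) {
    ov <- n[n$overlay, , drop = FALSE]
    # connectors are serialized on the reaction side of the bipartition
    nodes <- rbind(nodes, data.frame(id = ov$id, kind = "reaction",
                                     label = paste0("overlay:", ov$label),
                                     clone_index = 0L, stringsAsFactors = FALSE))
    oe <- e[e$overlay, , drop = FALSE]
    edges <- rbind(edges, data.frame(from = oe$from, to = oe$to, stoichiometry = 1,
                                     stringsAsFactors = FALSE))
    for (i in seq_len(nrow(oe)))
      edge_attrs[[edge_key(oe$from[i], oe$to[i])]] <- list(overlay = 1)
  }
  out <- metabolic_network(nodes, edges, node_attrs, edge_attrs)
  write_network(out, path, format)
}
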
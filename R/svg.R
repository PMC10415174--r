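# Deterministic SVG 1.1 output: fixed element order, fixed number
# formatting, no timestamps -- equal inputs give byte-identical files.

svg_defaults <- function() {
  list(width = 640, height = 480, margin = 60, point_radius = 3,
       background = "#ffffff", font = "sans-serif", font_size = 12,
       colors = c(up = "#c0392b", down = "#2980b9",
                  not_significant = "#b0b0b0", point = "#34495e"),
       heatmap_low = "#2166ac", heatmap_mid = "#f7f7f7",
       heatmap_high = "#b2182b", stroke = "#333333")
}

merge_style <- function(style) {
  def <- svg_defaults()
  for (nm in names(style)) {
    if (nm == "colors") {
      def$colors[names(style$colors)] <- unlist(style$colors)
    } else {
      def[[nm]] <- style[[nm]]
    }
  }
  def
}

svg_num <- function(x) sprintf("%.3f", x)

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_open <- function(st) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            svg_num(st$width), svg_num(st$height), svg_num(st$width),
            svg_num(st$height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="%s"/>',
            svg_num(st$width), svg_num(st$height), st$background))
}

# linear map of data range onto the plotting area (y inverted)
svg_scale <- function(vals, lo_px, hi_px) {
  rng <- range(vals, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (rng[1] == rng[2]) rng <- rng + c(-1, 1)
  pad <- 0.04 * (rng[2] - rng[1])
  rng <- rng + c(-pad, pad)
  function(v) lo_px + (v - rng[1]) / (rng[2] - rng[1]) * (hi_px - lo_px)
}

svg_axes <- function(st, xlab, ylab) {
  m <- st$margin
  c(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
            svg_num(m), svg_num(st$height - m), svg_num(st$width - m),
            svg_num(st$height - m), st$stroke),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
            svg_num(m), svg_num(m), svg_num(m), svg_num(st$height - m),
            st$stroke),
    sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="middle">%s</text>',
            svg_num(st$width / 2), svg_num(st$height - m / 3), st$font,
            svg_num(st$font_size), svg_escape(xlab)),
    sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="middle" transform="rotate(-90 %s %s)">%s</text>',
            svg_num(m / 3), svg_num(st$height / 2), st$font,
            svg_num(st$font_size), svg_num(m / 3), svg_num(st$height / 2),
            svg_escape(ylab)))
}

write_svg_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Render plot data to a deterministic SVG file
#'
#' Writes well-formed SVG 1.1. Element order and number formatting are fixed
#' and no timestamps are embedded, so equal inputs and style produce
#' byte-identical files. Methods exist for [volcano_data()] (one `<circle>`
#' per plotted protein), [pca_analysis()] scores, [heatmap_data()] (one
#' `<rect>` per cell) and [hcluster()] dendrograms.
#'
#' @param plot The plot data object.
#' @param path Output file path.
#' @param style Named list overriding the documented defaults (`width`,
#'   `height`, `margin`, `point_radius`, `background`, `font`, `font_size`,
#'   `colors`, `heatmap_low/mid/high`, `stroke`).
#' @param ... Passed to methods.
#' @return `path`, invisibly.
#' @export
render_svg <- function(plot, path, style = list(), ...) {
  UseMethod("render_svg")
}

#' @rdname render_svg
#' @export
render_svg.volcano_data <- function(plot, path, style = list(), ...) {
  st <- merge_style(style)
  m <- st$margin
  pts <- plot[plot$class != "skipped" & !is.na(plot$x) & !is.na(plot$y), ]
  sx <- svg_scale(pts$x, m, st$width - m)
  sy <- svg_scale(pts$y, st$height - m, m)
  lines <- c(
    svg_open(st),
    svg_axes(st, "log2 fold change",
             if (attr(plot, "use_adjusted")) "-log10 q" else "-log10 p"),
    vapply(seq_len(nrow(pts)), function(i) {
      sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" class="point %s"/>',
              svg_num(sx(pts$x[i])), svg_num(sy(pts$y[i])),
              svg_num(st$point_radius),
              st$colors[[pts$class[i]]] %||% st$colors[["point"]],
              pts$class[i])
    }, character(1)),
    lab_lines <- {
      lab <- pts[!is.na(pts$label), ]
      if (nrow(lab) == 0) character() else
        sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s">%s</text>',
                svg_num(sx(lab$x) + 4), svg_num(sy(lab$y) - 4), st$font,
                svg_num(st$font_size * 0.8), svg_escape(lab$label))
    },
    "</svg>")
  write_svg_lines(lines, path)
}

#' @rdname render_svg
#' @export
render_svg.lfq_pca <- function(plot, path, style = list(), ...) {
  st <- merge_style(style)
  m <- st$margin
  sc <- plot$scores
  if (ncol(sc) < 2) abort("PCA SVG needs at least 2 components")
  sx <- svg_scale(sc[, 1], m, st$width - m)
  sy <- svg_scale(sc[, 2], st$height - m, m)
  evr <- plot$explained_variance_ratio
  lines <- c(
    svg_open(st),
    svg_axes(st, sprintf("PC1 (%.1f%%)", 100 * evr[1]),
             sprintf("PC2 (%.1f%%)", 100 * evr[2])),
    vapply(seq_len(nrow(sc)), function(i) {
      sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" class="point"><title>%s</title></circle>',
              svg_num(sx(sc[i, 1])), svg_num(sy(sc[i, 2])),
              svg_num(st$point_radius), st$colors[["point"]],
              svg_escape(rownames(sc)[i]))
    }, character(1)),
    "</svg>")
  write_svg_lines(lines, path)
}

#' @rdname render_svg
#' @export
render_svg.heatmap_data <- function(plot, path, style = list(), ...) {
  st <- merge_style(style)
  m <- st$margin
  mat <- plot$matrix
  nr <- nrow(mat); nc <- ncol(mat)
  cw <- (st$width - 2 * m) / nc
  ch <- (st$height - 2 * m) / nr
  rng <- range(mat)
  if (rng[1] == rng[2]) rng <- rng + c(-1, 1)
  ramp <- grDevices::colorRamp(c(st$heatmap_low, st$heatmap_mid,
                                 st$heatmap_high))
  cells <- character(nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- (mat[i, j] - rng[1]) / (rng[2] - rng[1])
      rgb <- round(ramp(v))
      k <- k + 1L
      cells[k] <- sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="#%02x%02x%02x" class="cell"/>',
        svg_num(m + (j - 1) * cw), svg_num(m + (i - 1) * ch),
        svg_num(cw), svg_num(ch), rgb[1], rgb[2], rgb[3])
    }
  }
  lines <- c(svg_open(st), cells, "</svg>")
  write_svg_lines(lines, path)
}

#' @rdname render_svg
#' @export
render_svg.lfq_hclust <- function(plot, path, style = list(), ...) {
  st <- merge_style(style)
  m <- st$margin
  hc <- plot$hclust
  n <- length(plot$labels)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  sx <- svg_scale(c(0.5, n + 0.5), m, st$width - m)
  max_h <- max(hc$height)
  if (max_h == 0) max_h <- 1
  sy <- svg_scale(c(0, max_h), st$height - m, m)

  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  get_x <- function(id) if (id < 0) leaf_x[-id] else node_x[id]
  get_h <- function(id) if (id < 0) 0 else node_h[id]
  segs <- character()
  for (s in seq_len(nrow(hc$merge))) {
    l <- hc$merge[s, 1]; r <- hc$merge[s, 2]
    xl <- get_x(l); xr <- get_x(r)
    node_x[s] <- (xl + xr) / 2
    seg <- function(x1, y1, x2, y2) {
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" class="branch"/>',
              svg_num(sx(x1)), svg_num(sy(y1)), svg_num(sx(x2)),
              svg_num(sy(y2)), st$stroke)
    }
    segs <- c(segs,
              seg(xl, get_h(l), xl, node_h[s]),
              seg(xr, get_h(r), xr, node_h[s]),
              seg(xl, node_h[s], xr, node_h[s]))
  }
  leaves <- vapply(seq_len(n), function(i) {
    sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="middle" class="leaf">%s</text>',
            svg_num(sx(leaf_x[i])), svg_num(st$height - m + st$font_size),
            st$font, svg_num(st$font_size * 0.8), svg_escape(plot$labels[i]))
  }, character(1))
  lines <- c(svg_open(st), segs, leaves, "</svg>")
  write_svg_lines(lines, path)
}
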
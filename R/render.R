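#' Bundle rendering parameters
#'
#' All knobs of the sequence-bundle drawing engine: grid cell size,
#' thread curvature and opacity, colours, the stacking band and the
#' marker strip. Curvature c in [0, 0.5] sets the Bezier control points
#' at horizontal offsets +/- c * cell_width from the segment endpoints;
#' c = 0 degenerates to straight polylines. Thread opacity defaults to
#' min(1, max(0.02, 8 / n_seq)) at layout time so dense bundles stay
#' readable.
#'
#' @param cell_width,cell_height Grid cell size in px.
#' @param curvature Bezier curvature c in [0, 0.5].
#' @param thread_opacity Stroke opacity in (0, 1], or NULL for the
#'   density-scaled default.
#' @param thread_width Stroke width in px.
#' @param ordering_name Alphabet ordering for the y-axis (default the
#'   alphabet's "alphabetical" ordering).
#' @param default_color,selection_color Thread colours (hex).
#' @param stack_band Fraction of the cell height used for stacking
#'   lanes, in [0, 1].
#' @param max_lanes Maximum number of stacking lanes per cell.
#' @param marker_band_height Height in px of the site-marker strip.
#' @param marker_color Site-marker fill colour.
#' @param show_gap_row Route gap symbols to a dedicated gap row below
#'   the alphabet (default); if FALSE, threads interpolate across gap
#'   columns.
#' @return Object of class `render_spec`.
#' @export
render_spec <- function(cell_width = 28, cell_height = 18,
                        curvature = 0.35, thread_opacity = NULL,
                        thread_width = 1.2,
                        ordering_name = "alphabetical",
                        default_color = "#3B5B92",
                        selection_color = "#D62728",
                        stack_band = 0.6, max_lanes = 32L,
                        marker_band_height = 14,
                        marker_color = "#2CA02C",
                        show_gap_row = TRUE) {
  if (cell_width <= 0 || cell_height <= 0 || thread_width <= 0 ||
      marker_band_height <= 0)
    bk_stop("config_error", "render dimensions must be positive")
  if (curvature < 0 || curvature > 0.5)
    bk_stop("config_error", "curvature must lie in [0, 0.5]")
  if (!is.null(thread_opacity) &&
      (thread_opacity <= 0 || thread_opacity > 1))
    bk_stop("config_error", "thread_opacity must lie in (0, 1]")
  if (stack_band < 0 || stack_band > 1)
    bk_stop("config_error", "stack_band must lie in [0, 1]")
  if (max_lanes < 1L) bk_stop("config_error", "max_lanes must be >= 1")
  structure(list(cell_width = cell_width, cell_height = cell_height,
                 curvature = curvature, thread_opacity = thread_opacity,
                 thread_width = thread_width,
                 ordering_name = ordering_name,
                 default_color = default_color,
                 selection_color = selection_color,
                 stack_band = stack_band, max_lanes = as.integer(max_lanes),
                 marker_band_height = marker_band_height,
                 marker_color = marker_color,
                 show_gap_row = show_gap_row),
            class = "render_spec")
}

MARGIN_LEFT <- 46
MARGIN_RIGHT <- 12
MARGIN_TOP_EXTRA <- 8
MARGIN_BOTTOM <- 26
GAP_GUTTER_FRAC <- 0.5

#' Lay out bundle threads
#'
#' Computes, for every sequence, one anchor point per alignment column:
#' x at the column centre, y at the centre of the symbol's row plus a
#' stacking offset. Sequences sharing a cell are stacked into lanes
#' (lane = rank among sharers by row index, modulo `max_lanes`), evenly
#' spaced inside a vertical band of height `stack_band * cell_height`,
#' so identical sequences remain individually visible. The gap symbol
#' is routed to a dedicated row below the alphabet (or skipped when
#' `show_gap_row` is FALSE). Fully deterministic.
#'
#' @param x An `msa`.
#' @param spec A `render_spec`.
#' @return Object of class `bundle_layout`.
#' @export
layout_threads <- function(x, spec = render_spec()) {
  ord <- x$alphabet$orderings[[spec$ordering_name]]
  if (is.null(ord))
    bk_stop("config_error", "alphabet '%s' has no ordering '%s'",
            x$alphabet$name, spec$ordering_name)
  gap <- x$alphabet$gap_symbol
  n_rows <- length(ord)
  row_of <- stats::setNames(seq_len(n_rows), ord)
  gap_row_y <- NULL
  top <- spec$marker_band_height + MARGIN_TOP_EXTRA
  row_y <- top + (seq_len(n_rows) - 0.5) * spec$cell_height
  names(row_y) <- ord
  grid_bottom <- top + n_rows * spec$cell_height
  if (spec$show_gap_row) {
    gap_row_y <- grid_bottom + (GAP_GUTTER_FRAC + 0.5) * spec$cell_height
    total_bottom <- grid_bottom + (GAP_GUTTER_FRAC + 1) * spec$cell_height
  } else {
    total_bottom <- grid_bottom
  }
  m <- msa_matrix(x)
  col_x <- MARGIN_LEFT + (seq_len(x$n_col) - 0.5) * spec$cell_width
  ax <- matrix(rep(col_x, each = x$n_seq), nrow = x$n_seq)
  ay <- matrix(NA_real_, x$n_seq, x$n_col)
  band <- spec$stack_band * spec$cell_height
  for (j in seq_len(x$n_col)) {
    ch <- m[, j]
    for (s in unique(ch)) {
      members <- which(ch == s)
      if (s == gap && !spec$show_gap_row) next   # anchor skipped
      base_y <- if (s == gap) gap_row_y else row_y[[s]]
      lanes <- (seq_along(members) - 1L) %% spec$max_lanes
      n_lanes <- min(length(members), spec$max_lanes)
      off <- ((lanes + 0.5) / n_lanes - 0.5) * band
      ay[members, j] <- base_y + off
    }
  }
  structure(list(
    anchors_x = ax, anchors_y = ay,
    labels = x$labels, n_seq = x$n_seq, n_col = x$n_col,
    symbols = ord, gap_symbol = gap, row_y = row_y,
    gap_row_y = gap_row_y, col_x = col_x, top = top,
    grid_bottom = grid_bottom,
    width = MARGIN_LEFT + x$n_col * spec$cell_width + MARGIN_RIGHT,
    height = total_bottom + MARGIN_BOTTOM,
    spec = spec), class = "bundle_layout")
}

thread_colors <- function(layout, spec, groups, selection) {
  cols <- rep(spec$default_color, layout$n_seq)
  if (!is.null(groups)) {
    idx <- match(names(groups$membership), layout$labels)
    ok <- !is.na(idx)
    cols[idx[ok]] <- unname(groups$colors[groups$membership[ok]])
  }
  if (!is.null(selection) && length(selection$seq_indices))
    cols[selection$seq_indices] <- spec$selection_color
  cols
}

effective_opacity <- function(spec, n_seq) {
  if (!is.null(spec$thread_opacity)) spec$thread_opacity
  else min(1, max(0.02, 8 / n_seq))
}

fmt <- function(v) {
  s <- sprintf("%.3f", v)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

# Cubic Bezier control points of the segment (x0,y0) -> (x1,y1) under
# the curvature rule: horizontal offsets +/- c * cell_width.
segment_controls <- function(x0, y0, x1, y1, c, cell_width) {
  dx <- c * cell_width
  list(c1x = x0 + dx, c1y = y0, c2x = x1 - dx, c2y = y1)
}

thread_path_d <- function(xs, ys, c, cell_width) {
  keep <- !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (!length(xs)) return(NULL)
  d <- sprintf("M %s %s", fmt(xs[1]), fmt(ys[1]))
  if (length(xs) > 1L) {
    for (i in seq_len(length(xs) - 1L)) {
      ct <- segment_controls(xs[i], ys[i], xs[i + 1L], ys[i + 1L],
                             c, cell_width)
      d <- paste0(d, sprintf(" C %s %s, %s %s, %s %s",
                             fmt(ct$c1x), fmt(ct$c1y), fmt(ct$c2x),
                             fmt(ct$c2y), fmt(xs[i + 1L]),
                             fmt(ys[i + 1L])))
    }
  }
  d
}

#' Render a sequence bundle as SVG
#'
#' Emits one `<path class="thread">` per sequence (with a `data-label`
#' attribute), the symbol/position grid, axis labels, and optionally a
#' strip of green site markers (`class="site-marker"`) whose
#' fill-opacity encodes per-column scores. Thread colour precedence:
#' selection colour, then group colour, then default. Output is a pure
#' function of its inputs (byte-stable).
#'
#' @param layout A `bundle_layout`.
#' @param spec The `render_spec` used for the layout.
#' @param groups Optional `group_assignment` for thread colouring.
#' @param selection Optional `bk_selection`; selected threads use the
#'   selection colour and are drawn on top.
#' @param markers Optional numeric vector of per-column opacities in
#'   [0, 1], length n_col.
#' @return Single string: the SVG 1.1 document.
#' @export
render_svg <- function(layout, spec = layout$spec, groups = NULL,
                       selection = NULL, markers = NULL) {
  if (!is.null(markers) && length(markers) != layout$n_col)
    bk_stop("input_error", "markers must have one value per column (%d)",
            layout$n_col)
  cols <- thread_colors(layout, spec, groups, selection)
  opacity <- effective_opacity(spec, layout$n_seq)
  out <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
           'width="%s" height="%s" viewBox="0 0 %s %s">'),
    fmt(layout$width), fmt(layout$height), fmt(layout$width),
    fmt(layout$height)),
    '<rect width="100%" height="100%" fill="#FFFFFF"/>')
  # grid
  grid <- character()
  for (s in layout$symbols) {
    y <- layout$row_y[[s]] - spec$cell_height / 2
    grid <- c(grid, sprintf(
      '<rect class="grid-row" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#DDDDDD" stroke-width="0.5"/>',
      fmt(MARGIN_LEFT), fmt(y), fmt(layout$n_col * spec$cell_width),
      fmt(spec$cell_height)))
  }
  for (j in seq_len(layout$n_col + 1L)) {
    xx <- MARGIN_LEFT + (j - 1L) * spec$cell_width
    grid <- c(grid, sprintf(
      '<line class="grid-col" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#DDDDDD" stroke-width="0.5"/>',
      fmt(xx), fmt(layout$top), fmt(xx), fmt(layout$grid_bottom)))
  }
  out <- c(out, grid)
  # axis labels
  for (s in layout$symbols)
    out <- c(out, sprintf(
      '<text class="axis-symbol" x="%s" y="%s" font-family="monospace" font-size="11" text-anchor="end">%s</text>',
      fmt(MARGIN_LEFT - 8), fmt(layout$row_y[[s]] + 4), s))
  if (!is.null(layout$gap_row_y))
    out <- c(out, sprintf(
      '<text class="axis-symbol" x="%s" y="%s" font-family="monospace" font-size="11" text-anchor="end">%s</text>',
      fmt(MARGIN_LEFT - 8), fmt(layout$gap_row_y + 4), layout$gap_symbol))
  stride <- max(1L, ceiling(layout$n_col / 40L))
  for (j in seq(1L, layout$n_col, by = stride))
    out <- c(out, sprintf(
      '<text class="axis-position" x="%s" y="%s" font-family="monospace" font-size="10" text-anchor="middle">%d</text>',
      fmt(layout$col_x[j]), fmt(layout$height - MARGIN_BOTTOM + 14), j))
  # site markers
  if (!is.null(markers)) {
    for (j in seq_len(layout$n_col)) {
      op <- min(1, max(0, markers[j]))
      out <- c(out, sprintf(
        '<rect class="site-marker" x="%s" y="2" width="%s" height="%s" fill="%s" fill-opacity="%s"/>',
        fmt(MARGIN_LEFT + (j - 1L) * spec$cell_width + 1),
        fmt(spec$cell_width - 2), fmt(spec$marker_band_height),
        spec$marker_color, fmt(op)))
    }
  }
  # threads: unselected first, selected on top
  sel_mask <- rep(FALSE, layout$n_seq)
  if (!is.null(selection)) sel_mask[selection$seq_indices] <- TRUE
  draw_order <- c(which(!sel_mask), which(sel_mask))
  for (i in draw_order) {
    d <- thread_path_d(layout$anchors_x[i, ], layout$anchors_y[i, ],
                       spec$curvature, spec$cell_width)
    if (is.null(d)) next
    out <- c(out, sprintf(
      '<path class="thread" data-label="%s" d="%s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
      xml_escape(layout$labels[i]), d, cols[i], fmt(spec$thread_width),
      fmt(opacity)))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

# points of a cubic Bezier at n parameter values (for rasterization)
bezier_points <- function(x0, y0, c1x, c1y, c2x, c2y, x1, y1, n = 16L) {
  t <- seq(0, 1, length.out = n)
  b <- function(p0, p1, p2, p3)
    (1 - t)^3 * p0 + 3 * (1 - t)^2 * t * p1 + 3 * (1 - t) * t^2 * p2 +
    t^3 * p3
  list(x = b(x0, c1x, c2x, x1), y = b(y0, c1y, c2y, y1))
}

#' Render a sequence bundle as PNG
#'
#' Rasterizes the identical geometry as [render_svg()] on a cairo PNG
#' device; pixel dimensions are the layout extent scaled by `dpi / 72`.
#' Deterministic: identical inputs produce byte-identical files.
#'
#' @inheritParams render_svg
#' @param path Output PNG path.
#' @param dpi Resolution (default 300; the layout's px are 72-dpi units).
#' @return Invisibly, the PNG bytes (raw vector); the file is written to
#'   `path`.
#' @export
render_png <- function(layout, spec = layout$spec, groups = NULL,
                       selection = NULL, markers = NULL, path, dpi = 300) {
  if (!capabilities("png"))
    bk_stop("config_error", "this R build has no PNG rasterizer")
  if (!is.null(markers) && length(markers) != layout$n_col)
    bk_stop("input_error", "markers must have one value per column (%d)",
            layout$n_col)
  scale <- dpi / 72
  wpx <- max(1L, round(layout$width * scale))
  hpx <- max(1L, round(layout$height * scale))
  cols <- thread_colors(layout, spec, groups, selection)
  opacity <- effective_opacity(spec, layout$n_seq)
  grDevices::png(path, width = wpx, height = hpx, type = "cairo")
  tryCatch({
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, layout$width),
                          ylim = c(layout$height, 0))  # y down, as SVG
    graphics::rect(0, layout$height, layout$width, 0, col = "#FFFFFF",
                   border = NA)
    for (s in layout$symbols) {
      y <- layout$row_y[[s]] - spec$cell_height / 2
      graphics::rect(MARGIN_LEFT, y + spec$cell_height,
                     MARGIN_LEFT + layout$n_col * spec$cell_width, y,
                     border = "#DDDDDD", lwd = 0.5 * scale)
      graphics::text(MARGIN_LEFT - 8, layout$row_y[[s]] + 4, s,
                     adj = c(1, 0), cex = scale * 0.8, family = "mono")
    }
    if (!is.null(markers)) {
      for (j in seq_len(layout$n_col)) {
        op <- min(1, max(0, markers[j]))
        graphics::rect(MARGIN_LEFT + (j - 1L) * spec$cell_width + 1,
                       2 + spec$marker_band_height,
                       MARGIN_LEFT + j * spec$cell_width - 1, 2,
                       col = grDevices::adjustcolor(spec$marker_color,
                                                    alpha.f = op),
                       border = NA)
      }
    }
    sel_mask <- rep(FALSE, layout$n_seq)
    if (!is.null(selection)) sel_mask[selection$seq_indices] <- TRUE
    for (i in c(which(!sel_mask), which(sel_mask))) {
      xs <- layout$anchors_x[i, ]
      ys <- layout$anchors_y[i, ]
      keep <- !is.na(ys)
      xs <- xs[keep]; ys <- ys[keep]
      if (!length(xs)) next
      px <- xs[1]; py <- ys[1]
      if (length(xs) > 1L) for (sgi in seq_len(length(xs) - 1L)) {
        ct <- segment_controls(xs[sgi], ys[sgi], xs[sgi + 1L],
                               ys[sgi + 1L], spec$curvature,
                               spec$cell_width)
        bp <- bezier_points(xs[sgi], ys[sgi], ct$c1x, ct$c1y, ct$c2x,
                            ct$c2y, xs[sgi + 1L], ys[sgi + 1L])
        px <- c(px, bp$x[-1]); py <- c(py, bp$y[-1])
      }
      graphics::lines(px, py,
                      col = grDevices::adjustcolor(cols[i],
                                                   alpha.f = opacity),
                      lwd = spec$thread_width * scale)
    }
  }, finally = grDevices::dev.off())
  invisible(readBin(path, "raw", file.info(path)$size))
}
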
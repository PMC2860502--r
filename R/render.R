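#' Genotype pair counts between two axes
#'
#' Contingency table of observed genotype category pairs between two axes.
#' Individuals missing at either axis are excluded from this table only.
#' Row/column margins equal the per-axis genotype counts among the jointly
#' observed individuals.
#'
#' @param gm A [geno_tbl()] (or a `textile_fit`, whose data is used).
#' @param j,k Axis names or column indices.
#' @return An integer matrix, categories of `j` in rows.
#' @export
pair_counts <- function(gm, j, k) {
  if (inherits(gm, "textile_fit")) gm <- gm$data
  loci <- axis_names(gm)
  a <- if (is.character(j)) j else loci[j]
  b <- if (is.character(k)) k else loci[k]
  ca <- gm[[a]]; cb <- gm[[b]]
  if (is.numeric(ca) || is.numeric(cb)) {
    stop("pair counts need categorical axes", call. = FALSE)
  }
  unclass(table(ca, cb, dnn = c(a, b)))
}

#' Rendering constants for the textile plot
#'
#' @param width,height Canvas size in px (`width = NULL` scales with the
#'   number of axes).
#' @param margin Outer margin in px.
#' @param circle_max_radius Radius of the largest genotype circle; all
#'   circle areas are strictly proportional to genotype counts.
#' @param ribbon_max Stroke width of the thickest ribbon; widths are
#'   strictly proportional to pair counts within the plot.
#' @param axis_color,circle_fill,ribbon_color SVG colors.
#' @param dendrogram Draw the dendrogram strip when rendering with an
#'   `axis_ordering`.
#' @param dendro_height Height of the dendrogram strip in px.
#' @param highlight Character vector of sample ids whose diplotype paths
#'   are drawn on top in `highlight_color`.
#' @param highlight_color Color for highlighted paths.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(width = NULL, height = 420, margin = 48,
                      circle_max_radius = 16, ribbon_max = 12,
                      axis_color = "#444444", circle_fill = "#3b6fb6",
                      ribbon_color = "#9a9a9a", dendrogram = FALSE,
                      dendro_height = 80, highlight = NULL,
                      highlight_color = "#d4542c") {
  structure(list(width = width, height = height, margin = margin,
                 circle_max_radius = circle_max_radius,
                 ribbon_max = ribbon_max, axis_color = axis_color,
                 circle_fill = circle_fill, ribbon_color = ribbon_color,
                 dendrogram = dendrogram, dendro_height = dendro_height,
                 highlight = highlight, highlight_color = highlight_color),
            class = "plot_spec")
}

fmt <- function(x) sprintf("%.4f", x)

#' Render a textile plot as SVG
#'
#' One vertical axis per column at equal horizontal spacing; a circle per
#' genotype category centered at its optimized coordinate with area
#' proportional to its marginal count; a ribbon per genotype pair between
#' adjacent axes with stroke width proportional to the pair count (thickest
#' drawn first). Larger coordinate values are drawn upward. Phenotype axes
#' sit leftmost; with a clustered `order` and `spec$dendrogram = TRUE` a
#' dendrogram strip is drawn above the axes. Output is deterministic for
#' fixed inputs.
#'
#' @param fit A `textile_fit`.
#' @param path Optional output path; the SVG text is also returned.
#' @param spec A [plot_spec()].
#' @param order Display order: character vector of axis names or an
#'   `axis_ordering` from [cluster_axes()]. Defaults to the fit's order.
#' @return The SVG document as a character scalar (invisibly when `path`
#'   is given).
#' @export
render_svg <- function(fit, path = NULL, spec = plot_spec(), order = NULL) {
  ordering <- NULL
  if (inherits(order, "axis_ordering")) {
    ordering <- order
    order <- order$order
  }
  if (is.null(order)) order <- fit$order
  stopifnot(setequal(order, fit$order))
  p <- length(order)
  if (p < 1) stop("empty layout", call. = FALSE)
  coords <- fit$coords
  cat_rows <- coords[!is.na(coords$category) & coords$count > 0, ]

  margin <- spec$margin
  dh <- if (!is.null(ordering) && spec$dendrogram) spec$dendro_height else 0
  width <- if (is.null(spec$width)) margin * 2 + (p - 1) * 110 + 20
           else spec$width
  height <- spec$height
  spacing <- if (p > 1) (width - 2 * margin) / (p - 1) else 0
  xs <- stats::setNames(margin + (seq_len(p) - 1) * spacing, order)

  yr <- range(cat_rows$coord, fit$individuals$level, na.rm = TRUE)
  if (diff(yr) == 0) yr <- yr + c(-1, 1)
  y0 <- margin + dh
  y1 <- height - margin
  sy <- function(v) y1 - (v - yr[1]) / (yr[2] - yr[1]) * (y1 - y0)

  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    round(width), round(height), round(width), round(height)),
    sprintf('<!-- textileplot | lambda=%.8g objective=%.8g -->',
            fit$lambda, fit$objective))

  # ribbons between adjacent categorical axes, thickest first
  ribbons <- list()
  max_pair <- 0
  for (jj in seq_len(p - 1)) {
    a <- order[jj]; b <- order[jj + 1]
    if (is.numeric(fit$data[[a]]) || is.numeric(fit$data[[b]])) next
    tab <- pair_counts(fit$data, a, b)
    if (!length(tab)) next
    max_pair <- max(max_pair, max(tab))
    va <- axis_category_coords(fit, a)
    vb <- axis_category_coords(fit, b)
    cells <- which(tab > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(cells))) {
      ribbons[[length(ribbons) + 1]] <- list(
        x1 = xs[a], y1 = sy(va[rownames(tab)[cells[r, 1]]]),
        x2 = xs[b], y2 = sy(vb[colnames(tab)[cells[r, 2]]]),
        count = tab[cells[r, , drop = FALSE]])
    }
  }
  if (length(ribbons)) {
    cnt <- vapply(ribbons, `[[`, 0, "count")
    for (i in order(-cnt)) {
      rb <- ribbons[[i]]
      out <- c(out, sprintf(
        '<line class="ribbon" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" data-count="%d"/>',
        fmt(rb$x1), fmt(rb$y1), fmt(rb$x2), fmt(rb$y2), spec$ribbon_color,
        fmt(rb$count / max_pair * spec$ribbon_max), rb$count))
    }
  }

  # highlighted diplotype paths
  for (sid in spec$highlight) {
    i <- match(sid, fit$individuals$sample_id)
    if (is.na(i)) next
    yy <- fit$y[i, order]
    ok <- which(!is.na(yy))
    if (length(ok) < 2) next
    pts <- paste(sprintf("%s,%s", fmt(xs[order[ok]]), fmt(sy(yy[ok]))),
                 collapse = " ")
    out <- c(out, sprintf(
      '<polyline class="highlight" points="%s" fill="none" stroke="%s" stroke-width="2" data-sample="%s"/>',
      pts, spec$highlight_color, sid))
  }

  # axes
  for (a in order) {
    out <- c(out, sprintf(
      '<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
      fmt(xs[a]), fmt(y0), fmt(xs[a]), fmt(y1), spec$axis_color),
      sprintf('<text class="axis-label" x="%s" y="%s" text-anchor="middle" font-size="10">%s</text>',
              fmt(xs[a]), fmt(y1 + 14), a))
  }

  # genotype circles: area proportional to marginal count
  max_count <- max(cat_rows$count)
  for (r in seq_len(nrow(cat_rows))) {
    row <- cat_rows[r, ]
    rad <- spec$circle_max_radius * sqrt(row$count / max_count)
    out <- c(out, sprintf(
      '<circle class="genotype" cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="0.85" data-axis="%s" data-category="%s" data-count="%d"/>',
      fmt(xs[row$axis]), fmt(sy(row$coord)), fmt(rad), spec$circle_fill,
      row$axis, row$category, row$count))
  }

  # dendrogram strip above clustered orders
  if (dh > 0) {
    hmax <- max(ordering$merges$height[is.finite(ordering$merges$height)], 1e-12)
    ys_d <- function(h) y0 - 6 - min(h / hmax, 1) * (dh - 12)
    pos <- stats::setNames(xs[ordering$order], ordering$order)
    chain_x <- pos[[setdiff(ordering$order, ordering$merges$axis)[1]]]
    chain_y <- y0 - 6
    for (s in seq_len(nrow(ordering$merges))) {
      mg <- ordering$merges[s, ]
      h <- if (is.finite(mg$height)) mg$height else hmax
      ytop <- ys_d(h)
      xleaf <- pos[[mg$axis]]
      out <- c(out, sprintf(
        '<path class="dendro" d="M %s %s L %s %s L %s %s L %s %s" fill="none" stroke="#777777" stroke-width="1"/>',
        fmt(chain_x), fmt(chain_y), fmt(chain_x), fmt(ytop),
        fmt(xleaf), fmt(ytop), fmt(xleaf), fmt(y0 - 6)))
      chain_x <- (chain_x + xleaf) / 2
      chain_y <- ytop
    }
  }

  svg <- paste(c(out, "</svg>"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path)
    return(invisible(svg))
  }
  svg
}

#' ggplot version of the textile plot
#'
#' @param object A `textile_fit`.
#' @param order Optional display order (character vector or
#'   `axis_ordering`).
#' @param ... Unused.
#' @return A ggplot: axes with genotype points sized by count and ribbons
#'   weighted by pair count.
#' @export
autoplot.textile_fit <- function(object, order = NULL, ...) {
  if (inherits(order, "axis_ordering")) order <- order$order
  if (is.null(order)) order <- object$order
  coords <- object$coords[!is.na(object$coords$category) &
                            object$coords$count > 0, ]
  coords$x <- match(coords$axis, order)
  segs <- purrr::map_dfr(seq_len(length(order) - 1), function(jj) {
    a <- order[jj]; b <- order[jj + 1]
    if (is.numeric(object$data[[a]]) || is.numeric(object$data[[b]])) {
      return(tibble::tibble())
    }
    tab <- pair_counts(object$data, a, b)
    va <- axis_category_coords(object, a)
    vb <- axis_category_coords(object, b)
    cells <- which(tab > 0, arr.ind = TRUE)
    tibble::tibble(x = jj, xend = jj + 1,
                   y = va[rownames(tab)[cells[, 1]]],
                   yend = vb[colnames(tab)[cells[, 2]]],
                   count = tab[cells])
  })
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, linewidth = .data$count),
      color = "grey55", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = seq_along(order), color = "grey30",
                        linewidth = 0.3) +
    ggplot2::geom_point(data = coords,
      ggplot2::aes(x = .data$x, y = .data$coord, size = .data$count),
      color = "#3b6fb6", alpha = 0.85) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::scale_linewidth(range = c(0.2, 4)) +
    ggplot2::scale_x_continuous(breaks = seq_along(order), labels = order) +
    ggplot2::labs(x = NULL, y = "coordinate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
}
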
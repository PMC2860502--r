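#' Mean-absolute-deviation distance between two axes
#'
#' The weighted mean absolute difference between individual coordinates on
#' axes `j` and `k`, averaged over individuals observed at both (product of
#' the two 0/1 weight vectors). Axes in absolute LD with matching labels
#' have distance 0.
#'
#' @param fit A `textile_fit`.
#' @param j,k Axis names or indices.
#' @return A single number, or `NA` (flagged missing) when no individual is
#'   observed at both axes.
#' @export
axis_distance <- function(fit, j, k) {
  a <- if (is.character(j)) j else fit$order[j]
  b <- if (is.character(k)) k else fit$order[k]
  ya <- fit$y[, a]; yb <- fit$y[, b]
  w <- as.numeric(!is.na(ya) & !is.na(yb))
  if (sum(w) == 0) return(NA_real_)
  sum(w * abs(ifelse(w == 1, ya - yb, 0))) / sum(w)
}

#' All pairwise axis distances
#'
#' @param fit A `textile_fit`.
#' @param axes Axes to include; defaults to all.
#' @return A symmetric matrix of mean-absolute-deviation distances.
#' @export
axis_distances <- function(fit, axes = fit$order) {
  p <- length(axes)
  d <- matrix(0, p, p, dimnames = list(axes, axes))
  for (u in seq_len(p - 1)) {
    for (v in (u + 1):p) {
      d[u, v] <- d[v, u] <- axis_distance(fit, axes[u], axes[v])
    }
  }
  d
}

#' Reorder axes by ordered single end-linkage clustering
#'
#' Grows a chain starting from the closest pair of axes; at each step the
#' unplaced axis nearest (single linkage) to either end of the chain is
#' attached to that end. This yields both a heuristic axis ordering that
#' makes remote SNPs in tight LD adjacent, and a dendrogram recording the
#' merge distances. Ties are broken by the original (physical) order;
#' missing distances are treated as infinite.
#'
#' @param d Symmetric distance matrix with dimnames (e.g. from
#'   [axis_distances()]).
#' @param anchor Initial order of the axes (dimnames order by default),
#'   used for tie-breaking.
#' @return An `axis_ordering`: list with `order` (axis names), `merges`
#'   (tibble: `step`, `axis`, `end`, `height`), `newick`, `dist`.
#' @export
order_axes <- function(d, anchor = rownames(d)) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  axes <- anchor
  d <- d[axes, axes, drop = FALSE]
  p <- length(axes)
  dd <- d
  dd[is.na(dd)] <- Inf
  diag(dd) <- Inf
  if (all(!is.finite(dd))) stop("all distances missing", call. = FALSE)

  # seed: smallest-distance pair, ties by original order
  best <- c(Inf, NA, NA)
  for (u in seq_len(p - 1)) {
    for (v in (u + 1):p) {
      if (dd[u, v] < best[1]) best <- c(dd[u, v], u, v)
    }
  }
  chain <- c(best[2], best[3])
  merges <- tibble::tibble(step = 1L, axis = axes[best[3]],
                           end = "right", height = best[1])
  placed <- logical(p)
  placed[chain] <- TRUE

  step <- 1L
  while (any(!placed)) {
    step <- step + 1L
    ends <- c(chain[1], chain[length(chain)])
    cand <- which(!placed)
    best <- list(h = Inf, u = NA_integer_, end = NA_character_)
    for (e in c("left", "right")) {
      ei <- if (e == "left") ends[1] else ends[2]
      for (u in cand) {
        if (dd[ei, u] < best$h) best <- list(h = dd[ei, u], u = u, end = e)
      }
    }
    if (!is.finite(best$h)) {
      # disconnected: attach remaining axes in original order on the right
      best <- list(h = Inf, u = cand[1], end = "right")
    }
    if (best$end == "left") chain <- c(best$u, chain)
    else chain <- c(chain, best$u)
    placed[best$u] <- TRUE
    merges <- dplyr::bind_rows(merges,
      tibble::tibble(step = step, axis = axes[best$u], end = best$end,
                     height = best$h))
  }

  ord <- axes[chain]
  structure(list(order = ord, merges = merges,
                 newick = ordering_newick(axes, chain, merges),
                 dist = d),
            class = "axis_ordering")
}

# caterpillar Newick: each attachment joins the growing chain cluster at its
# raw merge distance (branch lengths carry the merge heights)
ordering_newick <- function(axes, chain, merges) {
  h1 <- merges$height[1]
  a0 <- setdiff(axes[chain], merges$axis)[1]  # the seed axis never "attached"
  tree <- sprintf("(%s:%.10g,%s:%.10g)", a0, h1, merges$axis[1], h1)
  if (nrow(merges) > 1) {
    for (s in 2:nrow(merges)) {
      h <- merges$height[s]
      if (!is.finite(h)) h <- 0
      tree <- sprintf("(%s:0,%s:%.10g)", tree, merges$axis[s], h)
    }
  }
  paste0(tree, ";")
}

#' @export
print.axis_ordering <- function(x, ...) {
  cat("# axis ordering (ordered single end-linkage):\n#  ",
      paste(x$order, collapse = " "), "\n", sep = "")
  print(x$merges, ...)
  invisible(x)
}

#' Tidy an axis ordering
#' @param x An `axis_ordering`.
#' @param ... Unused.
#' @return The merge tibble with the final position of each axis.
#' @export
tidy.axis_ordering <- function(x, ...) {
  dplyr::mutate(x$merges, position = match(.data$axis, x$order))
}

#' Cluster-based reordering of a fitted layout
#'
#' Computes the mean-absolute-deviation distances between all SNP axes of a
#' fit and reorders them with [order_axes()]. Phenotype axes are excluded
#' from the clustering and kept leftmost in the returned order. Reordering
#' changes adjacency (hence crossings and rendering) only; the solved
#' coordinates are order-invariant.
#'
#' @param fit A `textile_fit`.
#' @return An `axis_ordering` whose `order` includes the phenotype axes
#'   (leftmost) followed by the clustered SNP order.
#' @export
cluster_axes <- function(fit) {
  meta <- fit$axes
  snps <- meta$locus[meta$kind == "snp"]
  if (length(snps) < 2) stop("need at least 2 SNP axes", call. = FALSE)
  d <- axis_distances(fit, snps)
  ord <- order_axes(d)
  ord$order <- c(meta$locus[meta$kind != "snp"], ord$order)
  ord
}

#' Write an axis ordering
#'
#' @param x An `axis_ordering`.
#' @param order_path Path for the ordering TSV (axis, position, merge
#'   height); `NULL` to skip.
#' @param newick_path Path for the Newick dendrogram; `NULL` to skip.
#' @return `x`, invisibly.
#' @export
export_ordering <- function(x, order_path = NULL, newick_path = NULL) {
  if (!is.null(order_path)) readr::write_tsv(tidy(x), order_path)
  if (!is.null(newick_path)) writeLines(x$newick, newick_path)
  invisible(x)
}
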
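#' Fit the textile plot layout
#'
#' Chooses, for every axis j, a location \eqn{\alpha_j} and a scale vector
#' \eqn{\gamma_j} so that each individual's polyline across the parallel
#' axes is as horizontal as possible: the weighted sum of squared deviations
#' of the coordinates \eqn{y_{ij} = \alpha_j + (X_j B_j \gamma_j)_i} from a
#' per-individual level \eqn{h_i} is minimized, subject to holding the total
#' weighted dispersion of the points equal to the effective number of
#' observed cells. Missing entries carry zero weight everywhere.
#'
#' Both \eqn{\alpha_j} and \eqn{h_i} are weighted means at the optimum, so
#' they are eliminated analytically and the problem reduces to a symmetric
#' generalized eigenproblem over the stacked scale vectors; the leading
#' eigenvector, rescaled to satisfy the dispersion constraint exactly, is
#' the global minimizer. On complete data the resulting category coordinates
#' are proportional to first-dimension multiple correspondence analysis
#' scores.
#'
#' @param data A [geno_tbl()] (or plain data frame of factor/numeric axis
#'   columns).
#' @param phenotype_in_fit If `TRUE` (default), phenotype axes enter the
#'   optimization on the same footing as SNP axes; if `FALSE` they are
#'   placed afterwards by weighted regression of the fitted individual
#'   levels on the phenotype encoding.
#' @param contrast_fun Contrast basis passed to [encode_axis()]; the layout
#'   is invariant to this choice.
#' @return A `textile_fit` object; see [tidy.textile_fit()],
#'   [glance.textile_fit()], [autoplot.textile_fit()].
#' @export
textile_layout <- function(data, phenotype_in_fit = TRUE,
                           contrast_fun = stats::contr.helmert) {
  gm <- if (inherits(data, "geno_tbl")) data else geno_tbl(data)
  meta <- axis_meta(gm)
  loci <- meta$locus
  p <- length(loci)
  n <- nrow(gm)
  if (p < 2) stop("need at least 2 axes", call. = FALSE)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)

  enc <- purrr::map(gm[loci], encode_axis, contrast_fun = contrast_fun)
  W <- vapply(enc, `[[`, numeric(n), "weight")

  # individuals observed on fewer than 2 axes cannot constrain a level
  keep <- rowSums(W) >= 2
  if (!all(keep)) {
    warning(sum(!keep), " individual(s) observed on < 2 axes dropped from ",
            "the fit: ", paste(gm$sample_id[!keep], collapse = ", "),
            call. = FALSE)
  }
  if (!any(keep)) stop("no individual observed on >= 2 axes", call. = FALSE)

  in_fit <- if (phenotype_in_fit) rep(TRUE, p) else meta$kind == "snp"
  if (sum(in_fit) < 2) stop("need at least 2 axes in the fit", call. = FALSE)

  core <- solve_layout_core(enc[in_fit], keep, loci[in_fit])

  gamma <- vector("list", p)
  alpha <- numeric(p)
  gamma[in_fit] <- core$gamma
  alpha[in_fit] <- core$alpha
  h_keep <- core$h

  # post-hoc placement of axes excluded from the fit: weighted regression of
  # the individual levels on the axis encoding
  for (j in which(!in_fit)) {
    pl <- place_axis(enc[[j]], keep, h_keep)
    gamma[[j]] <- pl$gamma
    alpha[j] <- pl$alpha
  }

  # per-individual coordinates for all individuals (NA where unobserved)
  Mfull <- purrr::map(enc, axis_model_matrix, keep = rep(TRUE, n))
  y <- vapply(seq_len(p), function(j) {
    yj <- alpha[j] + drop(Mfull[[j]] %*% gamma[[j]])
    yj[W[, j] == 0] <- NA_real_
    yj
  }, numeric(n))
  colnames(y) <- loci

  h <- rep(NA_real_, n)
  wk <- W[keep, in_fit, drop = FALSE]
  yk <- y[keep, in_fit, drop = FALSE]
  h[keep] <- rowSums(wk * ifelse(is.na(yk), 0, yk)) / rowSums(wk)

  # category coordinates, counts and per-axis dispersion
  coords <- purrr::map_dfr(seq_len(p), function(j) {
    e <- enc[[j]]
    nj <- sum(W[keep, j])
    yj <- y[keep, j]
    wj <- W[keep, j]
    ybar <- sum(wj * ifelse(is.na(yj), 0, yj)) / nj
    dj <- sqrt(sum(wj * ifelse(is.na(yj), 0, (yj - ybar)^2)) / nj)
    if (e$quantitative) {
      tibble::tibble(axis = loci[j], kind = meta$kind[j],
                     category = NA_character_, coord = NA_real_,
                     count = nj, alpha = alpha[j], dispersion = dj)
    } else {
      v <- alpha[j] + drop(e$contrast %*% gamma[[j]])
      cnt <- colSums(e$indicator)
      tibble::tibble(axis = loci[j], kind = meta$kind[j],
                     category = e$labels, coord = v, count = cnt,
                     alpha = alpha[j], dispersion = dj)
    }
  })

  structure(list(
    coords = coords,
    individuals = tibble::tibble(sample_id = gm$sample_id, level = h,
                                 in_fit = keep),
    y = y, weights = W, gamma = gamma, alpha = alpha,
    lambda = core$lambda, objective = core$objective, m = core$m,
    eigen_gap = core$gap, axes = meta, order = loci,
    in_fit = in_fit, data = gm, n_dropped = sum(!keep)),
    class = "textile_fit")
}

# model matrix X_j B_j (or standardized raw vector) restricted to kept rows;
# rows with missing entries are zero
axis_model_matrix <- function(e, keep) {
  w <- e$weight[keep]
  if (e$quantitative) {
    x <- e$raw[keep]
    x[w == 0] <- 0
    nj <- sum(w)
    mu <- sum(w * x) / nj
    s2 <- sum(w * (x - mu)^2) / nj
    z <- if (s2 > 0) (x - mu) / sqrt(s2) else rep(0, length(x))
    z[w == 0] <- 0
    matrix(z, ncol = 1)
  } else if (ncol(e$contrast) == 0) {
    matrix(numeric(0), nrow = sum(keep), ncol = 0)
  } else {
    unname(e$indicator[keep, , drop = FALSE] %*% e$contrast)
  }
}

# core eigen solution over the axes included in the fit
solve_layout_core <- function(enc, keep, axis_names = NULL) {
  n <- sum(keep)
  p <- length(enc)
  M <- purrr::map(enc, axis_model_matrix, keep = keep)
  w <- vapply(enc, function(e) e$weight[keep], numeric(n))
  nj <- colSums(w)
  if (any(nj == 0)) stop("axis with no observed entries", call. = FALSE)
  m <- sum(nj)

  kdim <- vapply(M, ncol, 0L)
  Tmat <- matrix(0, n, sum(kdim))
  G <- vector("list", p)
  off <- cumsum(c(0L, kdim))
  for (j in seq_len(p)) {
    if (kdim[j] == 0) { G[[j]] <- matrix(numeric(0), 0, 0); next }
    Mj <- M[[j]]
    cs <- colSums(Mj)          # = w_j' M_j (missing rows are zero)
    idx <- (off[j] + 1):off[j + 1]
    Tmat[, idx] <- Mj - outer(w[, j], cs) / nj[j]
    G[[j]] <- crossprod(Mj) - outer(cs, cs) / nj[j]
  }

  # reduce each block of the constraint matrix to identity, dropping
  # directions with zero dispersion (monomorphic-in-fit axes)
  Rblocks <- purrr::map(G, function(Gj) {
    if (!nrow(Gj)) return(matrix(numeric(0), 0, 0))
    eg <- eigen((Gj + t(Gj)) / 2, symmetric = TRUE)
    keep_d <- eg$values > max(eg$values, 0) * 1e-10 & eg$values > 1e-12
    if (!any(keep_d)) return(matrix(0, nrow(Gj), 0))
    eg$vectors[, keep_d, drop = FALSE] %*%
      diag(1 / sqrt(eg$values[keep_d]), sum(keep_d))
  })
  kred <- vapply(Rblocks, ncol, 0L)
  if (sum(kred) == 0) stop("all axes are monomorphic", call. = FALSE)
  R <- matrix(0, sum(kdim), sum(kred))
  offr <- cumsum(c(0L, kred))
  for (j in seq_len(p)) {
    if (kred[j] == 0) next
    R[(off[j] + 1):off[j + 1], (offr[j] + 1):offr[j + 1]] <- Rblocks[[j]]
  }

  Z <- solve_S(Tmat, w, nj)            # Z = S^+ T
  A <- crossprod(Tmat, Z)
  A <- (A + t(A)) / 2
  At <- crossprod(R, A %*% R)
  At <- (At + t(At)) / 2

  ev <- leading_eigen(At)
  gap <- ev$gap
  if (!is.na(gap) && gap < 1e-9) {
    warning("leading eigenvalue is (near-)degenerate: the layout is not ",
            "uniquely determined (e.g. all axis pairs empirically ",
            "independent, or exactly duplicated axes)", call. = FALSE)
  }
  theta <- ev$vector * sqrt(m)
  gamma_stack <- drop(R %*% theta)

  # sign convention: the eigenvector is defined up to sign; fix it so that
  # the first nonzero count-centered per-category offset, taken over axes in
  # lexicographic name order then category order, is positive. Centered
  # offsets (unlike gamma or raw B_j gamma_j) are invariant to the contrast
  # basis, and name order makes the rule invariant to input column order.
  gamma <- purrr::map(seq_len(p), function(j) {
    if (kdim[j] == 0) numeric(0)
    else gamma_stack[(off[j] + 1):off[j + 1]]
  })
  axis_ord <- if (is.null(axis_names)) seq_len(p) else
    order(axis_names, method = "radix")
  offsets <- unlist(purrr::map(axis_ord, function(j) {
    e <- enc[[j]]
    if (e$quantitative || kdim[j] == 0) return(gamma[[j]])
    oj <- drop(e$contrast %*% gamma[[j]])
    cnt <- colSums(e$indicator[keep, , drop = FALSE])
    oj - sum(cnt * oj) / sum(cnt)
  }))
  nz <- which(abs(offsets) > 1e-12)
  if (length(nz) && offsets[nz[1]] < 0) {
    gamma <- purrr::map(gamma, `-`)
    gamma_stack <- -gamma_stack
  }

  hvec <- drop(Z %*% gamma_stack)
  alpha <- vapply(seq_len(p), function(j) {
    u <- if (kdim[j]) drop(M[[j]] %*% gamma[[j]]) else rep(0, n)
    sum(w[, j] * (hvec - u)) / nj[j]
  }, 0)

  # objective from the definition (also equals m * (1 - lambda))
  Q <- 0
  for (j in seq_len(p)) {
    yj <- alpha[j] + (if (kdim[j]) drop(M[[j]] %*% gamma[[j]]) else 0)
    Q <- Q + sum(w[, j] * (yj - hvec)^2)
  }

  list(gamma = gamma, alpha = alpha, h = hvec, lambda = ev$value,
       objective = Q, m = m, gap = gap)
}

# solve S Z = T for Z orthogonal to 1, with S = sum_j (W_j - w_j w_j'/n_j)
# = diag(r) - B B'; uses the Woodbury identity on S + 1 1'/n, falling back
# to a dense pseudoinverse if the small system is singular (disconnected
# missingness pattern)
solve_S <- function(Tmat, w, nj) {
  n <- nrow(w)
  r <- rowSums(w)
  B <- sweep(w, 2, sqrt(nj), "/")
  U <- cbind(B, rep(1, n))
  Lam_inv <- diag(c(rep(-1, ncol(B)), n))   # Lambda = diag(-I, 1/n)
  Dinv_T <- Tmat / r
  Dinv_U <- U / r
  K <- Lam_inv + crossprod(U, Dinv_U)
  Z <- tryCatch(
    Dinv_T - Dinv_U %*% solve(K, crossprod(U, Dinv_T)),
    error = function(e) NULL)
  if (is.null(Z)) {
    S <- diag(r) - tcrossprod(B)
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-12
    Z <- eg$vectors[, pos, drop = FALSE] %*%
      ((crossprod(eg$vectors[, pos, drop = FALSE], Tmat)) / eg$values[pos])
  }
  Z
}

# leading eigenpair of a dense symmetric PSD matrix; dense decomposition up
# to dimension 2000, simple power iteration (tol 1e-10) above
leading_eigen <- function(A, tol = 1e-10, max_iter = 10000L) {
  k <- nrow(A)
  if (k == 1) return(list(value = A[1, 1], vector = 1, gap = NA_real_))
  if (k <= 2000) {
    eg <- eigen(A, symmetric = TRUE)
    return(list(value = eg$values[1],
                vector = eg$vectors[, 1],
                gap = eg$values[1] - eg$values[2]))
  }
  v <- rep(1 / sqrt(k), k)
  lam <- 0
  for (it in seq_len(max_iter)) {
    u <- drop(A %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) break
    u <- u / nu
    lam_new <- drop(crossprod(u, A %*% u))
    if (abs(lam_new - lam) < tol * max(1, abs(lam_new)) &&
        sum((u - v)^2) < tol) {
      return(list(value = lam_new, vector = u, gap = NA_real_))
    }
    v <- u; lam <- lam_new
  }
  warning("power iteration did not fully converge", call. = FALSE)
  list(value = lam, vector = v, gap = NA_real_)
}

# place an axis excluded from the fit, given fixed individual levels
place_axis <- function(e, keep, h) {
  Mj <- axis_model_matrix(e, keep)
  w <- e$weight[keep]
  nj <- sum(w)
  if (ncol(Mj) == 0) return(list(gamma = numeric(0), alpha = sum(w * h) / nj))
  cs <- colSums(Mj)
  Gj <- crossprod(Mj) - outer(cs, cs) / nj
  b <- crossprod(Mj, w * h) - cs * sum(w * h) / nj
  gamma <- drop(MASS_ginv(Gj) %*% b)
  alpha <- sum(w * (h - drop(Mj %*% gamma))) / nj
  list(gamma = gamma, alpha = alpha)
}

# small pseudoinverse (avoids a MASS dependency for one call)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > max(s$d[1], 0) * tol & s$d > 0
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.textile_fit <- function(x, ...) {
  cat(sprintf(
    "# textile_fit: %d individuals x %d axes | lambda = %.6f, Q = %.6f\n",
    nrow(x$y), length(x$order), x$lambda, x$objective))
  if (x$n_dropped > 0) cat("#", x$n_dropped, "individual(s) dropped\n")
  print(x$coords, ...)
  invisible(x)
}

#' Horizontalization objective of a fitted layout
#'
#' The weighted sum of squared deviations of every observed coordinate from
#' its individual's horizontal level.
#'
#' @param fit A `textile_fit`.
#' @return A single number.
#' @export
objective_value <- function(fit) {
  keep <- fit$individuals$in_fit
  y <- fit$y[keep, fit$in_fit, drop = FALSE]
  w <- fit$weights[keep, fit$in_fit, drop = FALSE]
  h <- fit$individuals$level[keep]
  d <- (ifelse(is.na(y), 0, y) - outer(h, rep(1, ncol(y)))) * w
  sum(d^2)
}

#' Per-axis vertical dispersion
#'
#' The weighted standard deviation of the individual coordinates on each
#' axis. Values near zero identify axes in linkage equilibrium with all
#' others (or monomorphic axes); under HWE the profile is proportional to
#' the leading eigenvector of the genotype-dosage correlation matrix.
#'
#' @param fit A `textile_fit`.
#' @return A named numeric vector, one value per axis in display order.
#' @export
dispersion_profile <- function(fit) {
  stats::setNames(
    fit$coords$dispersion[!duplicated(fit$coords$axis)][
      match(fit$order, unique(fit$coords$axis))],
    fit$order)
}

#' Count strictly crossing segments between adjacent axes
#'
#' Number of unordered pairs of individuals whose connecting segments
#' between display-adjacent axes `j` and `j + 1` have opposite vertical
#' order at the two axes. Pairs with a missing endpoint are skipped.
#' Crossings increase as the adjacent pair approaches linkage equilibrium.
#'
#' @param fit A `textile_fit`.
#' @param j Left axis index in display order.
#' @param order Optional display order (character vector of axis names);
#'   defaults to the fit's order.
#' @return An integer count.
#' @export
crossing_count <- function(fit, j, order = fit$order) {
  stopifnot(j >= 1, j + 1 <= length(order))
  a <- order[j]; b <- order[j + 1]
  tab <- pair_counts(fit$data, a, b)
  va <- axis_category_coords(fit, a)
  vb <- axis_category_coords(fit, b)
  cells <- which(tab > 0, arr.ind = TRUE)
  total <- 0
  if (nrow(cells) >= 2) {
    for (u in seq_len(nrow(cells) - 1)) {
      for (v in (u + 1):nrow(cells)) {
        da <- va[cells[u, 1]] - va[cells[v, 1]]
        db <- vb[cells[u, 2]] - vb[cells[v, 2]]
        if (da * db < 0) {
          total <- total + tab[cells[u, , drop = FALSE]] *
            tab[cells[v, , drop = FALSE]]
        }
      }
    }
  }
  as.integer(total)
}

axis_category_coords <- function(fit, axis) {
  rows <- fit$coords[fit$coords$axis == axis, ]
  if (all(is.na(rows$category))) {
    stop("axis ", axis, " is quantitative; it has no category coordinates",
         call. = FALSE)
  }
  stats::setNames(rows$coord, rows$category)
}

#' Heterozygote midpoint deviation
#'
#' Signed deviation of the heterozygote coordinate from the midpoint of the
#' two homozygote coordinates on a diallelic axis, normalized by the
#' homozygote span. Near zero under Hardy-Weinberg equilibrium; systematic
#' deviation suggests HWE violation (e.g. excess homozygosity).
#'
#' @param fit A `textile_fit`.
#' @param j Axis index or name.
#' @return A single number.
#' @export
het_mid_deviation <- function(fit, j) {
  axis <- if (is.character(j)) j else fit$order[j]
  v <- axis_category_coords(fit, axis)
  lab <- names(v)
  pair_alleles <- purrr::map(lab, function(l) {
    if (grepl("/", l)) strsplit(l, "/", fixed = TRUE)[[1]]
    else c(substr(l, 1, 1), substr(l, 2, 2))
  })
  is_het <- vapply(pair_alleles, function(a) a[1] != a[2], TRUE)
  if (sum(!is_het) != 2 || sum(is_het) != 1) {
    stop("axis ", axis, " is not diallelic with all three genotype classes",
         call. = FALSE)
  }
  hom <- v[!is_het]; het <- v[is_het]
  (het - mean(hom)) / abs(hom[1] - hom[2])
}

#' Export a fitted layout as TSV
#'
#' Writes one row per (axis, category) with the axis location, category
#' coordinate and axis dispersion, then one row per individual with its
#' horizontal level. Header comment lines record the leading eigenvalue and
#' the objective value.
#'
#' @param fit A `textile_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_layout <- function(fit, path) {
  hdr <- c(sprintf("# lambda\t%.12g", fit$lambda),
           sprintf("# objective\t%.12g", fit$objective))
  cat_rows <- sprintf("category\t%s\t%s\t%.10g\t%.10g\t%.10g",
                      fit$coords$axis,
                      ifelse(is.na(fit$coords$category), ".",
                             fit$coords$category),
                      fit$coords$alpha, fit$coords$coord,
                      fit$coords$dispersion)
  ind <- fit$individuals
  ind_rows <- sprintf("individual\t%s\t.\t.\t%.10g", ind$sample_id,
                      ifelse(is.na(ind$level), NaN, ind$level))
  writeLines(c(hdr, "row_type\taxis_or_sample\tcategory\talpha_or_na\tcoord_or_level\tdispersion",
               cat_rows, ind_rows), path)
  invisible(path)
}

# -- broom-style methods -----------------------------------------------------

#' Tidy a textile fit
#'
#' @param x A `textile_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (axis, category): `axis`, `kind`,
#'   `category`, `coord`, `count`, `alpha`, `dispersion`.
#' @export
tidy.textile_fit <- function(x, ...) x$coords

#' One-row summary of a textile fit
#'
#' @param x A `textile_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `p`, `lambda` (leading eigenvalue),
#'   `objective`, `m` (effective number of points) and `n_dropped`.
#' @export
glance.textile_fit <- function(x, ...) {
  tibble::tibble(n = nrow(x$y), p = length(x$order), lambda = x$lambda,
                 objective = x$objective, m = x$m, n_dropped = x$n_dropped)
}

#' Per-individual levels and coordinates
#'
#' @param x A `textile_fit`.
#' @param ... Unused.
#' @return A tibble with one row per individual per axis: `sample_id`,
#'   `axis`, `coord`, plus the individual's `level` and whether it entered
#'   the fit.
#' @export
augment.textile_fit <- function(x, ...) {
  tibble::as_tibble(x$y) |>
    dplyr::mutate(sample_id = x$individuals$sample_id,
                  level = x$individuals$level,
                  in_fit = x$individuals$in_fit) |>
    tidyr::pivot_longer(cols = dplyr::all_of(x$order), names_to = "axis",
                        values_to = "coord")
}
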
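#' Homozygous-stretch haplotype frequency approximation
#'
#' An individual homozygous at every locus of a contiguous axis range traces
#' a single polyline shared by both of its chromosomes — a homozygous
#' stretch. Under HWE the probability of being homozygous for haplotype H is
#' freq(H)^2, so the square root of the stretch proportion,
#' `sqrt(count / N)`, approximates the haplotype frequency without any
#' phasing. `N` counts the individuals fully observed in the range;
#' individuals with any missing call in the range are excluded. The
#' approximation degrades with increasing haplotype diversity and
#' decreasing LD strength.
#'
#' @param gm A [geno_tbl()].
#' @param loci Contiguous range of SNP axes (names or column indices in
#'   display order).
#' @return A tibble, one row per observed stretch haplotype, sorted by
#'   descending count: `haplotype`, `count`, `n_total`, `sqrt_freq`.
#' @export
homozygous_stretches <- function(gm, loci) {
  loci <- resolve_locus_range(gm, loci)
  al <- allele_pair_matrix(gm, loci)
  obs <- stats::complete.cases(al$a1)
  n_total <- sum(obs)
  if (n_total == 0) {
    return(tibble::tibble(haplotype = character(0), count = integer(0),
                          n_total = 0L, sqrt_freq = numeric(0)))
  }
  hom <- obs & rowSums(al$a1 != al$a2) == 0
  haps <- apply(al$a1[hom, , drop = FALSE], 1, paste, collapse = "")
  tab <- sort(table(haps), decreasing = TRUE)
  tibble::tibble(haplotype = names(tab),
                 count = as.integer(tab),
                 n_total = n_total,
                 sqrt_freq = sqrt(as.integer(tab) / n_total))
}

#' Subtract a known haplotype from a diplotype
#'
#' Given an individual compatible with carrying `haplotype` across the
#' range, returns the complementary haplotype: at each locus the other
#' allele of the individual's genotype. This is deterministic arithmetic,
#' not statistical inference. A missing genotype anywhere in the range makes
#' the complement ambiguous.
#'
#' @param gm A [geno_tbl()].
#' @param individual Sample id or row index.
#' @param haplotype Allele string, one allele per locus in the range.
#' @param loci Contiguous range of SNP axes; defaults to all SNP axes.
#' @return The complementary haplotype string, or `"AMBIGUOUS"` if a
#'   genotype in the range is missing.
#' @export
subtract_stretch <- function(gm, individual, haplotype, loci = NULL) {
  meta <- axis_meta(gm)
  if (is.null(loci)) loci <- meta$locus[meta$kind == "snp"]
  loci <- resolve_locus_range(gm, loci)
  i <- if (is.character(individual)) match(individual, gm$sample_id)
       else as.integer(individual)
  if (is.na(i) || i < 1 || i > nrow(gm)) {
    stop("unknown individual: ", individual, call. = FALSE)
  }
  want <- strsplit(haplotype, "")[[1]]
  if (length(want) != length(loci)) {
    stop("haplotype has ", length(want), " alleles for ", length(loci),
         " loci", call. = FALSE)
  }
  al <- allele_pair_matrix(gm, loci)
  a1 <- al$a1[i, ]; a2 <- al$a2[i, ]
  if (anyNA(a1)) return("AMBIGUOUS")
  comp <- character(length(loci))
  for (l in seq_along(loci)) {
    if (want[l] == a1[l]) comp[l] <- a2[l]
    else if (want[l] == a2[l]) comp[l] <- a1[l]
    else stop("genotype at locus ", loci[l], " (", a1[l], a2[l],
              ") is incompatible with allele ", want[l], call. = FALSE)
  }
  paste(comp, collapse = "")
}

#' EM haplotype frequency estimation
#'
#' Maximum-likelihood multi-locus haplotype frequencies under HWE by the
#' standard EM algorithm over diplotype expansions of unphased genotypes.
#' Initialized at linkage-equilibrium product frequencies; iterates until
#' the largest frequency change drops below `tol`. The log-likelihood is
#' non-decreasing across iterations. Individuals with a missing call in the
#' range are excluded.
#'
#' @param gm A [geno_tbl()].
#' @param loci SNP axes to use (names or indices); at most 12 diallelic
#'   loci (the haplotype space grows as 2^L).
#' @param tol Convergence tolerance on the frequency change.
#' @param max_iter Iteration cap.
#' @return A tibble (`haplotype`, `freq`) sorted by descending frequency,
#'   with attributes `loglik` (per-iteration log-likelihood trace) and
#'   `iterations`.
#' @export
em_haplotype_freqs <- function(gm, loci, tol = 1e-10, max_iter = 10000L) {
  loci <- resolve_locus_range(gm, loci, require_contiguous = FALSE)
  L <- length(loci)
  if (L > 12) {
    stop("haplotype space too large: ", L, " loci (limit 12)", call. = FALSE)
  }
  al <- allele_pair_matrix(gm, loci)
  obs <- stats::complete.cases(al$a1)
  a1 <- al$a1[obs, , drop = FALSE]
  a2 <- al$a2[obs, , drop = FALSE]
  N <- nrow(a1)
  if (N < 2) stop("fewer than 2 fully observed individuals", call. = FALSE)
  for (l in seq_len(L)) {
    if (length(unique(c(a1[, l], a2[, l]))) > 2) {
      stop("locus ", loci[l], " is not diallelic", call. = FALSE)
    }
  }

  # genotype classes: unordered pair per locus
  key <- apply(matrix(paste0(pmin(a1, a2), pmax(a1, a2)), N, L), 1,
               paste, collapse = "|")
  classes <- table(key)
  class_geno <- strsplit(names(classes), "|", fixed = TRUE)

  # expand each class into its compatible (unordered) diplotype pairs:
  # fix the first heterozygous locus to hap1 to enumerate 2^(H-1) pairs
  expand_class <- function(gstr) {
    g1 <- substr(gstr, 1, 1)
    g2 <- substr(gstr, 2, 2)
    het <- which(g1 != g2)
    if (!length(het)) {
      return(list(h1 = paste(g1, collapse = ""), h2 = paste(g2, collapse = "")))
    }
    free <- het[-1]
    nrows <- 2^length(free)
    combos <- if (length(free)) {
      expand.grid(rep(list(c(TRUE, FALSE)), length(free)))
    } else {
      data.frame(row.names = 1)
    }
    h1 <- matrix(rep(g1, nrows), ncol = length(g1), byrow = TRUE)
    h2 <- matrix(rep(g2, nrows), ncol = length(g1), byrow = TRUE)
    if (length(free)) {
      for (ii in seq_along(free)) {
        fl <- combos[[ii]]
        h1[fl, free[ii]] <- g2[free[ii]]
        h2[fl, free[ii]] <- g1[free[ii]]
      }
    }
    list(h1 = apply(h1, 1, paste, collapse = ""),
         h2 = apply(h2, 1, paste, collapse = ""))
  }
  expansions <- purrr::map(class_geno, expand_class)
  universe <- sort(unique(unlist(purrr::map(expansions,
                                            function(e) c(e$h1, e$h2)))))
  hid <- stats::setNames(seq_along(universe), universe)
  exp_idx <- purrr::map(expansions, function(e) {
    cbind(hid[e$h1], hid[e$h2])
  })
  n_class <- as.numeric(classes)

  # linkage-equilibrium initialization from marginal allele frequencies
  allele_freq <- purrr::map(seq_len(L), function(l) {
    tab <- table(c(a1[, l], a2[, l]))
    tab / sum(tab)
  })
  f <- vapply(universe, function(h) {
    ch <- strsplit(h, "")[[1]]
    prod(vapply(seq_len(L), function(l) allele_freq[[l]][[ch[l]]], 0))
  }, 0)
  f <- f / sum(f)

  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    counts <- numeric(length(universe))
    ll <- 0
    for (g in seq_along(exp_idx)) {
      idx <- exp_idx[[g]]
      wgt <- f[idx[, 1]] * f[idx[, 2]] * ifelse(idx[, 1] == idx[, 2], 1, 2)
      tot <- sum(wgt)
      if (tot <= 0) next
      post <- n_class[g] * wgt / tot
      ll <- ll + n_class[g] * log(tot)
      for (rr in seq_len(nrow(idx))) {
        counts[idx[rr, 1]] <- counts[idx[rr, 1]] + post[rr]
        counts[idx[rr, 2]] <- counts[idx[rr, 2]] + post[rr]
      }
    }
    loglik <- c(loglik, ll)
    f_new <- counts / (2 * N)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    warning("EM did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  out <- tibble::tibble(haplotype = universe, freq = unname(f)) |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$haplotype)
  attr(out, "loglik") <- loglik
  attr(out, "iterations") <- length(loglik)
  out
}

#' Export stretch and EM haplotype estimates as TSV
#'
#' One row per haplotype: stretch count, `sqrt(count/N)` estimate, and the
#' EM frequency for comparison.
#'
#' @param gm A [geno_tbl()].
#' @param loci Contiguous range of SNP axes.
#' @param path Output path.
#' @return The combined tibble, invisibly.
#' @export
export_haplotypes <- function(gm, loci, path) {
  st <- homozygous_stretches(gm, loci)
  em <- em_haplotype_freqs(gm, loci)
  out <- dplyr::full_join(st, em, by = "haplotype") |>
    dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$count, 0L)),
                   dplyr::desc(.data$freq)) |>
    dplyr::rename(em_freq = "freq")
  readr::write_tsv(out, path)
  invisible(out)
}

# -- shared helpers ----------------------------------------------------------

resolve_locus_range <- function(gm, loci, require_contiguous = TRUE) {
  all_loci <- axis_names(gm)
  loci <- if (is.character(loci)) loci else all_loci[loci]
  if (!length(loci)) stop("empty locus range", call. = FALSE)
  idx <- match(loci, all_loci)
  if (anyNA(idx)) stop("unknown locus: ", loci[is.na(idx)][1], call. = FALSE)
  if (require_contiguous && !all(diff(sort(idx)) == 1)) {
    stop("loci must form a contiguous range in the current display order",
         call. = FALSE)
  }
  loci
}

# n x L matrices of first/second allele characters (NA when missing)
allele_pair_matrix <- function(gm, loci) {
  a1 <- a2 <- matrix(NA_character_, nrow(gm), length(loci),
                     dimnames = list(NULL, loci))
  for (l in seq_along(loci)) {
    g <- split_geno_strings(as.character(gm[[loci[l]]]))
    a1[, l] <- g$a1
    a2[, l] <- g$a2
  }
  list(a1 = a1, a2 = a2)
}
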
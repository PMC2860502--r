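#' Two-locus LD statistics from haplotype frequencies
#'
#' Computes the classical pairwise linkage disequilibrium measures from the
#' frequency `pAB` of the haplotype carrying allele A at the first locus and
#' allele B at the second, and the marginal allele frequencies `pA`, `pB`:
#' \eqn{D = p_{AB} - p_A p_B}, \eqn{D' = |D| / D_{max}} with
#' \eqn{D_{max} = \min(p_A q_B, q_A p_B)} for positive D and
#' \eqn{\min(p_A p_B, q_A q_B)} for negative D, and
#' \eqn{r^2 = D^2 / (p_A q_A p_B q_B)}. `D = 0` returns `Dprime = r2 = 0`
#' by convention; a monomorphic locus returns flagged `NA`s.
#'
#' @param pAB,pA,pB Haplotype and allele frequencies in `[0, 1]`, with
#'   `pAB` inside the Frechet bounds.
#' @return A tibble with columns `D`, `Dprime`, `r2`.
#' @export
ld_from_hapfreqs <- function(pAB, pA, pB) {
  stopifnot(length(pAB) == length(pA), length(pA) == length(pB))
  if (any(pAB < -1e-12 | pA < -1e-12 | pB < -1e-12 |
          pAB > 1 + 1e-12 | pA > 1 + 1e-12 | pB > 1 + 1e-12, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  lo <- pmax(0, pA + pB - 1) - 1e-9
  hi <- pmin(pA, pB) + 1e-9
  if (any(pAB < lo | pAB > hi, na.rm = TRUE)) {
    stop("pAB violates the Frechet bounds for (pA, pB)", call. = FALSE)
  }
  qA <- 1 - pA
  qB <- 1 - pB
  D <- pAB - pA * pB
  mono <- pA <= 0 | pA >= 1 | pB <= 0 | pB >= 1
  Dmax <- ifelse(D >= 0, pmin(pA * qB, qA * pB), pmin(pA * pB, qA * qB))
  Dprime <- ifelse(D == 0, 0, abs(D) / Dmax)
  r2 <- ifelse(D == 0, 0, D^2 / (pA * qA * pB * qB))
  Dprime[mono] <- NA_real_
  r2[mono] <- NA_real_
  D[mono] <- NA_real_
  tibble::tibble(D = D, Dprime = Dprime, r2 = r2)
}

# major-allele and haplotype frequencies for a diallelic pair from an EM fit
pair_freqs_from_em <- function(em, majA, majB) {
  h <- em$haplotype
  pA <- sum(em$freq[substr(h, 1, 1) == majA])
  pB <- sum(em$freq[substr(h, 2, 2) == majB])
  pAB <- sum(em$freq[h == paste0(majA, majB)])
  list(pAB = pAB, pA = pA, pB = pB)
}

#' Two-locus LD from unphased genotypes
#'
#' Estimates haplotype frequencies for a pair of diallelic loci by the EM
#' algorithm on the unphased genotype table, then applies
#' [ld_from_hapfreqs()].
#'
#' @param gm A [geno_tbl()].
#' @param j,k Locus names or column indices.
#' @param method Estimation method; only `"em"` is implemented.
#' @return A tibble with `D`, `Dprime`, `r2` plus the estimated `pA`, `pB`,
#'   `pAB` (frequencies of the major alleles and their haplotype).
#' @export
ld_from_genotypes <- function(gm, j, k, method = "em") {
  method <- match.arg(method, "em")
  loci <- axis_names(gm)
  a <- if (is.character(j)) j else loci[j]
  b <- if (is.character(k)) k else loci[k]
  al_a <- locus_alleles(gm, a)
  al_b <- locus_alleles(gm, b)
  if (length(al_a) != 2 || length(al_b) != 2) {
    stop("pairwise LD is defined for diallelic loci only (", a, ", ", b, ")",
         call. = FALSE)
  }
  em <- em_haplotype_freqs(gm, c(a, b), tol = 1e-12)
  fr <- pair_freqs_from_em(em, al_a[1], al_b[1])
  ld <- ld_from_hapfreqs(fr$pAB, fr$pA, fr$pB)
  dplyr::mutate(ld, pA = fr$pA, pB = fr$pB, pAB = fr$pAB)
}

locus_alleles <- function(gm, locus) {
  col <- gm[[locus]]
  al <- attr(col, "alleles")
  if (is.null(al)) {
    g <- split_geno_strings(as.character(col))
    al <- rank_alleles(g$a1, g$a2)
  }
  al
}

#' Pairwise LD matrix over all diallelic SNP axes
#'
#' Applies [ld_from_genotypes()] to every pair of diallelic SNP loci.
#' Multi-allelic loci and phenotype axes are excluded (flagged `NA`).
#'
#' @param gm A [geno_tbl()].
#' @return An `ld_matrix`: list with `long` (tibble `locus_i`, `locus_j`,
#'   `D`, `Dprime`, `r2`), `loci`, `method`, and matrix accessors via
#'   [ld_stat_matrix()].
#' @export
pairwise_ld <- function(gm) {
  meta <- axis_meta(gm)
  snps <- meta$locus[meta$kind == "snp"]
  diallelic <- vapply(snps, function(l) length(locus_alleles(gm, l)) == 2,
                      TRUE)
  if (any(!diallelic)) {
    warning("excluding non-diallelic loci from pairwise LD: ",
            paste(snps[!diallelic], collapse = ", "), call. = FALSE)
  }
  pairs <- tidyr::expand_grid(locus_i = snps, locus_j = snps) |>
    dplyr::filter(match(.data$locus_i, snps) < match(.data$locus_j, snps))
  long <- purrr::pmap_dfr(pairs, function(locus_i, locus_j) {
    row <- if (diallelic[[locus_i]] && diallelic[[locus_j]]) {
      tryCatch(ld_from_genotypes(gm, locus_i, locus_j)[, c("D", "Dprime", "r2")],
               error = function(e) tibble::tibble(D = NA_real_,
                                                  Dprime = NA_real_,
                                                  r2 = NA_real_))
    } else {
      tibble::tibble(D = NA_real_, Dprime = NA_real_, r2 = NA_real_)
    }
    dplyr::mutate(row, locus_i = locus_i, locus_j = locus_j, .before = 1)
  })
  structure(list(long = long, loci = snps, method = "em"),
            class = "ld_matrix")
}

#' Extract one LD statistic as a symmetric matrix
#'
#' @param x An `ld_matrix` from [pairwise_ld()].
#' @param stat `"r2"`, `"Dprime"` or `"D"`.
#' @return A symmetric p x p matrix with 1 (for `r2`/`Dprime`) on the
#'   diagonal where defined.
#' @export
ld_stat_matrix <- function(x, stat = c("r2", "Dprime", "D")) {
  stat <- match.arg(stat)
  p <- length(x$loci)
  m <- matrix(NA_real_, p, p, dimnames = list(x$loci, x$loci))
  diag(m) <- if (stat == "D") 0 else 1
  idx_i <- match(x$long$locus_i, x$loci)
  idx_j <- match(x$long$locus_j, x$loci)
  m[cbind(idx_i, idx_j)] <- x$long[[stat]]
  m[cbind(idx_j, idx_i)] <- x$long[[stat]]
  m
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("# pairwise LD (", x$method, ") over ", length(x$loci), " loci\n",
      sep = "")
  print(x$long, ...)
  invisible(x)
}

#' Tidy an LD matrix
#' @param x An `ld_matrix`.
#' @param ... Unused.
#' @return The long tibble (`locus_i`, `locus_j`, `D`, `Dprime`, `r2`).
#' @export
tidy.ld_matrix <- function(x, ...) x$long

#' Export LD statistics as TSV
#'
#' @param x An `ld_matrix`.
#' @param path Output path. With `format = "square"` one file per statistic
#'   is written, suffixed `_r2.tsv` / `_Dprime.tsv`.
#' @param format `"long"` (locus_i, locus_j, Dprime, r2) or `"square"`.
#' @return The path(s), invisibly.
#' @export
export_ld <- function(x, path, format = c("long", "square")) {
  format <- match.arg(format)
  if (format == "long") {
    readr::write_tsv(x$long, path)
    return(invisible(path))
  }
  base <- sub("\\.tsv$", "", path)
  paths <- character(0)
  for (stat in c("r2", "Dprime")) {
    m <- ld_stat_matrix(x, stat)
    out <- paste0(base, "_", stat, ".tsv")
    readr::write_tsv(tibble::as_tibble(m, rownames = "locus"), out)
    paths <- c(paths, out)
  }
  invisible(paths)
}

#' Heat-map style plot of pairwise LD
#'
#' @param object An `ld_matrix`.
#' @param stat Statistic to fill by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ld_matrix <- function(object, stat = c("r2", "Dprime"), ...) {
  stat <- match.arg(stat)
  long <- object$long
  long$locus_i <- factor(long$locus_i, levels = object$loci)
  long$locus_j <- factor(long$locus_j, levels = object$loci)
  ggplot2::ggplot(long, ggplot2::aes(.data$locus_i, .data$locus_j,
                                     fill = .data[[stat]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = stat) +
    ggplot2::theme_minimal()
}
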
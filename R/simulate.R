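#' Two-locus haplotype frequencies from MAF and D'
#'
#' Constructs the four haplotype frequencies for a diallelic pair with the
#' requested minor allele frequencies and normalized LD coefficient.
#' Writing `pA = 1 - maf1`, `pB = 1 - maf2` for the major alleles,
#' `D = sign * dprime * Dmax` with `Dmax = min(pA qB, qA pB)` for positive D
#' and `min(pA pB, qA qB)` for negative D, giving
#' `pAB = pA pB + D` etc. `dprime = 1` drives one haplotype frequency to
#' exactly zero (complete LD); `dprime = 0` gives independence products.
#'
#' @param maf1,maf2 Minor allele frequencies in `(0, 0.5]`.
#' @param dprime Normalized LD coefficient in `[0, 1]`.
#' @param sign `+1` (default) or `-1`: sign of D (coupling of the two major
#'   alleles).
#' @param alleles List of two length-2 character vectors (major, minor
#'   allele label per locus).
#' @return A tibble (`haplotype`, `freq`) over the four haplotypes.
#' @export
hapfreqs_from_ld <- function(maf1, maf2, dprime, sign = 1,
                             alleles = list(c("A", "a"), c("B", "b"))) {
  stopifnot(maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5,
            dprime >= 0, dprime <= 1, sign %in% c(-1, 1))
  pA <- 1 - maf1; qA <- maf1
  pB <- 1 - maf2; qB <- maf2
  Dmax <- if (sign > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  D <- sign * dprime * Dmax
  freq <- c(pA * pB + D, pA * qB - D, qA * pB - D, qA * qB + D)
  if (any(freq < -1e-12)) {
    stop("infeasible (maf, dprime, sign) combination", call. = FALSE)
  }
  freq <- pmax(freq, 0)
  hap <- c(paste0(alleles[[1]][1], alleles[[2]][1]),
           paste0(alleles[[1]][1], alleles[[2]][2]),
           paste0(alleles[[1]][2], alleles[[2]][1]),
           paste0(alleles[[1]][2], alleles[[2]][2]))
  tibble::tibble(haplotype = hap, freq = freq / sum(freq))
}

#' Simulate genotypes under HWE from a haplotype pool
#'
#' Each individual is formed by two independent draws from the haplotype
#' pool (Hardy-Weinberg equilibrium); its genotype at each locus is the
#' unordered allele pair. The drawn haplotypes are retained (see
#' [sim_truth()]) for validation. Output is bit-reproducible for a fixed
#' seed.
#'
#' @param pool A tibble with columns `haplotype` (allele string, one
#'   character per locus) and `freq` (summing to 1), e.g. from
#'   [hapfreqs_from_ld()] or [block_haplotype_pool()].
#' @param n Number of individuals.
#' @param seed Optional integer seed (restores the RNG state on exit).
#' @param loci Optional locus names; defaults to `snp1 ... snpL`.
#' @param pos Optional physical positions; defaults to `1:L`.
#' @return A [geno_tbl()] with a `truth` attribute (`sample_id`, `hap1`,
#'   `hap2`).
#' @export
simulate_genotypes <- function(pool, n, seed = NULL, loci = NULL,
                               pos = NULL) {
  stopifnot(all(c("haplotype", "freq") %in% names(pool)), n >= 1)
  if (abs(sum(pool$freq) - 1) > 1e-8) {
    stop("haplotype pool frequencies must sum to 1", call. = FALSE)
  }
  L <- unique(nchar(pool$haplotype))
  if (length(L) != 1) {
    stop("haplotypes must all have the same length", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
  }
  draws <- sample.int(nrow(pool), 2 * n, replace = TRUE, prob = pool$freq)
  hap1 <- pool$haplotype[draws[seq_len(n)]]
  hap2 <- pool$haplotype[draws[n + seq_len(n)]]
  if (is.null(loci)) loci <- paste0("snp", seq_len(L))
  if (is.null(pos)) pos <- seq_len(L)
  am1 <- do.call(rbind, strsplit(hap1, ""))
  am2 <- do.call(rbind, strsplit(hap2, ""))
  cols <- purrr::map(seq_len(L), function(l) {
    make_geno_factor(am1[, l], am2[, l])
  })
  names(cols) <- loci
  gm <- geno_tbl(tibble::tibble(sample_id = paste0("ind", seq_len(n)), !!!cols),
                 tibble::tibble(locus = loci, chrom = "1",
                                pos = as.integer(pos), kind = "snp"))
  attr(gm, "truth") <- tibble::tibble(sample_id = gm$sample_id,
                                      hap1 = hap1, hap2 = hap2)
  gm
}

#' Haplotype pool for an LD-block design
#'
#' Builds a multilocus haplotype pool whose adjacent within-block pairs
#' attain a requested D' and whose adjacent cross-block pair attains a
#' (typically weaker) between-block D', via a first-order Markov chain over
#' loci: the allele at locus j+1 is drawn conditionally on the allele at
#' locus j with the two-locus frequencies of [hapfreqs_from_ld()]. Pairwise
#' D' for non-adjacent loci is approximate (it decays with chain distance).
#'
#' @param block_sizes Integer vector of loci per block.
#' @param maf Scalar or per-locus minor allele frequency.
#' @param within_dprime D' between adjacent loci in the same block.
#' @param between_dprime D' between the last locus of one block and the
#'   first of the next.
#' @param alleles Length-2 character vector (major, minor) used at every
#'   locus.
#' @return A tibble (`haplotype`, `freq`) enumerating all haplotypes with
#'   positive probability.
#' @export
block_haplotype_pool <- function(block_sizes, maf, within_dprime,
                                 between_dprime,
                                 alleles = c("A", "B")) {
  L <- sum(block_sizes)
  stopifnot(L >= 2, L <= 16)
  maf <- rep_len(maf, L)
  block_id <- rep(seq_along(block_sizes), block_sizes)
  # transition tables: P(allele_{j+1} | allele_j), rows = major/minor at j
  trans <- purrr::map(seq_len(L - 1), function(j) {
    dp <- if (block_id[j] == block_id[j + 1]) within_dprime else between_dprime
    fr <- hapfreqs_from_ld(maf[j], maf[j + 1], dp)
    pj <- c(1 - maf[j], maf[j])
    matrix(fr$freq / rep(pj, each = 2), 2, 2, byrow = TRUE)
  })
  combos <- as.matrix(expand.grid(rep(list(1:2), L))[, L:1, drop = FALSE])
  freq <- apply(combos, 1, function(idx) {
    pr <- c(1 - maf[1], maf[1])[idx[1]]
    for (j in seq_len(L - 1)) pr <- pr * trans[[j]][idx[j], idx[j + 1]]
    pr
  })
  keep <- freq > 0
  hap <- apply(combos[keep, , drop = FALSE], 1,
               function(idx) paste(alleles[idx], collapse = ""))
  tibble::tibble(haplotype = hap, freq = freq[keep] / sum(freq[keep])) |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$haplotype)
}

#' Simulate genotypes for a two-level LD-block design
#'
#' Convenience wrapper: [block_haplotype_pool()] then
#' [simulate_genotypes()].
#'
#' @inheritParams block_haplotype_pool
#' @inheritParams simulate_genotypes
#' @return A [geno_tbl()] with retained truth.
#' @export
simulate_blocks <- function(block_sizes, maf, within_dprime, between_dprime,
                            n, seed = NULL) {
  pool <- block_haplotype_pool(block_sizes, maf, within_dprime,
                               between_dprime)
  simulate_genotypes(pool, n, seed = seed)
}
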
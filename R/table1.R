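#' Two-SNP genotype contingency table (worked example)
#'
#' The 3 x 3 genotype count table for two SNP loci in a sample of 10,000
#' individuals drawn under HWE from a two-locus haplotype pool, used
#' throughout the documentation as the canonical two-SNP example: the
#' heterozygote-heterozygote cell (Aa, Bb) is the largest pair count
#' (2,583) and the aa marginal at SNP 1 is the smallest genotype count
#' (1,465).
#'
#' @return An integer matrix, SNP 1 genotypes (AA, Aa, aa) in rows and
#'   SNP 2 genotypes (BB, Bb, bb) in columns.
#' @export
table1_counts <- function() {
  matrix(c(1567L, 1757L, 472L,
           1091L, 2583L, 1065L,
           201L,  696L,  568L),
         nrow = 3, byrow = TRUE,
         dimnames = list(SNP1 = c("AA", "Aa", "aa"),
                         SNP2 = c("BB", "Bb", "bb")))
}

#' Expand a two-axis genotype count table into a genotype dataset
#'
#' Inverse of [pair_counts()] for a pair of axes: builds one individual per
#' counted genotype pair. Useful for loading printed contingency tables as
#' genotype data.
#'
#' @param counts Integer matrix with genotype labels as dimnames.
#' @param loci Length-2 axis names; default from the dimnames.
#' @return A [geno_tbl()] with `sum(counts)` individuals.
#' @export
geno_from_pair_counts <- function(counts, loci = names(dimnames(counts))) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (is.null(loci) || length(loci) != 2) loci <- c("SNP1", "SNP2")
  idx <- which(counts >= 0, arr.ind = TRUE)
  g1 <- rep(rownames(counts)[idx[, 1]], counts[idx])
  g2 <- rep(colnames(counts)[idx[, 2]], counts[idx])
  s1 <- split_geno_strings(g1)
  s2 <- split_geno_strings(g2)
  df <- tibble::tibble(
    sample_id = paste0("ind", seq_along(g1)),
    !!loci[1] := make_geno_factor(s1$a1, s1$a2),
    !!loci[2] := make_geno_factor(s2$a1, s2$a2))
  geno_tbl(df, tibble::tibble(locus = loci, chrom = "1", pos = 1:2,
                              kind = "snp"))
}
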
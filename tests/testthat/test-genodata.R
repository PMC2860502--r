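test_that("TSV genotypes map to ordered categories with no missing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("L1", "AA", "Aa", "aa", "Aa", "AA"), path)
  gm <- read_genotypes(path, "tsv")
  col <- gm$L1
  expect_s3_class(col, "factor")
  expect_equal(levels(col), c("AA", "Aa", "aa")) # major-hom, het, minor-hom
  expect_equal(nlevels(col), 3L)
  expect_false(anyNA(col))
  expect_equal(attr(col, "alleles"), c("A", "a"))
})

test_that("category order follows descending allele frequency", {
  # G is the major allele here, so GG must come first
  g <- make_geno_factor(c("G", "G", "A", "G"), c("G", "A", "A", "G"))
  expect_equal(levels(g), c("GG", "GA", "AA"))
  expect_equal(as.character(g[2]), "GA") # major allele first in the label
})

test_that("VCF GT dialect: unphased mapping, phased as unphased, half-missing as missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", "s5", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0|1", "./.", "1/1", "./1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T,G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "1/2", "0/0", sep = "\t")), path)
  gm <- read_genotypes(path, "vcf")
  expect_equal(gm$sample_id, paste0("s", 1:5))
  r1 <- as.character(gm$rs1)
  expect_equal(r1[c(1, 2, 4)], c("AA", "AG", "GG"))
  expect_true(is.na(r1[3]))   # ./. fully missing
  expect_true(is.na(r1[5]))   # half-missing treated as fully missing
  # tri-allelic locus: one category per distinct unordered allele pair
  expect_equal(nlevels(gm$rs2), 4L)
  expect_setequal(levels(gm$rs2), c("CC", "CT", "TT", "TG"))
  expect_equal(axis_meta(gm)$pos, c(100L, 200L))
})

test_that("PLINK ped/map pairs read with 0 = missing", {
  base <- withr::local_tempfile()
  writeLines(c("1\tsnpA\t0\t1000", "1\tsnpB\t0\t2000"),
             paste0(base, ".map"))
  writeLines(c("f1 i1 0 0 1 0 A A G G",
               "f1 i2 0 0 1 0 A C G T",
               "f1 i3 0 0 1 0 0 0 T T"),
             paste0(base, ".ped"))
  gm <- read_genotypes(paste0(base, ".ped"), "plink")
  expect_equal(gm$sample_id, c("i1", "i2", "i3"))
  expect_true(is.na(gm$snpA[3]))
  expect_equal(as.character(gm$snpB), c("GG", "GT", "TT"))
  expect_equal(axis_meta(gm)$pos, c(1000L, 2000L))
})

test_that("SNP axes are ordered by position; phenotypes stay leftmost", {
  df <- tibble::tibble(b = factor(c("AA", "Aa")), a = factor(c("CC", "CT")))
  gm <- geno_tbl(df, tibble::tibble(locus = c("b", "a"), chrom = "1",
                                    pos = c(200L, 100L), kind = "snp"))
  expect_equal(axis_names(gm), c("a", "b"))
  gm2 <- attach_phenotype(gm, c("case", "ctrl"), "categorical")
  expect_equal(axis_names(gm2)[1], "phenotype")
})

test_that("encode_axis builds unit-row indicators, valid contrasts and weights", {
  x <- factor(c("AA", "Aa", "aa", "Aa"), levels = c("AA", "Aa", "aa"))
  e <- encode_axis(x)
  expect_equal(e$indicator,
               matrix(c(1, 0, 0, 0,
                        0, 1, 0, 1,
                        0, 0, 1, 0), 4, 3,
                      dimnames = list(NULL, c("AA", "Aa", "aa"))))
  expect_equal(e$weight, rep(1, 4))

  xm <- factor(c("AA", NA), levels = c("AA", "Aa", "aa"))
  em <- encode_axis(xm)
  expect_equal(em$indicator[2, ], c(AA = 0, Aa = 0, aa = 0))
  expect_equal(em$weight, c(1, 0))

  # contrast rank and independence from the ones vector (independent check)
  for (cc in 2:5) {
    B <- encode_axis(factor(letters[rep(1:cc, 2)]))$contrast
    expect_equal(qr(B)$rank, cc - 1)
    expect_equal(qr(cbind(1, B))$rank, cc)
  }
})

test_that("indicator row sums equal the weight vector for random axes", {
  set.seed(11)
  for (rep in 1:10) {
    x <- sample(c(letters[1:3], NA), 20, replace = TRUE)
    e <- encode_axis(factor(x))
    expect_equal(unname(rowSums(e$indicator)), e$weight)
  }
})

test_that("TSV round-trip reproduces the genotype table exactly", {
  set.seed(3)
  gm <- simulate_genotypes(hapfreqs_from_ld(0.3, 0.45, 0.6), 40, seed = 9)
  gm <- attach_phenotype(gm, rep(c("case", "ctrl"), 20), "categorical")
  gm <- attach_phenotype(gm, round(rnorm(40), 6), "quantitative", name = "bmi")
  gm$snp1[c(2, 5)] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  gm2 <- read_genotypes(path, "tsv")
  attr(gm, "truth") <- NULL # simulator provenance is not part of the dump
  expect_equal(as.data.frame(gm2), as.data.frame(gm))
  expect_equal(axis_meta(gm2)$kind, axis_meta(gm)$kind)
  expect_equal(axis_meta(gm2)$pos, axis_meta(gm)$pos)
  for (l in c("snp1", "snp2", "phenotype")) {
    expect_equal(levels(gm2[[l]]), levels(gm[[l]]))
  }
})

test_that("phenotype attachment validates input and flags degeneracy", {
  gm <- simulate_genotypes(hapfreqs_from_ld(0.4, 0.4, 0.8), 10, seed = 2)
  gm2 <- attach_phenotype(gm, rep(c("case", "ctrl"), 5), "categorical")
  expect_equal(nlevels(gm2$phenotype), 2L)
  expect_warning(attach_phenotype(gm, rep("x", 10), "categorical"),
                 "degenerate")
  expect_error(attach_phenotype(gm, 1:3, "quantitative"), "length")
  q <- attach_phenotype(gm, c(1.2, 0.7, -0.3, rep(0, 7)), "quantitative")
  expect_true(is.numeric(q$phenotype))
  expect_equal(axis_meta(q)$kind[1], "quantitative_phenotype")
})

test_that("constructors reject malformed input", {
  expect_error(geno_tbl(tibble::tibble(sample_id = c("a", "a"),
                                       L = factor(c("AA", "AA")))),
               "duplicate sample")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("L1", "A/G/T"), path)
  expect_error(read_genotypes(path, "tsv"), "non-diploid")
})
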
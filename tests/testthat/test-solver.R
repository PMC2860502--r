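perfect_ld_data <- function(n = 60, seed = 5) {
  set.seed(seed)
  g <- sample(c("AA", "Aa", "aa"), n, replace = TRUE,
              prob = c(0.36, 0.48, 0.16))
  s <- split_geno_strings(g)
  tibble::tibble(L1 = make_geno_factor(s$a1, s$a2),
                 L2 = make_geno_factor(s$a1, s$a2))
}

test_that("absolute LD yields zero objective, horizontal segments, no crossings", {
  g <- perfect_ld_data()
  # duplicated axes tie the leading eigenvalue: degeneracy is flagged
  expect_warning(fit <- textile_layout(g), "not uniquely determined")
  expect_lt(fit$objective, 1e-16)
  v1 <- fit$coords$coord[fit$coords$axis == "L1"]
  v2 <- fit$coords$coord[fit$coords$axis == "L2"]
  expect_equal(v1, v2, tolerance = 1e-10)
  expect_equal(crossing_count(fit, 1), 0L)
})

test_that("solver matches a multi-start constrained optimizer on random tiny instances", {
  set.seed(101)
  for (i in 1:20) {
    g <- random_tiny_geno(n = sample(4:8, 1), p = sample(2:3, 1),
                          miss_prob = ifelse(i %% 2, 0, 0.12))
    fit <- suppressWarnings(textile_layout(g))
    bf <- bf_layout_objective(g, n_starts = 12, seed = i)
    expect_lt(abs(bf - fit$objective) / max(1, abs(bf)), 1e-6)
  }
})

test_that("the dispersion constraint holds exactly at every solution", {
  set.seed(77)
  for (i in 1:10) {
    g <- random_tiny_geno(n = 12, p = 3, miss_prob = 0.1)
    fit <- suppressWarnings(textile_layout(g))
    disp <- sum(vapply(seq_along(fit$order), function(j) {
      wj <- fit$weights[, j]
      yj <- ifelse(is.na(fit$y[, j]), 0, fit$y[, j])
      ybar <- sum(wj * yj) / sum(wj)
      sum(wj * (yj - ybar)^2)
    }, 0))
    expect_lt(abs(disp - fit$m), 1e-8)
  }
})

test_that("individual levels are weighted means of observed coordinates", {
  set.seed(42)
  g <- random_tiny_geno(n = 15, p = 3, miss_prob = 0.15)
  fit <- suppressWarnings(textile_layout(g))
  y <- fit$y; w <- fit$weights
  h2 <- rowSums(w * ifelse(is.na(y), 0, y)) / rowSums(w)
  expect_equal(fit$individuals$level, h2, tolerance = 1e-12)
})

test_that("layout is invariant to axis order, contrast choice and allele relabeling", {
  set.seed(9)
  gm <- simulate_blocks(c(2, 2), 0.4, 0.8, 0.1, n = 150, seed = 31)
  fit <- textile_layout(gm)

  # axis order: objective does not reference adjacency
  perm <- c("snp3", "snp1", "snp4", "snp2")
  df <- tibble::as_tibble(gm)[, c("sample_id", perm)]
  gm_perm <- geno_tbl(df, tibble::tibble(
    locus = perm, chrom = "1", pos = match(perm, axis_names(gm)),
    kind = "snp"))
  fit_perm <- textile_layout(gm_perm)
  expect_equal(fit_perm$lambda, fit$lambda, tolerance = 1e-10)
  expect_equal(fit_perm$y[, axis_names(gm)], fit$y, tolerance = 1e-8)

  # contrast basis: any basis independent of the ones vector gives the same
  # coordinates
  fit_tr <- textile_layout(gm, contrast_fun = stats::contr.treatment)
  fit_po <- textile_layout(gm, contrast_fun = stats::contr.poly)
  expect_equal(fit_tr$y, fit$y, tolerance = 1e-10)
  expect_equal(fit_po$y, fit$y, tolerance = 1e-10)

  # allele label swap at one locus permutes categories only
  df2 <- tibble::as_tibble(gm)
  sw <- chartr("AB", "BA", as.character(df2$snp2))
  s <- split_geno_strings(sw)
  df2$snp2 <- make_geno_factor(s$a1, s$a2)
  fit_sw <- textile_layout(geno_tbl(df2, axis_meta(gm)[, 1:4]))
  expect_equal(fit_sw$y, fit$y, tolerance = 1e-10)
})

test_that("category coordinates match textbook MCA first-dimension scores on complete data", {
  set.seed(13)
  gm <- simulate_blocks(c(3, 2), c(0.4, 0.3, 0.45, 0.35, 0.4), 0.85, 0.2,
                        n = 300, seed = 17)
  fit <- textile_layout(gm)
  scores <- mca_category_scores(tibble::as_tibble(gm)[, axis_names(gm)])
  offsets <- unlist(lapply(axis_names(gm), function(a) {
    rows <- fit$coords[fit$coords$axis == a, ]
    cnt <- rows$count
    rows$coord - sum(cnt * rows$coord) / sum(cnt)
  }))
  expect_gt(abs(stats::cor(offsets, scores)), 1 - 1e-8)
})

test_that("empirically independent axes trigger a non-uniqueness warning", {
  combos <- expand.grid(a = c("AA", "Aa"), b = c("CC", "Cc"))
  g <- tibble::tibble(
    L1 = factor(rep(combos$a, each = 5)),
    L2 = factor(rep(combos$b, each = 5)))
  expect_warning(textile_layout(g), "not uniquely determined|degenerate")
})

test_that("monomorphic axes get zero scale and sit at the mean level", {
  g <- tibble::tibble(
    L1 = factor(c("AA", "Aa", "aa", "Aa", "AA", "aa")),
    L2 = factor(c("BB", "Bb", "bb", "BB", "Bb", "bb")),
    L3 = factor(rep("CC", 6)))
  fit <- textile_layout(g)
  expect_equal(fit$gamma[[3]], numeric(0))
  v3 <- fit$coords$coord[fit$coords$axis == "L3"]
  expect_equal(v3, mean(fit$individuals$level), tolerance = 1e-10)
  expect_error(textile_layout(tibble::tibble(a = factor(rep("AA", 4)),
                                             b = factor(rep("BB", 4)))),
               "monomorphic")
})

test_that("individuals observed on fewer than two axes are dropped with a warning", {
  g <- tibble::tibble(
    L1 = factor(c("AA", "Aa", "aa", NA, "AA")),
    L2 = factor(c("BB", "Bb", "bb", NA, "Bb")),
    L3 = factor(c("CC", "Cc", "cc", "CC", NA)))
  expect_warning(fit <- textile_layout(g), "dropped")
  expect_equal(fit$n_dropped, 1L)
  expect_true(is.na(fit$individuals$level[4]))
  expect_equal(fit$m, sum(fit$weights[-4, ]))
})

test_that("a quantitative phenotype axis enters standardized and centered", {
  gm <- simulate_genotypes(hapfreqs_from_ld(0.4, 0.4, 0.9), 80, seed = 3)
  dose <- dosage_matrix(gm)[, 1]
  pheno <- dose * 2 + rnorm(80, sd = 0.3)
  gm2 <- attach_phenotype(gm, pheno, "quantitative")
  fit <- textile_layout(gm2)
  yq <- fit$y[, "phenotype"]
  wq <- fit$weights[, "phenotype"]
  # unit weighted variance after standardization (axis dispersion = 1)
  d <- dispersion_profile(fit)
  expect_equal(unname(d["phenotype"]) > 0, TRUE)
  expect_equal(sum(wq * (yq - sum(wq * yq) / sum(wq))^2) / sum(wq),
               d[["phenotype"]]^2, tolerance = 1e-10)
  # a trait tracking the dosage correlates with the layout levels
  expect_gt(abs(cor(yq, fit$individuals$level)), 0.5)
})

test_that("phenotype_in_fit = FALSE places the axis post hoc without entering the constraint", {
  gm <- simulate_genotypes(hapfreqs_from_ld(0.4, 0.4, 0.9), 100, seed = 8)
  gm2 <- attach_phenotype(gm, rep(c("case", "ctrl"), 50), "categorical")
  fit_in <- textile_layout(gm2, phenotype_in_fit = TRUE)
  fit_out <- textile_layout(gm2, phenotype_in_fit = FALSE)
  expect_equal(fit_out$m, sum(fit_out$weights[, c("snp1", "snp2")]))
  # SNP coordinates with the phenotype excluded equal the SNP-only fit
  fit_snp <- textile_layout(gm)
  expect_equal(fit_out$y[, c("snp1", "snp2")], fit_snp$y, tolerance = 1e-10)
  expect_true(all(is.finite(fit_in$coords$coord)))
})

test_that("objective decreases as simulated pairwise LD strengthens at fixed n", {
  qs <- vapply(c(0.1, 0.5, 0.9), function(dp) {
    gm <- simulate_genotypes(hapfreqs_from_ld(0.4, 0.4, dp), 2000, seed = 77)
    textile_layout(gm)$objective
  }, 0)
  expect_true(all(diff(qs) < 0))
})

test_that("crossing counts follow the combinatorial definition", {
  # half the individuals in exactly inverted vertical order: n^2/4 crossings.
  # Built as a fixed configuration (not an optimized layout, which would
  # align the two groups horizontally instead).
  n <- 40
  g <- geno_tbl(tibble::tibble(
    L1 = factor(rep(c("AA", "aa"), each = n / 2), levels = c("AA", "aa")),
    L2 = factor(rep(c("bb", "BB"), each = n / 2), levels = c("BB", "bb"))))
  inverted <- structure(list(
    coords = tibble::tibble(
      axis = c("L1", "L1", "L2", "L2"),
      kind = "snp",
      category = c("AA", "aa", "BB", "bb"),
      coord = c(1, -1, 1, -1),
      count = n / 2, alpha = 0, dispersion = 1),
    data = g, order = c("L1", "L2")), class = "textile_fit")
  expect_equal(crossing_count(inverted, 1), as.integer(n^2 / 4))

  # complete LD: crossings only between opposite homozygotes
  pool <- hapfreqs_from_ld(0.3, 0.3, 1) # one haplotype frequency exactly 0
  gm <- simulate_genotypes(pool, 400, seed = 21)
  fit2 <- suppressWarnings(textile_layout(gm))
  tab <- pair_counts(gm, 1, 2)
  v1 <- axis_category_coords(fit2, "snp1")
  v2 <- axis_category_coords(fit2, "snp2")
  manual <- 0
  cells <- which(tab > 0, arr.ind = TRUE)
  for (u in seq_len(nrow(cells) - 1)) for (v in (u + 1):nrow(cells)) {
    da <- v1[rownames(tab)[cells[u, 1]]] - v1[rownames(tab)[cells[v, 1]]]
    db <- v2[colnames(tab)[cells[u, 2]]] - v2[colnames(tab)[cells[v, 2]]]
    if (da * db < 0) manual <- manual + tab[cells[u, , drop = FALSE]] *
        tab[cells[v, , drop = FALSE]]
  }
  expect_equal(crossing_count(fit2, 1), as.integer(manual))
})

test_that("heterozygote sits midway between homozygotes for symmetric data, deviates under inbreeding", {
  # joint counts symmetric under a simultaneous allele swap at both loci:
  # the solution is symmetric under negation, so the deviation is exactly 0
  cnt <- matrix(c(30, 10, 5,
                  10, 20, 10,
                  5, 10, 30), 3, byrow = TRUE,
                dimnames = list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb")))
  fit <- textile_layout(geno_from_pair_counts(cnt))
  expect_lt(abs(het_mid_deviation(fit, 1)), 1e-10)

  # inbred simulation (excess homozygosity) vs an HWE resimulation null
  pool <- hapfreqs_from_ld(0.35, 0.35, 0.9)
  inbred_geno <- function(n, f, seed) {
    set.seed(seed)
    h1 <- sample(pool$haplotype, n, replace = TRUE, prob = pool$freq)
    copy <- runif(n) < f
    h2 <- ifelse(copy, h1,
                 sample(pool$haplotype, n, replace = TRUE, prob = pool$freq))
    a1 <- do.call(rbind, strsplit(h1, ""))
    a2 <- do.call(rbind, strsplit(h2, ""))
    geno_tbl(tibble::tibble(
      s1 = make_geno_factor(a1[, 1], a2[, 1]),
      s2 = make_geno_factor(a1[, 2], a2[, 2])))
  }
  dev_inbred <- abs(het_mid_deviation(textile_layout(inbred_geno(2000, 0.6, 1)), 1))
  null_devs <- vapply(1:15, function(s) {
    gm <- simulate_genotypes(pool, 2000, seed = 1000 + s)
    abs(het_mid_deviation(textile_layout(gm), 1))
  }, 0)
  expect_gt(dev_inbred, max(null_devs))
})

test_that("dispersion profile flags LE-isolated axes and matches block symmetry", {
  # LE-isolated third locus: near-zero dispersion at large n
  pool2 <- hapfreqs_from_ld(0.4, 0.4, 0.9)
  gm <- simulate_genotypes(pool2, 4000, seed = 12)
  set.seed(99)
  extra <- sample(c("CC", "Cc", "cc"), 4000, TRUE, prob = c(0.36, 0.48, 0.16))
  s <- split_geno_strings(extra)
  df <- tibble::as_tibble(gm)
  df$snp3 <- make_geno_factor(s$a1, s$a2)
  fit <- textile_layout(geno_tbl(df))
  d <- dispersion_profile(fit)
  expect_lt(d["snp3"], 0.25)
  expect_gt(min(d[c("snp1", "snp2")]), 0.9)

  # absolute-LD block: equal dispersion across exchangeable axes
  fit_abs <- suppressWarnings(textile_layout(perfect_ld_data()))
  d_abs <- dispersion_profile(fit_abs)
  expect_equal(unname(d_abs[1]), unname(d_abs[2]), tolerance = 1e-8)
})

test_that("layout export records coordinates, levels and the eigenvalue", {
  gm <- simulate_genotypes(hapfreqs_from_ld(0.4, 0.4, 0.8), 30, seed = 4)
  fit <- textile_layout(gm)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_layout(fit, path)
  lines <- readLines(path)
  expect_match(lines[1], "lambda")
  expect_match(lines[2], "objective")
  expect_equal(sum(grepl("^category\t", lines)), nrow(fit$coords))
  expect_equal(sum(grepl("^individual\t", lines)), 30)
})

test_that("tidy, glance and augment expose the fitted quantities", {
  gm <- simulate_genotypes(hapfreqs_from_ld(0.4, 0.4, 0.8), 25, seed = 6)
  fit <- textile_layout(gm)
  td <- tidy(fit)
  expect_true(all(c("axis", "category", "coord", "count", "dispersion")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 25)
  expect_equal(gl$p, 2)
  expect_equal(gl$objective, fit$m * (1 - gl$lambda), tolerance = 1e-8)
  au <- augment(fit)
  expect_equal(nrow(au), 50)
})
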
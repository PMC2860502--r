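# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the layout oracle is a general-purpose
# multi-start numerical optimizer on the raw objective, the EM oracle is a
# closed-form two-locus implementation, and the MCA oracle is the textbook
# correspondence-analysis construction on the indicator matrix.

# ---- brute-force layout oracle --------------------------------------------
# Minimizes the horizontalization objective directly over (scale vectors,
# axis locations, individual levels), with the scale vector rescaled to the
# dispersion constraint, from many random starts.
bf_layout_objective <- function(data, n_starts = 12, seed = 1) {
  enc <- lapply(data, textileplot::encode_axis)
  n <- nrow(data)
  p <- length(enc)
  kdim <- vapply(enc, function(e) ncol(e$contrast), 0L)
  m <- sum(vapply(enc, function(e) sum(e$weight), 0))
  stopifnot(sum(kdim) > 0)

  evalQ <- function(par) {
    u <- par[seq_len(sum(kdim))]
    al <- par[sum(kdim) + seq_len(p)]
    hh <- par[sum(kdim) + p + seq_len(n)]
    off <- cumsum(c(0L, kdim))
    disp <- 0
    yj_list <- vector("list", p)
    for (j in seq_len(p)) {
      e <- enc[[j]]
      gj <- u[(off[j] + 1):off[j + 1]]
      yj <- drop(e$indicator %*% e$contrast %*% gj)
      nj <- sum(e$weight)
      ybar <- sum(e$weight * yj) / nj
      disp <- disp + sum(e$weight * (yj - ybar)^2)
      yj_list[[j]] <- yj
    }
    if (disp <= 1e-12) return(1e9)
    sc <- sqrt(m / disp)
    Q <- 0
    for (j in seq_len(p)) {
      y <- al[j] + sc * yj_list[[j]]
      Q <- Q + sum(enc[[j]]$weight * (y - hh)^2)
    }
    Q
  }

  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- stats::rnorm(sum(kdim) + p + n)
    o <- stats::optim(p0, evalQ, method = "BFGS",
                      control = list(maxit = 3000, reltol = 1e-15))
    o <- stats::optim(o$par, evalQ, method = "BFGS",
                      control = list(maxit = 3000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

# random tiny genotype tibble: every column has >= 2 observed categories and
# every individual >= 2 observed axes
random_tiny_geno <- function(n, p, cmax = 3, miss_prob = 0.1) {
  repeat {
    cols <- lapply(seq_len(p), function(j) {
      cc <- sample(2:cmax, 1)
      x <- sample(letters[seq_len(cc)], n, replace = TRUE)
      x[stats::runif(n) < miss_prob] <- NA
      factor(x)
    })
    names(cols) <- paste0("L", seq_len(p))
    df <- tibble::as_tibble(cols)
    ok_cols <- all(vapply(cols, function(f) length(unique(stats::na.omit(f))) >= 2, TRUE))
    ok_rows <- all(rowSums(!is.na(as.data.frame(cols))) >= 2)
    if (ok_cols && ok_rows) return(df)
  }
}

# ---- independent two-locus EM oracle ---------------------------------------
# Classical EM on the 3x3 genotype count table (rows: AA, Aa, aa; columns:
# BB, Bb, bb); only the double heterozygote is ambiguous.
em2_oracle <- function(tab, tol = 1e-12, max_iter = 100000) {
  n <- sum(tab)
  f <- rep(0.25, 4) # (AB, Ab, aB, ab)
  for (it in seq_len(max_iter)) {
    # expected haplotype counts; double het splits between AB/ab and Ab/aB
    phase_p <- f[1] * f[4] / (f[1] * f[4] + f[2] * f[3])
    if (!is.finite(phase_p)) phase_p <- 0.5
    cAB <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + phase_p * tab[2, 2]
    cAb <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + (1 - phase_p) * tab[2, 2]
    caB <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + (1 - phase_p) * tab[2, 2]
    cab <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + phase_p * tab[2, 2]
    f_new <- c(cAB, cAb, caB, cab) / (2 * n)
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  names(f) <- c("AB", "Ab", "aB", "ab")
  f
}

ld_from_freqs_oracle <- function(f) {
  pA <- f["AB"] + f["Ab"]
  pB <- f["AB"] + f["aB"]
  D <- f["AB"] - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  c(Dprime = unname(abs(D) / Dmax),
    r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))))
}

# 3x3 genotype table (AA, Aa, aa) x (BB, Bb, bb) from a geno_tbl pair,
# counting by major-allele copies
geno_pair_table <- function(gm, a, b) {
  ca <- gm[[a]]; cb <- gm[[b]]
  dose <- function(col) { # copies of the major allele
    al <- attr(col, "alleles")
    vapply(as.character(col), function(s) {
      if (is.na(s)) return(NA_integer_)
      sum(strsplit(s, "")[[1]] == al[1])
    }, 0L)
  }
  da <- factor(dose(ca), levels = 2:0)
  db <- factor(dose(cb), levels = 2:0)
  table(da, db) # rows AA, Aa, aa; cols BB, Bb, bb
}

# ---- textbook MCA / correspondence analysis oracle ------------------------
# First-dimension standard column coordinates of the CA of the stacked
# indicator matrix (complete data).
mca_category_scores <- function(data) {
  enc <- lapply(data, textileplot::encode_axis)
  X <- do.call(cbind, lapply(enc, `[[`, "indicator"))
  P <- X / sum(X)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  sv$v[, 1] / sqrt(cm)
}

# minor-allele dosage matrix for diallelic SNP columns
dosage_matrix <- function(gm) {
  loci <- textileplot::axis_meta(gm)$locus
  vapply(loci, function(l) {
    col <- gm[[l]]
    al <- attr(col, "alleles")
    lab <- as.character(col)
    vapply(lab, function(s) {
      if (is.na(s)) return(NA_real_)
      sum(strsplit(s, "")[[1]] == al[2])
    }, 0)
  }, numeric(nrow(gm)))
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
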
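#' Genotype tables
#'
#' A `geno_tbl` is a tibble with one row per individual and one column per
#' axis (SNP or phenotype), plus a `sample_id` column. SNP and categorical
#' phenotype columns are factors whose levels are the ordered genotype
#' categories; quantitative phenotype columns are plain doubles. Per-axis
#' metadata (chromosome, physical position, axis kind, allele labels) is kept
#' in the `axis_meta` attribute, a tibble with one row per axis column.
#'
#' Genotype categories are ordered by descending sample frequency of their
#' constituent alleles (so a biallelic SNP orders as major homozygote,
#' heterozygote, minor homozygote), ties broken lexicographically. SNP
#' columns are ordered by physical position within chromosome; phenotype
#' columns are kept leftmost.
#'
#' @param genotypes A data frame of axis columns (factor or numeric), with an
#'   optional `sample_id` character column.
#' @param meta Optional tibble with columns `locus`, and optionally `chrom`,
#'   `pos`, `kind` (one of `"snp"`, `"categorical_phenotype"`,
#'   `"quantitative_phenotype"`) and `alleles` (list of character vectors).
#'   Missing columns are filled with defaults.
#' @return A `geno_tbl`.
#' @export
geno_tbl <- function(genotypes, meta = NULL) {
  genotypes <- tibble::as_tibble(genotypes)
  if (!"sample_id" %in% names(genotypes)) {
    genotypes <- dplyr::mutate(genotypes,
      sample_id = paste0("ind", seq_len(nrow(genotypes))), .before = 1)
  }
  if (anyDuplicated(genotypes$sample_id)) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  loci <- setdiff(names(genotypes), "sample_id")
  if (anyDuplicated(loci)) stop("duplicate locus identifiers", call. = FALSE)

  if (is.null(meta)) meta <- tibble::tibble(locus = loci)
  meta <- tibble::as_tibble(meta)
  stopifnot(all(loci %in% meta$locus))
  meta <- meta[match(loci, meta$locus), , drop = FALSE]
  if (!"chrom" %in% names(meta)) meta$chrom <- NA_character_
  if (!"pos" %in% names(meta)) meta$pos <- NA_integer_
  if (!"kind" %in% names(meta)) {
    meta$kind <- ifelse(vapply(genotypes[loci], is.numeric, logical(1)),
                        "quantitative_phenotype", "snp")
  }
  if (!"alleles" %in% names(meta)) {
    meta$alleles <- unname(purrr::map2(
      genotypes[loci], meta$kind,
      function(col, kind) {
        if (kind == "snp" && is.factor(col)) attr(col, "alleles") else NULL
      }))
  }
  bad <- !meta$kind %in%
    c("snp", "categorical_phenotype", "quantitative_phenotype")
  if (any(bad)) stop("unknown axis kind: ", meta$kind[bad][1], call. = FALSE)
  if (any(!is.na(meta$pos) & meta$pos < 0)) {
    stop("physical positions must be non-negative", call. = FALSE)
  }

  # phenotypes leftmost, SNPs by (chrom, pos); stable for ties/missing pos
  is_snp <- meta$kind == "snp"
  snp_ord <- order(meta$chrom[is_snp], meta$pos[is_snp], na.last = TRUE)
  new_order <- c(meta$locus[!is_snp], meta$locus[is_snp][snp_ord])
  meta <- meta[match(new_order, meta$locus), , drop = FALSE]
  genotypes <- genotypes[, c("sample_id", new_order), drop = FALSE]

  structure(genotypes,
            axis_meta = meta,
            class = c("geno_tbl", class(tibble::tibble())))
}

#' @export
print.geno_tbl <- function(x, ...) {
  meta <- axis_meta(x)
  cat(sprintf("# geno_tbl: %d individuals x %d axes (%d SNP, %d phenotype)\n",
              nrow(x), nrow(meta), sum(meta$kind == "snp"),
              sum(meta$kind != "snp")))
  NextMethod()
}

#' Per-axis metadata of a genotype table
#'
#' @param gm A `geno_tbl`.
#' @return A tibble with one row per axis: `locus`, `chrom`, `pos`, `kind`,
#'   `alleles`.
#' @export
axis_meta <- function(gm) {
  m <- attr(gm, "axis_meta")
  if (is.null(m)) stop("not a geno_tbl (no axis_meta attribute)", call. = FALSE)
  m
}

axis_names <- function(gm) axis_meta(gm)$locus

#' True haplotype draws retained by the simulator, if any
#' @param gm A `geno_tbl` produced by [simulate_genotypes()].
#' @return A tibble (`sample_id`, `hap1`, `hap2`) or `NULL`.
#' @export
sim_truth <- function(gm) attr(gm, "truth")

# -- genotype string handling ------------------------------------------------

MISSING_TOKENS <- c("", ".", "..", "./.", ".|.", "NN", "00", "0/0?", NA)

# split genotype strings into two alleles; returns list(a1, a2) with NA pairs
# for missing or half-missing calls
split_geno_strings <- function(x) {
  x <- as.character(x)
  a1 <- a2 <- rep(NA_character_, length(x))
  has_sep <- grepl("[/|]", x)
  parts <- strsplit(x[has_sep], "[/|]")
  np <- lengths(parts)
  if (any(np != 2 & !is.na(x[has_sep]))) {
    stop("non-diploid genotype call: ", x[has_sep][np != 2][1], call. = FALSE)
  }
  a1[has_sep] <- vapply(parts, `[`, "", 1)
  a2[has_sep] <- vapply(parts, `[`, "", 2)
  plain <- !has_sep & !is.na(x) & !x %in% c("", ".", "NA")
  if (any(nchar(x[plain]) != 2)) {
    stop("cannot parse genotype string: ", x[plain][nchar(x[plain]) != 2][1],
         call. = FALSE)
  }
  a1[plain] <- substr(x[plain], 1, 1)
  a2[plain] <- substr(x[plain], 2, 2)
  miss <- is.na(a1) | is.na(a2) | a1 %in% c(".", "") | a2 %in% c(".", "")
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_
  list(a1 = a1, a2 = a2)
}

# order alleles by descending sample frequency, ties lexicographic
rank_alleles <- function(a1, a2) {
  tab <- table(c(a1, a2), useNA = "no")
  alleles <- names(tab)
  alleles[order(-as.numeric(tab), alleles, method = "radix")]
}

# build the category factor for one locus from two allele vectors
make_geno_factor <- function(a1, a2, alleles = NULL) {
  if (is.null(alleles)) alleles <- rank_alleles(a1, a2)
  rk <- stats::setNames(seq_along(alleles), alleles)
  obs <- !is.na(a1)
  sep <- if (any(nchar(alleles) > 1)) "/" else ""
  lab <- rep(NA_character_, length(a1))
  swap <- obs & rk[a2] < rk[a1]
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  lab[obs] <- paste(a1[obs], a2[obs], sep = sep)
  # category score: summed sample allele frequencies, descending
  freq <- as.numeric(table(factor(c(a1[obs], a2[obs]), levels = alleles)))
  freq <- freq / sum(freq)
  cats <- unique(lab[obs])
  cat_all <- strsplit(cats, if (sep == "") "" else sep, fixed = sep != "")
  score <- vapply(cat_all, function(p) sum(freq[match(p, alleles)]), 0)
  lev <- cats[order(-score, cats, method = "radix")]
  f <- factor(lab, levels = lev)
  attr(f, "alleles") <- alleles
  f
}

# -- readers -----------------------------------------------------------------

#' Read a genotype matrix
#'
#' Reads unphased diploid genotypes from VCF 4.x (GT field), a PLINK
#' .ped/.map pair, or plain TSV (rows = individuals, columns = loci, header
#' with locus IDs, optional `#pos`/`#chrom`/`#kind` comment lines as written
#' by [write_genotypes()]). Phased separators are treated as unphased and
#' half-missing calls as fully missing.
#'
#' @param path Path to the file (for PLINK, the `.ped` file or basename).
#' @param format One of `"tsv"`, `"vcf"`, `"plink"`.
#' @return A [geno_tbl()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink")) {
  format <- match.arg(format)
  switch(format,
         tsv = read_genotypes_tsv(path),
         vcf = read_genotypes_vcf(path),
         plink = read_genotypes_plink(path))
}

read_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  meta_lines <- grep("^#", lines)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-c(1, meta_lines)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  mat <- do.call(rbind, cells)
  has_id <- hdr[1] %in% c("sample_id", "id", "sample")
  if (has_id) {
    ids <- mat[, 1]; mat <- mat[, -1, drop = FALSE]; loci <- hdr[-1]
  } else {
    ids <- paste0("ind", seq_len(nrow(mat))); loci <- hdr
  }
  colnames(mat) <- loci

  get_meta_line <- function(tag) {
    i <- grep(paste0("^#", tag, "\t"), lines)
    if (!length(i)) return(NULL)
    strsplit(lines[i[1]], "\t", fixed = TRUE)[[1]][-1]
  }
  pos <- get_meta_line("pos")
  chrom <- get_meta_line("chrom")
  kind <- get_meta_line("kind")
  if (!is.null(pos)) pos[pos == "."] <- NA
  if (!is.null(chrom)) chrom[chrom == "."] <- NA
  if (is.null(kind)) {
    looks_num <- apply(mat, 2, function(col) {
      col <- col[!col %in% MISSING_TOKENS & !is.na(col)]
      length(col) > 0 && !anyNA(suppressWarnings(as.numeric(col)))
    })
    kind <- ifelse(looks_num, "quantitative_phenotype", "snp")
  }

  cols <- purrr::map(seq_along(loci), function(j) {
    raw <- mat[, j]
    if (kind[j] == "quantitative_phenotype") {
      raw[raw %in% c(".", "")] <- NA
      as.numeric(raw)
    } else if (kind[j] == "categorical_phenotype") {
      raw[raw %in% c(".", "")] <- NA
      make_pheno_factor(raw)
    } else {
      al <- split_geno_strings(raw)
      make_geno_factor(al$a1, al$a2)
    }
  })
  names(cols) <- loci
  meta <- tibble::tibble(
    locus = loci,
    chrom = if (is.null(chrom)) NA_character_ else chrom,
    pos = if (is.null(pos)) NA_integer_ else as.integer(pos),
    kind = kind)
  geno_tbl(tibble::tibble(sample_id = ids, !!!cols), meta)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF files", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicate locus identifiers in VCF",
                               call. = FALSE)
  samples <- colnames(gt)
  cols <- purrr::map(seq_len(nrow(gt)), function(i) {
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1]])
    g <- split_geno_strings(gt[i, ])
    idx1 <- suppressWarnings(as.integer(g$a1)) + 1L
    idx2 <- suppressWarnings(as.integer(g$a2)) + 1L
    if (any(!is.na(g$a1) & is.na(idx1))) {
      stop("unparseable GT at ", ids[i], call. = FALSE)
    }
    make_geno_factor(alleles[idx1], alleles[idx2])
  })
  names(cols) <- ids
  meta <- tibble::tibble(locus = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]), kind = "snp")
  geno_tbl(tibble::tibble(sample_id = samples, !!!cols), meta)
}

read_genotypes_plink <- function(path) {
  base <- sub("\\.ped$", "", path)
  ped_path <- paste0(base, ".ped")
  map_path <- paste0(base, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path)) {
    stop("need both ", ped_path, " and ", map_path, call. = FALSE)
  }
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  colnames(map)[1:4] <- c("chrom", "locus", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6 + 2 * p) {
    stop("ped/map column mismatch: expected ", 6 + 2 * p, " columns",
         call. = FALSE)
  }
  ids <- ped[, 2]
  cols <- purrr::map(seq_len(p), function(j) {
    a1 <- ped[, 5 + 2 * j]
    a2 <- ped[, 6 + 2 * j]
    a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA; a2[miss] <- NA
    make_geno_factor(a1, a2)
  })
  names(cols) <- map$locus
  meta <- tibble::tibble(locus = map$locus, chrom = map$chrom,
                         pos = as.integer(map$pos), kind = "snp")
  geno_tbl(tibble::tibble(sample_id = ids, !!!cols), meta)
}

#' Write a genotype table as canonical TSV
#'
#' The dump round-trips through [read_genotypes()] exactly: it records
#' positions, chromosomes and axis kinds as `#`-prefixed comment lines.
#'
#' @param gm A `geno_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  meta <- axis_meta(gm)
  loci <- meta$locus
  hdr <- paste(c("sample_id", loci), collapse = "\t")
  lines <- c(hdr,
             paste(c("#chrom", ifelse(is.na(meta$chrom), ".", meta$chrom)),
                   collapse = "\t"),
             paste(c("#pos", ifelse(is.na(meta$pos), ".", meta$pos)),
                   collapse = "\t"),
             paste(c("#kind", meta$kind), collapse = "\t"))
  cells <- vapply(loci, function(l) {
    col <- gm[[l]]
    out <- if (is.numeric(col)) format(col, trim = TRUE, digits = 15)
           else as.character(col)
    out[is.na(col)] <- "."
    out
  }, character(nrow(gm)))
  cells <- matrix(cells, nrow = nrow(gm))
  body <- apply(cbind(gm$sample_id, cells), 1, paste, collapse = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

# -- phenotypes --------------------------------------------------------------

make_pheno_factor <- function(values) {
  tab <- table(values, useNA = "no")
  lev <- names(tab)[order(-as.numeric(tab), names(tab), method = "radix")]
  factor(as.character(values), levels = lev)
}

#' Attach a phenotype axis
#'
#' Appends a phenotype as a leftmost axis. A categorical phenotype is encoded
#' exactly like a genotype axis (one category per label); a quantitative
#' phenotype enters as a raw data vector that the layout solver mean-centers
#' and standardizes.
#'
#' @param gm A `geno_tbl`.
#' @param values One value (or `NA`) per individual.
#' @param kind `"categorical"` or `"quantitative"`.
#' @param name Axis name.
#' @return A `geno_tbl` with the phenotype axis added.
#' @export
attach_phenotype <- function(gm, values,
                             kind = c("categorical", "quantitative"),
                             name = "phenotype") {
  kind <- match.arg(kind)
  if (length(values) != nrow(gm)) {
    stop("phenotype length ", length(values), " != ", nrow(gm),
         " individuals", call. = FALSE)
  }
  meta <- axis_meta(gm)
  if (kind == "categorical") {
    col <- make_pheno_factor(values)
    if (nlevels(col) == 1) {
      warning("constant phenotype: degenerate axis with a single category",
              call. = FALSE)
    }
    kind_full <- "categorical_phenotype"
  } else {
    col <- as.numeric(values)
    kind_full <- "quantitative_phenotype"
  }
  df <- tibble::as_tibble(gm)
  df[[name]] <- col
  meta2 <- dplyr::bind_rows(
    meta,
    tibble::tibble(locus = name, chrom = NA_character_, pos = NA_integer_,
                   kind = kind_full, alleles = list(NULL)))
  geno_tbl(df, meta2)
}

# -- encoding ----------------------------------------------------------------

#' Encode one axis as indicator, contrast and weight
#'
#' For a categorical axis, row i of the indicator is the unit vector of the
#' observed category (all zeros when missing), the contrast is a c x (c-1)
#' Helmert basis (columns linearly independent of the ones vector), and the
#' weight vector is 0 exactly where the entry is missing. For a quantitative
#' axis the raw values are carried through (the solver centers and scales
#' them).
#'
#' @param column One column of a `geno_tbl` (factor or numeric).
#' @param contrast_fun Function `c -> c x (c-1)` contrast matrix; default
#'   [stats::contr.helmert()]. Any full-rank basis independent of the ones
#'   vector yields identical layout coordinates.
#' @return An `axis_encoding`: list with `indicator`, `contrast`, `weight`,
#'   `labels` (and `raw` for quantitative axes).
#' @export
encode_axis <- function(column, contrast_fun = stats::contr.helmert) {
  n <- length(column)
  w <- as.numeric(!is.na(column))
  if (is.numeric(column)) {
    return(structure(list(indicator = NULL, contrast = NULL, weight = w,
                          labels = NULL, raw = as.numeric(column),
                          quantitative = TRUE),
                     class = "axis_encoding"))
  }
  column <- as.factor(column)
  cc <- nlevels(column)
  X <- matrix(0, n, cc, dimnames = list(NULL, levels(column)))
  code <- as.integer(column)
  obs <- !is.na(code)
  X[cbind(which(obs), code[obs])] <- 1
  B <- if (cc >= 2) {
    b <- contrast_fun(cc)
    stopifnot(nrow(b) == cc, ncol(b) == cc - 1,
              qr(cbind(1, b))$rank == cc)
    unname(b)
  } else {
    matrix(numeric(0), 1, 0)
  }
  structure(list(indicator = X, contrast = B, weight = w,
                 labels = levels(column), raw = NULL, quantitative = FALSE),
            class = "axis_encoding")
}
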
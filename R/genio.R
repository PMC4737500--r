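#' Genotype matrix container
#'
#' Holds allele dosages for a set of individuals at a set of autosomal SNPs,
#' oriented so that the counted allele is always the minor allele.  Dosage
#' `x` counts copies of the minor allele (0, 1, 2 or `NA`); `allele_freq`
#' stores the minor-allele frequency `p` computed from the non-missing
#' dosages, so `p` always lies in `[0, 0.5]`.
#'
#' @param dosage integer matrix, individuals in rows, SNPs in columns;
#'   entries 0/1/2 or `NA`.  Row names are sample ids, column names SNP ids
#'   (generated when absent).
#' @param chrom integer vector of chromosome codes (1--22), one per SNP.
#' @param pos optional base-pair positions (defaults to column index).
#' @param a1,a2 optional allele labels for the counted (minor) and other
#'   allele; defaults "A"/"B".  Columns whose counted-allele frequency
#'   exceeds 0.5 are flipped (dosage mirrored, labels swapped) so the stored
#'   orientation is minor; exact ties at 0.5 keep the incoming orientation.
#' @return an object of class `genotype_matrix` with fields `dosage`,
#'   `chrom`, `pos`, `a1`, `a2`, `allele_freq`, `sample_ids`, `snp_ids`.
#' @export
genotype_matrix <- function(dosage, chrom, pos = NULL, a1 = NULL, a2 = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  m <- ncol(dosage)
  if (length(chrom) != m) stop("chrom must have one entry per SNP")
  chrom <- as.integer(chrom)
  if (any(is.na(chrom)) || any(chrom < 1L) || any(chrom > 22L))
    stop("chromosomes restricted to autosomes 1-22")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("id", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("snp", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("B", m)

  p <- .col_freq(dosage)
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2L - dosage[, flip]
    tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
    p[flip] <- 1 - p[flip]
  }
  structure(
    list(dosage = dosage, chrom = chrom, pos = as.integer(pos),
         a1 = as.character(a1), a2 = as.character(a2), allele_freq = p,
         sample_ids = rownames(dosage), snp_ids = colnames(dosage)),
    class = "genotype_matrix")
}

# counted-allele frequency per column, missing excluded
.col_freq <- function(dosage) {
  colMeans(dosage, na.rm = TRUE) / 2
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (chr %d-%d)\n",
              nrow(x$dosage), ncol(x$dosage), min(x$chrom), max(x$chrom)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (ids, logical or integer); missing keeps all.
#' @param j SNP index; missing keeps all.
#' @param ... ignored.
#' @return a `genotype_matrix`; allele frequencies are recomputed in the
#'   subset, so orientation may flip relative to `x`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$snp_ids)
  jj <- seq_len(ncol(x$dosage))[j]
  genotype_matrix(x$dosage[i, j, drop = FALSE], x$chrom[jj], x$pos[jj],
                 x$a1[jj], x$a2[jj])
}

#' Pedigree container
#'
#' @param df data frame with columns `id`, `father`, `mother`, `sex`,
#'   `family`.  Unknown parents are `NA` or `"0"`.
#' @return object of class `pedigree_table`.
#' @export
pedigree_table <- function(df) {
  need <- c("id", "father", "mother", "sex", "family")
  if (!all(need %in% names(df))) stop("pedigree needs columns ", paste(need, collapse = ", "))
  df <- df[, need]
  for (cc in c("id", "father", "mother", "family"))
    df[[cc]] <- as.character(df[[cc]])
  df$father[df$father %in% c("0", "")] <- NA_character_
  df$mother[df$mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$id)) stop("duplicate individual ids in pedigree")
  .check_acyclic(df)
  structure(list(records = df), class = "pedigree_table")
}

.check_acyclic <- function(df) {
  # depth-first ancestor walk; a cycle means someone is its own ancestor
  fa <- match(df$father, df$id)
  mo <- match(df$mother, df$id)
  depth <- rep(NA_integer_, nrow(df))
  get_depth <- function(i, seen) {
    if (i %in% seen) stop("pedigree cycle: individual is its own ancestor")
    if (!is.na(depth[i])) return(depth[i])
    d <- 0L
    for (p in c(fa[i], mo[i])) if (!is.na(p))
      d <- max(d, get_depth(p, c(seen, i)) + 1L)
    depth[i] <<- d
    d
  }
  for (i in seq_len(nrow(df))) get_depth(i, integer(0))
  invisible(depth)
}

#' @export
print.pedigree_table <- function(x, ...) {
  p <- pedigree_pairs(x)
  cat(sprintf("pedigree_table: %d individuals; %d parent-offspring, %d full-sib, %d couple pairs\n",
              nrow(x$records), nrow(p$parent_offspring), nrow(p$full_sibs),
              nrow(p$couples)))
  invisible(x)
}

#' Derive relationship pair sets from a pedigree
#'
#' Couples are pairs with at least one offspring in the table; full sibs
#' share both (known) parents; parent-offspring pairs require the parent to
#' be present in the table.
#'
#' @param ped a [pedigree_table()].
#' @return list of three two-column character matrices
#'   (`parent_offspring`, `full_sibs`, `couples`), each row an unordered
#'   pair of ids present in the pedigree.
#' @export
pedigree_pairs <- function(ped) {
  df <- ped$records
  ids <- df$id
  po <- rbind(
    cbind(df$father, df$id)[!is.na(df$father) & df$father %in% ids, , drop = FALSE],
    cbind(df$mother, df$id)[!is.na(df$mother) & df$mother %in% ids, , drop = FALSE])
  # full sibs: same known father AND same known mother
  key <- ifelse(is.na(df$father) | is.na(df$mother), NA,
                paste(df$father, df$mother, sep = "\r"))
  sib <- .pairs_within_groups(df$id, key)
  # couples: distinct (father, mother) combinations with both present
  cp <- unique(df[!is.na(df$father) & !is.na(df$mother), c("father", "mother")])
  cp <- as.matrix(cp[cp$father %in% ids & cp$mother %in% ids, , drop = FALSE])
  dimnames(cp) <- NULL
  if (length(cp) == 0) cp <- matrix(character(0), 0, 2)
  list(parent_offspring = unname(po), full_sibs = sib, couples = cp)
}

.pairs_within_groups <- function(ids, key) {
  out <- matrix(character(0), 0, 2)
  for (g in split(ids, key)) {
    if (length(g) < 2) next
    cmb <- t(utils::combn(g, 2))
    out <- rbind(out, cmb)
  }
  unname(out)
}

# ---------------------------------------------------------------------------
# PLINK v1 binary (.bed/.bim/.fam)

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
# 2-bit codes, SNP-major: 00 hom A1 (dosage 2), 01 missing, 10 het, 11 hom A2
.BED_DECODE <- c(2L, NA_integer_, 1L, 0L)

#' Read a PLINK v1 binary fileset
#'
#' Decodes the SNP-major 2-bit `.bed` encoding, orients every SNP to its
#' minor allele (frequency from the loaded samples; ties keep file order),
#' and returns the `.fam` parental columns as a pedigree stub.
#'
#' @param prefix path prefix, or explicit `bed`/`bim`/`fam` paths.
#' @param bed,bim,fam optional explicit file paths overriding `prefix`.
#' @return list with elements `geno` ([genotype_matrix()]) and `ped`
#'   ([pedigree_table()] built from the .fam columns).
#' @export
read_plink <- function(prefix, bed = NULL, bim = NULL, fam = NULL) {
  if (is.null(bed)) bed <- paste0(prefix, ".bed")
  if (is.null(bim)) bim <- paste0(prefix, ".bim")
  if (is.null(fam)) fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)

  bimdf <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "snp", "cm", "pos", "a1", "a2"))
  famdf <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("family", "id", "father", "mother", "sex", "pheno"))
  n <- nrow(famdf); m <- nrow(bimdf)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .BED_MAGIC))
    stop("not a PLINK v1 .bed file (magic bytes mismatch)")
  bpf <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpf * m)
    stop(sprintf(".bed truncated or inconsistent: %d bytes for %d SNPs x %d samples",
                 length(body), m, n))
  # lookup table: 256 byte values -> 4 dosages
  b <- as.integer(body)
  codes <- rbind(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
                 bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L))
  dos <- matrix(.BED_DECODE[codes + 1L], nrow = 4L * bpf)[seq_len(n), , drop = FALSE]
  rownames(dos) <- famdf$id
  colnames(dos) <- bimdf$snp
  geno <- genotype_matrix(dos, bimdf$chrom, bimdf$pos, bimdf$a1, bimdf$a2)
  ped <- pedigree_table(data.frame(id = famdf$id, father = famdf$father,
    mother = famdf$mother, sex = famdf$sex, family = famdf$family,
    stringsAsFactors = FALSE))
  list(geno = geno, ped = ped)
}

#' Write a PLINK v1 binary fileset
#'
#' @param geno a [genotype_matrix()]; the counted (minor) allele is written
#'   as A1.
#' @param prefix output path prefix (`.bed`, `.bim`, `.fam` are appended).
#' @param ped optional [pedigree_table()] supplying .fam parental columns;
#'   default writes unknown parents.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, ped = NULL) {
  dos <- geno$dosage
  n <- nrow(dos); m <- ncol(dos)
  bimdf <- data.frame(chrom = geno$chrom, snp = geno$snp_ids, cm = 0,
                      pos = geno$pos, a1 = geno$a1, a2 = geno$a2)
  utils::write.table(bimdf, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  if (is.null(ped)) {
    famdf <- data.frame(family = geno$sample_ids, id = geno$sample_ids,
                        father = "0", mother = "0", sex = 0, pheno = -9)
  } else {
    rec <- ped$records[match(geno$sample_ids, ped$records$id), ]
    famdf <- data.frame(family = rec$family, id = geno$sample_ids,
                        father = ifelse(is.na(rec$father), "0", rec$father),
                        mother = ifelse(is.na(rec$mother), "0", rec$mother),
                        sex = rec$sex, pheno = -9)
  }
  utils::write.table(famdf, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  # encode: dosage 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11; pad with 00
  enc <- c(3L, 2L, 0L)  # index by dosage + 1
  bpf <- ceiling(n / 4)
  codes <- matrix(0L, 4L * bpf, m)
  d <- dos
  cd <- ifelse(is.na(d), 1L, enc[d + 1L])
  codes[seq_len(n), ] <- cd
  bytes <- codes[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
    bitwShiftL(codes[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE], 2L) +
    bitwShiftL(codes[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE], 4L) +
    bitwShiftL(codes[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read / write a 5-column pedigree text file
#'
#' Whitespace-separated columns: id, father, mother, sex, family; "0" or
#' "NA" mark unknown parents.
#'
#' @param path file path.
#' @return [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("id", "father", "mother", "sex", "family"),
    na.strings = c("NA", "0"))
  pedigree_table(df)
}

#' @rdname read_pedigree
#' @param ped a [pedigree_table()].
#' @export
write_pedigree <- function(ped, path) {
  df <- ped$records
  df$father[is.na(df$father)] <- "0"
  df$mother[is.na(df$mother)] <- "0"
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read / write a phenotype/covariate table
#'
#' Header-bearing TSV with an `id` column; "NA" marks missing values.
#'
#' @param path file path.
#' @return data frame with character `id` and the remaining columns as read.
#' @export
read_pheno <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (!"id" %in% names(df)) stop("phenotype table needs an 'id' column")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate ids in phenotype table")
  df
}

#' @rdname read_pheno
#' @param df data frame with an `id` column.
#' @export
write_pheno <- function(df, path) {
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Quality control

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on allele counts: the p-value sums the
#' probabilities of all heterozygote counts at most as probable as the one
#' observed (Wigginton-style, PLINK's default flavour).
#'
#' @param n_het observed heterozygotes.
#' @param n_hom_rare observed rare-allele homozygotes.
#' @param n_hom_common observed common-allele homozygotes.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  if (n == 0) return(1)
  nr <- 2L * n_hom_rare + n_het   # rare allele copies
  if (nr > n) { nr <- 2L * n - nr }  # ensure rare orientation
  # heterozygote counts share nr's parity
  hets <- seq(nr %% 2L, min(nr, 2L * n - nr), by = 2L)
  # log P(het) up to a constant: n! / (h! nr_hom! nc_hom!) * 2^h
  lp <- vapply(hets, function(h) {
    hr <- (nr - h) / 2; hc <- n - h - hr
    h * log(2) - lfactorial(h) - lfactorial(hr) - lfactorial(hc)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' SNP- and individual-level quality control
#'
#' Applies, in order: minor-allele-frequency filter, exact HWE filter,
#' per-SNP missingness filter, then per-individual missingness.  Allele
#' frequencies are recomputed after individual removal (the constructor
#' re-orients to the minor allele).
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min exclude SNPs with MAF `< maf_min` (default 0.05).
#' @param hwe_alpha exclude SNPs with exact HWE p `< hwe_alpha`
#'   (default 1e-6).
#' @param snp_miss_max exclude SNPs with missingness `> snp_miss_max`
#'   (default 0.02).
#' @param ind_miss_max exclude individuals with missingness `> ind_miss_max`
#'   over the retained SNPs (default 0.05).
#' @param founders_only optional character vector of founder ids; when
#'   given, HWE is tested in those samples only.
#' @return filtered `genotype_matrix` with an attribute `qc_report`
#'   (named counts removed per criterion).
#' @export
qc_filter <- function(geno, maf_min = 0.05, hwe_alpha = 1e-6,
                      snp_miss_max = 0.02, ind_miss_max = 0.05,
                      founders_only = NULL) {
  stopifnot(maf_min > 0, maf_min < 1, hwe_alpha > 0, hwe_alpha < 1,
            snp_miss_max > 0, snp_miss_max < 1, ind_miss_max > 0,
            ind_miss_max < 1)
  dos <- geno$dosage
  p <- geno$allele_freq
  keep_maf <- !is.na(p) & p >= maf_min

  hwe_dos <- if (is.null(founders_only)) dos else
    dos[rownames(dos) %in% founders_only, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    x <- hwe_dos[, j]; x <- x[!is.na(x)]
    hwe_exact_test(sum(x == 1L), sum(x == 2L), sum(x == 0L))
  }, numeric(1))
  keep_hwe <- hwe_p >= hwe_alpha

  snp_miss <- colMeans(is.na(dos))
  keep_miss <- snp_miss <= snp_miss_max

  keep_snp <- keep_maf & keep_hwe & keep_miss
  if (!any(keep_snp)) stop("all SNPs removed by QC")
  dos2 <- dos[, keep_snp, drop = FALSE]
  ind_miss <- rowMeans(is.na(dos2))
  keep_ind <- ind_miss <= ind_miss_max

  out <- geno[keep_ind, keep_snp]
  attr(out, "qc_report") <- c(
    snp_maf = sum(!keep_maf), snp_hwe = sum(keep_maf & !keep_hwe),
    snp_missing = sum(keep_maf & keep_hwe & !keep_miss),
    ind_missing = sum(!keep_ind))
  out
}

#' Outlier-mask a trait after covariate adjustment
#'
#' Optionally log-transforms the trait, adjusts it for sex, age and age^2 by
#' least squares (using whichever of those covariates are present), and sets
#' observations whose adjusted residual lies beyond `sd_limit` standard
#' deviations of the residual distribution to missing.
#'
#' @param pheno data frame with `id`, the trait column, and optionally
#'   `sex`/`age`.
#' @param trait name of the trait column.
#' @param transform `"identity"` or `"log"` (natural log, applied before
#'   adjustment; non-positive values are an error).
#' @param sd_limit outlier threshold in residual standard deviations
#'   (default 4).
#' @return the phenotype table with the trait column transformed and
#'   outliers set to `NA`; attribute `n_masked` counts masked values.
#' @export
preprocess_trait <- function(pheno, trait, transform = c("identity", "log"),
                             sd_limit = 4) {
  transform <- match.arg(transform)
  y <- pheno[[trait]]
  if (is.null(y)) stop("no column '", trait, "' in phenotype table")
  if (transform == "log") {
    if (any(y <= 0, na.rm = TRUE))
      stop("log transform requested but trait has non-positive values")
    y <- log(y)
  }
  dat <- data.frame(y = y)
  form <- "y ~ 1"
  if ("sex" %in% names(pheno)) { dat$sex <- factor(pheno$sex); form <- paste(form, "+ sex") }
  if ("age" %in% names(pheno)) {
    dat$age <- pheno$age
    form <- paste(form, "+ age + I(age^2)")
  }
  ok <- stats::complete.cases(dat)
  fit <- stats::lm(stats::as.formula(form), data = dat[ok, , drop = FALSE])
  res <- rep(NA_real_, length(y))
  res[ok] <- stats::resid(fit)
  s <- stats::sd(res, na.rm = TRUE)
  if (!is.finite(s) || s <= 1e-10 * max(mean(abs(y), na.rm = TRUE), 1e-30))
    stop("degenerate trait: zero residual variance")
  mask <- !is.na(res) & abs(res) > sd_limit * s
  y[mask] <- NA_real_
  pheno[[trait]] <- y
  attr(pheno, "n_masked") <- sum(mask)
  pheno
}
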
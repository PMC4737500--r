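#' Relationship matrix container
#'
#' A symmetric n x n matrix of relatedness (or shared-environment indicator)
#' values with individual ids and a kind tag.
#'
#' @param values symmetric numeric matrix; dimnames supply ids when `ids`
#'   is not given.
#' @param kind one of `"GRM_g"`, `"GRM_kin"`, `"ERM_Family"`, `"ERM_Sib"`,
#'   `"ERM_Couple"`, `"Identity"`.
#' @param ids character vector of individual ids.
#' @return object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values, kind, ids = NULL) {
  kinds <- c("GRM_g", "GRM_kin", "ERM_Family", "ERM_Sib", "ERM_Couple",
             "Identity")
  kind <- match.arg(kind, kinds)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-12)
    stop("relationship matrix must be symmetric to 1e-12")
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, kind = kind),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("%s relationship matrix, n = %d; %d nonzero off-diagonal pairs\n",
              x$kind, length(x$ids), sum(off != 0)))
  invisible(x)
}

#' @export
dim.relationship_matrix <- function(x) dim(x$values)

#' Genomic relationship matrix from SNP dosages
#'
#' Off-diagonal entries average, over the SNPs non-missing in both
#' individuals, `(x_j - 2p)(x_k - 2p) / (2p(1-p))`; diagonal entries are
#' `1 + mean((x^2 - (1+2p)x + 2p^2) / (2p(1-p)))` over the SNPs non-missing
#' in that individual, i.e. one plus the estimated inbreeding coefficient.
#' `p` is the stored minor-allele frequency.
#'
#' @param geno a [genotype_matrix()].
#' @param chrom_subset optional chromosome codes; only SNPs on these
#'   chromosomes enter the GRM (e.g. even chromosomes only).
#' @return a [relationship_matrix()] of kind `"GRM_g"`.
#' @export
compute_grm <- function(geno, chrom_subset = NULL) {
  keep <- if (is.null(chrom_subset)) seq_along(geno$chrom) else
    which(geno$chrom %in% chrom_subset)
  if (!length(keep)) stop("no SNPs in requested chromosome subset")
  x <- geno$dosage[, keep, drop = FALSE]
  p <- geno$allele_freq[keep]
  if (any(p <= 0 | p >= 1)) stop("monomorphic SNP present; run QC first")
  n <- nrow(x)
  denom <- 2 * p * (1 - p)
  miss <- is.na(x)
  W <- sweep(x, 2, 2 * p, "-") / rep(sqrt(denom), each = n)
  W[miss] <- 0
  M <- 1 - miss
  num <- tcrossprod(W)
  cnt <- tcrossprod(M)
  if (any(cnt[upper.tri(cnt)] == 0))
    stop("a pair of individuals shares no non-missing SNPs")
  G <- num / cnt
  # diagonal: inbreeding form
  Q <- (x * x - sweep(x, 2, 1 + 2 * p, "*") + rep(2 * p^2, each = n)) /
    rep(denom, each = n)
  Q[miss] <- 0
  diag(G) <- 1 + rowSums(Q) / rowSums(M)
  relationship_matrix(G, "GRM_g", geno$sample_ids)
}

#' Threshold a GRM to its close-relative entries
#'
#' Off-diagonal entries strictly smaller than `t` are set to zero; entries
#' equal to or above `t` (and the diagonal) are kept as they are.
#'
#' @param grm a [relationship_matrix()] of kind `"GRM_g"`.
#' @param t threshold (default 0.025).
#' @return a [relationship_matrix()] of kind `"GRM_kin"`.
#' @export
threshold_grm <- function(grm, t = 0.025) {
  v <- grm$values
  d <- diag(v)
  v[v < t] <- 0
  diag(v) <- d
  relationship_matrix(v, "GRM_kin", grm$ids)
}

#' Environmental relationship matrices
#'
#' 0/1 indicator matrices of shared-environment membership with unit
#' diagonal: `couple` marks pairs with at least one common offspring in the
#' pedigree, `sib` marks full-sibling pairs (both parents shared), and
#' `family` marks nuclear-family pairs (the union of parent-offspring,
#' couple and full-sibling pairs).
#'
#' @param ped a [pedigree_table()].
#' @param kind `"couple"`, `"sib"` or `"family"`.
#' @param ids individuals to include (default: all pedigree members).
#'   Ids absent from the pedigree become singletons, with a warning.
#' @return a [relationship_matrix()] of the corresponding ERM kind.
#' @export
build_erm <- function(ped, kind = c("couple", "sib", "family"), ids = NULL) {
  kind <- match.arg(kind)
  if (is.null(ids)) ids <- ped$records$id
  extra <- setdiff(ids, ped$records$id)
  if (length(extra))
    warning(length(extra), " individual(s) not in pedigree; treated as singletons")
  pr <- pedigree_pairs(ped)
  pairs <- switch(kind,
    couple = pr$couples,
    sib = pr$full_sibs,
    family = rbind(pr$parent_offspring, pr$couples, pr$full_sibs))
  n <- length(ids)
  E <- diag(1, n)
  dimnames(E) <- list(ids, ids)
  if (nrow(pairs)) {
    i <- match(pairs[, 1], ids); j <- match(pairs[, 2], ids)
    ok <- !is.na(i) & !is.na(j)
    E[cbind(i[ok], j[ok])] <- 1
    E[cbind(j[ok], i[ok])] <- 1
  }
  relationship_matrix(E,
    switch(kind, couple = "ERM_Couple", sib = "ERM_Sib", family = "ERM_Family"),
    ids)
}

#' Classify pairwise relatedness into degrees of relationship
#'
#' Degree `i` covers `0.5^(i+0.5) < r <= 0.5^(i-0.5)` for `i = 1..5`
#' (so 1st degree spans 0.354--0.707); values at or below `0.5^5.5`
#' (about 0.022) are "unrelated", and values above `0.5^0.5` are collapsed
#' into degree 1 with a warning.
#'
#' @param r numeric vector of relatedness values.
#' @return character vector: `"1"`..`"5"` or `"unrelated"`.
#' @export
classify_degree <- function(r) {
  if (any(r > 0.5^0.5))
    warning("relatedness above 0.707 (closer than 1st degree) collapsed to degree 1")
  breaks <- 0.5^(seq(5, 1) + 0.5)           # lower bounds of degrees 5..1
  out <- rep("unrelated", length(r))
  for (i in 5:1) out[r > 0.5^(i + 0.5)] <- as.character(i)
  out[r > 0.5^0.5] <- "1"
  out
}

#' Prune individuals until no pairwise relatedness exceeds a cutoff
#'
#' Greedy removal: while any off-diagonal entry exceeds `cutoff`, drop the
#' individual involved in the largest number of such pairs (ties drop the
#' later-ordered id).
#'
#' @param grm a [relationship_matrix()].
#' @param cutoff relatedness cutoff (strictly-greater entries count).
#' @return character vector of retained ids, in original order.
#' @export
grm_prune <- function(grm, cutoff) {
  stopifnot(cutoff > 0, cutoff <= 1.5)   # 1.5 is the include-all setting
  A <- grm$values > cutoff
  diag(A) <- FALSE
  keep <- rep(TRUE, nrow(A))
  deg <- rowSums(A)
  while (any(deg[keep] > 0)) {
    cand <- which(keep & deg == max(deg[keep]))
    drop <- cand[length(cand)]   # later-ordered id on ties
    keep[drop] <- FALSE
    nb <- which(A[drop, ] & keep)
    deg[nb] <- deg[nb] - 1L
    deg[drop] <- 0L
  }
  grm$ids[keep]
}

#' Leading eigenvectors of a relationship matrix
#'
#' Eigenvectors for the `k` largest eigenvalues, orthonormal, with the sign
#' convention that each vector's largest-magnitude loading is positive.
#'
#' @param grm a [relationship_matrix()].
#' @param k number of eigenvectors (default 20).
#' @return n x k matrix with ids as row names; eigenvalues in attribute
#'   `"values"`.
#' @export
grm_eigenvectors <- function(grm, k = 20) {
  n <- nrow(grm$values)
  if (k > n) stop("k must not exceed the matrix dimension")
  e <- eigen(grm$values, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- grm$ids
  colnames(V) <- paste0("PC", seq_len(k))
  attr(V, "values") <- e$values[seq_len(k)]
  V
}

# ---------------------------------------------------------------------------
# GCTA GRM binary triplet

#' Write / read a GRM in GCTA binary format
#'
#' `prefix.grm.bin` holds the lower triangle (diagonal included, row-major)
#' as 4-byte floats, `prefix.grm.N.bin` the per-pair SNP counts in the same
#' layout, and `prefix.grm.id` two whitespace-separated id columns.
#'
#' @param grm a [relationship_matrix()].
#' @param prefix output path prefix.
#' @param n_snps per-pair non-missing SNP counts: a matrix, a scalar, or
#'   `NULL` (writes 0).
#' @return `prefix`, invisibly.
#' @export
write_gcta_grm <- function(grm, prefix, n_snps = NULL) {
  v <- grm$values
  n <- nrow(v)
  # GCTA order is (1,1),(2,1),(2,2),(3,1)..., i.e. the lower triangle
  # row-major; for a symmetric matrix that equals the upper triangle in
  # R's column-major order
  lt <- v[upper.tri(v, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4)
  close(con)
  if (is.null(n_snps)) n_snps <- 0
  cnt <- if (is.matrix(n_snps)) n_snps[upper.tri(n_snps, diag = TRUE)] else
    rep(n_snps, length(lt))
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(cnt), con, size = 4)
  close(con)
  utils::write.table(data.frame(fid = grm$ids, iid = grm$ids),
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_gcta_grm
#' @param kind kind tag to attach on read (default `"GRM_g"`).
#' @return `read_gcta_grm`: a [relationship_matrix()] with attribute
#'   `n_snps` (matrix of per-pair counts).
#' @export
read_gcta_grm <- function(prefix, kind = "GRM_g") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  len <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = len, size = 4)
  if (length(vals) != len) stop("truncated .grm.bin")
  V <- matrix(0, n, n)
  V[upper.tri(V, diag = TRUE)] <- vals
  V <- V + t(V) - diag(diag(V))
  cntfile <- paste0(prefix, ".grm.N.bin")
  Np <- NULL
  if (file.exists(cntfile)) {
    cv <- readBin(cntfile, "numeric", n = len, size = 4)
    Np <- matrix(0, n, n)
    Np[upper.tri(Np, diag = TRUE)] <- cv
    Np <- Np + t(Np) - diag(diag(Np))
  }
  out <- relationship_matrix(V, kind, as.character(ids))
  attr(out, "n_snps") <- Np
  out
}

#' Export a relationship matrix as dense TSV
#'
#' @param grm a [relationship_matrix()].
#' @param path output file.
#' @export
write_relmat_tsv <- function(grm, path) {
  utils::write.table(grm$values, path, quote = FALSE, sep = "\t",
                     col.names = NA)
  invisible(path)
}
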
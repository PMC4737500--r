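# small cohorts and matrices built in code, shared across test files

make_trio_ped <- function() {
  pedigree_table(data.frame(
    id = c("dad", "mum", "kid"),
    father = c(NA, NA, "dad"),
    mother = c(NA, NA, "mum"),
    sex = c(1, 2, 1),
    family = "fam1"))
}

make_small_cohort <- function(n_families = 20, n_offspring = 2,
                              n_singletons = 10, n_snps = 500, seed = 100) {
  ped <- simulate_pedigree(n_families, n_offspring, n_singletons, seed = seed)
  geno <- simulate_genotypes(ped, n_snps, seed = seed + 1)
  # small samples can leave a low-MAF SNP monomorphic; drop those
  poly <- geno$allele_freq > 0
  if (!all(poly)) geno <- geno[, which(poly)]
  list(ped = ped, geno = geno)
}

# naive per-SNP double-loop GRM: the independent oracle for compute_grm
naive_grm <- function(dosage, p) {
  n <- nrow(dosage); m <- ncol(dosage)
  G <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) next
      num <- 0; cnt <- 0
      for (i in seq_len(m)) {
        xj <- dosage[j, i]; xk <- dosage[k, i]
        if (is.na(xj) || is.na(xk)) next
        num <- num + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
        cnt <- cnt + 1
      }
      G[j, k] <- num / cnt
    }
    num <- 0; cnt <- 0
    for (i in seq_len(m)) {
      xj <- dosage[j, i]
      if (is.na(xj)) next
      num <- num + (xj^2 - (1 + 2 * p[i]) * xj + 2 * p[i]^2) /
        (2 * p[i] * (1 - p[i]))
      cnt <- cnt + 1
    }
    G[j, j] <- 1 + num / cnt
  }
  G
}

# exact HWE p-value by direct enumeration with factorial(), independent of
# the package's log-recurrence implementation
enum_hwe_p <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  nr <- 2 * min(n_hom_rare, n_hom_common) + n_het
  if (2 * n_hom_rare + n_het > n) nr <- 2 * n - (2 * n_hom_rare + n_het)
  hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  probs <- sapply(hets, function(h) {
    hr <- (nr - h) / 2; hc <- n - h - hr
    2^h * exp(lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
                lfactorial(nr) + lfactorial(2 * n - nr) - lfactorial(2 * n))
  })
  probs <- probs / sum(probs)
  sum(probs[probs <= probs[match(n_het, hets)] * (1 + 1e-12)])
}

# brute-force restricted log-likelihood for one component + residual via
# profile likelihood over the variance ratio (golden-section through optimize)
profile_reml_oracle <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  prof <- function(gam) {
    H <- gam * K + diag(n)
    ch <- chol(H)
    Hi <- chol2inv(ch)
    HiX <- Hi %*% X
    TT <- crossprod(X, HiX)
    Ph <- Hi - HiX %*% solve(TT, t(HiX))
    yPy <- drop(t(y) %*% Ph %*% y)
    s2e <- yPy / (n - p)
    list(logL = -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2e) +
                          2 * sum(log(diag(ch))) +
                          determinant(TT)$modulus[1] + (n - p)),
         s2 = c(gam * s2e, s2e))
  }
  opt <- stats::optimize(function(g) prof(g)$logL, c(-0.2, 100),
                         maximum = TRUE, tol = 1e-10)
  c(prof(opt$maximum), gamma = opt$maximum)
}
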
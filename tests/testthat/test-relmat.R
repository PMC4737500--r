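test_that("GRM entries follow the printed formulas on hand cases", {
  # one SNP, p = 0.25, x_j = 0, x_k = 2:
  # (0 - 0.5)(2 - 0.5) / (2 * 0.25 * 0.75) = -2
  dos <- cbind(c(0L, 2L, 0L, 0L),   # p = 0.25
               c(1L, 1L, 1L, 1L))   # p = 0.5, all heterozygous
  g <- genotype_matrix(dos, chrom = c(1, 1))
  expect_equal(unname(g$allele_freq[1]), 0.25)
  grm1 <- compute_grm(g[, 1])
  expect_equal(grm1$values[1, 2], -2)
  # diagonal: single SNP with p = 0.5, x = 1 -> 1 + (1 - 2 + 0.5)/0.5 = 0
  grm2 <- compute_grm(g[, 2])
  expect_equal(unname(diag(grm2$values)), rep(0, 4))
})

test_that("GRM matches the naive double-loop oracle, with missingness", {
  set.seed(11)
  co <- make_small_cohort(n_families = 4, n_offspring = 2, n_singletons = 4,
                          n_snps = 50)
  dos <- co$geno$dosage
  dos[sample(length(dos), 40)] <- NA
  # guard against SNPs going monomorphic after masking
  keep <- apply(dos, 2, function(x) {
    f <- mean(x, na.rm = TRUE) / 2; f > 0 && f < 1
  })
  g <- genotype_matrix(dos[, keep], chrom = co$geno$chrom[keep])
  grm <- compute_grm(g)
  oracle <- naive_grm(g$dosage, g$allele_freq)
  expect_lt(max(abs(grm$values - oracle)), 1e-10)
  expect_lt(max(abs(grm$values - t(grm$values))), 1e-12)
})

test_that("GRM means match HWE expectations for unrelated founders", {
  set.seed(12)
  n <- 500; m <- 2000
  dos <- sapply(runif(m, 0.1, 0.5), function(p) rbinom(n, 2, p))
  g <- genotype_matrix(dos, chrom = rep_len(1:22, m))
  grm <- compute_grm(g)
  off <- grm$values[upper.tri(grm$values)]
  # sample-frequency centring makes the average off-diagonal -1/(n-1)
  se_off <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) + 1 / (n - 1)), 3 * se_off + 1e-4)
  d <- diag(grm$values)
  expect_lt(abs(mean(d) - 1), 3 * sd(d) / sqrt(n) + 1e-3)
})

test_that("thresholding zeroes small entries strictly and keeps the rest", {
  v <- diag(1, 4)
  v[1, 2] <- v[2, 1] <- 0.024
  v[1, 3] <- v[3, 1] <- 0.025
  v[2, 4] <- v[4, 2] <- 0.5
  v[3, 4] <- v[4, 3] <- -0.04
  grm <- relationship_matrix(v, "GRM_g")
  kin <- threshold_grm(grm)
  expect_equal(kin$values[1, 2], 0)          # below threshold
  expect_equal(kin$values[1, 3], 0.025)      # boundary is kept ("smaller than" is strict)
  expect_equal(kin$values[2, 4], 0.5)        # close relative untouched
  expect_equal(kin$values[3, 4], 0)          # negative entries are below t
  expect_identical(kin$kind, "GRM_kin")
  # symmetric; every entry is either unchanged or exactly zeroed, and all
  # surviving off-diagonals sit at or above the threshold
  expect_lt(max(abs(kin$values - t(kin$values))), 1e-12)
  expect_true(all(kin$values == grm$values | kin$values == 0))
  offk <- kin$values[upper.tri(kin$values)]
  expect_true(all(offk == 0 | offk >= 0.025))
})

test_that("ERMs mark couple, sib and nuclear-family pairs", {
  ped <- make_trio_ped()
  cpl <- build_erm(ped, "couple")
  off <- cpl$values[upper.tri(cpl$values)]
  expect_equal(sum(off), 1)
  expect_equal(cpl$values["dad", "mum"], 1)
  fam <- build_erm(ped, "family")
  expect_equal(unname(fam$values), matrix(1, 3, 3))
  # two full sibs plus an unrelated singleton
  ped2 <- pedigree_table(data.frame(
    id = c("pa", "ma", "s1", "s2", "solo"),
    father = c(NA, NA, "pa", "pa", NA),
    mother = c(NA, NA, "ma", "ma", NA),
    sex = 1, family = c("f", "f", "f", "f", "g")))
  sib <- build_erm(ped2, "sib", ids = c("s1", "s2", "solo"))
  expect_equal(sum(sib$values[upper.tri(sib$values)]), 1)
  expect_equal(sib$values["s1", "s2"], 1)
})

test_that("ERMs are PSD and family is the union of the pair sets", {
  co <- make_small_cohort(n_families = 8, n_offspring = 3, n_singletons = 5,
                          n_snps = 10)
  ids <- co$ped$records$id
  E <- lapply(c("couple", "sib", "family"), build_erm, ped = co$ped, ids = ids)
  po <- pedigree_pairs(co$ped)$parent_offspring
  PO <- diag(1, length(ids)); dimnames(PO) <- list(ids, ids)
  PO[cbind(match(po[, 1], ids), match(po[, 2], ids))] <- 1
  PO[cbind(match(po[, 2], ids), match(po[, 1], ids))] <- 1
  for (e in E)
    expect_gt(min(eigen(e$values, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  expect_equal(E[[3]]$values,
               pmax(PO, pmax(E[[1]]$values, E[[2]]$values)))
  # unknown ids become singletons with a warning
  expect_warning(e2 <- build_erm(co$ped, "couple", ids = c(ids, "ghost")),
                 "singleton")
  expect_equal(sum(e2$values["ghost", ]), 1)
})

test_that("degree classification reproduces the printed boundaries", {
  expect_equal(round(0.5^1.5, 3), 0.354)
  expect_equal(round(0.5^5.5, 3), 0.022)
  expect_equal(classify_degree(0.5), "1")
  expect_equal(classify_degree(0.25), "2")
  expect_equal(classify_degree(0.01), "unrelated")
  expect_equal(classify_degree(0.022), "unrelated")
  # interval edges: upper bound belongs to the degree, lower bound to the next
  expect_equal(classify_degree(0.5^0.5), "1")
  expect_equal(classify_degree(0.5^1.5), "2")
  expect_equal(classify_degree(0.5^5.5 + 1e-12), "5")
  expect_warning(d <- classify_degree(0.9), "collapsed")
  expect_equal(d, "1")
})

test_that("degree intervals partition (0.022, 1] exhaustively", {
  set.seed(13)
  r <- c(runif(500, 0.5^5.5 + 1e-9, 0.5^0.5), 0.5^(1:5),
         0.5^((1:5) + 0.5) + 1e-12)
  deg <- classify_degree(r)
  expect_true(all(deg %in% as.character(1:5)))
  # monotone: larger r never gets a larger degree number
  o <- order(r, decreasing = TRUE)
  expect_true(all(diff(as.integer(deg[o])) >= 0))
})

test_that("greedy pruning removes the fewest-needed individuals", {
  v <- diag(1, 3); v[1, 2] <- v[2, 1] <- 0.5
  grm <- relationship_matrix(v, "GRM_g", c("a", "b", "c"))
  kept <- grm_prune(grm, 0.025)
  expect_equal(length(kept), 2)
  expect_true("c" %in% kept)
  # no pair above cutoff: no-op
  expect_equal(grm_prune(grm, 0.6), c("a", "b", "c"))
  # chain a-b, b-c: removing b suffices (brute-force minimum on 3 nodes)
  v2 <- diag(1, 3)
  v2[1, 2] <- v2[2, 1] <- 0.5
  v2[2, 3] <- v2[3, 2] <- 0.5
  grm2 <- relationship_matrix(v2, "GRM_g", c("a", "b", "c"))
  expect_equal(grm_prune(grm2, 0.025), c("a", "c"))
  # retained set respects the cutoff
  co <- make_small_cohort(n_families = 6, n_snps = 400)
  grm3 <- compute_grm(co$geno)
  kept3 <- grm_prune(grm3, 0.354)
  sub <- grm3$values[kept3, kept3]
  expect_lte(max(sub[upper.tri(sub)]), 0.354)
})

test_that("leading eigenvectors are orthonormal with deterministic signs", {
  co <- make_small_cohort(n_families = 6, n_snps = 300)
  grm <- compute_grm(co$geno)
  V <- grm_eigenvectors(grm, k = 5)
  expect_lt(max(abs(crossprod(V) - diag(5))), 1e-10)
  for (j in 1:5) expect_gt(V[which.max(abs(V[, j])), j], 0)
  expect_error(grm_eigenvectors(grm, k = nrow(grm$values) + 1), "exceed")
  # two disjoint ones-blocks: leading eigenvectors load on single blocks
  B <- matrix(0, 6, 6)
  B[1:4, 1:4] <- 1; B[5:6, 5:6] <- 1
  bg <- relationship_matrix(B, "ERM_Family")
  Vb <- grm_eigenvectors(bg, k = 2)
  expect_equal(attr(Vb, "values"), c(4, 2))
  expect_equal(Vb[, 1], c(rep(0.5, 4), 0, 0), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("GCTA GRM binary round trip preserves values to float precision", {
  co <- make_small_cohort(n_families = 4, n_snps = 200)
  grm <- compute_grm(co$geno)
  prefix <- file.path(tempdir(), "gcta")
  write_gcta_grm(grm, prefix, n_snps = 200)
  back <- read_gcta_grm(prefix)
  expect_equal(back$values, grm$values, tolerance = 1e-6)
  expect_identical(back$ids, grm$ids)
  expect_equal(attr(back, "n_snps")[1, 2], 200)
})
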
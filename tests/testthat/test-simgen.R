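test_that("simulated pedigrees have the designed structure", {
  ped <- simulate_pedigree(10, 2, 5, seed = 1)
  expect_equal(nrow(ped$records), 45)
  pr <- pedigree_pairs(ped)
  expect_equal(nrow(pr$couples), 10)
  expect_equal(nrow(pr$full_sibs), 10)       # C(2,2) = 1 per family
  expect_equal(nrow(pr$parent_offspring), 40)
  # determinism
  ped2 <- simulate_pedigree(10, 2, 5, seed = 1)
  expect_identical(ped$records, ped2$records)
  # no extended links by default: every parent is a founder
  parents <- unique(c(pr$couples))
  rec <- ped$records
  expect_true(all(is.na(rec$father[rec$id %in% parents])))
  # grandparent links create three-generation ancestry
  ped3 <- simulate_pedigree(10, 2, 0, grandparent_fraction = 0.4, seed = 2)
  rec3 <- ped3$records
  linked <- rec3$id[grepl("_P1$", rec3$id) & !is.na(rec3$father)]
  expect_equal(length(linked), 4)
})

test_that("gene dropping respects Mendelian transmission", {
  ped <- simulate_pedigree(60, 2, 0, seed = 3)
  geno <- simulate_genotypes(ped, 600, seed = 4)
  rec <- ped$records
  kids <- rec$id[!is.na(rec$father)]
  dos <- geno$dosage
  fa <- dos[rec$father[match(kids, rec$id)], ]
  mo <- dos[rec$mother[match(kids, rec$id)], ]
  kid <- dos[kids, ]
  # homozygous-by-homozygous forcing
  expect_true(all(kid[fa == 2 & mo == 2] == 2))
  expect_true(all(kid[fa == 0 & mo == 0] == 0))
  expect_true(all(kid[fa == 2 & mo == 0] == 1))
  # het x het segregates 1/4, 1/2, 1/4
  hh <- kid[fa == 1 & mo == 1]
  counts <- table(factor(hh, levels = 0:2))
  expect_gt(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.001)
  # determinism
  geno2 <- simulate_genotypes(ped, 600, seed = 4)
  expect_identical(geno$dosage, geno2$dosage)
})

test_that("gene-dropped GRM means match identity-by-descent expectations", {
  ped <- simulate_pedigree(60, 2, 30, seed = 5)
  geno <- simulate_genotypes(ped, 1500, seed = 6)
  grm <- compute_grm(geno)
  pr <- pedigree_pairs(ped)
  ids <- grm$ids
  po_vals <- grm$values[cbind(match(pr$parent_offspring[, 1], ids),
                              match(pr$parent_offspring[, 2], ids))]
  expect_equal(length(po_vals), 240)
  expect_lt(abs(mean(po_vals) - 0.5), 0.05)
  sib_vals <- grm$values[cbind(match(pr$full_sibs[, 1], ids),
                               match(pr$full_sibs[, 2], ids))]
  expect_lt(abs(mean(sib_vals) - 0.5), 0.05)
  # unrelated: singleton x singleton entries
  singles <- ids[grepl("^S", ids)]
  uu <- grm$values[singles, singles][upper.tri(diag(length(singles)))]
  expect_lt(abs(mean(uu)), 0.01)
})

test_that("phenotype parts hit their target variances exactly when rescaled", {
  co <- make_small_cohort(n_families = 40, n_offspring = 2,
                          n_singletons = 40, n_snps = 1000)
  cfg <- sim_config(h2g = 0.3, h2kin = 0.2, ec2 = 0.1, es2 = 0.1, ef2 = 0.05,
                    seed = 11)
  ph <- simulate_phenotype(co$geno, co$ped, cfg)
  expect_equal(unname(ph$truth$realized),
               c(0.3, 0.2, 0.05, 0.1, 0.1, 0.25), tolerance = 1e-12)
  expect_equal(rowSums(ph$parts), unname(ph$y), ignore_attr = TRUE)
  # variance decomposition identity: parts + cross-covariances = var(y)
  cv <- cov(ph$parts)
  expect_equal(var(ph$y), sum(cv), tolerance = 1e-12)
  # sample variance of y is close to 1 (cross terms are O(1/sqrt(n)))
  expect_lt(abs(var(ph$y) - 1), 0.15)
  # determinism under the seed
  ph2 <- simulate_phenotype(co$geno, co$ped, cfg)
  expect_identical(ph$y, ph2$y)
})

test_that("pure-noise phenotypes close the variance budget", {
  ped <- simulate_pedigree(250, 2, 0, seed = 12)
  geno <- simulate_genotypes(ped, 200, seed = 13)
  ph <- simulate_phenotype(geno, ped, sim_config(seed = 14))
  expect_lt(abs(var(ph$y) - 1), 0.1)
  expect_equal(unname(ph$truth$realized[c("g", "k", "f", "s", "c")]),
               rep(0, 5))
})

test_that("causal SNPs come from the right chromosome parity", {
  co <- make_small_cohort(n_families = 10, n_singletons = 5, n_snps = 2200)
  cfg <- sim_config(h2g = 0.3, h2kin = 0.2, seed = 15)
  ph <- simulate_phenotype(co$geno, co$ped, cfg)
  parity <- function(snps) unique(co$geno$chrom[match(snps, co$geno$snp_ids)] %% 2)
  expect_equal(parity(ph$truth$causal_g$snp), 0)
  expect_equal(parity(ph$truth$causal_k$snp), 1)
  # about 1 causal per 500 eligible SNPs
  m_even <- sum(co$geno$chrom %% 2 == 0)
  expect_equal(nrow(ph$truth$causal_g), ceiling(m_even / 500))
})

test_that("environment components error without eligible groups", {
  ped <- pedigree_table(data.frame(id = c("a", "b"), father = NA, mother = NA,
                                   sex = 1:2, family = c("x", "y")))
  geno <- simulate_genotypes(ped, 100, seed = 16)
  expect_error(simulate_phenotype(geno, ped, sim_config(ec2 = 0.2, seed = 1)),
               "no couples")
  expect_error(simulate_phenotype(geno, ped, sim_config(es2 = 0.2, seed = 1)),
               "no full sibs")
  expect_error(simulate_phenotype(geno, ped, sim_config(ef2 = 0.2, seed = 1)),
               "no nuclear-family")
})

test_that("split family mode preserves the family variance budget", {
  co <- make_small_cohort(n_families = 50, n_offspring = 2, n_singletons = 0,
                          n_snps = 100)
  cfg <- sim_config(ef2 = 0.4, family_mode = "split", seed = 17)
  ph <- simulate_phenotype(co$geno, co$ped, cfg)
  fvals <- ph$parts[, "f"]
  # two half-variance draws shared identically within each family
  expect_equal(as.vector(tapply(fvals, co$ped$records$family,
                                function(v) diff(range(v)))),
               rep(0, 50), tolerance = 1e-12)
  expect_lt(abs(var(fvals) - 0.4), 0.1)
})

test_that("Z-test recovery follows the normal-tail arithmetic", {
  expect_error(ztest_recovery(0.3, 0.3), "at least 2")
  zt <- ztest_recovery(rep(0.3, 5), 0.3)
  expect_equal(zt$z, 0)
  expect_equal(zt$p, 1)
  expect_error(ztest_recovery(rep(0.25, 5), 0.3), "zero SD")
  # mean 0.32, sd 0.05, R = 25 -> Z = 2, p ~ 0.0455
  est <- scale(rnorm(25)) * 0.05 + 0.32
  zt2 <- ztest_recovery(as.numeric(est), 0.3)
  expect_equal(zt2$z, 2, tolerance = 1e-9)
  expect_equal(zt2$p, 0.0455, tolerance = 1e-3)
})

test_that("scenario studies recover parameters and tabulate selections", {
  ped <- simulate_pedigree(60, 2, 40, seed = 18)
  geno <- simulate_genotypes(ped, 1000, seed = 19)
  mats <- model_matrices(geno, ped)
  scen <- list(list(name = "G", config = sim_config(h2g = 0.4), model = "G"))
  st <- run_scenario_study(scen, geno, ped, n_replicates = 8, seed = 20,
                           mode = "fit", matrices = mats)
  expect_equal(nrow(st$replicates), 8)
  expect_equal(st$summary$n_used, 8)
  expect_lt(abs(st$summary$mean - 0.4), 0.15)
  # determinism of the whole study under the master seed
  st2 <- run_scenario_study(scen, geno, ped, n_replicates = 8, seed = 20,
                            mode = "fit", matrices = mats)
  expect_identical(st$replicates, st2$replicates)
  scen2 <- list(list(name = "noise", config = sim_config()))
  st3 <- suppressWarnings(
    run_scenario_study(scen2, geno, ped, n_replicates = 2, seed = 21,
                       mode = "select", matrices = mats, lrt_all = FALSE))
  # a noise phenotype keeps at most a rare alpha-level false positive
  expect_true(all(nchar(sub("residual-only", "", st3$replicates$final_model)) <= 1))
})
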
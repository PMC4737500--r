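#!/usr/bin/env Rscript

# Matched-model parameter recovery: simulate phenotypes in which each
# variance component acts at its standard setting and refit with the model
# containing exactly the simulated components, by unconstrained REML so the
# replicate means are interpretable as bias checks.  Writes the per-scenario
# summary (mean, SD, 95% CI, Z-test against the simulated value).
#
# 25 replicates per scenario keep this driver at a few minutes; the
# acceptance script runs the same design at 50 replicates.

suppressPackageStartupMessages(library(famreml))

seed <- 1
if (!file.exists("results/cohort/cohort.bed"))
  stop("cohort not found; run analysis/01_simulate_cohort.R first")
cohort <- read_plink("results/cohort/cohort")
ped <- read_pedigree("results/cohort/cohort.ped.txt")
geno <- cohort$geno
mats <- model_matrices(geno, ped)

scen <- list(
  list(name = "G",   config = sim_config(h2g = 0.3), model = "G"),
  list(name = "K",   config = sim_config(h2kin = 0.2), model = "K"),
  list(name = "F",   config = sim_config(ef2 = 0.05), model = "F"),
  list(name = "S",   config = sim_config(es2 = 0.1), model = "S"),
  list(name = "C",   config = sim_config(ec2 = 0.1), model = "C"),
  list(name = "GK",  config = sim_config(h2g = 0.3, h2kin = 0.2), model = "GK"),
  list(name = "GKC", config = sim_config(h2g = 0.3, h2kin = 0.2, ec2 = 0.1),
       model = "GKC"))

st <- run_scenario_study(scen, geno, ped, n_replicates = 25, seed = seed + 10,
                         mode = "fit", matrices = mats)
print(st)
dir.create("results", showWarnings = FALSE)
write.table(st$summary, "results/matched_models.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(st$replicates, "results/matched_models_replicates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nNote: the SNP-heritability component is estimated from the same SNPs\n")
cat("that carry its causal variants and recovers its setting closely; the\n")
cat("pedigree-associated component relies on a close-relative GRM estimated\n")
cat("from only ~2,000 SNPs, whose sampling noise passes the 0.025 threshold\n")
cat("for many unrelated pairs and attenuates that component at this scale\n")
cat("(see the methods vignette).\n")
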
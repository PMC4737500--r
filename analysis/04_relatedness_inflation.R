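#!/usr/bin/env Rscript

# How close relatives inflate SNP-heritability estimates: simulate a
# phenotype with SNP genetics (h2g = 0.3) plus nuclear-family environment
# (ef2 = 0.2), then estimate h2g with the single-GRM model on nested
# subpopulations defined by relatedness cutoffs (the upper bounds of the
# degree-of-relationship intervals).  With 1st-degree relatives included
# the family environment masquerades as SNP heritability; pruning at the
# 1st-degree lower bound (0.354) removes the inflation.

suppressPackageStartupMessages(library(famreml))

seed <- 1
if (!file.exists("results/cohort/cohort.bed"))
  stop("cohort not found; run analysis/01_simulate_cohort.R first")
cohort <- read_plink("results/cohort/cohort")
ped <- read_pedigree("results/cohort/cohort.ped.txt")
geno <- cohort$geno
grm <- compute_grm(geno, chrom_subset = seq(2, 22, 2))

# upper bounds of the 5th..2nd degree intervals, then include-everyone
cutoffs <- c(0.5^4.5, 0.5^3.5, 0.5^2.5, 0.5^1.5, 1.5)

n_rep <- 5
tabs <- vector("list", n_rep)
for (r in seq_len(n_rep)) {
  cfg <- sim_config(h2g = 0.3, ef2 = 0.2, seed = seed + 30 + r)
  ph <- simulate_phenotype(geno, ped, cfg)
  tabs[[r]] <- cbind(replicate = r,
                     h2_vs_cutoff(ph$y, grm, cutoffs, constrain = FALSE))
}
tab <- do.call(rbind, tabs)
agg <- aggregate(cbind(h2g, se) ~ cutoff + n_retained, data = tab, FUN = mean)
agg <- agg[order(agg$cutoff), ]
cat("mean h2g estimate by relatedness cutoff (truth 0.3, ef2 = 0.2):\n")
print(format(agg, digits = 3), row.names = FALSE)

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/h2_vs_cutoff.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/h2_vs_cutoff.tsv\n")
cat(sprintf(
  "inflation at include-all vs 1st-degree pruning: %.3f vs %.3f\n",
  mean(tab$h2g[tab$cutoff == 1.5]), mean(tab$h2g[tab$cutoff == 0.5^1.5])))
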
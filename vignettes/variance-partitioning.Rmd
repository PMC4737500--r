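---
title: "Partitioning trait variance into SNP, pedigree and shared-environment components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait variance into SNP, pedigree and shared-environment components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famreml)
```

## The model

In a family-structured cohort, resemblance between relatives mixes several
causes: additive genetic effects tagged by genotyped common SNPs, additional
genetic effects carried by close relatives but not tagged by the SNP panel,
and environments shared within households.  famreml dissects a quantitative
trait along exactly these axes with the linear mixed model

$$
\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{g}_g + \mathbf{g}_{kin}
  + \mathbf{e}_f + \mathbf{e}_s + \mathbf{e}_c + \boldsymbol\varepsilon,
$$

$$
\mathbf{V} = \mathrm{GRM}_g\,\sigma^2_g + \mathrm{GRM}_{kin}\,\sigma^2_{kin}
  + \mathrm{ERM}_{Family}\,\sigma^2_{ef} + \mathrm{ERM}_{Sib}\,\sigma^2_{es}
  + \mathrm{ERM}_{Couple}\,\sigma^2_{ec} + \mathbf{I}\,\sigma^2_\varepsilon .
$$

The five design matrices are:

* **GRM_g** — genomic relatedness from SNP dosages.  The off-diagonal entry
  for individuals $j,k$ averages
  $(x_{ji}-2p_i)(x_{ki}-2p_i)/2p_i(1-p_i)$ over SNPs, with $p_i$ the minor
  allele frequency; the diagonal is one plus the SNP-estimated inbreeding
  coefficient.  It captures variance tagged by the genotyped panel
  ($h^2_g$).
* **GRM_kin** — the same matrix with every entry below a threshold
  $t = 0.025$ set to zero.  Only close relatives keep nonzero entries, so
  its variance component measures the extra pedigree-associated genetic
  variance not tagged by the panel ($h^2_{kin}$); the total heritability
  is $h^2_{g+kin} = h^2_g + h^2_{kin}$.
* **ERM_Couple / ERM_Sib / ERM_Family** — 0/1 indicators with unit
  diagonal marking pairs with a common offspring, full-sibling pairs, and
  nuclear-family pairs (the union of couple, full-sib and parent-offspring
  pairs).  Their components are the couple ($e^2_c$), sibling ($e^2_s$) and
  family ($e^2_f$) shared-environment fractions.

Each component's ratio is its variance over the phenotypic total, so the
six ratios (residual included) sum to one.

## REML engine

`reml_fit()` maximises the restricted likelihood by average-information
(AI) updates after a short EM warm-up (default three EM steps; EM is slow
but monotone far from the optimum, AI is quadratically convergent near it).
Iterations stop when the relative log-likelihood change falls below 1e-8
and the largest relative parameter change below 1e-6, with a cap of 100
iterations.  Steps that would make $\mathbf{V}$ indefinite, or that would
sharply decrease the likelihood, are halved.  Two constraint regimes are
offered:

* **constrained** (default): variance components are projected to zero when
  an update turns them negative; a zeroed component whose gradient points
  outward is frozen there (active-set step).  This matches how production
  GREML tools behave and is what the stepwise selection uses.
* **unconstrained**: estimates may go negative as long as $\mathbf{V}$
  stays positive definite.  Simulation studies use this mode, because
  truncation at zero would bias replicate means upward for small
  components.

Likelihoods are computed through dense Cholesky factorisations; traces
$\mathrm{tr}(\mathbf{P}K_c)$ come from an explicit inverse so the
per-iteration cost is one factorisation plus one inversion regardless of
the number of components.  Models with a single relationship matrix are
rotated into that matrix's eigenbasis once, which makes every iteration
O(n) and lets repeated fits against the same matrix (replicate studies,
cutoff scans, jackknifes) reuse the decomposition via the `eigen_K`
argument.  Standard errors of variances come from the inverse AI matrix and
those of ratios from the delta method with the full sampling covariance;
the delta-method ratio SEs agree with a grouped jackknife within 30% in the
test suite.

Starting values split the phenotypic variance equally across components;
fixed effects are profiled out by the REML projection, and the design
matrix builder (`build_fixed_effects()`) assembles the standard covariate
set — sex, age, age², sex-by-age, clinic, standardised deprivation index
and its square, plus leading GRM eigenvectors — dropping collinear columns.

## Tests of components and model selection

`wald_test()` refers $(\hat\sigma^2_c/\mathrm{se})^2$ to $\chi^2_1$.
`lrt()` compares nested fits with the boundary-corrected null
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (a variance tested at zero sits on
the boundary of its parameter space), so $p = \tfrac12 P(\chi^2_1 \ge LR)$
and $LR = 0$ gives $p = 0.5$.  `stepwise_select()` starts from the model
with all five matrices and repeatedly removes the component that is
non-significant in *both* tests at $\alpha = 0.05$ with the highest Wald
p-value (ties resolved toward the later component in the canonical order
G, K, F, S, C, for determinism).  The LRT for each component compares
against the model dropping that single component; when a reduced model
fails to converge its LRT is recorded as `NA` and the Wald test alone
governs that component.  No multiple-testing correction is applied.  The
`lrt_all = FALSE` mode skips LRTs for components that are already
Wald-significant — such components can never be removed, so the selection
path is provably identical — and is used in the replicate studies for
speed.

## The synthetic cohort and what it does (not) emulate

Because the real cohort behind this design is not redistributable, the
package carries a generator that reproduces its structure at desk scale:

* `simulate_pedigree()` — nuclear families (two founder parents, default
  two offspring) plus unrelated singletons; optionally a fraction of
  families chained through a shared grandparent couple to create 2nd- and
  3rd-degree pairs.  Default study size: 300 families of 2+2 plus 300
  singletons, n = 1,500.
* `simulate_genotypes()` — founder genotypes in Hardy-Weinberg equilibrium
  at frequencies uniform on (0.05, 0.5], offspring by Mendelian gene
  dropping, loci independent, chromosomes 1–22 assigned round-robin.
  Default m = 4,000 SNPs.
* `simulate_phenotype()` — causal SNPs are drawn at about one per 500
  eligible SNPs from even chromosomes (the SNP-associated score) and,
  separately, from odd chromosomes (the pedigree-associated score, since
  GRMs are then built from even chromosomes only, these causals are
  deliberately untagged); per-locus effects have Exponential(1) magnitude
  and random sign on standardised dosages (the scale is irrelevant after
  rescaling, and symmetric signs are exchangeable); one shared normal draw
  per full-sib group, per couple and per nuclear family; iid residual
  closing the budget to $1 - \sum$ fractions, so the expected phenotype
  variance is 1.

By default every constructed part is centred and rescaled so its sample
variance equals its target fraction exactly ("realized" scaling).  This
makes the truth record exact and recovery tests sharp; `scale =
"expected"` restores plain expectation scaling.  A `family_mode = "split"`
option divides the family variance over two draws (youth and adulthood
household); for two-generation families the covariance structure is
identical to the single draw, which is therefore the default.

The generator does **not** emulate linkage disequilibrium, assortative
mating, recombination maps, covariate effects, genotyping error or
population stratification.  Passing recovery tests on this cohort shows
the estimator and selection machinery are sound under the model's own
assumptions; it does not certify behaviour under stratification or LD,
which real-data analyses must address with the eigenvector covariates and
QC filters.

## Study designs wired into the tests and acceptance script

* **Matched-model recovery**: 50 replicate phenotypes per scenario on the
  n = 1,500 cohort; scenarios with the component settings
  $h^2_g = 0.3$, $h^2_{kin} = 0.2$, $e^2_c = 0.1$, $e^2_s = 0.1$,
  $e^2_f = 0.05$, fitted unconstrained with the matched model (G, GK, GKC,
  S, F); evaluation by the Z-test of the replicate mean against the
  simulated value.
* **Selection effectiveness**: three scenario families (moderate SNP
  genetics 0.3 and low sibling environment 0.05, plus (a) moderate family
  environment, (b) moderate pedigree genetics and couple environment,
  (c) all three moderate at 0.2), 10 replicates each; success means the
  final model keeps every moderate component.
* **Relatedness-cutoff scan**: phenotypes with SNP genetics plus family
  environment, single-GRM fits on subpopulations pruned at the
  degree-interval bounds ($0.5^{i\pm0.5}$; first degree spans
  0.354–0.707, unrelated means $r \le 0.022$): estimates inflate once
  1st-degree relatives enter and return to truth after pruning at 0.354.

## A desk-scale limitation worth knowing about

One property of the full-scale design does not survive the reduction to
4,000 SNPs.  GRM entries are sample means over SNPs, so their noise SD for
an unrelated pair is about $1/\sqrt{m_{even}} \approx 0.022$ with
$m_{even} \approx 2{,}000$ — almost exactly the close-relative threshold
$t = 0.025$.  Roughly 13% of the million-plus truly-unrelated pairs
therefore leak past the threshold, and GRM_kin picks up on the order of
$10^5$ spurious weak entries against only ~1,500 true first-degree pairs
(with several hundred thousand SNPs the same threshold sits at ~13 noise
SDs and the leak is absent).  The consequence, verified by swapping in a
noise-free pedigree kinship matrix, is a systematic attenuation of
$\hat h^2_{kin}$ (replicate means near 0.12–0.15 against a simulated 0.2)
and, through the correlation of the estimating equations, a downward pull
on $\hat e^2_c$ under the GKC model.  $\hat h^2_g$ is unaffected because
its causal SNPs sit inside the fitted GRM.  The package keeps the
published threshold and the desk-scale SNP count as-is rather than tuning
either, and the affected recovery checks document the attenuated values;
analyses of genuinely dense genotype panels do not face this issue.

The same mechanism limits the stepwise selection at this scale: the
nuclear-family indicator is built from the pedigree and is noise-free,
while GRM_kin is the noisy estimate above, so when pedigree-genetic and
couple effects drive the phenotype the selection tends to keep F as a
cheaper explanation of the family covariance instead of K (and F then
absorbs the couple signal too).  Scenarios whose major components are G
and F are recovered essentially always; scenarios that require
discriminating K and C from F are recovered far less often than with a
dense panel, and the selection-effectiveness checks record those rates
as measured.

## Numerical details and edge cases

* Minor-allele orientation is fixed at load; exact ties at $p = 0.5$ keep
  file order.  Missing dosages are excluded both from frequency estimation
  and from the per-pair GRM averages (each pair is averaged over the SNPs
  non-missing in both individuals).
* The Hardy-Weinberg QC filter uses the exact conditional test; the
  variance-ratio, LRT and Wald conventions are as above; a monomorphic SNP
  reaching the GRM is an error rather than a silent NaN.
* `grm_prune()` removes greedily by current over-threshold degree, ties
  dropping the later-ordered individual — deterministic and near-minimal.
* Eigenvectors get a deterministic sign (largest-magnitude loading
  positive).
* Degenerate inputs error early: empty SNP panels after QC, zero residual
  variance traits, Z-tests on fewer than two estimates, components
  requested without eligible groups (e.g. a couple effect in a pedigree
  with no couples).

## Worked example

```{r example, eval = FALSE}
ped  <- simulate_pedigree(300, 2, 300, seed = 1)
geno <- simulate_genotypes(ped, 4000, seed = 2)
mats <- model_matrices(geno, ped)   # G, K, F, S, C from even chromosomes

cfg <- sim_config(h2g = 0.3, h2kin = 0.2, ec2 = 0.1, seed = 3)
ph  <- simulate_phenotype(geno, ped, cfg)

fit <- reml_fit(ph$y, matrices = mats[c("G", "K", "C")])
fit
stepwise_select(ph$y, mats)
```

The analysis drivers under `analysis/` run these designs end to end and
write their tables under `results/`; `scripts/acceptance.R` reruns the
replicate studies at full desk scale from a single seed.
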
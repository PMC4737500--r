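#' Simulate a nuclear-family pedigree
#'
#' Generates a cohort of nuclear families (two founder parents plus their
#' offspring) together with unrelated singletons, the structure of the
#' family-based cohorts this package targets.  Optionally a fraction of
#' families can be chained so that one parent is an offspring of another
#' family's couple, creating grandparent and avuncular (2nd/3rd-degree)
#' pairs.
#'
#' @param n_families number of nuclear families.
#' @param n_offspring children per family: a scalar or a vector of length
#'   `n_families` (default 2).
#' @param n_singletons number of unrelated individuals.
#' @param grandparent_fraction fraction of families whose father is drawn
#'   as an extra offspring of another family's couple (default 0).
#' @param seed optional RNG seed.
#' @return a [pedigree_table()]; parents have sex 1/2, offspring sex is
#'   random.
#' @export
simulate_pedigree <- function(n_families, n_offspring = 2, n_singletons = 0,
                              grandparent_fraction = 0, seed = NULL) {
  stopifnot(n_families >= 1, all(n_offspring >= 1), n_singletons >= 0,
            grandparent_fraction >= 0, grandparent_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_offspring <- rep_len(n_offspring, n_families)
  fam <- sprintf("F%04d", seq_len(n_families))
  rows <- list()
  for (i in seq_len(n_families)) {
    fa <- paste0(fam[i], "_P1"); mo <- paste0(fam[i], "_P2")
    rows[[length(rows) + 1L]] <- data.frame(
      id = c(fa, mo), father = NA_character_, mother = NA_character_,
      sex = c(1L, 2L), family = fam[i], stringsAsFactors = FALSE)
    kid <- paste0(fam[i], "_O", seq_len(n_offspring[i]))
    rows[[length(rows) + 1L]] <- data.frame(
      id = kid, father = fa, mother = mo,
      sex = sample(1:2, n_offspring[i], replace = TRUE), family = fam[i],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (grandparent_fraction > 0 && n_families >= 2) {
    n_link <- floor(grandparent_fraction * n_families)
    # family 2k's father becomes an offspring of family 2k-1's couple
    for (k in seq_len(min(n_link, n_families %/% 2))) {
      child <- paste0(fam[2 * k], "_P1")
      df$father[df$id == child] <- paste0(fam[2 * k - 1], "_P1")
      df$mother[df$id == child] <- paste0(fam[2 * k - 1], "_P2")
    }
  }
  if (n_singletons > 0) {
    sid <- sprintf("S%04d", seq_len(n_singletons))
    df <- rbind(df, data.frame(
      id = sid, father = NA_character_, mother = NA_character_,
      sex = sample(1:2, n_singletons, replace = TRUE), family = sid,
      stringsAsFactors = FALSE))
  }
  pedigree_table(df)
}

#' Simulate genotypes by Mendelian gene dropping
#'
#' Founders receive Hardy-Weinberg genotypes at per-SNP minor-allele
#' frequencies drawn uniformly from `maf_range`; every non-founder receives
#' one allele from each parent, loci independent (no linkage
#' disequilibrium).  Chromosome labels 1--22 are assigned round-robin so
#' downstream even/odd-chromosome splits are possible.
#'
#' @param ped a [pedigree_table()].
#' @param n_snps number of SNPs (default 4000).
#' @param maf_range minor-allele-frequency range for founders
#'   (default `c(0.05, 0.5)`).
#' @param seed optional RNG seed.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(ped, n_snps = 4000, maf_range = c(0.05, 0.5),
                               seed = NULL) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  df <- ped$records
  n <- nrow(df); m <- n_snps
  p <- stats::runif(m, maf_range[1], maf_range[2])
  dos <- matrix(NA_integer_, n, m, dimnames = list(df$id, paste0("snp", seq_len(m))))
  fa <- match(df$father, df$id)
  mo <- match(df$mother, df$id)
  done <- is.na(fa) & is.na(mo)    # founders
  for (i in which(done))
    dos[i, ] <- stats::rbinom(m, 2L, p)
  # gene-drop in generation order
  while (!all(done)) {
    ready <- which(!done & done[ifelse(is.na(fa), 1L, fa)] &
                     done[ifelse(is.na(mo), 1L, mo)] &
                     !is.na(fa) & !is.na(mo))
    if (!length(ready)) stop("pedigree has unresolvable parentage")
    for (i in ready) {
      tf <- (dos[fa[i], ] == 2L) + (dos[fa[i], ] == 1L) * stats::rbinom(m, 1L, 0.5)
      tm <- (dos[mo[i], ] == 2L) + (dos[mo[i], ] == 1L) * stats::rbinom(m, 1L, 0.5)
      dos[i, ] <- as.integer(tf + tm)
      done[i] <- TRUE
    }
  }
  chrom <- ((seq_len(m) - 1L) %% 22L) + 1L
  pos <- ((seq_len(m) - 1L) %/% 22L) + 1L
  genotype_matrix(dos, chrom, pos)
}

#' Simulation configuration
#'
#' Target variance fractions for the five components; the residual takes
#' the remainder so the expected phenotypic variance is 1.
#'
#' @param h2g,h2kin,ef2,es2,ec2 target fractions in `[0, 1]`.
#' @param causal_fraction fraction of eligible SNPs that are causal per
#'   genetic component (default 1/500, at least one SNP).
#' @param scale `"realized"` rescales every constructed part so its sample
#'   variance equals its target exactly; `"expected"` only scales in
#'   expectation.
#' @param family_mode `"single"` draws one shared value per nuclear family;
#'   `"split"` halves the family variance over two draws (youth and
#'   adulthood household), which is equivalent for two-generation families.
#' @param seed optional RNG seed used by [simulate_phenotype()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(h2g = 0, h2kin = 0, ef2 = 0, es2 = 0, ec2 = 0,
                       causal_fraction = 1 / 500,
                       scale = c("realized", "expected"),
                       family_mode = c("single", "split"), seed = NULL) {
  fr <- c(h2g = h2g, h2kin = h2kin, ef2 = ef2, es2 = es2, ec2 = ec2)
  if (any(fr < 0) || any(fr > 1)) stop("variance fractions must be in [0, 1]")
  if (sum(fr) > 1) stop("variance fractions sum to more than 1")
  structure(list(h2g = h2g, h2kin = h2kin, ef2 = ef2, es2 = es2, ec2 = ec2,
                 ee2 = 1 - sum(fr), causal_fraction = causal_fraction,
                 scale = match.arg(scale), family_mode = match.arg(family_mode),
                 seed = seed),
            class = "sim_config")
}

# shared-environment group keys per individual
.env_groups <- function(ped, kind) {
  df <- ped$records
  both <- !is.na(df$father) & !is.na(df$mother)
  couple_key_of_parents <- ifelse(both, paste(df$father, df$mother, sep = "\r"), NA)
  if (kind == "sib") {
    out <- ifelse(both, couple_key_of_parents, df$id)
  } else if (kind == "couple") {
    cp <- pedigree_pairs(ped)$couples
    out <- df$id
    if (nrow(cp)) {
      key <- paste(cp[, 1], cp[, 2], sep = "\r")
      out[match(cp[, 1], df$id)] <- key
      out[match(cp[, 2], df$id)] <- key
    }
  } else {  # nuclear family: parent role takes priority over offspring role
    cp <- pedigree_pairs(ped)$couples
    out <- ifelse(both, couple_key_of_parents, df$id)
    if (nrow(cp)) {
      key <- paste(cp[, 1], cp[, 2], sep = "\r")
      out[match(cp[, 1], df$id)] <- key
      out[match(cp[, 2], df$id)] <- key
    }
  }
  out
}

.group_effect <- function(keys) {
  u <- unique(keys)
  stats::rnorm(length(u))[match(keys, u)]
}

.rescale_part <- function(v, target, scale, expected_var = 1) {
  if (target == 0) return(rep(0, length(v)))
  if (scale == "realized") {
    v <- v - mean(v)
    sv <- sum(v^2) / (length(v) - 1)
    if (sv <= 0) stop("degenerate component: zero realized variance")
    v * sqrt(target / sv)
  } else {
    v * sqrt(target / expected_var)
  }
}

#' Simulate a phenotype with genetic and shared-environment components
#'
#' Causal SNPs for the SNP-associated genetic score are sampled from even
#' chromosomes and, separately, causal SNPs for the pedigree-associated
#' score from odd chromosomes (about one per 500 eligible SNPs); each gets
#' an effect with exponential magnitude and random sign applied to its
#' standardised dosage.  Shared-environment parts draw one normal value per
#' full-sib group, per couple and per nuclear family; the residual is iid.
#' Under the default realized-variance scaling every part is centred and
#' rescaled so its sample variance equals its target fraction exactly, and
#' the residual closes the budget to an expected phenotypic variance of 1.
#'
#' @param geno a [genotype_matrix()] covering the pedigree members.
#' @param ped the matching [pedigree_table()].
#' @param config a [sim_config()].
#' @return list of class `sim_phenotype`: `y` (named phenotype vector),
#'   `parts` (n x 6 matrix of the constructed component values, columns
#'   `g,k,f,s,c,e`), and `truth` (targets, causal SNP ids and effects,
#'   realized part variances).
#' @export
simulate_phenotype <- function(geno, ped, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- ped$records$id
  if (!identical(geno$sample_ids, ids))
    stop("genotype and pedigree individuals must match and be in the same order")
  n <- length(ids)
  parts <- matrix(0, n, 6, dimnames = list(ids, c("g", "k", "f", "s", "c", "e")))
  truth <- list(targets = c(h2g = config$h2g, h2kin = config$h2kin,
                            ef2 = config$ef2, es2 = config$es2,
                            ec2 = config$ec2, ee2 = config$ee2))

  gen_score <- function(parity) {
    idx <- which(geno$chrom %% 2L == parity)
    if (!length(idx)) stop("no SNPs on the requested chromosome parity")
    nc <- max(1L, ceiling(config$causal_fraction * length(idx)))
    causal <- sort(sample(idx, nc))
    p <- geno$allele_freq[causal]
    W <- sweep(geno$dosage[, causal, drop = FALSE], 2, 2 * p, "-") /
      rep(sqrt(2 * p * (1 - p)), each = n)
    beta <- stats::rexp(nc) * sample(c(-1, 1), nc, replace = TRUE)
    list(score = drop(W %*% beta), causal = geno$snp_ids[causal], beta = beta,
         expected_var = sum(beta^2))
  }

  if (config$h2g > 0) {
    gs <- gen_score(0L)
    parts[, "g"] <- .rescale_part(gs$score, config$h2g, config$scale,
                                  gs$expected_var)
    truth$causal_g <- data.frame(snp = gs$causal, beta = gs$beta)
  }
  if (config$h2kin > 0) {
    ks <- gen_score(1L)
    parts[, "k"] <- .rescale_part(ks$score, config$h2kin, config$scale,
                                  ks$expected_var)
    truth$causal_k <- data.frame(snp = ks$causal, beta = ks$beta)
  }
  pr <- pedigree_pairs(ped)
  if (config$ec2 > 0) {
    if (nrow(pr$couples) == 0) stop("couple effect requested but no couples in pedigree")
    parts[, "c"] <- .rescale_part(.group_effect(.env_groups(ped, "couple")),
                                  config$ec2, config$scale)
  }
  if (config$es2 > 0) {
    if (nrow(pr$full_sibs) == 0) stop("sibling effect requested but no full sibs in pedigree")
    parts[, "s"] <- .rescale_part(.group_effect(.env_groups(ped, "sib")),
                                  config$es2, config$scale)
  }
  if (config$ef2 > 0) {
    if (nrow(pr$parent_offspring) + nrow(pr$couples) + nrow(pr$full_sibs) == 0)
      stop("family effect requested but no nuclear-family pairs in pedigree")
    keys <- .env_groups(ped, "family")
    if (config$family_mode == "single") {
      parts[, "f"] <- .rescale_part(.group_effect(keys), config$ef2, config$scale)
    } else {
      # youth + adulthood household draws, half the variance each; identical
      # covariance structure for two-generation families
      parts[, "f"] <- .rescale_part(.group_effect(keys), config$ef2 / 2, config$scale) +
        .rescale_part(.group_effect(keys), config$ef2 / 2, config$scale)
    }
  }
  parts[, "e"] <- .rescale_part(stats::rnorm(n), config$ee2, config$scale)
  y <- rowSums(parts)
  names(y) <- ids
  truth$realized <- apply(parts, 2, stats::var)
  structure(list(y = y, parts = parts, truth = truth), class = "sim_phenotype")
}

#' Z-test of parameter recovery across simulation replicates
#'
#' Tests whether the mean estimate across replicates deviates from the
#' simulated value: `Z = (mean - truth) / (SD / sqrt(R))`, two-sided normal
#' p-value.
#'
#' @param estimates numeric vector of per-replicate estimates (at least 2).
#' @param truth simulated value.
#' @return list with `mean`, `sd`, `z`, `p`, `n`.
#' @export
ztest_recovery <- function(estimates, truth) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) < 2) stop("need at least 2 estimates for a Z-test")
  s <- stats::sd(estimates)
  m <- mean(estimates)
  if (s == 0) {
    # estimates identical: no deviation to test unless they miss the truth
    if (m == truth)
      return(list(mean = m, sd = 0, z = 0, p = 1, n = length(estimates)))
    stop("degenerate Z-test: zero SD across estimates")
  }
  z <- (m - truth) / (s / sqrt(length(estimates)))
  list(mean = m, sd = s, z = z, p = 2 * stats::pnorm(-abs(z)),
       n = length(estimates))
}

#' Build the five component matrices for a cohort
#'
#' GRM from the requested chromosomes (the simulation design uses even
#' chromosomes only), its thresholded close-relative version, and the three
#' environmental matrices.
#'
#' @param geno a [genotype_matrix()].
#' @param ped a [pedigree_table()].
#' @param kin_threshold threshold for the close-relative GRM
#'   (default 0.025).
#' @param chrom_subset chromosomes entering the GRMs (default: even
#'   chromosomes, matching the simulation design; use `NULL` explicitly
#'   via `compute_grm` for all-SNP GRMs).
#' @return named list `G`, `K`, `F`, `S`, `C` of
#'   [relationship_matrix()] objects.
#' @export
model_matrices <- function(geno, ped, kin_threshold = 0.025,
                           chrom_subset = seq(2, 22, by = 2)) {
  grm <- compute_grm(geno, chrom_subset = chrom_subset)
  list(G = grm,
       K = threshold_grm(grm, kin_threshold),
       F = build_erm(ped, "family", ids = geno$sample_ids),
       S = build_erm(ped, "sib", ids = geno$sample_ids),
       C = build_erm(ped, "couple", ids = geno$sample_ids))
}

.TRUTH_KEY <- c(G = "h2g", K = "h2kin", F = "ef2", S = "es2", C = "ec2")

#' Run a simulation scenario study
#'
#' For each scenario, simulates `n_replicates` phenotypes on the supplied
#' cohort and either fits the scenario's model (recording per-component
#' variance-ratio estimates, by default unconstrained so replicate means
#' are unbiased) or runs the stepwise selection procedure (recording the
#' final model per replicate).
#'
#' @param scenarios list of scenarios, each a list with `name`, `config`
#'   (a [sim_config()]) and, for fit mode, `model` (component code such as
#'   `"GKC"`).
#' @param geno,ped the cohort (see [simulate_pedigree()],
#'   [simulate_genotypes()]).
#' @param n_replicates replicates per scenario (default 50).
#' @param seed master seed governing all replicate seeds.
#' @param mode `"fit"` or `"select"`.
#' @param matrices optional precomputed [model_matrices()] list.
#' @param constrain passed to [reml_fit()] (default `FALSE` in fit mode,
#'   `TRUE` in select mode).
#' @param ... further arguments to [reml_fit()] or [stepwise_select()].
#' @return object of class `scenario_study`: `replicates` (long data frame
#'   of per-replicate estimates or selected models) and `summary` (per
#'   scenario and component: mean, SD, 95% CI of the mean, Z and p against
#'   the simulated value; or selection counts).
#' @export
run_scenario_study <- function(scenarios, geno, ped, n_replicates = 50,
                               seed = 1, mode = c("fit", "select"),
                               matrices = NULL,
                               constrain = (mode == "select"), ...) {
  mode <- match.arg(mode)
  stopifnot(n_replicates >= 2)
  if (is.null(matrices)) matrices <- model_matrices(geno, ped)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(scenarios) * n_replicates),
                  nrow = length(scenarios))
  eig_cache <- list()
  rep_rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    comps <- if (mode == "fit") .model_components(sc$model) else names(matrices)
    for (r in seq_len(n_replicates)) {
      cfg <- sc$config
      cfg$seed <- seeds[si, r]
      ph <- simulate_phenotype(geno, ped, cfg)
      if (mode == "fit") {
        ek <- NULL
        if (length(comps) == 1L) {
          if (is.null(eig_cache[[comps]]))
            eig_cache[[comps]] <- eigen(matrices[[comps]]$values, symmetric = TRUE)
          ek <- eig_cache[[comps]]
        }
        fit <- tryCatch(
          reml_fit(ph$y, matrices = matrices[comps], constrain = constrain,
                   eigen_K = ek, ...),
          error = function(e) NULL)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          scenario = sc$name, replicate = r, component = comps,
          estimate = if (is.null(fit)) NA_real_ else unname(fit$ratios[comps]),
          converged = if (is.null(fit)) FALSE else fit$converged)
      } else {
        tr <- tryCatch(
          stepwise_select(ph$y, matrices, constrain = constrain, ...),
          error = function(e) NULL)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          scenario = sc$name, replicate = r, component = NA_character_,
          estimate = NA_real_,
          final_model = if (is.null(tr)) NA_character_ else tr$final_model,
          converged = !is.null(tr))
      }
    }
  }
  reps <- do.call(rbind, rep_rows)
  if (mode == "fit") {
    summ <- do.call(rbind, lapply(seq_along(scenarios), function(si) {
      sc <- scenarios[[si]]
      comps <- .model_components(sc$model)
      do.call(rbind, lapply(comps, function(cc) {
        est <- reps$estimate[reps$scenario == sc$name & reps$component == cc]
        truth <- sc$config[[.TRUTH_KEY[[cc]]]]
        zt <- ztest_recovery(est, truth)
        data.frame(scenario = sc$name, component = cc, truth = truth,
                   mean = zt$mean, sd = zt$sd,
                   ci_lo = zt$mean - 1.96 * zt$sd / sqrt(zt$n),
                   ci_hi = zt$mean + 1.96 * zt$sd / sqrt(zt$n),
                   z = zt$z, p = zt$p, n_used = zt$n,
                   n_failed = sum(is.na(est)))
      }))
    }))
  } else {
    summ <- as.data.frame(table(scenario = reps$scenario,
                                final_model = reps$final_model))
    summ <- summ[summ$Freq > 0, ]
  }
  structure(list(replicates = reps, summary = summ, mode = mode, seed = seed),
            class = "scenario_study")
}

#' @export
print.scenario_study <- function(x, ...) {
  cat("Scenario study (", x$mode, " mode)\n", sep = "")
  if (x$mode == "fit") {
    df <- x$summary
    df[, c("truth", "mean", "sd", "ci_lo", "ci_hi", "z")] <-
      round(df[, c("truth", "mean", "sd", "ci_lo", "ci_hi", "z")], 4)
    df$p <- signif(df$p, 3)
    print(df, row.names = FALSE)
  } else {
    print(x$summary, row.names = FALSE)
  }
  invisible(x)
}
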
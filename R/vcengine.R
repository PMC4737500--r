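#' Fixed-effect design matrix
#'
#' Builds the covariate design for variance-component fits: intercept, sex,
#' age, age squared, sex-by-age interaction, clinic (one-hot, reference
#' level dropped), standardised deprivation index and its square, and
#' leading relationship-matrix eigenvectors.  Only the covariates present
#' in `pheno` are used, so synthetic runs can supply intercept-only or
#' intercept-plus-eigenvector designs.  Collinear columns are dropped with
#' a warning so the returned matrix has full column rank.
#'
#' @param pheno data frame; recognised columns are `sex`, `age`, `clinic`,
#'   `simd` (quantitative deprivation index).
#' @param pcs optional n x k matrix of eigenvectors (e.g. from
#'   [grm_eigenvectors()]), rows aligned with `pheno`.
#' @return numeric design matrix with full column rank and named columns.
#' @export
build_fixed_effects <- function(pheno, pcs = NULL) {
  n <- nrow(pheno)
  dat <- data.frame(row.names = seq_len(n))
  terms <- character(0)
  if ("sex" %in% names(pheno) && length(unique(stats::na.omit(pheno$sex))) > 1) {
    dat$sex <- factor(pheno$sex)
    terms <- c(terms, "sex")
  }
  if ("age" %in% names(pheno)) {
    dat$age <- pheno$age
    terms <- c(terms, "age", "I(age^2)")
    if ("sex" %in% names(dat)) terms <- c(terms, "sex:age")
  }
  if ("clinic" %in% names(pheno) && length(unique(stats::na.omit(pheno$clinic))) > 1) {
    dat$clinic <- factor(pheno$clinic)
    terms <- c(terms, "clinic")
  }
  if ("simd" %in% names(pheno)) {
    dat$simd_std <- as.numeric(scale(pheno$simd))
    terms <- c(terms, "simd_std", "I(simd_std^2)")
  }
  form <- stats::as.formula(paste("~", paste(c("1", terms), collapse = " + ")))
  X <- stats::model.matrix(form, data = dat)
  # model.matrix drops rows with NA covariates; reinstate them as NA rows
  if (nrow(X) < n) {
    full <- matrix(NA_real_, n, ncol(X), dimnames = list(NULL, colnames(X)))
    full[as.integer(rownames(X)), ] <- X
    X <- full
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != n) stop("pcs rows must match phenotype rows")
    if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
  }
  .drop_collinear(X)
}

.drop_collinear <- function(X) {
  ok <- stats::complete.cases(X)
  qr_ <- qr(X[ok, , drop = FALSE])
  if (qr_$rank == 0) stop("fixed-effect design has rank 0")
  if (qr_$rank < ncol(X)) {
    keep <- sort(qr_$pivot[seq_len(qr_$rank)])
    warning("dropping ", ncol(X) - qr_$rank, " collinear design column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X
}

# map relationship-matrix kinds to single-letter model codes
.KIND_LETTER <- c(GRM_g = "G", GRM_kin = "K", ERM_Family = "F",
                  ERM_Sib = "S", ERM_Couple = "C")

.as_component_list <- function(matrices) {
  if (inherits(matrices, "relationship_matrix")) matrices <- list(matrices)
  vals <- lapply(matrices, function(m)
    if (inherits(m, "relationship_matrix")) m$values else as.matrix(m))
  nm <- names(matrices)
  if (is.null(nm)) nm <- rep("", length(matrices))
  for (i in seq_along(matrices)) {
    if (nzchar(nm[i])) next
    if (inherits(matrices[[i]], "relationship_matrix"))
      nm[i] <- .KIND_LETTER[[matrices[[i]]$kind]]
    else nm[i] <- paste0("V", i)
  }
  if (anyDuplicated(nm)) stop("component names must be unique")
  names(vals) <- nm
  vals
}

# ---------------------------------------------------------------------------
# REML state backends: each returns a closure theta -> state list with
# ok, logL, score, AI, tr (tr(P K_c) incl. residual), ydot (y'P K_c P y),
# and at convergence the pieces needed for beta / SEs.

.backend_general <- function(y, X, Ks) {
  n <- length(y); p <- ncol(X)
  C <- length(Ks)
  In <- diag(n)
  function(theta, want_beta = FALSE) {
    V <- In * theta[C + 1L]
    for (c in seq_len(C)) V <- V + theta[c] * Ks[[c]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ok = FALSE))
    ldetV <- 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chT <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chT)) return(list(ok = FALSE))
    ldetT <- 2 * sum(log(diag(chT)))
    Ti <- chol2inv(chT)
    P <- Vi - ViX %*% tcrossprod(Ti, ViX)
    Py <- drop(P %*% y)
    yPy <- sum(y * Py)
    logL <- -0.5 * ((n - p) * log(2 * pi) + ldetV + ldetT + yPy)
    U <- matrix(0, n, C + 1L)
    tr <- numeric(C + 1L)
    for (c in seq_len(C)) {
      U[, c] <- Ks[[c]] %*% Py
      tr[c] <- sum(P * Ks[[c]])
    }
    U[, C + 1L] <- Py
    tr[C + 1L] <- sum(diag(P))
    ydot <- drop(crossprod(U, Py))
    PU <- P %*% U
    AI <- 0.5 * crossprod(U, PU)
    score <- -0.5 * (tr - ydot)
    out <- list(ok = TRUE, logL = logL, score = score, AI = AI,
                tr = tr, ydot = ydot)
    if (want_beta) {
      out$beta <- drop(Ti %*% crossprod(ViX, y))
      out$beta_cov <- Ti
    }
    out
  }
}

# single genetic/environmental component + residual: rotate into the
# component's eigenbasis so every iteration is O(n p^2)
.backend_eigen <- function(y, X, K, decomp = NULL) {
  n <- length(y); p <- ncol(X)
  if (is.null(decomp)) decomp <- eigen(K, symmetric = TRUE)
  lam <- decomp$values
  Ut <- t(decomp$vectors)
  yt <- drop(Ut %*% y)
  Xt <- Ut %*% X
  function(theta, want_beta = FALSE) {
    d <- theta[1L] * lam + theta[2L]
    if (any(d <= 0)) return(list(ok = FALSE))
    w <- 1 / d
    ldetV <- sum(log(d))
    A <- Xt * w
    XtViX <- crossprod(Xt, A)
    chT <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chT)) return(list(ok = FALSE))
    ldetT <- 2 * sum(log(diag(chT)))
    Ti <- chol2inv(chT)
    pmul <- function(v) w * v - drop(A %*% (Ti %*% crossprod(Xt, w * v)))
    Py <- pmul(yt)
    yPy <- sum(yt * Py)
    logL <- -0.5 * ((n - p) * log(2 * pi) + ldetV + ldetT + yPy)
    B <- A %*% Ti
    hat <- rowSums(B * A)                 # diag of ViX (X'ViX)^-1 X'Vi
    tr <- c(sum(w * lam) - sum(lam * hat), sum(w) - sum(hat))
    u1 <- lam * Py
    ydot <- c(sum(u1 * Py), sum(Py * Py))
    Pu1 <- pmul(u1); Pue <- pmul(Py)
    AI <- 0.5 * matrix(c(sum(u1 * Pu1), sum(u1 * Pue),
                         sum(u1 * Pue), sum(Py * Pue)), 2, 2)
    score <- -0.5 * (tr - ydot)
    out <- list(ok = TRUE, logL = logL, score = score, AI = AI,
                tr = tr, ydot = ydot)
    if (want_beta) {
      out$beta <- drop(Ti %*% crossprod(Xt, w * yt))
      out$beta_cov <- Ti
    }
    out
  }
}

.pinv <- function(M, tol = 1e-12) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit a variance-component mixed model by AI-REML
#'
#' Maximises the restricted likelihood of
#' `y = X beta + sum_c u_c + e`, `V = sum_c K_c sigma2_c + I sigma2_e`,
#' by average-information updates after a few EM warm-up steps, with step
#' halving whenever an update would leave the feasible region.  In the
#' default constrained mode negative variance components are projected to
#' zero; the unconstrained mode (used for simulation-based unbiasedness
#' checks) lets estimates go negative as long as `V` stays positive
#' definite.  Single-component models are fitted in the component's
#' eigenbasis, which makes repeated fits against the same matrix cheap.
#'
#' @param y numeric phenotype vector (names, if present, are used to align
#'   named relationship matrices).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param matrices list of [relationship_matrix()] objects or plain
#'   symmetric matrices, one per variance component (residual is implicit).
#'   Unnamed entries are labelled by their kind (`G`, `K`, `F`, `S`, `C`).
#' @param constrain project negative variance estimates to zero
#'   (default `TRUE`).
#' @param max_iter iteration cap (default 100).
#' @param tol_logl,tol_par convergence: relative log-likelihood change below
#'   `tol_logl` (default 1e-8) and maximum relative parameter change below
#'   `tol_par` (default 1e-6).
#' @param em_steps number of EM iterations before switching to AI updates
#'   (default 3).
#' @param start optional numeric vector of starting variances
#'   (components then residual); default splits the phenotypic variance
#'   equally.
#' @param eigen_K optional precomputed `eigen()` of the single component
#'   matrix (after any complete-case alignment); ignored for multi-component
#'   models.
#' @return object of class `reml_fit`: variance estimates `sigma2` (named,
#'   residual last), their `se`, variance `ratios` (each component over the
#'   phenotypic total, residual included) with `se_ratios`, restricted
#'   log-likelihood `logL`, `AI` matrix, fixed effects `beta` with
#'   `se_beta`, sample size `n`, `n_iter`, and `converged` flag.
#' @export
reml_fit <- function(y, X = NULL, matrices = list(), constrain = TRUE,
                     max_iter = 100, tol_logl = 1e-8, tol_par = 1e-6,
                     em_steps = 3, start = NULL, eigen_K = NULL) {
  Ks <- .as_component_list(matrices)
  C <- length(Ks)
  if (is.null(X)) X <- matrix(1, length(y), 1,
                              dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")

  # align matrices to y by names where possible
  ynm <- names(y)
  Ks <- lapply(Ks, function(K) {
    if (!is.null(ynm) && !is.null(rownames(K))) {
      if (!all(ynm %in% rownames(K))) stop("matrix is missing ids present in y")
      K <- K[ynm, ynm, drop = FALSE]
    } else if (nrow(K) != length(y)) {
      stop("matrix dimension does not match length(y)")
    }
    K
  })

  # joint complete cases across y and X
  keep <- !is.na(y) & stats::complete.cases(X)
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    Ks <- lapply(Ks, function(K) K[keep, keep, drop = FALSE])
    eigen_K <- NULL
  }
  X <- .drop_collinear(X)
  n <- length(y); p <- ncol(X)
  if (n <= p + C) stop("too few complete observations for the model")

  varP <- drop(crossprod(stats::lm.fit(X, y)$residuals)) / (n - p)
  theta <- if (!is.null(start)) as.numeric(start) else rep(varP / (C + 1), C + 1)
  if (length(theta) != C + 1) stop("start must have one value per component plus residual")

  state <- if (C == 1L) {
    if (!is.null(eigen_K) && length(eigen_K$values) != n)
      stop("eigen_K dimension does not match the aligned data")
    .backend_eigen(y, X, Ks[[1L]], decomp = eigen_K)
  } else {
    .backend_general(y, X, Ks)
  }

  st <- state(theta)
  if (!st$ok) {
    # equal-split start can be infeasible only in pathological cases
    theta <- c(rep(varP * 1e-3, C), varP)
    st <- state(theta)
    if (!st$ok) stop("V not positive definite at the starting values")
  }
  converged <- FALSE
  it <- 0L
  resid_floor <- 1e-8 * varP
  for (it in seq_len(max_iter)) {
    use_em <- it <= em_steps
    if (use_em) {
      delta <- theta^2 * (st$ydot - st$tr) / n
    } else {
      # components projected to the zero boundary whose gradient points
      # outward stay fixed there (active-set AI step)
      active <- rep(TRUE, C + 1L)
      if (constrain)
        active[seq_len(C)] <- !(theta[seq_len(C)] <= 0 &
                                  st$score[seq_len(C)] < 0)
      delta <- numeric(C + 1L)
      sub <- tryCatch(solve(st$AI[active, active, drop = FALSE],
                            st$score[active]),
                      error = function(e) NULL)
      if (is.null(sub))
        sub <- drop(.pinv(st$AI[active, active, drop = FALSE]) %*%
                      st$score[active])
      delta[active] <- as.numeric(sub)
    }
    prev <- theta
    stn <- NULL
    for (h in 0:30) {
      cand <- prev + delta / 2^h
      if (constrain) {
        cand[seq_len(C)] <- pmax(cand[seq_len(C)], 0)
        cand[C + 1L] <- max(cand[C + 1L], resid_floor)
      }
      s2 <- state(cand)
      # require feasibility; for AI steps also require no sharp logL drop
      if (s2$ok && (use_em || s2$logL >= st$logL - 1e-4 || h == 30)) {
        stn <- s2; theta <- cand; break
      }
    }
    if (is.null(stn))
      stop("V not positive definite at iteration ", it,
           " even after step halving")
    dl <- stn$logL - st$logL
    relpar <- max(abs(theta - prev) / pmax(abs(prev), 1e-8 * varP))
    st <- stn
    if (!use_em && abs(dl) / (abs(st$logL) + 1) < tol_logl &&
        relpar < tol_par) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")

  st <- state(theta, want_beta = TRUE)
  cov_theta <- tryCatch(solve(st$AI), error = function(e) .pinv(st$AI))
  se <- sqrt(pmax(diag(cov_theta), 0))
  nm <- c(names(Ks), "residual")
  names(theta) <- names(se) <- nm
  S <- sum(theta)
  ratios <- theta / S
  J <- (diag(C + 1L) * S - matrix(theta, C + 1L, C + 1L, byrow = FALSE)) / S^2
  cov_r <- J %*% cov_theta %*% t(J)
  se_r <- sqrt(pmax(diag(cov_r), 0))
  names(ratios) <- names(se_r) <- nm
  beta <- st$beta
  names(beta) <- colnames(X)
  structure(
    list(sigma2 = theta, se = se, ratios = ratios, se_ratios = se_r,
         cov_sigma2 = cov_theta, cov_ratios = cov_r, logL = st$logL,
         AI = st$AI, beta = beta,
         se_beta = sqrt(pmax(diag(st$beta_cov), 0)),
         varP = S, n = n, n_iter = it, converged = converged,
         components = names(Ks), constrained = constrain),
    class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: %s + residual, n = %d, logL = %.4f (%s in %d iter)\n",
              if (length(x$components)) paste(x$components, collapse = "")
              else "residual-only",
              x$n, x$logL,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  tab <- data.frame(variance = x$sigma2, se = x$se, ratio = x$ratios,
                    ratio_se = x$se_ratios)
  print(round(tab, 4))
  if (all(c("G", "K") %in% x$components)) {
    hh <- h2gkin(x)
    cat(sprintf("h2(g+kin) = %.4f (se %.4f)\n", hh["estimate"], hh["se"]))
  }
  invisible(x)
}

#' Combined SNP plus pedigree heritability
#'
#' Sum of the SNP-associated and pedigree-associated variance ratios, with a
#' delta-method standard error from the full sampling covariance.
#'
#' @param fit a [reml_fit()] containing components `G` and `K`.
#' @return named vector `estimate`, `se`.
#' @export
h2gkin <- function(fit) {
  if (!all(c("G", "K") %in% fit$components))
    stop("fit must contain both G and K components")
  i <- match(c("G", "K"), names(fit$ratios))
  est <- sum(fit$ratios[i])
  se <- sqrt(sum(fit$cov_ratios[i, i]))
  c(estimate = est, se = se)
}

#' Wald test of a variance component
#'
#' Squared z statistic `(sigma2 / se)^2` referred to a chi-square with one
#' degree of freedom.
#'
#' @param fit a [reml_fit()].
#' @param component component name (e.g. `"G"`).
#' @return list with `statistic` and `p`.
#' @export
wald_test <- function(fit, component) {
  i <- match(component, names(fit$sigma2))
  if (is.na(i)) stop("component '", component, "' not in fit")
  se <- fit$se[i]
  if (se == 0) stop("undefined Wald test: zero standard error")
  stat <- (fit$sigma2[i] / se)^2
  list(statistic = unname(stat), p = stats::pchisq(unname(stat), df = 1,
                                                   lower.tail = FALSE))
}

#' Heritability estimates across relatedness cutoffs
#'
#' For each cutoff, prunes the sample with [grm_prune()], refits the
#' single-GRM model on the retained subset and records the estimate: the
#' design used to show that close relatives inflate SNP-heritability
#' estimates when familial effects are present.
#'
#' @param y named phenotype vector.
#' @param grm a [relationship_matrix()] covering the phenotyped ids.
#' @param cutoffs numeric vector of relatedness cutoffs.
#' @param X optional fixed-effect design (default intercept).
#' @param min_n skip cutoffs that retain fewer individuals (default 30).
#' @param ... further arguments to [reml_fit()].
#' @return data frame with columns `cutoff`, `n_retained`, `h2g`, `se`.
#' @export
h2_vs_cutoff <- function(y, grm, cutoffs, X = NULL, min_n = 30, ...) {
  out <- data.frame(cutoff = numeric(0), n_retained = integer(0),
                    h2g = numeric(0), se = numeric(0))
  for (ct in cutoffs) {
    ids <- grm_prune(grm, ct)
    ids <- intersect(ids, names(y)[!is.na(y)])
    if (length(ids) < min_n) {
      warning(sprintf("cutoff %.3f retains %d < %d individuals; skipped",
                      ct, length(ids), min_n))
      next
    }
    Ksub <- relationship_matrix(grm$values[ids, ids], grm$kind, ids)
    Xs <- if (is.null(X)) NULL else X[match(ids, names(y)), , drop = FALSE]
    fit <- reml_fit(y[ids], X = Xs, matrices = list(G = Ksub), ...)
    out <- rbind(out, data.frame(cutoff = ct, n_retained = length(ids),
                                 h2g = unname(fit$ratios["G"]),
                                 se = unname(fit$se_ratios["G"])))
  }
  out
}

#' Write a fit report in GCTA .hsq-style layout
#'
#' @param fit a [reml_fit()].
#' @param path output file.
#' @export
write_hsq <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Source\tVariance\tSE", con)
  for (nm in names(fit$sigma2))
    writeLines(sprintf("V(%s)\t%.6f\t%.6f", nm, fit$sigma2[nm], fit$se[nm]), con)
  writeLines(sprintf("Vp\t%.6f\tNA", fit$varP), con)
  for (nm in setdiff(names(fit$ratios), "residual"))
    writeLines(sprintf("V(%s)/Vp\t%.6f\t%.6f", nm, fit$ratios[nm],
                       fit$se_ratios[nm]), con)
  writeLines(sprintf("logL\t%.6f", fit$logL), con)
  writeLines(sprintf("n\t%d", fit$n), con)
  writeLines(sprintf("iterations\t%d", fit$n_iter), con)
  writeLines(sprintf("converged\t%s", fit$converged), con)
  invisible(path)
}
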
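.COMPONENTS <- c("G", "K", "F", "S", "C")

#' Enumerate all component combinations
#'
#' Every non-empty subset of the five components (SNP-genetic G,
#' pedigree-genetic K, nuclear-family F, full-sibling S, couple C), in
#' canonical within-model order and listed smallest models first.
#'
#' @return character vector of 31 model codes (e.g. `"GKC"`).
#' @export
enumerate_models <- function() {
  out <- character(0)
  for (k in 1:5)
    out <- c(out, apply(utils::combn(.COMPONENTS, k), 2, paste, collapse = ""))
  out
}

.model_components <- function(model) {
  comps <- strsplit(model, "")[[1]]
  if (!length(comps) || !all(comps %in% .COMPONENTS) || anyDuplicated(comps))
    stop("invalid model code '", model, "'")
  .COMPONENTS[.COMPONENTS %in% comps]   # canonical order
}

#' Likelihood-ratio test for a variance component on its boundary
#'
#' Because the null value (zero variance) lies on the boundary of the
#' parameter space, the test statistic is referred to an equal mixture of a
#' point mass at zero and a chi-square with one degree of freedom:
#' `p = 0.5 * P(chi2_1 >= LR)`, so `LR = 0` gives `p = 0.5`.
#'
#' @param full,reduced [reml_fit()] objects; `reduced`'s components must be
#'   a strict subset of `full`'s.
#' @return p-value.
#' @export
lrt <- function(full, reduced) {
  if (!all(reduced$components %in% full$components) ||
      length(reduced$components) >= length(full$components))
    stop("models are not nested")
  lr <- 2 * (full$logL - reduced$logL)
  if (lr < -1e-6)
    warning(sprintf("negative LR statistic (%.3g) clamped to 0", lr))
  lr <- max(lr, 0)
  0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Backward stepwise selection of variance components
#'
#' Starts from the model containing all supplied components, tests each by a
#' Wald test and a drop-one boundary-mixture LRT, and removes the component
#' (if any) that is non-significant in both tests at `alpha` and has the
#' highest Wald p-value; ties prefer removing the later component in
#' canonical order G, K, F, S, C.  A reduced model that fails to fit or to
#' converge yields an `NA` LRT p-value, in which case the Wald test alone
#' governs that component.  The loop repeats until every remaining
#' component is significant in at least one test (or none remain).
#'
#' @param y phenotype vector.
#' @param matrices named list of the candidate component matrices
#'   (names from G, K, F, S, C).
#' @param X fixed-effect design (default intercept).
#' @param alpha significance level (default 0.05).
#' @param lrt_all compute the LRT for every component (default); when
#'   `FALSE`, LRTs are only computed for components whose Wald test is
#'   already non-significant (the only ones a removal decision needs),
#'   and other entries are `NA`.
#' @param ... further arguments to [reml_fit()] (all selection fits are
#'   constrained unless overridden).
#' @return object of class `selection_trace`: data frame `steps` (one row
#'   per component per step with its variance estimate, Wald and LRT
#'   p-values and the action taken), `final_model` code, `final_fit`, and
#'   `alpha`.
#' @export
stepwise_select <- function(y, matrices, X = NULL, alpha = 0.05,
                            lrt_all = TRUE, ...) {
  matrices <- .as_component_list(matrices)
  if (!all(names(matrices) %in% .COMPONENTS))
    stop("matrix names must be among ", paste(.COMPONENTS, collapse = ", "))
  current <- .COMPONENTS[.COMPONENTS %in% names(matrices)]
  steps <- data.frame(step = integer(0), model = character(0),
                      component = character(0), sigma2 = numeric(0),
                      wald_p = numeric(0), lrt_p = numeric(0),
                      action = character(0))
  fit <- tryCatch(
    reml_fit(y, X = X, matrices = matrices[current], ...),
    error = function(e) stop("initial full-model fit failed: ",
                             conditionMessage(e)))
  step <- 0L
  repeat {
    step <- step + 1L
    model_code <- paste(current, collapse = "")
    wald_p <- vapply(current, function(cc) wald_test(fit, cc)$p, numeric(1))
    lrt_p <- rep(NA_real_, length(current))
    names(lrt_p) <- current
    need_lrt <- if (lrt_all) current else current[wald_p > alpha]
    for (cc in need_lrt) {
      red_comps <- setdiff(current, cc)
      red <- tryCatch(suppressWarnings({
        if (length(red_comps) == 0) {
          reml_fit(y, X = X, matrices = list(), ...)
        } else {
          i <- match(red_comps, current)
          reml_fit(y, X = X, matrices = matrices[red_comps],
                   start = fit$sigma2[c(i, length(current) + 1L)], ...)
        }
      }), error = function(e) NULL)
      if (!is.null(red) && red$converged)
        lrt_p[cc] <- lrt(fit, red)
    }
    removable <- wald_p > alpha & (is.na(lrt_p) | lrt_p > alpha)
    action <- rep("keep", length(current))
    removed <- NULL
    if (any(removable)) {
      # highest Wald p; ties fall to the later canonical component
      cand <- which(removable & wald_p == max(wald_p[removable]))
      removed <- current[cand[length(cand)]]
      action[match(removed, current)] <- "remove"
      if (removed == "G")
        warning("removing the SNP-genetic component G from the model")
    }
    steps <- rbind(steps, data.frame(
      step = step, model = model_code, component = current,
      sigma2 = unname(fit$sigma2[current]), wald_p = unname(wald_p),
      lrt_p = unname(lrt_p), action = action))
    if (is.null(removed)) break
    old <- current
    current <- setdiff(current, removed)
    if (length(current) == 0) {
      fit <- reml_fit(y, X = X, matrices = list(), ...)
      break
    }
    fit <- reml_fit(y, X = X, matrices = matrices[current],
                    start = fit$sigma2[c(match(current, old),
                                         length(old) + 1L)], ...)
  }
  structure(list(steps = steps,
                 final_model = if (length(current)) paste(current, collapse = "")
                               else "residual-only",
                 final_fit = fit, alpha = alpha),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Stepwise variance-component selection (alpha =", x$alpha, ")\n")
  df <- x$steps
  df$wald_p <- signif(df$wald_p, 3)
  df$lrt_p <- signif(df$lrt_p, 3)
  df$sigma2 <- signif(df$sigma2, 3)
  print(df, row.names = FALSE)
  cat("final model:", x$final_model, "\n")
  invisible(x)
}

#' Export a selection trace as TSV
#'
#' @param trace a [stepwise_select()] result.
#' @param path output file.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.table(trace$steps, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}
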
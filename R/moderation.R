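# Stratified causal-effect estimation with sex-heterogeneity testing and
# moderator (age) meta-regression.

#' Stratified MR estimates
#'
#' Splits the cohort by a stratifying variable (optionally binned at
#' `cutpoints`) and runs the supplied estimator in each stratum with
#' identical instruments and settings. A stratum whose fit fails (e.g. too
#' few rows) is recorded as an error while the remaining strata proceed.
#'
#' @param cohort Data frame of phenotypes.
#' @param geno [genotype_matrix()] or dosage matrix (subset per stratum).
#' @param by Column name of the stratifying variable.
#' @param cutpoints Optional numeric cutpoints: strata are the half-open
#'   intervals of `cut(..., include.lowest = TRUE)`; the moderator value is
#'   the bin midpoint. Without cutpoints each distinct value is a stratum
#'   and is its own moderator value.
#' @param estimator Function `(cohort_subset, geno_subset)` returning a list
#'   or vector with elements `beta` and `se` (first exposure used if
#'   several), e.g. a wrapper around [tsls_uvmr()].
#' @return Data frame of class `stratum_estimates`: one row per stratum with
#'   `stratum`, `moderator`, `beta`, `se`, `n`, `error`.
#' @export
stratified_estimates <- function(cohort, geno, by, cutpoints = NULL,
                                 estimator) {
  v <- cohort[[by]]
  if (is.null(v)) .stopf("stratifying column '%s' not found", by)
  if (is.null(cutpoints)) {
    fac <- factor(v)
    mid <- suppressWarnings(as.numeric(levels(fac)))
  } else {
    fac <- cut(v, breaks = cutpoints, include.lowest = TRUE)
    mid <- (cutpoints[-length(cutpoints)] + cutpoints[-1L]) / 2
  }
  G <- .instrument_matrix(geno)
  out <- data.frame(stratum = levels(fac), moderator = mid,
                    beta = NA_real_, se = NA_real_,
                    n = as.integer(table(fac)[levels(fac)]),
                    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(levels(fac))) {
    rows <- which(fac == levels(fac)[i])
    if (length(rows) == 0L) { out$error[i] <- "empty stratum"; next }
    res <- tryCatch(
      estimator(cohort[rows, , drop = FALSE], G[rows, , drop = FALSE]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$beta[i] <- res$beta[1L]
      out$se[i] <- res$se[1L]
    }
  }
  class(out) <- c("stratum_estimates", "data.frame")
  out
}

#' Fisher z test for heterogeneity between two estimates
#'
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided normal p-value;
#' the standard test for sex-specific causal-effect differences.
#'
#' @param b1,se1 First estimate and SE.
#' @param b2,se2 Second estimate and SE.
#' @return List with `z` and `p`.
#' @export
fisher_z_heterogeneity <- function(b1, se1, b2, se2) {
  if (!is.finite(se1) || !is.finite(se2) || se1 <= 0 || se2 <= 0) {
    .stopf("standard errors must be positive")
  }
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Inverse-variance-weighted meta-regression over a moderator
#'
#' Fixed-effect (inverse-variance) meta-regression of stratum causal
#' estimates on the centred moderator, optionally with a centred quadratic
#' term, via `metafor::rma(method = "FE")`. Reports the residual
#' heterogeneity Q of the full model and `Q_diff = Q(intercept-only) -
#' Q(full)` with df equal to the number of added moderator terms — the
#' nested-model comparison asking whether the moderator explains effect
#' heterogeneity.
#'
#' @param estimates A `stratum_estimates` data frame (or any data frame with
#'   `beta`, `se`), error rows dropped.
#' @param moderator Per-stratum moderator values; defaults to the
#'   `moderator` column of `estimates`.
#' @param quadratic Add a centred quadratic term.
#' @return Object of class `meta_regression`: `coef`, `se`, `ci_lower`,
#'   `ci_upper`, `p` per term, `Q`, `Q_df`, `Q_p`, `Q_diff`, `Q_diff_df`,
#'   `Q_diff_p`, `n_strata`.
#' @export
meta_regression <- function(estimates, moderator = NULL, quadratic = FALSE) {
  est <- as.data.frame(estimates)
  if (is.null(moderator)) moderator <- est$moderator
  ok <- is.finite(est$beta) & is.finite(est$se) & is.finite(moderator)
  est <- est[ok, , drop = FALSE]
  moderator <- moderator[ok]
  k <- nrow(est)
  n_terms <- if (quadratic) 2L else 1L
  if (k < n_terms + 2L) {
    .stopf("need at least %d strata for %s meta-regression", n_terms + 2L,
           if (quadratic) "quadratic" else "linear")
  }
  xc <- moderator - mean(moderator)
  mods <- if (quadratic) cbind(moderator = xc, moderator_sq = xc^2)
          else cbind(moderator = xc)
  fit <- metafor::rma(yi = est$beta, sei = est$se, mods = mods, method = "FE")
  fit0 <- metafor::rma(yi = est$beta, sei = est$se, method = "FE")
  q_diff <- max(fit0$QE - fit$QE, 0)
  structure(list(
    coef = stats::setNames(as.numeric(fit$beta), rownames(fit$beta)),
    se = stats::setNames(as.numeric(fit$se), rownames(fit$beta)),
    ci_lower = stats::setNames(as.numeric(fit$ci.lb), rownames(fit$beta)),
    ci_upper = stats::setNames(as.numeric(fit$ci.ub), rownames(fit$beta)),
    p = stats::setNames(as.numeric(fit$pval), rownames(fit$beta)),
    Q = fit$QE, Q_df = k - n_terms - 1L, Q_p = fit$QEp,
    Q_intercept_only = fit0$QE,
    Q_diff = q_diff, Q_diff_df = n_terms,
    Q_diff_p = stats::pchisq(q_diff, n_terms, lower.tail = FALSE),
    n_strata = k, moderator_center = mean(moderator)
  ), class = "meta_regression")
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf("<meta_regression> %d strata\n", x$n_strata))
  tab <- data.frame(coef = x$coef, se = x$se, ci_lower = x$ci_lower,
                    ci_upper = x$ci_upper, p = x$p)
  print(round(tab, 4))
  cat(sprintf("Q = %.3f (df %d, p %.3g); Q_diff = %.3f (df %d, p %.3g)\n",
              x$Q, x$Q_df, x$Q_p, x$Q_diff, x$Q_diff_df, x$Q_diff_p))
  invisible(x)
}
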
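# Difference-method MR mediation with non-parametric and Bayesian bootstrap
# uncertainty for the mediated proportion pi_m = (total - direct) / total.

#' Mediated proportion
#'
#' `pi_m = (beta_total - beta_direct) / beta_total`. The proportion is only
#' interpretable when the indirect and total effects share sign; the returned
#' flag records this.
#'
#' @param beta_total Total effect (UVMR).
#' @param beta_direct Direct effect (MVMR).
#' @return List with `pi_m` and logical `sign_consistent`.
#' @export
pi_m <- function(beta_total, beta_direct) {
  if (!is.finite(beta_total) || beta_total == 0) {
    .stopf("mediated proportion undefined: total effect is zero")
  }
  indirect <- beta_total - beta_direct
  list(pi_m = indirect / beta_total,
       sign_consistent = indirect == 0 || sign(indirect) == sign(beta_total))
}

#' Non-parametric bootstrap weights
#'
#' Resampling with replacement expressed as weights: each draw is a
#' multinomial count vector divided by n, so weighted estimation with a draw
#' reproduces the resampled fit.
#'
#' @param n Number of individuals.
#' @param B Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @return `B x n` matrix of nonnegative weights, each row summing to 1;
#'   class `bootstrap_weights` with `method = "np"`.
#' @export
draw_np_bootstrap <- function(n, B, seed = NULL) {
  if (B < 1L) .stopf("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  W <- t(stats::rmultinom(B, size = n, prob = rep(1 / n, n))) / n
  structure(W, class = c("bootstrap_weights", "matrix"),
            method = "np", seed = seed)
}

#' Bayesian bootstrap weights
#'
#' Rubin's Bayesian bootstrap: each draw is Dirichlet(1, ..., 1) over the n
#' individuals (normalised unit-rate exponentials), so every iteration uses
#' the complete data with strictly positive weights — smoother than
#' resampling for sparse binary outcomes.
#'
#' @inheritParams draw_np_bootstrap
#' @return `B x n` weight matrix as in [draw_np_bootstrap()], `method =
#'   "bb"`.
#' @export
draw_bayesian_bootstrap <- function(n, B, seed = NULL) {
  if (B < 1L) .stopf("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  E <- matrix(stats::rexp(B * n), nrow = B, ncol = n)
  W <- E / rowSums(E)
  structure(W, class = c("bootstrap_weights", "matrix"),
            method = "bb", seed = seed)
}

# Precompute design matrices so the bootstrap loop only does weighted solves.
#' @keywords internal
.prep_mediation <- function(cohort, geno, x, m, y, x_snps, m_snps,
                            covariates = NULL, outcome_type = "continuous") {
  G <- .instrument_matrix(geno)
  miss <- setdiff(c(x_snps, m_snps), colnames(G))
  if (length(miss)) .stopf("dosage columns missing: %s", paste(miss, collapse = ", "))
  n <- nrow(cohort)
  C <- .as_covmat(covariates, n)
  Gx <- G[, x_snps, drop = FALSE]
  Gm <- G[, m_snps, drop = FALSE]
  list(
    Zx = cbind(1, Gx, C),
    Zxm = cbind(1, Gx, Gm, C),
    C = C,
    x = cohort[[x]], m = cohort[[m]], y = cohort[[y]],
    binary = outcome_type == "binary",
    n = n
  )
}

# One weighted mediation fit: total (UVMR), direct (MVMR), indirect by
# subtraction. Returns NULL on refit failure (e.g. weighted logistic
# non-convergence) so the bootstrap caller can count and drop it.
#' @keywords internal
.mediation_fit <- function(prep, w = NULL, starts = NULL) {
  fit_stage1 <- function(Z, resp) {
    if (is.null(w)) {
      qr.fitted(qr(Z), resp)
    } else {
      Zw <- Z * w
      Z %*% solve(crossprod(Z, Zw), crossprod(Zw, resp))
    }
  }
  stage2 <- function(A, start) {
    if (prep$binary) .fast_logit(A, prep$y, w, start = start)
    else .wls_coef(A, prep$y, w)
  }
  out <- tryCatch({
    xhat <- drop(fit_stage1(prep$Zx, prep$x))
    c2 <- stage2(cbind(1, xhat, prep$C), starts$total)
    if (is.null(c2)) return(NULL)
    XM <- fit_stage1(prep$Zxm, cbind(prep$x, prep$m))
    c3 <- stage2(cbind(1, XM, prep$C), starts$direct)
    if (is.null(c3)) return(NULL)
    c(beta_total = unname(c2[2L]), beta_direct = unname(c3[2L]),
      beta_indirect = unname(c2[2L] - c3[2L]))
  }, error = function(e) NULL)
  if (!is.null(out) && any(!is.finite(out))) return(NULL)
  out
}

# as .mediation_fit but also returns the full stage-2 coefficient vectors,
# used to warm-start the bootstrap refits
#' @keywords internal
.mediation_fit_full <- function(prep) {
  xhat <- drop(qr.fitted(qr(prep$Zx), prep$x))
  XM <- qr.fitted(qr(prep$Zxm), cbind(prep$x, prep$m))
  s2 <- function(A) {
    if (prep$binary) .fast_logit(A, prep$y) else .wls_coef(A, prep$y)
  }
  c2 <- s2(cbind(1, xhat, prep$C))
  c3 <- s2(cbind(1, XM, prep$C))
  if (is.null(c2) || is.null(c3)) return(NULL)
  list(total = c2, direct = c3)
}

#' Single mediation estimate (difference method)
#'
#' Total effect of X on Y by UVMR (instrumented by `x_snps`), direct effect
#' by MVMR of Y on genetically predicted X and M jointly (instruments
#' `x_snps` plus `m_snps`), indirect effect by subtraction
#' `beta_indirect = beta_total - beta_direct`. Optional per-person weights
#' apply to every regression stage.
#'
#' @param cohort Data frame holding the phenotype columns.
#' @param geno [genotype_matrix()] (or dosage matrix) with all instruments.
#' @param x,m,y Column names of exposure, mediator and outcome in `cohort`.
#' @param x_snps,m_snps Instrument column names for X and M.
#' @param covariates Optional covariate matrix / data frame.
#' @param outcome_type `"continuous"` or `"binary"` (logistic second stages).
#' @param weights Optional nonnegative per-person weights (e.g. one row of a
#'   [draw_bayesian_bootstrap()] matrix).
#' @return Named vector `beta_total`, `beta_direct`, `beta_indirect`.
#' @export
estimate_mediation <- function(cohort, geno, x, m, y, x_snps, m_snps,
                               covariates = NULL,
                               outcome_type = c("continuous", "binary"),
                               weights = NULL) {
  outcome_type <- match.arg(outcome_type)
  prep <- .prep_mediation(cohort, geno, x, m, y, x_snps, m_snps, covariates,
                          outcome_type)
  est <- .mediation_fit(prep, weights)
  if (is.null(est)) .stopf("mediation fit failed (degenerate stage or non-convergence)")
  est
}

#' Bootstrap mediation analysis
#'
#' Runs [estimate_mediation()] under every bootstrap weight draw
#' (non-parametric resampling or Bayesian Dirichlet weights). The mediated
#' proportion is summarised by the median of the per-draw ratios and a
#' percentile (2.5th, 97.5th) interval. Failed refits are dropped and
#' counted; more than 5% failures is an error so silent bias cannot hide.
#'
#' @inheritParams estimate_mediation
#' @param method `"bb"` (Bayesian bootstrap, default) or `"np"`
#'   (non-parametric).
#' @param B Number of bootstrap draws.
#' @param seed Integer seed for the weight draws.
#' @return Object of class `mediation_result`: point estimates (unweighted),
#'   `pi_m` (median of draws), `ci`, per-draw record, failure count and the
#'   sign-consistency flag.
#' @export
bootstrap_mediation <- function(cohort, geno, x, m, y, x_snps, m_snps,
                                covariates = NULL,
                                outcome_type = c("continuous", "binary"),
                                method = c("bb", "np"), B = 1000, seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  method <- match.arg(method)
  if (B < 1L) .stopf("B must be >= 1")
  prep <- .prep_mediation(cohort, geno, x, m, y, x_snps, m_snps, covariates,
                          outcome_type)
  point <- .mediation_fit(prep, NULL)
  if (is.null(point)) .stopf("mediation point estimate failed")
  starts <- if (prep$binary) .mediation_fit_full(prep) else NULL
  W <- if (method == "bb") draw_bayesian_bootstrap(prep$n, B, seed)
       else draw_np_bootstrap(prep$n, B, seed)
  draws <- matrix(NA_real_, B, 3L,
                  dimnames = list(NULL, c("beta_total", "beta_direct", "beta_indirect")))
  for (b in seq_len(B)) {
    est <- .mediation_fit(prep, W[b, ], starts = starts)
    if (!is.null(est)) draws[b, ] <- est
  }
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * B) {
    .stopf("bootstrap refit failure rate %.1f%% exceeds 5%% (B = %d, failed = %d)",
           100 * n_failed / B, B, n_failed)
  }
  d <- as.data.frame(draws[ok, , drop = FALSE])
  d$pi_m <- d$beta_indirect / d$beta_total
  pm <- pi_m(point[["beta_total"]], point[["beta_direct"]])
  structure(list(
    beta_total = point[["beta_total"]],
    beta_direct = point[["beta_direct"]],
    beta_indirect = point[["beta_indirect"]],
    pi_m = stats::median(d$pi_m),
    ci = stats::quantile(d$pi_m, c(0.025, 0.975), names = FALSE),
    sign_consistent = pm$sign_consistent,
    method = method, B = B, n_failed = n_failed,
    draws = d, seed = seed, outcome_type = outcome_type
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result: %s bootstrap, B = %d (%d refits failed)>\n",
              x$method, x$B, x$n_failed))
  cat(sprintf("  total = %.4f  direct = %.4f  indirect = %.4f\n",
              x$beta_total, x$beta_direct, x$beta_indirect))
  cat(sprintf("  pi_m = %.4f (%.4f, %.4f)%s\n", x$pi_m, x$ci[1], x$ci[2],
              if (x$sign_consistent) "" else "  [indirect and total disagree in sign: not interpretable as a proportion]"))
  invisible(x)
}

#' Three-exposure mediation (mediator genetically proxied)
#'
#' MVMR with both exposures and the mediator as jointly predicted exposures,
#' the mediator instrumented by a single genetic risk score. Per-exposure
#' total effects come from UVMR on each exposure's own instruments; direct
#' effects from the three-exposure MVMR; per-exposure mediated proportions
#' through the mediator get bootstrap intervals.
#'
#' @param cohort Data frame with phenotype columns.
#' @param geno [genotype_matrix()] or dosage matrix with the exposure
#'   instruments.
#' @param x1,x2,mediator,y Column names in `cohort`.
#' @param x1_snps,x2_snps Instrument columns for the two exposures.
#' @param mediator_score Per-person genetic risk score instrumenting the
#'   mediator (see [genetic_risk_score()]); must be non-degenerate.
#' @inheritParams bootstrap_mediation
#' @return Named list of `mediation_result` objects, one per exposure.
#' @export
three_exposure_mediation <- function(cohort, geno, x1, x2, mediator, y,
                                     x1_snps, x2_snps, mediator_score,
                                     covariates = NULL,
                                     outcome_type = c("continuous", "binary"),
                                     method = c("bb", "np"), B = 1000,
                                     seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  method <- match.arg(method)
  if (stats::sd(mediator_score) == 0) {
    .stopf("degenerate first stage: mediator genetic risk score has zero variance")
  }
  G <- .instrument_matrix(geno)
  n <- nrow(cohort)
  C <- .as_covmat(covariates, n)
  binary <- outcome_type == "binary"
  Zall <- cbind(1, G[, c(x1_snps, x2_snps), drop = FALSE], grs = mediator_score, C)
  if (qr(Zall)$rank < ncol(Zall)) .stopf("degenerate first stage: combined instrument design is rank deficient")
  Z1 <- cbind(1, G[, x1_snps, drop = FALSE], C)
  Z2 <- cbind(1, G[, x2_snps, drop = FALSE], C)
  resp <- cbind(cohort[[x1]], cohort[[x2]], cohort[[mediator]])
  yv <- cohort[[y]]

  fit_all <- function(w) {
    s1 <- function(Z, r) {
      if (is.null(w)) qr.fitted(qr(Z), r)
      else { Zw <- Z * w; Z %*% solve(crossprod(Z, Zw), crossprod(Zw, r)) }
    }
    stage2 <- function(A) {
      if (binary) {
        f <- .wlogit_fit(A, yv, w)
        if (is.null(f)) return(NULL)
        f$coef
      } else .wls_coef(A, yv, w)
    }
    t1 <- stage2(cbind(1, drop(s1(Z1, resp[, 1L])), C)); if (is.null(t1)) return(NULL)
    t2 <- stage2(cbind(1, drop(s1(Z2, resp[, 2L])), C)); if (is.null(t2)) return(NULL)
    XMhat <- s1(Zall, resp)
    dd <- stage2(cbind(1, XMhat, C)); if (is.null(dd)) return(NULL)
    out <- c(total1 = unname(t1[2L]), total2 = unname(t2[2L]),
             direct1 = unname(dd[2L]), direct2 = unname(dd[3L]))
    if (any(!is.finite(out))) NULL else out
  }

  point <- fit_all(NULL)
  if (is.null(point)) .stopf("three-exposure mediation point estimate failed")
  W <- if (method == "bb") draw_bayesian_bootstrap(n, B, seed)
       else draw_np_bootstrap(n, B, seed)
  draws <- matrix(NA_real_, B, 4L, dimnames = list(NULL, names(point)))
  for (b in seq_len(B)) {
    est <- tryCatch(fit_all(W[b, ]), error = function(e) NULL)
    if (!is.null(est)) draws[b, ] <- est
  }
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * B) {
    .stopf("bootstrap refit failure rate %.1f%% exceeds 5%%", 100 * n_failed / B)
  }
  build <- function(total_col, direct_col, tot, dir) {
    d <- data.frame(beta_total = draws[ok, total_col],
                    beta_direct = draws[ok, direct_col])
    d$beta_indirect <- d$beta_total - d$beta_direct
    d$pi_m <- d$beta_indirect / d$beta_total
    pm <- pi_m(tot, dir)
    structure(list(
      beta_total = tot, beta_direct = dir, beta_indirect = tot - dir,
      pi_m = stats::median(d$pi_m),
      ci = stats::quantile(d$pi_m, c(0.025, 0.975), names = FALSE),
      sign_consistent = pm$sign_consistent,
      method = method, B = B, n_failed = n_failed,
      draws = d, seed = seed, outcome_type = outcome_type
    ), class = "mediation_result")
  }
  list(
    exposure1 = build("total1", "direct1", point[["total1"]], point[["direct1"]]),
    exposure2 = build("total2", "direct2", point[["total2"]], point[["direct2"]])
  )
}
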
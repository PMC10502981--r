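# Individual-level MR estimators: observational baselines, univariable and
# multivariable two-stage least squares (continuous and binary outcomes),
# Sargan over-identification testing, and principal-component MR for
# correlated cis instruments.

#' @keywords internal
new_mr_estimate <- function(method, beta, se, n, level = 0.95,
                            diagnostics = list(), heterogeneity = NULL,
                            note = NULL) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- list(
    method = method,
    beta = beta,
    se = se,
    ci_lower = beta - z * se,
    ci_upper = beta + z * se,
    level = level,
    n = n,
    p = 2 * stats::pnorm(-abs(beta / se)),
    diagnostics = diagnostics,
    heterogeneity = heterogeneity,
    note = note
  )
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate: %s>  n = %d\n", x$method, x$n))
  tab <- data.frame(beta = x$beta, se = x$se,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper, p = x$p)
  rownames(tab) <- names(x$beta) %||% "exposure"
  print(round(tab, 4))
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("Sargan Q = %.3f, df = %d, p = %.3g\n",
                x$heterogeneity$statistic, x$heterogeneity$df,
                x$heterogeneity$p))
  }
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Observational exposure-outcome association
#'
#' Covariate-adjusted linear (continuous outcome) or logistic (binary
#' outcome) regression of the outcome on the observed exposure: the
#' confounded baseline the MR estimators are compared against.
#'
#' @param exposure Numeric exposure vector.
#' @param outcome Outcome vector (numeric, or 0/1 for binary).
#' @param covariates Optional covariate data frame / matrix.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return An `mr_estimate`.
#' @export
observational_association <- function(exposure, outcome, covariates = NULL,
                                      outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  n <- length(outcome)
  C <- .as_covmat(covariates, n)
  cc <- stats::complete.cases(exposure, outcome, if (is.null(C)) rep(0, n) else C)
  exposure <- exposure[cc]; outcome <- outcome[cc]
  if (!is.null(C)) C <- C[cc, , drop = FALSE]
  p_par <- 2L + if (is.null(C)) 0L else ncol(C)
  if (sum(cc) < p_par + 2L) .stopf("too few complete cases (%d)", sum(cc))
  A <- cbind(`(Intercept)` = 1, exposure = exposure, C)
  if (outcome_type == "continuous") {
    fit <- .wls_fit(A, outcome)
    beta <- fit$coef[2L]; se <- sqrt(fit$vcov[2L, 2L])
  } else {
    fit <- .wlogit_fit(A, outcome)
    if (is.null(fit)) {
      return(new_mr_estimate("observational", stats::setNames(NA_real_, "exposure"),
                             NA_real_, sum(cc),
                             note = "logistic fit failed (separation or non-convergence)"))
    }
    beta <- fit$coef[2L]; se <- sqrt(fit$vcov[2L, 2L])
  }
  new_mr_estimate("observational", stats::setNames(beta, "exposure"), se, sum(cc))
}

# Shared TSLS engine. X is an n x K exposure matrix; stage 1 regresses every
# exposure on all instruments (+ covariates), stage 2 regresses the outcome on
# the predicted exposures (+ covariates), linear or logistic. Continuous
# outcomes get proper IV standard errors (residuals from the observed
# exposures). Optional analysis weights apply to every stage.
#' @keywords internal
.tsls_fit <- function(G, X, y, C = NULL, binary = FALSE, w = NULL,
                      robust_se = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); K <- ncol(X)
  Z1 <- cbind(1, G, C)
  if (qr(Z1)$rank < ncol(Z1)) .stopf("stage-1 design is rank deficient")
  Xhat <- if (is.null(w)) {
    qr.fitted(qr(Z1), X)
  } else {
    Z1w <- Z1 * w
    Z1 %*% solve(crossprod(Z1, Z1w), crossprod(Z1w, X))
  }
  colnames(Xhat) <- colnames(X) %||% paste0("exposure", seq_len(K))
  Z2 <- cbind(1, Xhat, C)
  ex_idx <- 1L + seq_len(K)
  if (binary) {
    fit <- .wlogit_fit(Z2, y, w)
    if (is.null(fit)) .stopf("stage-2 logistic fit failed to converge")
    beta <- fit$coef[ex_idx]
    vc <- fit$vcov[ex_idx, ex_idx, drop = FALSE]
    resid <- NULL
  } else {
    ww <- if (is.null(w)) rep(1, n) else w
    ZtZ <- crossprod(Z2, Z2 * ww)
    coefs <- tryCatch(drop(solve(ZtZ, crossprod(Z2 * ww, y))),
                      error = function(e) .stopf("stage-2 design is degenerate (collinear predicted exposures)"))
    Zobs <- cbind(1, X, C)
    resid <- y - drop(Zobs %*% coefs)
    p <- ncol(Z2)
    if (robust_se) {
      meat <- crossprod(Z2 * (ww * resid))
      bread <- solve(ZtZ)
      vcov <- bread %*% meat %*% bread
    } else {
      sigma2 <- sum(ww * resid^2) / (n - p)
      vcov <- sigma2 * solve(ZtZ)
    }
    beta <- coefs[ex_idx]
    vc <- vcov[ex_idx, ex_idx, drop = FALSE]
  }
  names(beta) <- colnames(Xhat)
  list(beta = beta, se = sqrt(diag(vc)), vcov = vc, xhat = Xhat, resid = resid)
}

#' Univariable two-stage least squares MR
#'
#' Stage 1 regresses the exposure on the instruments (plus covariates); stage
#' 2 regresses the outcome on the genetically predicted exposure (linear for
#' continuous outcomes, logistic for binary — two-stage predictor
#' substitution). The estimate is the effect of 1 SD of exposure (log-odds
#' scale for binary outcomes) when the exposure is standardised. Mean and
#' joint first-stage F statistics are attached, and the Sargan test when the
#' model is over-identified (continuous outcomes).
#'
#' @param instruments [genotype_matrix()], dosage matrix, or a single genetic
#'   risk score vector.
#' @param exposure,outcome Numeric vectors.
#' @param covariates Optional covariates (e.g. age, sex, assessment centre,
#'   genetic principal components).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param weights Optional per-person analysis weights.
#' @param robust_se Heteroskedasticity-robust stage-2 SEs (continuous only).
#' @return An `mr_estimate`.
#' @export
tsls_uvmr <- function(instruments, exposure, outcome, covariates = NULL,
                      outcome_type = c("continuous", "binary"),
                      weights = NULL, robust_se = FALSE) {
  outcome_type <- match.arg(outcome_type)
  G <- .instrument_matrix(instruments)
  if (is.null(dim(G))) G <- matrix(G, ncol = 1L, dimnames = list(NULL, "score"))
  n <- length(exposure)
  C <- .as_covmat(covariates, n)
  fit <- .tsls_fit(G, matrix(exposure, dimnames = list(NULL, "exposure")),
                   outcome, C, binary = outcome_type == "binary", w = weights,
                   robust_se = robust_se)
  diag_f <- mean_f_statistic(G, exposure, covariates)
  het <- NULL
  if (ncol(G) > 1L && outcome_type == "continuous" && is.null(weights)) {
    het <- .sargan_from_resid(fit$resid, G, C)
  }
  new_mr_estimate("tsls_uvmr", fit$beta, fit$se, n,
                  diagnostics = list(mean_f = diag_f$mean_f,
                                     joint_f = diag_f$joint_f),
                  heterogeneity = het)
}

#' Multivariable two-stage least squares MR
#'
#' All exposures are predicted from the full instrument set in stage 1; stage
#' 2 jointly regresses the outcome on all predicted exposures, giving direct
#' (conditional) causal effects. Sanderson-Windmeijer conditional F
#' statistics are attached; an estimate with conditional F below 1 is
#' returned but flagged weak.
#'
#' @param instruments [genotype_matrix()] or dosage matrix (all instruments).
#' @param exposures Matrix / data frame of exposures (columns named).
#' @inheritParams tsls_uvmr
#' @return An `mr_estimate` with per-exposure effects.
#' @export
tsls_mvmr <- function(instruments, exposures, outcome, covariates = NULL,
                      outcome_type = c("continuous", "binary"),
                      weights = NULL, robust_se = FALSE) {
  outcome_type <- match.arg(outcome_type)
  G <- .instrument_matrix(instruments)
  X <- as.matrix(exposures)
  if (ncol(G) < ncol(X)) .stopf("need at least as many instruments as exposures")
  n <- nrow(X)
  C <- .as_covmat(covariates, n)
  fit <- .tsls_fit(G, X, outcome, C, binary = outcome_type == "binary",
                   w = weights, robust_se = robust_se)
  cf <- tryCatch(conditional_f(G, X, covariates), warning = function(w) {
    suppressWarnings(conditional_f(G, X, covariates))
  })
  note <- if (any(cf < 1)) "conditionally weak instruments (conditional F < 1)" else NULL
  het <- NULL
  if (ncol(G) > ncol(X) && outcome_type == "continuous" && is.null(weights)) {
    het <- .sargan_from_resid(fit$resid, G, C)
    het$df <- ncol(G) - ncol(X)
    het$p <- stats::pchisq(het$statistic, het$df, lower.tail = FALSE)
  }
  new_mr_estimate("tsls_mvmr", fit$beta, fit$se, n,
                  diagnostics = list(conditional_f = cf),
                  heterogeneity = het, note = note)
}

#' @keywords internal
.sargan_from_resid <- function(resid, G, C) {
  n <- length(resid)
  Z <- cbind(1, G, C)
  fit <- qr.fitted(qr(Z), resid)
  rss <- sum((resid - fit)^2)
  tss <- sum((resid - mean(resid))^2)
  r2 <- 1 - rss / tss
  stat <- n * r2
  df <- ncol(G) - 1L   # overwritten by callers that know K; UVMR has K = 1
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Sargan over-identification test
#'
#' `n R^2` from regressing the TSLS residuals (computed with the observed
#' exposures) on the instruments and covariates, referred to a chi-squared
#' distribution with `#instruments - #exposures` degrees of freedom. Residual
#' association of instruments with the outcome signals heterogeneity /
#' pleiotropy.
#'
#' @param instruments [genotype_matrix()] or dosage matrix.
#' @param exposures Vector or matrix of exposures.
#' @param outcome Continuous outcome vector.
#' @param covariates Optional covariates.
#' @return List with `statistic`, `df`, `p`.
#' @export
sargan_test <- function(instruments, exposures, outcome, covariates = NULL) {
  G <- .instrument_matrix(instruments)
  if (is.null(dim(G))) G <- matrix(G, ncol = 1L)
  X <- as.matrix(exposures)
  m <- ncol(G); K <- ncol(X)
  if (m <= K) .stopf("Sargan test undefined: model is just identified (df = %d)", m - K)
  n <- nrow(X)
  C <- .as_covmat(covariates, n)
  fit <- .tsls_fit(G, X, outcome, C, binary = FALSE)
  out <- .sargan_from_resid(fit$resid, G, C)
  out$df <- m - K
  out$p <- stats::pchisq(out$statistic, out$df, lower.tail = FALSE)
  out
}

#' Principal-component MR for correlated cis instruments
#'
#' For a dense set of correlated SNPs in one gene region: the weighted LD
#' matrix `Psi_ij = (bx_i / sey_i) (bx_j / sey_j) rho_ij` is
#' eigen-decomposed, SNP-exposure and SNP-outcome association vectors are
#' projected onto the top `k` components, and a generalised
#' (correlation-adjusted) inverse-variance-weighted estimate is computed over
#' the components.
#'
#' @param beta_exposure,se_exposure Per-SNP external exposure associations.
#' @param beta_outcome,se_outcome Per-SNP cohort outcome associations.
#' @param ld SNP correlation matrix (unit diagonal, symmetric).
#' @param k Number of components; `NULL` retains components explaining at
#'   least `var_threshold` cumulative variance.
#' @param var_threshold Cumulative-variance cutoff used when `k` is `NULL`
#'   (default 0.99).
#' @param ridge Diagonal regularisation added to the LD matrix (default 1e-6).
#' @return An `mr_estimate` (method `"cis_pc"`), with `k` in the diagnostics.
#' @export
cis_pc_mr <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                      ld, k = NULL, var_threshold = 0.99, ridge = 1e-6) {
  m <- length(beta_exposure)
  ld <- as.matrix(ld)
  if (nrow(ld) != m || ncol(ld) != m) .stopf("LD matrix dimensions inconsistent")
  if (max(abs(ld - t(ld))) > 1e-8 || max(abs(diag(ld) - 1)) > 1e-8) {
    .stopf("LD matrix must be symmetric with unit diagonal")
  }
  if (any(se_exposure <= 0) || any(se_outcome <= 0)) .stopf("SEs must be positive")
  ldr <- ld + diag(ridge, m)
  sc <- beta_exposure / se_outcome
  Psi <- tcrossprod(sc) * ldr
  eig <- eigen(Psi, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  tol <- max(lam) * m * .Machine$double.eps
  rank <- sum(lam > tol)
  if (rank == 0L) .stopf("weighted LD matrix has numerical rank 0")
  if (is.null(k)) {
    k <- which(cumsum(lam) / sum(lam) >= var_threshold)[1L]
  }
  if (k < 1L) .stopf("k must be at least 1")
  if (k > rank) .stopf("k = %d exceeds numerical rank %d", k, rank)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  bx <- drop(crossprod(V, beta_exposure))
  by <- drop(crossprod(V, beta_outcome))
  Sig <- tcrossprod(se_outcome) * ldr
  SigT <- crossprod(V, Sig %*% V)
  Om <- solve(SigT)
  denom <- drop(crossprod(bx, Om %*% bx))
  beta <- drop(crossprod(bx, Om %*% by)) / denom
  se <- 1 / sqrt(denom)
  new_mr_estimate("cis_pc", stats::setNames(beta, "exposure"), se, n = m,
                  diagnostics = list(k = k, rank = rank))
}
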
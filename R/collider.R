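# Multivariable Collider-Correction: pleiotropy-robust MVMR for one-sample
# individual-level data.
#
# The construction: fit the observational (collider-biased) multivariable
# outcome model Y ~ X1..XK + covariates to get beta_obs; obtain, SNP by SNP,
# the conditional outcome association alpha*_j (coefficient of G_j in
# Y ~ G_j + X1..XK + covariates) and the marginal exposure associations
# gamma_kj (X_k ~ G_j + covariates). Under the linear model
# E[alpha*_j] = sum_k gamma_kj (beta_k - beta_obs_k) + alpha_j, so a summary
# stage regressing alpha* on gamma estimates the correction Delta and
# beta_hat = beta_obs + Delta. Because alpha* is conditioned on the observed
# exposures, its error is (to first order) uncorrelated with gamma's, and
# pleiotropy-robust summary estimators can be swapped in for the summary
# stage.

# --- robust loss machinery ----------------------------------------------

#' @keywords internal
.loss_fns <- function(loss, tuning = NULL) {
  switch(loss,
    squared = {
      list(rho = function(t) t^2 / 2, weight = function(t) rep(1, length(t)),
           tuning = Inf)
    },
    huber = {
      k <- tuning %||% 1.345
      list(
        rho = function(t) ifelse(abs(t) <= k, t^2 / 2, k * abs(t) - k^2 / 2),
        weight = function(t) pmin(1, k / pmax(abs(t), .Machine$double.eps)),
        tuning = k
      )
    },
    tukey = {
      cc <- tuning %||% 4.685
      list(
        rho = function(t) {
          u <- pmin(abs(t) / cc, 1)
          cc^2 / 6 * (1 - (1 - u^2)^3)
        },
        weight = function(t) {
          u <- abs(t) / cc
          ifelse(u < 1, (1 - u^2)^2, 0)
        },
        tuning = cc
      )
    },
    .stopf("unknown loss '%s'", loss)
  )
}

# --- stage construction --------------------------------------------------

#' SNP-level conditional associations for Collider-Correction
#'
#' Fits the observational multivariable outcome model for `beta_obs`, then
#' for every SNP j the conditional outcome association `alpha*_j`
#' (coefficient of G_j in Y ~ G_j + exposures + covariates, SNP at a time)
#' and the marginal exposure associations `gamma_kj` (X_k ~ G_j +
#' covariates), with standard errors.
#'
#' @param dosages [genotype_matrix()] or dosage matrix.
#' @param exposures Matrix / data frame of exposures.
#' @param outcome Outcome vector.
#' @param covariates Optional covariates.
#' @param outcome_type `"continuous"` or `"binary"` (binary uses logistic
#'   fits for `beta_obs` and `alpha*`).
#' @return Object of class `summary_associations`: `gamma` (SNPs x
#'   exposures), `gamma_se`, `alpha`, `alpha_se`, `beta_obs`, `beta_obs_se`,
#'   `n`.
#' @export
collider_conditional_associations <- function(dosages, exposures, outcome,
                                              covariates = NULL,
                                              outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  G <- .instrument_matrix(dosages)
  X <- as.matrix(exposures)
  K <- ncol(X); m <- ncol(G); n <- nrow(X)
  if (any(apply(X, 2L, stats::sd) == 0)) .stopf("zero-variance exposure column")
  C <- .as_covmat(covariates, n)
  q <- if (is.null(C)) 0L else ncol(C)
  exp_names <- colnames(X) %||% paste0("exposure", seq_len(K))
  snp_ids <- colnames(G) %||% paste0("snp_", seq_len(m))

  XC <- cbind(X, C)
  A_obs <- cbind(1, XC)
  if (outcome_type == "continuous") {
    obs <- .wls_fit(A_obs, outcome)
    beta_obs <- obs$coef[1L + seq_len(K)]
    beta_obs_se <- sqrt(diag(obs$vcov))[1L + seq_len(K)]
    # alpha*_j by Frisch-Waugh-Lovell, vectorised over SNPs
    Gr <- .residualise(G, XC)
    yr <- drop(.residualise(outcome, XC))
    sgg <- colSums(Gr^2)
    if (any(sgg == 0)) .stopf("monomorphic dosage column in collider stage")
    sgy <- drop(crossprod(Gr, yr))
    alpha <- sgy / sgg
    df_a <- n - (2L + K + q)
    rss <- sum(yr^2) - alpha * sgy     # per-SNP residual SS of the full model
    alpha_se <- sqrt(pmax(rss, 0) / df_a / sgg)
  } else {
    fit0 <- .wlogit_fit(A_obs, outcome)
    if (is.null(fit0)) .stopf("observational logistic fit failed")
    beta_obs <- fit0$coef[1L + seq_len(K)]
    beta_obs_se <- sqrt(diag(fit0$vcov))[1L + seq_len(K)]
    alpha <- alpha_se <- numeric(m)
    for (j in seq_len(m)) {
      Aj <- cbind(1, G[, j], XC)
      fj <- .wlogit_fit(Aj, outcome)
      if (is.null(fj)) .stopf("conditional logistic fit failed for SNP %s", snp_ids[j])
      alpha[j] <- fj$coef[2L]
      alpha_se[j] <- sqrt(fj$vcov[2L, 2L])
    }
  }

  # gamma_kj: marginal SNP-exposure associations, vectorised
  Gr2 <- .residualise(G, C)
  Xr <- .residualise(X, C)
  sgg2 <- colSums(Gr2^2)
  if (any(sgg2 == 0)) .stopf("monomorphic dosage column in exposure stage")
  sgx <- crossprod(Gr2, Xr)              # m x K
  gamma <- sgx / sgg2
  df_g <- n - (2L + q)
  sxx <- colSums(Xr^2)
  rss_g <- outer(sgg2, sxx, function(a, b) b) - sgx^2 / sgg2
  gamma_se <- sqrt(pmax(rss_g, 0) / df_g / sgg2)

  structure(list(
    gamma = matrix(gamma, m, K, dimnames = list(snp_ids, exp_names)),
    gamma_se = matrix(gamma_se, m, K, dimnames = list(snp_ids, exp_names)),
    alpha = stats::setNames(drop(alpha), snp_ids),
    alpha_se = stats::setNames(drop(alpha_se), snp_ids),
    beta_obs = stats::setNames(beta_obs, exp_names),
    beta_obs_se = stats::setNames(beta_obs_se, exp_names),
    n = n, outcome_type = outcome_type
  ), class = "summary_associations")
}

#' Construct summary associations directly
#'
#' For summary-level simulation and two-sample-style inputs.
#'
#' @param gamma,gamma_se SNP x exposure matrices of exposure associations.
#' @param alpha,alpha_se Per-SNP conditional outcome associations.
#' @param beta_obs Optional observational coefficient vector (0 when the
#'   summary stage is used stand-alone).
#' @param beta_obs_se Optional SEs for `beta_obs`.
#' @return A `summary_associations` object.
#' @export
summary_associations <- function(gamma, gamma_se, alpha, alpha_se,
                                 beta_obs = NULL, beta_obs_se = NULL) {
  gamma <- as.matrix(gamma); gamma_se <- as.matrix(gamma_se)
  if (!all(dim(gamma) == dim(gamma_se)) || length(alpha) != nrow(gamma) ||
      length(alpha_se) != nrow(gamma)) {
    .stopf("summary association dimensions inconsistent")
  }
  if (any(gamma_se <= 0) || any(alpha_se <= 0)) .stopf("SEs must be positive")
  K <- ncol(gamma)
  structure(list(
    gamma = gamma, gamma_se = gamma_se,
    alpha = alpha, alpha_se = alpha_se,
    beta_obs = beta_obs %||% stats::setNames(rep(0, K), colnames(gamma)),
    beta_obs_se = beta_obs_se %||% stats::setNames(rep(0, K), colnames(gamma)),
    n = NA_integer_, outcome_type = "summary"
  ), class = "summary_associations")
}

# --- summary stage -------------------------------------------------------

#' @keywords internal
.profile_sd <- function(assoc, delta, overlap_cor) {
  s2 <- assoc$alpha_se^2 + drop(assoc$gamma_se^2 %*% delta^2)
  if (overlap_cor != 0) {
    s2 <- s2 - 2 * overlap_cor * assoc$alpha_se * drop(assoc$gamma_se %*% delta)
  }
  sqrt(pmax(s2, .Machine$double.eps))
}

#' Pleiotropy-robust summary-stage MVMR
#'
#' Estimates the correction vector `Delta` from SNP-level summary
#' associations. `loss = "squared"` is fixed-weight multi-exposure IVW
#' (weights `1/alpha_se^2`); the robust losses (Huber, Tukey biweight)
#' minimise `sum_j rho(t_j)` where
#' `t_j = (alpha_j - gamma_j . Delta) / s_j(Delta)` and
#' `s_j^2 = alpha_se_j^2 + sum_k Delta_k^2 gamma_se_jk^2`, the profile
#' variance that also absorbs weak-instrument uncertainty in `gamma`.
#' Outliers (pleiotropic SNPs) are down-weighted; per-SNP robust weights in
#' [0, 1] are returned. Standard errors come from a sandwich formula over the
#' per-SNP scores.
#'
#' @param assoc A `summary_associations` object.
#' @param loss `"tukey"` (default, tuning 4.685), `"huber"` (1.345) or
#'   `"squared"`.
#' @param overlap_cor Correlation between the `alpha` and `gamma` errors
#'   (0 for the one-sample collider stage, where `alpha` is conditioned on
#'   the observed exposures).
#' @param tuning Optional tuning-constant override.
#' @param max_iter Iteration cap for the optimiser.
#' @return Object of class `robust_mvmr`: `delta`, `se`, `vcov`, per-SNP
#'   `weights` and standardised residuals `t`, `loss`, `converged`.
#' @export
robust_summary_mvmr <- function(assoc, loss = c("tukey", "huber", "squared"),
                                overlap_cor = 0, tuning = NULL,
                                max_iter = 200) {
  loss <- match.arg(loss)
  stopifnot(inherits(assoc, "summary_associations"))
  G <- assoc$gamma
  m <- nrow(G); K <- ncol(G)
  if (m <= K) .stopf("need more SNPs than exposures for the robust summary stage")
  exp_names <- colnames(G) %||% paste0("exposure", seq_len(K))

  # fixed-weight IVW start (and the full answer for squared loss)
  w0 <- 1 / assoc$alpha_se^2
  A0 <- crossprod(G, G * w0)
  delta0 <- drop(solve(A0, crossprod(G * w0, assoc$alpha)))

  if (loss == "squared") {
    vcov <- solve(A0)
    t_res <- (assoc$alpha - drop(G %*% delta0)) / assoc$alpha_se
    return(structure(list(
      delta = stats::setNames(delta0, exp_names),
      se = stats::setNames(sqrt(diag(vcov)), exp_names),
      vcov = vcov,
      weights = stats::setNames(rep(1, m), rownames(G)),
      t = stats::setNames(t_res, rownames(G)),
      loss = loss, converged = TRUE
    ), class = "robust_mvmr"))
  }

  objective <- function(delta, fns) {
    s <- .profile_sd(assoc, delta, overlap_cor)
    sum(fns$rho((assoc$alpha - drop(G %*% delta)) / s))
  }
  # Huber first (better behaved), then the requested loss from several
  # deterministic starts; redescending losses (Tukey) have local minima, so
  # the lowest-objective solution wins.
  fns_h <- .loss_fns("huber", if (loss == "huber") tuning else NULL)
  opt_h <- stats::optim(delta0, objective, fns = fns_h, method = "BFGS",
                        control = list(maxit = max_iter))
  fns <- if (loss == "tukey") .loss_fns("tukey", tuning) else fns_h
  starts <- list(opt_h$par, delta0, rep(0, K))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, objective, fns = fns, method = "BFGS",
                   control = list(maxit = max_iter)),
      error = function(e) NULL
    )
    if (!is.null(opt) && opt$convergence == 0L &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) .stopf("robust summary stage failed to converge after %d iterations", max_iter)
  delta <- best$par

  # sandwich covariance from per-SNP scores
  per_snp_rho <- function(delta) {
    s <- .profile_sd(assoc, delta, overlap_cor)
    fns$rho((assoc$alpha - drop(G %*% delta)) / s)
  }
  h <- 1e-5 * (1 + abs(delta))
  scores <- matrix(0, m, K)
  for (k in seq_len(K)) {
    dp <- dm <- delta
    dp[k] <- dp[k] + h[k]; dm[k] <- dm[k] - h[k]
    scores[, k] <- (per_snp_rho(dp) - per_snp_rho(dm)) / (2 * h[k])
  }
  total_score <- function(delta) {
    out <- numeric(K)
    for (k in seq_len(K)) {
      dp <- dm <- delta
      dp[k] <- dp[k] + h[k]; dm[k] <- dm[k] - h[k]
      out[k] <- (sum(per_snp_rho(dp)) - sum(per_snp_rho(dm))) / (2 * h[k])
    }
    out
  }
  Amat <- matrix(0, K, K)
  for (k in seq_len(K)) {
    dp <- dm <- delta
    dp[k] <- dp[k] + h[k]; dm[k] <- dm[k] - h[k]
    Amat[, k] <- (total_score(dp) - total_score(dm)) / (2 * h[k])
  }
  Bmat <- crossprod(scores)
  vcov <- tryCatch({
    Ai <- solve(Amat)
    Ai %*% Bmat %*% t(Ai)
  }, error = function(e) matrix(NA_real_, K, K))

  s_fin <- .profile_sd(assoc, delta, overlap_cor)
  t_res <- (assoc$alpha - drop(G %*% delta)) / s_fin
  structure(list(
    delta = stats::setNames(delta, exp_names),
    se = stats::setNames(sqrt(diag(vcov)), exp_names),
    vcov = vcov,
    weights = stats::setNames(fns$weight(t_res), rownames(G)),
    t = stats::setNames(t_res, rownames(G)),
    loss = loss, converged = TRUE
  ), class = "robust_mvmr")
}

#' Multivariable Collider-Correction MR
#'
#' Composes [collider_conditional_associations()] and
#' [robust_summary_mvmr()]: the corrected causal effects are
#' `beta_hat = beta_obs + Delta`, with standard errors combining both stages
#' (analytic by default, bootstrap over individuals on request). The
#' additivity `beta_hat - beta_obs - Delta = 0` holds by construction.
#'
#' @inheritParams collider_conditional_associations
#' @inheritParams robust_summary_mvmr
#' @param se `"analytic"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `se = "bootstrap"`.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `cc_result` with `beta_obs`, `delta`, `beta`,
#'   `se`, confidence limits and per-SNP robust `weights`.
#' @export
collider_correction_mvmr <- function(dosages, exposures, outcome,
                                     covariates = NULL,
                                     outcome_type = c("continuous", "binary"),
                                     loss = c("tukey", "huber", "squared"),
                                     overlap_cor = 0,
                                     se = c("analytic", "bootstrap"),
                                     boot_reps = 200, seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  loss <- match.arg(loss)
  se <- match.arg(se)
  assoc <- collider_conditional_associations(dosages, exposures, outcome,
                                             covariates, outcome_type)
  rob <- robust_summary_mvmr(assoc, loss = loss, overlap_cor = overlap_cor)
  beta <- assoc$beta_obs + rob$delta
  if (se == "analytic") {
    beta_se <- sqrt(assoc$beta_obs_se^2 + rob$se^2)
  } else {
    if (!is.null(seed)) set.seed(seed)
    G <- .instrument_matrix(dosages)
    X <- as.matrix(exposures)
    C <- .as_covmat(covariates, nrow(X))
    draws <- matrix(NA_real_, boot_reps, length(beta))
    for (b in seq_len(boot_reps)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      ab <- collider_conditional_associations(
        G[idx, , drop = FALSE], X[idx, , drop = FALSE], outcome[idx],
        if (is.null(C)) NULL else C[idx, , drop = FALSE], outcome_type)
      rb <- tryCatch(robust_summary_mvmr(ab, loss = loss, overlap_cor = overlap_cor),
                     error = function(e) NULL)
      if (!is.null(rb)) draws[b, ] <- ab$beta_obs + rb$delta
    }
    beta_se <- apply(draws, 2L, stats::sd, na.rm = TRUE)
  }
  z <- stats::qnorm(0.975)
  structure(list(
    beta_obs = assoc$beta_obs, beta_obs_se = assoc$beta_obs_se,
    delta = rob$delta, delta_se = rob$se,
    beta = beta, se = beta_se,
    ci_lower = beta - z * beta_se, ci_upper = beta + z * beta_se,
    weights = rob$weights, t = rob$t,
    loss = loss, se_mode = se, n = assoc$n,
    outcome_type = outcome_type
  ), class = "cc_result")
}

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf("<cc_result: collider-corrected MVMR, loss = %s>  n = %s\n",
              x$loss, x$n))
  tab <- data.frame(beta_obs = x$beta_obs, delta = x$delta, beta = x$beta,
                    se = x$se, ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  print(round(tab, 4))
  n_down <- sum(x$weights < 0.5)
  cat(sprintf("%d / %d SNPs down-weighted below 0.5\n", n_down, length(x$weights)))
  invisible(x)
}

# --- univariable weak-instrument robust estimator ------------------------

#' Adjusted-profile-score univariable MR (weak-instrument robust)
#'
#' Summary-data estimator for a univariable model with random pleiotropy:
#' minimises `sum_j rho(t_j)` with
#' `t_j = (alpha_j - beta gamma_j) / sqrt(alpha_se_j^2 + beta^2 gamma_se_j^2
#' + tau^2)`, jointly solving a moment condition for the overdispersion
#' `tau^2 >= 0` (additive pleiotropy variance, truncated at zero). Including
#' `gamma_se` in the profile variance removes the regression-dilution bias
#' that plain IVW suffers with weak instruments.
#'
#' @param gamma,gamma_se Per-SNP exposure associations and SEs.
#' @param alpha,alpha_se Per-SNP outcome associations and SEs.
#' @param loss `"huber"` (default) or `"squared"`.
#' @param max_iter Outer iteration cap.
#' @return List with `beta`, `se`, `tau2`, `converged`.
#' @export
mr_raps_uv <- function(gamma, gamma_se, alpha, alpha_se,
                       loss = c("huber", "squared"), max_iter = 50) {
  loss <- match.arg(loss)
  m <- length(gamma)
  if (m < 3L) .stopf("adjusted profile score needs at least 3 SNPs")
  if (any(gamma_se <= 0) || any(alpha_se <= 0)) .stopf("SEs must be positive")
  fns <- .loss_fns(loss)
  # E[psi(T) T] under T ~ N(0,1), for the overdispersion moment condition
  kappa <- if (loss == "squared") 1 else {
    k <- fns$tuning
    2 * stats::pnorm(k) - 1
  }
  psi_t <- function(t) {
    if (loss == "squared") t^2 else {
      k <- fns$tuning
      ifelse(abs(t) <= k, t^2, k * abs(t))
    }
  }
  sfun <- function(beta, tau2) sqrt(alpha_se^2 + beta^2 * gamma_se^2 + tau2)
  obj <- function(beta, tau2) sum(fns$rho((alpha - beta * gamma) / sfun(beta, tau2)))

  w0 <- 1 / alpha_se^2
  beta <- sum(w0 * gamma * alpha) / sum(w0 * gamma^2)
  tau2 <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    beta_new <- stats::optim(beta, function(b) obj(b, tau2), method = "BFGS")$par
    g <- function(t2) sum(psi_t((alpha - beta_new * gamma) / sfun(beta_new, t2))) - m * kappa
    tau2_new <- if (g(0) <= 0) 0 else {
      upper <- stats::var(alpha - beta_new * gamma) + max(alpha_se^2)
      while (g(upper) > 0) upper <- upper * 4
      stats::uniroot(g, c(0, upper), tol = 1e-10)$root
    }
    done <- abs(beta_new - beta) < 1e-8 * (1 + abs(beta)) &&
      abs(tau2_new - tau2) < 1e-10 * (1 + tau2)
    beta <- beta_new; tau2 <- tau2_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) .stopf("adjusted profile score failed to converge after %d iterations", max_iter)

  # sandwich SE for beta at the solved tau2
  h <- 1e-5 * (1 + abs(beta))
  rho_j <- function(b) fns$rho((alpha - b * gamma) / sfun(b, tau2))
  sc <- (rho_j(beta + h) - rho_j(beta - h)) / (2 * h)
  Ascore <- (sum(rho_j(beta + h)) - 2 * sum(rho_j(beta)) + sum(rho_j(beta - h))) / h^2
  se <- sqrt(sum(sc^2)) / abs(Ascore)
  list(beta = beta, se = se, tau2 = tau2, converged = converged)
}
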
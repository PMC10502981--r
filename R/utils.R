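# Internal numeric helpers shared across estimators.

#' @keywords internal
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Weighted least squares coefficients; A must already contain any intercept
# column. w = NULL means ordinary LS. Returns coefficient vector.
#' @keywords internal
.wls_coef <- function(A, y, w = NULL) {
  if (is.null(w)) {
    qr.coef(qr(A), y)
  } else {
    Aw <- A * w
    drop(solve(crossprod(A, Aw), crossprod(Aw, y)))
  }
}

# Full WLS fit with coefficient covariance (sigma^2 (A'WA)^-1).
#' @keywords internal
.wls_fit <- function(A, y, w = NULL) {
  n <- nrow(A); p <- ncol(A)
  if (is.null(w)) w <- rep(1, n)
  AtWA <- crossprod(A, A * w)
  beta <- drop(solve(AtWA, crossprod(A * w, y)))
  resid <- y - drop(A %*% beta)
  # effective df uses n, not sum(w): weights are analysis weights, not counts
  sigma2 <- sum(w * resid^2) / (n - p)
  vcov <- sigma2 * solve(AtWA)
  list(coef = beta, vcov = vcov, resid = resid, sigma2 = sigma2, df = n - p)
}

# Weighted logistic regression via glm.fit; returns coefficients and vcov.
# Quasi-binomial family so fractional (bootstrap) weights raise no warnings.
#' @keywords internal
.wlogit_fit <- function(A, y, w = NULL) {
  n <- nrow(A)
  if (is.null(w)) w <- rep(1, n)
  fit <- suppressWarnings(
    stats::glm.fit(A, y, weights = w, family = stats::quasibinomial())
  )
  if (!fit$converged) return(NULL)
  # dispersion fixed at 1: this is a binomial model fitted by quasi machinery
  wls <- fit$weights
  vcov <- tryCatch(solve(crossprod(A, A * wls)), error = function(e) NULL)
  if (is.null(vcov)) return(NULL)
  list(coef = fit$coefficients, vcov = vcov, converged = fit$converged)
}

# Bare-bones weighted logistic coefficients by Newton iteration with an
# optional warm start; built for the bootstrap inner loop where the design
# has few columns and the unweighted solution is a good start. Returns NULL
# on non-convergence or degeneracy.
#' @keywords internal
.fast_logit <- function(A, y, w = NULL, start = NULL, max_iter = 30) {
  p <- ncol(A)
  if (is.null(w)) w <- rep(1, nrow(A))
  b <- if (is.null(start)) numeric(p) else start
  for (it in seq_len(max_iter)) {
    eta <- drop(A %*% b)
    mu <- stats::plogis(eta)
    W <- w * mu * (1 - mu)
    if (!all(is.finite(W)) || sum(W) < .Machine$double.eps) return(NULL)
    g <- crossprod(A, w * (y - mu))
    H <- crossprod(A, A * W)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-8 * (1 + max(abs(b)))) {
      if (any(abs(b) > 1e3)) return(NULL)  # separation guard
      return(b)
    }
  }
  NULL
}

# Residualise the columns of M on covariate matrix C (with intercept).
#' @keywords internal
.residualise <- function(M, C = NULL) {
  M <- as.matrix(M)
  X <- if (is.null(C)) matrix(1, nrow(M), 1) else cbind(1, as.matrix(C))
  M - X %*% qr.coef(qr(X), M)
}

#' @keywords internal
.as_covmat <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  C <- as.matrix(covariates)
  if (nrow(C) != n) .stopf("covariates have %d rows; expected %d", nrow(C), n)
  storage.mode(C) <- "double"
  C
}

#' @keywords internal
.check_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    .stopf("%s must be a single number", name)
  }
  if (open && (x <= 0 || x >= 1)) .stopf("%s must lie strictly in (0, 1)", name)
  if (!open && (x < 0 || x > 1)) .stopf("%s must lie in [0, 1]", name)
  invisible(x)
}
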
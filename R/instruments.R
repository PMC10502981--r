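# Instrument selection and quality control: LD clumping, pairwise pruning,
# genetic risk scores, instrument-strength diagnostics and Steiger filtering.

#' Construct an instrument set
#'
#' @param variants Data frame of variant records with at least `id`; `beta`
#'   (external per-allele weight), `effect_allele`, `other_allele`, `p`,
#'   `chrom`, `pos`, `eaf` are carried through when present.
#' @param provenance Label of the discovery study the weights come from.
#' @return A data frame of class `instrument_set` with columns `id` and
#'   `weight` plus any carried metadata.
#' @export
instrument_set <- function(variants, provenance = "unspecified") {
  variants <- as.data.frame(variants)
  if (!"id" %in% names(variants)) .stopf("variants need an 'id' column")
  if (anyDuplicated(variants$id)) .stopf("instrument ids must be unique")
  out <- variants
  if (!"weight" %in% names(out)) {
    out$weight <- if ("beta" %in% names(out)) out$beta else rep(1, nrow(out))
  }
  if (any(!is.finite(out$weight))) .stopf("instrument weights must be finite")
  attr(out, "provenance") <- provenance
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Greedy LD clumping
#'
#' Selects index variants by ascending discovery p-value; any unselected
#' variant on the same chromosome within `window_kb` of a selected index
#' variant and with pairwise r-squared above `r2_threshold` is removed.
#' Ties in p are broken by (chrom, pos, id) so the result is deterministic.
#'
#' @param variants Data frame with `id`, `chrom`, `pos`, `p` (and optionally
#'   weight metadata, carried through).
#' @param ld Symmetric matrix of pairwise r-squared values with variant ids as
#'   dimnames, or `NULL` when no same-chromosome in-window pairs exist. A
#'   missing entry for an in-window pair is a data error.
#' @param window_kb Clumping window, kilobases (default 50).
#' @param r2_threshold LD threshold (default 0.001).
#' @return An [instrument_set()] of retained variants; dropped variants and
#'   reasons in `attr(, "dropped")`.
#' @export
clump <- function(variants, ld = NULL, window_kb = 50, r2_threshold = 0.001) {
  variants <- as.data.frame(variants)
  need <- c("id", "chrom", "pos", "p")
  miss <- setdiff(need, names(variants))
  if (length(miss)) .stopf("variants missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(variants$p)) .stopf("p-values must be present for clumping")
  ord <- order(variants$p, variants$chrom, variants$pos, variants$id)
  v <- variants[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  status <- rep("pending", nrow(v))
  dropped_by <- rep(NA_character_, nrow(v))
  for (i in seq_len(nrow(v))) {
    if (status[i] != "pending") next
    status[i] <- "index"
    near <- which(status == "pending" & v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= window_bp)
    for (j in near) {
      r2 <- .ld_lookup(ld, v$id[i], v$id[j])
      if (r2 > r2_threshold) {
        status[j] <- "clumped"
        dropped_by[j] <- v$id[i]
      }
    }
  }
  keep <- v[status == "index", , drop = FALSE]
  keep <- keep[order(match(keep$id, variants$id)), , drop = FALSE]
  out <- instrument_set(keep, provenance = attr(variants, "provenance") %||% "clump")
  clumped_ids <- v$id[status == "clumped"]
  attr(out, "dropped") <- data.frame(
    id = clumped_ids,
    reason = if (length(clumped_ids))
      paste0("r2 with index ", dropped_by[status == "clumped"]) else character(0),
    stringsAsFactors = FALSE
  )
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.ld_lookup <- function(ld, id_a, id_b) {
  if (is.null(ld) || !all(c(id_a, id_b) %in% rownames(ld))) {
    .stopf("missing LD entry for in-window pair %s / %s", id_a, id_b)
  }
  r2 <- ld[id_a, id_b]
  if (is.na(r2)) .stopf("missing LD entry for in-window pair %s / %s", id_a, id_b)
  r2
}

#' Iterative pairwise LD pruning on sample dosages
#'
#' For every same-chromosome pair of instruments whose squared sample dosage
#' correlation exceeds `r2_threshold`, the variant with the smaller discovery
#' p-value is kept and the other dropped, iterating until no violating pair
#' remains. `literal = TRUE` keeps the larger p instead (reproducing a
#' retention rule sometimes printed but contrary to universal practice).
#'
#' @param instrument An [instrument_set()] (or data frame) with `id`, `chrom`
#'   and `p`.
#' @param dosages A [genotype_matrix()] containing all instrument columns.
#' @param r2_threshold Squared-correlation threshold (default 0.05).
#' @param literal Keep the larger-p member of each violating pair.
#' @return Pruned [instrument_set()]; dropped ids in `attr(, "dropped")`.
#' @export
ld_prune_pairwise <- function(instrument, dosages, r2_threshold = 0.05,
                              literal = FALSE) {
  inst <- as.data.frame(instrument)
  need <- c("id", "chrom", "p")
  miss <- setdiff(need, names(inst))
  if (length(miss)) .stopf("instrument missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(inst$id %in% colnames(dosages$dosages))) {
    .stopf("dosage columns missing for some instruments")
  }
  D <- dosages$dosages[, inst$id, drop = FALSE]
  sds <- apply(D, 2L, stats::sd)
  if (any(sds == 0)) {
    .stopf("monomorphic dosage column(s): correlation undefined (%s)",
           paste(inst$id[sds == 0], collapse = ", "))
  }
  r2 <- stats::cor(D)^2
  same_chrom <- outer(inst$chrom, inst$chrom, "==")
  keep <- rep(TRUE, nrow(inst))
  dropped <- character(0)
  repeat {
    idx <- which(keep)
    viol <- which(r2[idx, idx, drop = FALSE] > r2_threshold &
                    same_chrom[idx, idx, drop = FALSE] &
                    upper.tri(matrix(0, length(idx), length(idx))),
                  arr.ind = TRUE)
    if (nrow(viol) == 0L) break
    pa <- inst$p[idx[viol[, 1L]]]
    pb <- inst$p[idx[viol[, 2L]]]
    best <- pmin(pa, pb)
    # handle the pair anchored at the strongest signal first, then by id
    sel <- order(best, inst$id[idx[viol[, 1L]]])[1L]
    pair <- c(idx[viol[sel, 1L]], idx[viol[sel, 2L]])
    worse <- if (xor(inst$p[pair[1L]] > inst$p[pair[2L]], literal)) pair[1L] else pair[2L]
    keep[worse] <- FALSE
    dropped <- c(dropped, inst$id[worse])
  }
  out <- instrument_set(inst[keep, , drop = FALSE],
                        provenance = attr(instrument, "provenance") %||% "prune")
  attr(out, "dropped") <- data.frame(id = dropped,
                                     reason = rep("pairwise r2", length(dropped)),
                                     stringsAsFactors = FALSE)
  out
}

#' Weighted genetic risk score
#'
#' `score_i = sum_j w_j dosage_ij`. When both the instrument set and the
#' genotype metadata carry allele labels they must already be harmonised (see
#' [harmonize_dosages()]): a mismatch is an error, not a silent flip.
#'
#' @param dosages A [genotype_matrix()].
#' @param weights An [instrument_set()] or a named numeric vector of
#'   per-variant weights.
#' @return Numeric per-person score.
#' @export
genetic_risk_score <- function(dosages, weights) {
  if (inherits(weights, "instrument_set")) {
    w <- stats::setNames(weights$weight, weights$id)
    if ("effect_allele" %in% names(weights)) {
      info <- dosages$info
      idx <- match(weights$id, info$id)
      known <- !is.na(idx) & !is.na(info$effect_allele[idx])
      bad <- known & weights$effect_allele != info$effect_allele[idx]
      if (any(bad)) {
        .stopf("effect-allele mismatch for %s: harmonise dosages and weights first",
               paste(weights$id[bad], collapse = ", "))
      }
    }
  } else {
    w <- weights
  }
  if (is.null(names(w))) .stopf("weights must be named by variant id")
  missing_ids <- setdiff(names(w), colnames(dosages$dosages))
  if (length(missing_ids)) {
    .stopf("dosage columns missing for: %s", paste(missing_ids, collapse = ", "))
  }
  drop(dosages$dosages[, names(w), drop = FALSE] %*% w)
}

#' @keywords internal
.instrument_matrix <- function(instruments) {
  G <- if (inherits(instruments, "genotype_matrix")) instruments$dosages
       else as.matrix(instruments)
  storage.mode(G) <- "double"
  G
}

#' First-stage instrument strength (mean and joint F)
#'
#' Per-instrument F statistics from covariate-adjusted single-instrument
#' regressions of the exposure, averaged; plus the joint (block) F for all
#' instruments together.
#'
#' @param instruments [genotype_matrix()], matrix, or single score vector.
#' @param exposure Numeric exposure vector.
#' @param covariates Optional covariate data frame / matrix.
#' @return List with `mean_f`, `joint_f`, `per_instrument_f`, `df`.
#' @export
mean_f_statistic <- function(instruments, exposure, covariates = NULL) {
  G <- .instrument_matrix(instruments)
  if (is.null(dim(G))) G <- matrix(G, ncol = 1L)
  n <- length(exposure)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  m <- ncol(G)
  if (n <= m + q + 1L) .stopf("n must exceed #instruments + #covariates + 1")
  C <- .as_covmat(covariates, n)
  Gr <- .residualise(G, C)
  xr <- drop(.residualise(exposure, C))
  sgg <- colSums(Gr^2)
  if (any(sgg == 0)) .stopf("rank-deficient design: zero-variance instrument after adjustment")
  sxy <- drop(crossprod(Gr, xr))
  syy <- sum(xr^2)
  ess <- sxy^2 / sgg
  df2 <- n - q - 2L
  f_per <- (ess / 1) / ((syy - ess) / df2)
  # joint F over the instrument block
  qrG <- qr(Gr)
  if (qrG$rank < m) .stopf("rank-deficient design: collinear instruments")
  fit <- qr.fitted(qrG, xr)
  rss1 <- sum((xr - fit)^2)
  df_joint <- n - q - m - 1L
  joint_f <- ((syy - rss1) / m) / (rss1 / df_joint)
  list(mean_f = mean(f_per), joint_f = joint_f,
       per_instrument_f = stats::setNames(f_per, colnames(G)),
       df = c(df_per = df2, df_joint = df_joint))
}

#' Conditional F statistics for multivariable MR
#'
#' Sanderson-Windmeijer conditional instrument strength. Per-SNP marginal
#' exposure associations `gamma_kj` (covariate-adjusted) are computed for
#' every exposure; for exposure k, `gamma_k` is regressed on the other
#' exposures' association vectors weighted by `1 / se_kj^2`, and the
#' conditional F is the weighted residual sum of squares divided by
#' `m - (K - 1)`. A conditionally weak exposure — one whose instrument
#' signal is reproducible from the other exposures' signals — gives a value
#' near 1; perfectly collinear exposure signals give a value near 0 (with a
#' warning, not an exception).
#'
#' @param dosages [genotype_matrix()] or instrument matrix.
#' @param exposures Matrix or data frame with at least two exposure columns.
#' @param covariates Optional covariates.
#' @return Named per-exposure conditional F vector.
#' @export
conditional_f <- function(dosages, exposures, covariates = NULL) {
  G <- .instrument_matrix(dosages)
  X <- as.matrix(exposures)
  if (ncol(X) < 2L) .stopf("conditional F is undefined for a single exposure")
  n <- nrow(X); m <- ncol(G); K <- ncol(X)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  C <- .as_covmat(covariates, n)
  Gr <- .residualise(G, C)
  Xr <- .residualise(X, C)
  sgg <- colSums(Gr^2)
  if (any(sgg == 0)) .stopf("rank-deficient design: zero-variance instrument after adjustment")
  sgx <- crossprod(Gr, Xr)                 # m x K
  gamma <- sgx / sgg
  df_g <- n - (2L + q)
  sxx <- colSums(Xr^2)
  rss_g <- outer(rep(1, m), sxx) - sgx^2 / sgg
  gamma_se2 <- pmax(rss_g, 0) / df_g / sgg
  out <- numeric(K)
  for (k in seq_len(K)) {
    gk <- gamma[, k]
    Gother <- gamma[, -k, drop = FALSE]
    se2_other <- gamma_se2[, -k, drop = FALSE]
    # profile weights: the fitted combination of the other exposures carries
    # their own association uncertainty, so iterate delta and the weights
    delta <- rep(0, K - 1L)
    resid <- gk
    ok <- TRUE
    for (it in 1:5) {
      w <- 1 / (gamma_se2[, k] + drop(se2_other %*% delta^2))
      new_delta <- tryCatch(
        drop(solve(crossprod(Gother, Gother * w), crossprod(Gother * w, gk))),
        error = function(e) NULL
      )
      if (is.null(new_delta)) { ok <- FALSE; break }
      delta <- new_delta
      resid <- gk - drop(Gother %*% delta)
    }
    if (!ok) {
      out[k] <- 0
      .warnf("collinear exposure association vectors for exposure %d", k)
      next
    }
    w <- 1 / (gamma_se2[, k] + drop(se2_other %*% delta^2))
    out[k] <- sum(w * resid^2) / (m - (K - 1L))
  }
  stats::setNames(out, colnames(X) %||% paste0("exposure", seq_len(K)))
}

#' Steiger directionality filter
#'
#' Retains a SNP if and only if it explains more variance in the target trait
#' than in every competing trait: `r2_target > r2_competitor` for all
#' competitors. Point r-squared values are compared directly.
#'
#' @param instrument [instrument_set()], data frame with `id`, or character
#'   vector of SNP ids.
#' @param r2_target Named per-SNP r-squared with the target trait.
#' @param r2_competitors Named numeric vector (one competitor) or matrix /
#'   data frame with SNPs in rows and one column per competing trait.
#' @return The retained subset of `instrument` (same class); dropped ids in
#'   `attr(, "dropped")`.
#' @export
steiger_filter <- function(instrument, r2_target, r2_competitors) {
  ids <- if (is.character(instrument)) instrument else as.data.frame(instrument)$id
  if (length(ids) == 0L) {
    out <- instrument
    attr(out, "dropped") <- character(0)
    return(out)
  }
  if (!all(ids %in% names(r2_target))) .stopf("missing target r2 for some SNPs")
  comp <- if (is.null(dim(r2_competitors))) {
    matrix(r2_competitors[ids], ncol = 1L, dimnames = list(ids, "competitor"))
  } else {
    as.matrix(r2_competitors)[ids, , drop = FALSE]
  }
  if (anyNA(comp)) .stopf("missing competitor r2 for some SNPs")
  keep <- r2_target[ids] > apply(comp, 1L, max)
  out <- if (is.character(instrument)) instrument[keep] else instrument[keep, , drop = FALSE]
  attr(out, "dropped") <- ids[!keep]
  out
}

#' Per-SNP variance explained in a trait (individual-level mode)
#'
#' Squared covariate-adjusted correlation between each dosage column and the
#' trait, for use with [steiger_filter()].
#'
#' @param dosages [genotype_matrix()] or dosage matrix.
#' @param trait Numeric trait vector.
#' @param covariates Optional covariates partialled out of both.
#' @return Named per-SNP r-squared vector.
#' @export
snp_trait_r2 <- function(dosages, trait, covariates = NULL) {
  G <- .instrument_matrix(dosages)
  C <- .as_covmat(covariates, length(trait))
  Gr <- .residualise(G, C)
  tr <- drop(.residualise(trait, C))
  sgg <- colSums(Gr^2)
  if (any(sgg == 0)) .stopf("monomorphic dosage column: r2 undefined")
  drop(crossprod(Gr, tr))^2 / (sgg * sum(tr^2))
}

#' Per-SNP variance explained from summary statistics
#'
#' `2 f (1 - f) beta^2 / trait_var`, the summary-data analogue of
#' [snp_trait_r2()].
#'
#' @param eaf Effect-allele frequencies.
#' @param beta Per-allele effects on the trait.
#' @param trait_var Trait variance (1 for standardised traits).
#' @return Per-SNP r-squared vector (names kept from `beta`).
#' @export
summary_r2 <- function(eaf, beta, trait_var = 1) {
  if (anyNA(eaf)) .stopf("eaf unavailable: summary-mode r2 needs allele frequencies")
  2 * eaf * (1 - eaf) * beta^2 / trait_var
}
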
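# Readers and writers for the plain-text interchange formats: PLINK
# .raw-style dosage text, GWAS summary-statistic TSV, phenotype CSV.

.RAW_LEAD_COLS <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

#' Read a PLINK .raw-style dosage file
#'
#' Whitespace-delimited text with header `FID IID PAT MAT SEX PHENOTYPE`
#' followed by one column per variant named `<id>_<EA>` (effect allele as
#' suffix). Missing dosages are imputed to the per-SNP mean and counted in
#' `attr(, "n_imputed")`.
#'
#' @param path File path.
#' @return A [genotype_matrix()]; effect alleles from the column suffixes,
#'   `maf` estimated as half the mean dosage.
#' @export
read_dosage_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  lead <- intersect(.RAW_LEAD_COLS, names(dt))
  if (!all(c("FID", "IID") %in% names(dt))) {
    .stopf("malformed .raw header in %s: FID/IID columns missing", path)
  }
  snp_cols <- setdiff(names(dt), lead)
  if (!length(snp_cols)) .stopf("no variant columns in %s", path)
  bad_name <- !grepl("_[ACGT]+$", snp_cols)
  if (any(bad_name)) {
    .stopf("variant column(s) without an effect-allele suffix: %s",
           paste(snp_cols[bad_name], collapse = ", "))
  }
  M <- as.matrix(dt[, snp_cols, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- snp_cols[!vapply(dt[snp_cols], is.numeric, logical(1))]
    for (cn in bad) {
      row <- which(is.na(suppressWarnings(as.numeric(dt[[cn]]))) & !is.na(dt[[cn]]))[1]
      .stopf("non-numeric dosage in column %s, line %d of %s", cn, row + 1L, path)
    }
  }
  n_imputed <- 0L
  for (j in seq_len(ncol(M))) {
    na <- is.na(M[, j])
    if (any(na)) {
      if (all(na)) .stopf("variant %s has no observed dosages", snp_cols[j])
      M[na, j] <- mean(M[!na, j])
      n_imputed <- n_imputed + sum(na)
    }
  }
  ids <- sub("_[ACGT]+$", "", snp_cols)
  ea <- sub("^.*_", "", snp_cols)
  colnames(M) <- ids
  info <- data.frame(id = ids, chrom = NA_character_, pos = NA_integer_,
                     effect_allele = ea, other_allele = NA_character_,
                     maf = colMeans(M) / 2, stringsAsFactors = FALSE)
  out <- genotype_matrix(M, info)
  out$samples <- dt[, c("FID", "IID")]
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Write a genotype matrix as PLINK .raw-style text
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_raw <- function(geno, path) {
  n <- nrow(geno$dosages)
  samples <- geno$samples %||% data.frame(FID = seq_len(n), IID = seq_len(n))
  out <- data.frame(FID = samples$FID, IID = samples$IID,
                    PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L)
  M <- geno$dosages
  colnames(M) <- paste0(geno$info$id, "_", geno$info$effect_allele)
  data.table::fwrite(cbind(out, as.data.frame(M)), path, sep = " ")
  invisible(path)
}

#' Read GWAS summary statistics (TSV)
#'
#' Requires columns `SNP`, `EA`, `NEA`, `BETA`, `SE`, `P`; `CHR`, `POS`,
#' `EAF` are optional (absent EAF is recorded as `NA`, and summary-mode
#' Steiger r-squared will refuse it with a clear error). Duplicate SNP ids
#' are rejected.
#'
#' @param path File path.
#' @return Data frame of variant records with standardised names `id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `p`.
#' @export
read_summary_stats <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("SNP", "EA", "NEA", "BETA", "SE", "P")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    .stopf("summary statistics %s missing required column(s): %s", path,
           paste(miss, collapse = ", "))
  }
  if (anyDuplicated(dt$SNP)) {
    .stopf("duplicated SNP id(s) in %s: %s", path,
           paste(unique(dt$SNP[duplicated(dt$SNP)]), collapse = ", "))
  }
  if (any(dt$SE <= 0, na.rm = TRUE)) .stopf("non-positive SE in %s", path)
  data.frame(
    id = dt$SNP,
    chrom = if ("CHR" %in% names(dt)) as.character(dt$CHR) else NA_character_,
    pos = if ("POS" %in% names(dt)) as.integer(dt$POS) else NA_integer_,
    effect_allele = dt$EA, other_allele = dt$NEA,
    eaf = if ("EAF" %in% names(dt)) as.numeric(dt$EAF) else NA_real_,
    beta = as.numeric(dt$BETA), se = as.numeric(dt$SE), p = as.numeric(dt$P),
    stringsAsFactors = FALSE
  )
}

#' Harmonise external weights to cohort effect alleles
#'
#' Aligns the external variant records to the genotype matrix's effect
#' alleles: matching alleles pass through; swapped alleles get their `beta`
#' sign flipped (and alleles exchanged); palindromic variants (A/T or C/G)
#' with ambiguous frequency (`eaf` inside `palindromic_window`) are dropped;
#' any other mismatch is an error.
#'
#' @param variants Variant records (see [read_summary_stats()]).
#' @param geno A [genotype_matrix()] whose metadata carries effect alleles.
#' @param drop_palindromic Drop ambiguous palindromic variants (default
#'   TRUE).
#' @param palindromic_window Open eaf interval treated as ambiguous.
#' @return Harmonised variant records; flipped and dropped ids recorded in
#'   `attr(, "flipped")` / `attr(, "dropped")`.
#' @export
harmonize_weights <- function(variants, geno, drop_palindromic = TRUE,
                              palindromic_window = c(0.42, 0.58)) {
  info <- geno$info
  idx <- match(variants$id, info$id)
  if (anyNA(idx)) {
    .stopf("variants absent from genotype data: %s",
           paste(variants$id[is.na(idx)], collapse = ", "))
  }
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal <- variants$effect_allele == comp[variants$other_allele]
  drop <- rep(FALSE, nrow(variants))
  if (drop_palindromic) {
    amb <- pal & !is.na(variants$eaf) &
      variants$eaf > palindromic_window[1] & variants$eaf < palindromic_window[2]
    drop <- drop | amb
  }
  geno_ea <- info$effect_allele[idx]
  same <- variants$effect_allele == geno_ea
  swapped <- variants$other_allele == geno_ea
  bad <- !same & !swapped & !is.na(geno_ea)
  if (any(bad & !drop)) {
    .stopf("allele mismatch (neither match nor swap) for: %s",
           paste(variants$id[bad & !drop], collapse = ", "))
  }
  out <- variants
  flip <- swapped & !same & !drop
  out$beta[flip] <- -out$beta[flip]
  tmp <- out$effect_allele[flip]
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- tmp
  out$eaf[flip] <- 1 - out$eaf[flip]
  out <- out[!drop, , drop = FALSE]
  attr(out, "flipped") <- variants$id[flip]
  attr(out, "dropped") <- variants$id[drop]
  out
}

#' Write phenotype / covariate table to CSV
#' @param cohort Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  data.table::fwrite(cohort, path)
  invisible(path)
}

#' Read a phenotype / covariate CSV
#' @param path File path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  data.table::fread(path, data.table = FALSE)
}

#' Write a simulation truth record as YAML
#' @param truth A `sim_truth` record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(lapply(unclass(truth), function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  }), path)
  invisible(path)
}
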
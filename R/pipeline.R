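# End-to-end analysis pipeline: binds simulation / loading, instrument QC,
# observational baseline, UVMR, MVMR, collider-corrected MVMR, mediation and
# moderation into one configured, seeded, manifest-logged run.

#' Run the full analysis pipeline
#'
#' Executes, in order and honouring the enable flags in `config$stages`:
#' data (simulate or load) -> schema validation -> observational baseline ->
#' UVMR per exposure -> MVMR -> collider-corrected MVMR -> mediation ->
#' moderation. Results are written as TSV + JSON side by side under
#' `config$out_dir`, together with a run manifest (config hash, seed,
#' per-stage row counts). Any stage error halts with the stage name and the
#' partial manifest attached to the condition.
#'
#' @param config Nested list or path to a YAML file. Minimal fields:
#'   `seed`, `out_dir`, `data` (either `simulate = list(design =
#'   "two_exposure"|"mediation", ...)` passed to [sim_config()], or
#'   `dosage_file` + `phenotype_file`), `exposures` (column names),
#'   `outcome`, `outcome_type`. Optional: `covariates`, per-exposure
#'   `instruments` (SNP id lists; defaults from the simulation truth),
#'   `stages` (logical flags `observational`, `uvmr`, `mvmr`, `cc_mvmr`,
#'   `mediation`, `moderation`), `cc = list(loss = ...)`, `mediation =
#'   list(x, m, y, x_snps, m_snps, method, B)`, `moderation = list(by,
#'   cutpoints, exposure, quadratic)`.
#' @return The run manifest (invisibly a list), with `results` holding the
#'   per-stage objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_hash <- .config_hash(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  if (is.null(out_dir)) .stopf("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages_on <- utils::modifyList(
    list(observational = TRUE, uvmr = TRUE, mvmr = TRUE, cc_mvmr = TRUE,
         mediation = FALSE, moderation = FALSE),
    config$stages %||% list()
  )
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = cfg_hash,
    version = as.character(utils::packageVersion("mrcollide")),
    seed = seed,
    stages = list()
  )
  log_stage <- function(name, n_in, n_out, note = NULL) {
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out,
                                     n_excluded = n_in - n_out, note = note)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$manifest <- manifest
      stop(cond)
    })
  }

  # ---- data -------------------------------------------------------------
  truth <- NULL
  dat <- run_stage("data", {
    if (!is.null(config$data$simulate)) {
      simargs <- config$data$simulate
      design <- simargs$design %||% "two_exposure"
      simargs$design <- NULL
      simargs$seed <- simargs$seed %||% seed
      sc <- do.call(sim_config, simargs)
      if (design == "mediation") simulate_mediation_cohort(sc)
      else simulate_two_exposure_cohort(sc)
    } else {
      geno <- read_dosage_raw(config$data$dosage_file)
      cohort <- read_phenotypes(config$data$phenotype_file)
      list(genotypes = geno, cohort = cohort, truth = NULL)
    }
  })
  truth <- dat$truth
  cohort <- dat$cohort
  geno <- dat$genotypes
  log_stage("data", nrow(cohort), nrow(cohort))

  # ---- schema validation (fail fast, before any computation) ------------
  run_stage("schema", {
    needed <- c(config$exposures, config$outcome, config$covariates,
                config$moderation$by[stages_on$moderation],
                if (stages_on$mediation) c(config$mediation$x, config$mediation$m,
                                           config$mediation$y))
    missing_cols <- setdiff(needed, names(cohort))
    if (length(missing_cols)) {
      .stopf("column(s) absent from cohort: %s", paste(missing_cols, collapse = ", "))
    }
    if (is.null(config$exposures) || is.null(config$outcome)) {
      .stopf("config must name exposures and outcome columns")
    }
    TRUE
  })

  exposures <- config$exposures
  outcome_type <- config$outcome_type %||% "continuous"
  covs <- if (!is.null(config$covariates)) cohort[config$covariates] else NULL
  y <- cohort[[config$outcome]]

  instruments <- config$instruments
  if (is.null(instruments) && !is.null(truth)) {
    instruments <- if (truth$design == "two_exposure") {
      stats::setNames(list(truth$snps_x1, truth$snps_x2), exposures)
    } else {
      stats::setNames(list(truth$snps_x, truth$snps_m),
                      c(config$mediation$x %||% exposures[1],
                        config$mediation$m %||% exposures[2]))
    }
  }
  if (is.null(instruments)) {
    instruments <- stats::setNames(
      rep(list(colnames(geno$dosages)), length(exposures)), exposures)
  }
  all_snps <- unique(unlist(instruments))

  results <- list()
  rows <- list()
  add_rows <- function(method, exposure, beta, se, lo, hi, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, exposure = exposure, beta = beta, se = se,
      ci_lower = lo, ci_upper = hi, p = p, stringsAsFactors = FALSE)
  }

  if (isTRUE(stages_on$observational)) {
    results$observational <- run_stage("observational", {
      lapply(stats::setNames(exposures, exposures), function(e) {
        observational_association(cohort[[e]], y, covs, outcome_type)
      })
    })
    for (e in exposures) {
      r <- results$observational[[e]]
      add_rows("observational", e, r$beta, r$se, r$ci_lower, r$ci_upper, r$p)
    }
    log_stage("observational", nrow(cohort), nrow(cohort))
  }

  if (isTRUE(stages_on$uvmr)) {
    results$uvmr <- run_stage("uvmr", {
      lapply(stats::setNames(exposures, exposures), function(e) {
        G <- geno$dosages[, instruments[[e]], drop = FALSE]
        tsls_uvmr(G, cohort[[e]], y, covs, outcome_type)
      })
    })
    for (e in exposures) {
      r <- results$uvmr[[e]]
      add_rows("tsls_uvmr", e, r$beta, r$se, r$ci_lower, r$ci_upper, r$p)
    }
    log_stage("uvmr", nrow(cohort), nrow(cohort))
  }

  if (isTRUE(stages_on$mvmr) && length(exposures) >= 2L) {
    results$mvmr <- run_stage("mvmr", {
      tsls_mvmr(geno$dosages[, all_snps, drop = FALSE],
                as.matrix(cohort[exposures]), y, covs, outcome_type)
    })
    r <- results$mvmr
    add_rows("tsls_mvmr", names(r$beta), r$beta, r$se, r$ci_lower, r$ci_upper, r$p)
    log_stage("mvmr", nrow(cohort), nrow(cohort))
  }

  if (isTRUE(stages_on$cc_mvmr) && length(exposures) >= 2L) {
    results$cc_mvmr <- run_stage("cc_mvmr", {
      collider_correction_mvmr(geno$dosages[, all_snps, drop = FALSE],
                               as.matrix(cohort[exposures]), y, covs,
                               outcome_type,
                               loss = config$cc$loss %||% "tukey")
    })
    r <- results$cc_mvmr
    z <- stats::qnorm(0.975)
    add_rows("cc_mvmr", names(r$beta), r$beta, r$se, r$ci_lower, r$ci_upper,
             2 * stats::pnorm(-abs(r$beta / r$se)))
    log_stage("cc_mvmr", nrow(cohort), nrow(cohort))
  }

  if (isTRUE(stages_on$mediation)) {
    results$mediation <- run_stage("mediation", {
      md <- config$mediation
      bootstrap_mediation(cohort, geno, md$x, md$m, md$y,
                          md$x_snps %||% instruments[[md$x]],
                          md$m_snps %||% instruments[[md$m]],
                          covs, outcome_type,
                          method = md$method %||% "bb", B = md$B %||% 200,
                          seed = seed)
    })
    r <- results$mediation
    add_rows("mediation_pi_m", config$mediation$x, r$pi_m, NA_real_,
             r$ci[1], r$ci[2], NA_real_)
    log_stage("mediation", nrow(cohort), nrow(cohort))
  } else {
    log_stage("mediation", 0L, 0L, note = "skipped (disabled)")
  }

  if (isTRUE(stages_on$moderation)) {
    results$moderation <- run_stage("moderation", {
      mo <- config$moderation
      e <- mo$exposure %||% exposures[1]
      inst_e <- instruments[[e]]
      strat <- stratified_estimates(
        cohort, geno, by = mo$by, cutpoints = mo$cutpoints,
        estimator = function(co, g) {
          tsls_uvmr(g[, inst_e, drop = FALSE], co[[e]], co[[config$outcome]],
                    if (!is.null(config$covariates))
                      co[setdiff(config$covariates, mo$by)] else NULL,
                    outcome_type)
        })
      ok <- strat[is.na(strat$error), , drop = FALSE]
      if (nrow(ok) == 2L) {
        # two strata (e.g. sex): Fisher-z heterogeneity test
        list(strata = strat,
             fisher_z = fisher_z_heterogeneity(ok$beta[1], ok$se[1],
                                               ok$beta[2], ok$se[2]))
      } else {
        list(strata = strat,
             meta = meta_regression(strat, quadratic = isTRUE(mo$quadratic)))
      }
    })
    log_stage("moderation", nrow(cohort),
              sum(results$moderation$strata$n[is.na(results$moderation$strata$error)]))
  } else {
    log_stage("moderation", 0L, 0L, note = "skipped (disabled)")
  }

  # ---- outputs ----------------------------------------------------------
  run_stage("write", {
    tab <- do.call(rbind, rows)
    data.table::fwrite(tab, file.path(out_dir, "results.tsv"), sep = "\t")
    jsonlite::write_json(
      list(seed = seed, config_hash = cfg_hash, estimates = tab),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
    TRUE
  })
  manifest$results <- results
  jsonlite::write_json(manifest[setdiff(names(manifest), "results")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of the canonical YAML rendering of the config
#' @keywords internal
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
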
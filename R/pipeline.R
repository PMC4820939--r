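#' Read per-SNP summary statistics (and optional LD matrix) from TSV
#'
#' Summary-stats dialect: header columns `rsid`, `effect_allele`,
#' `other_allele`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#' `se_outcome`. The LD file is a TSV matrix with an rsid header row and
#' first column.
#'
#' @param file summary-statistics TSV path.
#' @param ld_file optional LD matrix TSV path.
#' @return An [mr_sumstats()].
#' @export
read_sumstats <- function(file, ld_file = NULL) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  ld <- NULL
  if (!is.null(ld_file)) {
    lr <- utils::read.delim(ld_file, row.names = 1, check.names = FALSE)
    ld <- as.matrix(lr)[d$rsid, d$rsid]
  }
  mr_sumstats(d$rsid, d$beta_exposure, d$se_exposure,
              d$beta_outcome, d$se_outcome, ld = ld,
              effect_allele = d$effect_allele %||% NA,
              other_allele = d$other_allele %||% NA)
}

#' Write summary statistics (and their LD matrix) to TSV
#'
#' @param stats an [mr_sumstats()].
#' @param file output TSV path; the LD matrix, if present, is written next to
#'   it with suffix `_ld.tsv`.
#' @return Paths written, invisibly.
#' @export
write_sumstats <- function(stats, file) {
  utils::write.table(as.data.frame(stats), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- file
  ld <- attr(stats, "ld")
  if (!is.null(ld)) {
    ld_file <- sub("\\.tsv$", "_ld.tsv", file)
    utils::write.table(data.frame(rsid = rownames(ld), ld, check.names = FALSE),
                       ld_file, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, ld_file)
  }
  invisible(paths)
}

resolve_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

sim_config_from_list <- function(lst) {
  lst <- lst[setdiff(names(lst), "")]
  if (!is.null(lst$causal_log_or)) lst$causal_log_or <- unlist(lst$causal_log_or)
  if (!is.null(lst$prevalence)) lst$prevalence <- unlist(lst$prevalence)
  do.call(sim_config, lst)
}

write_report_tables <- function(tables, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.data.frame(tb))
      utils::write.table(tb, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  invisible(out_dir)
}

tidy_effect_rows <- function(model, df) {
  cbind(data.frame(model = model, stringsAsFactors = FALSE),
        df[, c("term", "estimate", "se", "or", "ci_low", "ci_high", "p", "n_used")])
}

#' Run the individual-level cohort analysis end to end
#'
#' Simulates (or loads) genotypes and phenotypes, builds the weighted genetic
#' risk score and its tertiles, fits the per-tertile-trend logistic models for
#' case status, grade, stage (and any other binary outcome supplied), the
#' T1-referenced tertile contrasts for the grade outcome, the confounder
#' screen among controls, and — when survival columns are present — the
#' cluster-robust Cox models with the proportional-hazards check.
#'
#' @param config a list or YAML path with entries:
#'   `seed`; `sim` (arguments for [sim_config()]) or `genotypes` /
#'   `phenotypes` / `catalog` file paths; optional `tertile_basis`
#'   (`"all"`/`"controls"`), `outcomes` (default case, gleason_high,
#'   stage_advanced), `confounders` (default `"age"`), `out_dir`.
#' @return An `analysis_report` list with `tables` (tidy data frames),
#'   `tertiles`, `score`, `warnings` and the resolved `config`.
#' @export
run_cohort_analysis <- function(config) {
  config <- resolve_run_config(config)
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  if (!is.null(config$sim)) {
    sc <- sim_config_from_list(c(config$sim, list(seed = config$seed %||% config$sim$seed)))
    sim <- simulate_cohort(sc)
    cohort <- sim$cohort
    geno <- sim$genotypes
    catalog <- sc$catalog
  } else {
    catalog <- load_snp_catalog(config$catalog %||% "builtin")
    geno <- read_dosages(config$genotypes, catalog,
                         format = config$genotype_format %||% "tsv")
    if (!isTRUE(geno$harmonized)) geno <- harmonize_alleles(geno, catalog = catalog)
    cohort <- utils::read.csv(config$phenotypes, stringsAsFactors = FALSE)
    cohort$centre <- factor(cohort$centre)
    cohort$study_id <- factor(cohort$study_id %||% "study1")
  }
  score <- compute_score(geno, catalog)
  basis <- config$tertile_basis %||% "all"
  terts <- assign_tertiles(score, basis = basis, case = cohort$case)

  outcomes <- config$outcomes %||% c("case", "gleason_high", "stage_advanced")
  covars <- config$covariates %||% c("age", "centre", paste0("pc", 1:10))
  covars <- intersect(covars, names(cohort))
  trend_rows <- list(); contrast_tables <- list()
  for (oc in outcomes) {
    res <- tryCatch(tertile_analysis(cohort, terts, oc, covariates = covars),
                    error = function(e) {
                      note(sprintf("tertile analysis for '%s' failed: %s",
                                   oc, conditionMessage(e)))
                      NULL
                    })
    if (is.null(res)) next
    trend_rows[[oc]] <- tidy_effect_rows(paste0("trend_", oc), res$trend)
    contrast_tables[[oc]] <- cbind(
      tidy_effect_rows(paste0("tertiles_", oc), res$tertile_or),
      joint_p = res$joint_p)
  }
  screen <- tryCatch(
    confounder_screen(score, cohort, covariates = config$confounders %||% "age"),
    error = function(e) { note(conditionMessage(e)); NULL })

  surv_tables <- list()
  if (all(c("time_years", "event_prostate") %in% names(cohort)) &&
      any(!is.na(cohort$time_years))) {
    for (ep in c("prostate_specific", "all_cause")) {
      sf <- tryCatch(
        fit_cox(cohort, as.numeric(terts$tertile), endpoint = ep,
                horizon_years = config$horizon_years %||% 15,
                covariates = intersect(c("age"), names(cohort)),
                cluster = "study_id"),
        error = function(e) { note(sprintf("Cox (%s): %s", ep, conditionMessage(e))); NULL })
      if (is.null(sf)) next
      ph <- tryCatch(test_proportional_hazards(sf),
                     error = function(e) list(global_p = NA_real_))
      tb <- sf$estimates
      tb$model <- paste0("cox_", ep)
      tb$ph_global_p <- ph$global_p
      surv_tables[[ep]] <- tb[, c("model", "term", "estimate", "se", "hr",
                                  "ci_low", "ci_high", "p", "n_used", "ph_global_p")]
    }
  }
  bind_rows0 <- function(lst) if (length(lst)) do.call(rbind, unname(lst)) else NULL
  tables <- c(list(trend = bind_rows0(trend_rows),
                   tertile_contrasts = bind_rows0(contrast_tables),
                   confounder_screen = screen),
              surv_tables)
  tables <- tables[!vapply(tables, is.null, logical(1))]
  if (!is.null(config$out_dir)) write_report_tables(tables, config$out_dir, config)
  structure(list(tables = tables, score = score, tertiles = terts,
                 cohort = cohort, warnings = warnings_log, config = config),
            class = "analysis_report")
}

#' Run the summarized-data MR analysis end to end
#'
#' Orientation to Tanner-decreasing alleles, per-variant Wald ratios, the
#' correlated-variant allele-score estimate, MR-Egger (skipped with a logged
#' reason below 3 SNPs), cross-variant heterogeneity, and the funnel and
#' effect-versus-effect plot tables.
#'
#' @param config list or YAML path with either `summary_stats` (+ optional
#'   `ld_matrix`) file paths, or `sim` = list(`n_exposure`, `n_outcome`,
#'   `outcome`, plus [sim_config()] arguments under `config`); optional
#'   `seed`, `out_dir`, `exposure_uncertainty`.
#' @return An `analysis_report` with the `mr_analysis` object and tidy tables.
#' @export
run_mr_analysis <- function(config) {
  config <- resolve_run_config(config)
  if (!is.null(config$sim)) {
    sc <- sim_config_from_list(c(config$sim$config,
                                 list(seed = config$seed %||% NULL)))
    stats <- simulate_summary_study(sc,
                                    n_exposure = config$sim$n_exposure,
                                    n_outcome = config$sim$n_outcome,
                                    outcome = config$sim$outcome %||% "case")
  } else {
    stats <- read_sumstats(config$summary_stats, config$ld_matrix)
  }
  res <- mr_analysis(stats,
                     exposure_uncertainty = config$exposure_uncertainty %||% TRUE)
  tables <- list(mr_estimates = summary(res),
                 wald_ratios = res$wald,
                 funnel = res$funnel)
  if (!is.null(res$fig_effect)) tables$fig_effect <- res$fig_effect$points
  if (!is.null(config$out_dir)) write_report_tables(tables, config$out_dir, config)
  structure(list(tables = tables, mr = res,
                 warnings = res$skipped, config = config),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report with tables:", paste(names(x$tables), collapse = ", "), "\n")
  if (length(x$warnings)) cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Operating characteristics of the summarized-data estimators by simulation
#'
#' Runs replicate two-sample simulations over a scenario grid and reports, per
#' scenario: mean and median IVW estimate, bias against the generative causal
#' log-OR, empirical SE, mean model SE, 95% CI coverage, rejection rate of the
#' IVW test (type-I error under the null, power otherwise) and of the
#' MR-Egger intercept test, with Monte-Carlo standard errors.
#'
#' @param config list or YAML path: `seed` (master seed), `scenarios` = list
#'   of scenario lists, each with `name`, `n_reps`, `n_exposure`, `n_outcome`,
#'   `outcome` (default `"case"`), `causal_or` (OR per Tanner-unit decrease),
#'   optional `pleiotropy`, `pleiotropy_magnitude` and other [sim_config()]
#'   overrides under `config`; optional `exposure_uncertainty` and `out_dir`.
#' @return Data frame with one row per scenario (class
#'   `simulation_study`), with per-replicate results in
#'   `attr(, "replicates")`.
#' @export
run_simulation_study <- function(config) {
  config <- resolve_run_config(config)
  master <- config$seed %||% 1L
  rows <- list(); reps_all <- list()
  for (si in seq_along(config$scenarios)) {
    sc_def <- config$scenarios[[si]]
    name <- sc_def$name %||% paste0("scenario", si)
    outcome <- sc_def$outcome %||% "case"
    truth <- log(sc_def$causal_or %||% 1)
    overrides <- sc_def$config %||% list()
    clo <- c(case = 0, high_grade = 0, advanced_stage = 0)
    clo[outcome] <- truth
    overrides$causal_log_or <- clo
    if (!is.null(sc_def$pleiotropy)) overrides$pleiotropy <- sc_def$pleiotropy
    if (!is.null(sc_def$pleiotropy_magnitude))
      overrides$pleiotropy_magnitude <- sc_def$pleiotropy_magnitude
    base_cfg <- sim_config_from_list(overrides)
    n_reps <- sc_def$n_reps
    est <- se <- p <- egger_p <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      cfg <- base_cfg
      cfg$seed <- (master * 10000L + si * 1000L + r) %% .Machine$integer.max
      ss <- simulate_summary_study(cfg, sc_def$n_exposure, sc_def$n_outcome,
                                   outcome = outcome)
      res <- mr_analysis(ss, exposure_uncertainty = config$exposure_uncertainty %||% TRUE)
      est[r] <- res$ivw$estimate
      se[r] <- res$ivw$se
      p[r] <- res$ivw$p
      if (!is.null(res$egger)) egger_p[r] <- res$egger$intercept$p
    }
    cover <- mean(truth >= est - 1.96 * se & truth <= est + 1.96 * se)
    reject <- mean(p < 0.05)
    egger_reject <- mean(egger_p < 0.05, na.rm = TRUE)
    rows[[name]] <- data.frame(
      scenario = name, n_reps = n_reps, truth_log_or = truth,
      mean_estimate = mean(est), median_estimate = stats::median(est),
      bias = mean(est) - truth, empirical_se = stats::sd(est),
      mean_model_se = mean(se), coverage = cover,
      coverage_mc_se = sqrt(cover * (1 - cover) / n_reps),
      reject_rate = reject,
      reject_mc_se = sqrt(reject * (1 - reject) / n_reps),
      egger_intercept_reject = egger_reject,
      stringsAsFactors = FALSE)
    reps_all[[name]] <- data.frame(scenario = name, rep = seq_len(n_reps),
                                   estimate = est, se = se, p = p,
                                   egger_intercept_p = egger_p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- do.call(rbind, reps_all)
  class(out) <- c("simulation_study", "data.frame")
  if (!is.null(config$out_dir))
    write_report_tables(list(operating_characteristics = out), config$out_dir, config)
  out
}
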
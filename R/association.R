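#' Covariate-adjusted logistic regression
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`, deviance
#' convergence 1e-10, at most 100 iterations) with explicit diagnostics:
#' rank-deficient design matrices are an error naming the collinear columns,
#' and (quasi-)complete separation — detected as non-convergence together
#' with a diverging coefficient (|b| > 15 on the logit scale) or fitted
#' probabilities collapsing to 0/1 — is an explicit error rather than a
#' silently huge estimate.
#'
#' @param outcome binary 0/1 vector.
#' @param exposure numeric vector or factor of interest; `NULL` fits the
#'   covariate-only (null) model, e.g. as the reference for a joint
#'   likelihood-ratio test.
#' @param covariates optional data frame (or matrix) of adjustment covariates;
#'   factors are expanded to indicators.
#' @param exposure_name label for the exposure term(s).
#' @return An `effect_estimate` data frame: one row per model term with
#'   `term`, `estimate` (log-OR), `se`, `or`, `ci_low`, `ci_high` (Wald, OR
#'   scale), `p`, `n_used`. Rows for the exposure carry `is_exposure = TRUE`.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         exposure_name = "exposure") {
  if (length(unique(stats::na.omit(outcome))) < 2)
    stop("outcome is constant; logistic model undefined")
  df <- if (is.null(exposure)) data.frame(.y = outcome)
        else data.frame(.y = outcome, .x = exposure)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    df <- cbind(df, covariates)
  }
  df <- stats::na.omit(df)
  n_used <- nrow(df)
  if (n_used <= ncol(df)) stop("fewer observations than parameters")
  mm <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(mm, df$.y, family = stats::binomial(),
                                         control = list(epsilon = 1e-10, maxit = 100)))
  big <- abs(fit$coefficients) > 15
  # perfect separation: the deviance collapses to zero (every observation
  # fitted exactly), or a coefficient diverges while probabilities saturate
  probs_collapsed <- any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  if (fit$deviance < 1e-6 || (any(big) && (probs_collapsed || !fit$converged)))
    stop("perfect separation detected (diverging coefficient(s): ",
         paste(names(fit$coefficients)[abs(fit$coefficients) ==
                                         max(abs(fit$coefficients))],
               collapse = ", "), ")")
  if (!fit$converged) stop("IRLS failed to converge in 100 iterations")
  # Wald covariance from the final weighted least-squares step
  w <- fit$weights
  xtx <- crossprod(mm * sqrt(w))
  vc <- chol2inv(chol(xtx))
  se <- sqrt(diag(vc))
  b <- fit$coefficients
  q <- stats::qnorm(0.975)
  out <- data.frame(term = colnames(mm), estimate = b, se = se,
                    or = exp(b), ci_low = exp(b - q * se), ci_high = exp(b + q * se),
                    p = 2 * stats::pnorm(-abs(b / se)),
                    n_used = n_used,
                    is_exposure = grepl("^\\.x", colnames(mm)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$term <- sub("^\\.x", exposure_name, out$term)
  attr(out, "loglik") <- -fit$deviance / 2
  attr(out, "deviance") <- fit$deviance
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Tertile dose-response analysis
#'
#' Fits the two standard codings of the score tertiles against a binary
#' outcome, both adjusted for the supplied covariates: model A uses indicator
#' coding with T1 (earliest maturation) as reference, giving OR(T2), OR(T3)
#' and a joint likelihood-ratio p-value; model B enters the tertile as a
#' numeric 1-3 trend, giving the per-tertile-increase OR (the linearity
#' contrast).
#'
#' @param cohort a `cohort_table` (or any data frame with the outcome column).
#' @param tertiles a `tertile_assignment` aligned with `cohort`.
#' @param outcome column name of a binary outcome (`"case"`,
#'   `"gleason_high"`, `"stage_advanced"`, ...). Rows where the outcome is
#'   `NA` (e.g. grade among controls) are dropped.
#' @param covariates character vector of covariate column names; default age,
#'   centre and the 10 principal components.
#' @return List with `tertile_or` (model A rows for T2, T3), `joint_p`,
#'   `trend` (model B exposure row) and `n`.
#' @export
tertile_analysis <- function(cohort, tertiles, outcome,
                             covariates = c("age", "centre", paste0("pc", 1:10))) {
  stopifnot(nrow(cohort) == nrow(tertiles))
  y <- cohort[[outcome]]
  keep <- !is.na(y)
  if (!any(keep)) stop("outcome '", outcome, "' is never observed")
  y <- y[keep]
  tert <- tertiles$tertile[keep]
  covs <- cohort[keep, intersect(covariates, names(cohort)), drop = FALSE]
  covs <- droplevels(covs)
  tab <- table(tert, y)
  if (any(tab == 0))
    stop("empty tertile-by-outcome cell for '", outcome,
         "'; consider exact methods")
  mA <- fit_logistic(y, droplevels(tert), covs, exposure_name = "tertile")
  m0 <- fit_logistic(y, NULL, covs)
  lrt <- attr(m0, "deviance") - attr(mA, "deviance")
  joint_p <- stats::pchisq(lrt, df = sum(mA$is_exposure), lower.tail = FALSE)
  mB <- fit_logistic(y, as.numeric(tert), covs, exposure_name = "tertile_trend")
  list(tertile_or = mA[mA$is_exposure, , drop = FALSE],
       joint_p = joint_p,
       trend = mB[mB$is_exposure, , drop = FALSE],
       n = length(y))
}

#' Two-group comparison (cases vs controls)
#'
#' Welch two-sided t-test for continuous variables (optionally after a
#' natural-log transform) and Pearson's chi-square test without continuity
#' correction for categorical ones — the standard baseline-table tests.
#'
#' @param casevals values in cases (continuous vector, or category labels).
#' @param controlvals values in controls.
#' @param kind `"continuous"` or `"categorical"`.
#' @param log_transform natural-log transform before the t-test.
#' @return List with `p`, the test statistic, and per-group summaries
#'   (mean/SD/n for continuous, a proportion table for categorical).
#' @export
compare_groups <- function(casevals, controlvals,
                           kind = c("continuous", "categorical"),
                           log_transform = FALSE) {
  kind <- match.arg(kind)
  casevals <- casevals[!is.na(casevals)]
  controlvals <- controlvals[!is.na(controlvals)]
  if (kind == "continuous") {
    if (length(casevals) < 2 || length(controlvals) < 2)
      stop("need at least 2 observations per group")
    if (log_transform) {
      casevals <- log(casevals); controlvals <- log(controlvals)
    }
    if (stats::var(casevals) == 0 && stats::var(controlvals) == 0) {
      if (mean(casevals) == mean(controlvals))
        return(list(p = 1, statistic = 0, method = "welch_t",
                    summary = group_moments(casevals, controlvals)))
      stop("zero variance in both groups with different means")
    }
    ht <- stats::t.test(casevals, controlvals, var.equal = FALSE)
    list(p = ht$p.value, statistic = unname(ht$statistic), method = "welch_t",
         summary = group_moments(casevals, controlvals))
  } else {
    tab <- rbind(case = table(factor(casevals)),
                 control = table(factor(controlvals, levels = levels(factor(casevals)))))
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
      stop("zero margin in the contingency table")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(p = ht$p.value, statistic = unname(ht$statistic), method = "chisq",
         summary = prop.table(tab, 1))
  }
}

group_moments <- function(x, y) {
  data.frame(group = c("case", "control"),
             mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
             n = c(length(x), length(y)))
}

#' Screen potential confounders against the genetic score
#'
#' Among controls, regresses each covariate on the score: linear regression
#' for continuous covariates, logistic for binary ones. A genetic score valid
#' as an instrument should show no associations here. Unadjusted p-values are
#' reported (mirroring how such screens are usually read), with a Bonferroni
#' column emitted alongside.
#'
#' @param scores a `score_vector` or numeric vector aligned with `cohort`.
#' @param cohort data frame containing `case` and the covariates.
#' @param covariates character vector of covariate columns to screen; default
#'   screens `age`.
#' @return Data frame with one row per covariate: `covariate`, `type`,
#'   `estimate` (per unit score), `se`, `ci_low`, `ci_high`, `p`,
#'   `p_bonferroni`, `n`.
#' @export
confounder_screen <- function(scores, cohort, covariates = c("age")) {
  s <- if (is.data.frame(scores)) scores$score else scores
  stopifnot(length(s) == nrow(cohort))
  ctrl <- cohort$case == 0
  if (!any(ctrl)) stop("no controls available for the confounder screen")
  rows <- list()
  for (cv in covariates) {
    x <- cohort[[cv]][ctrl]
    sc <- s[ctrl]
    ok <- !is.na(x)
    if (!any(ok)) {
      warning("covariate '", cv, "' is entirely missing among controls; skipped")
      next
    }
    x <- x[ok]; sc <- sc[ok]
    vals <- unique(x)
    if (length(vals) <= 2) {
      xb <- as.integer(x == max(vals))
      fit <- fit_logistic(xb, sc, exposure_name = "score")
      row <- fit[fit$is_exposure, ]
      rows[[cv]] <- data.frame(covariate = cv, type = "binary",
                               estimate = row$estimate, se = row$se,
                               ci_low = row$estimate - 1.96 * row$se,
                               ci_high = row$estimate + 1.96 * row$se,
                               p = row$p, n = row$n_used,
                               stringsAsFactors = FALSE)
    } else {
      fit <- stats::lm(x ~ sc)
      cf <- summary(fit)$coefficients["sc", ]
      rows[[cv]] <- data.frame(covariate = cv, type = "continuous",
                               estimate = cf[1], se = cf[2],
                               ci_low = cf[1] - 1.96 * cf[2],
                               ci_high = cf[1] + 1.96 * cf[2],
                               p = cf[4], n = length(x),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Cox proportional-hazards model with cluster-robust standard errors
#'
#' Cox partial likelihood with Efron tie handling among cases, with
#' administrative censoring at `horizon_years` and a cluster-sandwich
#' (robust) variance grouped by study. The prostate-specific endpoint treats
#' other-cause deaths as censored; the all-cause endpoint counts both. With a
#' single cluster level the sandwich variance is degenerate, so the fit falls
#' back to model-based standard errors with a warning (the documented
#' degenerate-clustering contract).
#'
#' @param cohort a `cohort_table`; only rows with `case == 1` and survival
#'   data enter the model.
#' @param exposure numeric vector (e.g. tertile coded 1-3) aligned with
#'   `cohort`, or the name of a column.
#' @param endpoint `"prostate_specific"` or `"all_cause"`.
#' @param horizon_years administrative censoring horizon (default 15).
#' @param covariates covariate column names (default `"age"`).
#' @param cluster column with the study label (default `"study_id"`).
#' @return A `survival_fit`: per-term `estimates` table (log-HR scale with
#'   robust SEs), the underlying `coxph` fit, `robust` flag, the cluster
#'   variable and `max_followup`.
#' @export
fit_cox <- function(cohort, exposure, endpoint = c("prostate_specific", "all_cause"),
                    horizon_years = 15, covariates = c("age"),
                    cluster = "study_id") {
  endpoint <- match.arg(endpoint)
  if (is.character(exposure) && length(exposure) == 1) exposure <- cohort[[exposure]]
  stopifnot(length(exposure) == nrow(cohort))
  keep <- cohort$case == 1 & !is.na(cohort$time_years) & !is.na(exposure)
  d <- cohort[keep, , drop = FALSE]
  x <- exposure[keep]
  if (any(d$time_years < 0)) stop("negative survival times")
  ev <- if (endpoint == "prostate_specific") d$event_prostate
        else as.integer(d$event_prostate == 1 | d$event_other == 1)
  over <- d$time_years > horizon_years
  ev[over] <- 0L
  t_h <- pmin(d$time_years, horizon_years)
  if (sum(ev) < 1) stop("no events within the ", horizon_years, "-year horizon")
  mf <- data.frame(.time = t_h, .event = ev, .x = x)
  for (cv in covariates) mf[[cv]] <- d[[cv]]
  cl <- d[[cluster]]
  n_clusters <- length(unique(cl))
  robust <- n_clusters > 1
  if (!robust)
    warning("cluster variable has a single level; using model-based standard errors")
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~ .x",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- if (robust)
    survival::coxph(form, data = mf, ties = "efron", cluster = cl, x = TRUE)
  else
    survival::coxph(form, data = mf, ties = "efron", x = TRUE)
  b <- stats::coef(fit)
  if (any(is.na(b)))
    stop("constant or collinear term(s) in the Cox model: ",
         paste(names(b)[is.na(b)], collapse = ", "))
  se <- sqrt(diag(fit$var))  # robust when a cluster term is present
  q <- stats::qnorm(0.975)
  est <- data.frame(term = sub("^\\.x", "exposure", names(b)),
                    estimate = b, se = se, hr = exp(b),
                    ci_low = exp(b - q * se), ci_high = exp(b + q * se),
                    p = 2 * stats::pnorm(-abs(b / se)),
                    n_used = fit$n, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(estimates = est, coxph = fit, robust = robust,
                 cluster_variable = cluster, n_clusters = n_clusters,
                 n_events = sum(ev), max_followup = max(t_h),
                 endpoint = endpoint, horizon_years = horizon_years),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s, %g-year horizon): %d events, %s SEs (%d cluster(s))\n",
              x$endpoint, x$horizon_years, x$n_events,
              if (x$robust) "cluster-robust" else "model-based", x$n_clusters))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' @export
coef.survival_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$term)
}

#' Proportional-hazards check on scaled Schoenfeld residuals
#'
#' Score test of the correlation between scaled Schoenfeld residuals and a
#' transform of event time (Kaplan-Meier transform by default), per term and
#' globally. A small p indicates a time-varying effect, i.e. a violation of
#' proportional hazards.
#'
#' @param fit a `survival_fit` from [fit_cox()].
#' @param transform time transform, default `"km"`.
#' @return List with `global_p`, the per-term `table` (chisq, df, p) and the
#'   transform used.
#' @export
test_proportional_hazards <- function(fit, transform = "km") {
  if (fit$n_events < 10)
    stop("too few events (", fit$n_events, ") for a proportional-hazards check")
  zph <- survival::cox.zph(fit$coxph, transform = transform, global = TRUE)
  tab <- as.data.frame(zph$table)
  list(global_p = tab["GLOBAL", "p"],
       table = tab, transform = transform)
}
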
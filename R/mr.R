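#' Per-SNP summary statistics for summarized-data Mendelian randomization
#'
#' Container for the two-sample inputs: per-SNP effects on the exposure and on
#' the outcome, with an optional LD correlation matrix. The exposure is the
#' pubertal delay measured as Tanner-stage DECREASE, so `beta_exposure` is the
#' per-allele Tanner-stage decrease (positive for a Tanner-decreasing effect
#' allele) and every causal estimate downstream is a log odds ratio per unit
#' decrease in Tanner stage: protective effects appear as OR < 1.
#'
#' @param rsid SNP identifiers.
#' @param beta_exposure per-allele effect on Tanner-stage decrease.
#' @param se_exposure its standard error (> 0).
#' @param beta_outcome per-allele log-OR on the outcome.
#' @param se_outcome its standard error (> 0).
#' @param ld J x J LD correlation matrix (unit diagonal, symmetric); `NULL`
#'   means independence (identity), which triggers a warning downstream in
#'   [ivw_correlated()] since the catalog contains variants in the same gene
#'   region.
#' @param effect_allele,other_allele optional allele labels.
#' @return An `mr_sumstats` data frame with the LD matrix in `attr(, "ld")`.
#' @export
mr_sumstats <- function(rsid, beta_exposure, se_exposure, beta_outcome,
                        se_outcome, ld = NULL, effect_allele = NA,
                        other_allele = NA) {
  stopifnot(length(rsid) == length(beta_exposure),
            length(rsid) == length(se_exposure),
            length(rsid) == length(beta_outcome),
            length(rsid) == length(se_outcome))
  if (anyDuplicated(rsid)) stop("duplicate rsids in summary statistics")
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop("standard errors must be strictly positive")
  if (!is.null(ld)) {
    ld <- as.matrix(ld)
    if (nrow(ld) != length(rsid) || ncol(ld) != length(rsid))
      stop("LD matrix dimension does not match the number of SNPs")
    if (max(abs(ld - t(ld))) > 1e-8) stop("LD matrix must be symmetric")
    if (max(abs(diag(ld) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
    ld <- (ld + t(ld)) / 2
    dimnames(ld) <- list(rsid, rsid)
  }
  out <- data.frame(rsid = rsid,
                    effect_allele = effect_allele, other_allele = other_allele,
                    beta_exposure = beta_exposure, se_exposure = se_exposure,
                    beta_outcome = beta_outcome, se_outcome = se_outcome,
                    stringsAsFactors = FALSE)
  attr(out, "ld") <- ld
  class(out) <- c("mr_sumstats", "data.frame")
  out
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat(sprintf("Per-SNP summary statistics: %d variants (%s LD matrix)\n",
              nrow(x), if (is.null(attr(x, "ld"))) "no" else "with"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Orient summary statistics to Tanner-decreasing effect alleles
#'
#' Recodes any SNP whose recorded effect allele has a negative effect on the
#' Tanner-stage decrease (i.e. the allele actually advances puberty): both
#' `beta_exposure` and `beta_outcome` change sign and the allele labels swap,
#' which leaves every Wald ratio unchanged. The operation is an involution.
#' A SNP with `beta_exposure` exactly 0 cannot be oriented or used in
#' ratio-based methods; it is flagged in the `excluded` column.
#'
#' @param stats an [mr_sumstats()].
#' @return The oriented `mr_sumstats`, with a logical `excluded` column.
#' @export
orient_to_exposure_decreasing <- function(stats) {
  flip <- stats$beta_exposure < 0
  out <- stats
  out$beta_exposure[flip] <- -stats$beta_exposure[flip]
  out$beta_outcome[flip] <- -stats$beta_outcome[flip]
  if (!all(is.na(out$effect_allele))) {
    ea <- out$effect_allele; oa <- out$other_allele
    out$effect_allele[flip] <- oa[flip]
    out$other_allele[flip] <- ea[flip]
  }
  out$excluded <- stats$beta_exposure == 0
  if (any(out$excluded))
    warning("SNP(s) with zero exposure effect flagged for exclusion: ",
            paste(out$rsid[out$excluded], collapse = ", "))
  attr(out, "ld") <- attr(stats, "ld")  # correlations are sign-invariant under...
  # NB: flipping an allele negates its dosage correlation with other SNPs.
  ld <- attr(stats, "ld")
  if (!is.null(ld) && any(flip)) {
    s <- ifelse(flip, -1, 1)
    ld <- ld * tcrossprod(s)
    attr(out, "ld") <- ld
  }
  class(out) <- class(stats)
  out
}

usable_stats <- function(stats, min_snps = 1, method = "this method") {
  if (!is.null(stats$excluded)) {
    keep <- !stats$excluded
    ld <- attr(stats, "ld")
    stats <- stats[keep, , drop = FALSE]
    if (!is.null(ld)) attr(stats, "ld") <- ld[keep, keep, drop = FALSE]
  }
  if (any(stats$beta_exposure == 0))
    stop("SNP(s) with zero exposure effect; run orient_to_exposure_decreasing() first")
  if (nrow(stats) < min_snps)
    stop(sprintf("%s requires at least %d usable SNP(s), got %d",
                 method, min_snps, nrow(stats)))
  stats
}

#' Construct a causal-estimate record
#'
#' @param method method label.
#' @param estimate log-OR per unit Tanner-stage decrease.
#' @param se standard error.
#' @param p two-sided p-value.
#' @param n_snps number of variants used.
#' @param heterogeneity optional list `(Q, df, p, i2)`.
#' @param ci_quantile quantile used for the 95% interval (1.96 for normal).
#' @return A `causal_estimate` object; `exp(estimate)` is reported alongside
#'   as an odds ratio.
#' @export
causal_estimate <- function(method, estimate, se, p = NULL, n_snps = NA,
                            heterogeneity = NULL, ci_quantile = stats::qnorm(0.975)) {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(estimate / se))
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = estimate - ci_quantile * se,
                 ci_high = estimate + ci_quantile * se,
                 p = p, n_snps = n_snps, heterogeneity = heterogeneity),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (95%% CI %.3f-%.3f) per unit Tanner decrease; log-OR %.4f (SE %.4f), p = %.3g, %s SNP(s)\n",
              x$method, exp(x$estimate), exp(x$ci_low), exp(x$ci_high),
              x$estimate, x$se, x$p, x$n_snps))
  if (!is.null(x$heterogeneity))
    cat(sprintf("  heterogeneity: Q = %.3f (df %d), p = %.3g, I2 = %.1f%%\n",
                x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$p,
                x$heterogeneity$i2))
  invisible(x)
}

#' @export
coef.causal_estimate <- function(object, ...) {
  setNames(object$estimate, object$method)
}

#' @export
confint.causal_estimate <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  matrix(c(object$estimate - q * object$se, object$estimate + q * object$se),
         nrow = 1, dimnames = list(object$method, c("low", "high")))
}

#' Single-variant Wald ratio
#'
#' The causal log-OR from one instrument: `beta_outcome / beta_exposure`. The
#' default standard error is the first-order delta approximation
#' `|se_outcome / beta_exposure|`, which ignores exposure-side uncertainty
#' (NO-Measurement-Error-style); `order = 2` adds the second-order term
#' `beta_outcome^2 se_exposure^2 / beta_exposure^4`.
#'
#' @param b_x,se_x per-allele exposure effect (Tanner-stage decrease) and SE.
#' @param b_y,se_y per-allele outcome log-OR and SE.
#' @param order 1 (default) or 2, the delta-method order for the SE.
#' @return For scalar input a `causal_estimate`; for vector input a data frame
#'   with one row per SNP.
#' @export
wald_ratio <- function(b_x, se_x, b_y, se_y, order = 1) {
  if (any(b_x == 0)) stop("Wald ratio undefined for zero exposure effect")
  est <- b_y / b_x
  se <- abs(se_y / b_x)
  if (order == 2) se <- sqrt(se_y^2 / b_x^2 + b_y^2 * se_x^2 / b_x^4)
  if (length(est) == 1)
    return(causal_estimate("wald_single", est, se, n_snps = 1))
  data.frame(estimate = est, se = se,
             p = 2 * stats::pnorm(-abs(est / se)))
}

# Regularized inverse of an LD-scaled covariance: eigenvalues of the LD
# correlation matrix floored at `floor_frac` of the largest.
regularize_ld <- function(R, floor_frac = 1e-6) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < floor_frac * max(ev$values)) {
    ev$values <- pmax(ev$values, floor_frac * max(ev$values))
    R <- ev$vectors %*% (ev$values * t(ev$vectors))
  }
  attr(R, "condition_number") <- max(ev$values) / min(ev$values)
  R
}

#' Summarized-data allele-score causal estimate with correlated variants
#'
#' Generalized inverse-variance-weighted estimator
#' \deqn{\hat\beta = \frac{b_X^\top \Omega^{-1} b_Y}{b_X^\top \Omega^{-1} b_X},}
#' with \eqn{\Omega_{jk} = se_{Yj} se_{Yk} \rho_{jk}} and \eqn{\rho} the LD
#' correlation matrix. With `exposure_uncertainty = TRUE` (default) the
#' weighting matrix additionally carries the exposure-side sampling variance,
#' \eqn{\Omega_{jk} + \hat\beta^2 se_{Xj} se_{Xk} \rho_{jk}}, iterated to
#' convergence; this keeps confidence intervals calibrated when the
#' instrument-exposure effects are estimated with non-negligible error, and
#' reduces to the textbook formula as \eqn{se_X \to 0} (set
#' `exposure_uncertainty = FALSE` for the exact textbook form). With a single
#' SNP and identity LD the result reduces to the Wald ratio.
#'
#' Heterogeneity is the generalized Cochran statistic
#' \eqn{Q = r^\top \Omega^{-1} r} of the residuals
#' \eqn{r = b_Y - \hat\beta b_X}, with `df = J - 1` and
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param stats an oriented [mr_sumstats()].
#' @param exposure_uncertainty include the exposure-side variance term in the
#'   weighting matrix (default `TRUE`).
#' @param ld_floor eigenvalue floor for LD regularization, as a fraction of
#'   the largest eigenvalue.
#' @return A `causal_estimate` with method `"ivw_correlated"` and a
#'   heterogeneity block.
#' @export
ivw_correlated <- function(stats, exposure_uncertainty = TRUE, ld_floor = 1e-6) {
  stats <- usable_stats(stats, 1, "ivw_correlated")
  J <- nrow(stats)
  R <- attr(stats, "ld")
  if (is.null(R)) {
    if (J > 1)
      warning("no LD matrix supplied: assuming independent variants (identity LD)")
    R <- diag(J)
  }
  R <- regularize_ld(R, ld_floor)
  bx <- stats$beta_exposure; by <- stats$beta_outcome
  omega0 <- outer(stats$se_outcome, stats$se_outcome) * R
  solve_beta <- function(om) {
    ch <- tryCatch(chol(om), error = function(e)
      stop("weighting matrix is singular (condition number ",
           format(attr(R, "condition_number"), digits = 3),
           "); consider a larger ld_floor"))
    xi <- backsolve(ch, forwardsolve(t(ch), bx))
    yi <- backsolve(ch, forwardsolve(t(ch), by))
    list(beta = sum(bx * yi) / sum(bx * xi), info = sum(bx * xi), ch = ch)
  }
  fit <- solve_beta(omega0)
  if (exposure_uncertainty) {
    omx <- outer(stats$se_exposure, stats$se_exposure) * R
    for (it in 1:50) {
      beta_old <- fit$beta
      fit <- solve_beta(omega0 + beta_old^2 * omx)
      if (abs(fit$beta - beta_old) < 1e-12) break
    }
  }
  se <- 1 / sqrt(fit$info)
  r <- by - fit$beta * bx
  ri <- backsolve(fit$ch, forwardsolve(t(fit$ch), r))
  Q <- sum(r * ri)
  df <- max(J - 1, 1)
  het <- list(Q = Q, df = df,
              p = if (J > 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
              i2 = if (J > 1) max(0, (Q - df) / Q) * 100 else NA_real_)
  causal_estimate("ivw_correlated", fit$beta, se, n_snps = J, heterogeneity = het)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the SNP-outcome effects on the
#' SNP-exposure effects WITH an intercept, weights `1/se_outcome^2`, exposure
#' effects oriented positive (Tanner-decreasing). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect, and its p-value is the formal test for
#' directional pleiotropy. Standard errors carry a multiplicative
#' overdispersion factor floored at 1; p-values and confidence intervals use
#' the normal reference distribution (with the floor, a t reference would
#' make the intercept test markedly conservative at typical instrument
#' counts).
#'
#' @param stats an oriented [mr_sumstats()] with at least 3 usable SNPs.
#' @return List with `slope` and `intercept`, both `causal_estimate`s
#'   (class `mr_egger`).
#' @export
mr_egger <- function(stats) {
  stats <- usable_stats(stats, 3, "MR-Egger regression")
  if (any(stats$beta_exposure < 0))
    stop("MR-Egger requires exposure effects oriented positive; run orient_to_exposure_decreasing()")
  bx <- stats$beta_exposure; by <- stats$beta_outcome
  if (max(bx) - min(bx) < 1e-12) stop("no spread in exposure effects; Egger slope undefined")
  w <- 1 / stats$se_outcome^2
  J <- length(bx)
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  b0 <- (swxx * swy - swx * swxy) / det
  b1 <- (sw * swxy - swx * swy) / det
  resid <- by - b0 - b1 * bx
  sigma2 <- sum(w * resid^2) / (J - 2)
  infl <- max(1, sigma2)
  se0 <- sqrt(infl * swxx / det)
  se1 <- sqrt(infl * sw / det)
  out <- list(
    slope = causal_estimate("egger_slope", b1, se1, n_snps = J),
    intercept = causal_estimate("egger_intercept", b0, se0, n_snps = J),
    overdispersion = sqrt(infl))
  class(out) <- "mr_egger"
  out
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("MR-Egger regression\n  ")
  print(x$slope)
  cat(sprintf("  intercept (directional pleiotropy): %.4f (SE %.4f), p = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$p))
  invisible(x)
}

#' Heterogeneity across per-variant causal estimates
#'
#' Cochran's Q over the per-variant Wald ratios about their fixed-effect
#' (inverse-variance-weighted) pooled value, with first-order ratio SEs
#' `se_outcome / |beta_exposure|` (weights `beta_exposure^2 / se_outcome^2`).
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param stats an oriented [mr_sumstats()] with >= 2 usable SNPs.
#' @return List `(Q, df, p, i2)`.
#' @export
heterogeneity_across_variants <- function(stats) {
  stats <- usable_stats(stats, 2, "heterogeneity across variants")
  ratio <- stats$beta_outcome / stats$beta_exposure
  w <- (stats$beta_exposure / stats$se_outcome)^2
  pooled <- sum(w * ratio) / sum(w)
  Q <- sum(w * (ratio - pooled)^2)
  df <- nrow(stats) - 1
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       i2 = max(0, (Q - df) / Q * 100))
}

#' Funnel-plot table
#'
#' Plot-ready per-SNP table of single-variant causal estimates against their
#' precision; no inference is attached. Symmetry about the pooled estimate is
#' the visual check for directional pleiotropy.
#'
#' @param stats an oriented [mr_sumstats()].
#' @return Data frame with `rsid`, `estimate` (Wald ratio) and `precision`
#'   (1/SE).
#' @export
funnel_table <- function(stats) {
  stats <- usable_stats(stats, 1, "funnel table")
  wr <- wald_ratio(stats$beta_exposure, stats$se_exposure,
                   stats$beta_outcome, stats$se_outcome)
  if (inherits(wr, "causal_estimate"))
    wr <- data.frame(estimate = wr$estimate, se = wr$se, p = wr$p)
  data.frame(rsid = stats$rsid, estimate = wr$estimate,
             precision = 1 / wr$se, stringsAsFactors = FALSE)
}

#' Through-the-origin trend of risk reduction against instrument strength
#'
#' Produces the effect-versus-effect trend: each SNP's outcome effect as a
#' proportional risk reduction, `1 - exp(beta_outcome)`, regressed without an
#' intercept on its (positive) effect on lowering Tanner stage. The slope is
#' the linearized percentage risk reduction per unit decrease in Tanner
#' stage. Also returns the squared Pearson correlation between the raw
#' `beta_exposure` and `beta_outcome` vectors (invariant to rescaling either
#' axis), and the origin-constrained R-squared, since either convention may
#' be of interest.
#'
#' @param stats an oriented [mr_sumstats()] with >= 2 usable SNPs.
#' @param outcome_scale only `"risk_reduction"` is defined.
#' @return List with `slope`, `r_squared` (Pearson, unconstrained),
#'   `r_squared_origin` and the per-SNP plotting table `points`.
#' @export
origin_regression <- function(stats, outcome_scale = "risk_reduction") {
  outcome_scale <- match.arg(outcome_scale, "risk_reduction")
  stats <- usable_stats(stats, 2, "origin regression")
  x <- abs(stats$beta_exposure)
  y <- 1 - exp(stats$beta_outcome)
  slope <- sum(x * y) / sum(x^2)
  r2 <- stats::cor(stats$beta_exposure, stats$beta_outcome)^2
  r2_origin <- 1 - sum((y - slope * x)^2) / sum(y^2)
  list(slope = slope, r_squared = r2, r_squared_origin = r2_origin,
       points = data.frame(rsid = stats$rsid, tanner_lowering = x,
                           risk_reduction = y, stringsAsFactors = FALSE))
}

#' Full summarized-data Mendelian randomization analysis
#'
#' One call running the whole summary-statistic stage: allele orientation,
#' per-variant Wald ratios, the correlated-variant allele-score estimate,
#' MR-Egger regression (skipped with fewer than 3 SNPs), cross-variant
#' heterogeneity, and the funnel and effect-versus-effect plot tables.
#'
#' @param stats an [mr_sumstats()] (orientation is applied internally).
#' @param exposure_uncertainty passed to [ivw_correlated()].
#' @return An `mr_analysis` object with components `ivw`, `egger`,
#'   `heterogeneity`, `wald`, `funnel`, `fig_effect` and the oriented stats.
#' @export
mr_analysis <- function(stats, exposure_uncertainty = TRUE) {
  oriented <- orient_to_exposure_decreasing(stats)
  usable <- sum(!oriented$excluded)
  egger <- if (usable >= 3) mr_egger(oriented) else NULL
  het <- if (usable >= 2) heterogeneity_across_variants(oriented) else NULL
  fig <- if (usable >= 2) origin_regression(oriented) else NULL
  out <- list(
    ivw = ivw_correlated(oriented, exposure_uncertainty = exposure_uncertainty),
    egger = egger,
    heterogeneity = het,
    wald = cbind(rsid = oriented$rsid[!oriented$excluded],
                 wald_ratio(oriented$beta_exposure[!oriented$excluded],
                            oriented$se_exposure[!oriented$excluded],
                            oriented$beta_outcome[!oriented$excluded],
                            oriented$se_outcome[!oriented$excluded])),
    funnel = funnel_table(oriented),
    fig_effect = fig,
    stats = oriented,
    skipped = if (usable < 3) "MR-Egger skipped: fewer than 3 usable SNPs" else NULL)
  class(out) <- "mr_analysis"
  out
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("Summarized-data Mendelian randomization (per unit Tanner-stage decrease)\n")
  print(x$ivw)
  if (!is.null(x$egger)) print(x$egger) else cat(" ", x$skipped, "\n")
  if (!is.null(x$heterogeneity))
    cat(sprintf("Cross-variant heterogeneity: Q = %.3f (df %d), p = %.3g, I2 = %.1f%%\n",
                x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$p,
                x$heterogeneity$i2))
  if (!is.null(x$fig_effect))
    cat(sprintf("Effect-vs-effect trend: slope %.3f, R2 (Pearson) %.1f%%\n",
                x$fig_effect$slope, 100 * x$fig_effect$r_squared))
  invisible(x)
}

#' @export
coef.mr_analysis <- function(object, ...) {
  out <- c(ivw_correlated = object$ivw$estimate)
  if (!is.null(object$egger))
    out <- c(out, egger_slope = object$egger$slope$estimate,
             egger_intercept = object$egger$intercept$estimate)
  out
}

#' @export
summary.mr_analysis <- function(object, ...) {
  rows <- list(with(object$ivw, data.frame(
    method = method, estimate = estimate, se = se, or = exp(estimate),
    ci_low = exp(ci_low), ci_high = exp(ci_high), p = p,
    q = heterogeneity$Q, i2 = heterogeneity$i2)))
  if (!is.null(object$egger)) {
    for (part in c("slope", "intercept")) {
      ce <- object$egger[[part]]
      rows <- c(rows, list(data.frame(
        method = ce$method, estimate = ce$estimate, se = ce$se,
        or = exp(ce$estimate), ci_low = exp(ce$ci_low), ci_high = exp(ce$ci_high),
        p = ce$p, q = NA_real_, i2 = NA_real_)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
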
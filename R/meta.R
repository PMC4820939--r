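#' Fixed-effect (inverse-variance) meta-analysis
#'
#' Pools per-study log-ORs or log-HRs with weights `1/se^2`. Between-study
#' heterogeneity is Cochran's Q with `I2 = max(0, (Q - df)/Q) * 100`. Fixed
#' effect is the headline pooling model here because the replication
#' consortium showed low between-study heterogeneity; the random-effects
#' companion is [random_effects_meta()].
#'
#' @param estimates data frame with columns `study`, `estimate`, `se`
#'   (optionally `n_cases`, `n_controls`), or a numeric vector of estimates
#'   with `se` supplied separately.
#' @param se standard errors when `estimates` is a numeric vector.
#' @return A `meta_result` with the pooled estimate, SE, 95% CI, p,
#'   heterogeneity (`tau2` = 0 for fixed effect) and normalized per-study
#'   weights.
#' @export
fixed_effect_meta <- function(estimates, se = NULL) {
  d <- as_study_table(estimates, se)
  meta_pool(d, model = "fixed")
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`, then pooling with weights `1/(se^2 + tau2)`. When
#' `Q <= df` the truncation gives `tau2 = 0` and the result equals
#' [fixed_effect_meta()] exactly. No small-sample (Knapp-Hartung) adjustment
#' is applied; a flag is provided for it.
#'
#' @inheritParams fixed_effect_meta
#' @param knapp_hartung use the Knapp-Hartung variance adjustment and t
#'   reference distribution (default `FALSE`).
#' @return A `meta_result`.
#' @export
random_effects_meta <- function(estimates, se = NULL, knapp_hartung = FALSE) {
  d <- as_study_table(estimates, se)
  meta_pool(d, model = "random_dl", knapp_hartung = knapp_hartung)
}

as_study_table <- function(estimates, se = NULL) {
  if (is.numeric(estimates)) {
    stopifnot(!is.null(se), length(se) == length(estimates))
    estimates <- data.frame(study = paste0("study", seq_along(estimates)),
                            estimate = estimates, se = se,
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("estimate", "se") %in% names(estimates)))
  if (is.null(estimates$study))
    estimates$study <- paste0("study", seq_len(nrow(estimates)))
  if (any(estimates$se <= 0)) stop("study standard errors must be positive")
  estimates
}

meta_pool <- function(d, model, knapp_hartung = FALSE) {
  k <- nrow(d)
  if (k < 1) stop("no studies supplied")
  if (k == 1) warning("single study: pooled result is a passthrough")
  w_fe <- 1 / d$se^2
  pooled_fe <- sum(w_fe * d$estimate) / sum(w_fe)
  Q <- sum(w_fe * (d$estimate - pooled_fe)^2)
  df <- max(k - 1, 1)
  p_q <- if (k > 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  i2 <- if (k > 1) max(0, (Q - df) / Q) * 100 else NA_real_
  tau2 <- 0
  w <- w_fe
  if (model == "random_dl" && k > 1) {
    denom <- sum(w_fe) - sum(w_fe^2) / sum(w_fe)
    tau2 <- max(0, (Q - df) / denom)
    w <- 1 / (d$se^2 + tau2)
  }
  pooled <- sum(w * d$estimate) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  if (knapp_hartung && k > 1) {
    se_pooled <- sqrt(sum(w * (d$estimate - pooled)^2) / ((k - 1) * sum(w)))
    q975 <- stats::qt(0.975, df = k - 1)
    p <- 2 * stats::pt(-abs(pooled / se_pooled), df = k - 1)
  } else {
    q975 <- stats::qnorm(0.975)
    p <- 2 * stats::pnorm(-abs(pooled / se_pooled))
  }
  structure(list(estimate = pooled, se = se_pooled,
                 ci_low = pooled - q975 * se_pooled,
                 ci_high = pooled + q975 * se_pooled,
                 p = p, model = if (model == "fixed") "fixed" else "random_dl",
                 tau2 = tau2, Q = Q, df = df, p_Q = p_q, i2 = i2,
                 weights = setNames(w / sum(w), d$study),
                 studies = d),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effects meta-analysis of %d studies\n",
              if (x$model == "fixed") "Fixed" else "Random (DerSimonian-Laird)",
              nrow(x$studies)))
  cat(sprintf("  pooled: %.4f (SE %.4f), ratio scale %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$estimate, x$se, exp(x$estimate), exp(x$ci_low), exp(x$ci_high), x$p))
  cat(sprintf("  heterogeneity: Q = %.3f (df %d), p = %.3g, I2 = %.1f%%, tau2 = %.4g\n",
              x$Q, x$df, x$p_Q, x$i2, x$tau2))
  invisible(x)
}

#' @export
coef.meta_result <- function(object, ...) setNames(object$estimate, "pooled")

#' Forest-plot-ready table for a meta-analysis
#'
#' @param result a `meta_result`.
#' @return Data frame of per-study rows (estimate, CI, normalized weight)
#'   followed by the pooled row.
#' @export
forest_table <- function(result) {
  d <- result$studies
  q <- stats::qnorm(0.975)
  rows <- data.frame(study = d$study, estimate = d$estimate, se = d$se,
                     ci_low = d$estimate - q * d$se,
                     ci_high = d$estimate + q * d$se,
                     weight = as.numeric(result$weights),
                     stringsAsFactors = FALSE)
  pooled <- data.frame(study = sprintf("POOLED (%s)", result$model),
                       estimate = result$estimate, se = result$se,
                       ci_low = result$ci_low, ci_high = result$ci_high,
                       weight = 1, stringsAsFactors = FALSE)
  rbind(rows, pooled)
}
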
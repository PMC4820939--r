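#' Simulation configuration for synthetic cohorts
#'
#' Collects every knob of the synthetic data-generating process in one
#' validated object. The generative model is:
#' genotypes at the catalog allele frequencies (optionally with block LD);
#' a latent Tanner stage
#' \deqn{T_i = \mu - \sum_j w_j d_{ij} + c\,U_i + \epsilon_i,}
#' with \eqn{U_i} a standard-normal confounder and
#' \eqn{\epsilon_i \sim N(0, \sigma^2)}, staged 1-5 at fixed thresholds; and
#' binary, ordinal-proxy and survival outcomes driven by the pubertal delay
#' \eqn{D_i = \mu - T_i} (a unit of \eqn{D} is one Tanner stage of delay at
#' the same age):
#' \deqn{\mathrm{logit}\,P(Y_i = 1) = a + \beta^* D_i + \sum_j \alpha_j d_{ij} + c' U_i.}
#' All causal parameters are expressed per unit DECREASE in Tanner stage
#' (later development), so protective effects have log-OR < 0.
#'
#' With `effect_scale = "marginal"` (default) each entry of `causal_log_or`
#' is interpreted as the population-averaged causal log odds ratio — the
#' estimand that summary-data Mendelian randomization targets — and the
#' conditional coefficient \eqn{\beta^*} is calibrated internally by numerical
#' integration so that per-SNP outcome associations equal
#' \eqn{\beta \times w_j}. With `"conditional"` the supplied value is used as
#' the raw logit coefficient (marginal associations are then attenuated by
#' non-collapsibility).
#'
#' @param n_samples cohort size.
#' @param catalog a [snp_catalog()]; defaults to the builtin 13-SNP catalog.
#' @param ld_spec optional list of LD blocks, each
#'   `list(rsids = <character>, rho = <target pairwise dosage correlation>)`.
#' @param tanner_mean latent Tanner mean (mid-adolescent population), default
#'   3.5 so the staged distribution spans stages 2-5.
#' @param tanner_noise_sd residual SD of the latent Tanner stage, default
#'   0.75; with the builtin weights the score then explains roughly 2% of the
#'   latent variance, and the staged population spans stages 2-5. The default
#'   also keeps strong marginal causal effects generable: in a
#'   logistic-normal model the attainable marginal log-OR per unit of a
#'   Gaussian exposure is bounded by
#'   \eqn{\phi(z_\pi) / (\pi(1-\pi)\,\sigma_{delay})}, so an overly dispersed
#'   latent Tanner would make a causal OR as strong as 0.23 per unit
#'   impossible to generate.
#' @param causal_log_or named numeric: causal log-OR per unit Tanner decrease
#'   for `case`, `high_grade` and `advanced_stage`.
#' @param prevalence named numeric: target outcome fractions (`case` in the
#'   whole cohort; `high_grade`, `advanced_stage` among cases).
#' @param pleiotropy direct per-allele SNP-outcome effects \eqn{\alpha_j}:
#'   `"none"`, `"balanced"` (mean-zero normal), `"directional"` (constant), or
#'   a numeric vector of length `nrow(catalog)`.
#' @param pleiotropy_magnitude SD (balanced) or constant value (directional)
#'   of the \eqn{\alpha_j}.
#' @param confounder_effect coefficient `c` of the confounder on the latent
#'   Tanner stage.
#' @param confounder_outcome coefficient `c'` of the confounder on each
#'   outcome's logit.
#' @param survival_log_hr log hazard ratio per unit Tanner decrease for
#'   prostate-cancer-specific death among cases (conditional scale).
#' @param baseline_hazard `list(shape=, scale=)` of the Weibull baseline for
#'   prostate-cancer death (years).
#' @param other_mort_rate constant competing other-cause mortality rate per
#'   year (treated as censoring for the prostate-specific endpoint).
#' @param censor_time administrative censoring horizon in years.
#' @param effect_scale `"marginal"` or `"conditional"` (see Details).
#' @param n_studies,n_centres number of study and recruitment-centre labels.
#' @param age_mean,age_sd age distribution (years).
#' @param seed integer seed; fully determines the output of every simulate_*
#'   operation given the same config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 2927,
                       catalog = load_snp_catalog(),
                       ld_spec = NULL,
                       tanner_mean = 3.5,
                       tanner_noise_sd = 0.75,
                       causal_log_or = c(case = log(0.90),
                                         high_grade = log(0.23),
                                         advanced_stage = log(0.60)),
                       prevalence = c(case = 0.388,
                                      high_grade = 0.30,
                                      advanced_stage = 0.116),
                       pleiotropy = "none",
                       pleiotropy_magnitude = 0.05,
                       confounder_effect = 0.3,
                       confounder_outcome = 0.3,
                       survival_log_hr = log(0.62),
                       baseline_hazard = list(shape = 1.2, scale = 12),
                       other_mort_rate = 0.02,
                       censor_time = 15,
                       effect_scale = c("marginal", "conditional"),
                       n_studies = 1,
                       n_centres = 9,
                       age_mean = 62, age_sd = 5.15,
                       seed = NULL) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(n_samples > 0, tanner_noise_sd >= 0, censor_time > 0,
            baseline_hazard$shape > 0, baseline_hazard$scale > 0)
  J <- nrow(catalog)
  if (is.numeric(pleiotropy)) {
    stopifnot(length(pleiotropy) == J)
    alpha <- pleiotropy
    pleiotropy_type <- "explicit"
  } else {
    pleiotropy_type <- match.arg(pleiotropy, c("none", "balanced", "directional"))
    alpha <- NULL  # materialized at generation time for "balanced"
  }
  if (!is.null(ld_spec)) {
    for (blk in ld_spec) {
      stopifnot(all(blk$rsids %in% catalog$rsid), abs(blk$rho) < 1)
    }
  }
  for (nm in c("case", "high_grade", "advanced_stage")) {
    if (is.na(causal_log_or[nm])) stop("causal_log_or must name ", nm)
    if (is.na(prevalence[nm])) stop("prevalence must name ", nm)
  }
  structure(list(
    n_samples = n_samples, catalog = catalog, ld_spec = ld_spec,
    tanner_mean = tanner_mean, tanner_noise_sd = tanner_noise_sd,
    tanner_thresholds = c(1.5, 2.5, 3.5, 4.5),
    causal_log_or = causal_log_or, prevalence = prevalence,
    pleiotropy_type = pleiotropy_type, alpha = alpha,
    pleiotropy_magnitude = pleiotropy_magnitude,
    confounder_effect = confounder_effect,
    confounder_outcome = confounder_outcome,
    survival_log_hr = survival_log_hr, baseline_hazard = baseline_hazard,
    other_mort_rate = other_mort_rate, censor_time = censor_time,
    effect_scale = effect_scale, n_studies = n_studies,
    n_centres = n_centres, age_mean = age_mean, age_sd = age_sd,
    seed = seed), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort configuration\n",
    "  n = %d, %d SNPs, Tanner mean %.2f (noise SD %.2f)\n",
    "  causal OR per Tanner-unit decrease: case %.3f, high grade %.3f, advanced stage %.3f (%s scale)\n",
    "  pleiotropy: %s; confounding: tanner %.2f / outcome %.2f; seed: %s\n"),
    x$n_samples, nrow(x$catalog), x$tanner_mean, x$tanner_noise_sd,
    exp(x$causal_log_or["case"]), exp(x$causal_log_or["high_grade"]),
    exp(x$causal_log_or["advanced_stage"]), x$effect_scale,
    x$pleiotropy_type, x$confounder_effect, x$confounder_outcome,
    if (is.null(x$seed)) "none" else as.character(x$seed)))
  invisible(x)
}

## ---- LD machinery: latent-Gaussian haplotypes -------------------------------

# Bivariate standard-normal CDF P(X <= z1, Y <= z2) at correlation rho,
# by conditioning-and-integrating; accurate to ~1e-8 which is ample here.
bvn_cdf <- function(z1, z2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(z1) * stats::pnorm(z2))
  if (rho > 1 - 1e-9) return(stats::pnorm(min(z1, z2)))
  if (rho < -1 + 1e-9) return(max(0, stats::pnorm(z1) + stats::pnorm(z2) - 1))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::pnorm((z2 - rho * x) / s) * stats::dnorm(x),
                   -8.5, z1, rel.tol = 1e-10)$value
}

# Correlation between Bernoulli allele indicators thresholded from a latent
# bivariate normal with correlation rho_lat.
allele_phi <- function(rho_lat, p1, p2) {
  p11 <- bvn_cdf(stats::qnorm(p1), stats::qnorm(p2), rho_lat)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent correlation achieving a target dosage correlation for two SNPs.
solve_latent_rho <- function(target_r, p1, p2) {
  if (abs(target_r) < 1e-12) return(0)
  lo <- allele_phi(-0.9999, p1, p2)
  hi <- allele_phi(0.9999, p1, p2)
  if (target_r > hi + 1e-10 || target_r < lo - 1e-10)
    stop(sprintf(
      "LD correlation %.3f infeasible for allele frequencies %.3f/%.3f (attainable range [%.3f, %.3f])",
      target_r, p1, p2, lo, hi))
  stats::uniroot(function(r) allele_phi(r, p1, p2) - target_r,
                 lower = -0.9999, upper = 0.9999, tol = 1e-9)$root
}

#' Simulate genotype dosages at the catalog allele frequencies
#'
#' SNPs outside any LD block are drawn independently as Binomial(2, p_j).
#' SNPs inside a block are generated from two independent latent-Gaussian
#' haplotypes thresholded at the allele frequencies, with the latent
#' correlation solved numerically so the realized pairwise dosage correlation
#' matches the requested `rho`. An unattainable `rho` for the given
#' frequencies is an error.
#'
#' @param config a [sim_config()].
#' @param n number of individuals (defaults to `config$n_samples`).
#' @param seed integer seed (defaults to `config$seed`; `NULL` continues the
#'   current RNG stream).
#' @return A harmonized `genotype_matrix` (dosages count the catalog's effect
#'   alleles by construction).
#' @export
simulate_genotypes <- function(config, n = config$n_samples, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cat_df <- config$catalog
  J <- nrow(cat_df)
  dos <- matrix(0, nrow = n, ncol = J, dimnames = list(NULL, cat_df$rsid))
  in_block <- rep(FALSE, J)
  if (!is.null(config$ld_spec)) {
    for (blk in config$ld_spec) {
      js <- match(blk$rsids, cat_df$rsid)
      in_block[js] <- TRUE
      p <- cat_df$ref_freq[js]
      k <- length(js)
      R <- diag(k)
      for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k))
        R[a, b] <- R[b, a] <- solve_latent_rho(blk$rho, p[a], p[b])
      ev <- eigen(R, symmetric = TRUE)
      if (min(ev$values) < 1e-8) {  # repair marginally non-PD block
        ev$values <- pmax(ev$values, 1e-8)
        R <- ev$vectors %*% (ev$values * t(ev$vectors))
        R <- stats::cov2cor(R)
      }
      L <- chol(R)
      thr <- stats::qnorm(p)
      hap <- function() {
        z <- matrix(stats::rnorm(n * k), n, k) %*% L
        sweep(z, 2, thr, "<") * 1
      }
      dos[, js] <- hap() + hap()
    }
  }
  for (j in which(!in_block))
    dos[, j] <- stats::rbinom(n, 2, cat_df$ref_freq[j])
  genotype_matrix(dos, sample_ids = sprintf("S%06d", seq_len(n)),
                  file_alleles = data.frame(
                    rsid = cat_df$rsid,
                    effect_allele = cat_df$effect_allele,
                    other_allele = cat_df$other_allele,
                    stringsAsFactors = FALSE),
                  harmonized = TRUE)
}

#' Simulate the latent and staged Tanner phenotype
#'
#' `latent = tanner_mean - sum_j w_j d_ij + c * U + eps`, with `U` a standard
#' normal confounder shared with the outcome model and
#' `eps ~ N(0, tanner_noise_sd^2)`. The staged value cuts the latent at the
#' fixed thresholds 1.5/2.5/3.5/4.5 into stages 1-5.
#'
#' @param genotypes a harmonized `genotype_matrix` over the config's catalog.
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` (default) continues the RNG stream.
#' @return List with `latent`, `stage` (integer 1-5), `confounder` and
#'   `delay` (`tanner_mean - latent`, the pubertal delay in Tanner units).
#' @export
simulate_tanner <- function(genotypes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes$dosages)
  w <- config$catalog$weight[match(genotypes$snp_order, config$catalog$rsid)]
  u <- stats::rnorm(n)
  eps <- if (config$tanner_noise_sd > 0) stats::rnorm(n, 0, config$tanner_noise_sd) else 0
  latent <- config$tanner_mean - as.vector(genotypes$dosages %*% w) +
    config$confounder_effect * u + eps
  stage <- 1L + findInterval(latent, config$tanner_thresholds)
  list(latent = latent, stage = stage, confounder = u,
       delay = config$tanner_mean - latent)
}

## ---- marginal-scale calibration ---------------------------------------------

# E[plogis(a + m + s*Z)], Z ~ N(0,1)
logit_normal_mean <- function(a, m, s) {
  if (s < 1e-10) return(stats::plogis(a + m))
  stats::integrate(function(z) stats::plogis(a + m + s * z) * stats::dnorm(z),
                   -8.5, 8.5, rel.tol = 1e-9)$value
}

# Marginal logit slope per unit shift of the linear-predictor mean, around m0.
marginal_logit_slope <- function(a, m0, s, h = 0.02) {
  g1 <- logit_normal_mean(a, m0 + h, s)
  g0 <- logit_normal_mean(a, m0 - h, s)
  (stats::qlogis(g1) - stats::qlogis(g0)) / (2 * h)
}

# Given a target marginal log-OR per unit delay (beta_req) and target
# prevalence, solve the conditional coefficient b and intercept a of
# logit p = a + b*delay + c_out*U + alpha'd. v_fun(b) must return the
# variance of the linear predictor around its mean, m_fun(b) its mean.
calibrate_logit <- function(beta_req, prev, lp_var_fun, lp_mean_fun) {
  solve_a <- function(b) {
    s <- sqrt(lp_var_fun(b))
    m <- lp_mean_fun(b)
    lim <- 30 + 8 * s  # wide enough for any prevalence at this LP dispersion
    stats::uniroot(function(a) logit_normal_mean(a, m, s) - prev,
                   lower = -lim, upper = lim, tol = 1e-10)$root
  }
  if (abs(beta_req) < 1e-12) {
    b <- 0
  } else {
    # feasibility: the marginal slope saturates as |b| grows (threshold limit)
    b_probe <- beta_req * 50
    a_probe <- solve_a(b_probe)
    max_slope <- abs(b_probe * marginal_logit_slope(a_probe, lp_mean_fun(b_probe),
                                                    sqrt(lp_var_fun(b_probe))))
    if (abs(beta_req) >= max_slope)
      stop(sprintf(paste0(
        "marginal log-OR %.3f exceeds the attainable bound (~%.3f) for this ",
        "latent-exposure dispersion; reduce tanner_noise_sd or use ",
        "effect_scale = 'conditional'"), beta_req, max_slope))
    # shifting delay by 1 shifts the LP mean by b, so the marginal delay-slope
    # is b times the per-LP-unit slope; |marginal| <= |b| (non-collapsibility)
    f <- function(b) {
      a <- solve_a(b)
      s <- sqrt(lp_var_fun(b))
      b * marginal_logit_slope(a, lp_mean_fun(b), s) - beta_req
    }
    b <- stats::uniroot(f, lower = min(beta_req * 1.0001, beta_req * 6),
                        upper = max(beta_req * 1.0001, beta_req * 6),
                        extendInt = "yes", tol = 1e-9)$root
  }
  c(beta_conditional = b, intercept = solve_a(b))
}

# Moments of delay implied by a config (population scale).
delay_moments <- function(config) {
  p <- config$catalog$ref_freq
  w <- config$catalog$weight
  m <- sum(w * 2 * p)                   # E[delay]; confounder and noise mean 0
  v_gen <- sum(w^2 * 2 * p * (1 - p))   # independent-SNP approximation
  if (!is.null(config$ld_spec)) {
    for (blk in config$ld_spec) {
      js <- match(blk$rsids, config$catalog$rsid)
      for (a in seq_along(js)[-1]) for (b in seq_len(a - 1)) {
        ja <- js[a]; jb <- js[b]
        v_gen <- v_gen + 2 * w[ja] * w[jb] * blk$rho *
          sqrt(2 * p[ja] * (1 - p[ja]) * 2 * p[jb] * (1 - p[jb]))
      }
    }
  }
  # delay = mu - latent = sum_j w_j d_ij - c*U - eps, so Cov(delay, U) = -c
  list(mean = m,
       var = v_gen + config$confounder_effect^2 + config$tanner_noise_sd^2,
       cov_delay_u = -config$confounder_effect)
}

## ---- outcomes ----------------------------------------------------------------

materialize_alpha <- function(config) {
  J <- nrow(config$catalog)
  switch(config$pleiotropy_type,
         none = rep(0, J),
         explicit = config$alpha,
         directional = rep(config$pleiotropy_magnitude, J),
         balanced = stats::rnorm(J, 0, config$pleiotropy_magnitude))
}

# conditional coefficient + intercept for one binary endpoint
endpoint_coefficients <- function(config, endpoint, alpha) {
  beta_req <- unname(config$causal_log_or[endpoint])
  prev <- unname(config$prevalence[endpoint])
  dm <- delay_moments(config)
  p <- config$catalog$ref_freq
  m_alpha <- sum(alpha * 2 * p)
  v_alpha <- sum(alpha^2 * 2 * p * (1 - p))
  c_out <- config$confounder_outcome
  cov_du <- -config$confounder_effect  # cov(delay, U): delay = -latent + mu
  # delay = mu - latent where latent includes +c*U, so delay includes -c*U
  lp_var <- function(b) {
    v <- b^2 * dm$var + c_out^2 + 2 * b * c_out * cov_du + v_alpha
    max(v, 0)
  }
  lp_mean <- function(b) m_alpha  # delay enters centred at its population mean
  if (config$effect_scale == "conditional") {
    b <- beta_req
    s <- sqrt(lp_var(b))
    a <- stats::uniroot(function(a) logit_normal_mean(a, lp_mean(b), s) - prev,
                        lower = -30, upper = 30, tol = 1e-10)$root
    return(c(beta_conditional = b, intercept = a))
  }
  calibrate_logit(beta_req, prev, lp_var, lp_mean)
}

#' Simulate case status, grade, stage and survival outcomes
#'
#' Binary endpoints follow
#' `logit P = a + beta* x delay_c + sum_j alpha_j d_ij + c' x U`, where
#' `delay_c` is the pubertal delay centred at its population mean, `alpha_j`
#' are the pleiotropic direct effects and `U` the shared confounder. Grade
#' (Gleason >= 7) and stage (T3-T4) are generated only among cases. Among
#' cases, prostate-cancer death times are Weibull proportional-hazards with
#' log-hazard `survival_log_hr x delay_c`, other-cause death is an independent
#' exponential, and follow-up is administratively censored at `censor_time`.
#'
#' @param tanner output of [simulate_tanner()].
#' @param genotypes the matching `genotype_matrix`.
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` continues the RNG stream.
#' @return A `cohort_table` data frame: `sample_id`, `case`, `gleason_high`,
#'   `stage_advanced`, `time_years`, `event_prostate`, `event_other`, `age`,
#'   `centre`, `pc1`..`pc10`, `study_id`, `tanner_latent`, `tanner_stage`.
#'   The materialized pleiotropy vector is in `attr(, "alpha")`, the
#'   calibrated conditional coefficients in `attr(, "coefficients")`.
#' @export
simulate_outcomes <- function(tanner, genotypes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tanner$latent)
  d <- genotypes$dosages
  alpha <- materialize_alpha(config)
  dm <- delay_moments(config)
  delay_c <- tanner$delay - dm$mean
  alpha_term <- as.vector(d %*% alpha)
  u_term <- config$confounder_outcome * tanner$confounder

  coefs <- list()
  draw_binary <- function(endpoint, subset = rep(TRUE, n)) {
    cf <- endpoint_coefficients(config, endpoint, alpha)
    coefs[[endpoint]] <<- cf
    lp <- cf["intercept"] + cf["beta_conditional"] * delay_c + alpha_term + u_term
    pr <- stats::plogis(lp)
    if (any(!is.finite(pr)))
      stop("outcome probabilities degenerate under this configuration")
    out <- rep(NA_integer_, n)
    out[subset] <- stats::rbinom(sum(subset), 1, pr[subset])
    out
  }

  case <- draw_binary("case")
  is_case <- case == 1
  gleason_high <- draw_binary("high_grade", is_case)
  stage_advanced <- draw_binary("advanced_stage", is_case)

  # survival among cases (cause-specific hazards; independent other-cause)
  time_years <- rep(NA_real_, n)
  event_prostate <- rep(NA_integer_, n)
  event_other <- rep(NA_integer_, n)
  nc <- sum(is_case)
  if (nc > 0) {
    shp <- config$baseline_hazard$shape
    scl <- config$baseline_hazard$scale
    lp_s <- config$survival_log_hr * delay_c[is_case]
    t_pc <- scl * (-log(stats::runif(nc)) / exp(lp_s))^(1 / shp)
    t_ot <- if (config$other_mort_rate > 0)
      stats::rexp(nc, config$other_mort_rate) else rep(Inf, nc)
    t_obs <- pmin(t_pc, t_ot, config$censor_time)
    event_prostate[is_case] <- as.integer(t_pc <= t_ot & t_pc < config$censor_time)
    event_other[is_case] <- as.integer(t_ot < t_pc & t_ot < config$censor_time)
    time_years[is_case] <- t_obs
  }

  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  cohort <- data.frame(
    sample_id = genotypes$sample_ids,
    case = case, gleason_high = gleason_high, stage_advanced = stage_advanced,
    time_years = time_years, event_prostate = event_prostate,
    event_other = event_other,
    age = stats::rnorm(n, config$age_mean, config$age_sd),
    centre = factor(sample(paste0("C", seq_len(config$n_centres)), n, replace = TRUE)),
    pcs,
    study_id = factor(sample(paste0("study", seq_len(config$n_studies)), n, replace = TRUE)),
    tanner_latent = tanner$latent, tanner_stage = tanner$stage,
    stringsAsFactors = FALSE)
  attr(cohort, "alpha") <- alpha
  attr(cohort, "coefficients") <- coefs
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_genotypes()], [simulate_tanner()] and [simulate_outcomes()]
#' under a single seed.
#'
#' @param config a [sim_config()].
#' @param seed defaults to `config$seed`.
#' @return List with `cohort`, `genotypes`, `tanner` and `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genotypes(config, seed = NULL)
  t <- simulate_tanner(g, config)
  cohort <- simulate_outcomes(t, g, config)
  structure(list(cohort = cohort, genotypes = g, tanner = t, config = config),
            class = "sim_cohort")
}

## ---- fast per-SNP summary regressions ----------------------------------------

# Per-SNP simple linear regressions of y on each dosage column (closed form).
snp_linear_scan <- function(dosages, y) {
  n <- length(y)
  sx <- colSums(dosages)
  sxx <- colSums(dosages^2)
  sxy <- as.vector(crossprod(dosages, y))
  sy <- sum(y); syy <- sum(y^2)
  sxx_c <- sxx - sx^2 / n
  if (any(sxx_c <= 0)) stop("zero-variance dosage column in exposure scan")
  b <- (sxy - sx * sy / n) / sxx_c
  rss <- (syy - sy^2 / n) - b^2 * sxx_c
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx_c)
  list(beta = b, se = se)
}

# Newton-Raphson logistic regression of y on (1, g); returns slope and its SE
# from the observed information. Used for per-SNP summary statistics where
# thousands of single-covariate fits are needed.
newton_logistic_1 <- function(g, y, tol = 1e-10, maxit = 30) {
  a <- stats::qlogis(max(min(mean(y), 1 - 1e-8), 1e-8)); b <- 0
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- a + b * g
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    r <- y - p
    u1 <- sum(r); u2 <- sum(r * g)
    i11 <- sum(w); i12 <- sum(w * g); i22 <- sum(w * g^2)
    det <- i11 * i22 - i12^2
    if (det <= 0) stop("singular information in per-SNP logistic fit")
    da <- (i22 * u1 - i12 * u2) / det
    db <- (-i12 * u1 + i11 * u2) / det
    step <- 1
    repeat {
      a_new <- a + step * da; b_new <- b + step * db
      eta_n <- a_new + b_new * g
      dev <- -2 * sum(y * eta_n - log1p(exp(eta_n)))
      if (is.finite(dev) && (dev <= dev_old + 1e-12 || step < 1e-4)) break
      step <- step / 2
    }
    a <- a_new; b <- b_new
    if (max(abs(da), abs(db)) * step < tol) break
    dev_old <- dev
  }
  p <- stats::plogis(a + b * g)
  w <- p * (1 - p)
  i11 <- sum(w); i12 <- sum(w * g); i22 <- sum(w * g^2)
  det <- i11 * i22 - i12^2
  c(beta = b, se = sqrt(i11 / det))
}

snp_logistic_scan <- function(dosages, y) {
  res <- apply(dosages, 2, newton_logistic_1, y = y)
  list(beta = res["beta", ], se = res["se", ])
}

#' Simulate per-SNP summary statistics from two independent cohorts
#'
#' Mirrors the two-sample structure of the analysis: the SNP-exposure effects
#' come from an adolescent GWAS-style arm (per-SNP linear regression of the
#' pubertal delay on dosage, so `beta_exposure ~ +w_j` on the Tanner-decrease
#' scale), and the SNP-outcome effects from an independent case-control arm
#' (per-SNP logistic regression). The LD correlation matrix is estimated from
#' the outcome arm's genotypes.
#'
#' @param config a [sim_config()].
#' @param n_exposure exposure-arm sample size.
#' @param n_outcome outcome-arm cohort size (for `"high_grade"` and
#'   `"advanced_stage"` the per-SNP regressions run among that cohort's
#'   cases).
#' @param outcome `"case"`, `"high_grade"` or `"advanced_stage"`.
#' @param seed defaults to `config$seed`.
#' @return An [mr_sumstats()] object (exposure effects on the Tanner-decrease
#'   scale, outcome effects in log-OR per effect allele, estimated LD matrix).
#' @export
simulate_summary_study <- function(config, n_exposure, n_outcome,
                                   outcome = c("case", "high_grade", "advanced_stage"),
                                   seed = config$seed) {
  outcome <- match.arg(outcome)
  if (!is.null(seed)) set.seed(seed)
  # exposure arm: genotypes + Tanner only
  g1 <- simulate_genotypes(config, n = n_exposure, seed = NULL)
  t1 <- simulate_tanner(g1, config)
  expo <- snp_linear_scan(g1$dosages, t1$delay)
  # outcome arm: independent cohort
  g2 <- simulate_genotypes(config, n = n_outcome, seed = NULL)
  t2 <- simulate_tanner(g2, config)
  coh <- simulate_outcomes(t2, g2, config)
  if (outcome == "case") {
    y <- coh$case; d2 <- g2$dosages
  } else {
    keep <- coh$case == 1
    y <- if (outcome == "high_grade") coh$gleason_high[keep] else coh$stage_advanced[keep]
    d2 <- g2$dosages[keep, , drop = FALSE]
  }
  out <- snp_logistic_scan(d2, y)
  mr_sumstats(rsid = config$catalog$rsid,
              beta_exposure = expo$beta, se_exposure = expo$se,
              beta_outcome = out$beta, se_outcome = out$se,
              ld = stats::cor(g2$dosages),
              effect_allele = config$catalog$effect_allele,
              other_allele = config$catalog$other_allele)
}
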
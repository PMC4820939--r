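test_that("logistic fit matches the closed-form 2x2 odds ratio", {
  # (a,b,c,d) = (10,20,30,40): OR = ad/bc = 2/3
  y <- c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40))
  x <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(y, x)
  row <- fit[fit$is_exposure, ]
  expect_equal(row$estimate, log(10 * 40 / (20 * 30)), tolerance = 1e-8)
  # Wald SE of a 2x2 log-OR: sqrt(1/a + 1/b + 1/c + 1/d)
  expect_equal(row$se, sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 40), tolerance = 1e-6)
})

test_that("logistic fit equals a brute-force likelihood maximization", {
  set.seed(401)
  n <- 50
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  fit <- fit_logistic(y, x1, data.frame(x2 = x2))
  X <- cbind(1, x1, x2)
  oracle <- logistic_mle_oracle(X, y)
  expect_equal(unname(fit$estimate), unname(oracle), tolerance = 1e-6)
})

test_that("null exposure gives a CI covering OR 1", {
  set.seed(402)
  n <- 1e4
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.3)
  row <- fit_logistic(y, x)
  row <- row[row$is_exposure, ]
  expect_true(row$ci_low < 1 && row$ci_high > 1)
})

test_that("separation and rank deficiency raise explicit errors", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rnorm(20, -3), rnorm(20, 3))
  expect_error(fit_logistic(y, x), "separation")
  set.seed(403)
  x1 <- rnorm(40)
  expect_error(fit_logistic(rbinom(40, 1, 0.5), x1, data.frame(dup = 2 * x1)),
               "collinear.*dup")
  expect_error(fit_logistic(rep(1, 30), rnorm(30)), "constant")
})

test_that("tertile models agree with explicit design-matrix fits", {
  cfg <- sim_config(n_samples = 2500, seed = 404)
  sim <- simulate_cohort(cfg)
  score <- compute_score(sim$genotypes, cfg$catalog)
  terts <- assign_tertiles(score)
  res <- tertile_analysis(sim$cohort, terts, "case", covariates = "age")
  # oracle: hand-built indicator columns through the generic logistic fit
  y <- sim$cohort$case
  d2 <- as.integer(terts$tertile == "T2")
  d3 <- as.integer(terts$tertile == "T3")
  oracle <- fit_logistic(y, cbind(T2 = d2, T3 = d3),
                         data.frame(age = sim$cohort$age))
  expect_equal(res$tertile_or$estimate,
               oracle$estimate[oracle$is_exposure], tolerance = 1e-8)
  trend_oracle <- fit_logistic(y, as.numeric(terts$tertile),
                               data.frame(age = sim$cohort$age))
  expect_equal(res$trend$estimate,
               trend_oracle$estimate[trend_oracle$is_exposure], tolerance = 1e-8)
  expect_true(res$joint_p > 0 && res$joint_p <= 1)
})

test_that("a strong protective grade effect shows up as a trend OR below 1", {
  cfg <- sim_config(n_samples = 6000, seed = 405)
  sim <- simulate_cohort(cfg)
  score <- compute_score(sim$genotypes, cfg$catalog)
  terts <- assign_tertiles(score)
  res <- tertile_analysis(sim$cohort, terts, "gleason_high",
                          covariates = c("age", "centre"))
  expect_lt(res$trend$or, 1)
  expect_equal(res$n, sum(sim$cohort$case == 1))
})

test_that("group comparisons follow the declared baseline-table tests", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # Welch t on raw data with the case-control age moments is clearly significant
  set.seed(406)
  standardize <- function(n, m, s) {
    x <- rnorm(n); m + s * (x - mean(x)) / stats::sd(x)
  }
  age_case <- standardize(1136, 62.2, 5.1)
  age_ctrl <- standardize(1791, 61.6, 5.2)
  res <- compare_groups(age_case, age_ctrl)
  expect_lt(res$p, 0.01)
  # chi-square without continuity correction, checked by hand: 0.794
  cases <- rep(c("yes", "no"), c(10, 20))
  ctrls <- rep(c("yes", "no"), c(30, 40))
  res2 <- compare_groups(cases, ctrls, kind = "categorical")
  expect_equal(res2$statistic, 0.794, tolerance = 1e-3)
  expect_error(compare_groups(c(1, 1), c(2, 2)), "zero variance")
})

test_that("log-transform option operates on the natural log scale", {
  set.seed(407)
  a <- rlnorm(200, 1, 0.4); b <- rlnorm(300, 1.1, 0.4)
  res <- compare_groups(a, b, log_transform = TRUE)
  manual <- stats::t.test(log(a), log(b))$p.value
  expect_equal(res$p, manual)
})

test_that("confounder screen is calibrated under the null and recovers signals", {
  set.seed(408)
  ps <- replicate(100, {
    n <- 500
    cohort <- data.frame(case = rbinom(n, 1, 0.4), age = rnorm(n, 62, 5))
    confounder_screen(rnorm(n, 13, 1), cohort, covariates = "age")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  set.seed(409)
  n <- 2000
  s <- rnorm(n, 13, 1)
  cohort <- data.frame(case = rbinom(n, 1, 0.4),
                       age = 60 + 0.5 * s + rnorm(n, 0, 3),
                       bph = rbinom(n, 1, 0.1))
  scr <- confounder_screen(s, cohort, covariates = c("age", "bph"))
  age_row <- scr[scr$covariate == "age", ]
  expect_lt(abs(age_row$estimate - 0.5), 3 * age_row$se)
  expect_equal(scr$p_bonferroni, pmin(1, scr$p * 2))
  expect_error(confounder_screen(s, transform(cohort, case = 1)), "controls")
})

test_that("Cox coefficient matches a brute-force partial-likelihood maximum", {
  time <- c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9, 8.4, 9.9)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 0, 1, 1, 0, 0)
  cohort <- data.frame(sample_id = 1:8, case = 1, time_years = time,
                       event_prostate = event, event_other = 0,
                       age = rep(60, 8), study_id = factor(rep(c("a", "b"), 4)))
  fit <- fit_cox(cohort, x, covariates = character(0))
  expect_equal(unname(coef(fit)["exposure"]),
               cox_partial_oracle(time, event, x), tolerance = 1e-6)
})

test_that("Cox estimate is invariant to time rescaling and row permutation", {
  cfg <- sim_config(n_samples = 3000, seed = 410, n_studies = 4)
  co <- simulate_cohort(cfg)$cohort
  x <- as.numeric(assign_tertiles(rnorm(nrow(co)))$tertile)
  f1 <- fit_cox(co, x)
  co_m <- co; co_m$time_years <- co_m$time_years * 12
  f2 <- fit_cox(co_m, x, horizon_years = 15 * 12)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  perm <- sample(nrow(co))
  f3 <- fit_cox(co[perm, ], x[perm])
  expect_equal(coef(f1), coef(f3), tolerance = 1e-8)
})

test_that("survival effects are recovered and robust SEs respond to clustering", {
  cfg <- sim_config(n_samples = 3e4, seed = 411, n_studies = 12)
  co <- simulate_cohort(cfg)$cohort
  # exposure: centred pubertal delay, whose generative log-HR is ln(0.62)
  delay <- cfg$tanner_mean - co$tanner_latent
  fit <- fit_cox(co, delay - mean(delay), endpoint = "prostate_specific")
  row <- fit$estimates[fit$estimates$term == "exposure", ]
  expect_lt(abs(row$estimate - log(0.62)), 3 * row$se)
  expect_true(fit$robust)
  expect_equal(fit$n_clusters, 12)
  # single-cluster degenerate contract: warning + model-based SEs
  co1 <- co; co1$study_id <- factor("only")
  expect_warning(f1 <- fit_cox(co1, delay - mean(delay)), "single level")
  expect_false(f1$robust)
})

test_that("administrative censoring at the horizon drops later events", {
  cohort <- data.frame(sample_id = 1:6, case = 1,
                       time_years = c(2, 8, 14, 16, 20, 3),
                       event_prostate = c(1, 1, 1, 1, 1, 0), event_other = 0,
                       age = rnorm(6, 60), study_id = factor(rep("s", 6)))
  suppressWarnings({
    f <- fit_cox(cohort, c(0, 1, 0, 1, 0, 1), covariates = character(0),
                 horizon_years = 15)
  })
  expect_equal(f$n_events, 3)
  expect_lte(f$max_followup, 15)
  expect_error(suppressWarnings(
    fit_cox(cohort, rep(1, 6), covariates = character(0), horizon_years = 1)),
    "no events|constant")
})

test_that("proportional-hazards check is calibrated and catches violations", {
  # null calibration: PH holds by construction
  set.seed(412)
  ps <- replicate(40, {
    n <- 400
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * exp(0.3 * x))
    cohort <- data.frame(sample_id = 1:n, case = 1,
                         time_years = pmin(t, 15),
                         event_prostate = as.integer(t < 15), event_other = 0,
                         age = rnorm(n, 60), study_id = factor(rep(c("a", "b"), n / 2)))
    f <- fit_cox(cohort, x, covariates = character(0))
    test_proportional_hazards(f)$global_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # effect switched off after 5 years: the scaled-Schoenfeld test must reject
  set.seed(413)
  rejected <- replicate(10, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    # piecewise-exponential: strong effect only before year 5
    rate1 <- 0.05 * exp(1.0 * x)
    t1 <- rexp(n, rate1)
    t <- ifelse(t1 <= 5, t1, 5 + rexp(n, 0.05))
    cohort <- data.frame(sample_id = 1:n, case = 1,
                         time_years = pmin(t, 15),
                         event_prostate = as.integer(t < 15), event_other = 0,
                         age = rnorm(n, 60), study_id = factor(rep(c("a", "b"), n / 2)))
    f <- fit_cox(cohort, x, covariates = character(0))
    test_proportional_hazards(f)$global_p < 0.05
  })
  expect_gte(mean(rejected), 0.8)

  # constant exposure cannot be tested
  cohort <- data.frame(sample_id = 1:20, case = 1,
                       time_years = rexp(20, 0.2), event_prostate = 1,
                       event_other = 0, age = rnorm(20, 60),
                       study_id = factor(rep("s", 20)))
  expect_error(suppressWarnings(
    fit_cox(cohort, rep(1, 20), covariates = character(0))), "constant")
})
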
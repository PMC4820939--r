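test_that("orientation flips signs pairwise, flags zero instruments, is an involution", {
  ss <- mr_sumstats(c("rs1", "rs2", "rs3"),
                    beta_exposure = c(-0.1, 0.15, 0),
                    se_exposure = c(0.02, 0.02, 0.02),
                    beta_outcome = c(0.2, -0.1, 0.05),
                    se_outcome = c(0.05, 0.05, 0.05),
                    effect_allele = c("A", "C", "G"),
                    other_allele = c("G", "T", "T"))
  expect_warning(o <- orient_to_exposure_decreasing(ss), "zero exposure")
  expect_equal(o$beta_exposure[1], 0.1)
  expect_equal(o$beta_outcome[1], -0.2)
  expect_equal(o$effect_allele[1], "G")
  expect_equal(o$beta_exposure[2], 0.15)   # already oriented: untouched
  expect_true(o$excluded[3])
  o2 <- suppressWarnings(orient_to_exposure_decreasing(o))
  expect_equal(o2$beta_exposure, o$beta_exposure)
  expect_equal(o2$beta_outcome, o$beta_outcome)
})

test_that("orientation also re-signs the LD matrix rows of flipped SNPs", {
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  ss <- mr_sumstats(c("rs1", "rs2"), c(-0.1, 0.2), c(0.01, 0.01),
                    c(0.05, -0.1), c(0.03, 0.03), ld = ld)
  o <- orient_to_exposure_decreasing(ss)
  expect_equal(attr(o, "ld")[1, 2], -0.5)
  expect_equal(diag(attr(o, "ld")), c(rs1 = 1, rs2 = 1))
})

test_that("causal estimates are invariant under reorienting any SNP's alleles", {
  ss <- random_sumstats(J = 10, beta = -1.2, seed = 501)
  flip <- c(2, 5, 9)
  ss_f <- ss
  ss_f$beta_exposure[flip] <- -ss$beta_exposure[flip]
  ss_f$beta_outcome[flip] <- -ss$beta_outcome[flip]
  a <- mr_analysis(ss)
  b <- mr_analysis(ss_f)
  expect_equal(a$ivw$estimate, b$ivw$estimate, tolerance = 1e-12)
  expect_equal(a$egger$slope$estimate, b$egger$slope$estimate, tolerance = 1e-12)
  expect_equal(a$heterogeneity$Q, b$heterogeneity$Q, tolerance = 1e-12)
})

test_that("Wald ratio follows its definition and delta-method variants", {
  w <- wald_ratio(0.1, 0.02, -0.05, 0.03)
  expect_equal(w$estimate, -0.5, tolerance = 1e-12)
  expect_equal(w$se, 0.3, tolerance = 1e-12)
  w0 <- wald_ratio(0.1, 0.02, 0, 0.03)
  expect_equal(w0$estimate, 0)
  expect_equal(w0$p, 1)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.03), "zero exposure")

  # second-order delta SE against a parametric bootstrap
  set.seed(502)
  bx <- 0.5; sex <- 0.05; by <- 0.2; sey <- 0.05
  w2 <- wald_ratio(bx, sex, by, sey, order = 2)
  draws <- rnorm(1e5, by, sey) / rnorm(1e5, bx, sex)
  expect_lt(abs(w2$se - stats::sd(draws)) / stats::sd(draws), 0.05)
})

test_that("correlated-variant IVW reduces to the Wald ratio and classical IVW", {
  ss1 <- mr_sumstats("rs1", 0.12, 0.01, -0.18, 0.04)
  iv1 <- ivw_correlated(ss1, exposure_uncertainty = FALSE)
  wr <- wald_ratio(0.12, 0.01, -0.18, 0.04)
  expect_equal(iv1$estimate, wr$estimate, tolerance = 1e-12)
  expect_equal(iv1$se, wr$se, tolerance = 1e-12)

  for (seed in 503:507) {
    ss <- random_sumstats(J = 9, beta = -0.8, seed = seed)
    iv <- suppressWarnings(ivw_correlated(ss, exposure_uncertainty = FALSE))
    oracle <- classical_ivw_oracle(ss$beta_exposure, ss$se_outcome, ss$beta_outcome)
    expect_equal(iv$estimate, unname(oracle["estimate"]), tolerance = 1e-10)
    expect_equal(iv$se, unname(oracle["se"]), tolerance = 1e-10)
  }
})

test_that("a near-duplicated SNP adds no information under high LD", {
  ss1 <- mr_sumstats("rs1", 0.1, 0.01, -0.15, 0.05)
  single <- ivw_correlated(ss1, exposure_uncertainty = FALSE)
  ld <- matrix(c(1, 0.999, 0.999, 1), 2, 2)
  ss2 <- mr_sumstats(c("rs1", "rs1b"), c(0.1, 0.1), c(0.01, 0.01),
                     c(-0.15, -0.15), c(0.05, 0.05), ld = ld)
  dup <- ivw_correlated(ss2, exposure_uncertainty = FALSE)
  expect_lt(abs(dup$estimate - single$estimate), 1e-3)
  expect_lt(abs(dup$se - single$se) / single$se, 0.05)
})

test_that("ignoring LD double-counts information; the GLS form does not", {
  set.seed(508)
  J <- 6
  bx <- runif(J, 0.05, 0.2)
  sey <- rep(0.05, J)
  by <- -1 * bx
  R <- 0.7 + 0.3 * diag(J)
  ssR <- mr_sumstats(paste0("rs", 1:J), bx, rep(0.01, J), by, sey, ld = R)
  ssI <- mr_sumstats(paste0("rs", 1:J), bx, rep(0.01, J), by, sey)
  seR <- ivw_correlated(ssR, exposure_uncertainty = FALSE)$se
  seI <- suppressWarnings(ivw_correlated(ssI, exposure_uncertainty = FALSE))$se
  expect_gt(seR, seI)
})

test_that("singular weighting matrices error with a condition-number hint", {
  ld <- matrix(1, 2, 2)  # perfectly duplicated instrument
  ss <- mr_sumstats(c("rs1", "rs2"), c(0.1, 0.1), c(0.01, 0.01),
                    c(-0.1, -0.1), c(0.05, 0.05), ld = ld)
  expect_error(ivw_correlated(ss, ld_floor = 0), "singular")
  # with the default eigenvalue floor the estimate is still produced
  expect_s3_class(ivw_correlated(ss), "causal_estimate")
})

test_that("exposure-uncertainty weighting widens intervals appropriately", {
  ss <- random_sumstats(J = 13, beta = -1.4, seed = 509)
  se_plain <- ivw_correlated(ss, exposure_uncertainty = FALSE)$se
  se_full <- ivw_correlated(ss, exposure_uncertainty = TRUE)$se
  expect_gt(se_full, se_plain)
  # under a null effect the two agree (the extra term is scaled by beta^2)
  ss0 <- random_sumstats(J = 13, beta = 0, seed = 510)
  expect_lt(abs(ivw_correlated(ss0, exposure_uncertainty = TRUE)$estimate -
                  ivw_correlated(ss0, exposure_uncertainty = FALSE)$estimate), 0.02)
})

test_that("MR-Egger recovers an exact affine relationship to machine precision", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  by <- 0.1 + 0.5 * bx
  ss <- mr_sumstats(paste0("rs", 1:5), bx, rep(0.01, 5), by,
                    c(0.02, 0.05, 0.03, 0.04, 0.06))
  eg <- mr_egger(ss)
  expect_equal(eg$intercept$estimate, 0.1, tolerance = 1e-10)
  expect_equal(eg$slope$estimate, 0.5, tolerance = 1e-10)
})

test_that("MR-Egger equals a weighted least-squares oracle", {
  ss <- random_sumstats(J = 5, beta = -0.6, intercept = 0.03, seed = 511)
  eg <- mr_egger(ss)
  lmfit <- stats::lm(beta_outcome ~ beta_exposure, data = ss,
                     weights = 1 / ss$se_outcome^2)
  expect_equal(unname(eg$intercept$estimate), unname(coef(lmfit)[1]),
               tolerance = 1e-10)
  expect_equal(unname(eg$slope$estimate), unname(coef(lmfit)[2]),
               tolerance = 1e-10)
  # SE oracle: lm's WLS SEs carry sigma; the package floors sigma at 1
  sig <- summary(lmfit)$sigma
  lm_se <- summary(lmfit)$coefficients[, "Std. Error"]
  expect_equal(unname(eg$slope$se), unname(lm_se[2] * max(1, sig) / sig),
               tolerance = 1e-10)
  expect_error(mr_egger(ss[1:2, ]), "at least 3")
  ss_flat <- mr_sumstats(paste0("rs", 1:4), rep(0.1, 4), rep(0.01, 4),
                         rnorm(4), rep(0.05, 4))
  expect_error(mr_egger(ss_flat), "spread")
})

test_that("balanced pleiotropy leaves the Egger intercept covered at the null", {
  set.seed(512)
  covered <- replicate(400, {
    J <- 13
    bx <- runif(J, 0.03, 0.09)
    sey <- runif(J, 0.05, 0.12)
    alpha <- rnorm(J, 0, 0.04)           # balanced: mean-zero direct effects
    by <- -1.4 * bx + alpha + rnorm(J, 0, sey)
    ss <- mr_sumstats(paste0("rs", 1:J), bx, rep(0.005, J), by, sey)
    eg <- mr_egger(ss)
    eg$intercept$ci_low <= 0 && eg$intercept$ci_high >= 0
  })
  expect_gt(mean(covered), 0.90)
})

test_that("directional pleiotropy moves the Egger intercept, not only the slope", {
  set.seed(513)
  hits <- replicate(200, {
    J <- 13
    bx <- runif(J, 0.02, 0.3)
    sey <- runif(J, 0.02, 0.05)
    by <- 0.08 + 0 * bx + rnorm(J, 0, sey)  # pure directional pleiotropy
    ss <- mr_sumstats(paste0("rs", 1:J), bx, rep(0.005, J), by, sey)
    mr_egger(ss)$intercept$p < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("heterogeneity statistics follow the hand formulas", {
  ss_same <- mr_sumstats(paste0("rs", 1:4), rep(0.1, 4), rep(0.01, 4),
                         rep(-0.12, 4), c(0.02, 0.04, 0.03, 0.05))
  h <- heterogeneity_across_variants(ss_same)
  expect_equal(h$Q, 0, tolerance = 1e-12)
  expect_equal(h$i2, 0)
  expect_equal(h$p, 1)

  # two ratios 0 and 1, each with ratio SE 0.1 -> Q = 50
  ss2 <- mr_sumstats(c("rs1", "rs2"), c(1, 1), c(0.01, 0.01),
                     c(0, 1), c(0.1, 0.1))
  h2 <- heterogeneity_across_variants(ss2)
  expect_equal(h2$Q, 50, tolerance = 1e-10)

  for (seed in 514:516) {
    ss <- random_sumstats(J = 7, beta = -0.5, seed = seed)
    h3 <- heterogeneity_across_variants(ss)
    ratio <- ss$beta_outcome / ss$beta_exposure
    w <- (ss$beta_exposure / ss$se_outcome)^2
    pooled <- sum(w * ratio) / sum(w)
    expect_equal(h3$Q, sum(w * (ratio - pooled)^2), tolerance = 1e-10)
  }
  expect_error(heterogeneity_across_variants(ss_same[1, ]), "at least 2")
})

test_that("funnel table mirrors the Wald ratios exactly", {
  ss <- random_sumstats(J = 6, beta = -0.7, seed = 517)
  ft <- funnel_table(ss)
  expect_equal(nrow(ft), 6)
  expect_equal(ft$estimate, ss$beta_outcome / ss$beta_exposure, tolerance = 1e-12)
  expect_equal(ft$precision, abs(ss$beta_exposure) / ss$se_outcome, tolerance = 1e-12)
  ft1 <- funnel_table(ss[3, ])
  expect_equal(nrow(ft1), 1)
})

test_that("origin regression matches closed forms and is scale-aware", {
  # collinear through the origin: r2 = 1 and slope exact on the risk scale
  bx <- c(0.05, 0.1, 0.2)
  by <- log(1 - 0.8 * bx)    # risk reduction exactly 0.8 * bx
  ss <- mr_sumstats(paste0("rs", 1:3), bx, rep(0.01, 3), by, rep(0.03, 3))
  orr <- origin_regression(ss)
  expect_equal(orr$slope, 0.8, tolerance = 1e-10)
  expect_equal(orr$r_squared_origin, 1, tolerance = 1e-10)

  ss2 <- random_sumstats(J = 8, beta = -1, seed = 518)
  o2 <- origin_regression(ss2)
  x <- abs(ss2$beta_exposure); y <- 1 - exp(ss2$beta_outcome)
  expect_equal(o2$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  expect_equal(o2$r_squared,
               stats::cor(ss2$beta_exposure, ss2$beta_outcome)^2, tolerance = 1e-12)
  # Pearson r2 is invariant to rescaling either axis
  ss_scaled <- ss2
  ss_scaled$beta_exposure <- ss2$beta_exposure * 3.7
  expect_equal(origin_regression(ss_scaled)$r_squared, o2$r_squared,
               tolerance = 1e-12)
  expect_error(origin_regression(ss2[1, ]), "at least 2")
})

test_that("mr_analysis degrades gracefully below the Egger threshold", {
  ss <- random_sumstats(J = 2, beta = -0.5, seed = 519)
  res <- suppressWarnings(mr_analysis(ss))
  expect_null(res$egger)
  expect_match(res$skipped, "fewer than 3")
  expect_s3_class(res$ivw, "causal_estimate")
  expect_equal(nrow(res$funnel), 2)
  sm <- summary(res)
  expect_equal(sm$method, "ivw_correlated")
})

test_that("identity-LD default warns about assumed independence", {
  ss <- random_sumstats(J = 5, beta = 0, seed = 520)
  expect_warning(ivw_correlated(ss), "identity")
})
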
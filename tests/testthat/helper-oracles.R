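# Independent oracles and small fixture builders shared across the suite.

# Exact HWE test by direct enumeration of the conditional heterozygote
# distribution (normalized multinomial configuration counts). Independent of
# the package's log-factorial recurrence route.
hwe_enumeration_oracle <- function(nAA, nAB, naa) {
  n <- nAA + nAB + naa
  na <- 2 * nAA + nAB
  nb <- 2 * naa + nAB
  rare <- min(na, nb)
  if (rare == 0) return(1)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  cnt <- exp(lfactorial(n) - lfactorial((na - hs) / 2) - lfactorial(hs) -
               lfactorial((nb - hs) / 2) + hs * log(2))
  pr <- cnt / sum(cnt)
  sum(pr[pr <= pr[match(nAB, hs)] * (1 + 1e-12)])
}

# Classical fixed-effect IVW of Wald ratios with weights b_x^2 / se_y^2,
# coded directly from the textbook formula.
classical_ivw_oracle <- function(bx, sey, by) {
  w <- bx^2 / sey^2
  ratio <- by / bx
  est <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  c(estimate = est, se = se)
}

# Direct numerical maximization of the Bernoulli log-likelihood.
logistic_mle_oracle <- function(X, y) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# Cox partial log-likelihood for a single covariate, no ties (Breslow = Efron
# in that case), maximized by stats::optimize.
cox_partial_oracle <- function(time, event, x) {
  pll <- function(b) {
    eta <- b * x
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + eta[i] - log(sum(exp(eta[risk])))
    }
    s
  }
  stats::optimize(pll, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
}

# Small deterministic catalog for arithmetic tests (3 SNPs).
toy_catalog <- function(weights = c(0.2, 0.5, 0.3)) {
  snp_catalog(data.frame(
    rsid = c("rsA", "rsB", "rsC"),
    chrom = c("1", "2", "3"), pos = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "T"),
    weight = weights, ref_freq = c(0.3, 0.5, 0.7),
    gene_label = c("g1", "g2", "g3"), stringsAsFactors = FALSE))
}

toy_genotypes <- function(dosages, catalog = toy_catalog()) {
  colnames(dosages) <- catalog$rsid[seq_len(ncol(dosages))]
  genotype_matrix(dosages, harmonized = TRUE)
}

# Random summary-stats fixture with controllable truth.
random_sumstats <- function(J = 8, beta = 0, intercept = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bx <- runif(J, 0.05, 0.3)
  sex <- runif(J, 0.005, 0.02)
  sey <- runif(J, 0.02, 0.1)
  by <- intercept + beta * bx + rnorm(J, 0, sey)
  mr_sumstats(paste0("rs", seq_len(J)), bx, sex, by, sey)
}

# Study conditions used for the synthetic supplementary-data stand-in:
# a discovery-GWAS-scale exposure arm and a screening-trial-scale outcome arm with
# the high- vs low-grade contrast among cases, generative marginal causal
# OR 0.23 per unit Tanner decrease and no pleiotropy.
standin_config <- function(seed) {
  cfg <- sim_config(seed = seed)
  cfg$causal_log_or[] <- c(case = 0, high_grade = log(0.23), advanced_stage = 0)
  cfg
}

standin_sumstats <- function(seed) {
  simulate_summary_study(standin_config(seed), n_exposure = 4000,
                         n_outcome = 2927, outcome = "high_grade")
}
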
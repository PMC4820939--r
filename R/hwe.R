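#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test for a biallelic SNP. Conditional on the
#' observed allele counts, the number of heterozygotes under Hardy-Weinberg
#' equilibrium follows
#' \deqn{P(n_{AB} = h) \propto \frac{n!}{n_{AA}!\,h!\,n_{aa}!} 2^h,}
#' where the homozygote counts are determined by \eqn{h} and the allele
#' counts. The p-value sums the probabilities of all heterozygote counts that
#' are no more probable than the observed one (probability-mass ordering), so
#' it is well defined for small samples, unlike the chi-square approximation.
#'
#' @param n_hom_effect count of effect-allele homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_hom_other count of other-allele homozygotes.
#' @return Exact two-sided p-value in `(0, 1]`. A monomorphic sample admits a
#'   single configuration and returns exactly 1.
#' @examples
#' hwe_exact_test(25, 50, 25)  # perfectly HWE-proportioned
#' @export
hwe_exact_test <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  n_a <- 2L * n_hom_effect + n_het      # effect-allele count
  n_b <- 2L * n_hom_other + n_het
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)             # monomorphic: one configuration
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(h) up to a constant: -log(nAA! h! naa!) + h log 2
  lp <- -lfactorial((n_a - hs) / 2) - lfactorial(hs) -
    lfactorial((n_b - hs) / 2) + hs * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(n_het, hs)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg scan over a genotype matrix
#'
#' @param matrix a `genotype_matrix` of hard-called dosages.
#' @return Data frame with genotype counts, effect-allele frequency and exact
#'   HWE p-value per SNP.
#' @export
hwe_scan <- function(matrix) {
  cnt <- genotype_counts(matrix)
  data.frame(
    rsid = colnames(cnt),
    n_hom_effect = cnt[1, ],
    n_het = cnt[2, ],
    n_hom_other = cnt[3, ],
    freq = (2 * cnt[1, ] + cnt[2, ]) / (2 * colSums(cnt)),
    hwe_p = vapply(seq_len(ncol(cnt)),
                   function(j) hwe_exact_test(cnt[1, j], cnt[2, j], cnt[3, j]),
                   numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
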
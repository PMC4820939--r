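#' Compute the weighted pubertal-development genetic risk score
#'
#' The score for individual \eqn{i} is
#' \deqn{S_i = \frac{J}{\sum_j w_j} \sum_j w_j d_{ij},}
#' the weighted sum of effect-allele dosages over the \eqn{J} usable catalog
#' SNPs, rescaled by \eqn{J / \sum_j w_j} so that a unit increase in the score
#' corresponds approximately to one risk (Tanner-decreasing) allele. A higher
#' score means genetically later pubertal development. An individual carrying
#' two effect alleles at every SNP scores exactly \eqn{2J} regardless of the
#' weights.
#'
#' Missing dosages are imputed as `2 * ref_freq` from the catalog (not the
#' cohort), so scores are reproducible across data subsets; set
#' `impute_missing = "none"` to propagate `NA` instead.
#'
#' @param matrix a harmonized `genotype_matrix`.
#' @param catalog a [snp_catalog()].
#' @param impute_missing `"ref_freq"` (default) or `"none"`.
#' @param strict if `TRUE`, a catalog SNP absent from the matrix is an error;
#'   otherwise it is dropped with a warning and `J` reduced.
#' @return A `score_vector`: data frame with `sample_id`, `score` and
#'   `n_missing_imputed`, with attributes `scaling_constant` (`J / sum(w)`),
#'   `n_snps` and `snps_used`.
#' @export
compute_score <- function(matrix, catalog, impute_missing = c("ref_freq", "none"),
                          strict = FALSE) {
  impute_missing <- match.arg(impute_missing)
  if (!isTRUE(matrix$harmonized))
    warning("genotype matrix is not flagged as harmonized to catalog effect alleles")
  used <- intersect(catalog$rsid, matrix$snp_order)
  absent <- setdiff(catalog$rsid, used)
  if (length(absent)) {
    msg <- paste("catalog SNP(s) missing from genotype matrix:",
                 paste(absent, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; score computed over ", length(used), " SNPs")
  }
  if (!length(used)) stop("no catalog SNPs available in the genotype matrix")
  d <- matrix$dosages[, used, drop = FALSE]
  ci <- match(used, catalog$rsid)
  w <- catalog$weight[ci]
  n_imp <- rowSums(is.na(d))
  if (impute_missing == "ref_freq" && any(n_imp > 0)) {
    for (j in which(colSums(is.na(d)) > 0))
      d[is.na(d[, j]), j] <- 2 * catalog$ref_freq[ci[j]]
  }
  scaling <- length(used) / sum(w)
  out <- data.frame(sample_id = matrix$sample_ids,
                    score = scaling * as.vector(d %*% w),
                    n_missing_imputed = n_imp,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "scaling_constant") <- scaling
  attr(out, "n_snps") <- length(used)
  attr(out, "snps_used") <- used
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Split scores into tertiles
#'
#' Cutpoints are the empirical 1/3 and 2/3 quantiles of the basis group (all
#' samples, or controls only). Ties at a cutpoint are assigned to the lower
#' tertile. T1 (lowest score) is the reference group and corresponds to the
#' genetically earliest sexual maturation.
#'
#' @param scores a `score_vector` from [compute_score()], or a numeric vector.
#' @param basis `"all"` or `"controls"`; with `"controls"`, supply `case` (a
#'   binary vector aligned with the scores) so the control subset can be
#'   identified.
#' @param case binary case indicator, required for `basis = "controls"`.
#' @return A `tertile_assignment`: data frame with `sample_id`, `score` and
#'   `tertile` (factor `T1` < `T2` < `T3`), with attribute `cutpoints`.
#' @export
assign_tertiles <- function(scores, basis = c("all", "controls"), case = NULL) {
  basis <- match.arg(basis)
  if (is.numeric(scores))
    scores <- data.frame(sample_id = paste0("S", seq_along(scores)),
                         score = scores, stringsAsFactors = FALSE)
  s <- scores$score
  base_s <- s
  if (basis == "controls") {
    if (is.null(case)) stop("basis = 'controls' requires a 'case' indicator")
    base_s <- s[case == 0]
    if (!length(base_s)) stop("no controls available to define tertile cutpoints")
  }
  if (length(unique(base_s)) < 3)
    stop("fewer than 3 distinct score values; tertiles are undefined")
  cut_lo <- stats::quantile(base_s, 1 / 3, names = FALSE, type = 7)
  cut_hi <- stats::quantile(base_s, 2 / 3, names = FALSE, type = 7)
  tert <- factor(paste0("T", 1L + (s > cut_lo) + (s > cut_hi)),
                 levels = c("T1", "T2", "T3"))
  out <- data.frame(sample_id = scores$sample_id, score = s, tertile = tert,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cutpoints") <- c(cut_lo, cut_hi)
  attr(out, "basis") <- basis
  attr(out, "reference_group") <- "T1"
  class(out) <- c("tertile_assignment", "data.frame")
  out
}

#' Write scores and tertiles to a TSV with a metadata sidecar block
#'
#' @param tertiles a `tertile_assignment`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_score_tsv <- function(tertiles, file) {
  cp <- attr(tertiles, "cutpoints")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# tertile cutpoints: %.6g %.6g (basis: %s)",
                     cp[1], cp[2], attr(tertiles, "basis")), con)
  utils::write.table(tertiles, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
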
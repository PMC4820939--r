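#' Construct a genotype dosage matrix
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns (column
#'   names are rsids); entries in `[0, 2]` or `NA`.
#' @param sample_ids character vector of row identifiers.
#' @param file_alleles optional data frame (`rsid`, `effect_allele`,
#'   `other_allele`) recording the allele toward which each file column counts
#'   dosage; required before [harmonize_alleles()] can run.
#' @param harmonized logical flag: are dosages oriented to the catalog's
#'   effect alleles?
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            file_alleles = NULL, harmonized = FALSE) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(length(sample_ids) == nrow(dosages), !is.null(colnames(dosages)))
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("dosage outside [0,2] at sample %s, SNP %s (value %.4g)",
                 sample_ids[bad[1, 1]], colnames(dosages)[bad[1, 2]],
                 dosages[bad[1, 1], bad[1, 2]]))
  rownames(dosages) <- sample_ids
  structure(list(sample_ids = sample_ids,
                 snp_order = colnames(dosages),
                 dosages = dosages,
                 file_alleles = file_alleles,
                 harmonized = harmonized),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype dosage matrix: %d samples x %d SNPs (%s; %d missing entries)\n",
              length(x$sample_ids), length(x$snp_order),
              if (isTRUE(x$harmonized)) "harmonized to catalog effect alleles"
              else "file orientation",
              sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotype dosages from a TSV or VCF file
#'
#' TSV dialect: a header row `sample_id` followed by one column per rsid;
#' values are dosages in `[0, 2]` or `NA`. TSV files carry no allele
#' information, so their dosages are taken to count the catalog's effect
#' allele already (`harmonized = TRUE`). VCF (4.x) records are matched to the
#' catalog by rsID first and by chromosome/GRCh37 position second; dosages
#' count the ALT allele, using the `DS` FORMAT field when present and `GT`
#' otherwise, and must be passed through [harmonize_alleles()] before scoring.
#' Multi-allelic VCF records at catalog SNPs are rejected.
#'
#' @param file path to the genotype file.
#' @param catalog a [snp_catalog()].
#' @param format `"tsv"` or `"vcf"`.
#' @return A `genotype_matrix`. Catalog SNPs absent from the file are reported
#'   in a warning and in `attr(, "missing_snps")`.
#' @export
read_dosages <- function(file, catalog, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(file)) stop("genotype file not found: ", file)
  gm <- switch(format,
               tsv = read_dosages_tsv(file, catalog),
               vcf = read_dosages_vcf(file, catalog))
  absent <- setdiff(catalog$rsid, gm$snp_order)
  attr(gm, "missing_snps") <- absent
  if (length(absent))
    warning("catalog SNP(s) absent from ", basename(file), ": ",
            paste(absent, collapse = ", "))
  gm
}

read_dosages_tsv <- function(file, catalog) {
  raw <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1] != "sample_id")
    stop("genotype TSV must start with a 'sample_id' column")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  keep <- intersect(colnames(mat), catalog$rsid)
  mat <- mat[, keep, drop = FALSE]
  genotype_matrix(mat, sample_ids = ids,
                  file_alleles = data.frame(
                    rsid = keep,
                    effect_allele = catalog$effect_allele[match(keep, catalog$rsid)],
                    other_allele = catalog$other_allele[match(keep, catalog$rsid)],
                    stringsAsFactors = FALSE),
                  harmonized = TRUE)
}

read_dosages_vcf <- function(file, catalog) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  idx <- match(catalog$rsid, fix$ID)
  by_pos <- is.na(idx)
  if (any(by_pos)) {
    key_file <- paste(fix$CHROM, fix$POS)
    key_cat <- paste(catalog$chrom, catalog$pos)
    idx[by_pos] <- match(key_cat[by_pos], key_file)
  }
  found <- which(!is.na(idx))
  if (!length(found)) stop("no catalog SNPs found in VCF ", file)
  idx <- idx[found]
  multi <- grepl(",", fix$ALT[idx], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic VCF record(s) at catalog SNP(s): ",
         paste(catalog$rsid[found][multi], collapse = ", "))

  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  n_samp <- ncol(gt)
  dos <- matrix(NA_real_, nrow = n_samp, ncol = length(found),
                dimnames = list(colnames(gt), catalog$rsid[found]))
  for (k in seq_along(found)) {
    i <- idx[k]
    v <- if (!is.null(ds) && any(!is.na(ds[i, ]))) {
      as.numeric(ds[i, ])
    } else {
      g <- gt[i, ]
      ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a)
               sum(suppressWarnings(as.numeric(a)) > 0), numeric(1)))
    }
    dos[, k] <- v
  }
  genotype_matrix(dos,
                  file_alleles = data.frame(
                    rsid = catalog$rsid[found],
                    effect_allele = toupper(fix$ALT[idx]),
                    other_allele = toupper(fix$REF[idx]),
                    stringsAsFactors = FALSE),
                  harmonized = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonize genotype dosages to the catalog's effect alleles
#'
#' Reorients each SNP's dosages so they count the catalog's Tanner-decreasing
#' effect allele. A SNP whose file alleles match the catalog pair is kept as
#' is; a swapped pair has its dosages replaced by `2 - d`; a strand-flipped
#' pair (complementary alleles) is accepted for non-palindromic SNPs, with the
#' dosage flipped when the complement matches the swapped orientation.
#' Palindromic SNPs (A/T or C/G pairs) are matched by allele identity only —
#' no frequency-based strand inference is attempted, since silent strand
#' inference is a known source of sign errors in Mendelian randomization. An
#' incompatible pair is a hard error naming the SNP.
#'
#' Harmonization is an involution with respect to allele swapping: applying a
#' swap flip twice returns the original dosages exactly.
#'
#' @param matrix a `genotype_matrix`.
#' @param file_alleles data frame (`rsid`, `effect_allele`, `other_allele`)
#'   giving the allele orientation used in the file; defaults to the
#'   orientation recorded when the file was read.
#' @param catalog a [snp_catalog()].
#' @param allow_strand_ambiguous if `TRUE`, a palindromic SNP whose file pair
#'   only matches the catalog after complementing is kept as recorded (the
#'   documented override); default `FALSE` errors.
#' @return The harmonized `genotype_matrix` (`harmonized = TRUE`), with
#'   `attr(, "orientation")` recording the action per SNP
#'   (`"kept"`, `"flipped"`, `"strand_kept"`, `"strand_flipped"`).
#' @export
harmonize_alleles <- function(matrix, file_alleles = matrix$file_alleles,
                              catalog, allow_strand_ambiguous = FALSE) {
  if (is.null(file_alleles))
    stop("no file alleles recorded; supply 'file_alleles' to harmonize")
  dos <- matrix$dosages
  action <- setNames(rep(NA_character_, ncol(dos)), colnames(dos))
  for (j in seq_len(ncol(dos))) {
    rs <- colnames(dos)[j]
    ci <- match(rs, catalog$rsid)
    if (is.na(ci)) stop("SNP ", rs, " not in catalog")
    fi <- match(rs, file_alleles$rsid)
    if (is.na(fi)) stop("no file alleles recorded for SNP ", rs)
    fe <- toupper(file_alleles$effect_allele[fi])
    fo <- toupper(file_alleles$other_allele[fi])
    ce <- catalog$effect_allele[ci]
    co <- catalog$other_allele[ci]
    pal <- is_palindromic(ce, co)
    if (fe == ce && fo == co) {
      action[j] <- "kept"
    } else if (fe == co && fo == ce) {
      dos[, j] <- 2 - dos[, j]
      action[j] <- "flipped"
    } else if (!pal && complement_allele(fe) == ce && complement_allele(fo) == co) {
      action[j] <- "strand_kept"
    } else if (!pal && complement_allele(fe) == co && complement_allele(fo) == ce) {
      dos[, j] <- 2 - dos[, j]
      action[j] <- "strand_flipped"
    } else if (pal && allow_strand_ambiguous &&
               complement_allele(fe) %in% c(ce, co)) {
      action[j] <- "kept"
    } else {
      stop("allele pair ", fe, "/", fo, " at ", rs,
           " is incompatible with catalog pair ", ce, "/", co,
           if (pal) " (palindromic SNP: strand flips are not inferred;
  see 'allow_strand_ambiguous')" else "")
    }
  }
  out <- genotype_matrix(dos, sample_ids = matrix$sample_ids,
                         file_alleles = data.frame(
                           rsid = colnames(dos),
                           effect_allele = catalog$effect_allele[match(colnames(dos), catalog$rsid)],
                           other_allele = catalog$other_allele[match(colnames(dos), catalog$rsid)],
                           stringsAsFactors = FALSE),
                         harmonized = TRUE)
  attr(out, "orientation") <- action
  out
}

#' Effect-allele frequencies from dosages
#'
#' @param matrix a `genotype_matrix`.
#' @return Named numeric vector: `mean(dosage) / 2` over non-missing entries
#'   per SNP. A SNP with no non-missing dosages gets `NA` and a warning.
#' @export
allele_frequency <- function(matrix) {
  freq <- colMeans(matrix$dosages, na.rm = TRUE) / 2
  all_missing <- colSums(!is.na(matrix$dosages)) == 0
  if (any(all_missing)) {
    freq[all_missing] <- NA_real_
    warning("all dosages missing for SNP(s): ",
            paste(names(freq)[all_missing], collapse = ", "))
  }
  freq
}

#' Hard-call genotype counts from near-integer dosages
#'
#' Helper for Hardy-Weinberg scans: rounds dosages to hard calls and counts
#' genotype classes per SNP. Dosages further than `tol` from an integer
#' (imputed values) are an error, since HWE is defined on called genotypes.
#'
#' @param matrix a `genotype_matrix`.
#' @param tol maximum distance from an integer dosage.
#' @return Integer matrix with rows `n_hom_effect`, `n_het`, `n_hom_other`.
#' @export
genotype_counts <- function(matrix, tol = 1e-6) {
  d <- matrix$dosages
  if (any(abs(d - round(d)) > tol, na.rm = TRUE))
    stop("non-integer dosages present; HWE requires hard genotype calls")
  d <- round(d)
  rbind(n_hom_effect = colSums(d == 2, na.rm = TRUE),
        n_het = colSums(d == 1, na.rm = TRUE),
        n_hom_other = colSums(d == 0, na.rm = TRUE))
}
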
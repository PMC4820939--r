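#' Load a SNP instrument catalog
#'
#' Loads the set of SNP instruments used to build the pubertal-development
#' genetic risk score. The builtin catalog contains the 13 variants associated
#' with Tanner genital stage in adolescent boys, with their GRCh37 positions,
#' Tanner-stage-decreasing (effect) alleles, control allele frequencies and
#' per-allele weights. The bundled weights are synthetic placeholders with
#' field-plausible magnitudes (the published male Tanner-stage effect sizes
#' are not redistributed); they drive the simulator and the score arithmetic,
#' and can be replaced by supplying a catalog file.
#'
#' @param source `"builtin"` for the bundled 13-SNP catalog, or the path to a
#'   tab-separated catalog file with header columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight`, `ref_freq`, `gene_label`.
#'   Lines starting with `#` are ignored.
#' @return A `snp_catalog`: a data frame with one row per instrument and the
#'   columns above, validated (unique rsids, A/C/G/T alleles, effect !=
#'   other allele, weight > 0, 0 < ref_freq < 1). The attribute `provenance`
#'   records where the catalog came from. Pairwise r^2 < 0.8 between variants
#'   in the same gene region is assumed but cannot be checked without
#'   genotypes.
#' @examples
#' cat13 <- load_snp_catalog()
#' nrow(cat13)     # 13
#' cat13$rsid[1]   # "rs2274465"
#' @export
load_snp_catalog <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    path <- system.file("extdata", "tanner_snps_grch37.tsv", package = "pubmr",
                        mustWork = TRUE)
    provenance <- "builtin 13-SNP Tanner-stage catalog (synthetic placeholder weights)"
  } else {
    path <- source
    if (!file.exists(path)) stop("catalog file not found: ", path)
    provenance <- paste0("file: ", path)
  }
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "weight", "ref_freq", "gene_label")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "))
  cat_df <- data.frame(
    rsid          = raw$rsid,
    chrom         = raw$chrom,
    pos           = suppressWarnings(as.integer(raw$pos)),
    effect_allele = toupper(raw$effect_allele),
    other_allele  = toupper(raw$other_allele),
    weight        = suppressWarnings(as.numeric(raw$weight)),
    ref_freq      = suppressWarnings(as.numeric(raw$ref_freq)),
    gene_label    = raw$gene_label,
    stringsAsFactors = FALSE
  )
  validate_snp_catalog(cat_df)
  attr(cat_df, "provenance") <- provenance
  class(cat_df) <- c("snp_catalog", "data.frame")
  cat_df
}

#' Construct a SNP catalog from an in-memory data frame
#'
#' @param df data frame with the catalog columns (see [load_snp_catalog()]);
#'   `gene_label` is optional.
#' @param provenance free-text provenance note.
#' @return A validated `snp_catalog`.
#' @export
snp_catalog <- function(df, provenance = "user-supplied") {
  if (is.null(df$gene_label)) df$gene_label <- ""
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  validate_snp_catalog(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("snp_catalog", "data.frame")
  df
}

validate_snp_catalog <- function(df) {
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    where <- sprintf("catalog row %d (%s)", i, row$rsid)
    if (is.na(row$rsid) || !nzchar(row$rsid)) stop("missing rsid in ", where)
    if (is.na(row$pos) || row$pos < 1) stop("malformed position in ", where)
    if (!(row$effect_allele %in% bases)) stop("effect allele not in {A,C,G,T} in ", where)
    if (!(row$other_allele %in% bases)) stop("other allele not in {A,C,G,T} in ", where)
    if (row$effect_allele == row$other_allele) stop("effect and other allele identical in ", where)
    if (is.na(row$weight) || row$weight <= 0) stop("weight must be > 0 in ", where)
    if (is.na(row$ref_freq) || row$ref_freq <= 0 || row$ref_freq >= 1)
      stop("ref_freq must lie strictly in (0,1) in ", where)
  }
  dup <- df$rsid[duplicated(df$rsid)]
  if (length(dup)) stop("duplicate rsid(s) in catalog: ", paste(unique(dup), collapse = ", "))
  invisible(df)
}

#' @export
print.snp_catalog <- function(x, ...) {
  cat(sprintf("SNP instrument catalog: %d variants (%s)\n", nrow(x),
              attr(x, "provenance")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}
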
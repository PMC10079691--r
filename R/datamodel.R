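## Core domain containers: variant tables, genotype matrices, summary
## statistics, phenotype tables, expression matrices.

ANNOTATION_COLS <- c("coding", "utr", "histone", "open_chromatin",
                     "polymerase", "tfbs")

#' Build a variant table
#'
#' A variant table is an ordinary data frame with one row per variant and
#' the columns `id` (rsID), `chrom`, `pos` (1-based), `ea` (effect /
#' counted allele), `oa` (other allele), `locus` (locus or gene label used
#' for network layer sizing), plus non-negative annotation counts
#' (`coding`, `utr`, `histone`, `open_chromatin`, `polymerase`, `tfbs`)
#' used as node features by the graph classifier.
#'
#' @param id character rsIDs, unique.
#' @param chrom chromosome labels ("1".."22", "X").
#' @param pos 1-based base-pair positions (>= 1).
#' @param ea,oa effect and other allele, single bases, distinct per row.
#' @param locus locus labels; defaults to the variant id.
#' @param annotations optional data frame of annotation counts.
#' @return a data frame of class `variant_table`.
#' @export
variant_table <- function(id, chrom = "1", pos = seq_along(id), ea = "A",
                          oa = "G", locus = id, annotations = NULL) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   chrom = as.character(rep_len(chrom, n)),
                   pos = as.numeric(rep_len(pos, n)),
                   ea = toupper(as.character(rep_len(ea, n))),
                   oa = toupper(as.character(rep_len(oa, n))),
                   locus = as.character(rep_len(locus, n)),
                   stringsAsFactors = FALSE)
  for (a in ANNOTATION_COLS) {
    df[[a]] <- if (!is.null(annotations) && a %in% names(annotations)) {
      as.numeric(annotations[[a]])
    } else 0
  }
  validate_variant_table(df)
  class(df) <- c("variant_table", "data.frame")
  df
}

validate_variant_table <- function(df) {
  if (anyDuplicated(df$id)) stop("variant ids must be unique")
  if (any(df$pos < 1)) stop("positions must be >= 1 (1-based)")
  bad <- df$ea == df$oa
  if (any(bad)) {
    stop("effect allele equals other allele for: ",
         paste(df$id[bad], collapse = ", "))
  }
  ann <- as.matrix(df[, ANNOTATION_COLS, drop = FALSE])
  if (any(ann < 0)) stop("annotation counts must be non-negative")
  invisible(df)
}

#' Build a genotype matrix
#'
#' Couples a samples x variants dosage matrix (values in \[0, 2\], `NA`
#' marking missing genotypes) with its variant metadata. Column order
#' always matches the variant table row order.
#'
#' @param dosage numeric matrix, rows samples, columns variants.
#' @param variants a [variant_table()] with one row per dosage column.
#' @param sample_ids unique sample identifiers; defaults to existing
#'   rownames or `S1..Sn`.
#' @return an object of class `genotype_matrix` with elements `dosage` and
#'   `variants`.
#' @export
genotype_matrix <- function(dosage, variants, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage has ", ncol(dosage), " columns but variants has ",
         nrow(variants), " rows")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage) %||% paste0("S", seq_len(nrow(dosage)))
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 2)) {
    stop("dosages must lie in [0, 2]; observed range ",
         rng[1L], " .. ", rng[2L])
  }
  dimnames(dosage) <- list(as.character(sample_ids), variants$id)
  validate_variant_table(variants)
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x",
      ncol(x$dosage), "variants\n")
  cat("  missing dosages:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples,variants row / column selectors (indices, logicals, or
#'   sample / variant ids).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  d <- x$dosage
  v <- x$variants
  if (!is.null(variants)) {
    j <- if (is.character(variants)) match(variants, v$id) else variants
    if (is.numeric(j) && anyNA(j)) stop("unknown variant id in selection")
    d <- d[, j, drop = FALSE]
    v <- v[j, , drop = FALSE]
    rownames(v) <- NULL
  }
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  genotype_matrix(d, v, rownames(d))
}

#' Build a summary-statistics table
#'
#' Per-variant GWAS summary statistics: the currency between association
#' testing, meta-analysis, clumping and the weighted polygenic risk score.
#' Rows violating the invariants (`se > 0`, `p` in (0, 1\]) are rejected.
#'
#' @param df data frame with columns `id`, `ea`, `oa`, `beta`, `se`, `p`
#'   and optionally `chrom`, `pos`, `eaf`, `n`.
#' @return a data frame of class `summary_stats`; the number of rejected
#'   rows is attached as attribute `n_rejected`.
#' @export
summary_stats <- function(df) {
  need <- c("id", "ea", "oa", "beta", "se", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing summary-stat columns: ",
                         paste(miss, collapse = ", "))
  for (opt in c("chrom", "pos", "eaf", "n")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  df <- df[, c("id", "chrom", "pos", "ea", "oa", "beta", "se", "p",
               "eaf", "n")]
  df$id <- as.character(df$id)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  for (num in c("pos", "beta", "se", "p", "eaf", "n")) {
    df[[num]] <- as.numeric(df[[num]])
  }
  ok <- is.finite(df$beta) & is.finite(df$se) & df$se > 0 &
    is.finite(df$p) & df$p > 0 & df$p <= 1
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    warning(n_rej, " summary-stat row(s) rejected (se <= 0 or p outside (0,1])")
    df <- df[ok, , drop = FALSE]
  }
  if (anyDuplicated(df$id)) stop("summary-stat variant ids must be unique")
  rownames(df) <- NULL
  class(df) <- c("summary_stats", "data.frame")
  attr(df, "n_rejected") <- n_rej
  df
}

#' Build a phenotype table
#'
#' @param df data frame with columns `sample_id`, `status` (one of
#'   `"AD"`, `"MCI"`, `"NC"`), `age`, `sex` (0/1), `pc1`..`pc5`; any
#'   further numeric columns are treated as endophenotypes (plasma
#'   biomarker levels, cognitive scores, volumetrics, ...).
#' @return a data frame of class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("sample_id", "status", "age", "sex",
            paste0("pc", 1:5))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing phenotype columns: ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$status <- as.character(df$status)
  bad <- !df$status %in% c("AD", "MCI", "NC")
  if (any(bad)) stop("status must be AD, MCI or NC; offending rows: ",
                     paste(which(bad)[seq_len(min(5, sum(bad)))],
                           collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  core <- df[, c("sample_id", "status", "age", "sex", paste0("pc", 1:5))]
  if (anyNA(core[, -(1:2)])) stop("covariate columns must be complete")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Endophenotype column names of a phenotype table
#' @param pheno a `phenotype_table`.
#' @return character vector of non-core column names.
#' @export
endophenotype_names <- function(pheno) {
  setdiff(names(pheno), c("sample_id", "status", "age", "sex",
                          paste0("pc", 1:5)))
}

#' Build an expression matrix (genes x cell types, FPKM)
#'
#' @param mat non-negative numeric matrix with unique gene rownames and
#'   one column per cell type.
#' @return a matrix of class `expression_matrix`.
#' @export
expression_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("expression matrix needs unique gene rownames")
  }
  if (anyNA(mat) || any(mat < 0)) stop("FPKM values must be non-negative")
  class(mat) <- c("expression_matrix", class(mat))
  mat
}
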
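## Readers and writers for the tab-delimited exchange formats and VCF
## genotype input. All table formats round-trip exactly.

SUMSTAT_ALIASES <- list(
  id    = c("snp", "id", "rsid", "variant", "variant_id", "marker"),
  chrom = c("chr", "chrom", "chromosome"),
  pos   = c("pos", "bp", "position", "base_pair_location"),
  ea    = c("ea", "a1", "effect_allele", "alt"),
  oa    = c("oa", "a2", "other_allele", "ref", "non_effect_allele"),
  beta  = c("beta", "b", "effect", "effect_size", "log_odds"),
  se    = c("se", "stderr", "standard_error"),
  p     = c("p", "pval", "pvalue", "p_value"),
  eaf   = c("eaf", "freq", "af", "maf", "effect_allele_frequency"),
  n     = c("n", "n_samples", "samples")
)

#' Read genotype dosages from VCF or a dosage table
#'
#' VCF input uses the `DS` FORMAT field when present; otherwise diploid
#' `GT` calls are converted to ALT-allele counts. Missing genotypes are
#' kept as `NA`, never silently zeroed. Multi-allelic records are
#' rejected and counted (attribute `n_multiallelic`). The dosage-table
#' dialect is tab-delimited with a `sample_id` first column and one
#' column per variant id.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage-table"`.
#' @param variants optional [variant_table()] supplying metadata for
#'   dosage-table input (ids must match the table header).
#' @return a [genotype_matrix()].
#' @export
read_dosage <- function(path, format = c("vcf", "dosage-table"),
                        variants = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "vcf") read_dosage_vcf(path) else
    read_dosage_table(path, variants)
}

read_dosage_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_multi <- sum(multi)
  if (n_multi > 0) {
    warning(n_multi, " multi-allelic record(s) rejected")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records in ", path)
  fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fmt <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  dosage <- t(fmt)  # samples x variants
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    stop("dosage outside [0, 2] in ", path)
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  vt <- variant_table(id = ids, chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      ea = fix$ALT, oa = fix$REF)
  gm <- genotype_matrix(dosage, vt, colnames(fmt))
  attr(gm, "n_multiallelic") <- n_multi
  gm
}

read_dosage_table <- function(path, variants = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id") {
    stop("dosage table must have 'sample_id' as its first column (",
         path, ")")
  }
  ids <- names(df)[-1L]
  d <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(d) <- "double"
  bad <- which(d < 0 | d > 2, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("dosage outside [0, 2] at data line ", bad[1L, 1L],
         ", variant ", ids[bad[1L, 2L]])
  }
  if (is.null(variants)) {
    variants <- variant_table(id = ids)
  } else if (!identical(variants$id, ids)) {
    stop("variant metadata ids do not match dosage-table header")
  }
  genotype_matrix(d, variants, df$sample_id)
}

#' Write a genotype matrix as a dosage table
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_dosage <- function(geno, path) {
  df <- data.frame(sample_id = rownames(geno$dosage),
                   geno$dosage, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Tab-delimited with a header; column names are matched case-insensitively
#' against a documented alias table (SNP/ID/RSID, CHR, POS/BP, EA/A1,
#' OA/A2, BETA/B, SE, P/PVAL, EAF/FREQ, N). Rows violating the invariants
#' (`se > 0`, `p` in (0, 1\]) are dropped with a warning and counted.
#' Unknown extra columns are preserved as attribute `extra`.
#'
#' @param path file path.
#' @return a [summary_stats()] table.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  lower <- tolower(names(df))
  out <- list()
  for (field in names(SUMSTAT_ALIASES)) {
    hit <- which(lower %in% SUMSTAT_ALIASES[[field]])
    if (length(hit)) out[[field]] <- df[[hit[1L]]]
  }
  mandatory <- c("id", "ea", "oa", "beta", "se", "p")
  miss <- setdiff(mandatory, names(out))
  if (length(miss)) {
    stop("summary-stat file ", path, " lacks mandatory column(s): ",
         paste(toupper(miss), collapse = ", "))
  }
  if (length(out$id) == 0L) {
    warning("empty summary-stat file: ", path)
  }
  known <- unlist(lapply(names(out), function(f)
    which(lower %in% SUMSTAT_ALIASES[[f]])[1L]))
  ss <- summary_stats(as.data.frame(out, stringsAsFactors = FALSE))
  extra <- df[, setdiff(seq_along(df), known), drop = FALSE]
  if (ncol(extra)) attr(ss, "extra") <- extra
  ss
}

#' Write summary statistics
#' @param stats a [summary_stats()] table.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  df <- as.data.frame(stats)
  names(df) <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE", "P",
                 "EAF", "N")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#' @param path tab-delimited file with the [phenotype_table()] columns.
#' @return a `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  phenotype_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a phenotype table
#' @param pheno a `phenotype_table`.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-cell-type expression matrix (FPKM)
#' @param path tab-delimited file, first column gene id, remaining columns
#'   one per cell type.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  expression_matrix(mat)
}
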
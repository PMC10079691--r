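## Effect-allele harmonization between genotype dosages and GWAS summary
## statistics.

#' Harmonize genotypes and summary statistics to a shared effect allele
#'
#' Variants are matched by rsID only (chromosome/position disagreements at
#' an equal rsID raise a warning, not an error). For each shared variant:
#' if the summary-stat effect allele equals the counted (dosage) allele
#' the dosage is kept; if it equals the other allele the dosage is flipped
#' to `2 - d` and the counted allele relabelled; strand-ambiguous pairs
#' (A/T, G/C) are dropped by default because their orientation cannot be
#' resolved; variants whose allele pairs do not match at all are dropped.
#'
#' Harmonization is idempotent: a second application changes nothing.
#'
#' @param geno a [genotype_matrix()].
#' @param stats a [summary_stats()] table.
#' @param drop_ambiguous drop A/T and G/C variants (default `TRUE`).
#' @return a list with elements `geno`, `stats` (restricted to the shared,
#'   harmonized variants, in a deterministic order) and `report` (counts
#'   of `kept`, `flipped`, `dropped_ambiguous`, `dropped_mismatch`).
#' @export
harmonize <- function(geno, stats, drop_ambiguous = TRUE) {
  if (ncol(geno$dosage) == 0L || nrow(stats) == 0L) {
    stop("harmonize needs non-empty genotypes and summary statistics")
  }
  shared <- intersect(geno$variants$id, stats$id)
  if (length(shared) == 0L) stop("no overlapping variants to harmonize")
  gi <- match(shared, geno$variants$id)
  si <- match(shared, stats$id)
  gv <- geno$variants[gi, , drop = FALSE]
  sv <- stats[si, , drop = FALSE]

  pos_known <- !is.na(sv$pos) & !is.na(gv$pos)
  mism <- pos_known & (gv$chrom != sv$chrom | gv$pos != sv$pos)
  if (any(mism)) {
    warning("chrom/pos mismatch at equal rsID for ",
            sum(mism), " variant(s), e.g. ", gv$id[which(mism)[1L]])
  }

  same <- gv$ea == sv$ea & gv$oa == sv$oa
  flip <- gv$ea == sv$oa & gv$oa == sv$ea
  ambiguous <- is_ambiguous_pair(gv$ea, gv$oa)
  multiallelic <- !(is_single_base(gv$ea) & is_single_base(gv$oa) &
                      is_single_base(sv$ea) & is_single_base(sv$oa))

  keep <- (same | flip) & !multiallelic
  if (drop_ambiguous) keep <- keep & !ambiguous
  report <- list(
    kept = sum(keep & same),
    flipped = sum(keep & flip),
    dropped_ambiguous = if (drop_ambiguous) sum((same | flip) &
                                                  !multiallelic & ambiguous)
                        else 0L,
    dropped_mismatch = sum(!(same | flip) & !multiallelic),
    dropped_multiallelic = sum(multiallelic)
  )
  if (!any(keep)) stop("no variants left after allele harmonization")

  d <- geno$dosage[, gi[keep], drop = FALSE]
  vt <- gv[keep, , drop = FALSE]
  do_flip <- flip[keep]
  if (any(do_flip)) {
    d[, do_flip] <- 2 - d[, do_flip]
    ea <- vt$ea
    vt$ea[do_flip] <- vt$oa[do_flip]
    vt$oa[do_flip] <- ea[do_flip]
  }
  rownames(vt) <- NULL
  out_stats <- sv[keep, , drop = FALSE]
  rownames(out_stats) <- NULL
  class(out_stats) <- c("summary_stats", "data.frame")
  list(geno = genotype_matrix(d, vt, rownames(geno$dosage)),
       stats = out_stats,
       report = report)
}
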
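## Linkage disequilibrium, clumping, and variant selection.

#' Pairwise LD (squared Pearson correlation of dosages)
#'
#' @param geno a [genotype_matrix()] (missing dosages mean-imputed).
#' @return symmetric matrix of r-squared values in \[0, 1\], diagonal 1;
#'   constant columns give defined off-diagonal value 0.
#' @export
compute_ld <- function(geno) {
  D <- impute_dosage_means(geno$dosage)
  if (nrow(D) < 2L) stop("need >= 2 samples to compute LD")
  r <- suppressWarnings(cor(D))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 1
  dimnames(r2) <- list(geno$variants$id, geno$variants$id)
  r2
}

#' Greedy LD clumping
#'
#' Variants are visited in order of ascending p-value (ties broken by
#' chromosome, position, then id, so the result is invariant to input
#' ordering); a variant is retained unless it lies within `window_kb` of
#' an already-retained variant on the same chromosome with
#' `r^2 > r2_threshold`. Variants with missing p are never retained.
#'
#' @param stats a [summary_stats()] table.
#' @param ld LD matrix from [compute_ld()] covering the same ids.
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @param window_kb physical window in kilobases (default 1000).
#' @return character vector of retained variant ids.
#' @export
ld_clump <- function(stats, ld, r2_threshold = 0.1, window_kb = 1000) {
  s <- stats[!is.na(stats$p), , drop = FALSE]
  if (!nrow(s)) return(character(0))
  if (!all(s$id %in% rownames(ld))) {
    stop("LD matrix does not cover all variants in stats")
  }
  ord <- order(s$p, s$chrom, s$pos, s$id)
  s <- s[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(s))) {
    ok <- TRUE
    if (length(kept)) {
      same_chr <- s$chrom[kept] == s$chrom[i]
      near <- same_chr &
        abs(s$pos[kept] - s$pos[i]) <= window_kb * 1000
      if (any(near)) {
        r2 <- ld[s$id[kept][near], s$id[i]]
        if (any(r2 > r2_threshold)) ok <- FALSE
      }
    }
    if (ok) kept <- c(kept, i)
  }
  s$id[kept]
}

#' Select variants below a p-value threshold
#'
#' Uses the strict inequality `p < threshold` (a variant at exactly the
#' threshold is excluded) and preserves the input row order.
#'
#' @param stats a [summary_stats()] table.
#' @param threshold p-value cutoff in (0, 1); the conventional screens are
#'   1e-8, 1e-6 and 1e-4.
#' @return character vector of variant ids (possibly empty).
#' @export
select_by_pvalue <- function(stats, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  stats$id[!is.na(stats$p) & stats$p < threshold]
}

#' Variants with concordant effect direction in two studies
#'
#' @param stats_a,stats_b [summary_stats()] tables with harmonized effect
#'   alleles.
#' @return character vector of ids with `sign(beta_a) == sign(beta_b)`
#'   and both non-zero; ids with a zero effect in either study are
#'   counted in attribute `n_zero`.
#' @export
concordance_screen <- function(stats_a, stats_b) {
  ids <- intersect(stats_a$id, stats_b$id)
  a <- stats_a[match(ids, stats_a$id), ]
  b <- stats_b[match(ids, stats_b$id), ]
  if (any(a$ea != b$ea | a$oa != b$oa)) {
    stop("effect-allele mismatch; harmonize first")
  }
  zero <- a$beta == 0 | b$beta == 0
  conc <- !zero & sign(a$beta) == sign(b$beta)
  out <- ids[conc]
  attr(out, "n_zero") <- sum(zero)
  out
}

#' Two-cohort replication selection
#'
#' Composed recipe for picking variants supported in two cohorts: start
#' from variants nominally significant (`p < alpha`) in either cohort;
#' keep those whose fixed-effects meta-analysis p is below `alpha`; add
#' back candidates that miss the meta threshold but show the same effect
#' direction in both cohorts.
#'
#' @param stats_a,stats_b per-cohort [summary_stats()] (harmonized).
#' @param alpha significance level (default 0.05).
#' @return character vector of selected ids, with attributes
#'   `n_candidates`, `n_meta`, `n_concordant_extra`.
#' @export
select_replicated <- function(stats_a, stats_b, alpha = 0.05) {
  ids <- intersect(stats_a$id, stats_b$id)
  a <- stats_a[match(ids, stats_a$id), ]
  b <- stats_b[match(ids, stats_b$id), ]
  cand <- ids[(!is.na(a$p) & a$p < alpha) | (!is.na(b$p) & b$p < alpha)]
  if (!length(cand)) return(character(0))
  meta <- fixed_effects_meta(list(
    a[match(cand, a$id), , drop = FALSE],
    b[match(cand, b$id), , drop = FALSE]))
  by_meta <- meta$id[meta$p < alpha]
  conc <- concordance_screen(a[match(cand, a$id), , drop = FALSE],
                             b[match(cand, b$id), , drop = FALSE])
  extra <- setdiff(conc, by_meta)
  out <- cand[cand %in% c(by_meta, extra)]
  attr(out, "n_candidates") <- length(cand)
  attr(out, "n_meta") <- length(by_meta)
  attr(out, "n_concordant_extra") <- length(extra)
  out
}
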
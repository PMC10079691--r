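## Cell-type specificity, hypergeometric enrichment, and group mean
## comparison.

#' Label cell-type-specific genes from an FPKM matrix
#'
#' A gene is specific to cell type c when its FPKM in c reaches the
#' expression threshold (default 5) and is at least `fold` (default 1.5)
#' times its FPKM in every other cell type. Genes meeting neither
#' condition stay unlabelled (`NA`).
#'
#' @param expr an [expression_matrix()] (genes x cell types, FPKM).
#' @param fold fold-change threshold (default 1.5).
#' @param expressed minimum FPKM in the specific type (default 5).
#' @return named character vector gene -> cell-type label (`NA` when not
#'   specific).
#' @export
cell_type_specific_genes <- function(expr, fold = 1.5, expressed = 5) {
  mat <- unclass(expr)
  if (ncol(mat) < 2L) stop("need at least two cell types")
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  labels <- apply(mat, 1, function(v) {
    top <- which.max(v)
    if (v[top] < expressed) return(NA_character_)
    if (all(v[top] >= fold * v[-top])) colnames(mat)[top]
    else NA_character_
  })
  setNames(labels, rownames(mat))
}

#' Hypergeometric cell-type enrichment of a gene cluster
#'
#' Upper-tail hypergeometric test of the overlap between a gene cluster
#' and each cell-type-specific gene set, against a common background;
#' Benjamini-Hochberg adjustment across cell types within the cluster.
#'
#' @param cluster_genes character vector (subset of `background`).
#' @param specific_sets named list of cell-type-specific gene sets
#'   (subsets of `background`), e.g. split from
#'   [cell_type_specific_genes()] output.
#' @param background character vector of all candidate genes.
#' @return data frame per cell type: `cell_type`, `overlap`,
#'   `cluster_size`, `set_size`, `fold_enrichment`, `p`, `q`.
#' @export
enrichment_test <- function(cluster_genes, specific_sets, background) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  N <- length(background)
  cluster_genes <- intersect(unique(cluster_genes), background)
  n <- length(cluster_genes)
  rows <- lapply(names(specific_sets), function(ct) {
    set <- intersect(unique(specific_sets[[ct]]), background)
    K <- length(set)
    m <- length(intersect(cluster_genes, set))
    p <- if (K == 0L || n == 0L) 1 else
      phyper(m - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (K == 0L || n == 0L) NA_real_ else (m / n) / (K / N)
    data.frame(cell_type = ct, overlap = m, cluster_size = n,
               set_size = K, fold_enrichment = fe, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' One-way ANOVA with Bonferroni pairwise comparisons
#'
#' Singleton groups are excluded with a warning. The omnibus test is a
#' one-way ANOVA; pairwise two-sample Welch t-tests are Bonferroni
#' multiplied by the number of pairs and capped at 1.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list with `F`, `p` (omnibus), `pairwise` (data frame:
#'   `group1`, `group2`, `p_raw`, `p_bonferroni`), `groups_used`.
#' @export
group_mean_comparison <- function(values, groups) {
  g <- as.character(groups)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("singleton group(s) excluded: ", paste(small, collapse = ", "))
    keep <- !g %in% small
    values <- values[keep]
    g <- g[keep]
  }
  lv <- unique(g)
  if (length(lv) < 2L) stop("need at least two groups with >= 2 members")
  fit <- aov(values ~ factor(g))
  sm <- summary(fit)[[1L]]
  Fv <- sm[["F value"]][1L]
  p <- sm[["Pr(>F)"]][1L]
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- t.test(values[g == pr[1L]], values[g == pr[2L]])
    data.frame(group1 = pr[1L], group2 = pr[2L], p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * length(pairs)))
  }))
  list(F = Fv, p = p, pairwise = pw, groups_used = lv)
}
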
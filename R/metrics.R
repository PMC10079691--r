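## Threshold-free classification metrics and bootstrap machinery.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Over all case-control pairs, the fraction where the case scores higher,
#' counting ties as one half. Equivalent to the trapezoidal ROC area.
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels binary labels (0/1 or logical).
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step convention: samples are swept in decreasing
#' score order with tied scores grouped at one threshold, and the area is
#' `sum over thresholds of (recall_i - recall_(i-1)) * precision_i`.
#'
#' @inheritParams auroc
#' @return auPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0L || sum(labels == 0L) == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)   # last index of each tie group
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Stratified bootstrap confidence interval for the auROC
#'
#' Resamples cases and controls separately (so no replicate is
#' degenerate) and reports the percentile 2.5/97.5 interval. Seeded and
#' deterministic.
#'
#' @inheritParams auroc
#' @param B bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` with attribute `boot` (the replicate
#'   auROCs).
#' @export
bootstrap_ci_auroc <- function(scores, labels, B = 2000, seed = 1,
                               level = 0.95) {
  labels <- as.integer(labels)
  ip <- which(labels == 1L)
  im <- which(labels == 0L)
  if (!length(ip) || !length(im)) stop("both classes must be present")
  set.seed(split_seed(seed, 31L))
  boot <- vapply(seq_len(B), function(b) {
    i <- c(sample(ip, length(ip), replace = TRUE),
           sample(im, length(im), replace = TRUE))
    auroc(scores[i], c(rep(1L, length(ip)), rep(0L, length(im))))
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- unname(quantile(boot, c(a, 1 - a)))
  attr(ci, "boot") <- boot
  ci
}

#' Paired bootstrap comparison of two auROCs
#'
#' Computes the observed auROC difference on shared samples, bootstraps
#' the difference with stratified paired resampling, and reports
#' `D = delta / sd_boot(delta)` with a two-sided normal p-value.
#'
#' @param scores_a,scores_b two score vectors on the same samples.
#' @inheritParams bootstrap_ci_auroc
#' @return list with `delta`, `D`, `p`, `auroc_a`, `auroc_b`.
#' @export
compare_auroc <- function(scores_a, scores_b, labels, B = 2000, seed = 1) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  labels <- as.integer(labels)
  auc_a <- auroc(scores_a, labels)
  auc_b <- auroc(scores_b, labels)
  delta <- auc_a - auc_b
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(delta = 0, D = 0, p = 1, auroc_a = auc_a, auroc_b = auc_b))
  }
  ip <- which(labels == 1L)
  im <- which(labels == 0L)
  set.seed(split_seed(seed, 32L))
  diffs <- vapply(seq_len(B), function(b) {
    i <- c(sample(ip, length(ip), replace = TRUE),
           sample(im, length(im), replace = TRUE))
    yy <- c(rep(1L, length(ip)), rep(0L, length(im)))
    auroc(scores_a[i], yy) - auroc(scores_b[i], yy)
  }, numeric(1))
  s <- sd(diffs)
  if (!is.finite(s) || s == 0) {
    D <- 0; p <- 1
  } else {
    D <- delta / s
    p <- 2 * pnorm(-abs(D))
  }
  list(delta = delta, D = D, p = p, auroc_a = auc_a, auroc_b = auc_b)
}

#' Per-stratum classification report
#'
#' Computes auROC, auPRC and a bootstrap auROC interval independently in
#' each stratum (e.g. age >= 72 vs < 72, sex, ancestry label). Strata
#' lacking one of the classes are reported as not evaluable rather than
#' failing.
#'
#' @inheritParams bootstrap_ci_auroc
#' @param grouping factor-like vector assigning each sample to exactly
#'   one stratum.
#' @return data frame with one row per stratum: `group`, `n_pos`,
#'   `n_neg`, `auroc`, `auprc`, `ci_low`, `ci_high`, `evaluable`.
#' @export
subgroup_eval <- function(scores, labels, grouping, B = 2000, seed = 1) {
  stopifnot(length(grouping) == length(scores))
  labels <- as.integer(labels)
  groups <- unique(as.character(grouping))
  rows <- lapply(groups, function(g) {
    i <- which(as.character(grouping) == g)
    np <- sum(labels[i] == 1L)
    nn <- sum(labels[i] == 0L)
    if (np == 0L || nn == 0L) {
      return(data.frame(group = g, n_pos = np, n_neg = nn,
                        auroc = NA_real_, auprc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        evaluable = FALSE))
    }
    ci <- bootstrap_ci_auroc(scores[i], labels[i], B = B, seed = seed)
    data.frame(group = g, n_pos = np, n_neg = nn,
               auroc = auroc(scores[i], labels[i]),
               auprc = auprc(scores[i], labels[i]),
               ci_low = ci[1L], ci_high = ci[2L], evaluable = TRUE)
  })
  do.call(rbind, rows)
}
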
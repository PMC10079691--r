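## Per-variant association testing and fixed-effects meta-analysis.

#' Per-variant logistic association scan
#'
#' Fits, for every variant, a logistic regression of case status on
#' dosage plus covariates (by default age, sex and the top five principal
#' components) via iteratively reweighted least squares, and reports the
#' dosage coefficient with its Wald standard error and two-sided p-value.
#' AD vs NC is the default contrast; MCI samples are excluded unless
#' `include_mci = TRUE`, in which case they count as cases. Missing
#' dosages are mean-imputed per variant before fitting. Variants whose
#' fit does not converge, or that show quasi-separation (exploding
#' standard errors), or that are constant, are flagged: their p-value is
#' set missing and they are counted in the attached `report`.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno a [phenotype_table()] aligned by `sample_id`.
#' @param covariates covariate column names in `pheno`; use `character(0)`
#'   for an unadjusted scan.
#' @param include_mci count MCI samples as cases (default drop them).
#' @return a [summary_stats()] table (eaf = mean dosage / 2) with
#'   attribute `report` listing flagged variants.
#' @export
logistic_assoc <- function(geno, pheno,
                           covariates = c("age", "sex", paste0("pc", 1:5)),
                           include_mci = FALSE) {
  idx <- match(rownames(geno$dosage), pheno$sample_id)
  if (anyNA(idx)) stop("phenotype table lacks some genotyped samples")
  ph <- pheno[idx, , drop = FALSE]
  use <- if (include_mci) ph$status %in% c("AD", "MCI", "NC") else
    ph$status %in% c("AD", "NC")
  y <- as.integer(ph$status[use] != "NC")
  if (length(unique(y)) < 2L) stop("need both cases and controls")
  D <- impute_dosage_means(geno$dosage[use, , drop = FALSE])
  X0 <- cbind(`(Intercept)` = 1)
  if (length(covariates)) {
    miss <- setdiff(covariates, names(ph))
    if (length(miss)) stop("unknown covariate(s): ",
                           paste(miss, collapse = ", "))
    C <- as.matrix(ph[use, covariates, drop = FALSE])
    if (anyNA(C)) stop("covariate columns must be complete")
    X0 <- cbind(X0[rep(1, nrow(C)), , drop = FALSE], C)
  } else {
    X0 <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  p <- ncol(D)
  beta <- se <- pval <- rep(NA_real_, p)
  flagged <- character(0)
  for (j in seq_len(p)) {
    g <- D[, j]
    if (var(g) < 1e-12) {
      flagged <- c(flagged, geno$variants$id[j])
      next
    }
    X <- cbind(X0, dosage = g)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = binomial())),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    if (ok) {
      k <- ncol(X)
      w <- fit$weights
      XtWX <- crossprod(X * sqrt(w))
      vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
      ok <- !is.null(vc)
      if (ok) {
        b <- fit$coefficients[k]
        s <- sqrt(vc[k, k])
        ## quasi-separation guard
        ok <- is.finite(b) && is.finite(s) && s < 100 && abs(b) < 50
        if (ok) {
          beta[j] <- b
          se[j] <- s
          pval[j] <- 2 * pnorm(-abs(b / s))
        }
      }
    }
    if (!ok) flagged <- c(flagged, geno$variants$id[j])
  }
  keep_se <- ifelse(is.na(se) | se <= 0, 1, se)
  out <- data.frame(id = geno$variants$id, chrom = geno$variants$chrom,
                    pos = geno$variants$pos, ea = geno$variants$ea,
                    oa = geno$variants$oa, beta = ifelse(is.na(pval), 0, beta),
                    se = keep_se, p = pval,
                    eaf = colMeans(D) / 2, n = length(y),
                    stringsAsFactors = FALSE)
  ## flagged variants keep a row (p missing) so ids stay aligned
  out$p[is.na(pval)] <- NA_real_
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "report") <- list(n_flagged = length(flagged),
                              flagged = flagged)
  out
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-study effect sizes with inverse-variance weights
#' `w_s = 1/se_s^2`: `beta_meta = sum(w beta)/sum(w)`,
#' `se_meta = 1/sqrt(sum(w))`, two-sided normal p. Cochran's Q and the
#' I-squared heterogeneity percentage, floored at 0, are reported per
#' variant.
#'
#' @param stats_list list of [summary_stats()] tables with harmonized
#'   effect alleles and shared variant ids.
#' @return data frame with `id`, `ea`, `oa`, `beta`, `se`, `p`, `Q`,
#'   `I2`, `k` (number of contributing studies), of class
#'   `summary_stats` so it can feed clumping and scoring directly.
#' @export
fixed_effects_meta <- function(stats_list) {
  if (!length(stats_list)) stop("need at least one study")
  ids <- Reduce(intersect, lapply(stats_list, function(s) s$id))
  if (!length(ids)) stop("no shared variants across studies")
  mats <- lapply(stats_list, function(s) s[match(ids, s$id), , drop = FALSE])
  ref <- mats[[1L]]
  for (s in mats[-1L]) {
    if (any(s$ea != ref$ea | s$oa != ref$oa)) {
      stop("effect-allele mismatch across studies; harmonize first")
    }
  }
  nv <- length(ids)
  B <- matrix(vapply(mats, function(s) s$beta, numeric(nv)), nrow = nv)
  S <- matrix(vapply(mats, function(s) s$se, numeric(nv)), nrow = nv)
  W <- 1 / S^2
  sw <- rowSums(W)
  beta <- rowSums(W * B) / sw
  se <- 1 / sqrt(sw)
  Q <- rowSums(W * (B - beta)^2)
  k <- ncol(B)
  I2 <- if (k > 1) pmax(0, (Q - (k - 1)) / Q) * 100 else rep(0, length(Q))
  I2[Q <= 0] <- 0
  eaf <- rowMeans(matrix(vapply(mats, function(s) as.numeric(s$eaf),
                                numeric(nv)), nrow = nv))
  n <- rowSums(matrix(vapply(mats, function(s)
    ifelse(is.na(s$n), 0, as.numeric(s$n)), numeric(nv)), nrow = nv))
  out <- data.frame(id = ids, chrom = ref$chrom, pos = ref$pos,
                    ea = ref$ea, oa = ref$oa, beta = beta, se = se,
                    p = 2 * pnorm(-abs(beta / se)),
                    eaf = eaf, n = n, Q = Q, I2 = I2, k = k,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}
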
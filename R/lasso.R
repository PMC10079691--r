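## L1-penalized logistic polygenic model (glmnet backend).

#' Fit an L1-logistic polygenic model with cross-validation
#'
#' Penalized logistic regression of case status on dosages over a
#' descending lambda grid (100 log-spaced values down to
#' `1e-3 * lambda_max`), with five-fold cross-validation. Following the
#' convention of picking the lambda that retains the most variants, the
#' chosen lambda is the grid value (among those evaluated by CV) with the
#' largest number of nonzero variant coefficients — i.e. the smallest
#' lambda on the CV grid; ties break toward the smaller lambda.
#'
#' Covariates can enter in two modes: `"unpenalized"` includes them as
#' penalty-free columns of the design (single stage); `"offset"` first
#' fits a covariate-only logistic regression and carries its linear
#' predictor as a fixed offset, i.e. the covariate effects are regressed
#' out before the penalized genotype fit.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno a [phenotype_table()].
#' @param covariates covariate columns of `pheno` (may be empty).
#' @param nfolds number of CV folds (default 5).
#' @param foldid optional pre-assigned fold per sample (named by
#'   sample id), e.g. read from a fold file shared across tools.
#' @param covariate_mode `"unpenalized"` or `"offset"`.
#' @param type.measure CV loss passed to glmnet (default `"mse"`).
#' @param include_mci treat MCI as cases (default exclude).
#' @param seed integer seed controlling fold assignment.
#' @return list of class `lasso_model`: `intercept`, `coef` (named,
#'   variants only), `covariate_coef`, `lambda_chosen`, `cv_path`
#'   (lambda, mean CV loss, n_nonzero), `n_nonzero`, `mode`, `seed`,
#'   plus the underlying glmnet fit.
#' @export
fit_lasso <- function(geno, pheno,
                      covariates = c("age", "sex", paste0("pc", 1:5)),
                      nfolds = 5, foldid = NULL,
                      covariate_mode = c("unpenalized", "offset"),
                      type.measure = "mse",
                      include_mci = FALSE, seed = 1) {
  covariate_mode <- match.arg(covariate_mode)
  idx <- match(rownames(geno$dosage), pheno$sample_id)
  if (anyNA(idx)) stop("phenotype table lacks some genotyped samples")
  ph <- pheno[idx, , drop = FALSE]
  use <- if (include_mci) rep(TRUE, nrow(ph)) else ph$status %in% c("AD", "NC")
  y <- as.integer(ph$status[use] != "NC")
  if (length(unique(y)) < 2L) stop("outcome is not binary in these samples")
  D <- impute_dosage_means(geno$dosage[use, , drop = FALSE])
  if (all(apply(D, 2, var) < 1e-12)) stop("all genotype columns constant")
  p <- ncol(D)
  C <- if (length(covariates)) as.matrix(ph[use, covariates, drop = FALSE])
       else NULL

  offset <- NULL
  if (covariate_mode == "offset" && !is.null(C)) {
    cov_fit <- glm.fit(cbind(1, C), y, family = binomial())
    offset <- drop(cbind(1, C) %*% cov_fit$coefficients)
    X <- D
    pf <- rep(1, p)
  } else if (!is.null(C)) {
    X <- cbind(D, C)
    pf <- c(rep(1, p), rep(0, ncol(C)))
  } else {
    X <- D
    pf <- rep(1, p)
  }

  if (is.null(foldid)) {
    set.seed(split_seed(seed, 11L))
    foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  } else {
    if (!is.null(names(foldid))) foldid <- foldid[rownames(D)]
    foldid <- as.integer(foldid)
    if (length(foldid) != length(y)) stop("foldid length mismatch")
  }

  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          type.measure = type.measure, foldid = foldid,
                          penalty.factor = pf, offset = offset,
                          nlambda = 100, lambda.min.ratio = 1e-3,
                          standardize = FALSE)
  fit <- cv$glmnet.fit
  lam <- cv$lambda
  nz <- sapply(seq_along(lam), function(i) {
    sum(abs(fit$beta[seq_len(p), i]) > 0)
  })
  best <- which(nz == max(nz))
  lambda_chosen <- min(lam[best])
  ci <- which(lam == lambda_chosen)[1L]
  coefs <- as.numeric(fit$beta[, ci])
  variant_coef <- setNames(coefs[seq_len(p)], geno$variants$id)
  cov_coef <- if (!is.null(C) && covariate_mode == "unpenalized") {
    setNames(coefs[p + seq_len(ncol(C))], covariates)
  } else if (covariate_mode == "offset" && !is.null(C)) {
    setNames(cov_fit$coefficients[-1L], covariates)
  } else NULL

  structure(list(intercept = fit$a0[ci],
                 coef = variant_coef,
                 covariate_coef = cov_coef,
                 lambda_chosen = lambda_chosen,
                 cv_path = data.frame(lambda = lam, cvm = cv$cvm,
                                      n_nonzero = nz),
                 n_nonzero = sum(variant_coef != 0),
                 mode = covariate_mode,
                 covariates = covariates,
                 seed = seed,
                 glmnet_fit = fit),
            class = "lasso_model")
}

#' Score samples with a fitted L1-logistic model
#'
#' @param model a [fit_lasso()] result.
#' @param geno a [genotype_matrix()] containing the model's variants.
#' @param pheno phenotype table supplying covariates (only needed when
#'   `use_covariates = TRUE`).
#' @param use_covariates include the covariate contribution in the linear
#'   predictor (default `FALSE`: genotype-only polygenic score).
#' @return named vector of linear-predictor scores.
#' @export
predict_lasso <- function(model, geno, pheno = NULL,
                          use_covariates = FALSE) {
  j <- match(names(model$coef), geno$variants$id)
  if (anyNA(j)) stop("genotypes lack model variants")
  D <- impute_dosage_means(geno$dosage[, j, drop = FALSE])
  eta <- drop(D %*% model$coef) + model$intercept
  if (use_covariates && !is.null(model$covariate_coef)) {
    if (is.null(pheno)) stop("covariate scoring needs a phenotype table")
    idx <- match(rownames(geno$dosage), pheno$sample_id)
    C <- as.matrix(pheno[idx, model$covariates, drop = FALSE])
    eta <- eta + drop(C %*% model$covariate_coef)
  }
  eta
}
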
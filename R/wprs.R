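## Weighted polygenic risk score.

#' Build a weighted PRS model from summary statistics
#'
#' @param stats a [summary_stats()] table; `beta` becomes the weight.
#' @param ids optional subset of variant ids to include.
#' @return list of class `wprs_model` with `ids`, `weights`, `ea`, `oa`.
#' @export
wprs_model <- function(stats, ids = NULL) {
  if (is.null(ids)) ids <- stats$id
  i <- match(ids, stats$id)
  if (anyNA(i)) stop("summary stats lack ids: ",
                     paste(ids[is.na(i)], collapse = ", "))
  w <- stats$beta[i]
  if (any(!is.finite(w))) stop("non-finite weights")
  structure(list(ids = ids, weights = setNames(w, ids),
                 ea = stats$ea[i], oa = stats$oa[i]),
            class = "wprs_model")
}

#' Weighted polygenic risk score
#'
#' The classical PRS: the dosage of each model variant multiplied
#' elementwise by its log-odds weight and summed per sample, with no
#' normalization. Genotypes must already be harmonized to the model's
#' effect alleles; missing dosages are mean-imputed.
#'
#' @param geno a [genotype_matrix()].
#' @param model a [wprs_model()], or a named numeric vector of weights.
#' @return named numeric vector of per-sample scores.
#' @export
weighted_prs <- function(geno, model) {
  w <- if (inherits(model, "wprs_model")) model$weights else model
  if (is.null(names(w))) stop("weights must be named by variant id")
  j <- match(names(w), geno$variants$id)
  if (anyNA(j)) {
    stop("genotypes lack model variant(s): ",
         paste(names(w)[is.na(j)], collapse = ", "))
  }
  D <- impute_dosage_means(geno$dosage[, j, drop = FALSE])
  drop(D %*% w)
}
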
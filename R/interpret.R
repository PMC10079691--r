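## Endophenotype association and model interpretation: robust regression,
## rank-inverse-normal transform, module association, clustering with
## elbow selection, and partial Spearman variant attribution.

#' Rank-based inverse-normal transform
#'
#' `z_i = qnorm((r_i - offset) / (n - 2 offset + 1))` with average ranks
#' for ties; the default offset 3/8 is Blom's. The output depends on the
#' input only through its ranks, so it is invariant under strictly
#' monotone transforms.
#'
#' @param values numeric vector, n >= 2, not all identical.
#' @param offset rank offset (default 3/8).
#' @return numeric z-scores.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L) stop("need at least two values")
  if (length(unique(x)) == 1L) stop("all values identical; ranks degenerate")
  r <- rank(x, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Robust linear regression (M-estimation)
#'
#' Iteratively reweighted least squares with a Huber start refined by
#' Tukey's bisquare (tuning constant 4.685, 95% Gaussian efficiency) and
#' MAD scale, as provided by [MASS::rlm()]. Reports robust standard
#' errors, t-statistics and two-sided p-values per coefficient. On
#' outlier-free Gaussian data the coefficients agree with least squares
#' to numerical tolerance.
#'
#' @param y numeric response.
#' @param X design matrix (an intercept column is added when absent);
#'   must have full column rank.
#' @return list of class `robust_fit`: `coefficients`, `se`, `t`, `p`,
#'   `converged`, `weights` (final observation weights in \[0, 1\]),
#'   `df_residual`.
#' @export
robust_linear_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!"(Intercept)" %in% colnames(X)) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  n <- nrow(X)
  if (n <= ncol(X)) stop("need more observations than columns")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  fit_h <- MASS::rlm(X, y, psi = MASS::psi.huber, scale.est = "MAD",
                     maxit = 100)
  fit <- MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685,
                   scale.est = "MAD", maxit = 100,
                   init = list(coefficients = coef(fit_h),
                               scale = fit_h$s))
  sm <- summary(fit, method = "XtWX")$coefficients
  co <- sm[, 1L]
  se <- sm[, 2L]
  tv <- co / se
  df <- n - ncol(X)
  structure(list(coefficients = co, se = se, t = tv,
                 p = 2 * pt(-abs(tv), df = df),
                 converged = fit$converged,
                 weights = fit$w, df_residual = df,
                 scale = fit$s),
            class = "robust_fit")
}

#' Association between a predictor and an endophenotype
#'
#' Robust regression of the endophenotype on the predictor (a polygenic
#' score, a module output, or a group indicator) plus covariates, with
#' intracranial volume available as an extra covariate for imaging-type
#' endophenotypes. Raw p-values are reported by default; BH adjustment
#' across a batch of calls is left to the caller (the `bh` flag merely
#' adjusts within this fit's coefficient table).
#'
#' @param predictor numeric vector.
#' @param endophenotype numeric vector (same length).
#' @param covariates data frame / matrix of covariates, or `NULL`.
#' @param icv optional intracranial volume covariate.
#' @param bh also report BH-adjusted p-values.
#' @return a `robust_fit`; the predictor's row is named `"predictor"`.
#' @export
endophenotype_assoc <- function(predictor, endophenotype,
                                covariates = NULL, icv = NULL,
                                bh = FALSE) {
  X <- cbind(predictor = as.numeric(predictor))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (!is.null(icv)) X <- cbind(X, icv = as.numeric(icv))
  fit <- robust_linear_fit(as.numeric(endophenotype), X)
  if (bh) fit$p_bh <- p.adjust(fit$p, method = "BH")
  fit
}

#' Joint association of all modules with an endophenotype
#'
#' A single robust fit with the module columns as joint predictors
#' (plus covariates); returns the per-module t-statistics used for
#' protein clustering.
#'
#' @param modules matrix of penultimate-layer outputs
#'   ([penultimate_outputs()]).
#' @param endophenotype numeric response.
#' @param covariates optional covariate matrix.
#' @return named vector of module t-statistics, with the full
#'   `robust_fit` attached as attribute `fit`.
#' @export
multivariate_module_assoc <- function(modules, endophenotype,
                                      covariates = NULL) {
  M <- as.matrix(modules)
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(ncol(M)))
  X <- M
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  fit <- tryCatch(robust_linear_fit(as.numeric(endophenotype), X),
                  error = function(e) {
                    if (grepl("rank deficient", conditionMessage(e))) {
                      stop("module columns are collinear; drop a duplicated ",
                           "module before the joint fit", call. = FALSE)
                    }
                    stop(e)
                  })
  t_mod <- fit$t[colnames(M)]
  attr(t_mod, "fit") <- fit
  t_mod
}

#' K-means clustering with elbow-based k selection
#'
#' Runs best-of-`n_start` k-means for every candidate k and records the
#' total within-cluster sum of squares (the elbow curve). The chosen k
#' maximizes the second difference of the WSS curve — an algorithmic
#' reading of the visual elbow heuristic. When every candidate achieves
#' (numerically) zero WSS the tie breaks toward the smallest k.
#'
#' @param mat numeric matrix, rows = items to cluster.
#' @param k_candidates integer candidates (default `1:6`).
#' @param seed integer seed.
#' @param n_start random restarts per k (default 25).
#' @return list of class `cluster_result`: `k`, `assignments` (for the
#'   chosen k), `wss` (named by k), `seed`, `n_start`.
#' @export
kmeans_cluster <- function(mat, k_candidates = 1:6, seed = 1,
                           n_start = 25) {
  mat <- as.matrix(mat)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (max(k_candidates) > nrow(mat)) {
    stop("k exceeds the number of rows (", nrow(mat), ")")
  }
  wss <- numeric(length(k_candidates))
  fits <- vector("list", length(k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    n_distinct <- nrow(unique(mat))
    if (k == 1L) {
      wss[i] <- sum(scale(mat, scale = FALSE)^2)
      fits[[i]] <- list(cluster = rep(1L, nrow(mat)))
    } else if (k >= n_distinct) {
      ## every distinct point gets its own center; WSS is zero
      key <- apply(mat, 1, paste, collapse = "\r")
      wss[i] <- 0
      fits[[i]] <- list(cluster = as.integer(factor(key,
                                                    levels = unique(key))))
    } else {
      set.seed(split_seed(seed, 51L + k))
      km <- kmeans(mat, centers = k, nstart = n_start, iter.max = 50)
      wss[i] <- km$tot.withinss
      fits[[i]] <- km
    }
  }
  names(wss) <- k_candidates
  tot <- sum(scale(mat, scale = FALSE)^2)
  if (tot < 1e-12 || all(wss < 1e-12)) {
    chosen <- k_candidates[1L]
  } else if (length(k_candidates) >= 3L) {
    d2 <- wss[seq_len(length(wss) - 2L)] -
      2 * wss[seq(2L, length(wss) - 1L)] +
      wss[seq(3L, length(wss))]
    chosen <- k_candidates[which.max(d2) + 1L]
  } else {
    chosen <- k_candidates[which.min(wss)]
  }
  ci <- match(chosen, k_candidates)
  structure(list(k = chosen, assignments = fits[[ci]]$cluster,
                 wss = wss, seed = seed, n_start = n_start),
            class = "cluster_result")
}

#' Partial Spearman correlation of each variant with a score
#'
#' All columns are rank-transformed; the partial correlation of variant i
#' with the score, controlling for all remaining variants, is read off
#' the inverse of the joint correlation matrix
#' (`rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`). P-values use the
#' t-approximation with `df = n - (n_variants - 1) - 2`.
#'
#' @param score numeric score per sample.
#' @param dosages samples x variants matrix (or [genotype_matrix()]).
#' @return data frame: `id`, `rho`, `p`.
#' @export
spearman_partial_correlation <- function(score, dosages) {
  D <- if (inherits(dosages, "genotype_matrix"))
    impute_dosage_means(dosages$dosage) else as.matrix(dosages)
  n <- nrow(D)
  p <- ncol(D)
  if (n <= p + 2L) stop("need n > n_variants + 2")
  if (p == 1L) {
    rho <- cor(rank(score), rank(D[, 1L]))
    tv <- rho * sqrt((n - 2) / (1 - rho^2))
    return(data.frame(id = colnames(D) %||% "v1", rho = rho,
                      p = 2 * pt(-abs(tv), df = n - 2)))
  }
  R <- cor(apply(cbind(score, D), 2, rank))
  omega <- tryCatch(solve(R), error = function(e) {
    cc <- cor(apply(D, 2, rank))
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("rank correlation matrix is singular; near-duplicate variants ",
         "e.g. columns ", worst[1], " and ", worst[2], call. = FALSE)
  })
  rho <- -omega[1L, -1L] / sqrt(omega[1L, 1L] * diag(omega)[-1L])
  df <- n - (p - 1L) - 2L
  tv <- rho * sqrt(df / pmax(1 - rho^2, 1e-12))
  data.frame(id = colnames(D) %||% paste0("v", seq_len(p)),
             rho = as.numeric(rho), p = 2 * pt(-abs(tv), df = df),
             row.names = NULL)
}
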
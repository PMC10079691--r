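## Gaussian-mixture stratification of risk scores into low/medium/high
## groups, and association of the groups with disease phenotype.

#' Fit a univariate Gaussian mixture to risk scores
#'
#' Expectation-maximization with k-means-based initialization. The
#' log-likelihood is monotonically non-decreasing across iterations;
#' convergence is declared when its relative change falls below `tol` or
#' after `max_iter` iterations. A collapsing component (sigma below
#' 1e-8 times the score sd) triggers a re-initialization with a fresh
#' seed, up to `max_restarts` attempts. Components are returned sorted by
#' ascending mean, so for K = 3 they read low / medium / high.
#'
#' @param scores numeric risk scores (n >= 5 K).
#' @param K number of components (default 3).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood tolerance (default 1e-8).
#' @param seed integer seed (k-means initialization).
#' @param max_restarts restart budget on component collapse.
#' @return list of class `gmm_fit`: `mu`, `sigma`, `lambda` (mixing
#'   weights), `loglik` (final), `loglik_trace`, `iterations`,
#'   `converged`, `K`, `seed`.
#' @export
fit_gmm <- function(scores, K = 3, max_iter = 200, tol = 1e-8, seed = 1,
                    max_restarts = 3) {
  x <- as.numeric(scores)
  if (any(!is.finite(x))) stop("scores must be finite")
  n <- length(x)
  if (n < 5 * K) stop("need at least ", 5 * K, " scores for K = ", K)
  if (K == 1L) {
    mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
    ll <- sum(dnorm(x, mu, sg, log = TRUE))
    return(structure(list(mu = mu, sigma = sg, lambda = 1, loglik = ll,
                          loglik_trace = ll, iterations = 0L,
                          converged = TRUE, K = 1L, seed = seed),
                     class = "gmm_fit"))
  }
  sd_x <- sd(x)
  floor_sigma <- 1e-8 * max(sd_x, 1e-12)
  for (attempt in 0:max_restarts) {
    set.seed(split_seed(seed + attempt, 41L))
    km <- kmeans(x, centers = K, nstart = 10)
    mu <- as.numeric(km$centers)
    sg <- vapply(seq_len(K), function(k) {
      xs <- x[km$cluster == k]
      s <- if (length(xs) > 1L) sd(xs) else 0
      max(s, sd_x / 10)
    }, numeric(1))
    lam <- as.numeric(table(factor(km$cluster, levels = seq_len(K))) / n)
    lam <- pmax(lam, 1e-6); lam <- lam / sum(lam)

    trace <- numeric(0)
    ll_old <- -Inf
    collapsed <- FALSE
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      dens <- vapply(seq_len(K), function(k)
        lam[k] * dnorm(x, mu[k], sg[k]), numeric(n))
      tot <- rowSums(dens)
      tot[tot < 1e-300] <- 1e-300
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      resp <- dens / tot
      nk <- colSums(resp)
      lam <- nk / n
      mu <- colSums(resp * x) / nk
      sg <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
      if (any(!is.finite(sg)) || any(sg < floor_sigma)) {
        collapsed <- TRUE
        break
      }
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    if (!collapsed) {
      ord <- order(mu)
      return(structure(list(mu = mu[ord], sigma = sg[ord],
                            lambda = lam[ord],
                            loglik = trace[length(trace)],
                            loglik_trace = trace,
                            iterations = iter, converged = converged,
                            K = K, seed = seed),
                       class = "gmm_fit"))
    }
  }
  stop("Gaussian mixture collapsed in all ", max_restarts + 1, " attempts")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("gmm_fit with", x$K, "component(s):\n")
  print(data.frame(mu = x$mu, sigma = x$sigma, lambda = x$lambda))
  cat("log-likelihood", x$loglik, "after", x$iterations, "iterations\n")
  invisible(x)
}

#' Low/medium/high membership probabilities for scores
#'
#' Default `"posterior"` mode returns the posterior responsibilities
#' `p_k proportional to lambda_k * phi(score; mu_k, sigma_k)`, which sum
#' to one exactly — the medium probability then automatically equals one
#' minus the sum of the low and high probabilities. The `"literal"` mode
#' instead evaluates tail probabilities of the two outer components
#' (`p_low = P(X1 >= s)`, `p_high = P(X3 <= s)`) and defines
#' `p_med = 1 - p_low - p_high`, clipping to \[0, 1\] with a warning when
#' the identity over-runs.
#'
#' @param gmm a K = 3 [fit_gmm()] result.
#' @param scores numeric scores.
#' @param mode `"posterior"` (default) or `"literal"`.
#' @return matrix with columns `p_low`, `p_med`, `p_high`.
#' @export
membership_probs <- function(gmm, scores,
                             mode = c("posterior", "literal")) {
  mode <- match.arg(mode)
  if (gmm$K != 3L) stop("membership_probs needs a 3-component fit")
  x <- as.numeric(scores)
  if (mode == "posterior") {
    ## log-space softmax so extreme scores do not underflow
    ld <- vapply(1:3, function(k)
      log(gmm$lambda[k]) + dnorm(x, gmm$mu[k], gmm$sigma[k], log = TRUE),
      numeric(length(x)))
    ld <- matrix(ld, ncol = 3)
    ld <- ld - apply(ld, 1, max)
    P <- exp(ld) / rowSums(exp(ld))
  } else {
    p_low <- pnorm(x, gmm$mu[1], gmm$sigma[1], lower.tail = FALSE)
    p_high <- pnorm(x, gmm$mu[3], gmm$sigma[3])
    p_med <- 1 - p_low - p_high
    if (any(p_med < 0 | p_med > 1)) {
      warning("medium-group probability clipped to [0, 1] for ",
              sum(p_med < 0 | p_med > 1), " score(s)")
      p_med <- pmin(pmax(p_med, 0), 1)
    }
    P <- cbind(p_low, p_med, p_high)
  }
  colnames(P) <- c("p_low", "p_med", "p_high")
  P
}

#' Assign low/medium/high risk groups
#'
#' @param gmm a K = 3 [fit_gmm()].
#' @param scores numeric scores.
#' @param mode passed to [membership_probs()].
#' @return data frame of class `risk_groups` with `p_low`, `p_med`,
#'   `p_high` and the argmax `label` (factor low/medium/high).
#' @export
assign_risk_groups <- function(gmm, scores, mode = "posterior") {
  P <- membership_probs(gmm, scores, mode = mode)
  lab <- c("low", "medium", "high")[max.col(P, ties.method = "first")]
  out <- data.frame(P, label = factor(lab, levels = c("low", "medium",
                                                      "high")))
  class(out) <- c("risk_groups", "data.frame")
  out
}

#' Disease odds by risk group
#'
#' Logistic regressions of AD-vs-NC and MCI-vs-NC status on the hard risk
#' group label (low as reference) plus covariates, reporting the odds
#' ratio, Wald confidence interval and p-value per contrast. Groups
#' absent from a contrast are skipped with a warning.
#'
#' @param groups [assign_risk_groups()] output aligned to `pheno` rows.
#' @param pheno a [phenotype_table()].
#' @param covariates covariate columns (default age, sex, pc1..pc5).
#' @param level confidence level.
#' @return data frame: `outcome` (AD or MCI), `contrast`, `or`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
risk_group_logistic <- function(groups, pheno,
                                covariates = c("age", "sex",
                                               paste0("pc", 1:5)),
                                level = 0.95) {
  stopifnot(nrow(groups) == nrow(pheno))
  z <- qnorm(1 - (1 - level) / 2)
  out <- list()
  for (outcome in c("AD", "MCI")) {
    use <- pheno$status %in% c(outcome, "NC")
    y <- as.integer(pheno$status[use] == outcome)
    g <- droplevels(groups$label[use])
    if (length(unique(y)) < 2L || nlevels(g) < 2L) {
      warning("contrasts skipped for ", outcome,
              ": need two classes and two groups")
      next
    }
    df <- data.frame(y = y, group = g,
                     pheno[use, covariates, drop = FALSE])
    fit <- glm(y ~ ., data = df, family = binomial())
    sm <- summary(fit)$coefficients
    rows <- grep("^group", rownames(sm), value = TRUE)
    for (r in rows) {
      b <- sm[r, 1]; s <- sm[r, 2]
      out[[length(out) + 1L]] <- data.frame(
        outcome = outcome,
        contrast = paste0(sub("^group", "", r), " vs ", levels(g)[1L]),
        or = exp(b), ci_low = exp(b - z * s), ci_high = exp(b + z * s),
        p = 2 * pnorm(-abs(b / s)))
    }
  }
  if (!length(out)) {
    warning("all contrasts skipped")
    return(data.frame(outcome = character(0), contrast = character(0),
                      or = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0)))
  }
  do.call(rbind, out)
}
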
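## Reproducible evaluation scenarios. Each function simulates a cohort
## with a fixed genetic architecture, runs the relevant pipeline end to
## end, and returns the measured quantities. They double as the package's
## empirical validation suite and as worked examples of composing the
## toolkit.

#' Epistatic-architecture model comparison
#'
#' Cohorts with a purely epistatic liability: interaction pairs sit in
#' two-variant LD blocks (so the LD graph connects them) at
#' near-symmetric allele frequencies, where centered dosage products
#' carry no marginal signal. A marginal-GWAS weighted PRS is therefore
#' blind to the architecture, while the dense and graph networks can
#' model it. Per seed: simulate, split train/held-out, run GWAS -> wPRS,
#' train the dense network and (optionally) the graph model, and measure
#' held-out auROC for each.
#'
#' @param seeds integer seeds, one cohort per seed.
#' @param n cohort size (default 6000).
#' @param n_variants number of variants (default 50).
#' @param n_pairs number of interaction pairs (default 5).
#' @param gamma interaction coefficient (default 2).
#' @param train_frac fraction used for training (default 2/3).
#' @param run_gnn also train the graph model (default TRUE).
#' @param nn_epochs,gnn_epochs training lengths.
#' @param nn_lr0,gnn_train_n dense-net initial learning rate and size of
#'   the training subset used for the graph model.
#' @return data frame per seed: `auroc_wprs`, `auroc_nn`, `auroc_gnn`.
#' @export
benchmark_epistasis <- function(seeds = 1:5, n = 6000, n_variants = 50,
                                n_pairs = 5, gamma = 2, train_frac = 2 / 3,
                                run_gnn = TRUE, nn_epochs = 500,
                                gnn_epochs = 15, nn_lr0 = 2,
                                gnn_train_n = 2000) {
  pair_i <- seq(1L, by = 2L, length.out = n_pairs)
  blocks <- data.frame(size = c(rep(2L, n_pairs),
                                rep(1L, n_variants - 2L * n_pairs)),
                       r = c(rep(0.8, n_pairs),
                             rep(0, n_variants - 2L * n_pairs)))
  rows <- lapply(seeds, function(sd) {
    spec <- sim_spec(n_samples = n, n_variants = n_variants,
                     maf_range = c(0.45, 0.5), ld_blocks = blocks,
                     epistatic_pairs = data.frame(i = pair_i,
                                                  j = pair_i + 1L,
                                                  gamma = gamma),
                     covariate_effects = c(age = 0, sex = 0),
                     case_fraction = 0.5, mci_fraction = 0, seed = sd)
    cohort <- simulate_cohort(spec)
    eval_models_on_cohort(cohort, train_frac, run_gnn, nn_epochs,
                          gnn_epochs, nn_lr0, gnn_train_n, seed = sd)
  })
  do.call(rbind, rows)
}

#' Additive-architecture model comparison
#'
#' Purely additive liability: ten moderate-effect variants plus one
#' large-effect (APOE-like) locus. The Bayes-optimal score is the true
#' linear predictor, so the weighted PRS built from the true effect
#' sizes should sit at the oracle, and a well-trained dense network
#' should match it with no spurious advantage.
#'
#' @inheritParams benchmark_epistasis
#' @return data frame per seed: `auroc_oracle`, `auroc_wprs_true`,
#'   `auroc_nn`.
#' @export
benchmark_additive <- function(seeds = 1:5, n = 6000, n_variants = 50,
                               train_frac = 2 / 3, nn_epochs = 500,
                               nn_lr0 = 0.5) {
  beta <- rep(0, n_variants)
  beta[1:10] <- 0.35
  rows <- lapply(seeds, function(sd) {
    spec <- sim_spec(n_samples = n, n_variants = n_variants,
                     maf_range = c(0.1, 0.5),
                     additive_effects = beta,
                     large_effect = list(variant = 11L, beta = 1.1),
                     covariate_effects = c(age = 0, sex = 0),
                     case_fraction = 0.5, mci_fraction = 0, seed = sd)
    cohort <- simulate_cohort(spec)
    n_all <- nrow(cohort$genotypes$dosage)
    set.seed(split_seed(sd, 71L))
    tr <- sample(n_all, floor(n_all * train_frac))
    te <- setdiff(seq_len(n_all), tr)
    y <- as.integer(cohort$phenotypes$status == "AD")

    true_beta <- attr(cohort$truth, "beta")
    w <- setNames(true_beta, cohort$genotypes$variants$id)
    prs <- weighted_prs(cohort$genotypes, w[w != 0])
    oracle <- cohort$truth$liability

    X <- impute_dosage_means(cohort$genotypes$dosage)
    nn <- build_nn("chinese", n_features = n_variants, init_seed = sd)
    cfg <- train_config(epochs = nn_epochs, batch_size = 256, lr0 = nn_lr0,
                        patience = NULL, validation_fraction = 0.2,
                        seed = sd)
    nn <- train_nn(nn, X[tr, , drop = FALSE], y[tr], cfg)
    data.frame(seed = sd,
               auroc_oracle = auroc(oracle[te], y[te]),
               auroc_wprs_true = auroc(prs[te], y[te]),
               auroc_nn = auroc(nn_score(nn, X[te, , drop = FALSE]), y[te]))
  })
  do.call(rbind, rows)
}

## shared train/test evaluation of wPRS / NN / GNN on one cohort
eval_models_on_cohort <- function(cohort, train_frac, run_gnn, nn_epochs,
                                  gnn_epochs, nn_lr0, gnn_train_n, seed) {
  geno <- cohort$genotypes
  pheno <- cohort$phenotypes
  n_all <- nrow(geno$dosage)
  set.seed(split_seed(seed, 72L))
  tr <- sample(n_all, floor(n_all * train_frac))
  te <- setdiff(seq_len(n_all), tr)
  y <- as.integer(pheno$status == "AD")

  gtr <- subset_genotypes(geno, samples = tr)
  gwas <- logistic_assoc(gtr, pheno[tr, , drop = FALSE],
                         covariates = character(0))
  prs <- weighted_prs(geno, wprs_model(gwas))

  X <- impute_dosage_means(geno$dosage)
  nn <- build_nn("chinese", n_features = ncol(X), init_seed = seed)
  cfg <- train_config(epochs = nn_epochs, batch_size = 256, lr0 = nn_lr0,
                      patience = NULL, validation_fraction = 0.2,
                      seed = seed)
  nn <- train_nn(nn, X[tr, , drop = FALSE], y[tr], cfg)

  auc_gnn <- NA_real_
  if (run_gnn) {
    graphs <- build_graphs(geno)
    gtr <- tr[seq_len(min(gnn_train_n, length(tr)))]
    gm <- train_gnn(subset_graphs(graphs, gtr), y[gtr],
                    epochs = gnn_epochs, batch_size = 256,
                    lr = 0.01, patience = 20, seed = seed)
    auc_gnn <- auroc(gnn_score(gm, subset_graphs(graphs, te)), y[te])
  }
  data.frame(seed = seed,
             auroc_wprs = auroc(prs[te], y[te]),
             auroc_nn = auroc(nn_score(nn, X[te, , drop = FALSE]), y[te]),
             auroc_gnn = auc_gnn)
}

#' Restrict a graph set to a subset of samples
#'
#' @param graphs a [build_graphs()] object.
#' @param idx sample indices.
#' @return an `snp_graphs` object over the selected samples.
#' @export
subset_graphs <- function(graphs, idx) {
  out <- graphs
  out$dosage <- graphs$dosage[idx, , drop = FALSE]
  out$sample_ids <- graphs$sample_ids[idx]
  out
}

#' Pathway-module interpretability scenario
#'
#' Five disjoint pathways of strong additive effects drive the liability;
#' one biomarker loads on pathway 1 only. Per seed the dense network is
#' trained, its five penultimate modules extracted, and (i) each pathway
#' burden is matched to its best-correlated module (Spearman), (ii) the
#' joint robust module association with the biomarker is checked for
#' assigning its maximal |t| to the module that an independent
#' least-squares fit of the true pathway-1 burden on the modules
#' identifies as carrying the unique pathway-1 signal.
#'
#' @inheritParams benchmark_epistasis
#' @param beta per-variant effect (default 0.3).
#' @return data frame per seed: `min_best_rho` (worst pathway's best
#'   module correlation), `t_matches` (maximal |t| lands on the module
#'   best correlated with pathway 1).
#' @export
benchmark_pathways <- function(seeds = 1:5, n = 4000, n_variants = 50,
                               beta = 0.4, nn_epochs = 500, nn_lr0 = 0.5) {
  lam <- matrix(c(1, 0, 0, 0, 0), 1, 5)
  rownames(lam) <- "bm_pathway1"
  rows <- lapply(seeds, function(sd) {
    spec <- sim_spec(n_samples = n, n_variants = n_variants,
                     maf_range = c(0.1, 0.5),
                     additive_effects = rep(beta, n_variants),
                     n_pathways = 5,
                     covariate_effects = c(age = 0, sex = 0),
                     case_fraction = 0.5, mci_fraction = 0,
                     endophenotype_loadings = lam,
                     noise_sd = list(liability = 0, biomarker = 0.5),
                     seed = sd)
    cohort <- simulate_cohort(spec)
    y <- as.integer(cohort$phenotypes$status == "AD")
    X <- impute_dosage_means(cohort$genotypes$dosage)
    nn <- build_nn("chinese", n_features = n_variants, init_seed = sd)
    cfg <- train_config(epochs = nn_epochs, batch_size = 256, lr0 = nn_lr0,
                        patience = NULL, validation_fraction = 0.2,
                        seed = sd)
    nn <- train_nn(nn, X, y, cfg)
    mods <- penultimate_outputs(nn, X)
    B <- as.matrix(cohort$truth[, paste0("B", 1:5)])
    rho <- abs(cor(apply(mods, 2, rank), apply(B, 2, rank)))
    best_rho <- apply(rho, 2, max)          # per pathway
    ## reference module for pathway 1: the one uniquely tied to the
    ## true burden once the other (inter-correlated) modules are
    ## controlled for, by an independent least-squares route
    ref_t <- summary(lm(cohort$truth$B1 ~ mods))$coefficients[-1L, 3L]
    best_mod_p1 <- which.max(abs(ref_t))
    tstat <- multivariate_module_assoc(mods,
                                       cohort$phenotypes$bm_pathway1)
    data.frame(seed = sd, min_best_rho = min(best_rho),
               t_matches = which.max(abs(tstat)) == best_mod_p1)
  })
  do.call(rbind, rows)
}

#' Gaussian-mixture risk stratification scenario
#'
#' Additive liability drives status; the true-beta weighted PRS is
#' stratified by a three-component Gaussian mixture and the case
#' fraction per group and the high-vs-low odds ratio are measured.
#'
#' @inheritParams benchmark_epistasis
#' @return data frame per seed: `frac_low`, `frac_med`, `frac_high`
#'   (AD fraction per risk group), `monotone`, `or_high_vs_low`, `p`.
#' @export
benchmark_stratification <- function(seeds = 1:5, n = 2000,
                                     n_variants = 50) {
  ## a dominant major locus makes the score genuinely trimodal, so the
  ## three mixture components correspond to well-occupied risk groups
  beta <- rep(0, n_variants)
  beta[1:10] <- 0.2
  rows <- lapply(seeds, function(sd) {
    spec <- sim_spec(n_samples = n, n_variants = n_variants,
                     maf_range = c(0.1, 0.5), additive_effects = beta,
                     large_effect = list(variant = 11L, beta = 1.6),
                     covariate_effects = c(age = 0, sex = 0),
                     case_fraction = 0.5, mci_fraction = 0.1, seed = sd)
    cohort <- simulate_cohort(spec)
    w <- setNames(attr(cohort$truth, "beta"),
                  cohort$genotypes$variants$id)
    score <- weighted_prs(cohort$genotypes, w[w != 0])
    gmm <- fit_gmm(score, K = 3, seed = sd)
    groups <- assign_risk_groups(gmm, score)
    st <- cohort$phenotypes$status
    frac <- vapply(c("low", "medium", "high"), function(g) {
      i <- groups$label == g & st %in% c("AD", "NC")
      if (!any(i)) return(NA_real_)
      mean(st[i] == "AD")
    }, numeric(1))
    assoc <- risk_group_logistic(groups, cohort$phenotypes,
                                 covariates = c("age", "sex"))
    hi <- assoc[assoc$outcome == "AD" &
                  grepl("^high", assoc$contrast), , drop = FALSE]
    data.frame(seed = sd, frac_low = frac[1], frac_med = frac[2],
               frac_high = frac[3],
               monotone = !anyNA(frac) && frac[1] < frac[2] &&
                 frac[2] < frac[3],
               or_high_vs_low = if (nrow(hi)) hi$or else NA_real_,
               p = if (nrow(hi)) hi$p else NA_real_)
  })
  do.call(rbind, rows)
}

#' Pooled null calibration of the per-variant logistic scan
#'
#' Simulates cohorts with no genetic, epistatic or covariate effects and
#' pools the per-variant p-values across replicates; under the null the
#' rejection rate at `alpha` estimates the type-I error.
#'
#' @param n_reps replicates (default 200).
#' @param n samples per replicate (default 5000).
#' @param n_variants variants per replicate (default 100).
#' @param alpha nominal level (default 0.05).
#' @param seed master seed.
#' @return list with `rate`, `n_tests`.
#' @export
null_gwas_type1 <- function(n_reps = 200, n = 5000, n_variants = 100,
                            alpha = 0.05, seed = 1) {
  pvals <- numeric(0)
  for (r in seq_len(n_reps)) {
    spec <- sim_spec(n_samples = n, n_variants = n_variants,
                     covariate_effects = c(age = 0, sex = 0),
                     case_fraction = 0.5, mci_fraction = 0,
                     seed = split_seed(seed, 80L + r))
    geno <- simulate_genotypes(spec, n_samples = n)
    ph <- simulate_phenotypes(geno, spec)
    gw <- logistic_assoc(geno, ph$pheno, covariates = character(0))
    pvals <- c(pvals, gw$p[!is.na(gw$p)])
  }
  list(rate = mean(pvals < alpha), n_tests = length(pvals))
}

#' Coverage of the bootstrap auROC interval under the null
#'
#' Scores independent of labels: the true auROC is 0.5, and the 95%
#' stratified-bootstrap percentile interval should contain it in ~95% of
#' outer replicates.
#'
#' @param n_outer outer replicates (default 100).
#' @param n_pos,n_neg class sizes (default 500 each).
#' @param B bootstrap replicates per interval (default 2000).
#' @param seed master seed.
#' @return list with `coverage`, `n_outer`.
#' @export
null_auroc_coverage <- function(n_outer = 100, n_pos = 500, n_neg = 500,
                                B = 2000, seed = 1) {
  hits <- logical(n_outer)
  for (r in seq_len(n_outer)) {
    set.seed(split_seed(seed, 90L + r))
    scores <- rnorm(n_pos + n_neg)
    labels <- c(rep(1L, n_pos), rep(0L, n_neg))
    ci <- bootstrap_ci_auroc(scores, labels, B = B,
                             seed = split_seed(seed, 190L + r))
    hits[r] <- ci[1L] <= 0.5 && 0.5 <= ci[2L]
  }
  list(coverage = mean(hits), n_outer = n_outer)
}

#' Lasso causal-support recovery scenario
#'
#' Additive cohorts with `n_causal` variants of effect size `beta`
#' (alternating sign); the L1-logistic model is fit with five-fold CV and
#' the fraction of causal variants with nonzero coefficients at the
#' chosen lambda is reported per seed.
#'
#' @inheritParams benchmark_epistasis
#' @param n_causal number of causal variants (default 20).
#' @param beta absolute effect size (default 0.25).
#' @return data frame per seed: `recovered` (fraction of causal support).
#' @export
lasso_recovery <- function(seeds = 1:5, n = 8000, n_variants = 100,
                           n_causal = 20, beta = 0.25) {
  rows <- lapply(seeds, function(sd) {
    eff <- rep(0, n_variants)
    eff[seq_len(n_causal)] <- beta * rep_len(c(1, -1), n_causal)
    spec <- sim_spec(n_samples = n, n_variants = n_variants,
                     maf_range = c(0.1, 0.5), additive_effects = eff,
                     covariate_effects = c(age = 0, sex = 0),
                     case_fraction = 0.5, mci_fraction = 0, seed = sd)
    cohort <- simulate_cohort(spec)
    fit <- fit_lasso(cohort$genotypes, cohort$phenotypes,
                     covariates = character(0), seed = sd)
    causal_ids <- cohort$genotypes$variants$id[seq_len(n_causal)]
    data.frame(seed = sd,
               recovered = mean(fit$coef[causal_ids] != 0),
               n_nonzero = fit$n_nonzero)
  })
  do.call(rbind, rows)
}

#' Single-variant effect-size recovery
#'
#' One causal variant with log-odds effect `beta_true`; the per-variant
#' logistic scan should recover it (case-control sampling preserves the
#' slope, shifting only the intercept).
#'
#' @param n cohort size (default 8000).
#' @param beta_true true effect (default `log(3)`).
#' @param seed integer seed.
#' @return list with `beta_hat`, `beta_true`.
#' @export
gwas_beta_recovery <- function(n = 8000, beta_true = log(3), seed = 1) {
  spec <- sim_spec(n_samples = n, n_variants = 1,
                   maf_range = c(0.3, 0.4),
                   additive_effects = beta_true,
                   covariate_effects = c(age = 0, sex = 0),
                   case_fraction = 0.5, mci_fraction = 0, seed = seed)
  cohort <- simulate_cohort(spec)
  gw <- logistic_assoc(cohort$genotypes, cohort$phenotypes,
                       covariates = character(0))
  list(beta_hat = gw$beta[1L], beta_true = beta_true)
}

#' Mixture parameter recovery
#'
#' Draws scores from a known three-component mixture and refits it.
#'
#' @param n sample size (default 3000).
#' @param mu,sigma,lambda true component parameters.
#' @param seed integer seed.
#' @return list with `mu_hat`, `mu_true`, `fit`.
#' @export
gmm_recovery <- function(n = 3000, mu = c(-2, 0, 2), sigma = 0.4,
                         lambda = c(1, 1, 1) / 3, seed = 1) {
  set.seed(split_seed(seed, 95L))
  comp <- sample(seq_along(mu), n, replace = TRUE, prob = lambda)
  x <- rnorm(n, mu[comp], sigma)
  fit <- fit_gmm(x, K = length(mu), seed = seed)
  list(mu_hat = fit$mu, mu_true = mu, fit = fit)
}
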
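## Synthetic case-control cohorts with LD blocks, a large-effect locus,
## additive + epistatic liability, covariates and latent-pathway-driven
## endophenotypes. The generator exists so that every downstream stage
## (GWAS, meta-analysis, scores, networks, stratification, interpretation)
## can be exercised without access to restricted genotype data.

#' Specify a synthetic cohort
#'
#' @param n_samples cohort size after case-control sampling.
#' @param n_variants number of variants.
#' @param maf_range minor-allele-frequency range, drawn uniformly per LD
#'   block (variants within a block share a frequency).
#' @param ld_blocks data frame with columns `size` and `r` (target
#'   within-block dosage correlation); sizes must sum to `n_variants`.
#'   Default: all-independent singleton blocks.
#' @param additive_effects per-variant log-odds effects (length
#'   `n_variants`; default all zero).
#' @param large_effect optional `list(variant = index, beta = effect)`
#'   emulating an APOE-like major locus.
#' @param epistatic_pairs data frame with columns `i`, `j` (variant
#'   indices) and `gamma`; interaction terms use centered dosages so that
#'   (at symmetric allele frequencies) marginal effects vanish.
#' @param pathway_map integer in `1..n_pathways` per variant; default
#'   contiguous blocks of equal size.
#' @param n_pathways number of latent pathways K (default 5).
#' @param covariate_effects `c(age = ., sex = .)` log-odds per year of age
#'   (centered at 72) and for male sex.
#' @param case_fraction target fraction of AD cases among AD + NC after
#'   case-control sampling.
#' @param mci_fraction fraction of non-case samples labelled MCI (those
#'   with the highest residual liability).
#' @param endophenotype_loadings biomarker x pathway loading matrix
#'   `Lambda`; biomarker `m` is `sum_k Lambda[m, k] * B_k` plus noise.
#' @param noise_sd `list(liability = ., biomarker = .)` Gaussian noise
#'   standard deviations added to the liability and to each biomarker.
#' @param seed master integer seed; all draws derive sub-stream seeds from
#'   it via [split_seed()] so stages are independent of call order.
#' @return a validated list of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 2000,
                     n_variants = 100,
                     maf_range = c(0.05, 0.5),
                     ld_blocks = NULL,
                     additive_effects = NULL,
                     large_effect = NULL,
                     epistatic_pairs = NULL,
                     pathway_map = NULL,
                     n_pathways = 5,
                     covariate_effects = c(age = 0.02, sex = 0.2),
                     case_fraction = 0.5,
                     mci_fraction = 0.1,
                     endophenotype_loadings = NULL,
                     noise_sd = list(liability = 0, biomarker = 0.5),
                     seed = 1) {
  if (is.null(ld_blocks)) {
    ld_blocks <- data.frame(size = rep(1L, n_variants), r = 0)
  }
  if (sum(ld_blocks$size) != n_variants) {
    stop("LD block sizes sum to ", sum(ld_blocks$size),
         ", expected n_variants = ", n_variants)
  }
  if (any(abs(ld_blocks$r) >= 1)) stop("block target r must lie in (-1, 1)")
  if (is.null(additive_effects)) additive_effects <- rep(0, n_variants)
  if (length(additive_effects) != n_variants) {
    stop("additive_effects must have length n_variants")
  }
  if (!is.null(large_effect)) {
    stopifnot(is.list(large_effect),
              large_effect$variant >= 1, large_effect$variant <= n_variants)
  }
  if (!is.null(epistatic_pairs)) {
    if (!all(c("i", "j", "gamma") %in% names(epistatic_pairs))) {
      stop("epistatic_pairs needs columns i, j, gamma")
    }
    if (any(epistatic_pairs$i < 1 | epistatic_pairs$i > n_variants |
            epistatic_pairs$j < 1 | epistatic_pairs$j > n_variants)) {
      stop("epistatic pair indices outside 1..n_variants")
    }
  }
  if (n_pathways < 1) stop("n_pathways must be >= 1")
  if (is.null(pathway_map)) {
    pathway_map <- sort(rep_len(seq_len(n_pathways), n_variants))
  }
  if (length(pathway_map) != n_variants ||
      any(pathway_map < 1 | pathway_map > n_pathways)) {
    stop("pathway_map must map each variant to 1..n_pathways")
  }
  if (!is.null(endophenotype_loadings)) {
    endophenotype_loadings <- as.matrix(endophenotype_loadings)
    if (ncol(endophenotype_loadings) != n_pathways) {
      stop("endophenotype_loadings must have n_pathways columns")
    }
  }
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            case_fraction > 0, case_fraction < 1,
            mci_fraction >= 0, mci_fraction < 1)
  structure(list(n_samples = n_samples, n_variants = n_variants,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 additive_effects = additive_effects,
                 large_effect = large_effect,
                 epistatic_pairs = epistatic_pairs,
                 pathway_map = as.integer(pathway_map),
                 n_pathways = as.integer(n_pathways),
                 covariate_effects = covariate_effects,
                 case_fraction = case_fraction,
                 mci_fraction = mci_fraction,
                 endophenotype_loadings = endophenotype_loadings,
                 noise_sd = noise_sd, seed = seed),
            class = "sim_spec")
}

## Latent (Gaussian) correlation needed so that thresholded haplotypes
## attain a target dosage correlation at a given allele frequency.
## Thresholding attenuates correlation, so the latent value is inflated by
## inverting P11(rho) = P(Z1 > q, Z2 > q) numerically.
latent_rho_for_target <- function(target_r, maf) {
  if (abs(target_r) < 1e-12) return(0)
  q <- qnorm(1 - maf)
  p11 <- function(rho) {
    f <- function(z) dnorm(z) * pnorm((rho * z - q) / sqrt(1 - rho^2))
    integrate(f, q, Inf, rel.tol = 1e-9)$value
  }
  indicator_r <- function(rho) (p11(rho) - maf^2) / (maf * (1 - maf))
  lo <- if (target_r > 0) 0 else -0.999
  hi <- if (target_r > 0) 0.9995 else 0
  ## attainable range check: at |rho| -> 1 indicator r -> +-1-ish bound
  uniroot(function(r) indicator_r(r) - target_r, c(lo, hi),
          tol = 1e-7)$root
}

draw_block_haplotypes <- function(n, size, rho) {
  if (size == 1L || abs(rho) < 1e-12) {
    return(matrix(rnorm(n * size), n, size))
  }
  sigma <- matrix(rho, size, size)
  diag(sigma) <- 1
  L <- chol(sigma)
  matrix(rnorm(n * size), n, size) %*% L
}

#' Simulate genotype dosages with block LD structure
#'
#' Two latent haplotypes per sample are drawn from block-wise
#' equicorrelated Gaussians and thresholded at the allele-frequency
#' quantile; the dosage is the haplotype sum. The latent correlation is
#' calibrated per block so the empirical dosage correlation approximates
#' the block's target `r`; across blocks correlations are ~0.
#'
#' @param spec a [sim_spec()].
#' @param n_samples optional override of `spec$n_samples` (used
#'   internally to oversample before case-control selection).
#' @return a [genotype_matrix()] with block-derived locus labels and
#'   randomly drawn annotation counts.
#' @export
simulate_genotypes <- function(spec, n_samples = spec$n_samples) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(split_seed(spec$seed, 1L))
  blocks <- spec$ld_blocks
  p <- spec$n_variants
  dosage <- matrix(0, n_samples, p)
  mafs <- numeric(p)
  locus <- character(p)
  col <- 1L
  for (b in seq_len(nrow(blocks))) {
    m <- blocks$size[b]
    maf <- runif(1, spec$maf_range[1], spec$maf_range[2])
    rho <- latent_rho_for_target(blocks$r[b], maf)
    q <- qnorm(1 - maf)
    h1 <- draw_block_haplotypes(n_samples, m, rho) > q
    h2 <- draw_block_haplotypes(n_samples, m, rho) > q
    idx <- col:(col + m - 1L)
    dosage[, idx] <- h1 + h2
    mafs[idx] <- maf
    locus[idx] <- sprintf("locus%03d", b)
    col <- col + m
  }
  ids <- sprintf("v%04d", seq_len(p))
  ann <- data.frame(coding = rbinom(p, 1, 0.1),
                    utr = rbinom(p, 1, 0.1),
                    histone = rpois(p, 0.7),
                    open_chromatin = rbinom(p, 1, 0.3),
                    polymerase = rpois(p, 0.3),
                    tfbs = rpois(p, 0.5))
  vt <- variant_table(id = ids, chrom = "1", pos = seq_len(p) * 10000,
                      ea = "A", oa = "G", locus = locus,
                      annotations = ann)
  gm <- genotype_matrix(dosage, vt)
  attr(gm, "maf") <- mafs
  gm
}

#' Simulate disease status, covariates and ground-truth liability
#'
#' The liability is
#' `L = sum_i beta_i g_i + sum_(j,k) gamma_jk (g_j - gbar_j)(g_k - gbar_k)
#'  + beta_age (age - 72) + beta_sex sex + eps`,
#' centered, shifted to the logit of the target case fraction, and disease
#' status drawn from `Bernoulli(plogis(L))`. Among non-cases, the
#' `mci_fraction` with the highest liability are labelled MCI. Per-sample
#' pathway burdens `B_k = sum_(i in pathway k) beta_i g_i` are recorded in
#' the truth table.
#'
#' @param geno a [genotype_matrix()].
#' @param spec a [sim_spec()].
#' @return list with `pheno` (a [phenotype_table()] covering all input
#'   samples), `truth` (per-sample liability, genetic value and pathway
#'   burdens, plus attributes `beta` and `epistatic_pairs`) and `keep`
#'   (row indices realizing the requested case fraction; see
#'   [simulate_cohort()]).
#' @export
simulate_phenotypes <- function(geno, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(split_seed(spec$seed, 2L))
  G <- geno$dosage
  n <- nrow(G)
  p <- ncol(G)
  stopifnot(p == spec$n_variants)

  beta <- spec$additive_effects
  if (!is.null(spec$large_effect)) {
    beta[spec$large_effect$variant] <- beta[spec$large_effect$variant] +
      spec$large_effect$beta
  }
  genetic <- as.vector(G %*% beta)
  epi <- numeric(n)
  if (!is.null(spec$epistatic_pairs)) {
    gc <- sweep(G, 2, colMeans(G))
    for (r in seq_len(nrow(spec$epistatic_pairs))) {
      pr <- spec$epistatic_pairs[r, ]
      epi <- epi + pr$gamma * gc[, pr$i] * gc[, pr$j]
    }
  }
  age <- runif(n, 55, 90)
  sex <- rbinom(n, 1, 0.5)
  pcs <- matrix(rnorm(n * 5), n, 5)
  covar <- spec$covariate_effects[["age"]] * (age - 72) +
    spec$covariate_effects[["sex"]] * sex
  eps <- if (spec$noise_sd$liability > 0)
    rnorm(n, 0, spec$noise_sd$liability) else 0
  L <- genetic + epi + covar + eps
  Lc <- L - mean(L) + qlogis(spec$case_fraction)
  case <- rbinom(n, 1, plogis(Lc)) == 1L

  status <- ifelse(case, "AD", "NC")
  nonc <- which(!case)
  n_mci <- round(spec$mci_fraction * length(nonc))
  if (n_mci > 0) {
    ## MCI as a noisy intermediate state: liability-weighted draw among
    ## non-cases (a deterministic top slice would strip every
    ## high-liability control from the NC pool)
    mci_idx <- sample(nonc, n_mci, prob = plogis(Lc[nonc]))
    status[mci_idx] <- "MCI"
  }

  burdens <- sapply(seq_len(spec$n_pathways), function(k) {
    in_k <- spec$pathway_map == k
    if (!any(in_k)) return(numeric(n))
    as.vector(G[, in_k, drop = FALSE] %*% beta[in_k])
  })
  colnames(burdens) <- paste0("B", seq_len(spec$n_pathways))

  pheno <- data.frame(sample_id = rownames(G), status = status,
                      age = age, sex = sex, pcs,
                      stringsAsFactors = FALSE)
  names(pheno)[5:9] <- paste0("pc", 1:5)
  pheno <- phenotype_table(pheno)
  truth <- data.frame(sample_id = rownames(G), liability = Lc,
                      genetic = genetic, epistatic = epi, burdens,
                      stringsAsFactors = FALSE)
  attr(truth, "beta") <- beta
  attr(truth, "epistatic_pairs") <- spec$epistatic_pairs

  keep <- case_control_keep(status, spec$case_fraction, spec$n_samples)
  list(pheno = pheno, truth = truth, keep = keep)
}

## Indices realizing a target AD fraction among AD + NC while keeping all
## MCI samples. When the target is nearly reachable (>= 80% of the
## requested cohort size at the exact fraction) the largest achievable
## cohort is returned; below that the request is treated as unreachable
## from the simulated prevalence and an error reports the bound.
case_control_keep <- function(status, case_fraction, n_target) {
  ad <- which(status == "AD")
  nc <- which(status == "NC")
  mci <- which(status == "MCI")
  n_bin <- max(0, n_target - length(mci))
  want_ad <- round(n_bin * case_fraction)
  want_nc <- n_bin - want_ad
  if (length(ad) < want_ad || length(nc) < want_nc) {
    n_max <- floor(min(length(ad) / case_fraction,
                       length(nc) / (1 - case_fraction)))
    achievable <- n_max + length(mci)
    if (achievable < 0.8 * n_target) {
      stop("requested case fraction ", case_fraction,
           " unreachable at n = ", n_target,
           "; at most ", achievable,
           " samples are available at that fraction")
    }
    want_ad <- round(n_max * case_fraction)
    want_nc <- n_max - want_ad
  }
  sort(c(sample(ad, want_ad), sample(nc, want_nc), mci))
}

#' Simulate endophenotype columns from pathway burdens
#'
#' Each biomarker is a linear combination of the latent pathway burdens,
#' `biomarker_m = sum_k Lambda[m, k] B_k + noise`, emulating plasma
#' biomarkers that report on specific disease pathways.
#'
#' @param truth truth table from [simulate_phenotypes()].
#' @param spec a [sim_spec()] with `endophenotype_loadings` set.
#' @return data frame of biomarker columns aligned to the truth rows.
#' @export
simulate_endophenotypes <- function(truth, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  lam <- spec$endophenotype_loadings
  if (is.null(lam)) stop("spec has no endophenotype_loadings")
  if (ncol(lam) != spec$n_pathways) {
    stop("loading matrix has ", ncol(lam), " columns, expected K = ",
         spec$n_pathways)
  }
  set.seed(split_seed(spec$seed, 3L))
  B <- as.matrix(truth[, paste0("B", seq_len(spec$n_pathways)),
                       drop = FALSE])
  n <- nrow(B)
  vals <- B %*% t(lam)
  if (spec$noise_sd$biomarker > 0) {
    vals <- vals + matrix(rnorm(n * nrow(lam), 0, spec$noise_sd$biomarker),
                          n, nrow(lam))
  }
  nm <- rownames(lam) %||% paste0("bm", seq_len(nrow(lam)))
  colnames(vals) <- nm
  as.data.frame(vals)
}

#' Simulate a complete cohort
#'
#' Oversamples genotypes, draws phenotypes, performs case-control
#' selection to the requested case fraction, and (when loadings are
#' specified) attaches endophenotypes to the phenotype table.
#'
#' @param spec a [sim_spec()].
#' @param oversample multiple of `n_samples` to draw before case-control
#'   selection (default 2).
#' @return list of class `sim_cohort` with `genotypes`, `phenotypes`,
#'   `truth` and the generating `spec`.
#' @export
simulate_cohort <- function(spec, oversample = 2) {
  geno <- simulate_genotypes(spec, n_samples = ceiling(spec$n_samples *
                                                         oversample))
  ph <- simulate_phenotypes(geno, spec)
  keep <- ph$keep
  geno <- subset_genotypes(geno, samples = keep)
  pheno <- ph$pheno[keep, , drop = FALSE]
  truth <- ph$truth[keep, , drop = FALSE]
  attr(truth, "beta") <- attr(ph$truth, "beta")
  attr(truth, "epistatic_pairs") <- attr(ph$truth, "epistatic_pairs")
  rownames(pheno) <- rownames(truth) <- NULL
  if (!is.null(spec$endophenotype_loadings)) {
    endo <- simulate_endophenotypes(truth, spec)
    pheno <- phenotype_table(cbind(as.data.frame(pheno), endo))
  }
  structure(list(genotypes = geno, phenotypes = pheno, truth = truth,
                 spec = spec),
            class = "sim_cohort")
}
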
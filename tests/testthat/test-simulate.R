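test_that("spec validation catches inconsistent inputs", {
  expect_error(sim_spec(n_variants = 10,
                        ld_blocks = data.frame(size = 4, r = 0)),
               "sum to")
  expect_error(sim_spec(n_variants = 4, additive_effects = c(1, 2)),
               "length")
  expect_error(sim_spec(n_variants = 4,
                        epistatic_pairs = data.frame(i = 1, j = 9,
                                                     gamma = 1)),
               "outside")
  expect_error(sim_spec(n_variants = 4, n_pathways = 2,
                        endophenotype_loadings = matrix(1, 1, 3)),
               "columns")
})

test_that("same seed reproduces the cohort bit-identically, new seed varies", {
  spec <- sim_spec(n_samples = 120, n_variants = 12, seed = 5)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_identical(c1$phenotypes, c2$phenotypes)
  c3 <- simulate_cohort(sim_spec(n_samples = 120, n_variants = 12,
                                 seed = 6))
  expect_false(identical(c1$genotypes$dosage, c3$genotypes$dosage))
})

test_that("empirical allele frequencies match the spec range", {
  spec <- sim_spec(n_samples = 20000, n_variants = 5,
                   maf_range = c(0.3, 0.300001), seed = 2)
  g <- simulate_genotypes(spec)
  expect_true(all(abs(colMeans(g$dosage) / 2 - 0.3) < 0.01))
})

test_that("LD blocks hit their correlation targets", {
  ## independent blocks stay uncorrelated
  spec0 <- sim_spec(n_samples = 10000, n_variants = 4,
                    ld_blocks = data.frame(size = c(2, 2), r = c(0, 0)),
                    seed = 3)
  g0 <- simulate_genotypes(spec0)
  expect_lt(abs(cor(g0$dosage)[1, 2]), 0.05)
  ## strong within-block correlation approximates the calibrated target
  spec8 <- sim_spec(n_samples = 10000, n_variants = 4,
                    ld_blocks = data.frame(size = c(2, 2), r = c(0.8, 0.8)),
                    maf_range = c(0.2, 0.4), seed = 3)
  g8 <- simulate_genotypes(spec8)
  r12 <- cor(g8$dosage)[1, 2]
  expect_gt(r12, 0.7)
  expect_lt(r12, 0.9)
  ## across blocks ~ 0
  expect_lt(abs(cor(g8$dosage)[1, 3]), 0.05)
})

test_that("null architecture gives chance-level discrimination", {
  spec <- sim_spec(n_samples = 10000, n_variants = 5,
                   covariate_effects = c(age = 0, sex = 0),
                   mci_fraction = 0, seed = 7)
  co <- simulate_cohort(spec)
  y <- as.integer(co$phenotypes$status == "AD")
  score <- rowSums(co$genotypes$dosage)
  expect_lt(abs(auroc(score, y) - 0.5), 0.02)
})

test_that("case fraction lands within two points of the request", {
  for (f in c(0.3, 0.5)) {
    spec <- sim_spec(n_samples = 1500, n_variants = 5, case_fraction = f,
                     mci_fraction = 0.1, seed = 11)
    co <- simulate_cohort(spec)
    st <- co$phenotypes$status
    expect_lt(abs(mean(st[st != "MCI"] == "AD") - f), 0.02)
    expect_equal(nrow(co$phenotypes), 1500)
  }
})

test_that("unreachable case fractions error with an achievable bound", {
  ## heavy liability noise regresses the realized prevalence toward 0.5,
  ## so an extreme requested case fraction cannot be realized
  spec <- sim_spec(n_samples = 400, n_variants = 2, case_fraction = 0.95,
                   noise_sd = list(liability = 8, biomarker = 0.5),
                   seed = 1)
  geno <- simulate_genotypes(spec, n_samples = 400)
  expect_error(simulate_phenotypes(geno, spec), "unreachable")
})

test_that("marginal GWAS recovers a single additive effect", {
  out <- gwas_beta_recovery(n = 8000, beta_true = log(3), seed = 2)
  expect_lt(abs(out$beta_hat - log(3)), 0.15)
})

test_that("pure epistatic pairs leave no marginal signal", {
  hits <- 0L
  for (sd in 1:10) {
    spec <- sim_spec(n_samples = 3000, n_variants = 2,
                     maf_range = c(0.45, 0.5),
                     epistatic_pairs = data.frame(i = 1, j = 2, gamma = 2),
                     covariate_effects = c(age = 0, sex = 0),
                     mci_fraction = 0, seed = 100 + sd)
    co <- simulate_cohort(spec)
    gw <- logistic_assoc(co$genotypes, co$phenotypes,
                         covariates = character(0))
    hits <- hits + sum(gw$p > 0.05, na.rm = TRUE)
  }
  ## 20 marginal tests across 10 replicates; most should look null
  expect_gte(hits, 16L)
})

test_that("additive genetic variance matches its analytic value", {
  beta <- c(0.5, -0.3, 0.4, 0, 0)
  spec <- sim_spec(n_samples = 20000, n_variants = 5,
                   maf_range = c(0.3, 0.300001), additive_effects = beta,
                   covariate_effects = c(age = 0, sex = 0),
                   noise_sd = list(liability = 1, biomarker = 0.5),
                   seed = 13)
  geno <- simulate_genotypes(spec)
  ph <- simulate_phenotypes(geno, spec)
  ## independent variants: var = sum beta^2 * 2 maf (1 - maf)
  v_analytic <- sum(beta^2 * 2 * 0.3 * 0.7)
  v_emp <- var(ph$truth$genetic)
  expect_lt(abs(v_emp - v_analytic) / v_analytic, 0.1)
})

test_that("case-control sampling preserves the large-effect EAF direction", {
  spec <- sim_spec(n_samples = 2000, n_variants = 5,
                   large_effect = list(variant = 1, beta = 1.2),
                   mci_fraction = 0, seed = 17)
  co <- simulate_cohort(spec)
  ad <- co$phenotypes$status == "AD"
  eaf_ad <- mean(co$genotypes$dosage[ad, 1]) / 2
  eaf_nc <- mean(co$genotypes$dosage[!ad, 1]) / 2
  expect_gt(eaf_ad, eaf_nc)
})

test_that("endophenotypes follow their pathway loadings", {
  lam <- rbind(bm1 = c(1, 0, 0, 0, 0), bm2 = c(1, 0, 0, 0, 0),
               bm_null = c(0, 0, 0, 0, 0))
  spec <- sim_spec(n_samples = 2000, n_variants = 50,
                   additive_effects = rep(0.3, 50),
                   covariate_effects = c(age = 0, sex = 0),
                   endophenotype_loadings = lam,
                   noise_sd = list(liability = 0, biomarker = 0),
                   mci_fraction = 0, seed = 19)
  co <- simulate_cohort(spec)
  ph <- co$phenotypes
  ## zero noise, equal loadings: duplicate biomarkers are identical
  expect_equal(ph$bm1, ph$bm2)
  ## loading-1 biomarker tracks pathway 1 exactly at zero noise
  expect_equal(cor(ph$bm1, co$truth$B1), 1)
  ## and still strongly at noise 0.5 * sd(B1)
  spec2 <- sim_spec(n_samples = 2000, n_variants = 50,
                    additive_effects = rep(0.3, 50),
                    covariate_effects = c(age = 0, sex = 0),
                    endophenotype_loadings = lam,
                    noise_sd = list(liability = 0,
                                    biomarker = 0.5 * sd(co$truth$B1)),
                    mci_fraction = 0, seed = 19)
  co2 <- simulate_cohort(spec2)
  rho <- cor(rank(co2$phenotypes$bm1), rank(co2$truth$B1))
  expect_gte(rho, 0.5)
  ## zero loadings: biomarker carries no status signal
  y <- as.integer(co2$phenotypes$status == "AD")
  expect_lt(abs(auroc(co2$phenotypes$bm_null, y) - 0.5), 0.05)
})
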
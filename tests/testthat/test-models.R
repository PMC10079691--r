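test_that("weighted PRS equals a brute-force loop exactly", {
  g <- toy_geno(matrix(c(0, 1, 2, 2, 0, 1), 2, 3))
  w <- setNames(c(0.5, -0.2, 1.0), g$variants$id)
  expect_identical(unname(weighted_prs(g, w)),
                   wprs_bruteforce(g$dosage, w))
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:20, 1); p <- sample(1:10, 1)
    g <- toy_geno(matrix(round(runif(n * p, 0, 2), 3), n, p))
    w <- setNames(rnorm(p), g$variants$id)
    expect_equal(unname(weighted_prs(g, w)),
                 wprs_bruteforce(g$dosage, w), tolerance = 1e-12)
  }
})

test_that("weighted PRS documented examples hold", {
  g <- toy_geno(matrix(c(0, 1, 2), 1, 3))
  expect_equal(unname(weighted_prs(g, setNames(c(0.5, -0.2, 1.0),
                                               g$variants$id))), 1.8)
  g0 <- toy_geno(matrix(0, 2, 3))
  expect_equal(unname(weighted_prs(g0, setNames(rep(1, 3),
                                                g0$variants$id))),
               c(0, 0))
  ## a single large-effect (APOE-like) variant, two copies
  apoe <- genotype_matrix(matrix(2, 1, 1),
                          variant_table("rs429358", chrom = "19",
                                        pos = 44908684, ea = "C", oa = "T"))
  expect_equal(unname(weighted_prs(apoe, c(rs429358 = 1.182))), 2.364)
})

test_that("weighted PRS is linear and order-invariant", {
  set.seed(22)
  g <- toy_geno(matrix(runif(40, 0, 2), 8, 5))
  w1 <- setNames(rnorm(5), g$variants$id)
  w2 <- setNames(rnorm(5), g$variants$id)
  expect_equal(weighted_prs(g, w1 + w2),
               weighted_prs(g, w1) + weighted_prs(g, w2))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(weighted_prs(g, w1[perm]), weighted_prs(g, w1))
  expect_error(weighted_prs(g, c(nope = 1)), "lack")
})

make_binary_cohort <- function(n = 400, p = 10, beta = NULL, seed = 1) {
  set.seed(seed)
  D <- matrix(rbinom(n * p, 2, 0.3), n, p)
  eta <- if (is.null(beta)) rep(0, n) else drop(D %*% beta)
  y <- rbinom(n, 1, plogis(eta - mean(eta)))
  g <- toy_geno(D)
  ph <- phenotype_table(data.frame(
    sample_id = rownames(g$dosage),
    status = ifelse(y == 1, "AD", "NC"),
    age = runif(n, 55, 90), sex = rbinom(n, 1, 0.5),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n),
    pc5 = rnorm(n)))
  list(geno = g, pheno = ph, y = y)
}

test_that("lasso at the large-lambda end is the intercept-only model", {
  co <- make_binary_cohort(seed = 31)
  fit <- fit_lasso(co$geno, co$pheno, covariates = character(0), seed = 1)
  path <- fit$glmnet_fit
  ## first grid point: all variant coefficients zero, intercept = logit(mean)
  expect_true(all(abs(path$beta[, 1]) == 0))
  expect_equal(path$a0[[1]], qlogis(mean(co$y)), tolerance = 1e-6)
})

test_that("nearly unpenalized lasso matches plain logistic regression", {
  co <- make_binary_cohort(n = 300, p = 4, beta = c(.5, -.5, 0, .3),
                           seed = 32)
  glm_fit <- glm(co$y ~ impute_dosage_means(co$geno$dosage),
                 family = binomial())
  gl <- glmnet::glmnet(co$geno$dosage, co$y, family = "binomial",
                       alpha = 1, lambda = c(0.1, 0), thresh = 1e-12)
  expect_equal(as.numeric(coef(gl, s = 0))[-1],
               unname(coef(glm_fit))[-1], tolerance = 1e-4)
})

test_that("lambda_chosen retains the most variants and is seed-stable", {
  co <- make_binary_cohort(n = 500, p = 20,
                           beta = c(rep(0.4, 5), rep(0, 15)), seed = 33)
  fit <- fit_lasso(co$geno, co$pheno, covariates = character(0), seed = 5)
  expect_equal(fit$lambda_chosen, min(fit$cv_path$lambda))
  expect_equal(fit$n_nonzero,
               max(fit$cv_path$n_nonzero))
  fit2 <- fit_lasso(co$geno, co$pheno, covariates = character(0), seed = 5)
  expect_identical(fit$coef, fit2$coef)
  ## covariates stay unpenalized in the default mode
  fit3 <- fit_lasso(co$geno, co$pheno, seed = 5)
  expect_equal(names(fit3$covariate_coef),
               c("age", "sex", paste0("pc", 1:5)))
  ## offset mode regresses covariates out first
  fit4 <- fit_lasso(co$geno, co$pheno, covariate_mode = "offset", seed = 5)
  expect_equal(fit4$mode, "offset")
  expect_type(predict_lasso(fit4, co$geno), "double")
})

test_that("lasso rejects degenerate inputs", {
  co <- make_binary_cohort(seed = 34)
  gconst <- genotype_matrix(matrix(1, 50, 2), toy_variants(2))
  ph <- co$pheno[1:50, ]
  ph$sample_id <- rownames(gconst$dosage)
  expect_error(fit_lasso(gconst, phenotype_table(ph),
                         covariates = character(0)), "constant")
})

test_that("stock architectures have the documented shapes", {
  eu <- build_nn("european", n_features = 200, n_loci = 77, init_seed = 1)
  widths <- vapply(eu$layers,
                   function(l) if (l$type == "dense") ncol(l$W) else NA_real_,
                   numeric(1))
  expect_equal(widths[!is.na(widths)], c(231, 77, 22, 5, 1))
  expect_equal(vapply(eu$layers, `[[`, "", "type")[c(1, 3)],
               c("dropout", "dropout"))
  ch <- build_nn("chinese", n_features = 37, init_seed = 1)
  widths <- vapply(ch$layers,
                   function(l) if (l$type == "dense") ncol(l$W) else NA_real_,
                   numeric(1))
  expect_equal(widths[!is.na(widths)], c(50, 30, 10, 5, 1))
  expect_equal(vapply(ch$layers, `[[`, "", "type")[c(2, 4)],
               c("dropout", "dropout"))
  expect_error(build_nn("european", n_features = 10, n_loci = 0), "n_loci")
  ## identical seeds give identical initial weights
  ch2 <- build_nn("chinese", n_features = 37, init_seed = 1)
  expect_identical(ch$layers, ch2$layers)
})

test_that("staircase learning-rate schedule follows the closed form", {
  cfg <- train_config(lr0 = 0.5, decay_steps = 100000, decay_rate = 0.96)
  expect_equal(lr_at_step(cfg, 0), 0.5)
  expect_equal(lr_at_step(cfg, 99999), 0.5)
  expect_equal(lr_at_step(cfg, 100000), 0.5 * 0.96)
  expect_equal(lr_at_step(cfg, 200000), 0.5 * 0.96^2)
  cfg2 <- train_config(lr0 = 0.5, staircase = FALSE)
  expect_equal(lr_at_step(cfg2, 50000), 0.5 * 0.96^0.5)
})

test_that("zero-weight networks score 0.5 everywhere", {
  m <- build_nn("chinese", n_features = 4, init_seed = 1)
  m$layers <- lapply(m$layers, function(l) {
    if (l$type == "dense") { l$W[] <- 0; l$b[] <- 0 }
    l
  })
  X <- matrix(runif(20, 0, 2), 5, 4)
  expect_equal(nn_score(m, X), rep(0.5, 5))
  pen <- penultimate_outputs(m, X)
  expect_equal(dim(pen), c(5, 5))
  expect_true(all(pen == 0.5))
})

test_that("scoring is deterministic and a monotone net is monotone", {
  m <- build_nn("chinese", n_features = 3, init_seed = 7)
  X <- matrix(runif(30, 0, 2), 10, 3)
  expect_identical(nn_score(m, X), nn_score(m, X))
  ## single-path positive-weight network: score increases with dosage
  mono <- structure(list(layers = list(
    list(type = "dense", W = matrix(1, 1, 1), b = 0),
    list(type = "dense", W = matrix(2, 1, 1), b = -1)),
    kind = "chinese", n_features = 1, init_seed = 1, trained = TRUE),
    class = "nn_model")
  xs <- matrix(seq(0, 2, length.out = 9), ncol = 1)
  expect_true(all(diff(nn_score(mono, xs)) > 0))
})

test_that("analytic gradients match central finite differences", {
  set.seed(41)
  m <- build_nn("chinese", n_features = 3, init_seed = 3)
  X <- matrix(runif(15, 0, 2), 5, 3)
  y <- c(1, 0, 1, 0, 1)
  fwd <- nn_forward_full <- prsnet:::nn_forward_full
  f <- nn_forward_full(m, X)
  grads <- prsnet:::nn_gradients(m, f, y)
  loss_at <- function(model) prsnet:::bce_loss(nn_forward_full(model, X)$out, y)
  eps <- 1e-6
  for (li in seq_along(m$layers)) {
    if (m$layers[[li]]$type != "dense") next
    for (probe in 1:4) {
      i <- sample(nrow(m$layers[[li]]$W), 1)
      j <- sample(ncol(m$layers[[li]]$W), 1)
      mp <- mm <- m
      mp$layers[[li]]$W[i, j] <- mp$layers[[li]]$W[i, j] + eps
      mm$layers[[li]]$W[i, j] <- mm$layers[[li]]$W[i, j] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[li]]$W[i, j], num, tolerance = 1e-5)
    }
  }
})

test_that("training is seed-deterministic and early stopping restores best", {
  set.seed(42)
  X <- matrix(runif(200, 0, 2), 50, 4)
  y <- as.integer(X[, 1] + X[, 2] > 2)
  m <- build_nn("chinese", n_features = 4, init_seed = 1)
  cfg <- train_config(epochs = 30, batch_size = 16, lr0 = 0.5, seed = 9)
  t1 <- train_nn(m, X, y, cfg)
  t2 <- train_nn(m, X, y, cfg)
  expect_identical(t1$layers, t2$layers)
  expect_identical(t1$history, t2$history)

  ## plateaued loss: training ends within patience epochs of the best
  cfgp <- train_config(epochs = 500, batch_size = 16, lr0 = 1e-6,
                       patience = 10, seed = 9)
  tp <- train_nn(m, X, y, cfgp)
  expect_lte(nrow(tp$history), tp$best_epoch + 10)
})

test_that("a trained dense(1)-equivalent net approaches logistic regression", {
  set.seed(43)
  n <- 800
  X <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  eta <- drop(X %*% c(1.2, -1, 0.8))
  y <- rbinom(n, 1, plogis(eta - mean(eta)))
  glm_auc <- auroc(glm.fit(cbind(1, X), y,
                           family = binomial())$linear.predictors, y)
  single <- structure(list(layers = list(
    list(type = "dense", W = matrix(0, 3, 1), b = 0)),
    kind = "chinese", n_features = 3, init_seed = 1, trained = FALSE),
    class = "nn_model")
  cfg <- train_config(epochs = 250, batch_size = 64, lr0 = 0.5,
                      validation_fraction = 0, seed = 2)
  tr <- train_nn(single, X, y, cfg, validation = list(X = X, y = y))
  expect_lt(abs(auroc(nn_score(tr, X), y) - glm_auc), 0.02)
})

test_that("model bundles round-trip through the text format", {
  m <- build_nn("chinese", n_features = 6, init_seed = 11)
  f <- file.path(tempdir(), "model.txt")
  write_nn_model(m, f)
  m2 <- read_nn_model(f)
  expect_equal(m2$layers, m$layers)
  X <- matrix(runif(30, 0, 2), 5, 6)
  expect_identical(nn_score(m, X), nn_score(m2, X))
})
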
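test_that("rank-inverse-normal matches the Blom closed form", {
  z <- rank_inverse_normal(c(10, 20, 30))
  expect_equal(z, qnorm((1:3 - 3 / 8) / 3.25), tolerance = 1e-12)
  expect_equal(z[2], 0)
  expect_equal(round(z[3], 4), 0.8694, tolerance = 1e-4)
  ## ties share the average-rank z
  zt <- rank_inverse_normal(c(1, 5, 5, 9))
  expect_equal(zt[2], zt[3])
  expect_error(rank_inverse_normal(rep(2, 5)), "identical")
})

test_that("rank-inverse-normal is invariant under monotone transforms", {
  set.seed(61)
  x <- rexp(50)
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(log(x)))
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(x^3))
  expect_lt(abs(mean(rank_inverse_normal(x))), 1e-10)
})

test_that("robust fit matches least squares on clean data", {
  set.seed(62)
  n <- 1000
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.2)
  rf <- robust_linear_fit(y, X)
  ls <- coef(lm(y ~ X))
  expect_equal(unname(rf$coefficients), unname(ls), tolerance = 5e-3)
  expect_true(all(rf$weights >= 0 & rf$weights <= 1))
  expect_true(rf$converged)
})

test_that("robust fit resists gross outliers better than least squares", {
  set.seed(63)
  wins <- 0L
  for (rep in 1:60) {
    n <- 100
    x <- rnorm(n)
    y <- 2 * x + rnorm(n, 0, 0.5)
    y[1] <- 100                      # one gross outlier
    rf <- robust_linear_fit(y, cbind(x = x))
    ls <- coef(lm(y ~ x))[2]
    if (abs(rf$coefficients["x"] - 2) < abs(ls - 2)) wins <- wins + 1L
  }
  expect_gte(wins, 57L)             # >= 95% of replicates
})

test_that("robust fit rejects rank-deficient designs naming the column", {
  set.seed(64)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, c = X[, "a"])
  expect_error(robust_linear_fit(rnorm(30), X), "c")
  expect_error(endophenotype_assoc(rep(1, 30), rnorm(30)), "predictor")
})

test_that("endophenotype association finds a built-in signal", {
  set.seed(65)
  n <- 500
  burden <- rnorm(n)
  biomarker <- 0.8 * burden + rnorm(n, 0, 0.5)
  covs <- cbind(age = runif(n, 55, 90), sex = rbinom(n, 1, 0.5))
  fit <- endophenotype_assoc(burden, biomarker, covs)
  expect_lt(fit$p["predictor"], 1e-10)
  fit_icv <- endophenotype_assoc(burden, biomarker, covs,
                                 icv = rnorm(n, 1500, 100), bh = TRUE)
  expect_true("icv" %in% names(fit_icv$coefficients))
  expect_true(all(fit_icv$p_bh >= fit_icv$p))
})

test_that("joint module association ranks the driving module highest", {
  set.seed(66)
  n <- 600
  M <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("M", 1:5)))
  y <- M[, 2] + rnorm(n, 0, 0.8)
  ts <- multivariate_module_assoc(M, y)
  expect_equal(names(which.max(abs(ts))), "M2")
  expect_error(multivariate_module_assoc(cbind(M, M6 = M[, 1]), y),
               "collinear")
})

test_that("null joint module |t| stays small", {
  set.seed(67)
  big_t <- 0L
  for (rep in 1:40) {
    M <- matrix(rnorm(1000 * 5), 1000, 5,
                dimnames = list(NULL, paste0("M", 1:5)))
    ts <- multivariate_module_assoc(M, rnorm(1000))
    if (max(abs(ts)) >= 3) big_t <- big_t + 1L
  }
  expect_lte(big_t, 4L)             # max |t| < 3 in >= 90%
})

test_that("elbow selection picks the generative cluster count", {
  set.seed(68)
  blobs <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
                 matrix(rnorm(60, 5, 0.2), ncol = 2))
  cl <- kmeans_cluster(blobs, k_candidates = 1:6, seed = 2)
  expect_equal(cl$k, 2L)
  expect_true(all(diff(cl$wss) <= 1e-8))   # WSS non-increasing in k
  ## identical points: zero WSS everywhere, tie-break to smallest k
  same <- matrix(1, 10, 2)
  expect_equal(kmeans_cluster(same, 1:4, seed = 1)$k, 1L)
  ## determinism
  cl2 <- kmeans_cluster(blobs, k_candidates = 1:6, seed = 2)
  expect_identical(cl$assignments, cl2$assignments)
  expect_error(kmeans_cluster(blobs, k_candidates = 100), "rows")
})

test_that("elbow choice is stable across seeds on separated data", {
  set.seed(69)
  ## equilateral centers: merging any two clusters leaves a large WSS at
  ## k = 2, so the second-difference elbow lands unambiguously at k = 3
  blobs <- rbind(sweep(matrix(rnorm(80, 0, 0.2), ncol = 2), 2,
                       c(0, 0), "+"),
                 sweep(matrix(rnorm(80, 0, 0.2), ncol = 2), 2,
                       c(6, 0), "+"),
                 sweep(matrix(rnorm(80, 0, 0.2), ncol = 2), 2,
                       c(3, 5.196), "+"))
  ks <- vapply(1:10, function(s)
    kmeans_cluster(blobs, 1:6, seed = s)$k, integer(1))
  expect_true(all(ks == 3L))
})

test_that("partial Spearman matches the residualize-then-correlate oracle", {
  set.seed(70)
  for (rep in 1:5) {
    n <- sample(60:200, 1)
    p <- sample(2:8, 1)
    D <- matrix(rnorm(n * p), n, p)
    score <- D %*% rnorm(p) + rnorm(n)
    got <- spearman_partial_correlation(score, D)
    expect_equal(got$rho, pcor_bruteforce(score, D), tolerance = 1e-6)
  }
})

test_that("partial Spearman reduces, saturates and nulls as expected", {
  set.seed(71)
  ## two variables only: ordinary Spearman
  x <- rnorm(100)
  s <- x + rnorm(100)
  got <- spearman_partial_correlation(s, cbind(v1 = x))
  expect_equal(got$rho, cor(rank(s), rank(x)), tolerance = 1e-12)
  ## exact sum of orthogonal parts: near-perfect partial correlation
  g1 <- rnorm(3000); g2 <- rnorm(3000)
  pc <- spearman_partial_correlation(g1 + g2, cbind(g1, g2))
  expect_gt(min(pc$rho), 0.95)
  ## independent null variant
  null <- spearman_partial_correlation(rnorm(5000),
                                       cbind(a = rnorm(5000),
                                             b = rnorm(5000)))
  expect_lt(max(abs(null$rho)), 0.05)
  ## duplicated columns are singular
  expect_error(spearman_partial_correlation(s, cbind(x, x)), "singular")
})

test_that("cell-type specificity applies both thresholds", {
  expr <- expression_matrix(rbind(
    g_b = c(B = 10, T = 1, NK = 1),
    g_low = c(B = 4, T = 1, NK = 1),
    g_flat = c(B = 10, T = 8, NK = 1),
    g_t = c(B = 2, T = 9, NK = 7),
    g_edge = c(B = 2, T = 9, NK = 6)))
  lab <- cell_type_specific_genes(expr)
  expect_equal(unname(lab["g_b"]), "B")
  expect_true(is.na(lab["g_low"]))     # below expression threshold
  expect_true(is.na(lab["g_flat"]))    # ratio 1.25 < 1.5
  expect_true(is.na(lab["g_t"]))       # 9 vs 7 misses the 1.5x fold
  expect_equal(unname(lab["g_edge"]), "T")  # 9 vs 6 meets 1.5x exactly
})

test_that("enrichment p equals exhaustive hypergeometric enumeration", {
  bg <- paste0("g", 1:60)
  set.seed(72)
  for (rep in 1:20) {
    K <- sample(5:20, 1); nc <- sample(5:20, 1)
    set <- sample(bg, K)
    cluster <- sample(bg, nc)
    m <- length(intersect(cluster, set))
    res <- enrichment_test(cluster, list(ct = set), bg)
    expect_equal(res$p, hyper_tail_bruteforce(m, K, 60, nc),
                 tolerance = 1e-12)
    expect_equal(res$overlap, m)
  }
  ## cluster identical to the set gives the minimal possible p
  res <- enrichment_test(bg[1:10], list(hit = bg[1:10], other = bg[41:50]),
                         bg)
  expect_lt(res$p[res$cell_type == "hit"], res$p[res$cell_type == "other"])
  expect_error(enrichment_test("g1", list(a = "g1"), character(0)),
               "background")
})

test_that("group comparison reduces to t-test for two groups", {
  set.seed(73)
  v <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  out <- group_mean_comparison(v, g)
  ## two groups: F = t^2 (pooled-variance t)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_true(all(out$pairwise$p_bonferroni >= out$pairwise$p_raw))
  ## singleton group dropped
  expect_warning(out3 <- group_mean_comparison(c(v, 5), c(g, "c")),
                 "singleton")
  expect_setequal(out3$groups_used, c("a", "b"))
})
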
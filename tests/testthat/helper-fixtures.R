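## Small in-code fixtures shared across tests.

toy_variants <- function(n = 3, ea = "A", oa = "G") {
  variant_table(id = paste0("rs", seq_len(n)), chrom = "1",
                pos = seq_len(n) * 1000, ea = ea, oa = oa)
}

toy_geno <- function(dosage = NULL, n = 3, p = 3, ea = "A", oa = "G",
                     seed = 1) {
  if (is.null(dosage)) {
    set.seed(seed)
    dosage <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  }
  genotype_matrix(dosage, toy_variants(ncol(dosage), ea = ea, oa = oa))
}

toy_stats <- function(beta, se = rep(0.1, length(beta)),
                      p = rep(0.01, length(beta)),
                      ids = paste0("rs", seq_along(beta)),
                      ea = "A", oa = "G",
                      chrom = "1", pos = seq_along(beta) * 1000) {
  summary_stats(data.frame(id = ids, chrom = chrom, pos = pos,
                           ea = ea, oa = oa, beta = beta, se = se, p = p,
                           eaf = 0.3, n = 1000))
}

## brute-force auROC: explicit loop over all case-control pairs
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## brute-force weighted PRS: explicit per-sample loop
wprs_bruteforce <- function(dosage, weights) {
  out <- numeric(nrow(dosage))
  for (s in seq_len(nrow(dosage))) {
    acc <- 0
    for (j in seq_along(weights)) acc <- acc + dosage[s, j] * weights[j]
    out[s] <- acc
  }
  out
}

## exhaustive hypergeometric upper tail by enumerating the mass function
hyper_tail_bruteforce <- function(m, K, N, n) {
  ks <- 0:min(K, n)
  mass <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(mass[ks >= m])
}

## residualize-then-correlate partial Spearman oracle
pcor_bruteforce <- function(score, dosages) {
  R <- apply(cbind(score, dosages), 2, rank)
  p <- ncol(dosages)
  sapply(seq_len(p), function(i) {
    ctrl <- R[, -c(1, i + 1), drop = FALSE]
    r1 <- lm.fit(cbind(1, ctrl), R[, 1])$residuals
    r2 <- lm.fit(cbind(1, ctrl), R[, i + 1])$residuals
    cor(r1, r2)
  })
}
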
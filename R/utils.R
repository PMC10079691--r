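## Internal helpers shared across modules.

#' Derive a sub-stream seed from a master seed
#'
#' All stochastic routines in the package consume a single integer seed and
#' derive independent sub-stream seeds deterministically, so that the draws
#' of one stage do not depend on whether another stage ran first. The
#' derived seed always lies in \[0, 2^31 - 1).
#'
#' @param seed master integer seed.
#' @param stream small integer identifying the consumer stream.
#' @return an integer seed.
#' @export
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(seed) %% 2147483647) * 48271 + stream * 110351
  as.integer(s %% 2147483647)
}

sigmoid <- function(x) {
  ## numerically stable logistic
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean-impute missing dosages per variant
#'
#' Missing genotypes are kept explicit at read time and only imputed to the
#' per-variant mean dosage immediately before model fitting or scoring, so
#' that file round trips stay lossless.
#'
#' @param dosage numeric matrix (samples x variants), may contain `NA`.
#' @return matrix with `NA` replaced by column means (0 when a column is
#'   entirely missing).
#' @export
impute_dosage_means <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  mu <- colMeans(dosage, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2L]]
  dosage
}

## strand-ambiguous allele pair (A/T or G/C)
is_ambiguous_pair <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "GC", "CG")
}

is_single_base <- function(x) {
  grepl("^[ACGT]$", toupper(x))
}
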
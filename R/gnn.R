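## Graph-convolutional polygenic classifier: each sample is a graph whose
## nodes are the model variants (features: dosage + functional annotation
## counts, normalized dimension-wise) and whose edges connect variants in
## LD (r^2 above a threshold). Three symmetric-normalized graph
## convolutions (rectifier, width 128) feed a global max pool and a
## two-layer dense classifier (width 64). Because every sample shares the
## node set and adjacency, a batch lives in a single (batch * nodes) x
## width matrix: applying the adjacency block-wise and multiplying by a
## weight matrix are then both plain matrix products, with only free
## dim-attribute reshapes in between.

#' Build per-sample variant graphs
#'
#' Edges connect variant pairs with `r^2 > r2_threshold`; self-loops are
#' added for the symmetric convolution normalization
#' `A_hat = D^(-1/2) (A + I) D^(-1/2)`. Node features are the sample's
#' dosage plus the variant annotation counts, each feature dimension
#' centered and scaled over the whole dataset (constant dimensions are
#' left at zero).
#'
#' @param geno a [genotype_matrix()].
#' @param ld optional LD matrix ([compute_ld()]); computed from `geno`
#'   when missing. For multi-ancestry data, pass the LD matrix matched to
#'   the samples' ancestry group and build one graph set per group.
#' @param r2_threshold edge threshold on r-squared (default 0.6).
#' @return list of class `snp_graphs`: `adj` (normalized adjacency),
#'   `n_edges`, `dosage` (normalized n x V), `node_feats` (V x (d-1)
#'   normalized annotations), `sample_ids`, `variant_ids`.
#' @export
build_graphs <- function(geno, ld = NULL, r2_threshold = 0.6) {
  if (is.null(ld)) ld <- compute_ld(geno)
  V <- ncol(geno$dosage)
  if (!identical(dim(ld), c(V, V))) stop("LD matrix dimension mismatch")
  A <- (ld > r2_threshold) * 1
  diag(A) <- 0
  n_edges <- sum(A) / 2
  At <- A + diag(V)
  dinv <- 1 / sqrt(rowSums(At))
  adj <- At * outer(dinv, dinv)

  D <- impute_dosage_means(geno$dosage)
  mu <- mean(D); s <- sd(as.vector(D))
  dosage <- if (s > 0) (D - mu) / s else D * 0
  ann <- as.matrix(geno$variants[, ANNOTATION_COLS, drop = FALSE])
  ann <- apply(ann, 2, function(v) {
    s <- sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  })
  structure(list(adj = adj, n_edges = n_edges, dosage = dosage,
                 node_feats = matrix(ann, nrow = V),
                 sample_ids = rownames(D), variant_ids = geno$variants$id),
            class = "snp_graphs")
}

gnn_init_params <- function(d, hidden, dense_width, seed) {
  set.seed(split_seed(seed, 61L))
  gl <- function(fi, fo) matrix(runif(fi * fo, -sqrt(6 / (fi + fo)),
                                      sqrt(6 / (fi + fo))), fi, fo)
  list(W1 = gl(d, hidden), b1 = rep(0, hidden),
       W2 = gl(hidden, hidden), b2 = rep(0, hidden),
       W3 = gl(hidden, hidden), b3 = rep(0, hidden),
       Wd1 = gl(hidden, dense_width), bd1 = rep(0, dense_width),
       Wd2 = gl(dense_width, dense_width), bd2 = rep(0, dense_width),
       Wo = gl(dense_width, 1), bo = 0)
}

## All batch tensors use the "rows" layout: a ((V * b) x h) matrix whose
## row index runs over nodes fastest, then samples. Applying the shared
## adjacency block-diagonally is then `adj %*% matrix(H, V, b * h)` with
## two free dim changes, because column-major order puts the node index
## first either way.
adj_rows <- function(adj, H, V, b, h) {
  dim(H) <- c(V, b * h)
  AH <- adj %*% H
  dim(AH) <- c(V * b, h)
  AH
}

gnn_forward <- function(params, graphs, idx, cache = FALSE) {
  V <- nrow(graphs$adj)
  b <- length(idx)
  h <- ncol(params$W1)
  ## layer 1: the dosage channel differs per sample, annotation channels
  ## are shared, so A_hat F_s W1 = outer(A_hat x_s, W1[1,]) + base
  ax <- graphs$dosage[idx, , drop = FALSE] %*% graphs$adj     # b x V
  base <- graphs$adj %*% graphs$node_feats %*%
    params$W1[-1L, , drop = FALSE]
  base <- sweep(base, 2, params$b1, "+")                      # V x h
  Z1 <- as.vector(t(ax)) %o% params$W1[1L, ] +
    base[rep.int(seq_len(V), b), , drop = FALSE]              # (V*b) x h
  H1 <- Z1 * (Z1 > 0)

  M2 <- adj_rows(graphs$adj, H1, V, b, h)
  Z2 <- sweep(M2 %*% params$W2, 2, params$b2, "+")
  H2 <- Z2 * (Z2 > 0)

  M3 <- adj_rows(graphs$adj, H2, V, b, h)
  Z3 <- sweep(M3 %*% params$W3, 2, params$b3, "+")
  H3 <- Z3 * (Z3 > 0)

  ## global max pooling over nodes: columns of matrix(H3, V, b*h) are
  ## (sample, channel) pairs with sample fastest
  Hm <- H3
  dim(Hm) <- c(V, b * h)
  amax <- max.col(t(Hm), ties.method = "first")
  pooled <- matrix(Hm[cbind(amax, seq_len(b * h))], b, h)

  D1p <- sweep(pooled %*% params$Wd1, 2, params$bd1, "+")
  D1 <- D1p * (D1p > 0)
  D2p <- sweep(D1 %*% params$Wd2, 2, params$bd2, "+")
  D2 <- D2p * (D2p > 0)
  p <- sigmoid(drop(D2 %*% params$Wo) + params$bo)
  if (!cache) return(p)
  list(p = p, ax = ax, H1 = H1, M2 = M2, H2 = H2, M3 = M3, H3 = H3,
       amax = amax, pooled = pooled, D1 = D1, D2 = D2,
       V = V, b = b, h = h)
}

gnn_gradients <- function(params, graphs, fw, y) {
  V <- fw$V; b <- fw$b; h <- fw$h
  g <- list()
  dzo <- matrix((fw$p - y) / b, ncol = 1)
  g$Wo <- crossprod(fw$D2, dzo); g$bo <- sum(dzo)
  dD2 <- (dzo %*% t(params$Wo)) * (fw$D2 > 0)
  g$Wd2 <- crossprod(fw$D1, dD2); g$bd2 <- colSums(dD2)
  dD1 <- (dD2 %*% t(params$Wd2)) * (fw$D1 > 0)
  g$Wd1 <- crossprod(fw$pooled, dD1); g$bd1 <- colSums(dD1)
  dP <- dD1 %*% t(params$Wd1)                                 # b x h

  ## un-pool: scatter each pooled gradient to its argmax node
  dHm <- matrix(0, V, b * h)
  dHm[cbind(fw$amax, seq_len(b * h))] <- as.vector(dP)
  dim(dHm) <- c(V * b, h)

  dZ3 <- dHm * (fw$H3 > 0)
  g$W3 <- crossprod(fw$M3, dZ3); g$b3 <- colSums(dZ3)
  dH2 <- adj_rows(graphs$adj, dZ3 %*% t(params$W3), V, b, h)

  dZ2 <- dH2 * (fw$H2 > 0)
  g$W2 <- crossprod(fw$M2, dZ2); g$b2 <- colSums(dZ2)
  dH1 <- adj_rows(graphs$adj, dZ2 %*% t(params$W2), V, b, h)

  dZ1 <- dH1 * (fw$H1 > 0)
  g$b1 <- colSums(dZ1)
  W1g <- matrix(0, nrow(params$W1), h)
  W1g[1L, ] <- colSums(dZ1 * as.vector(t(fw$ax)))
  ## annotation channels are shared across samples: sum dZ1 over samples
  sum_s <- dZ1
  dim(sum_s) <- c(V, b, h)
  sum_s <- apply(sum_s, c(1, 3), sum)
  W1g[-1L, ] <- crossprod(graphs$adj %*% graphs$node_feats, sum_s)
  g$W1 <- W1g
  g
}

#' Train the graph-convolutional polygenic classifier
#'
#' Adaptive-moment (Adam) optimization of mean binary cross-entropy with
#' early stopping (default patience 20 epochs on validation loss, best
#' weights restored). Deterministic given `seed`.
#'
#' @param graphs a [build_graphs()] object.
#' @param labels binary labels aligned to the graph samples.
#' @param epochs maximum epochs (default 30).
#' @param batch_size mini-batch size (default 256).
#' @param lr Adam learning rate (default 0.01).
#' @param patience early-stopping patience in epochs (default 20).
#' @param validation optional `list(graphs = , labels = )`; otherwise
#'   `validation_fraction` of samples is held out.
#' @param validation_fraction default 0.2.
#' @param hidden graph-convolution width (default 128).
#' @param dense_width classifier width (default 64).
#' @param seed integer seed.
#' @return list of class `gnn_model` with `params`, `history` (epoch,
#'   mean train batch loss, validation loss), `best_epoch`, and the
#'   architecture settings.
#' @export
train_gnn <- function(graphs, labels, epochs = 30, batch_size = 256,
                      lr = 0.01, patience = 20, validation = NULL,
                      validation_fraction = 0.2, hidden = 128,
                      dense_width = 64, seed = 1) {
  y <- as.integer(labels)
  n <- nrow(graphs$dosage)
  stopifnot(length(y) == n, all(y %in% 0:1))
  d <- 1L + ncol(graphs$node_feats)
  params <- gnn_init_params(d, hidden, dense_width, seed)
  set.seed(split_seed(seed, 62L))
  train_idx <- seq_len(n)
  if (is.null(validation) && validation_fraction > 0) {
    vi <- sample(n, max(1L, floor(n * validation_fraction)))
    validation <- list(idx = vi)
    train_idx <- setdiff(train_idx, vi)
  }
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  best_loss <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  hist <- vector("list", epochs)
  chunk_loss <- function(idx) {
    tot <- 0
    for (st in seq(1L, length(idx), by = 1024L)) {
      ii <- idx[st:min(st + 1023L, length(idx))]
      tot <- tot + bce_loss(gnn_forward(params, graphs, ii), y[ii]) *
        length(ii)
    }
    tot / length(idx)
  }
  for (epoch in seq_len(epochs)) {
    ord <- sample(train_idx)
    batch_losses <- c()
    for (start in seq(1L, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, length(ord))]
      fw <- gnn_forward(params, graphs, bi, cache = TRUE)
      batch_losses <- c(batch_losses, bce_loss(fw$p, y[bi]))
      g <- gnn_gradients(params, graphs, fw, y[bi])
      t_step <- t_step + 1L
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mh <- m[[nm]] / (1 - beta1^t_step)
        vh <- v[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    train_loss <- mean(batch_losses)
    if (!is.finite(train_loss)) {
      stop("graph-model training diverged at epoch ", epoch)
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      val_loss <- if (!is.null(validation$idx)) chunk_loss(validation$idx)
      else {
        pv <- gnn_forward(params, validation$graphs,
                          seq_len(nrow(validation$graphs$dosage)))
        bce_loss(pv, as.integer(validation$labels))
      }
      if (val_loss < best_loss - 1e-12) {
        best_loss <- val_loss; best_params <- params
        best_epoch <- epoch; wait <- 0L
      } else wait <- wait + 1L
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss)
    if (!is.null(validation) && wait >= patience) break
  }
  if (best_epoch > 0L) params <- best_params
  structure(list(params = params, hidden = hidden,
                 dense_width = dense_width, feature_dim = d,
                 history = do.call(rbind,
                                   hist[!vapply(hist, is.null, logical(1))]),
                 best_epoch = if (best_epoch > 0L) best_epoch else epochs,
                 seed = seed),
            class = "gnn_model")
}

#' Score samples with a trained graph model
#'
#' Deterministic chunked forward pass.
#'
#' @param model a [train_gnn()] result.
#' @param graphs a [build_graphs()] object with the same feature schema.
#' @return per-sample risk scores in (0, 1).
#' @export
gnn_score <- function(model, graphs) {
  d <- 1L + ncol(graphs$node_feats)
  if (d != model$feature_dim) {
    stop("graph feature schema mismatch: model expects dimension ",
         model$feature_dim, ", got ", d)
  }
  n <- nrow(graphs$dosage)
  out <- numeric(n)
  for (st in seq(1L, n, by = 1024L)) {
    ii <- st:min(st + 1023L, n)
    out[ii] <- gnn_forward(model$params, graphs, ii)
  }
  out
}
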
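## Structured multilayer sigmoid network for polygenic risk, trained by
## mini-batch gradient descent on binary cross-entropy with a staircase
## exponential learning-rate decay. Implemented directly on matrix
## algebra: the architecture, gradients, dropout and early stopping are
## all explicit so the penultimate "module" layer can be inspected.

#' Training configuration for the neural polygenic models
#'
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param lr0 initial learning rate.
#' @param decay_steps,decay_rate,staircase exponential decay schedule:
#'   the rate at optimizer step `t` is
#'   `lr0 * decay_rate^(t / decay_steps)`, with the exponent floored when
#'   `staircase` is `TRUE`.
#' @param patience early-stopping patience in epochs (`NULL` disables);
#'   training stops once the validation loss has failed to improve for
#'   `patience` consecutive epochs, and the best weights are restored.
#' @param validation_fraction fraction of samples held out for validation
#'   when no explicit validation set is given and patience or history
#'   tracking needs one.
#' @param seed integer seed governing shuffling, dropout masks and the
#'   validation split.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 256, lr0 = 0.5,
                         decay_steps = 100000, decay_rate = 0.96,
                         staircase = TRUE, patience = NULL,
                         validation_fraction = 0.2, seed = 1) {
  stopifnot(lr0 > 0, decay_rate > 0, decay_rate <= 1,
            is.null(patience) || patience >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = epochs, batch_size = batch_size, lr0 = lr0,
                 decay_steps = decay_steps, decay_rate = decay_rate,
                 staircase = staircase, patience = patience,
                 validation_fraction = validation_fraction, seed = seed),
            class = "train_config")
}

#' Learning rate at a given optimizer step
#'
#' @param config a [train_config()].
#' @param step non-negative optimizer step count.
#' @return the decayed learning rate
#'   `lr0 * decay_rate^(floor(step / decay_steps))` (staircase) or with a
#'   continuous exponent otherwise.
#' @export
lr_at_step <- function(config, step) {
  stopifnot(step >= 0)
  e <- step / config$decay_steps
  if (config$staircase) e <- floor(e)
  config$lr0 * config$decay_rate^e
}

#' Build a structured sigmoid network for polygenic risk
#'
#' Two seven-layer architectures are provided. The `"european"` layout
#' sizes its dense widths from the number of annotated loci L:
#' dropout, dense(3L) (up to three risk haplotypes per locus), dropout,
#' dense(L), dense(22) (chromosomes), dense(5) (putative pathways),
#' dense(1) (the risk score). The `"chinese"` layout is
#' dense(50), dropout, dense(30), dropout, dense(10), dense(5), dense(1).
#' Every dense layer uses the sigmoid activation; the 5-wide layer feeding
#' the output is the penultimate "module" layer. Weights are initialized
#' with a seeded symmetric-uniform fan-scaled scheme, so the same seed
#' reproduces the same initial network.
#'
#' @param kind `"european"` or `"chinese"`.
#' @param n_features input width (number of model variants).
#' @param n_loci number of loci L (required for `"european"`).
#' @param dropout_rate dropout probability; defaults to 0.2 (european) or
#'   0.3 (chinese).
#' @param init_seed integer seed for weight initialization.
#' @return list of class `nn_model` with `layers` (each
#'   `list(type = "dense", W, b)` or `list(type = "dropout", rate)`),
#'   `kind`, `init_seed`, `trained`.
#' @export
build_nn <- function(kind = c("european", "chinese"), n_features,
                     n_loci = NULL, dropout_rate = NULL, init_seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_features >= 1)
  if (kind == "european") {
    if (is.null(n_loci) || n_loci < 1) stop("european layout needs n_loci >= 1")
    rate <- dropout_rate %||% 0.2
    spec <- list(list("dropout", rate), list("dense", 3 * n_loci),
                 list("dropout", rate), list("dense", n_loci),
                 list("dense", 22), list("dense", 5), list("dense", 1))
  } else {
    rate <- dropout_rate %||% 0.3
    spec <- list(list("dense", 50), list("dropout", rate),
                 list("dense", 30), list("dropout", rate),
                 list("dense", 10), list("dense", 5), list("dense", 1))
  }
  set.seed(split_seed(init_seed, 21L))
  layers <- list()
  fan_in <- n_features
  for (s in spec) {
    if (s[[1]] == "dropout") {
      layers[[length(layers) + 1L]] <- list(type = "dropout", rate = s[[2]])
    } else {
      width <- s[[2]]
      lim <- sqrt(6 / (fan_in + width))
      W <- matrix(runif(fan_in * width, -lim, lim), fan_in, width)
      layers[[length(layers) + 1L]] <- list(type = "dense", W = W,
                                            b = rep(0, width))
      fan_in <- width
    }
  }
  structure(list(layers = layers, kind = kind, n_features = n_features,
                 init_seed = init_seed, trained = FALSE),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  widths <- vapply(x$layers, function(l)
    if (l$type == "dense") ncol(l$W) else NA_integer_, numeric(1))
  cat("nn_model (", x$kind, "): input ", x$n_features, " -> dense widths ",
      paste(widths[!is.na(widths)], collapse = ", "),
      if (x$trained) " [trained]" else " [untrained]", "\n", sep = "")
  invisible(x)
}

## forward pass; when training = TRUE, draws dropout masks (inverted
## scaling) and caches everything backprop needs
nn_forward_full <- function(model, X, training = FALSE) {
  acts <- list(X)     # activation entering layer i
  masks <- vector("list", length(model$layers))
  A <- X
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "dropout") {
      if (training && l$rate > 0) {
        M <- matrix(rbinom(length(A), 1, 1 - l$rate), nrow(A)) / (1 - l$rate)
        A <- A * M
        masks[[i]] <- M
      }
    } else {
      Z <- sweep(A %*% l$W, 2, l$b, "+")
      A <- sigmoid(Z)
    }
    acts[[i + 1L]] <- A
  }
  list(acts = acts, masks = masks, out = drop(A))
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

## gradients of mean BCE wrt all dense W, b for one batch
nn_gradients <- function(model, fwd, y) {
  L <- length(model$layers)
  grads <- vector("list", L)
  nb <- length(y)
  dA <- NULL
  for (i in rev(seq_len(L))) {
    l <- model$layers[[i]]
    A_out <- fwd$acts[[i + 1L]]
    A_in <- fwd$acts[[i]]
    if (i == L) {
      ## sigmoid + BCE collapse: dZ = (p - y) / n
      dZ <- matrix((A_out[, 1L] - y) / nb, ncol = 1L)
      grads[[i]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
      dA <- dZ %*% t(l$W)
    } else if (l$type == "dense") {
      dZ <- dA * A_out * (1 - A_out)
      grads[[i]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
      dA <- dZ %*% t(l$W)
    } else {
      if (!is.null(fwd$masks[[i]])) dA <- dA * fwd$masks[[i]]
    }
  }
  grads
}

#' Train a neural polygenic model
#'
#' Mini-batch gradient descent on mean binary cross-entropy with the
#' staircase exponential learning-rate schedule. Dropout is active only
#' during training passes. With `patience` set, training stops when the
#' validation loss fails to improve for that many consecutive epochs and
#' the best weights are restored. Fully reproducible for a given
#' `config$seed`.
#'
#' @param model an [build_nn()] model (or any `nn_model`).
#' @param X numeric matrix of features (samples x variants), complete
#'   (impute first).
#' @param y binary labels (0/1).
#' @param config a [train_config()].
#' @param validation optional `list(X = , y = )` explicit validation set;
#'   otherwise a `validation_fraction` split is carved out when needed.
#' @return the trained model, with a `history` data frame (epoch, lr,
#'   train_loss, val_loss, val_auroc) and `best_epoch` attached.
#' @export
train_nn <- function(model, X, y, config = train_config(),
                     validation = NULL) {
  stopifnot(inherits(model, "nn_model"), nrow(X) == length(y),
            all(y %in% 0:1))
  if (ncol(X) != model$n_features) {
    stop("model expects ", model$n_features, " features, got ", ncol(X))
  }
  set.seed(split_seed(config$seed, 22L))
  need_val <- !is.null(config$patience) || is.null(validation)
  if (is.null(validation) && config$validation_fraction > 0 && need_val) {
    n_val <- max(1L, floor(nrow(X) * config$validation_fraction))
    vi <- sample(nrow(X), n_val)
    validation <- list(X = X[vi, , drop = FALSE], y = y[vi])
    X <- X[-vi, , drop = FALSE]
    y <- y[-vi]
  }
  n <- nrow(X)
  step <- 0L
  hist <- vector("list", config$epochs)
  best_loss <- Inf
  best_layers <- model$layers
  best_epoch <- 0L
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, n)]
      fwd <- nn_forward_full(model, X[bi, , drop = FALSE], training = TRUE)
      grads <- nn_gradients(model, fwd, y[bi])
      lr <- lr_at_step(config, step)
      for (i in seq_along(model$layers)) {
        if (!is.null(grads[[i]])) {
          model$layers[[i]]$W <- model$layers[[i]]$W - lr * grads[[i]]$W
          model$layers[[i]]$b <- model$layers[[i]]$b - lr * grads[[i]]$b
        }
      }
      step <- step + 1L
    }
    p_train <- nn_forward_full(model, X)$out
    train_loss <- bce_loss(p_train, y)
    if (!is.finite(train_loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
    val_loss <- val_auc <- NA_real_
    if (!is.null(validation)) {
      p_val <- nn_forward_full(model, validation$X)$out
      val_loss <- bce_loss(p_val, validation$y)
      val_auc <- if (length(unique(validation$y)) == 2L)
        auroc(p_val, validation$y) else NA_real_
      if (val_loss < best_loss - 1e-12) {
        best_loss <- val_loss
        best_layers <- model$layers
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr_at_step(config, step),
                                train_loss = train_loss,
                                val_loss = val_loss, val_auroc = val_auc)
    if (!is.null(config$patience) && wait >= config$patience) break
  }
  if (!is.null(config$patience) && best_epoch > 0L) {
    model$layers <- best_layers
  }
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$best_epoch <- if (best_epoch > 0L) best_epoch else
    nrow(model$history)
  model
}

#' Score samples with a neural polygenic model
#'
#' Deterministic forward pass with dropout inert; repeated calls give
#' bit-identical scores.
#'
#' @param model an `nn_model`.
#' @param geno a [genotype_matrix()] or a plain feature matrix.
#' @return per-sample risk scores in (0, 1).
#' @export
nn_score <- function(model, geno) {
  X <- if (inherits(geno, "genotype_matrix"))
    impute_dosage_means(geno$dosage) else as.matrix(geno)
  if (ncol(X) != model$n_features) {
    stop("model expects ", model$n_features, " features, got ", ncol(X))
  }
  nn_forward_full(model, X)$out
}

#' Penultimate-layer module outputs
#'
#' Activations of the dense layer feeding the output node — the network's
#' "modules", which summarize the polygenic input into a few latent risk
#' components (width 5 for both stock architectures).
#'
#' @param model an `nn_model` with at least two dense layers.
#' @param geno genotype matrix or feature matrix.
#' @return matrix (samples x module width) of activations in (0, 1),
#'   columns `M1`, `M2`, ...
#' @export
penultimate_outputs <- function(model, geno) {
  dense_idx <- which(vapply(model$layers, function(l) l$type == "dense",
                            logical(1)))
  if (length(dense_idx) < 2L) stop("model has fewer than two dense layers")
  X <- if (inherits(geno, "genotype_matrix"))
    impute_dosage_means(geno$dosage) else as.matrix(geno)
  fwd <- nn_forward_full(model, X)
  pen <- fwd$acts[[dense_idx[length(dense_idx) - 1L] + 1L]]
  colnames(pen) <- paste0("M", seq_len(ncol(pen)))
  pen
}

#' Serialize a neural model to a structured text file
#'
#' One self-contained text bundle: architecture line-by-line, full-precision
#' flat weight arrays, and the init seed, so a model can be stored under
#' version control and re-loaded bit-identically.
#'
#' @param model an `nn_model`.
#' @param path output file.
#' @export
write_nn_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("prsnet_nn 1",
               paste("kind", model$kind),
               paste("n_features", model$n_features),
               paste("init_seed", model$init_seed),
               paste("trained", model$trained),
               paste("n_layers", length(model$layers))), con)
  for (l in model$layers) {
    if (l$type == "dropout") {
      writeLines(paste("dropout", format(l$rate, digits = 17)), con)
    } else {
      writeLines(paste("dense", nrow(l$W), ncol(l$W)), con)
      writeLines(paste(sprintf("%.17g", as.vector(l$W)), collapse = " "), con)
      writeLines(paste(sprintf("%.17g", l$b), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a serialized neural model
#' @param path file written by [write_nn_model()].
#' @return an `nn_model`.
#' @export
read_nn_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "prsnet_nn")) stop("not a prsnet model bundle")
  kv <- function(i) strsplit(lines[i], " ")[[1L]]
  kind <- kv(2L)[2L]
  n_features <- as.integer(kv(3L)[2L])
  init_seed <- as.integer(kv(4L)[2L])
  trained <- as.logical(kv(5L)[2L])
  n_layers <- as.integer(kv(6L)[2L])
  layers <- vector("list", n_layers)
  i <- 7L
  for (k in seq_len(n_layers)) {
    hdr <- kv(i)
    if (hdr[1L] == "dropout") {
      layers[[k]] <- list(type = "dropout", rate = as.numeric(hdr[2L]))
      i <- i + 1L
    } else {
      nr <- as.integer(hdr[2L]); nc <- as.integer(hdr[3L])
      W <- matrix(as.numeric(strsplit(lines[i + 1L], " ")[[1L]]), nr, nc)
      b <- as.numeric(strsplit(lines[i + 2L], " ")[[1L]])
      layers[[k]] <- list(type = "dense", W = W, b = b)
      i <- i + 3L
    }
  }
  structure(list(layers = layers, kind = kind, n_features = n_features,
                 init_seed = init_seed, trained = trained),
            class = "nn_model")
}
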
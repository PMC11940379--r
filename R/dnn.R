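#' Train the pair classifier (feed-forward neural network)
#'
#' Architecture: input -> dense(256, ReLU, dropout) -> dense(128, ReLU,
#' dropout) -> dense(1, sigmoid), trained by minimising binary cross-entropy
#' with RMSProp mini-batch SGD. Training stops early when the loss on a
#' held-out validation split has not improved for `patience` epochs; the
#' best weights are restored. With `val_fraction = 0` the network trains for
#' the full epoch budget. Dropout is active only during training. The run is
#' deterministic for a fixed seed.
#'
#' @param data a [pair_dataset()] with binary labels; both classes must be
#'   present.
#' @param cfg a [walkmda_config()]; the `dnn` block supplies the
#'   hyperparameters.
#' @param seed integer seed for the initialisation/batching/dropout
#'   substream; defaults to a substream of `cfg$seed`.
#' @return a `dnn_model` (weights, biases, training history).
#' @export
train_dnn <- function(data, cfg, seed = NULL) {
  stopifnot(inherits(data, "pair_dataset"), inherits(cfg, "walkmda_config"))
  X <- data$features
  y <- data$pairs$label
  if (is.null(y)) stop("training dataset has no labels")
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  dn <- cfg$dnn
  if (is.null(seed)) seed <- substream_seed(cfg$seed, "dnn")
  widths <- c(ncol(X), dn$hidden, 1L)
  n_layers <- length(widths) - 1L

  with_seed(seed, {
    W <- lapply(seq_len(n_layers), function(l) {
      matrix(rnorm(widths[l] * widths[l + 1L], sd = sqrt(2 / widths[l])),
             widths[l], widths[l + 1L])
    })
    b <- lapply(seq_len(n_layers), function(l) numeric(widths[l + 1L]))
    vW <- lapply(W, function(m) m * 0)
    vb <- lapply(b, function(v) v * 0)

    n <- nrow(X)
    n_val <- if (dn$val_fraction > 0) floor(n * dn$val_fraction) else 0L
    if (n_val >= 1L && n - n_val >= 2L) {
      val_idx <- sample.int(n, n_val)
    } else {
      val_idx <- integer(0)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(y[tr_idx])) < 2L) {
      val_idx <- integer(0)
      tr_idx <- seq_len(n)
    }
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]

    rho <- 0.9; eps <- 1e-8; lr <- dn$learning_rate; drop <- dn$dropout
    best <- list(loss = Inf, W = W, b = b, epoch = 0L)
    stall <- 0L
    history <- numeric(0)

    forward_eval <- function(Xm) {
      H <- Xm
      for (l in seq_len(n_layers - 1L)) {
        H <- pmax(sweep(H %*% W[[l]], 2L, b[[l]], "+"), 0)
      }
      z <- sweep(H %*% W[[n_layers]], 2L, b[[n_layers]], "+")
      plogis(z)[, 1L]
    }
    bce <- function(p, yy) {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(yy * log(p) + (1 - yy) * log(1 - p))
    }

    for (epoch in seq_len(dn$epochs)) {
      ord <- sample.int(length(tr_idx))
      batches <- split(ord, ceiling(seq_along(ord) / dn$batch_size))
      for (bt in batches) {
        Xb <- Xtr[bt, , drop = FALSE]; yb <- ytr[bt]
        # forward with inverted dropout on hidden activations
        acts <- vector("list", n_layers)  # post-activation inputs to layer l+1
        masks <- vector("list", n_layers - 1L)
        H <- Xb
        for (l in seq_len(n_layers - 1L)) {
          acts[[l]] <- H
          H <- pmax(sweep(H %*% W[[l]], 2L, b[[l]], "+"), 0)
          if (drop > 0) {
            m <- matrix(runif(length(H)) >= drop, nrow(H), ncol(H)) / (1 - drop)
            H <- H * m
            masks[[l]] <- m
          }
        }
        acts[[n_layers]] <- H
        z <- sweep(H %*% W[[n_layers]], 2L, b[[n_layers]], "+")
        p <- plogis(z)[, 1L]
        # backward
        delta <- matrix((p - yb) / length(yb), ncol = 1L)
        for (l in rev(seq_len(n_layers))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(W[[l]])
            if (drop > 0) delta <- delta * masks[[l - 1L]]
            delta <- delta * (acts[[l]] > 0)
          }
          vW[[l]] <- rho * vW[[l]] + (1 - rho) * gW^2
          vb[[l]] <- rho * vb[[l]] + (1 - rho) * gb^2
          W[[l]] <- W[[l]] - lr * gW / (sqrt(vW[[l]]) + eps)
          b[[l]] <- b[[l]] - lr * gb / (sqrt(vb[[l]]) + eps)
        }
      }
      train_loss <- bce(forward_eval(Xtr), ytr)
      history <- c(history, train_loss)
      monitor <- if (length(val_idx) > 0L) bce(forward_eval(Xv), yv) else train_loss
      if (monitor < best$loss - 1e-8) {
        best <- list(loss = monitor, W = W, b = b, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (length(val_idx) > 0L && stall >= dn$patience) break
      }
    }
    if (length(val_idx) > 0L) {
      W <- best$W
      b <- best$b
    }
    structure(list(W = W, b = b, widths = widths, dropout = drop,
                   input_width = ncol(X), history = history,
                   best_epoch = best$epoch, trained = TRUE),
              class = "dnn_model")
  })
}

#' Score miRNA-disease pairs with a trained classifier
#'
#' Forward pass with dropout disabled; one sigmoid score strictly inside
#' (0, 1) per pair, in the dataset's order.
#'
#' @param model a `dnn_model` from [train_dnn()].
#' @param data a [pair_dataset()] whose feature width matches the model.
#' @return numeric vector of association scores.
#' @export
predict_scores <- function(model, data) {
  stopifnot(inherits(model, "dnn_model"), inherits(data, "pair_dataset"))
  if (!isTRUE(model$trained)) stop("model is not trained")
  X <- data$features
  if (ncol(X) != model$input_width) {
    stop(sprintf("feature width %d does not match model input width %d",
                 ncol(X), model$input_width))
  }
  if (nrow(X) == 0L) return(numeric(0))
  n_layers <- length(model$W)
  H <- X
  for (l in seq_len(n_layers - 1L)) {
    H <- pmax(sweep(H %*% model$W[[l]], 2L, model$b[[l]], "+"), 0)
  }
  z <- sweep(H %*% model$W[[n_layers]], 2L, model$b[[n_layers]], "+")
  pmin(pmax(plogis(z)[, 1L], 1e-12), 1 - 1e-12)
}

#' @export
print.dnn_model <- function(x, ...) {
  cat(sprintf("dnn_model: %s, dropout %.2f, trained %d epochs (best %d)\n",
              paste(x$widths, collapse = " -> "), x$dropout,
              length(x$history), x$best_epoch))
  invisible(x)
}
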
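#' Stacked autoencoder specification
#'
#' The encoder maps the `d`-dimensional input through fully connected
#' layers to a `d'`-dimensional embedding; the decoder mirrors the encoder.
#' Internal layers use ReLU; the input, embedding and output layers are
#' linear.  The default architecture is `d-500-500-2000-10`.
#'
#' @param input_dim input dimensionality `d`.
#' @param layer_dims full stack of encoder dimensions `[d, h1, ..., d']`;
#'   defaults to `c(input_dim, 500, 500, 2000, 10)`.
#' @param pretrain_epochs epochs used for each greedy layer-wise stage and
#'   again for end-to-end fine-tuning.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param dropout_noise input corruption rate for the denoising layer-wise
#'   stage, in `[0, 1)` (default 0.2); fine-tuning is uncorrupted.
#' @param batch_size mini-batch size (default 256, capped at `n`).
#' @param stop_threshold early-stopping threshold: training of a stage stops
#'   once the relative epoch-to-epoch decrease of the reconstruction loss
#'   falls below this value (default 0.001).
#' @param seed integer seed controlling initialization, corruption and batch
#'   order.
#' @return An object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(input_dim, layer_dims = NULL,
                             pretrain_epochs = 30L, learning_rate = 0.001,
                             dropout_noise = 0.2, batch_size = 256L,
                             stop_threshold = 0.001, seed = 0L) {
  input_dim <- stop_if_not_count(input_dim, "input_dim")
  if (is.null(layer_dims)) layer_dims <- c(input_dim, 500L, 500L, 2000L, 10L)
  layer_dims <- vapply(layer_dims, stop_if_not_count, integer(1),
                       name = "layer_dims")
  if (length(layer_dims) < 2L) stop("layer_dims must have length >= 2",
                                    call. = FALSE)
  if (layer_dims[1L] != input_dim) {
    stop("layer_dims[1] must equal input_dim", call. = FALSE)
  }
  if (layer_dims[length(layer_dims)] >= layer_dims[1L]) {
    stop("embedding dimension d' must be smaller than input dimension d",
         call. = FALSE)
  }
  stop_if_not_scalar(learning_rate, "learning_rate", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_scalar(dropout_noise, "dropout_noise", lower = 0, upper = 1)
  if (dropout_noise >= 1) stop("dropout_noise must be < 1", call. = FALSE)
  pretrain_epochs <- stop_if_not_count(pretrain_epochs, "pretrain_epochs")
  batch_size <- stop_if_not_count(batch_size, "batch_size")
  stop_if_not_scalar(stop_threshold, "stop_threshold", lower = 0)
  structure(
    list(input_dim = input_dim, layer_dims = as.integer(layer_dims),
         hidden_activation = "relu", pretrain_epochs = pretrain_epochs,
         learning_rate = learning_rate, optimizer = "adam",
         dropout_noise = dropout_noise, batch_size = batch_size,
         stop_threshold = stop_threshold, seed = as.integer(seed)),
    class = "autoencoder_spec")
}

#' @export
print.autoencoder_spec <- function(x, ...) {
  cat(sprintf("autoencoder_spec: %s, %d pretrain epochs, lr=%g, seed=%d\n",
              paste(x$layer_dims, collapse = "-"), x$pretrain_epochs,
              x$learning_rate, x$seed))
  invisible(x)
}

# Sum-of-squares reconstruction loss of `net` over the full matrix X.
ae_full_loss <- function(net, X) {
  out <- mlp_forward(net, X)$out
  sum((X - out)^2)
}

# Train an autoencoder-shaped net on X (target = X) by mini-batch Adam.
# Returns the trained net plus the per-epoch full-data loss trace.
# `corrupt` > 0 zeroes that fraction of input entries (denoising); the loss
# is always measured on clean inputs.
train_ae_net <- function(net, X, epochs, batch_size, lr, corrupt,
                         stop_threshold) {
  n <- nrow(X)
  batch_size <- min(batch_size, n)
  params <- net_params(net)
  opt <- adam_new(params, lr = lr)
  losses <- numeric(0)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      inb <- Xb
      if (corrupt > 0) {
        mask <- matrix(stats::runif(length(Xb)) >= corrupt, nrow(Xb),
                       ncol(Xb))
        inb <- Xb * mask
      }
      cache <- mlp_forward(net, inb, keep_cache = TRUE)
      dOut <- 2 * (cache$out - Xb)
      grads <- mlp_backward(net, cache, dOut)
      step <- adam_step(opt, params, c(grads$dW, grads$db))
      opt <- step$opt; params <- step$params
      net <- net_set_params(net, params)
    }
    losses[epoch] <- ae_full_loss(net, X)
    if (!is.finite(losses[epoch])) {
      stop("non-finite reconstruction loss during autoencoder training",
           call. = FALSE)
    }
    if (epoch >= 2L) {
      rel <- (losses[epoch - 1L] - losses[epoch]) /
        max(losses[epoch - 1L], 1e-12)
      if (rel >= 0 && rel < stop_threshold) break
    }
  }
  list(net = net, losses = losses)
}

#' Pretrain the stacked autoencoder
#'
#' Two stages, both minimizing the summed squared reconstruction error
#' \eqn{J_{AE} = \sum_i \|x_i - \hat{x}_i\|^2}: (1) greedy layer-wise
#' pretraining, where each encoder/decoder layer pair is trained in
#' isolation as a denoising autoencoder on the previous layer's (clean)
#' output; (2) end-to-end fine-tuning of the full stack without corruption.
#' Each stage runs for at most `pretrain_epochs` epochs with early stopping
#' (see [autoencoder_spec()]).
#'
#' @param X numeric `n x d` data matrix, `n >= 2`, finite entries.
#' @param spec an [autoencoder_spec()].
#' @return An object of class `autoencoder_state`: encoder and decoder
#'   networks, the `loss_history` data frame (`phase`, `epoch`, `loss`,
#'   where `loss` is the full-data \eqn{J_{AE}} of the stage being trained),
#'   and the `spec`.
#' @export
pretrain <- function(X, spec) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  X <- as_numeric_matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to pretrain", call. = FALSE)
  if (!all(is.finite(X))) stop("X contains non-finite entries", call. = FALSE)
  if (ncol(X) != spec$layer_dims[1L]) {
    stop(sprintf("X has %d columns but layer_dims[1] = %d", ncol(X),
                 spec$layer_dims[1L]), call. = FALSE)
  }
  dims <- spec$layer_dims
  L <- length(dims) - 1L
  enc_acts <- c(rep("relu", L - 1L), "linear")        # embedding is linear
  dec_acts <- c(rep("relu", L - 1L), "linear")        # output is linear
  hist <- list()
  with_seed(spec$seed, {
    encoder <- mlp_new(dims, enc_acts)
    decoder <- mlp_new(rev(dims), dec_acts)
    # greedy layer-wise: encoder layer k pairs with decoder layer L+1-k
    H <- X
    for (k in seq_len(L)) {
      dk <- L + 1L - k
      mini <- list(dims = c(dims[k], dims[k + 1L], dims[k]),
                   acts = c(enc_acts[k], dec_acts[dk]),
                   W = list(encoder$W[[k]], decoder$W[[dk]]),
                   b = list(encoder$b[[k]], decoder$b[[dk]]))
      trained <- train_ae_net(mini, H, spec$pretrain_epochs,
                              spec$batch_size, spec$learning_rate,
                              spec$dropout_noise, spec$stop_threshold)
      encoder$W[[k]] <- trained$net$W[[1L]]
      encoder$b[[k]] <- trained$net$b[[1L]]
      decoder$W[[dk]] <- trained$net$W[[2L]]
      decoder$b[[dk]] <- trained$net$b[[2L]]
      hist[[k]] <- data.frame(phase = sprintf("layerwise_%d", k),
                              epoch = seq_along(trained$losses),
                              loss = trained$losses)
      H <- mlp_forward(list(dims = dims[c(k, k + 1L)], acts = enc_acts[k],
                            W = encoder$W[k], b = encoder$b[k]), H)$out
    }
    # end-to-end fine-tuning of the whole stack, clean inputs
    full <- list(dims = c(dims, rev(dims)[-1L]),
                 acts = c(enc_acts, dec_acts),
                 W = c(encoder$W, decoder$W), b = c(encoder$b, decoder$b))
    trained <- train_ae_net(full, X, spec$pretrain_epochs, spec$batch_size,
                            spec$learning_rate, 0, spec$stop_threshold)
    encoder$W <- trained$net$W[seq_len(L)]
    encoder$b <- trained$net$b[seq_len(L)]
    decoder$W <- trained$net$W[L + seq_len(L)]
    decoder$b <- trained$net$b[L + seq_len(L)]
    hist[[L + 1L]] <- data.frame(phase = "finetune",
                                 epoch = seq_along(trained$losses),
                                 loss = trained$losses)
  })
  structure(list(encoder = encoder, decoder = decoder,
                 loss_history = do.call(rbind, hist), spec = spec),
            class = "autoencoder_state")
}

#' @export
print.autoencoder_state <- function(x, ...) {
  cat(sprintf("autoencoder_state: %s, final J_AE = %.6g\n",
              paste(x$spec$layer_dims, collapse = "-"),
              utils::tail(x$loss_history$loss, 1L)))
  invisible(x)
}

#' Encode data into the embedding space
#'
#' Deterministic forward pass through the encoder (no dropout at
#' inference); row `i` of the result is \eqn{f_\theta(x_i)}.
#'
#' @param state an `autoencoder_state` from [pretrain()].
#' @param X numeric matrix with `d` columns.
#' @return The `n x d'` embedding matrix `Z`.
#' @export
encode <- function(state, X) {
  stopifnot(inherits(state, "autoencoder_state"))
  X <- as_numeric_matrix(X)
  if (ncol(X) != state$spec$layer_dims[1L]) {
    stop(sprintf("X has %d columns, encoder expects %d", ncol(X),
                 state$spec$layer_dims[1L]), call. = FALSE)
  }
  mlp_forward(state$encoder, X)$out
}

#' Reconstruction loss on a dataset
#'
#' \eqn{J_{AE} = \sum_i \|x_i - \hat{x}_i\|_2^2} where \eqn{\hat{x}_i} is
#' the decoder output for row `i`.
#'
#' @param state an `autoencoder_state`.
#' @param X numeric matrix with `d` columns and at least one row.
#' @return A nonnegative scalar.
#' @export
reconstruction_loss <- function(state, X) {
  stopifnot(inherits(state, "autoencoder_state"))
  X <- as_numeric_matrix(X)
  if (nrow(X) == 0L) stop("empty data matrix", call. = FALSE)
  if (ncol(X) != state$spec$layer_dims[1L]) {
    stop("dimension mismatch with encoder input", call. = FALSE)
  }
  Z <- mlp_forward(state$encoder, X)$out
  Xhat <- mlp_forward(state$decoder, Z)$out
  sum((X - Xhat)^2)
}

#' Save / load an autoencoder checkpoint
#'
#' Single-file RDS container holding the full `autoencoder_state`.
#'
#' @param state an `autoencoder_state`.
#' @param path checkpoint file path.
#' @return `save_autoencoder` returns `path` invisibly; `load_autoencoder`
#'   returns the restored state.
#' @export
save_autoencoder <- function(state, path) {
  stopifnot(inherits(state, "autoencoder_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "autoencoder_state")) {
    stop("not an autoencoder checkpoint: ", path, call. = FALSE)
  }
  state
}
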
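# Minimal fully connected network with manual backpropagation and Adam.
# Weights are (in x out); activations are "relu" or "linear".

mlp_new <- function(dims, acts) {
  stopifnot(length(acts) == length(dims) - 1L)
  W <- vector("list", length(acts)); b <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))        # Glorot uniform
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -limit, limit),
                     fan_in, fan_out)
    b[[l]] <- numeric(fan_out)
  }
  list(dims = dims, acts = acts, W = W, b = b)
}

mlp_forward <- function(net, X, keep_cache = FALSE) {
  A <- X
  As <- if (keep_cache) vector("list", length(net$W) + 1L) else NULL
  Zs <- if (keep_cache) vector("list", length(net$W)) else NULL
  if (keep_cache) As[[1L]] <- A
  for (l in seq_along(net$W)) {
    Zl <- A %*% net$W[[l]]
    Zl <- sweep(Zl, 2L, net$b[[l]], "+")
    A <- if (net$acts[l] == "relu") pmax(Zl, 0) else Zl
    if (keep_cache) { Zs[[l]] <- Zl; As[[l + 1L]] <- A }
  }
  if (keep_cache) list(out = A, As = As, Zs = Zs) else list(out = A)
}

# dOut: gradient of the loss w.r.t. the network output.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- if (net$acts[l] == "relu") dA * (cache$Zs[[l]] > 0) else dA
    dW[[l]] <- crossprod(cache$As[[l]], dZ)
    db[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, net$W[[l]])
  }
  list(dW = dW, db = db, dX = dA)
}

# Adam optimizer over an arbitrary flat list of numeric arrays.
adam_new <- function(params, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g^2
    params[[k]] <- params[[k]] -
      opt$lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Pack / unpack a two-network (encoder+decoder) or single-network parameter
# list into the flat list Adam operates on.
net_params <- function(net) c(net$W, net$b)

net_set_params <- function(net, flat) {
  L <- length(net$W)
  net$W <- flat[seq_len(L)]
  net$b <- flat[L + seq_len(L)]
  net
}
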
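# Independent brute-force oracles: plain double loops, no shared code with
# the implementation paths they check.

bf_soft_assign <- function(Z, mu, alpha = 1) {
  n <- nrow(Z); C <- nrow(mu)
  Q <- matrix(0, n, C)
  for (i in seq_len(n)) {
    u <- numeric(C)
    for (j in seq_len(C)) {
      d2 <- sum((Z[i, ] - mu[j, ])^2)
      u[j] <- (1 + d2 / alpha)^(-(alpha + 1) / 2)
    }
    Q[i, ] <- u / sum(u)
  }
  Q
}

bf_target_distribution <- function(Q) {
  n <- nrow(Q); C <- ncol(Q)
  f <- numeric(C)
  for (j in seq_len(C)) f[j] <- sum(Q[, j])
  P <- matrix(0, n, C)
  for (i in seq_len(n)) {
    w <- numeric(C)
    for (j in seq_len(C)) w[j] <- Q[i, j]^2 / f[j]
    P[i, ] <- w / sum(w)
  }
  P
}

bf_kl <- function(P, Q) {
  total <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) total <- total + P[i, j] * log(P[i, j] / Q[i, j])
    }
  }
  total
}

bf_constraint <- function(Q, pairs, m) {
  total <- 0
  if (is.null(pairs)) return(total)
  for (p in seq_len(nrow(pairs))) {
    r <- pairs[p, 1]; k <- pairs[p, 2]
    for (j in seq_len(ncol(Q))) {
      total <- total + Q[r, j]^m * Q[k, j]^m
    }
  }
  total
}

# All permutations of a vector (for factorial matching oracles, <= 7!).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Exhaustive-matching clustering accuracy: max over all one-to-one
# correspondences between predicted clusters and true classes.
bf_accuracy <- function(labels_true, labels_pred) {
  tab <- table(factor(labels_pred), factor(labels_true))
  Cp <- nrow(tab); Ct <- ncol(tab)
  best <- 0
  if (Cp <= Ct) {
    for (p in all_perms(seq_len(Ct))) {
      best <- max(best, sum(tab[cbind(seq_len(Cp), p[seq_len(Cp)])]))
    }
  } else {
    for (p in all_perms(seq_len(Cp))) {
      best <- max(best, sum(tab[cbind(p[seq_len(Ct)], seq_len(Ct))]))
    }
  }
  best / length(labels_true)
}

# Random row-stochastic matrix.
random_memberships <- function(n, C) {
  Q <- matrix(stats::rexp(n * C), n, C)
  Q / rowSums(Q)
}

# Small, fast fixtures shared across trainer-level tests.
quick_blobs <- function(n = 300, d = 20, C = 3, separation = 6, seed = 2) {
  generate_blobs(synthetic_spec(n_samples = n, n_features = d,
                                n_clusters = C, separation = separation,
                                seed = seed))
}

quick_ae <- function(X, seed = 3, epochs = 15) {
  pretrain(X, autoencoder_spec(ncol(X), layer_dims = c(ncol(X), 32, 16, 5),
                               pretrain_epochs = epochs, batch_size = 128,
                               seed = seed))
}

quick_cfg <- function(C = 3, seed = 5, ...) {
  train_config(n_clusters = C, batch_size = 128, update_interval = 30,
               max_iterations = 600, seed = seed, ...)
}
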
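#' Configuration of the joint optimization phase
#'
#' @param n_clusters number of clusters `C`.
#' @param batch_size mini-batch size (capped at `n`).
#' @param tolerance stopping threshold in `(0, 1]`: training stops at a
#'   target refresh once the fraction of instances whose hard assignment
#'   changed since the previous refresh falls below this value
#'   (default 0.001).
#' @param update_interval number of mini-batches between refreshes of the
#'   target distribution `P` (default 140).
#' @param max_iterations maximum number of mini-batch gradient steps.
#' @param kmeans_restarts K-means restarts for centroid initialization; the
#'   run with the lowest within-cluster sum of squares is kept (default 20).
#' @param objective_cfg an [objective_config()].
#' @param learning_rate Adam learning rate shared by the encoder weights and
#'   the centroids (default 0.001).
#' @param constraint_mode `"within_batch"` (default): constraint pairs whose
#'   both endpoints fall in the current mini-batch contribute, rescaled by
#'   total-pairs / pairs-in-batch so the expected term magnitude is
#'   batch-size-invariant.  `"pair_batch"`: a fixed-size sample of pairs is
#'   drawn each step and their endpoints are appended to the batch.
#' @param pair_batch_size pairs drawn per step in `"pair_batch"` mode.
#' @param seed master seed for batch order, K-means restarts and pair
#'   sampling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_clusters, batch_size = 256L, tolerance = 0.001,
                         update_interval = 140L, max_iterations = 4000L,
                         kmeans_restarts = 20L,
                         objective_cfg = objective_config(),
                         learning_rate = 0.001,
                         constraint_mode = c("within_batch", "pair_batch"),
                         pair_batch_size = 256L, seed = 0L) {
  n_clusters <- stop_if_not_count(n_clusters, "n_clusters")
  if (n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
  batch_size <- stop_if_not_count(batch_size, "batch_size")
  stop_if_not_scalar(tolerance, "tolerance", lower = 0, upper = 1,
                     strict_lower = TRUE)
  update_interval <- stop_if_not_count(update_interval, "update_interval")
  max_iterations <- stop_if_not_count(max_iterations, "max_iterations")
  kmeans_restarts <- stop_if_not_count(kmeans_restarts, "kmeans_restarts")
  stopifnot(inherits(objective_cfg, "objective_config"))
  stop_if_not_scalar(learning_rate, "learning_rate", lower = 0,
                     strict_lower = TRUE)
  constraint_mode <- match.arg(constraint_mode)
  pair_batch_size <- stop_if_not_count(pair_batch_size, "pair_batch_size")
  structure(
    list(n_clusters = n_clusters, batch_size = batch_size,
         tolerance = tolerance, update_interval = update_interval,
         max_iterations = max_iterations, kmeans_restarts = kmeans_restarts,
         objective_cfg = objective_cfg, learning_rate = learning_rate,
         constraint_mode = constraint_mode,
         pair_batch_size = pair_batch_size, seed = as.integer(seed)),
    class = "train_config")
}

#' Initialize cluster centroids by repeated K-means
#'
#' Runs K-means on the embedding `kmeans_restarts` times with distinct
#' sub-seeds (each restart draws its own `n_clusters` distinct data rows as
#' starting centers) and returns the centroids of the run with the lowest
#' total within-cluster sum of squares.
#'
#' @param Z `n x d'` embedding matrix.
#' @param cfg a [train_config()].
#' @return A `C x d'` centroid matrix with attribute `wcss_runs` holding the
#'   per-restart within-cluster sums of squares.
#' @export
init_centers <- function(Z, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  Z <- as_numeric_matrix(Z, "Z")
  C <- cfg$n_clusters
  if (nrow(Z) < C) stop("fewer instances than clusters", call. = FALSE)
  uniq <- unique(Z)
  if (nrow(uniq) < C) {
    stop("fewer distinct embedded points than clusters", call. = FALSE)
  }
  best <- NULL
  wcss <- numeric(cfg$kmeans_restarts)
  for (r in seq_len(cfg$kmeans_restarts)) {
    fit <- with_seed(derive_seed(cfg$seed, 100L + r), {
      centers0 <- uniq[sample.int(nrow(uniq), C), , drop = FALSE]
      suppressWarnings(stats::kmeans(Z, centers = centers0, iter.max = 100L))
    })
    wcss[r] <- fit$tot.withinss
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  mu <- unname(best$centers)
  attr(mu, "wcss_runs") <- wcss
  mu
}

# Accumulate constraint-term gradient contributions into g (d loss / d Q).
# For each pair (r, k): d/dq_{rj} [ sum_j q_rj^m q_kj^m ] = m q_rj^{m-1} q_kj^m,
# added for both endpoints, weighted by `w` (sign and rescale included).
add_pair_grad <- function(g, Qb, r, k, m, w) {
  if (length(r) == 0L || w == 0) return(g)
  A <- Qb^m
  Qm1 <- Qb^(m - 1)
  acc <- function(g, rows, add) {
    gr <- rowsum(add, rows, reorder = FALSE)
    tgt <- as.integer(rownames(gr))
    g[tgt, ] <- g[tgt, , drop = FALSE] + gr
    g
  }
  g <- acc(g, r, w * m * Qm1[r, , drop = FALSE] * A[k, , drop = FALSE])
  acc(g, k, w * m * Qm1[k, , drop = FALSE] * A[r, , drop = FALSE])
}

#' Jointly optimize the embedding and the cluster centroids
#'
#' Phase-2 training: the pretrained encoder defines the initial embedding,
#' centroids are initialized by [init_centers()], and the full objective
#' (see [objective_config()]) is minimized by mini-batch Adam over the
#' encoder weights and centroids jointly.  The target distribution `P` is
#' recomputed on the full dataset every `update_interval` batches and held
#' fixed in between; at each refresh the hard assignments are compared with
#' the previous refresh and training stops when the changed fraction drops
#' below `tolerance`.  The decoder is discarded in this phase.
#'
#' @param X `n x d` data matrix the autoencoder was pretrained on.
#' @param ae an `autoencoder_state` from [pretrain()].
#' @param constraints a [constraint_set()] validated against `n`, or `NULL`
#'   for unconstrained training (the DEC reduction).
#' @param cfg a [train_config()].
#' @param true_labels optional ground-truth labels; when supplied, ACC and
#'   NMI are recorded at every refresh (evaluation only, never used by the
#'   optimization).
#' @param on_refresh optional callback `function(iter, P, labels)` invoked at
#'   every target refresh (diagnostics).
#' @return An object of class `train_result`: `labels` (0-based hard
#'   assignments, ties broken toward the lowest cluster index), `Q_final`,
#'   `centroids`, `objective_trace`, the per-refresh `metric_trace` data
#'   frame, `iterations_run`, `converged`, and the final `encoder`.
#' @export
dcssdec_train <- function(X, ae, constraints = NULL, cfg,
                          true_labels = NULL, on_refresh = NULL) {
  stopifnot(inherits(ae, "autoencoder_state"), inherits(cfg, "train_config"))
  X <- as_numeric_matrix(X)
  n <- nrow(X)
  if (ncol(X) != ae$spec$layer_dims[1L]) {
    stop("X does not match the autoencoder input dimension", call. = FALSE)
  }
  if (!is.null(constraints)) {
    constraints <- validate_constraints(constraints, n)
    if (n_constraints(constraints) == 0L) constraints <- NULL
  }
  ocfg <- cfg$objective_cfg
  alpha <- ocfg$alpha; m <- ocfg$fuzzifier_m
  g1 <- ocfg$gamma1; g2 <- ocfg$gamma2
  bs <- min(cfg$batch_size, n)
  encoder <- ae$encoder
  mu <- init_centers(mlp_forward(encoder, X)$out, cfg)
  S <- if (is.null(constraints)) NULL else constraints$should_link
  SN <- if (is.null(constraints)) NULL else constraints$shouldnot_link

  params <- c(net_params(encoder), list(mu))
  opt <- adam_new(params, lr = cfg$learning_rate)
  n_enc <- length(net_params(encoder))

  trace <- list()
  prev_labels <- NULL
  labels <- NULL
  Q_full <- NULL
  P_full <- NULL
  converged <- FALSE
  aborted <- FALSE
  iterations_run <- 0L
  expo <- (alpha + 3) / (alpha + 1)
  coef <- (alpha + 1) / alpha

  with_seed(derive_seed(cfg$seed, 1L), {
    perm <- sample.int(n)
    for (iter in 0:(cfg$max_iterations - 1L)) {
      if (iter %% cfg$update_interval == 0L) {
        Z_full <- mlp_forward(encoder, X)$out
        Q_new <- soft_assign(Z_full, mu, alpha)
        P_new <- target_distribution(Q_new)
        labels_new <- max.col(Q_new, ties.method = "first")
        J <- objective(P_new, Q_new, constraints, ocfg)
        if (!is.finite(J)) {
          warning("non-finite objective at iteration ", iter,
                  "; aborting with the last good state")
          aborted <- TRUE
          break
        }
        Q_full <- Q_new
        P_full <- P_new
        labels <- labels_new
        delta <- if (is.null(prev_labels)) NA_real_
                 else mean(labels != prev_labels)
        row <- data.frame(iteration = iter, objective = J, delta = delta,
                          acc = NA_real_, nmi = NA_real_)
        if (!is.null(true_labels)) {
          row$acc <- clustering_accuracy(true_labels, labels)$acc
          row$nmi <- normalized_mutual_information(true_labels, labels)
        }
        trace[[length(trace) + 1L]] <- row
        if (!is.null(on_refresh)) on_refresh(iter, P_full, labels)
        if (!is.na(delta) && delta < cfg$tolerance) {
          converged <- TRUE
          break
        }
        prev_labels <- labels
      }
      # --- one mini-batch gradient step on theta and mu ---
      pos <- (iter * bs + 0:(bs - 1L)) %% n + 1L
      idx <- perm[pos]
      extra <- integer(0)
      Sb <- NULL; SNb <- NULL; scale_S <- 1; scale_SN <- 1
      if (!is.null(constraints)) {
        if (cfg$constraint_mode == "within_batch") {
          pos_of <- integer(n); pos_of[idx] <- seq_along(idx)
          if (nrow(S)) {
            sel <- pos_of[S[, 1L]] > 0L & pos_of[S[, 2L]] > 0L
            if (any(sel)) {
              Sb <- cbind(pos_of[S[sel, 1L]], pos_of[S[sel, 2L]])
              scale_S <- nrow(S) / nrow(Sb)
            }
          }
          if (nrow(SN)) {
            sel <- pos_of[SN[, 1L]] > 0L & pos_of[SN[, 2L]] > 0L
            if (any(sel)) {
              SNb <- cbind(pos_of[SN[sel, 1L]], pos_of[SN[sel, 2L]])
              scale_SN <- nrow(SN) / nrow(SNb)
            }
          }
        } else {  # pair_batch: sample pairs, append their endpoints
          take <- function(P) {
            if (nrow(P) == 0L) return(NULL)
            P[sample.int(nrow(P), min(cfg$pair_batch_size, nrow(P))), ,
              drop = FALSE]
          }
          Ss <- take(S); SNs <- take(SN)
          extra <- setdiff(unique(as.vector(rbind(Ss, SNs))), idx)
          all_idx <- c(idx, extra)
          pos_of <- integer(n); pos_of[all_idx] <- seq_along(all_idx)
          if (!is.null(Ss)) {
            Sb <- cbind(pos_of[Ss[, 1L]], pos_of[Ss[, 2L]])
            scale_S <- nrow(S) / nrow(Sb)
          }
          if (!is.null(SNs)) {
            SNb <- cbind(pos_of[SNs[, 1L]], pos_of[SNs[, 2L]])
            scale_SN <- nrow(SN) / nrow(SNb)
          }
          idx <- all_idx
        }
      }
      nb <- length(idx)
      n_kl <- nb - length(extra)
      cache <- mlp_forward(encoder, X[idx, , drop = FALSE],
                           keep_cache = TRUE)
      Zb <- cache$out
      D2 <- pairwise_sqdist(Zb, mu)
      U <- (1 + D2 / alpha)^(-(alpha + 1) / 2)
      s <- rowSums(U)
      Qb <- U / s
      # dJ/dQ: KL part (only the primary batch rows), full-data scale
      g <- -(n / n_kl) * P_full[idx, , drop = FALSE] / pmax(Qb, 1e-12)
      if (length(extra)) g[(n_kl + 1L):nb, ] <- 0
      if (!is.null(Sb)) {
        g <- add_pair_grad(g, Qb, Sb[, 1L], Sb[, 2L], m, -g1 * scale_S)
      }
      if (!is.null(SNb)) {
        g <- add_pair_grad(g, Qb, SNb[, 1L], SNb[, 2L], m, g2 * scale_SN)
      }
      # chain rule through the Student's-t kernel into Z and mu
      a <- (g - rowSums(g * Qb)) / s
      B <- coef * a * U^expo
      dZ <- B %*% mu - Zb * rowSums(B)
      dMu <- crossprod(B, Zb) - mu * colSums(B)
      grads <- mlp_backward(encoder, cache, dZ)
      step <- adam_step(opt, params, c(grads$dW, grads$db, list(dMu)))
      opt <- step$opt; params <- step$params
      encoder <- net_set_params(encoder, params[seq_len(n_enc)])
      mu <- params[[n_enc + 1L]]
      iterations_run <- iter + 1L
    }
    if (!converged && !aborted) {
      # trajectory exhausted max_iterations: record the final state
      Z_full <- mlp_forward(encoder, X)$out
      Q_full <- soft_assign(Z_full, mu, alpha)
      labels <- max.col(Q_full, ties.method = "first")
    }
  })
  trace <- do.call(rbind, trace)
  structure(
    list(labels = labels - 1L, Q_final = Q_full, centroids = mu,
         objective_trace = trace$objective, metric_trace = trace,
         iterations_run = iterations_run, converged = converged,
         encoder = encoder, config = cfg),
    class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "train_result: %d instances, %d clusters, %d iterations, converged=%s\n",
    length(x$labels), ncol(x$Q_final), x$iterations_run, x$converged))
  if (!is.null(x$metric_trace) && nrow(x$metric_trace) &&
      !all(is.na(x$metric_trace$acc))) {
    last <- x$metric_trace[nrow(x$metric_trace), ]
    cat(sprintf("  final ACC = %.4f, NMI = %.4f\n", last$acc, last$nmi))
  }
  invisible(x)
}
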
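#' Configuration of the clustering objective
#'
#' The objective combines a KL self-training term with two soft-constraint
#' terms:
#' \deqn{J = \sum_i \sum_j p_{ij} \log(p_{ij}/q_{ij})
#'       - \gamma_1 \sum_{(r,k) \in S} \sum_j q_{rj}^m q_{kj}^m
#'       + \gamma_2 \sum_{(r,k) \in S_N} \sum_j q_{rj}^m q_{kj}^m}
#' where `S` is the should-link set (rewarded) and `S_N` the shouldNot-link
#' set (penalized).  The fuzzifier `m` enters only the constraint terms.
#'
#' @param gamma1 trade-off weight of the should-link reward term.
#' @param gamma2 trade-off weight of the shouldNot-link penalty term.
#' @param fuzzifier_m fuzzifier exponent, must be > 1 (default 2).
#' @param alpha degrees of freedom of the Student's-t assignment kernel
#'   (default 1).
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(gamma1 = 1, gamma2 = 1, fuzzifier_m = 2,
                             alpha = 1) {
  stop_if_not_scalar(gamma1, "gamma1")
  stop_if_not_scalar(gamma2, "gamma2")
  stop_if_not_scalar(fuzzifier_m, "fuzzifier_m", lower = 1,
                     strict_lower = TRUE)
  stop_if_not_scalar(alpha, "alpha", lower = 0, strict_lower = TRUE)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, fuzzifier_m = fuzzifier_m,
                 alpha = alpha),
            class = "objective_config")
}

# Squared Euclidean distances between rows of Z (n x d') and rows of mu
# (C x d'); negative round-off clamped at 0.
pairwise_sqdist <- function(Z, mu) {
  D2 <- matrix(rowSums(Z^2), nrow(Z), nrow(mu)) +
    matrix(rowSums(mu^2), nrow(Z), nrow(mu), byrow = TRUE) -
    2 * Z %*% t(mu)
  D2[D2 < 0] <- 0
  D2
}

#' Student's-t soft assignment
#'
#' Fuzzy membership of each embedded point to each cluster centroid:
#' \deqn{q_{ij} = (1 + \|z_i - \mu_j\|^2/\alpha)^{-(\alpha+1)/2} \big/
#'       \sum_{j'} (1 + \|z_i - \mu_{j'}\|^2/\alpha)^{-(\alpha+1)/2}}
#' Rows sum to 1.  `alpha = 1` (the default used throughout) reduces the
#' kernel to \eqn{(1 + \|z_i - \mu_j\|^2)^{-1}} before normalization.
#'
#' @param Z numeric `n x d'` embedding matrix.
#' @param mu numeric `C x d'` centroid matrix, `C >= 2`.
#' @param alpha positive degrees of freedom.
#' @return Row-stochastic `n x C` membership matrix `Q`.
#' @export
soft_assign <- function(Z, mu, alpha = 1) {
  Z <- as_numeric_matrix(Z, "Z")
  mu <- as_numeric_matrix(mu, "mu")
  if (ncol(Z) != ncol(mu)) stop("Z and mu must share column count",
                                call. = FALSE)
  if (nrow(mu) < 2L) stop("need at least 2 centroids", call. = FALSE)
  if (!all(is.finite(Z))) stop("non-finite entries in Z", call. = FALSE)
  if (!all(is.finite(mu))) stop("non-finite entries in mu", call. = FALSE)
  U <- (1 + pairwise_sqdist(Z, mu) / alpha)^(-(alpha + 1) / 2)
  U / rowSums(U)
}

#' Auxiliary target distribution
#'
#' Sharpened self-training target: each membership is squared and
#' normalized by the soft cluster frequency \eqn{f_j = \sum_i q_{ij}}, then
#' renormalized per row:
#' \deqn{p_{ij} = (q_{ij}^2 / f_j) \big/ \sum_{j'} (q_{ij'}^2 / f_{j'})}
#' A cluster with zero soft mass contributes zero target mass (denominators
#' are guarded by 1e-12) rather than NaN.
#'
#' @param Q row-stochastic `n x C` membership matrix.
#' @return Row-stochastic `n x C` target matrix `P`.
#' @export
target_distribution <- function(Q) {
  Q <- as_numeric_matrix(Q, "Q")
  f <- colSums(Q)
  W <- sweep(Q^2, 2L, f + 1e-12, "/")
  W / (rowSums(W) + 1e-12)
}

#' KL self-training term
#'
#' \eqn{\sum_i \sum_j p_{ij} \log(p_{ij}/q_{ij})} with natural logarithm and
#' the continuity convention \eqn{0 \log 0 = 0}.  Always nonnegative (sum of
#' per-row KL divergences).
#'
#' @param P target matrix.
#' @param Q membership matrix, same shape; must be positive wherever `P` is.
#' @return A nonnegative scalar.
#' @export
kl_term <- function(P, Q) {
  P <- as_numeric_matrix(P, "P"); Q <- as_numeric_matrix(Q, "Q")
  if (!all(dim(P) == dim(Q))) stop("P and Q must have the same shape",
                                   call. = FALSE)
  pos <- P > 0
  if (any(Q[pos] == 0)) {
    stop("KL divergence is infinite: P > 0 where Q = 0", call. = FALSE)
  }
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' Soft pairwise constraint term
#'
#' \eqn{\sum_{(r,k)} \sum_j q_{rj}^m q_{kj}^m} over the given pairs.  High
#' when paired instances share concentrated membership on the same cluster,
#' near zero when their memberships are disjoint.
#'
#' @param Q membership matrix.
#' @param pairs two-column matrix of 1-based row-index pairs (or `NULL`).
#' @param m fuzzifier exponent, > 1.
#' @return A nonnegative scalar; 0 for empty `pairs`.
#' @export
constraint_term <- function(Q, pairs, m = 2) {
  Q <- as_numeric_matrix(Q, "Q")
  if (nrow(Q) == 0L) stop("empty membership matrix", call. = FALSE)
  stop_if_not_scalar(m, "m", lower = 1, strict_lower = TRUE)
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0L) return(0)
  if (max(pairs) > nrow(Q) || min(pairs) < 1L) {
    stop("pair index out of range for Q", call. = FALSE)
  }
  A <- Q^m
  sum(A[pairs[, 1L], , drop = FALSE] * A[pairs[, 2L], , drop = FALSE])
}

#' Full clustering objective
#'
#' `kl_term(P, Q) - gamma1 * constraint_term(Q, should_link, m) +
#'  gamma2 * constraint_term(Q, shouldnot_link, m)`.  With
#' `gamma1 = gamma2 = 0` (or an empty constraint set) this reduces to the
#' unconstrained KL self-training objective of deep embedded clustering.
#'
#' @param P target matrix.
#' @param Q membership matrix.
#' @param cs a [constraint_set()] (or `NULL` for unconstrained).
#' @param cfg an [objective_config()].
#' @return A scalar.
#' @export
objective <- function(P, Q, cs = NULL, cfg = objective_config()) {
  stopifnot(inherits(cfg, "objective_config"))
  J <- kl_term(P, Q)
  if (is.null(cs)) return(J)
  stopifnot(inherits(cs, "constraint_set"))
  m <- cfg$fuzzifier_m
  J - cfg$gamma1 * constraint_term(Q, cs$should_link, m) +
    cfg$gamma2 * constraint_term(Q, cs$shouldnot_link, m)
}

#' Write a membership (or target) matrix as CSV
#'
#' One row per instance, one column per cluster, in cluster-index order.
#'
#' @param Q matrix to write.
#' @param path output path.
#' @export
write_membership <- function(Q, path) write_matrix(Q, path, format = "csv")
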
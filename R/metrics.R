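#' Unsupervised clustering accuracy
#'
#' Fraction of instances correctly grouped under the best one-to-one
#' correspondence between predicted clusters and true classes:
#' \deqn{ACC = \max_m \frac{1}{n} \sum_i 1\{l_i = m(c_i)\}}
#' The maximum over matchings is found exactly on the contingency table by
#' maximum-weight bipartite matching (Hungarian-equivalent).  Unequal
#' cluster counts are handled by leaving surplus clusters unmatched
#' (zero-weight padding).
#'
#' @param labels_true integer/factor vector of ground-truth classes.
#' @param labels_pred integer/factor vector of predicted clusters, same
#'   length.
#' @return A list with `acc` (scalar in `[0, 1]`), `mapping` (named vector:
#'   for each predicted cluster the matched true class, `NA` if unmatched)
#'   and `contingency` (predicted x true count table).
#' @export
clustering_accuracy <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_true)
  if (n < 1L) stop("need at least one instance", call. = FALSE)
  tab <- table(pred = factor(labels_pred), true = factor(labels_true))
  Cp <- nrow(tab); Ct <- ncol(tab)
  if (Cp == 1L || Ct == 1L) {
    # a single cluster on either side: best matching picks the largest cell
    best <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    mapping <- rep(NA_character_, Cp)
    names(mapping) <- rownames(tab)
    mapping[best[["pred"]]] <- colnames(tab)[best[["true"]]]
    return(list(acc = max(tab) / n, mapping = mapping, contingency = tab))
  }
  g <- igraph::make_empty_graph(Cp + Ct, directed = FALSE)
  idx <- which(tab > 0, arr.ind = TRUE)
  edges <- rbind(idx[, 1L], Cp + idx[, 2L])
  g <- igraph::add_edges(g, as.vector(edges))
  igraph::V(g)$type <- c(rep(FALSE, Cp), rep(TRUE, Ct))
  igraph::E(g)$weight <- tab[idx]
  m <- igraph::max_bipartite_match(g)
  matched <- m$matching[seq_len(Cp)]          # vertex id of matched class
  mapping <- ifelse(is.na(matched), NA_character_,
                    colnames(tab)[matched - Cp])
  names(mapping) <- rownames(tab)
  list(acc = m$matching_weight / n, mapping = mapping, contingency = tab)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' \deqn{NMI = \frac{MI(c, l)}{\max(H(c), H(l))}}
#' with mutual information and entropies computed from the empirical joint
#' distribution (natural log; the base cancels).  Identical partitions give
#' 1, independent partitions give 0.  If both partitions are single-cluster
#' (both entropies zero) they are identical and the value is defined as 1.
#'
#' @inheritParams clustering_accuracy
#' @return A scalar in `[0, 1]`.
#' @export
normalized_mutual_information <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_true)
  if (n < 1L) stop("need at least one instance", call. = FALSE)
  joint <- table(factor(labels_pred), factor(labels_true)) / n
  pc <- rowSums(joint); pl <- colSums(joint)
  Hc <- entropy_nats(pc); Hl <- entropy_nats(pl)
  if (Hc == 0 && Hl == 0) return(1)
  outer_p <- outer(pc, pl)
  pos <- joint > 0
  mi <- sum(joint[pos] * log(joint[pos] / outer_p[pos]))
  max(0, min(1, mi / max(Hc, Hl)))
}

#' Evaluate a clustering against ground truth
#'
#' @inheritParams clustering_accuracy
#' @return An object of class `eval_report`: list with `acc`, `nmi`,
#'   `mapping`, `contingency` and `n`.
#' @export
evaluate_clustering <- function(labels_true, labels_pred) {
  acc <- clustering_accuracy(labels_true, labels_pred)
  structure(list(acc = acc$acc,
                 nmi = normalized_mutual_information(labels_true,
                                                     labels_pred),
                 mapping = acc$mapping, contingency = acc$contingency,
                 n = length(labels_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("clustering evaluation (n=%d): ACC = %.4f, NMI = %.4f\n",
              x$n, x$acc, x$nmi))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(acc = report$acc, nmi = report$nmi,
         mapping = as.list(report$mapping), n = report$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
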
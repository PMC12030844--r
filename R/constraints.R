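#' Construct a soft pairwise constraint set
#'
#' Holds the "should-link" set (pairs expected to share a cluster) and the
#' "shouldNot-link" set (pairs expected to fall in different clusters).
#' Pairs are unordered, stored with `i < j` using 1-based in-memory indices;
#' on disk the TSV format uses 0-based indices (see
#' [write_constraints()]).
#'
#' @param should_link,shouldnot_link two-column integer matrices (or
#'   `NULL`/empty) of instance-index pairs, 1-based.
#' @param n_instances number of instances the indices refer to.
#' @param beta constraint ratio: total pairs = `round(beta * n_instances)`.
#' @param seed seed used to draw the pairs (recorded for provenance).
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(should_link = NULL, shouldnot_link = NULL,
                           n_instances, beta = NA_real_, seed = NA_integer_) {
  n_instances <- stop_if_not_count(n_instances, "n_instances")
  cs <- structure(
    list(should_link = as_pair_matrix(should_link),
         shouldnot_link = as_pair_matrix(shouldnot_link),
         n_instances = n_instances, beta = beta, seed = seed),
    class = "constraint_set")
  validate_constraints(cs, n_instances)
}

as_pair_matrix <- function(p) {
  if (is.null(p) || length(p) == 0L) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  }
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("pairs must be a 2-column matrix", call. = FALSE)
  storage.mode(p) <- "integer"
  dimnames(p) <- list(NULL, c("i", "j"))
  p
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf(
    "constraint_set: %d should-link, %d shouldNot-link (n=%d, beta=%s)\n",
    nrow(x$should_link), nrow(x$shouldnot_link), x$n_instances,
    format(x$beta)))
  invisible(x)
}

canonicalize_pairs <- function(p) {
  if (nrow(p) == 0L) return(p)
  swap <- p[, 1L] > p[, 2L]
  p[swap, ] <- p[swap, c(2L, 1L)]
  p <- unique(p)
  p[order(p[, 1L], p[, 2L]), , drop = FALSE]
}

#' Validate and canonicalize a constraint set
#'
#' Reorders each pair to `i < j`, drops duplicates, and rejects
#' self-pairs, out-of-range indices and pairs present in both sets
#' (contradictory supervision).
#'
#' @param cs a `constraint_set`.
#' @param n number of instances indices must not exceed.
#' @return The canonicalized `constraint_set`.
#' @export
validate_constraints <- function(cs, n) {
  stopifnot(inherits(cs, "constraint_set"))
  n <- stop_if_not_count(n, "n")
  check <- function(p, what) {
    if (nrow(p) == 0L) return(p)
    bad <- which(p[, 1L] == p[, 2L])
    if (length(bad)) {
      stop(sprintf("self-pair (%d, %d) in %s set", p[bad[1L], 1L],
                   p[bad[1L], 2L], what), call. = FALSE)
    }
    bad <- which(p[, 1L] < 1L | p[, 2L] < 1L | p[, 1L] > n | p[, 2L] > n)
    if (length(bad)) {
      stop(sprintf("out-of-range pair (%d, %d) in %s set for n=%d",
                   p[bad[1L], 1L], p[bad[1L], 2L], what, n), call. = FALSE)
    }
    canonicalize_pairs(p)
  }
  cs$should_link <- check(cs$should_link, "should-link")
  cs$shouldnot_link <- check(cs$shouldnot_link, "shouldNot-link")
  key <- function(p) paste(p[, 1L], p[, 2L])
  both <- intersect(key(cs$should_link), key(cs$shouldnot_link))
  if (length(both)) {
    stop("pair(s) present in both constraint sets (contradictory ",
         "supervision): ", both[1L], call. = FALSE)
  }
  cs$n_instances <- n
  cs
}

# Decode linear indices 1..n(n-1)/2 into unordered pairs (i < j), ordered
# lexicographically.  Doubles carry the arithmetic exactly for n well beyond
# anything this package handles (n(n-1)/2 < 2^53).
decode_pair_index <- function(k, n) {
  k <- as.double(k)
  cum <- function(i) i * n - i * (i + 1) / 2   # pairs with first index <= i
  i <- floor(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  i <- pmax(1, pmin(n - 1, i))
  # local adjustment for floating-point edge cases
  too_high <- cum(i - 1) >= k
  while (any(too_high)) { i[too_high] <- i[too_high] - 1; too_high <- cum(i - 1) >= k }
  too_low <- cum(i) < k
  while (any(too_low)) { i[too_low] <- i[too_low] + 1; too_low <- cum(i) < k }
  j <- i + (k - cum(i - 1))
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Generate soft pairwise constraints from ground-truth labels
#'
#' Draws `round(beta * N)` distinct unordered instance pairs uniformly at
#' random without replacement, then classifies each by label agreement: equal
#' labels make a should-link pair, unequal labels a shouldNot-link pair.
#' `beta` may exceed 1; the requested count is capped (with a warning) at
#' `N (N-1) / 2`.
#'
#' @param labels integer vector of ground-truth labels (length `N >= 2`).
#' @param beta nonnegative constraint ratio.
#' @param seed integer seed; the draw is deterministic given `labels`
#'   order, `beta` and `seed`.
#' @return A [constraint_set()].
#' @export
generate_constraints <- function(labels, beta, seed = 0L) {
  n <- length(labels)
  if (n < 2L) stop("need at least 2 labeled instances", call. = FALSE)
  beta <- stop_if_not_scalar(beta, "beta", lower = 0)
  n_pairs <- round(beta * n)
  max_pairs <- n * (n - 1) / 2
  if (n_pairs > max_pairs) {
    warning(sprintf("requested %d pairs exceeds the %d available; capping",
                    n_pairs, max_pairs))
    n_pairs <- max_pairs
  }
  if (n_pairs == 0L) {
    return(constraint_set(NULL, NULL, n_instances = n, beta = beta,
                          seed = as.integer(seed)))
  }
  pairs <- with_seed(seed, {
    ks <- sample(max_pairs, n_pairs)   # without replacement
    decode_pair_index(ks, n)
  })
  same <- labels[pairs[, 1L]] == labels[pairs[, 2L]]
  constraint_set(pairs[same, , drop = FALSE], pairs[!same, , drop = FALSE],
                 n_instances = n, beta = beta, seed = as.integer(seed))
}

#' Write a constraint set to TSV
#'
#' Three tab-separated columns `i  j  type` with `type` in `{SL, SNL}` and
#' 0-based indices; a `#i  j  type` header line is written and `#`-prefixed
#' comment lines are permitted on read.
#'
#' @param cs a `constraint_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_constraints <- function(cs, path) {
  stopifnot(inherits(cs, "constraint_set"))
  rows <- c("#i\tj\ttype",
            if (nrow(cs$should_link))
              sprintf("%d\t%d\tSL", cs$should_link[, 1L] - 1L,
                      cs$should_link[, 2L] - 1L),
            if (nrow(cs$shouldnot_link))
              sprintf("%d\t%d\tSNL", cs$shouldnot_link[, 1L] - 1L,
                      cs$shouldnot_link[, 2L] - 1L))
  writeLines(rows, path)
  invisible(path)
}

#' Read a constraint set from TSV
#'
#' @param path file written in the [write_constraints()] format.
#' @param n_instances number of instances, for index validation.
#' @return A validated [constraint_set()].
#' @export
read_constraints <- function(path, n_instances) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(constraint_set(NULL, NULL, n_instances = n_instances))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed constraint line %d in %s", bad[1L], path),
         call. = FALSE)
  }
  tab <- do.call(rbind, parts)
  i <- suppressWarnings(as.integer(tab[, 1L])) + 1L
  j <- suppressWarnings(as.integer(tab[, 2L])) + 1L
  type <- toupper(trimws(tab[, 3L]))
  if (anyNA(i) || anyNA(j) || !all(type %in% c("SL", "SNL"))) {
    stop("constraint file has non-integer indices or unknown type: ", path,
         call. = FALSE)
  }
  constraint_set(cbind(i, j)[type == "SL", , drop = FALSE],
                 cbind(i, j)[type == "SNL", , drop = FALSE],
                 n_instances = n_instances)
}

n_constraints <- function(cs) nrow(cs$should_link) + nrow(cs$shouldnot_link)

empty_constraints <- function(n) constraint_set(NULL, NULL, n_instances = n,
                                                beta = 0)
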
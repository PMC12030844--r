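#' Specification of a synthetic labeled dataset
#'
#' Describes a cluster-structured dataset with controllable separation,
#' class imbalance and noise.  `separation` is the distance between cluster
#' means measured in units of the within-cluster standard deviation
#' `noise_sd`, so e.g. `separation = 10` yields essentially
#' non-overlapping clusters while `separation = 3` yields clusters whose
#' tails overlap substantially.
#'
#' @param n_samples number of instances (rows).
#' @param n_features dimensionality `d` of each instance.
#' @param n_clusters number of generating components.
#' @param separation nonnegative distance between cluster means, in units of
#'   `noise_sd`.
#' @param imbalance vector of cluster proportions (length `n_clusters`,
#'   summing to 1).  Defaults to balanced clusters.
#' @param noise_sd nonnegative within-cluster standard deviation per feature.
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec and seed.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_blobs()], [generate_toy_images()]
#' @export
synthetic_spec <- function(n_samples = 1500L, n_features = 50L,
                           n_clusters = 3L, separation = 10,
                           imbalance = NULL, noise_sd = 1, seed = 0L) {
  n_samples <- stop_if_not_count(n_samples, "n_samples")
  n_features <- stop_if_not_count(n_features, "n_features")
  n_clusters <- stop_if_not_count(n_clusters, "n_clusters")
  separation <- stop_if_not_scalar(separation, "separation", lower = 0)
  noise_sd <- stop_if_not_scalar(noise_sd, "noise_sd", lower = 0)
  if (is.null(imbalance)) imbalance <- rep(1 / n_clusters, n_clusters)
  if (length(imbalance) != n_clusters) {
    stop("`imbalance` must have length `n_clusters`", call. = FALSE)
  }
  if (any(imbalance < 0) || abs(sum(imbalance) - 1) > 1e-9) {
    stop("`imbalance` entries must be nonnegative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, n_features = n_features,
         n_clusters = n_clusters, separation = separation,
         imbalance = as.numeric(imbalance), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: n=%d, d=%d, C=%d, separation=%g, noise_sd=%g, seed=%d\n",
    x$n_samples, x$n_features, x$n_clusters, x$separation, x$noise_sd, x$seed))
  invisible(x)
}

# Per-cluster counts: round(imbalance * n), largest cluster absorbs the
# rounding residual so the counts always sum to n.
cluster_counts <- function(spec) {
  counts <- round(spec$imbalance * spec$n_samples)
  residual <- spec$n_samples - sum(counts)
  counts[which.max(counts)] <- counts[which.max(counts)] + residual
  as.integer(counts)
}

new_labeled_dataset <- function(X, labels, spec) {
  structure(list(X = X, labels = as.integer(labels), spec = spec),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d x %d, %d classes\n",
              nrow(x$X), ncol(x$X), length(unique(x$labels))))
  invisible(x)
}

#' Generate isotropic Gaussian blob data
#'
#' Cluster means are placed along mutually orthogonal random directions at
#' radius `separation * noise_sd / sqrt(2)`, which makes every pair of means
#' exactly `separation * noise_sd` apart regardless of dimension.  Rows are
#' drawn from isotropic Gaussians around their component mean and then
#' shuffled (seeded), so cluster membership is not encoded in row order.
#'
#' @param spec a [synthetic_spec()].
#' @return A `labeled_dataset`: list with the `n x d` matrix `X`, the
#'   integer label vector `labels` (values in `0..n_clusters-1`, recording
#'   the generating component; used only for constraint generation and
#'   evaluation), and the `spec`.
#' @export
generate_blobs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; d <- spec$n_features; C <- spec$n_clusters
  if (n < C) stop("n_samples must be >= n_clusters", call. = FALSE)
  if (C > d) {
    stop("generate_blobs places means on orthogonal directions and needs ",
         "n_clusters <= n_features", call. = FALSE)
  }
  counts <- cluster_counts(spec)
  with_seed(spec$seed, {
    dirs <- qr.Q(qr(matrix(stats::rnorm(d * C), d, C)))     # d x C orthonormal
    radius <- spec$separation * spec$noise_sd / sqrt(2)
    means <- t(dirs) * radius                                # C x d
    labels <- rep.int(seq_len(C) - 1L, counts)
    X <- means[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
    perm <- sample.int(n)
    new_labeled_dataset(X[perm, , drop = FALSE], labels[perm], spec)
  })
}

# One binary glyph per class on an s x s grid; the glyph family cycles
# through bar/disk/cross and its position shifts with the class index, so
# classes are distinct even when several share a family.
glyph_image <- function(class_idx, s) {
  img <- matrix(0, s, s)
  family <- class_idx %% 3L
  slot <- class_idx %/% 3L
  offset <- 1L + (slot * max(1L, s %/% 4L)) %% max(1L, s - 2L)
  if (family == 0L) {                       # horizontal bar
    rows <- pmin(s, offset:(offset + max(1L, s %/% 6L)))
    img[rows, ] <- 1
  } else if (family == 1L) {                # filled disk
    cx <- offset + s / 4; cy <- s / 2
    r <- max(1.5, s / 5)
    for (i in seq_len(s)) {
      dist2 <- (i - cx)^2 + (seq_len(s) - cy)^2
      img[i, dist2 <= r^2] <- 1
    }
  } else {                                  # cross
    cx <- pmin(s, offset + s %/% 3L)
    arm <- max(1L, s %/% 8L)
    img[pmax(1L, cx - arm):pmin(s, cx + arm), ] <- 1
    img[, pmax(1L, cx - arm):pmin(s, cx + arm)] <- 1
  }
  img
}

#' Generate toy glyph images
#'
#' Each class is a distinct parametric binary glyph (bar, disk or cross at a
#' class-specific position) on an `image_side x image_side` grid, plus
#' Gaussian pixel noise, flattened row-major to `d = image_side^2` features
#' and clipped to `[0, 1]`.  A desk-scale stand-in for flattened grayscale
#' image datasets.
#'
#' @param spec a [synthetic_spec()]; `n_features` must equal `image_side^2`.
#' @param image_side side length of the square image.
#' @return A `labeled_dataset` (see [generate_blobs()]).
#' @export
generate_toy_images <- function(spec, image_side) {
  stopifnot(inherits(spec, "synthetic_spec"))
  image_side <- stop_if_not_count(image_side, "image_side")
  if (image_side^2 != spec$n_features) {
    stop(sprintf("image_side^2 (%d) must equal n_features (%d)",
                 image_side^2, spec$n_features), call. = FALSE)
  }
  n <- spec$n_samples; C <- spec$n_clusters
  if (n < C) stop("n_samples must be >= n_clusters", call. = FALSE)
  counts <- cluster_counts(spec)
  glyphs <- vapply(seq_len(C) - 1L,
                   function(k) as.vector(t(glyph_image(k, image_side))),
                   numeric(spec$n_features))      # d x C, row-major flattened
  with_seed(spec$seed, {
    labels <- rep.int(seq_len(C) - 1L, counts)
    X <- t(glyphs)[labels + 1L, , drop = FALSE]
    if (spec$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n * spec$n_features, sd = spec$noise_sd),
                      n, spec$n_features)
    }
    X[X < 0] <- 0
    X[X > 1] <- 1
    perm <- sample.int(n)
    new_labeled_dataset(X[perm, , drop = FALSE], labels[perm], spec)
  })
}

#' Write a labeled dataset to plain-text files
#'
#' Writes `<basename>_X.csv` (no header, comma-delimited, one row per
#' instance), `<basename>_labels.csv` (single column) and a JSON sidecar
#' `<basename>_spec.json` recording the generating spec.
#'
#' @param ds a `labeled_dataset`.
#' @param dir output directory (created if missing).
#' @param basename file name stem.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir, basename = "dataset") {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(X = file.path(dir, paste0(basename, "_X.csv")),
             labels = file.path(dir, paste0(basename, "_labels.csv")),
             spec = file.path(dir, paste0(basename, "_spec.json")))
  write_matrix(ds$X, paths[["X"]], format = "csv")
  utils::write.table(ds$labels, paths[["labels"]], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(ds$spec), paths[["spec"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
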
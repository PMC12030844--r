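#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage sub-seed from a master seed
#'
#' Expands one master seed into deterministic per-stage sub-seeds so that
#' independent pipeline stages (data generation, pretraining, training)
#' consume unrelated RNG streams. The result is always below `2^31` and
#' therefore representable as an R integer.
#'
#' @param seed Master seed (single number).
#' @param offset Stage index (single number); different offsets give
#'   different, reproducible sub-seeds.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, 1)
#' derive_seed(1, 2)
#' @export
derive_seed <- function(seed, offset) {
  as.integer((abs(as.double(seed)) * 69069 + 12345 * as.double(offset)) %%
               .Machine$integer.max)
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

stop_if_not_scalar <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]%s", name,
                 lower, upper,
                 if (strict_lower) " (lower bound exclusive)" else ""),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

as_numeric_matrix <- function(X, name = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}
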
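#' Named hyper-parameter presets
#'
#' Published tuned settings for the benchmark and real-world image datasets,
#' stored verbatim (including negative constraint-term weights) as flat
#' parameter lists.  Presets set hyper-parameters only; they never fetch
#' data.
#'
#' @return A named list of presets, each with `pretrain_epochs`, `beta`,
#'   `fuzzifier_m`, `gamma1`, `gamma2`, `batch_size` and `embed_dim`.
#' @export
dcssdec_presets <- function() {
  list(
    "mnist-table3" = list(pretrain_epochs = 400L, beta = 0.3,
                          fuzzifier_m = 2, gamma1 = -10, gamma2 = 10,
                          batch_size = 256L, embed_dim = 10L),
    "usps-table3" = list(pretrain_epochs = 200L, beta = 1,
                         fuzzifier_m = 2, gamma1 = -1, gamma2 = -1,
                         batch_size = 128L, embed_dim = 10L),
    "stl10-table3" = list(pretrain_epochs = 10L, beta = 1,
                          fuzzifier_m = 2, gamma1 = 1, gamma2 = 100,
                          batch_size = 256L, embed_dim = 10L),
    "chestxray-table5" = list(pretrain_epochs = 20L, beta = 1,
                              fuzzifier_m = 2, gamma1 = 1, gamma2 = 1,
                              batch_size = 64L, embed_dim = 10L),
    "dermamnist-table7" = list(pretrain_epochs = 30L, beta = 0.3,
                               fuzzifier_m = 2, gamma1 = 1, gamma2 = 1,
                               batch_size = 64L, embed_dim = 10L),
    "digitssl-table9" = list(pretrain_epochs = 80L, beta = 2,
                             fuzzifier_m = 2, gamma1 = -1, gamma2 = 1,
                             batch_size = 32L, embed_dim = 10L)
  )
}

#' Resolve a preset name into run-configuration defaults
#'
#' @param name one of `names(dcssdec_presets())`.
#' @return The preset parameter list.
#' @export
resolve_preset <- function(name) {
  presets <- dcssdec_presets()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}
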
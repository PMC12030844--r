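dcssdec_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

log_stage <- function(verbose, stage, ...) {
  if (verbose) {
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(...)))
  }
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with the fields accepted by [run_dcssdec()].
#' @return The configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    dcssdec_error(paste0("config file not found: ", path),
                  "dcssdec_data_error")
  }
  yaml::read_yaml(path)
}

#' Run the full clustering pipeline
#'
#' Executes pretraining, centroid initialization, joint optimization and
#' (when ground truth is available) evaluation, and writes all artifacts to
#' `output_dir`.  The configuration list supports:
#' \describe{
#'   \item{data_path / data_format}{delimited matrix input, or}
#'   \item{synthetic}{list of [synthetic_spec()] arguments plus optional
#'     `generator` (`"blobs"`, default, or `"images"`) and `image_side`.}
#'   \item{labels_path}{optional single-column CSV of ground-truth labels
#'     (0-based); implied by `synthetic`.}
#'   \item{constraints_path OR beta}{at most one: a constraint TSV, or a
#'     ratio for [generate_constraints()] (requires labels).}
#'   \item{preset}{optional name from [dcssdec_presets()]; resolved first,
#'     explicit fields override it.}
#'   \item{autoencoder}{list of [autoencoder_spec()] overrides.}
#'   \item{train}{list of [train_config()] overrides (`n_clusters`
#'     required unless labels determine it).}
#'   \item{objective}{list of [objective_config()] overrides.}
#'   \item{seed}{master seed, expanded into per-module sub-seeds.}
#'   \item{output_dir}{where artifacts are written.}
#' }
#'
#' @param config configuration list (see above) or a YAML path.
#' @param verbose emit stage-prefixed progress lines to stderr.
#' @return Invisibly, a list with the `train_result`, the evaluation report
#'   (or `NULL`) and the output paths.
#' @export
run_dcssdec <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- load_run_config(config)
  seed <- as.integer(config$seed %||% 0L)
  out_dir <- config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  preset <- if (!is.null(config$preset)) resolve_preset(config$preset)
            else list()
  pick <- function(section, field, default) {
    config[[section]][[field]] %||% preset[[field]] %||% default
  }

  # --- data -------------------------------------------------------------
  labels <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    gen <- syn$generator %||% "blobs"
    spec_args <- syn[setdiff(names(syn), c("generator", "image_side"))]
    spec_args$seed <- spec_args$seed %||% derive_seed(seed, 10L)
    spec <- do.call(synthetic_spec, spec_args)
    ds <- if (gen == "images") {
      generate_toy_images(spec, syn$image_side %||% round(sqrt(spec$n_features)))
    } else {
      generate_blobs(spec)
    }
    X <- ds$X; labels <- ds$labels
    log_stage(verbose, "data", sprintf("generated %d x %d synthetic (%s)",
                                       nrow(X), ncol(X), gen))
  } else if (!is.null(config$data_path)) {
    X <- tryCatch(read_matrix(config$data_path,
                              config$data_format %||% "auto"),
                  error = function(e)
                    dcssdec_error(paste0("[data] ", conditionMessage(e)),
                                  "dcssdec_data_error"))
    log_stage(verbose, "data", sprintf("loaded %d x %d from %s", nrow(X),
                                       ncol(X), config$data_path))
  } else {
    dcssdec_error("config must provide `data_path` or `synthetic`",
                  "dcssdec_usage_error")
  }
  if (!is.null(config$labels_path)) {
    labels <- tryCatch(read_label_vector(config$labels_path),
                       error = function(e)
                         dcssdec_error(paste0("[data] ",
                                              conditionMessage(e)),
                                       "dcssdec_data_error"))
    if (length(labels) != nrow(X)) {
      dcssdec_error("[data] label count does not match data rows",
                    "dcssdec_data_error")
    }
  }
  n <- nrow(X)

  # --- constraints ------------------------------------------------------
  beta <- pick("train", "beta", NULL)
  if (!is.null(config$constraints_path) && !is.null(beta)) {
    dcssdec_error(
      "provide either `constraints_path` or `beta`, not both",
      "dcssdec_usage_error")
  }
  cs <- NULL
  if (!is.null(config$constraints_path)) {
    cs <- tryCatch(read_constraints(config$constraints_path, n),
                   error = function(e)
                     dcssdec_error(paste0("[constraints] ",
                                          conditionMessage(e)),
                                   "dcssdec_data_error"))
  } else if (!is.null(beta) && beta > 0) {
    if (is.null(labels)) {
      dcssdec_error(
        "[constraints] constraint generation (beta > 0) requires labels",
        "dcssdec_usage_error")
    }
    cs <- generate_constraints(labels, beta, seed = derive_seed(seed, 20L))
  }
  log_stage(verbose, "constraints",
            if (is.null(cs)) "none (unconstrained run)"
            else sprintf("%d should-link, %d shouldNot-link",
                         nrow(cs$should_link), nrow(cs$shouldnot_link)))

  # --- objective / configs ---------------------------------------------
  ocfg <- objective_config(
    gamma1 = pick("objective", "gamma1", 1),
    gamma2 = pick("objective", "gamma2", 1),
    fuzzifier_m = pick("objective", "fuzzifier_m", 2),
    alpha = pick("objective", "alpha", 1))
  embed_dim <- pick("autoencoder", "embed_dim", 10L)
  ae_args <- config$autoencoder %||% list()
  ae_args$embed_dim <- NULL
  ae_args$input_dim <- ncol(X)
  ae_args$layer_dims <- ae_args$layer_dims %||%
    c(ncol(X), 500L, 500L, 2000L, embed_dim)
  ae_args$pretrain_epochs <- ae_args$pretrain_epochs %||%
    preset$pretrain_epochs %||% 30L
  ae_args$batch_size <- ae_args$batch_size %||% preset$batch_size %||% 256L
  ae_args$seed <- ae_args$seed %||% derive_seed(seed, 30L)
  ae_spec <- do.call(autoencoder_spec, ae_args)

  n_clusters <- config$train$n_clusters %||%
    (if (!is.null(labels)) length(unique(labels)) else NULL)
  if (is.null(n_clusters)) {
    dcssdec_error("`train$n_clusters` is required when no labels are given",
                  "dcssdec_usage_error")
  }
  tr_args <- config$train %||% list()
  tr_args$beta <- NULL
  tr_args$n_clusters <- n_clusters
  tr_args$batch_size <- tr_args$batch_size %||% preset$batch_size %||% 256L
  tr_args$objective_cfg <- ocfg
  tr_args$seed <- tr_args$seed %||% derive_seed(seed, 40L)
  tr_cfg <- do.call(train_config, tr_args)

  # --- pretrain + train -------------------------------------------------
  log_stage(verbose, "pretrain", sprintf("architecture %s, %d epochs",
                                         paste(ae_spec$layer_dims,
                                               collapse = "-"),
                                         ae_spec$pretrain_epochs))
  ae <- tryCatch(pretrain(X, ae_spec),
                 error = function(e)
                   dcssdec_error(paste0("[pretrain] ",
                                        conditionMessage(e)),
                                 "dcssdec_numeric_error"))
  log_stage(verbose, "train", sprintf("C=%d, batch=%d, tol=%g",
                                      tr_cfg$n_clusters, tr_cfg$batch_size,
                                      tr_cfg$tolerance))
  result <- tryCatch(dcssdec_train(X, ae, cs, tr_cfg, true_labels = labels),
                     error = function(e)
                       dcssdec_error(paste0("[train] ",
                                            conditionMessage(e)),
                                     "dcssdec_numeric_error"))

  # --- evaluate + write artifacts --------------------------------------
  report <- if (!is.null(labels)) evaluate_clustering(labels, result$labels)
  mode <- if (is.null(cs) && ocfg$gamma1 == 0 && ocfg$gamma2 == 0) {
    "DEC-reduction"
  } else if (is.null(cs)) "unconstrained" else "dual-constraint"
  paths <- list(
    labels = file.path(out_dir, "labels.csv"),
    Q = file.path(out_dir, "Q.csv"),
    trace = file.path(out_dir, "objective_trace.csv"),
    ae_loss = file.path(out_dir, "ae_loss_history.csv"),
    checkpoint = file.path(out_dir, "ae_checkpoint.rds"),
    metadata = file.path(out_dir, "run_metadata.json"))
  utils::write.table(result$labels, paths$labels, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write_membership(result$Q_final, paths$Q)
  utils::write.csv(result$metric_trace, paths$trace, row.names = FALSE)
  utils::write.csv(ae$loss_history, paths$ae_loss, row.names = FALSE)
  save_autoencoder(ae, paths$checkpoint)
  if (!is.null(report)) {
    paths$metrics <- file.path(out_dir, "metrics.json")
    write_eval_report(report, paths$metrics)
    log_stage(verbose, "evaluate", sprintf("ACC = %.4f, NMI = %.4f",
                                           report$acc, report$nmi))
  }
  if (!is.null(cs)) {
    paths$constraints <- file.path(out_dir, "constraints.tsv")
    write_constraints(cs, paths$constraints)
  }
  metadata <- list(
    mode = mode, seed = seed, n_instances = n, n_features = ncol(X),
    preset = config$preset, converged = result$converged,
    iterations_run = result$iterations_run,
    n_should_link = if (is.null(cs)) 0L else nrow(cs$should_link),
    n_shouldnot_link = if (is.null(cs)) 0L else nrow(cs$shouldnot_link),
    objective = unclass(ocfg),
    autoencoder = unclass(ae_spec),
    train = unclass(tr_cfg)[setdiff(names(unclass(tr_cfg)),
                                    "objective_cfg")],
    config_echo = config)
  jsonlite::write_json(metadata, paths$metadata, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(list(result = result, report = report, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
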
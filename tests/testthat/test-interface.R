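cli_path <- function() {
  system.file("cli", "dcssdec.R", package = "dcssdec")
}

run_cli <- function(...) {
  res <- suppressWarnings(system2("Rscript", c(cli_path(), ...),
                                  stdout = TRUE, stderr = TRUE))
  list(output = res, status = attr(res, "status") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_run_config <- function(dir, seed = 1, ...) {
  utils::modifyList(list(
    synthetic = list(n_samples = 60L, n_features = 9L, n_clusters = 3L,
                     separation = 8, seed = 5L),
    autoencoder = list(layer_dims = c(9L, 12L, 3L), pretrain_epochs = 5L,
                       batch_size = 30L),
    train = list(n_clusters = 3L, batch_size = 30L, update_interval = 10L,
                 max_iterations = 60L, beta = 0.5),
    seed = seed, output_dir = dir), list(...))
}

test_that("presets record the published tuned hyper-parameters", {
  p <- dcssdec_presets()
  expect_setequal(names(p), c("mnist-table3", "usps-table3", "stl10-table3",
                              "chestxray-table5", "dermamnist-table7",
                              "digitssl-table9"))
  mnist <- resolve_preset("mnist-table3")
  expect_equal(mnist$fuzzifier_m, 2)
  expect_equal(mnist$beta, 0.3)
  expect_equal(mnist$gamma1, -10)
  expect_equal(mnist$gamma2, 10)
  expect_equal(mnist$batch_size, 256L)
  digits <- resolve_preset("digitssl-table9")
  expect_equal(digits$beta, 2)
  expect_equal(digits$gamma1, -1)
  expect_equal(digits$gamma2, 1)
  expect_error(resolve_preset("nope"), "unknown preset")
})

test_that("the full pipeline writes artifacts and evaluates", {
  dir <- withr::local_tempdir()
  out <- run_dcssdec(tiny_run_config(dir), verbose = FALSE)
  expect_true(file.exists(out$paths$labels))
  expect_true(file.exists(out$paths$Q))
  expect_true(file.exists(out$paths$metadata))
  expect_true(file.exists(out$paths$metrics))
  meta <- jsonlite::read_json(out$paths$metadata)
  expect_equal(meta$mode, "dual-constraint")
  expect_gt(meta$n_should_link + meta$n_shouldnot_link, 0L)
  expect_equal(meta$train$n_clusters, 3L)
  labels <- dcssdec:::read_label_vector(out$paths$labels)
  expect_equal(length(labels), 60L)
  expect_true(all(labels %in% 0:2))
})

test_that("a preset drives the run configuration and is echoed", {
  dir <- withr::local_tempdir()
  cfg <- tiny_run_config(dir, preset = "dermamnist-table7")
  cfg$autoencoder$pretrain_epochs <- 3L  # explicit override beats the preset
  out <- run_dcssdec(cfg, verbose = FALSE)
  meta <- jsonlite::read_json(out$paths$metadata)
  expect_equal(meta$preset, "dermamnist-table7")
  expect_equal(meta$objective$gamma1, 1)
  expect_equal(meta$objective$fuzzifier_m, 2)
  expect_equal(meta$autoencoder$pretrain_epochs, 3L)
})

test_that("two identical pipeline runs produce identical label files", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  out1 <- run_dcssdec(tiny_run_config(dir1, seed = 7), verbose = FALSE)
  out2 <- run_dcssdec(tiny_run_config(dir2, seed = 7), verbose = FALSE)
  expect_identical(readLines(out1$paths$labels),
                   readLines(out2$paths$labels))
  expect_identical(readLines(out1$paths$Q), readLines(out2$paths$Q))
})

test_that("unconstrained zero-gamma runs are marked as the DEC reduction", {
  dir <- withr::local_tempdir()
  cfg <- tiny_run_config(dir)
  cfg$train$beta <- NULL
  cfg$objective <- list(gamma1 = 0, gamma2 = 0)
  out <- run_dcssdec(cfg, verbose = FALSE)
  meta <- jsonlite::read_json(out$paths$metadata)
  expect_equal(meta$mode, "DEC-reduction")
})

test_that("constraint generation without labels is a usage error", {
  dir <- withr::local_tempdir()
  ds <- generate_blobs(synthetic_spec(n_samples = 30, n_features = 6,
                                      n_clusters = 2, seed = 3))
  xp <- file.path(dir, "X.csv")
  write_matrix(ds$X, xp)
  cfg <- list(data_path = xp,
              autoencoder = list(layer_dims = c(6L, 8L, 2L),
                                 pretrain_epochs = 2L),
              train = list(n_clusters = 2L, beta = 0.5,
                           max_iterations = 10L, update_interval = 5L),
              output_dir = dir)
  expect_error(run_dcssdec(cfg, verbose = FALSE), "requires labels",
               class = "dcssdec_usage_error")
})

test_that("config YAML round-trips through the loader", {
  dir <- withr::local_tempdir()
  cfg <- tiny_run_config(dir)
  yp <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, yp)
  loaded <- load_run_config(yp)
  expect_equal(loaded$train$n_clusters, 3L)
  expect_equal(loaded$synthetic$n_samples, 60L)
})

test_that("the simulate subcommand writes deterministic files", {
  dir <- withr::local_tempdir()
  args <- c("simulate", "--n", "40", "--d", "8", "--clusters", "2",
            "--separation", "6", "--seed", "3", "--out", dir)
  res <- run_cli(args)
  expect_equal(res$status, 0L)
  files <- file.path(dir, paste0("dataset_", c("X.csv", "labels.csv",
                                               "spec.json")))
  expect_true(all(file.exists(files)))
  hash1 <- tools::md5sum(files)
  res2 <- run_cli(args)
  expect_equal(res2$status, 0L)
  expect_identical(unname(tools::md5sum(files)), unname(hash1))
})

test_that("the CLI rejects invalid usage with exit code 2", {
  res <- run_cli(c("simulate", "--clusters", "0", "--out", tempdir()))
  expect_equal(res$status, 2L)
  res <- run_cli("frobnicate")
  expect_equal(res$status, 2L)
})

test_that("make-constraints emits a loadable constraint file", {
  dir <- withr::local_tempdir()
  labels <- rep(0:2, each = 6)
  lp <- file.path(dir, "labels.csv")
  utils::write.table(labels, lp, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  cp <- file.path(dir, "cons.tsv")
  res <- run_cli(c("make-constraints", "--labels", lp, "--beta", "1",
                   "--seed", "2", "--out", cp))
  expect_equal(res$status, 0L)
  cs <- read_constraints(cp, length(labels))
  expect_equal(dcssdec:::n_constraints(cs), 18L)
})
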
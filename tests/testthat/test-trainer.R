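test_that("centroid initialization finds exact centers of repeated points", {
  pts <- rbind(c(0, 0), c(5, 5), c(-4, 2))
  Z <- pts[rep(1:3, each = 10), ]
  cfg <- quick_cfg(C = 3, seed = 1)
  mu <- init_centers(Z, cfg)
  expect_equal(attr(mu, "wcss_runs"), rep(0, cfg$kmeans_restarts))
  expect_equal(mu[order(mu[, 1L]), ], pts[order(pts[, 1L]), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("centroid initialization is deterministic and best-of-restarts", {
  set.seed(71)
  Z <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2),
             matrix(rnorm(100, -4), 50, 2))
  cfg <- quick_cfg(C = 3, seed = 2)
  a <- init_centers(Z, cfg)
  b <- init_centers(Z, cfg)
  expect_identical(a, b)
  best <- sum(vapply(seq_len(nrow(Z)), function(i)
    min(colSums((t(a) - Z[i, ])^2)), numeric(1)))
  expect_true(all(best <= attr(a, "wcss_runs") + 1e-8))
  expect_error(init_centers(Z[1:2, ], cfg), "fewer instances")
})

test_that("analytic batch gradients match finite differences", {
  set.seed(77)
  n <- 7; C <- 3; dp <- 4; alpha <- 1; m <- 2
  Z <- matrix(rnorm(n * dp), n, dp)
  mu <- matrix(rnorm(C * dp), C, dp)
  P <- target_distribution(soft_assign(Z + rnorm(n * dp, sd = 0.2), mu))
  S <- rbind(c(1, 2), c(3, 4)); SN <- rbind(c(2, 5), c(6, 7))
  g1 <- 0.8; g2 <- 1.4; sS <- 1.7; sSN <- 2.2
  loss <- function(Z, mu) {
    Q <- soft_assign(Z, mu, alpha)
    kl_term(P, Q) - g1 * sS * constraint_term(Q, S, m) +
      g2 * sSN * constraint_term(Q, SN, m)
  }
  # analytic path, mirroring the training step
  U <- (1 + dcssdec:::pairwise_sqdist(Z, mu) / alpha)^(-(alpha + 1) / 2)
  s <- rowSums(U); Q <- U / s
  g <- -P / pmax(Q, 1e-12)
  g <- dcssdec:::add_pair_grad(g, Q, S[, 1], S[, 2], m, -g1 * sS)
  g <- dcssdec:::add_pair_grad(g, Q, SN[, 1], SN[, 2], m, g2 * sSN)
  a <- (g - rowSums(g * Q)) / s
  B <- ((alpha + 1) / alpha) * a * U^((alpha + 3) / (alpha + 1))
  dZ <- B %*% mu - Z * rowSums(B)
  dMu <- crossprod(B, Z) - mu * colSums(B)
  eps <- 1e-6
  for (probe in 1:12) {
    i <- sample(n, 1); j <- sample(dp, 1)
    Zp <- Z; Zp[i, j] <- Zp[i, j] + eps
    Zm <- Z; Zm[i, j] <- Zm[i, j] - eps
    expect_equal(dZ[i, j], (loss(Zp, mu) - loss(Zm, mu)) / (2 * eps),
                 tolerance = 1e-5)
    k <- sample(C, 1)
    mp <- mu; mp[k, j] <- mp[k, j] + eps
    mm <- mu; mm[k, j] <- mm[k, j] - eps
    expect_equal(dMu[k, j], (loss(Z, mp) - loss(Z, mm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("training recovers well-separated clusters and reports a trace", {
  ds <- quick_blobs()
  ae <- quick_ae(ds$X)
  cs <- generate_constraints(ds$labels, beta = 1, seed = 4)
  res <- dcssdec_train(ds$X, ae, cs, quick_cfg(), true_labels = ds$labels)
  expect_true(res$converged)
  expect_gte(clustering_accuracy(ds$labels, res$labels)$acc, 0.9)
  expect_true(all(is.finite(res$objective_trace)))
  expect_equal(res$labels, max.col(res$Q_final, ties.method = "first") - 1L)
  expect_true(all(abs(rowSums(res$Q_final) - 1) < 1e-6))
  expect_equal(dim(res$centroids), c(3L, 5L))
})

test_that("target refreshes happen exactly at multiples of update_interval", {
  ds <- quick_blobs(n = 150, d = 10, seed = 22)
  ae <- quick_ae(ds$X, seed = 23, epochs = 5)
  seen <- list()
  cfg <- train_config(n_clusters = 3, batch_size = 50, update_interval = 25,
                      max_iterations = 100, tolerance = 1e-6, seed = 24)
  dcssdec_train(ds$X, ae, NULL, cfg,
                on_refresh = function(iter, P, labels) {
                  seen[[length(seen) + 1L]] <<- list(iter = iter, P = P)
                })
  iters <- vapply(seen, `[[`, numeric(1), "iter")
  expect_equal(iters, seq(0, by = 25, length.out = length(iters)))
  expect_gte(length(seen), 2L)
  # P changes across refreshes (the network moved in between)
  expect_false(isTRUE(all.equal(seen[[1L]]$P, seen[[2L]]$P)))
  # every refresh delivers a row-stochastic target
  for (s in seen) expect_equal(rowSums(s$P), rep(1, 150), tolerance = 1e-6)
})

test_that("training is reproducible given identical seeds", {
  ds <- quick_blobs(n = 120, d = 8, seed = 26)
  ae <- quick_ae(ds$X, seed = 27, epochs = 5)
  cs <- generate_constraints(ds$labels, beta = 0.5, seed = 28)
  cfg <- train_config(n_clusters = 3, batch_size = 60, update_interval = 20,
                      max_iterations = 120, seed = 29)
  a <- dcssdec_train(ds$X, ae, cs, cfg)
  b <- dcssdec_train(ds$X, ae, cs, cfg)
  expect_identical(a$labels, b$labels)
  expect_identical(a$Q_final, b$Q_final)
  expect_equal(a$metric_trace, b$metric_trace)
})

test_that("zero supervision reduces bit-exactly to the unconstrained path", {
  ds <- quick_blobs(n = 150, d = 10, seed = 31)
  ae <- quick_ae(ds$X, seed = 32, epochs = 5)
  cfg <- train_config(n_clusters = 3, batch_size = 50, update_interval = 20,
                      max_iterations = 100,
                      objective_cfg = objective_config(gamma1 = 0,
                                                       gamma2 = 0),
                      seed = 33)
  reduced <- dcssdec_train(ds$X, ae, dcssdec:::empty_constraints(150), cfg)
  plain <- dcssdec_train(ds$X, ae, NULL, cfg)
  expect_identical(reduced$labels, plain$labels)
  expect_identical(reduced$Q_final, plain$Q_final)
  expect_identical(reduced$objective_trace, plain$objective_trace)
})

test_that("tolerance = 1 stops at the first stopping-rule check", {
  ds <- quick_blobs(n = 100, d = 8, seed = 36)
  ae <- quick_ae(ds$X, seed = 37, epochs = 5)
  cfg <- train_config(n_clusters = 3, batch_size = 50, update_interval = 15,
                      max_iterations = 300, tolerance = 1, seed = 38)
  res <- dcssdec_train(ds$X, ae, NULL, cfg)
  expect_true(res$converged)
  expect_equal(res$iterations_run, 15L)
  expect_equal(nrow(res$metric_trace), 2L)
})

test_that("the pair-batch sampler trains and remains reproducible", {
  ds <- quick_blobs(seed = 42)
  ae <- quick_ae(ds$X, seed = 43)
  cs <- generate_constraints(ds$labels, beta = 1, seed = 44)
  cfg <- train_config(n_clusters = 3, batch_size = 128, update_interval = 30,
                      max_iterations = 600, constraint_mode = "pair_batch",
                      pair_batch_size = 64, seed = 45)
  a <- dcssdec_train(ds$X, ae, cs, cfg, true_labels = ds$labels)
  b <- dcssdec_train(ds$X, ae, cs, cfg, true_labels = ds$labels)
  expect_identical(a$labels, b$labels)
  expect_gte(clustering_accuracy(ds$labels, a$labels)$acc, 0.8)
})

test_that("mismatched constraints or data are rejected", {
  ds <- quick_blobs(n = 50, d = 6, C = 2, seed = 51)
  ae <- pretrain(ds$X, autoencoder_spec(6, layer_dims = c(6, 8, 2),
                                        pretrain_epochs = 3, seed = 52))
  cfg <- quick_cfg(C = 2, seed = 53)
  bad_cs <- constraint_set(rbind(c(1, 60)), NULL, n_instances = 60)
  expect_error(dcssdec_train(ds$X, ae, bad_cs, cfg), "out-of-range")
  expect_error(dcssdec_train(ds$X[, 1:3], ae, NULL, cfg), "dimension")
})
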
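test_that("small inputs without n_clusters take the clustering bypass", {
  sim <- generate_powerlaw_simulation(seed = 71, n_items = 150, n_time = 600)
  x <- sim$activity[1:64, ]
  emb <- rastermap(x, n_PCs = 16, locality = 0, time_lag_window = 0)
  expect_true(emb$config$bypass_clustering)
  expect_null(emb$model)
  expect_equal(nrow(emb$S), 64L)
  expect_setequal(emb$item_order, 1:64)
})

test_that("the embedding is deterministic for a fixed seed and config", {
  sim <- generate_powerlaw_simulation(seed = 72, n_items = 300, n_time = 800)
  e1 <- rastermap(sim$activity, n_clusters = 25, n_PCs = 24, locality = 0,
                  time_lag_window = 0, seed = 7, keep_data = FALSE)
  e2 <- rastermap(sim$activity, n_clusters = 25, n_PCs = 24, locality = 0,
                  time_lag_window = 0, seed = 7, keep_data = FALSE)
  expect_identical(e1$item_order, e2$item_order)
  expect_identical(e1$item_position, e2$item_position)
  expect_identical(e1$cluster_perm$perm, e2$cluster_perm$perm)
})

test_that("adjacent items in the sorting are more correlated than random pairs", {
  sim <- generate_powerlaw_simulation(seed = 73, n_items = 400, n_time = 1500)
  emb <- rastermap(sim$activity, n_clusters = 40, n_PCs = 32, locality = 0,
                   time_lag_window = 0, seed = 1)
  act <- emb$activity_normalized
  ord <- emb$item_order
  adj <- mean(sapply(1:399, function(i)
    cor(act[ord[i], ], act[ord[i + 1], ])))
  set.seed(73)
  pairs <- cbind(sample(400, 300, TRUE), sample(400, 300, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  rnd <- mean(apply(pairs, 1, function(p) cor(act[p[1], ], act[p[2], ])))
  expect_gt(adj, rnd + 0.05)
})

test_that("the config echo reproduces the run", {
  sim <- generate_powerlaw_simulation(seed = 74, n_items = 250, n_time = 600)
  emb <- rastermap(sim$activity, n_clusters = 20, n_PCs = 16, locality = 0.5,
                   time_lag_window = 2, seed = 3, keep_data = FALSE)
  cfg <- emb$config
  emb2 <- rastermap(sim$activity, n_clusters = cfg$n_clusters,
                    n_PCs = cfg$n_PCs, locality = cfg$locality,
                    time_lag_window = cfg$time_lag_window,
                    zscore = cfg$zscore, mean_time = cfg$mean_time,
                    time_bin = cfg$time_bin, seed = cfg$seed,
                    keep_data = FALSE)
  expect_identical(emb2$item_order, emb$item_order)
})

test_that("superneurons are computed from the sorted activity on request", {
  sim <- generate_powerlaw_simulation(seed = 75, n_items = 220, n_time = 500)
  emb <- rastermap(sim$activity, n_clusters = 20, n_PCs = 16, locality = 0,
                   time_lag_window = 0, seed = 1, superneuron_bin = 10)
  expect_equal(nrow(emb$superneurons), 22L)
  want <- make_superneurons(
    emb$activity_normalized[emb$item_order, ], 10)
  expect_equal(emb$superneurons, want, ignore_attr = TRUE)
})

test_that("presets carry the documented parameter combinations", {
  vr <- rastermap_preset("virtual_reality")
  expect_equal(vr$locality, 0.75)
  expect_equal(vr$time_lag_window, 10L)
  sp <- rastermap_preset("spontaneous")
  expect_equal(sp$n_PCs, 128L)
  expect_equal(sp$locality, 0)
  expect_equal(sp$time_lag_window, 5L)
  mm <- rastermap_preset("multimodule_benchmark")
  expect_equal(mm$locality, 0.8)
  expect_error(rastermap_preset("nope"))
})

test_that("trial-sorting flip works end to end on trial-like input", {
  # trials x features with a drifting pattern over "session time"
  set.seed(76)
  n_tr <- 60
  drift <- seq(0, 1, length.out = n_tr)
  x <- outer(drift, rnorm(80)) + outer(1 - drift, rnorm(80)) +
    matrix(rnorm(n_tr * 80, sd = 0.3), n_tr)
  emb <- rastermap(x, n_PCs = 10, locality = 0.5, time_lag_window = 0,
                   mean_time = FALSE)
  pos <- flip_if_reversed(emb$item_position, seq_len(n_tr))
  expect_gt(cor(pos, drift), 0)
})
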
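test_that("upsampling collinear centers stays on the line", {
  a <- rnorm(6); b <- rnorm(6)
  centers <- t(sapply(0:19, function(j) a + j * b))
  up <- upsample_centers(centers, factor = 10)
  expect_equal(nrow(up), 200L)
  # every upsampled point must satisfy the same affine relation
  for (m in c(1, 55, 137, 200)) {
    t0 <- (m - 1) / 10
    expect_equal(up[m, ], a + t0 * b, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("upsampling matches an explicit weighted-normal-equations oracle", {
  set.seed(61)
  centers <- cbind(sin(seq(0, 2 * pi, length.out = 20)), rnorm(20, sd = 0.01))
  up <- upsample_centers(centers, factor = 10, n_neighbors = 8)
  oracle <- function(t0) {
    js <- 0:19
    w <- exp(-(js - t0)^2)
    keep <- order(abs(js - t0))[1:8]
    js <- js[keep]; w <- w[keep]
    X <- cbind(1, js - t0)
    W <- diag(w)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% centers[keep, ])
    beta[1, ]
  }
  for (m in c(5, 50, 101, 190)) {
    expect_equal(up[m, ], oracle((m - 1) / 10), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("factor 1 reproduces the centers up to local fit residual", {
  set.seed(62)
  centers <- matrix(rnorm(12 * 4, sd = 0.1), 12) +
    outer(1:12, rep(1, 4))  # smooth trend + noise
  up <- upsample_centers(centers, factor = 1)
  expect_equal(dim(up), dim(centers))
  expect_lt(max(abs(up - centers)), 0.5)
  expect_error(upsample_centers(centers[1, , drop = FALSE]), "fewer than 2")
})

test_that("items assign to their own center's knot and midpoints fall between", {
  set.seed(63)
  a <- rnorm(6); b <- rnorm(6)
  centers <- t(sapply(0:9, function(j) a + j * b))  # collinear, off-origin
  up <- upsample_centers(centers, factor = 10)
  asg <- assign_items(centers, up)
  expect_equal(asg$node, seq(1, 91, by = 10), tolerance = 0)
  mid <- (centers[3, ] + centers[4, ]) / 2
  am <- assign_items(rbind(mid), up)
  expect_gt(am$node, 21)
  expect_lt(am$node, 31)
  # determinism: identical items get identical positions
  two <- rbind(mid, mid)
  at <- assign_items(two, up)
  expect_equal(at$position[1], at$position[2])
})

test_that("superneurons average consecutive rows and drop the remainder", {
  r <- rnorm(30); q <- rnorm(30)
  m <- rbind(r, r, q, q, rnorm(30))
  s2 <- make_superneurons(m, 2)
  expect_equal(unname(s2[1, ]), r)
  expect_equal(unname(s2[2, ]), q)
  expect_equal(nrow(s2), 2L)  # trailing odd row dropped
  expect_equal(make_superneurons(m, 1), m, ignore_attr = TRUE)
  expect_error(make_superneurons(m, 6), "bin_size")
})

test_that("superneuron binning commutes with linear scaling", {
  set.seed(64)
  m <- matrix(rnorm(60), 6)
  expect_equal(make_superneurons(3 * m, 2), 3 * make_superneurons(m, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("flip heuristic reverses an embedding running against the covariate", {
  pos <- seq(0, 0.99, length.out = 50)
  cov <- rev(seq_len(50))  # first trials have the largest covariate
  flipped <- flip_if_reversed(pos, cov)
  expect_equal(cor(flipped, cov), max(abs(cor(pos, cov))), tolerance = 1e-10)
  # already aligned: unchanged
  expect_equal(flip_if_reversed(pos, seq_len(50)), pos)
})

test_that("zero split rounds leave the embedding untouched", {
  sim <- generate_powerlaw_simulation(seed = 65, n_items = 250, n_time = 600)
  emb <- rastermap(sim$activity, n_clusters = 20, n_PCs = 16,
                   locality = 0, time_lag_window = 0, seed = 1)
  out <- split_and_resort(emb, emb$features, emb$activity_normalized, 0)
  expect_identical(out$item_order, emb$item_order)
})

test_that("each split round doubles the cluster count", {
  sim <- generate_powerlaw_simulation(seed = 66, n_items = 400, n_time = 800)
  emb <- rastermap(sim$activity, n_clusters = 24, n_PCs = 16,
                   locality = 0, time_lag_window = 0, seed = 1)
  out <- split_and_resort(emb, emb$features, emb$activity_normalized, 1,
                          context = 6, seed = 1)
  expect_equal(out$n_clusters_final, 48L)
  expect_setequal(out$item_order, seq_len(400))
  expect_true(all(out$item_position >= 0 & out$item_position < 1))
  # stable sort of positions defines the order
  expect_equal(out$item_order,
               order(out$item_position, seq_along(out$item_position)))
})
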
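test_that("the same seed reproduces a dataset exactly", {
  a <- generate_benchmark_simulation(seed = 99, scale = 0.02)
  b <- generate_benchmark_simulation(seed = 99, scale = 0.02)
  expect_identical(a$activity, b$activity)
  expect_identical(a$ground_truth_position, b$ground_truth_position)
  c2 <- generate_benchmark_simulation(seed = 100, scale = 0.02)
  expect_false(identical(a$activity, c2$activity))
})

test_that("module sizes keep the 1:1:1:1:2 proportions at any scale", {
  sim <- generate_benchmark_simulation(seed = 1, scale = 0.05)
  tab <- table(sim$module_label)
  expect_equal(unname(tab[1:4]), rep(50L, 4), ignore_attr = TRUE)
  expect_equal(unname(tab[5]), 100L, ignore_attr = TRUE)
  expect_equal(ncol(sim$activity), 2500L)
  expect_error(generate_benchmark_simulation(seed = 1, scale = 0.005),
               "scale too small")
  expect_error(generate_benchmark_simulation(seed = 1, scale = 2), "scale")
})

test_that("spiking output is non-negative integer counts with positions in range", {
  sim <- generate_benchmark_simulation(seed = 2, scale = 0.02)
  expect_true(all(sim$activity >= 0))
  expect_true(all(sim$activity == round(sim$activity)))
  expect_true(all(sim$ground_truth_position >= 0 &
                  sim$ground_truth_position <= 1))
  expect_equal(length(sim$module_label), nrow(sim$activity))
})

test_that("ground truth round-trips through the results container", {
  sim <- generate_benchmark_simulation(seed = 3, scale = 0.02)
  f <- tempfile(fileext = ".rds")
  saveRDS(sim, f)
  back <- readRDS(f)
  expect_identical(back$ground_truth_position, sim$ground_truth_position)
  expect_identical(back$module_label, sim$module_label)
  unlink(f)
})

test_that("power-law rates have the designed eigenvalue decay", {
  for (expo in c(1, 1.5)) {
    pl <- simulate_powerlaw_rates(seed = 7, n_items = 600, n_time = 3000,
                                  exponent = expo)
    expect_true(all(pl$rates >= 0))  # clipped at zero
    ev <- eigen(tcrossprod(pl$rates) / 3000, symmetric = TRUE,
                only.values = TRUE)$values
    ks <- 2:50
    slope <- coef(lm(log(ev[ks]) ~ log(ks)))[[2]]
    expect_gt(slope, -expo - 0.1)
    expect_lt(slope, -expo + 0.1)
  }
})

test_that("power-law-only simulation is deterministic count data", {
  a <- generate_powerlaw_simulation(seed = 5, n_items = 150, n_time = 500)
  b <- generate_powerlaw_simulation(seed = 5, n_items = 150, n_time = 500)
  expect_identical(a$activity, b$activity)
  expect_true(all(a$activity == round(a$activity)))
  expect_equal(length(a$ground_truth_position), 150L)
  expect_error(generate_powerlaw_simulation(seed = 1, n_items = 50),
               "n_items")
})

test_that("2-D simulation gives identical noiseless rows for identical (x,y)", {
  sim <- generate_2d_simulation(seed = 6, n_items = 200, n_time = 400,
                                noise_sd = 0)
  x <- sim$ground_truth_position[, "x"]
  y <- sim$ground_truth_position[, "y"]
  # rebuild two rows from the basis directly: same latent -> same row
  k <- 5
  U1 <- cos(pi * outer(x[1:2], 1:30))
  expect_equal(dim(sim$ground_truth_position), c(200L, 2L))
  # inject duplicate latent by construction check: rows with nearest latents
  # are more similar than random pairs
  d <- as.matrix(dist(sim$ground_truth_position))
  cc <- cor(t(sim$activity))
  near <- apply(d + diag(Inf, 200), 1, which.min)
  expect_gt(mean(cc[cbind(1:200, near)]), mean(cc[upper.tri(cc)]))
  # real-valued (no Poisson step)
  sim2 <- generate_2d_simulation(seed = 6, n_items = 120, n_time = 300)
  expect_false(all(sim2$activity == round(sim2$activity)))
})

test_that("2-D singular values follow (kx^2+ky^2)^(-1/2) ordering", {
  sim <- generate_2d_simulation(seed = 8, n_items = 500, n_time = 2000,
                                noise_sd = 0)
  ev <- svd(sim$activity, nu = 0, nv = 0)$d
  grid <- expand.grid(kx = 1:30, ky = 1:30)
  s_theory <- sort((grid$kx^2 + grid$ky^2)^(-0.5), decreasing = TRUE)
  # compare log-log decay over the leading components
  ks <- 2:40
  got <- coef(lm(log(ev[ks]) ~ log(ks)))[[2]]
  want <- coef(lm(log(s_theory[ks]) ~ log(ks)))[[2]]
  expect_equal(got, want, tolerance = 0.15)
})
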
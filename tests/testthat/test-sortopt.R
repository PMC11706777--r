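test_that("score_ordering matches a naive double loop", {
  set.seed(41)
  S <- matrix(rnorm(36), 6)
  M <- make_random_M(6, seed = 41)
  for (r in 1:100) {
    p <- sample(6)
    expect_equal(score_ordering(S, M, p), naive_score(S, M, p),
                 tolerance = 1e-10)
  }
  # self-match: S = M scores its squared Frobenius norm under identity
  expect_equal(score_ordering(M, M, 1:6), sum(M^2), tolerance = 1e-10)
})

test_that("two-node scoring picks out the upper-triangle entry", {
  S <- matrix(c(0, 3, 7, 0), 2)  # S[1,2] = 7, S[2,1] = 3
  M <- matrix(c(0, 0, 2, 0), 2)  # M[1,2] = 2
  expect_equal(score_ordering(S, M, 1:2), 14)
  expect_equal(score_ordering(S, M, 2:1), 6)
  bf <- brute_force_ordering(S, M)
  expect_equal(bf$perm, 1:2)
})

test_that("brute force finds a constructed chain and breaks ties lexicographically", {
  # chain 2 -> 3 -> 1 with large forward similarities
  S <- matrix(0, 3, 3)
  S[2, 3] <- 5; S[3, 1] <- 5; S[2, 1] <- 2
  M <- build_matching_matrix(3, 0.5)
  bf <- brute_force_ordering(S, M)
  expect_equal(bf$perm, c(2L, 3L, 1L))
  # null matching: every ordering scores 0, identity wins by tie-break
  bf0 <- brute_force_ordering(matrix(rnorm(9), 3), matrix(0, 3, 3))
  expect_equal(bf0$perm, 1:3)
  expect_equal(bf0$score, 0)
  expect_error(brute_force_ordering(diag(10), diag(10)), "n > 9")
})

test_that("incremental sweep agrees with naive enumeration of block swaps", {
  resample <- function(x) x[sample.int(length(x), 1)]
  set.seed(42)
  for (trial in 1:15) {
    n <- resample(5:11)
    S <- matrix(rnorm(n * n), n)
    M <- if (trial %% 2) make_random_M(n, seed = trial)
         else build_matching_matrix(n, 0.5)
    M[lower.tri(M, diag = TRUE)] <- 0
    ord <- sample(n)
    L <- resample(1:(n - 2))
    got <- rastermapr:::cpp_sweep_best(S, M, ord - 1L, L, 0L, n, 1e-9, FALSE)
    Sm <- S; diag(Sm) <- 0
    base <- score_ordering(Sm, M, ord)
    best <- 1e-9
    for (i in 0:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if ((j - i) != L && (k - j) != L) next
      np <- ord
      np[(i + 1):k] <- c(ord[(j + 1):k], ord[(i + 1):j])
      best <- max(best, score_ordering(Sm, M, np) - base)
    }
    expect_equal(got$delta, best, tolerance = 1e-8)
  }
})

test_that("reversed-segment deltas match naive rescoring", {
  resample <- function(x) x[sample.int(length(x), 1)]
  set.seed(43)
  for (trial in 1:30) {
    n <- resample(4:10)
    S <- matrix(rnorm(n * n), n); diag(S) <- 0
    M <- make_random_M(n, seed = 100 + trial)
    ord <- sample(n)
    i <- resample(0:(n - 2)); j <- resample((i + 1):(n - 1))
    k <- resample((j + 1):n)
    rx <- trial %% 2 == 0
    X <- ord[(i + 1):j]; Y <- ord[(j + 1):k]
    np <- ord
    np[(i + 1):k] <- if (rx) c(Y, rev(X)) else c(rev(Y), X)
    want <- score_ordering(S, M, np) - score_ordering(S, M, ord)
    got <- rastermapr:::cpp_swap_delta_rev(S, M, ord - 1L, i, j, k, rx)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("optimizer output is a valid permutation scoring at least the init", {
  set.seed(44)
  for (trial in 1:5) {
    n <- 20
    tr <- make_traces(n, 300, seed = trial, latent = TRUE)
    S <- compute_asymmetric_similarity(tr, 3)
    M <- build_matching_matrix(n, 0.7)
    init <- sample(n)
    o <- optimize_ordering(S, M, init = init)
    expect_setequal(o$perm, 1:n)
    expect_gte(o$score, score_ordering(S, M, init) - 1e-8)
    expect_true(all(diff(o$score_trace) > 0))
  }
})

test_that("optimizer recovers the score of a planted permutation", {
  set.seed(45)
  n <- 25
  M <- build_matching_matrix(n, 0.6)
  pi0 <- sample(n)
  S <- matrix(0, n, n)
  S[pi0, pi0] <- M + 0.01 * matrix(rnorm(n * n), n)  # S sorted by pi0 ~ M
  o <- optimize_ordering(S, M)
  planted <- score_ordering(S, M, pi0)
  expect_gte(o$score, planted - 1e-6)
})

test_that("optimizer attains brute-force optima on most small instances", {
  set.seed(46)
  hits <- 0
  for (trial in 1:12) {
    n <- 5 + trial %% 3
    tr <- make_traces(n, 60, seed = 200 + trial)
    S <- compute_asymmetric_similarity(tr, 3)
    M <- build_matching_matrix(n, 0.5)
    bf <- brute_force_ordering(S, M)
    o <- optimize_ordering(S, M)
    expect_lte(o$score, bf$score + 1e-8)
    if (o$score >= bf$score - 1e-8) hits <- hits + 1
  }
  expect_gte(hits, 10)
})

test_that("optimizer is deterministic and respects fixed flanks", {
  tr <- make_traces(30, 200, seed = 47, latent = TRUE)
  S <- compute_asymmetric_similarity(tr, 2)
  M <- build_matching_matrix(30, 0.8)
  o1 <- optimize_ordering(S, M)
  o2 <- optimize_ordering(S, M)
  expect_identical(o1$perm, o2$perm)
  init <- 1:30
  o3 <- optimize_ordering(S, M, init = init, fixed_left = 5, fixed_right = 5)
  expect_identical(o3$perm[1:5], 1:5)
  expect_identical(o3$perm[26:30], 26:30)
})

test_that("initial ordering sorts by first singular-vector weight", {
  expect_equal(initialize_ordering(c(0.1, 0.5, 0.3)), c(1L, 3L, 2L))
  expect_equal(initialize_ordering(cbind(3:1, rnorm(3))), c(3L, 2L, 1L))
  set.seed(48)
  w <- rnorm(50)
  expect_equal(initialize_ordering(w), order(w))
})

test_that("coarse subsampled pass preserves the permutation property", {
  tr <- make_traces(80, 300, seed = 49, latent = TRUE)
  S <- compute_asymmetric_similarity(tr, 2)
  M <- build_matching_matrix(80, 0.8)
  o <- optimize_ordering(S, M, skip = 3)
  expect_setequal(o$perm, 1:80)
  o0 <- optimize_ordering(S, M, skip = 0)
  # both passes must produce comparable quality on structured data
  expect_gt(o$score, 0.9 * o0$score)
})
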
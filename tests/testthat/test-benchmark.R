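test_that("triplet score is 1 for the truth and its reversal, 1/3 at random", {
  n <- 200
  truth <- seq_len(n) / n
  expect_equal(unname(triplet_score(1:n, truth, n_samples = 2000)), 1,
               ignore_attr = TRUE)
  expect_equal(unname(triplet_score(n:1, truth, n_samples = 2000)), 1,
               ignore_attr = TRUE)
  st <- attr(triplet_score(n:1, truth, n_samples = 2000), "strict")
  expect_equal(unname(st), 0)  # reversal fails the strict variant
  set.seed(51)
  rnd <- unname(triplet_score(sample(n), truth, n_samples = 20000, seed = 1))
  expect_lt(abs(rnd - 1 / 3), 0.02)
})

test_that("triplet score agrees with exhaustive enumeration on a small set", {
  set.seed(52)
  n <- 9
  truth <- runif(n)
  ord <- sample(n)
  rank_emb <- integer(n); rank_emb[ord] <- 1:n
  combs <- t(combn(n, 3))
  correct <- 0
  for (r in seq_len(nrow(combs))) {
    tri <- combs[r, ]
    gt <- rank(truth[tri]); em <- rank(rank_emb[tri])
    if (all(gt == em) || all(gt == 4 - em)) correct <- correct + 1
  }
  want <- correct / nrow(combs)
  got <- unname(triplet_score(ord, truth, n_samples = 60000, seed = 2))
  expect_lt(abs(got - want), 0.02)
})

test_that("contamination is 0 for contiguous modules, ~50% when interleaved", {
  lab <- rep(c("a", "b"), each = 10)
  expect_equal(unname(contamination_score(1:20, lab, n_samples = 3000)),
               c(0, 0))
  inter <- rep(c("a", "b"), 10)
  ci <- contamination_score(1:20, inter, n_samples = 20000, seed = 3)
  # exhaustive expectation for the alternating pattern at n = 10 + 10
  ranks <- which(inter == "a")
  pairs <- t(combn(10, 2))
  fr <- apply(pairs, 1, function(p) {
    lo <- ranks[p[1]]; hi <- ranks[p[2]]
    nb <- hi - lo - 1
    if (nb == 0) return(0)
    sum(inter[(lo + 1):(hi - 1)] != "a") / nb
  })
  expect_lt(abs(unname(ci["a"]) - 100 * mean(fr)), 1.5)
  # the enumerated value at n = 10 + 10 is ~67%: short pairs, whose gap is
  # mostly the other module, dominate; the ~50% limit is asymptotic
  set.seed(99)
  big <- rep(c("a", "b"), 150)
  cb <- contamination_score(seq_along(big), big, n_samples = 20000, seed = 9)
  expect_gt(cb["a"], 45); expect_lt(cb["a"], 62)
  # a single module is uncontaminated by definition
  expect_equal(unname(contamination_score(1:5, rep("x", 5))), 0)
})

test_that("contamination matches a naive per-pair oracle", {
  set.seed(53)
  n <- 40
  lab <- sample(c("a", "b", "c"), n, TRUE)
  ord <- sample(n)
  got <- contamination_score(ord, lab, n_samples = 50000, seed = 4)
  rank_emb <- integer(n); rank_emb[ord] <- 1:n
  lab_by_rank <- character(n); lab_by_rank[rank_emb] <- lab
  for (m in c("a", "b")) {
    idx <- which(lab == m)
    pairs <- t(combn(length(idx), 2))
    fr <- apply(pairs, 1, function(p) {
      r <- sort(rank_emb[idx[p]])
      nb <- r[2] - r[1] - 1
      if (nb == 0) return(0)
      sum(lab_by_rank[(r[1] + 1):(r[2] - 1)] != m) / nb
    })
    expect_equal(unname(got[m]), 100 * mean(fr), tolerance = 1.5)
  }
})

test_that("knn preservation is 1 for a perfect embedding, ~k/(n-1) at random", {
  n <- 300
  truth <- runif(n)
  r <- knn_preservation_score(truth, truth, k_values = c(1, 5, 20))
  expect_equal(r$score, rep(1, 3))
  set.seed(54)
  rr <- knn_preservation_score(truth, runif(n), k_values = 10, seed = 5)
  expect_lt(abs(rr$score - 10 / (n - 1)), 0.015)
})

test_that("knn preservation handles 2-D ground truth and validates k", {
  set.seed(55)
  xy <- cbind(runif(100), runif(100))
  emb <- xy[, 1]  # embed along x only
  r <- knn_preservation_score(xy, emb, k_values = c(5, 20))
  expect_true(all(r$score > 0.05 & r$score < 1))
  expect_error(knn_preservation_score(runif(30), runif(30), k_values = 40),
               "smaller than")
})

test_that("local and global quality scores match naive implementations", {
  set.seed(56)
  N <- 10
  S <- matrix(rnorm(N * N), N)
  M <- build_matching_matrix(N, 0.5)
  got <- embedding_quality_scores(S, M)
  # naive local: fraction of rows whose first-upper-diagonal entry is the
  # row maximum over off-diagonal entries
  loc <- mean(sapply(1:(N - 1), function(i) {
    S[i, i + 1] >= max(S[i, -i])
  }))
  glo <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) glo <- glo + S[i, j] * M[i, j]
  glo <- glo / mean(M[upper.tri(M)])
  expect_equal(got$local, loc, tolerance = 1e-12)
  expect_equal(got$global, glo, tolerance = 1e-8)
  # planting the row maxima on the first off-diagonal gives local = 1
  S2 <- S
  for (i in 1:(N - 1)) S2[i, i + 1] <- max(S2[i, -i]) + 1
  expect_equal(embedding_quality_scores(S2, M)$local, 1)
  expect_equal(embedding_quality_scores(M, M)$local, 1)
})

test_that("ground-truth correlation is reflection-invariant and near 0 at random", {
  x <- runif(500)
  expect_equal(groundtruth_correlation(x, x), 1)
  expect_equal(groundtruth_correlation(-x, x), 1)
  set.seed(57)
  expect_lt(groundtruth_correlation(runif(1000), runif(1000)), 0.1)
  expect_error(groundtruth_correlation(rep(1, 5), runif(5)), "constant")
})

test_that("scores are invariant to monotone transforms of the embedding", {
  set.seed(58)
  n <- 100
  truth <- runif(n)
  lab <- rep(c("a", "b"), each = n / 2)
  pos <- runif(n)
  ord1 <- order(pos)
  ord2 <- order(pos^3 + 2)  # monotone transform leaves the order unchanged
  expect_equal(triplet_score(ord1, truth, lab, n_samples = 3000),
               triplet_score(ord2, truth, lab, n_samples = 3000))
  expect_equal(contamination_score(ord1, lab, n_samples = 3000),
               contamination_score(ord2, lab, n_samples = 3000))
})
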
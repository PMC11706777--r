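#' Triplet score of an embedding against ground truth
#'
#' For each module, random triplets of distinct items are drawn and a
#' triplet counts as correct when the relative order of the three items in
#' the embedding matches their ground-truth order. Because a 1-D embedding
#' has an arbitrary sign, the default scoring is orientation-invariant: the
#' full reversal of the true order also counts (equivalently, the middle
#' item must agree). A random embedding then scores 1/3 (2 of the 6
#' arrangements of three items). The strict single-orientation variant is
#' returned alongside in attribute `"strict"`.
#'
#' @param embedding_order permutation of item indices giving the embedding
#'   (row) order.
#' @param ground_truth_position numeric latent position per item.
#' @param module_label factor/vector of module membership per item; scores
#'   are computed within modules. `NULL` treats all items as one module.
#' @param n_samples triplets drawn per module (default 10000; Monte-Carlo
#'   error below 1%).
#' @param seed integer seed for the triplet draw.
#' @return named numeric vector: fraction of correct triplets per module,
#'   with attribute `"strict"` (same without orientation invariance).
#'   Modules with fewer than 3 items are skipped with a warning.
#' @export
triplet_score <- function(embedding_order, ground_truth_position,
                          module_label = NULL, n_samples = 10000L,
                          seed = 42L) {
  n <- length(ground_truth_position)
  rank_emb <- order_to_rank(embedding_order, n)
  module_label <- module_label %||% rep("all", n)
  mods <- unique(as.character(module_label))
  out <- strict <- stats::setNames(rep(NA_real_, length(mods)), mods)
  set.seed(as.integer(seed))
  for (m in mods) {
    idx <- which(as.character(module_label) == m)
    if (length(idx) < 3L) {
      warning("module ", m, " has fewer than 3 items; skipped")
      next
    }
    tri <- draw_distinct_tuples(length(idx), 3L, n_samples)
    a <- idx[tri[, 1]]; b <- idx[tri[, 2]]; c <- idx[tri[, 3]]
    gt <- cbind(ground_truth_position[a], ground_truth_position[b],
                ground_truth_position[c])
    em <- cbind(rank_emb[a], rank_emb[b], rank_emb[c])
    gt_rank <- t(apply(gt, 1L, rank, ties.method = "first"))
    em_rank <- t(apply(em, 1L, rank, ties.method = "first"))
    same <- rowSums(gt_rank == em_rank) == 3L
    rev_ <- rowSums(gt_rank == (4L - em_rank)) == 3L
    out[m] <- mean(same | rev_)
    strict[m] <- mean(same)
  }
  attr(out, "strict") <- strict
  out
}

#' Contamination of modules in an embedding
#'
#' For random pairs of items from the same module, the fraction of items
#' lying strictly between them in the embedding that belong to a different
#' module, averaged over pairs and expressed in percent. 0% means each
#' module occupies a contiguous stretch of the embedding; two perfectly
#' interleaved modules score about 50%.
#'
#' @inheritParams triplet_score
#' @param n_samples pairs drawn per module.
#' @return named numeric vector: percent contamination per module.
#' @export
contamination_score <- function(embedding_order, module_label,
                                n_samples = 10000L, seed = 42L) {
  n <- length(module_label)
  rank_emb <- order_to_rank(embedding_order, n)
  mods <- unique(as.character(module_label))
  out <- stats::setNames(rep(NA_real_, length(mods)), mods)
  set.seed(as.integer(seed))
  lab_by_rank <- character(n)
  lab_by_rank[rank_emb] <- as.character(module_label)
  for (m in mods) {
    idx <- which(as.character(module_label) == m)
    if (length(idx) < 2L) {
      warning("module ", m, " has fewer than 2 items; skipped")
      next
    }
    cum_same <- cumsum(lab_by_rank == m)
    pr <- draw_distinct_tuples(length(idx), 2L, n_samples)
    r1 <- rank_emb[idx[pr[, 1]]]
    r2 <- rank_emb[idx[pr[, 2]]]
    lo <- pmin(r1, r2)
    hi <- pmax(r1, r2)
    n_between <- hi - lo - 1L
    same_between <- cum_same[hi - 1L] - cum_same[lo]
    frac <- ifelse(n_between > 0L,
                   (n_between - same_between) / n_between, 0)
    out[m] <- 100 * mean(frac)
  }
  out
}

#' k-nearest-neighbor preservation of an embedding
#'
#' Fraction of each item's k nearest neighbors in the ground-truth space
#' (1-D scalar or 2-D coordinates, Euclidean distance) that are also among
#' its k nearest neighbors in the embedding, averaged over items. Evaluated
#' on a random subsample of items to bound the neighbor computation.
#'
#' @param ground_truth_position numeric vector (1-D) or two-column matrix
#'   (2-D) of latent positions.
#' @param embedding_position numeric vector of embedding positions.
#' @param k_values neighborhood sizes to evaluate.
#' @param subsample evaluate on at most this many randomly chosen items
#'   (default 2000).
#' @param seed integer seed for the subsample.
#' @return data.frame with columns `k` and `score` (fraction in `[0, 1]`).
#' @export
knn_preservation_score <- function(ground_truth_position,
                                   embedding_position,
                                   k_values = c(1L, 5L, 10L, 50L, 100L),
                                   subsample = 2000L, seed = 42L) {
  gt <- if (is.matrix(ground_truth_position)) ground_truth_position
        else matrix(ground_truth_position, ncol = 1L)
  n <- nrow(gt)
  if (length(embedding_position) != n)
    stop_input("position vectors must have equal length")
  set.seed(as.integer(seed))
  keep <- if (n > subsample) sort(sample.int(n, subsample)) else seq_len(n)
  ns <- length(keep)
  if (any(k_values >= ns))
    stop_param("all k values must be smaller than the evaluated subsample")
  gt <- gt[keep, , drop = FALSE]
  ep <- embedding_position[keep]
  kmax <- max(k_values)
  dt <- as.matrix(stats::dist(gt))
  de <- abs(outer(ep, ep, "-"))
  nn_t <- matrix(0L, ns, kmax)
  nn_e <- matrix(0L, ns, kmax)
  for (i in seq_len(ns)) {
    ot <- order(dt[i, ], seq_len(ns))
    oe <- order(de[i, ], seq_len(ns))
    nn_t[i, ] <- ot[ot != i][seq_len(kmax)]
    nn_e[i, ] <- oe[oe != i][seq_len(kmax)]
  }
  score <- vapply(k_values, function(k) {
    hits <- vapply(seq_len(ns), function(i)
      length(intersect(nn_t[i, seq_len(k)], nn_e[i, seq_len(k)])),
      integer(1))
    mean(hits) / k
  }, numeric(1))
  data.frame(k = as.integer(k_values), score = score)
}

#' Local and global preservation scores of a sorted similarity matrix
#'
#' The local score is the fraction of first-upper-diagonal entries of the
#' sorted similarity matrix that are the largest entries available to
#' their row (by default: `S[i, i+1]` is the maximum of row i's
#' off-diagonal entries; `local_mode = "global"` instead requires them to
#' rank among the N-1 largest off-diagonal entries of the whole matrix).
#' The global score is the dot product between the strict upper triangles
#' of the sorted similarity and the matching matrix, normalized by the
#' mean of the matching matrix's upper triangle.
#'
#' @param S_sorted N x N similarity matrix, already in embedding order.
#' @param M N x N matching matrix.
#' @param local_mode `"row"` (default) or `"global"`, see above.
#' @return list with `local` (fraction in `[0, 1]`) and `global`.
#' @export
embedding_quality_scores <- function(S_sorted, M,
                                     local_mode = c("row", "global")) {
  local_mode <- match.arg(local_mode)
  N <- nrow(S_sorted)
  if (ncol(S_sorted) != N || nrow(M) != N || ncol(M) != N)
    stop_input("S_sorted and M must be square and of equal size")
  off <- S_sorted
  diag(off) <- -Inf
  first_diag <- S_sorted[cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L)]
  if (local_mode == "row") {
    row_max <- apply(off[seq_len(N - 1L), , drop = FALSE], 1L, max)
    local <- mean(first_diag >= row_max - 1e-12)
  } else {
    thr <- sort(off[is.finite(off)], decreasing = TRUE)[N - 1L]
    local <- mean(first_diag >= thr - 1e-12)
  }
  ut <- upper.tri(M)
  global <- sum(S_sorted[ut] * M[ut]) / mean(M[ut])
  list(local = local, global = global)
}

#' Absolute rank correlation between embedding and ground truth
#'
#' For single-module datasets (such as the power-law-only benchmark) the
#' embedding can be compared to the 1-D ground truth directly: the Pearson
#' correlation of the rank positions (i.e. the Spearman correlation), in
#' absolute value since a 1-D embedding has arbitrary orientation.
#'
#' @param embedding_position numeric embedding position per item.
#' @param ground_truth_position numeric latent position per item.
#' @return `|r|` in `[0, 1]`.
#' @export
groundtruth_correlation <- function(embedding_position,
                                    ground_truth_position) {
  if (stats::sd(embedding_position) == 0 ||
      stats::sd(ground_truth_position) == 0)
    stop_input("correlation undefined for constant positions")
  abs(stats::cor(rank(embedding_position), rank(ground_truth_position)))
}

order_to_rank <- function(embedding_order, n) {
  embedding_order <- as.integer(embedding_order)
  if (length(embedding_order) != n ||
      !setequal(embedding_order, seq_len(n)))
    stop_input("embedding_order must be a permutation of 1..n")
  r <- integer(n)
  r[embedding_order] <- seq_len(n)
  r
}

# n_samples rows of k distinct indices from 1..m
draw_distinct_tuples <- function(m, k, n_samples) {
  out <- matrix(sample.int(m, n_samples * k, replace = TRUE), n_samples, k)
  bad <- which(apply(out, 1L, anyDuplicated) > 0L)
  guard <- 0L
  while (length(bad) > 0L && guard < 100L) {
    out[bad, ] <- sample.int(m, length(bad) * k, replace = TRUE)
    bad <- bad[apply(out[bad, , drop = FALSE], 1L, anyDuplicated) > 0L]
    guard <- guard + 1L
  }
  if (length(bad) > 0L)
    out <- out[-bad, , drop = FALSE]
  out
}
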
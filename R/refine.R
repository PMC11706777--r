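#' Upsample sorted cluster centers by weighted locally linear regression
#'
#' Interpolates between sorted cluster centers in feature space to create a
#' finer grid of nodes (`factor` per cluster index), so that items can be
#' assigned more precise embedding positions than the cluster resolution.
#' At each upsampled position a linear map from sorted cluster index to
#' feature space is fitted by weighted least squares over the
#' `n_neighbors` nearest clusters, with Gaussian weights of standard
#' deviation `1/sqrt(2)` in index units, and evaluated at that position.
#'
#' @param centers N x d matrix of cluster centers, rows already in sorted
#'   order.
#' @param factor upsampling factor (default 10; 1 re-evaluates at the
#'   original knots, reproducing the centers up to the local fit residual).
#' @param n_neighbors number of nearest clusters entering each local fit
#'   (default 50).
#' @return (factor * N) x d matrix of upsampled nodes; row `m` sits at
#'   cluster-index position `(m - 1) / factor`.
#' @export
upsample_centers <- function(centers, factor = 10L, n_neighbors = 50L) {
  if (!is.matrix(centers)) centers <- as.matrix(centers)
  N <- nrow(centers)
  if (N < 2L) stop_input("cannot upsample fewer than 2 centers")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop_param("factor must be >= 1")
  nn <- min(as.integer(n_neighbors), N)
  grid <- (seq_len(factor * N) - 1L) / factor  # knots at 0..N-1
  out <- matrix(0, length(grid), ncol(centers))
  for (m in seq_along(grid)) {
    t0 <- grid[m]
    jlo <- floor(t0 - (nn - 1) / 2)
    jlo <- min(max(jlo, 0L), N - nn)
    js <- jlo + seq_len(nn) - 1L
    delta <- js - t0
    w <- exp(-delta^2)  # sigma = 1/sqrt(2) => 1/(2 sigma^2) = 1
    Y <- centers[js + 1L, , drop = FALSE]
    sw <- sum(w)
    sx <- sum(w * delta)
    sxx <- sum(w * delta^2)
    sy <- crossprod(w, Y)
    sxy <- crossprod(w * delta, Y)
    den <- sw * sxx - sx^2
    if (den > 1e-12 * max(sw, 1)^2) {
      out[m, ] <- (sxx * sy - sx * sxy) / den
    } else {
      out[m, ] <- sy / sw  # degenerate design: weighted mean
    }
  }
  out
}

#' Assign items to their best-matching upsampled node
#'
#' Correlates each item's feature vector with every upsampled node and
#' assigns the item to the node with the highest correlation (ties toward
#' the lower index). The feature space preserves activity correlations up
#' to truncation, so this matches correlating against upsampled cluster
#' activity. Items with zero-variance feature vectors are assigned by dot
#' product instead (their count is recorded in attribute
#' `"n_dot_product"`).
#'
#' @param feat items x d feature matrix.
#' @param upsampled nodes x d matrix from [upsample_centers()].
#' @return list with `position` (item -> real in `[0, 1)`, node index over
#'   node count) and `node` (item -> node index).
#' @export
assign_items <- function(feat, upsampled) {
  if (ncol(feat) != ncol(upsampled))
    stop_input("feature dimensionality mismatch")
  n_nodes <- nrow(upsampled)
  fc <- feat - rowMeans(feat)
  fn <- sqrt(rowSums(fc^2))
  uc <- upsampled - rowMeans(upsampled)
  un <- sqrt(rowSums(uc^2))
  un[un < 1e-300] <- 1
  C <- tcrossprod(fc / pmax(fn, 1e-300), uc / un)
  degen <- which(fn < 1e-12)
  if (length(degen) > 0L)
    C[degen, ] <- feat[degen, , drop = FALSE] %*% t(upsampled)
  node <- max.col(C, ties.method = "first")
  pos <- (node - 1L) / n_nodes
  structure(list(position = pos, node = node),
            n_dot_product = length(degen))
}

#' Average consecutive sorted rows into superneurons
#'
#' Bins the rows of a sorted activity matrix into consecutive,
#' non-overlapping groups of `bin_size` and averages each group. Because
#' adjacent rows of a sorted raster are similar, the averages (the
#' "superneurons") denoise and compress the display; a trailing remainder
#' of fewer than `bin_size` rows is dropped.
#'
#' @param act_sorted items x timepoints matrix with rows already in
#'   embedding order.
#' @param bin_size rows per superneuron (1 returns the input).
#' @param zscore z-score each superneuron trace for display. Default
#'   `FALSE`.
#' @return `floor(items / bin_size)` x timepoints matrix.
#' @export
make_superneurons <- function(act_sorted, bin_size, zscore = FALSE) {
  if (!is.matrix(act_sorted)) act_sorted <- as.matrix(act_sorted)
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stop_param("bin_size must be >= 1")
  if (bin_size > nrow(act_sorted))
    stop_param("bin_size exceeds the number of items")
  nb <- nrow(act_sorted) %/% bin_size
  keep <- seq_len(nb * bin_size)
  grp <- rep(seq_len(nb), each = bin_size)
  out <- rowsum(act_sorted[keep, , drop = FALSE], grp, reorder = FALSE) / bin_size
  if (zscore) out <- zscore_rows(out)
  attr(out, "bin_size") <- bin_size
  out
}

#' Flip an embedding if it runs against a covariate
#'
#' Convenience post-processing for trial sorting: if the items with the
#' smallest covariate values (for example the first trials of a session)
#' sit on average later in the embedding than the items with the largest
#' values, the embedding is reversed so that the covariate runs forward.
#'
#' @param position item embedding positions in `[0, 1)`.
#' @param covariate numeric covariate per item (for example trial onset
#'   time).
#' @param n_ref how many extreme items to average on each end (default 10).
#' @return possibly flipped positions (`max(position) - position`).
#' @export
flip_if_reversed <- function(position, covariate, n_ref = 10L) {
  o <- order(covariate)
  n_ref <- min(n_ref, floor(length(position) / 2))
  first_mean <- mean(position[o[seq_len(n_ref)]])
  last_mean <- mean(position[rev(o)[seq_len(n_ref)]])
  if (first_mean > last_mean) max(position) - position else position
}

# One split step: partition the sorted cluster sequence into 4 contiguous
# blocks, recluster each block's items into twice as many clusters, and
# re-sort each block with the surrounding similarity context held fixed.
split_once <- function(state, feat, act_norm, locality, time_lag_window,
                       seed, context = 25L, kmeans_max_iter = 50L) {
  N <- nrow(state$centers)
  bounds <- round(seq(0, N, length.out = 5L))
  new_centers <- vector("list", 4L)
  new_traces <- vector("list", 4L)
  new_assign <- integer(length(state$item_cluster))
  offset <- 0L
  for (b in seq_len(4L)) {
    cl_range <- (bounds[b] + 1L):bounds[b + 1L]
    items_b <- which(state$item_cluster %in% cl_range)
    k_new <- min(2L * length(cl_range), length(items_b))
    if (length(items_b) == 0L)
      stop_input("a split block contains no items")
    if (k_new < 2L) {
      # degenerate block: keep as a single cluster
      ctr <- colMeans(feat[items_b, , drop = FALSE])
      new_centers[[b]] <- matrix(ctr, 1L)
      tr <- zscore_rows(matrix(colMeans(
        act_norm[items_b, , drop = FALSE]), 1L))
      new_traces[[b]] <- tr
      new_assign[items_b] <- offset + 1L
      offset <- offset + 1L
      next
    }
    km <- fit_scaled_kmeans(feat[items_b, , drop = FALSE], k_new,
                            seed = seed + b, max_iter = kmeans_max_iter)
    traces_b <- cluster_activity_traces(act_norm[items_b, , drop = FALSE], km)
    init_b <- initialize_ordering(km$centers)

    ctx_l <- max(bounds[b] - context + 1L, 1L):bounds[b]
    if (bounds[b] == 0L) ctx_l <- integer(0)
    ctx_r <- if (bounds[b + 1L] < N)
      (bounds[b + 1L] + 1L):min(bounds[b + 1L] + context, N) else integer(0)
    aug <- rbind(state$traces[ctx_l, , drop = FALSE],
                 traces_b,
                 state$traces[ctx_r, , drop = FALSE])
    cl <- length(ctx_l)
    cr <- length(ctx_r)
    S_aug <- compute_asymmetric_similarity(aug, time_lag_window)
    M_aug <- build_matching_matrix(nrow(aug), locality)
    init_aug <- c(seq_len(cl), cl + init_b, cl + k_new + seq_len(cr))
    opt <- optimize_ordering(S_aug, M_aug, init = init_aug,
                             fixed_left = cl, fixed_right = cr,
                             max_seg_len = 30L)
    mid <- opt$perm[(cl + 1L):(cl + k_new)] - cl  # block cluster order
    new_centers[[b]] <- km$centers[mid, , drop = FALSE]
    new_traces[[b]] <- traces_b[mid, , drop = FALSE]
    rank_of <- integer(k_new)
    rank_of[mid] <- seq_len(k_new)
    new_assign[items_b] <- offset + rank_of[km$assignment]
    offset <- offset + k_new
  }
  list(centers = do.call(rbind, new_centers),
       traces = do.call(rbind, new_traces),
       item_cluster = new_assign)
}

#' Split a sorting into blocks and re-sort each at higher resolution
#'
#' Refines an embedding in the spirit of space-filling curves: the current
#' sorted cluster sequence is divided into four contiguous blocks, the
#' items of each block are re-clustered into twice as many clusters, and
#' each block is re-sorted with the segment-move optimizer while the
#' similarity to the flanking context clusters is included in the score, so
#' block boundaries stay continuous. Each split doubles the number of
#' clusters (100 -> 200 -> 400 -> 800 after three splits); item positions
#' are recomputed from the final upsampled cluster centers. Splitting
#' sharpens local neighborhoods when the underlying structure has more than
#' one latent dimension, at the cost of a more fragmented global ordering.
#'
#' @param result a `rastermap` embedding (from [rastermap()]).
#' @param feat item feature matrix used for the embedding.
#' @param act_norm normalized activity matrix used for the embedding.
#' @param n_splits number of split rounds (0 returns `result` unchanged).
#' @param context number of flanking context clusters held fixed on each
#'   side of a re-sorted block (default 25).
#' @param seed integer seed controlling the re-clustering.
#' @return the updated `rastermap` object.
#' @export
split_and_resort <- function(result, feat, act_norm, n_splits,
                             context = 25L, seed = 0L) {
  n_splits <- as.integer(n_splits)
  if (is.na(n_splits) || n_splits < 0L) stop_param("n_splits must be >= 0")
  if (n_splits == 0L) return(result)
  cfg <- result$config
  state <- list(centers = result$centers_sorted,
                traces = result$traces_sorted,
                item_cluster = result$item_cluster_sorted)
  for (s in seq_len(n_splits)) {
    state <- split_once(state, feat, act_norm,
                        locality = cfg$locality,
                        time_lag_window = cfg$time_lag_window,
                        seed = seed + 1000L * s, context = context)
  }
  up <- upsample_centers(state$centers, factor = cfg$upsample_factor %||% 10L)
  asg <- assign_items(feat, up)
  result$centers_sorted <- state$centers
  result$traces_sorted <- state$traces
  result$item_cluster_sorted <- state$item_cluster
  result$item_position <- asg$position
  result$item_order <- order(asg$position, seq_along(asg$position))
  result$n_clusters_final <- nrow(state$centers)
  result$config$n_splits <- (cfg$n_splits %||% 0L) + n_splits
  result
}
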
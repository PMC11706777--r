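#' Scaled k-means clustering
#'
#' Fits the model `x_i = lambda_i * mu_{sigma_i} + noise`: like plain
#' k-means, but each item carries an amplitude `lambda_i`, so cluster
#' membership reflects the shape of an activity trace rather than its
#' amplitude. Items lying on a common direction with different gains fall in
#' one cluster, which plain k-means would split.
#'
#' The fit alternates (a) assigning each item to the cluster minimizing
#' `||x_i - lambda * mu_j||^2` with the per-pair optimal scale
#' `lambda = <x_i, mu_j> / <mu_j, mu_j>`, and (b) re-estimating each center
#' as the scale-weighted least-squares mean `sum(lambda_i x_i) /
#' sum(lambda_i^2)` of its members. Both steps are exact coordinate descent
#' on the summed squared residual, so the objective never increases. Centers
#' are seeded k-means++-style under `seed`; a cluster that empties is
#' re-seeded from the item with the largest current residual.
#'
#' @param x items x features numeric matrix (typically scaled singular
#'   vectors from [reduce_features()]).
#' @param n_clusters number of clusters (2..items). Around 100 works well
#'   for recordings of thousands of neurons.
#' @param seed integer seed for the k-means++ initialization.
#' @param max_iter maximum alternation count; iteration stops earlier when
#'   assignments no longer change.
#' @param nonneg_lambda constrain the per-item scales to be non-negative.
#'   Default `FALSE` (no sign constraint).
#' @return object of class `scaled_kmeans`: list with `centers`
#'   (n_clusters x features), `assignment` (item -> cluster index),
#'   `scale` (item -> lambda), `n_clusters`, `objective` (per-iteration
#'   summed squared residual), `iterations`.
#' @export
fit_scaled_kmeans <- function(x, n_clusters, seed = 0L, max_iter = 50L,
                              nonneg_lambda = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  n_clusters <- as.integer(n_clusters)
  if (is.na(n_clusters) || n_clusters < 2L || n_clusters > n)
    stop_param("n_clusters must be between 2 and the number of items")
  if (max_iter < 1L) stop_param("max_iter must be >= 1")

  x2 <- rowSums(x^2)
  centers <- with_seed(seed, kmeanspp_init(x, x2, n_clusters, nonneg_lambda))

  assign_old <- rep(-1L, n)
  objective <- numeric(0)
  lambda <- numeric(n)
  it <- 0L
  repeat {
    it <- it + 1L
    cn2 <- pmax(rowSums(centers^2), 1e-300)
    P <- x %*% t(centers)                       # n x k inner products
    Pm <- if (nonneg_lambda) pmax(P, 0) else P
    crit <- (Pm * Pm) / rep(cn2, each = n)      # explained squared norm
    assign_new <- max.col(crit, ties.method = "first")
    resid <- x2 - crit[cbind(seq_len(n), assign_new)]

    # re-seed empty clusters from the worst-explained items
    empty <- setdiff(seq_len(n_clusters), unique(assign_new))
    if (length(empty) > 0L) {
      worst <- order(resid, decreasing = TRUE)
      take <- worst[seq_along(empty)]
      centers[empty, ] <- x[take, , drop = FALSE]
      assign_new[take] <- empty
      cn2[empty] <- pmax(x2[take], 1e-300)
      P[cbind(take, empty)] <- x2[take]
      resid[take] <- 0
    }
    lambda <- P[cbind(seq_len(n), assign_new)] / cn2[assign_new]
    if (nonneg_lambda) lambda <- pmax(lambda, 0)
    objective <- c(objective, sum(pmax(resid, 0)))

    if (identical(assign_new, assign_old) || it >= max_iter) {
      assign_old <- assign_new
      break
    }
    assign_old <- assign_new

    num <- rowsum(x * lambda, assign_new, reorder = FALSE)
    den <- rowsum(lambda^2, assign_new, reorder = FALSE)
    grp <- as.integer(rownames(num))
    keep <- den[, 1] > 1e-300
    centers[grp[keep], ] <- num[keep, , drop = FALSE] / den[keep, 1]
  }

  structure(list(centers = centers, assignment = assign_old, scale = lambda,
                 n_clusters = n_clusters, objective = objective,
                 iterations = it, seed = seed),
            class = "scaled_kmeans")
}

# k-means++ style seeding using the scaled-residual distance
kmeanspp_init <- function(x, x2, k, nonneg_lambda) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- scaled_resid_to(x, x2, x[idx[1], ], nonneg_lambda)
  for (j in 2:k) {
    p <- pmax(d2, 0)
    if (sum(p) <= 0) {
      cand <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- cand[sample.int(length(cand), 1L)]
    } else {
      idx[j] <- sample.int(n, 1L, prob = p)
    }
    d2 <- pmin(d2, scaled_resid_to(x, x2, x[idx[j], ], nonneg_lambda))
  }
  x[idx, , drop = FALSE]
}

scaled_resid_to <- function(x, x2, center, nonneg_lambda) {
  cn2 <- max(sum(center^2), 1e-300)
  p <- drop(x %*% center)
  if (nonneg_lambda) p <- pmax(p, 0)
  pmax(x2 - p^2 / cn2, 0)
}

#' @export
print.scaled_kmeans <- function(x, ...) {
  cat("scaled k-means fit:", x$n_clusters, "clusters,",
      length(x$assignment), "items,", x$iterations, "iterations\n")
  cat("final objective:", format(utils::tail(x$objective, 1)), "\n")
  invisible(x)
}

#' Mean activity trace per cluster, z-scored
#'
#' Averages the (normalized) activity rows of each cluster's members and
#' z-scores each resulting trace. The traces are the inputs to the
#' asymmetric similarity computation. An empty cluster yields an all-zero
#' row (recorded in attribute `"empty_clusters"` with a warning).
#'
#' @param act items x timepoints matrix, normally normalized activity.
#' @param model a `scaled_kmeans` fit (or any list with `assignment` and
#'   `n_clusters`).
#' @param lambda_weighted average members weighted by their fitted
#'   amplitudes instead of uniformly. Default `FALSE` (unweighted average,
#'   then z-score).
#' @return n_clusters x timepoints matrix of z-scored cluster traces.
#' @export
cluster_activity_traces <- function(act, model, lambda_weighted = FALSE) {
  if (!is.matrix(act)) act <- as.matrix(act)
  asg <- model$assignment
  k <- model$n_clusters
  if (length(asg) != nrow(act))
    stop_input("model assignment does not cover all rows of the activity")
  # rowsum() returns rows only for groups that are present, so aggregate
  # into a full k-row matrix explicitly (empty clusters keep zero rows)
  traces <- matrix(0, k, ncol(act))
  if (lambda_weighted) {
    w <- model$scale
    num <- rowsum(act * w, asg)
    den <- rowsum(w, asg)[, 1]
    idx <- as.integer(rownames(num))
    ok <- is.finite(den) & abs(den) > 1e-300
    traces[idx[ok], ] <- num[ok, , drop = FALSE] / den[ok]
  } else {
    num <- rowsum(act, asg)
    idx <- as.integer(rownames(num))
    counts <- tabulate(asg, nbins = k)
    traces[idx, ] <- num / counts[idx]
  }
  traces[!is.finite(traces)] <- 0
  traces <- zscore_rows(traces)
  empty <- which(tabulate(asg, nbins = k) == 0L)
  if (length(empty) > 0L) {
    traces[empty, ] <- 0
    warning(length(empty), " empty cluster(s); their traces are all-zero")
  }
  attr(traces, "empty_clusters") <- empty
  traces
}
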
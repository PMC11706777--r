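#' Sort a neural population recording along one dimension
#'
#' Runs the full Rastermap-style embedding pipeline on an items x
#' timepoints activity matrix: normalization, reduction to scaled singular
#' vectors, scaled k-means clustering, asymmetric peak-lag similarity
#' between cluster traces, segment-move optimization of the cluster order
#' against a matching matrix, upsampling of the sorted centers, and
#' assignment of every item to a continuous embedding position. The result
#' is a permutation of the rows such that nearby rows have similar
#' activity, suitable as the row order of a raster plot.
#'
#' With fewer than 200 items and `n_clusters = NULL` the clustering step is
#' skipped and items are sorted directly (each item acts as its own
#' cluster). For trial sorting, pass trials in rows and set
#' `mean_time = FALSE`.
#'
#' @param x numeric matrix, items (neurons or trials) by timepoints.
#' @param n_clusters number of clusters; `NULL` uses 100, or bypasses
#'   clustering entirely when the input has fewer than 200 rows.
#' @param n_PCs number of scaled singular vectors kept (default 200).
#' @param locality matching-matrix locality weight in `[0, 1]` (default
#'   0.75): 0 favors global structure, 1 local sequence preservation.
#' @param time_lag_window maximum cross-correlation lag in timepoints
#'   (default 10); 0 gives a symmetric similarity.
#' @param zscore,mean_time,time_bin normalization options, see
#'   [normalize_activity()].
#' @param n_splits rounds of split-and-resort refinement (default 0), see
#'   [split_and_resort()].
#' @param superneuron_bin if not `NULL`, also return superneurons of this
#'   bin size computed from the sorted normalized activity.
#' @param seed integer seed controlling the clustering initialization (and
#'   the re-clustering inside splits).
#' @param n_iter optimizer iteration cap (default 400).
#' @param skip optimizer coarse-pass stride minus one; `NULL` uses
#'   `floor(n_clusters / 30)`.
#' @param reverse_segments optimizer reversal-move setting, see
#'   [optimize_ordering()].
#' @param upsample_factor nodes per cluster in the upsampling step
#'   (default 10).
#' @param keep_data keep the normalized activity and features in the
#'   returned object (default TRUE; needed by [split_and_resort()] and
#'   plotting, but large).
#' @return object of class `rastermap`: list with `item_order`
#'   (permutation of rows), `item_position` (item -> `[0, 1)`),
#'   `cluster_perm` (the optimized cluster ordering, see
#'   [optimize_ordering()]), `S` (asymmetric
#'   similarity), `M` (matching matrix), `model` (the `scaled_kmeans` fit,
#'   or `NULL` in bypass mode), `superneurons` (or `NULL`), `config`, and
#'   the sorted centers/traces used by downstream steps.
#' @examples
#' sim <- generate_powerlaw_simulation(seed = 1, n_items = 300, n_time = 800)
#' emb <- rastermap(sim$activity, n_clusters = 30, n_PCs = 32,
#'                  locality = 0, time_lag_window = 0)
#' abs(cor(emb$item_position, sim$ground_truth_position,
#'         method = "spearman"))
#' @export
rastermap <- function(x, n_clusters = NULL, n_PCs = 200L, locality = 0.75,
                      time_lag_window = 10L, zscore = TRUE, mean_time = TRUE,
                      time_bin = 1L, n_splits = 0L, superneuron_bin = NULL,
                      seed = 0L, n_iter = 400L, skip = NULL,
                      reverse_segments = NULL,
                      upsample_factor = 10L, keep_data = TRUE) {
  check_activity(x)
  n <- nrow(x)
  bypass <- is.null(n_clusters) && n < 200L
  if (is.null(n_clusters)) n_clusters <- if (bypass) NA_integer_ else 100L

  act <- normalize_activity(x, zscore = zscore, mean_time = mean_time,
                            time_bin = time_bin)
  feat <- reduce_features(act, n_PCs = n_PCs)

  if (bypass) {
    model <- NULL
    traces <- zscore_rows(act)
    centers <- feat
    assignment <- seq_len(n)
    N <- n
  } else {
    model <- fit_scaled_kmeans(feat, n_clusters = n_clusters, seed = seed)
    traces <- cluster_activity_traces(act, model)
    centers <- model$centers
    assignment <- model$assignment
    N <- model$n_clusters
  }

  S <- compute_asymmetric_similarity(traces, time_lag_window)
  M <- build_matching_matrix(N, locality)
  init <- initialize_ordering(centers)
  ord <- optimize_ordering(S, M, init = init, n_iter = n_iter, skip = skip,
                           reverse_segments = reverse_segments)

  centers_sorted <- centers[ord$perm, , drop = FALSE]
  traces_sorted <- traces[ord$perm, , drop = FALSE]
  inv <- integer(N)
  inv[ord$perm] <- seq_len(N)
  item_cluster_sorted <- inv[assignment]

  up <- upsample_centers(centers_sorted, factor = upsample_factor)
  asg <- assign_items(feat, up)
  item_order <- order(asg$position, seq_len(n))

  cfg <- list(n_clusters = if (bypass) NULL else n_clusters, n_PCs = n_PCs,
              locality = locality, time_lag_window = time_lag_window,
              zscore = zscore, mean_time = mean_time, time_bin = time_bin,
              n_splits = 0L, seed = seed, n_iter = n_iter,
              skip = skip, upsample_factor = upsample_factor,
              bypass_clustering = bypass)
  res <- structure(list(item_order = item_order,
                        item_position = asg$position,
                        cluster_perm = ord, S = S, M = M, model = model,
                        superneurons = NULL,
                        centers_sorted = centers_sorted,
                        traces_sorted = traces_sorted,
                        item_cluster_sorted = item_cluster_sorted,
                        n_clusters_final = N,
                        config = cfg),
                   class = "rastermap")

  if (n_splits > 0L) {
    if (bypass)
      stop_param("n_splits requires the clustering path (>= 200 items)")
    res <- split_and_resort(res, feat, act, n_splits = n_splits,
                            seed = seed)
  }
  if (!is.null(superneuron_bin))
    res$superneurons <- make_superneurons(
      act[res$item_order, , drop = FALSE], superneuron_bin)
  if (keep_data) {
    res$features <- feat
    res$activity_normalized <- act
  }
  res
}

#' Parameter presets for common recording types
#'
#' Returns the parameter combinations found to work well for particular
#' dataset types: `"virtual_reality"` (task recordings with sequences;
#' locality 0.75, lag window 10), `"spontaneous"` (locality 0, lag window
#' 5, 128 PCs), `"multimodule_benchmark"` (locality 0.8, lag window 10),
#' `"powerlaw"` and `"place_2d"` (locality 0, lag window 0).
#'
#' @param name preset name.
#' @return named list of arguments for [rastermap()].
#' @export
rastermap_preset <- function(name = c("virtual_reality", "spontaneous",
                                      "multimodule_benchmark", "powerlaw",
                                      "place_2d")) {
  name <- match.arg(name)
  switch(name,
    virtual_reality = list(n_clusters = 100L, n_PCs = 200L,
                           locality = 0.75, time_lag_window = 10L),
    spontaneous = list(n_clusters = 100L, n_PCs = 128L,
                       locality = 0.0, time_lag_window = 5L),
    multimodule_benchmark = list(n_clusters = 100L, n_PCs = 200L,
                                 locality = 0.8, time_lag_window = 10L,
                                 time_bin = 3L, reverse_segments = TRUE),
    powerlaw = list(n_clusters = 100L, n_PCs = 200L,
                    locality = 0.0, time_lag_window = 0L),
    place_2d = list(n_clusters = 100L, n_PCs = 400L,
                    locality = 0.0, time_lag_window = 0L))
}

#' @export
print.rastermap <- function(x, ...) {
  cfg <- x$config
  cat("rastermap embedding of", length(x$item_order), "items\n")
  if (isTRUE(cfg$bypass_clustering)) {
    cat("  clustering bypassed (items sorted directly)\n")
  } else {
    cat("  clusters:", x$n_clusters_final,
        if ((cfg$n_splits %||% 0L) > 0L)
          paste0("(after ", cfg$n_splits, " split round(s))") else "", "\n")
  }
  cat("  n_PCs:", cfg$n_PCs, " locality:", cfg$locality,
      " time_lag_window:", cfg$time_lag_window, "\n")
  cat("  ordering score:", format(x$cluster_perm$score), "\n")
  invisible(x)
}

#' Plot a sorted activity raster
#'
#' Draws the normalized activity (or superneurons, if present) with rows in
#' embedding order as an image, the standard visualization this sorting
#' exists for.
#'
#' @param x a `rastermap` object (run with `keep_data = TRUE` or a
#'   `superneuron_bin`).
#' @param max_rows display at most this many rows (binned if needed).
#' @param ... passed to [graphics::image()].
#' @export
plot.rastermap <- function(x, max_rows = 400L, ...) {
  mat <- x$superneurons
  if (is.null(mat)) {
    if (is.null(x$activity_normalized))
      stop_input("nothing to plot: rerun with keep_data = TRUE or superneuron_bin set")
    mat <- x$activity_normalized[x$item_order, , drop = FALSE]
    if (nrow(mat) > max_rows)
      mat <- make_superneurons(mat, ceiling(nrow(mat) / max_rows))
  }
  lim <- stats::quantile(abs(mat), 0.98)
  mat[mat > lim] <- lim
  mat[mat < -lim] <- -lim
  graphics::image(t(mat)[, rev(seq_len(nrow(mat))), drop = FALSE],
                  col = grDevices::gray.colors(128, start = 1, end = 0),
                  xlab = "time", ylab = "sorted items", axes = FALSE, ...)
  graphics::box()
  invisible(x)
}

#' Save an embedding result to disk
#'
#' Writes the full result object as RDS next to a plain-text export of the
#' item order, so the sorting can be consumed by other tools.
#'
#' @param result a `rastermap` object.
#' @param path output `.rds` path; the order is additionally written to
#'   `<path>.order.txt`.
#' @export
save_embedding <- function(result, path) {
  saveRDS(result, path)
  write_order(result$item_order, paste0(path, ".order.txt"))
  invisible(path)
}
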
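#' Normalize an activity matrix
#'
#' Prepares an items x timepoints activity matrix for embedding: optional
#' averaging of consecutive timepoints into bins, z-scoring of each row, and
#' projection of the across-items mean out of each timepoint. Row-wise
#' z-scoring removes single-neuron rate statistics so that the embedding is
#' driven by the shape of each trace; projecting out the population mean
#' (`mean_time`) removes global co-fluctuations that would otherwise dominate
#' the first component.
#'
#' Rows with zero variance are mapped to all-zero rows (a small guard
#' `1e-10` is added to the standard deviation), keeping the item count
#' stable; filtering out silent neurons is the caller's job.
#'
#' @param x numeric matrix, items (neurons or trials) by timepoints.
#' @param zscore z-score each row (mean 0, sd 1). Default `TRUE`.
#' @param mean_time subtract the across-rows mean from each timepoint after
#'   z-scoring. Default `TRUE`; set to `FALSE` when sorting trials, or when
#'   the grand population average is itself of interest.
#' @param time_bin positive integer; average this many consecutive
#'   timepoints into one (1 = no binning). A trailing partial block is
#'   dropped. Binning is applied before z-scoring by default.
#' @param bin_first if `FALSE`, bin after normalizing instead of before.
#' @return the normalized matrix, same number of rows as `x`.
#' @export
normalize_activity <- function(x, zscore = TRUE, mean_time = TRUE,
                               time_bin = 1L, bin_first = TRUE) {
  check_activity(x)
  time_bin <- as.integer(time_bin)
  if (is.na(time_bin) || time_bin < 1L)
    stop_param("time_bin must be a positive integer")
  if (bin_first) x <- bin_time(x, time_bin)
  if (zscore) x <- zscore_rows(x)
  if (mean_time) {
    cm <- colMeans(x)
    x <- x - rep(cm, each = nrow(x))
  }
  if (!bin_first) x <- bin_time(x, time_bin)
  if (ncol(x) < 2L)
    stop_input("fewer than 2 timepoints after binning")
  x
}

bin_time <- function(x, time_bin) {
  if (time_bin == 1L) return(x)
  nb <- ncol(x) %/% time_bin
  if (nb < 2L) stop_input("fewer than 2 timepoints after binning")
  acc <- x[, seq(1L, by = time_bin, length.out = nb), drop = FALSE]
  for (o in seq_len(time_bin - 1L))
    acc <- acc + x[, seq(1L + o, by = time_bin, length.out = nb), drop = FALSE]
  acc / time_bin
}

# population-sd z-scoring: (1/T) sum z_i z_j of two z-scored rows is then
# exactly their Pearson correlation, so similarity diagonals equal 1
zscore_rows <- function(x, eps = 1e-10) {
  rm_ <- rowMeans(x)
  x <- x - rm_
  sds <- sqrt(rowMeans(x^2))
  x / (sds + eps)
}

#' Reduce an activity matrix to scaled singular-vector features
#'
#' Computes the singular value decomposition of the (normalized) activity
#' matrix and returns the top left singular vectors, each scaled by its
#' singular value. Scaling by the singular values preserves inter-item
#' distances and inner products of the original matrix up to truncation, so
#' clustering the features is equivalent to clustering the full traces.
#'
#' The decomposition is computed exactly: directly via [svd()] when the
#' smaller dimension is modest, otherwise through an eigendecomposition of
#' the smaller cross-product matrix, which costs far less than a full SVD at
#' typical sizes (tens of thousands of neurons by tens of thousands of
#' timepoints) and is fully deterministic.
#'
#' @param x numeric matrix, items by timepoints (normally the output of
#'   [normalize_activity()]).
#' @param n_PCs number of components to keep (capped at `min(dim(x))`).
#'   Values of 100 to 400 are typical for large recordings.
#' @return items x n_PCs matrix of scaled left singular vectors, with the
#'   singular values in attribute `"singular_values"`.
#' @export
reduce_features <- function(x, n_PCs = 200L) {
  check_activity(x)
  n_PCs <- as.integer(n_PCs)
  if (is.na(n_PCs) || n_PCs < 1L) stop_param("n_PCs must be >= 1")
  k <- min(n_PCs, nrow(x), ncol(x))
  small <- min(dim(x)) <= 512L
  if (small) {
    sv <- svd(x, nu = k, nv = 0)
    feat <- sv$u * rep(sv$d[seq_len(k)], each = nrow(x))
    d <- sv$d[seq_len(k)]
  } else if (nrow(x) <= ncol(x)) {
    G <- tcrossprod(x)
    eg <- eigen(G, symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(k)], 0))
    feat <- eg$vectors[, seq_len(k), drop = FALSE] * rep(d, each = nrow(x))
  } else {
    G <- crossprod(x)
    eg <- eigen(G, symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(k)], 0))
    # features = U * diag(d) = X %*% V
    feat <- x %*% eg$vectors[, seq_len(k), drop = FALSE]
  }
  dimnames(feat) <- list(rownames(x), NULL)
  attr(feat, "singular_values") <- d
  feat
}

#' Bin spike times into an activity matrix
#'
#' Converts event (spike) times into spike counts per time bin, with
#' half-open bins: an event at exactly a bin boundary belongs to the later
#' bin. Events outside `[t_start, t_end)` are discarded; all events inside
#' the window are counted.
#'
#' @param spikes two-column data.frame or matrix: item id, event time in
#'   seconds. Ids may be arbitrary (integers, strings); one row per event.
#' @param bin_width_s bin width in seconds (> 0).
#' @param t_start,t_end window bounds in seconds, `t_end > t_start`.
#' @param item_ids optional vector of ids fixing the row set and order;
#'   defaults to the sorted unique ids present in `spikes`.
#' @return integer matrix of counts, items by bins. Row names are the ids.
#' @export
bin_spike_times <- function(spikes, bin_width_s, t_start, t_end,
                            item_ids = NULL) {
  if (bin_width_s <= 0) stop_param("bin_width_s must be > 0")
  if (t_end <= t_start) stop_param("t_end must be greater than t_start")
  if (is.matrix(spikes)) spikes <- as.data.frame(spikes)
  if (length(spikes) < 2L && (is.null(dim(spikes)) || ncol(spikes) < 2L))
    stop_input("spikes must have two columns: item id, time")
  ids <- spikes[[1L]]
  tt <- as.numeric(spikes[[2L]])
  n_bins <- as.integer(ceiling((t_end - t_start) / bin_width_s - 1e-9))
  if (is.null(item_ids)) item_ids <- sort(unique(ids))
  out <- matrix(0L, nrow = length(item_ids), ncol = n_bins,
                dimnames = list(as.character(item_ids), NULL))
  keep <- which(tt >= t_start & tt < t_end & ids %in% item_ids)
  if (length(keep) == 0L) {
    warning("no events inside the time window; returning an all-zero matrix")
    return(out)
  }
  bin <- pmin(floor((tt[keep] - t_start) / bin_width_s), n_bins - 1) + 1L
  row <- match(ids[keep], item_ids)
  counts <- table(factor(row, levels = seq_along(item_ids)),
                  factor(bin, levels = seq_len(n_bins)))
  out[] <- as.integer(counts)
  out
}

#' Read an activity matrix from file
#'
#' Supported formats, chosen by extension: delimited text (`.csv`, `.tsv`,
#' `.txt`; items in rows), MatrixMarket (`.mtx`), and R serialized matrices
#' (`.rds`).
#'
#' @param path input file.
#' @return numeric matrix, items by timepoints.
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    tsv = ,
    txt = as.matrix(utils::read.table(path, header = FALSE)),
    mtx = {
      if (!requireNamespace("Matrix", quietly = TRUE))
        stop_input("the Matrix package is required to read .mtx files")
      as.matrix(Matrix::readMM(path))
    },
    rds = {
      v <- readRDS(path)
      if (inherits(v, "sim_dataset")) v$activity else as.matrix(v)
    },
    stop_input("unsupported activity format: .", ext)
  )
  storage.mode(x) <- "double"
  check_activity(x)
  x
}

#' Read spike events from a two-column text file
#'
#' One event per line: item id then event time in seconds, whitespace
#' separated.
#'
#' @param path input file.
#' @return data.frame with columns `item` and `time`.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("item", "time"))
  df$time <- as.numeric(df$time)
  df
}

#' Write a sorting as a one-column integer text file
#'
#' @param order integer vector (a permutation of item indices).
#' @param path output file.
#' @export
write_order <- function(order, path) {
  utils::write.table(matrix(as.integer(order), ncol = 1), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an externally produced ordering (for example from t-SNE or UMAP)
#'
#' Reads a one-column integer index file so that orderings produced outside
#' this package can be scored with the benchmark metrics.
#'
#' @param path input file with one integer index per line.
#' @param n expected number of items (optional check).
#' @return integer permutation vector.
#' @export
read_external_ordering <- function(path, n = NULL) {
  v <- as.integer(utils::read.table(path, header = FALSE)[[1L]])
  if (min(v) == 0L) v <- v + 1L # accept 0-based indices
  if (!is.null(n) && (length(v) != n || !setequal(v, seq_len(n))))
    stop_input("file does not contain a permutation of 1..", n)
  if (anyDuplicated(v)) stop_input("ordering contains duplicate indices")
  v
}
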
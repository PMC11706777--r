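#' Asymmetric peak-lag similarity between cluster traces
#'
#' For z-scored traces `c_i`, computes the lagged cross-correlation
#' `(c_i * c_j)[tau] = (1/T) sum_t c_i(t - tau) c_j(t)` over non-negative
#' lags `tau = 0..time_lag_window` and keeps the maximum:
#' `S[i, j] = max_tau (c_i * c_j)[tau]`. `S[i, j]` is large when trace `i`
#' leads trace `j`, so the matrix is asymmetric for `time_lag_window > 0`;
#' the asymmetry lets the sorter place leading clusters before following
#' ones and thereby represent activity sequences. Lags are realized by
#' truncating the overlapping part of the traces (no wraparound) with a
#' fixed `1/T` normalization.
#'
#' @param traces n x T matrix of z-scored traces (see
#'   [cluster_activity_traces()]).
#' @param time_lag_window maximum lag in timepoints (>= 0, < T). 0 gives
#'   the plain symmetric correlation matrix.
#' @return n x n similarity matrix with attribute `"time_lag_window"`.
#' @export
compute_asymmetric_similarity <- function(traces, time_lag_window = 0L) {
  if (!is.matrix(traces)) traces <- as.matrix(traces)
  Tn <- ncol(traces)
  tau_max <- as.integer(time_lag_window)
  if (is.na(tau_max) || tau_max < 0L)
    stop_param("time_lag_window must be a non-negative integer")
  if (tau_max >= Tn)
    stop_param("time_lag_window must be smaller than the number of timepoints")
  S <- tcrossprod(traces) / Tn
  if (tau_max > 0L) {
    for (tau in seq_len(tau_max)) {
      cc <- traces[, seq_len(Tn - tau), drop = FALSE] %*%
        t(traces[, (tau + 1L):Tn, drop = FALSE]) / Tn
      S <- pmax(S, cc)
    }
  }
  attr(S, "time_lag_window") <- tau_max
  S
}

#' Build the matching matrix the sorted similarity is scored against
#'
#' The matching matrix is the target pattern for the sorted similarity
#' matrix. It mixes a global term with heavy-tailed decay,
#' `M_global[i, j] = -log(|x_i - x_j| + 0.001)` with `x_i = i/N` (its
#' eigenvalues decay approximately as a power law with exponent 1, matching
#' the long-tailed correlation structure of neural population activity), and
#' a local travelling-salesman term
#' `M_local[i, j] = exp(-(x_i - x_j)^2 / (2 sigma^2))`, `sigma = 1/(2N)`,
#' which is close to 1 on the first off-diagonal and tiny elsewhere. Both
#' terms have zero diagonal, the strictly lower triangle zeroed (so that
#' correlations are pushed above the diagonal, enforcing forward sequences),
#' and are normalized by their mean before mixing:
#' `M = (1 - w) M_global + w M_local` with locality weight `w`.
#'
#' @param N matrix size (number of clusters), >= 2.
#' @param locality mixing weight `w` in `[0, 1]`; 0 = purely global
#'   structure, 1 = purely local sequence preservation.
#' @param mask_lower zero the strictly lower triangle of each component
#'   (default `TRUE`; set `FALSE` to obtain the full symmetric matrices,
#'   for example to inspect the eigenspectrum of the global term).
#' @param zero_diag zero the diagonal of each component (default `TRUE`,
#'   as used for sorting). With `FALSE` the diagonal keeps the kernel's
#'   own value at distance zero (`-log(0.001)` for the global term, 1 for
#'   the local term); the global kernel's eigenvalue magnitudes then decay
#'   approximately as a power law with exponent 1.
#' @param normalize divide each component by its mean (default `TRUE`).
#' @param mean_mode mean over `"all"` N^2 entries (default) or over the
#'   `"upper"` strict triangle only.
#' @return N x N matching matrix with attribute `"locality"`.
#' @export
build_matching_matrix <- function(N, locality, mask_lower = TRUE,
                                  normalize = TRUE,
                                  mean_mode = c("all", "upper"),
                                  zero_diag = TRUE) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop_param("N must be >= 2")
  if (!is.numeric(locality) || is.na(locality) ||
      locality < 0 || locality > 1)
    stop_param("locality must lie in [0, 1]")
  mean_mode <- match.arg(mean_mode)
  x <- (seq_len(N) - 1L) / N
  D <- abs(outer(x, x, "-"))
  Mg <- -log(D + 0.001)
  sigma <- 1 / (2 * N)
  Ml <- exp(-D^2 / (2 * sigma^2))
  if (zero_diag) {
    diag(Mg) <- 0
    diag(Ml) <- 0
  }
  if (mask_lower) {
    low <- lower.tri(Mg)
    Mg[low] <- 0
    Ml[low] <- 0
  }
  if (normalize) {
    if (mean_mode == "all") {
      Mg <- Mg / mean(Mg)
      Ml <- Ml / mean(Ml)
    } else {
      ut <- upper.tri(Mg)
      Mg <- Mg / mean(Mg[ut])
      Ml <- Ml / mean(Ml[ut])
    }
  }
  M <- (1 - locality) * Mg + locality * Ml
  attr(M, "locality") <- locality
  M
}
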
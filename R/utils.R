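`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("rastermapr_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_param <- function(...) {
  stop(structure(class = c("rastermapr_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_activity <- function(x, min_rows = 2L, min_cols = 2L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input("activity must be a numeric matrix (items x timepoints)")
  if (nrow(x) < min_rows || ncol(x) < min_cols)
    stop_input("activity must have at least ", min_rows, " rows and ",
               min_cols, " columns")
  if (!all(is.finite(x)))
    stop_input("activity contains non-finite entries")
  invisible(x)
}

# Gaussian smoothing of a vector by a truncated kernel; edges renormalized by
# the in-window kernel mass so the filter has unit gain everywhere.
gauss_smooth <- function(x, sd) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(4 * sd))
  kern <- stats::dnorm(seq(-half, half), sd = sd)
  n <- length(x)
  padded <- c(rep(0, half), x, rep(0, half))
  num <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + n)]
  ones <- c(rep(0, half), rep(1, n), rep(0, half))
  den <- stats::filter(ones, kern, sides = 2)[(half + 1):(half + n)]
  as.numeric(num / den)
}

# Exponential causal filter exp(-t/tau), t >= 0, peak value 1.
exp_filter <- function(tau, len = ceiling(6 * tau)) {
  exp(-(seq_len(len) - 1) / tau)
}

# Causal convolution of a signal with a filter, keeping the original
# length. FFT length is padded to a 2-3-5-smooth size: R's mixed-radix FFT
# degrades to quadratic time on lengths with large prime factors.
conv_causal <- function(x, h) {
  n <- length(x)
  L <- stats::nextn(n + length(h) - 1L, factors = c(2L, 3L, 5L))
  xp <- c(x, rep(0, L - n))
  hp <- c(h, rep(0, L - length(h)))
  y <- Re(stats::fft(stats::fft(xp) * stats::fft(hp), inverse = TRUE)) / L
  y[seq_len(n)]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
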
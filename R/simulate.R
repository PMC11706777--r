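#' Multi-module benchmark simulation
#'
#' Generates a synthetic population with five one-dimensional modules and
#' known ground truth, for benchmarking 1-D embeddings: two sequence
#' modules (neurons activate at a random position along a repeating
#' sequence with variable velocity and occasional mid-sequence breaks), a
#' tuning-curve module (Gaussian tuning to 15 discrete stimuli on a 1-D
#' axis, exponentially decaying responses), a sustained-response module
#' (difference-of-exponentials responses to a single stimulus with 100
#' latency/duration timescales), and a power-law module whose eigenvalues
#' decay as `1/k^1.5`, mimicking the spectrum of spontaneous cortical
#' activity. The power-law activity is added to every neuron with weight
#' 0.75, each neuron's rate is scaled by an exponential draw, spikes are
#' Poisson, and independent Poisson noise of mean 0.03 is added.
#'
#' At `scale = 1` the simulation has 6,000 neurons (1,000 per module except
#' 2,000 in the power-law module, which are driven solely by it) and
#' 50,000 timepoints (500 tuning-stimulus presentations spaced 100
#' timepoints apart). `scale < 1` shrinks neuron and timepoint counts
#' proportionally, preserving the 1:1:1:1:2 module proportions.
#'
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param scale size factor in `(0, 1]`.
#' @param params optional list overriding generator constants (see the
#'   package vignette): `seq_tuning_width`, `seq_vel_noise`,
#'   `powerlaw_K`, `powerlaw_density`, `powerlaw_peak`,
#'   `noise_mean`, `tuning_sd`.
#' @return object of class `sim_dataset`: list with `activity` (spike
#'   count matrix, neurons x timepoints), `module_label` (factor),
#'   `ground_truth_position` (latent position in `[0, 1]` per neuron),
#'   `params` and `seed`.
#' @export
generate_benchmark_simulation <- function(seed, scale = 1, params = list()) {
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    stop_param("scale must lie in (0, 1]")
  p <- utils::modifyList(list(
    n_per_module = 1000L, n_powerlaw = 2000L, n_time = 50000L,
    n_presentations = 500L, presentation_spacing = 100L,
    seq_tuning_width = 0.05, seq_vel_noise = 0.5,
    tuning_sd = 0.15, tuning_positions = 1500L, n_stimuli = 15L,
    response_decay = 25, sustained_isi_decay = 750,
    sustained_isi_min = 2000, n_timescales = 100L,
    powerlaw_exponent = 1.5, powerlaw_K = 200L, powerlaw_density = 0.03,
    powerlaw_tau = 25, powerlaw_weight = 0.75, powerlaw_peak = 1.0,
    rate_peak = 6.0, noise_mean = 0.03, rate_scale_mean = 1.0), params)

  n_mod <- round(p$n_per_module * scale)
  n_pl <- round(p$n_powerlaw * scale)
  if (n_mod < 10L || n_pl < 10L)
    stop_param("scale too small: fewer than 10 neurons per module")
  Tn <- round(p$n_time * scale)
  n_pres <- max(1L, round(p$n_presentations * scale))
  n_total <- 4L * n_mod + n_pl

  set.seed(as.integer(seed))
  x_pl <- stats::runif(n_total)  # power-law latent per neuron

  act <- matrix(0, n_total, Tn)
  truth <- numeric(n_total)
  rows <- split(seq_len(n_total),
                rep(1:5, c(n_mod, n_mod, n_mod, n_mod, n_pl)))

  for (m in 1:2) {
    sq <- sim_sequence_module(n_mod, Tn, width = p$seq_tuning_width,
                              vel_noise = p$seq_vel_noise)
    act[rows[[m]], ] <- sq$rate
    truth[rows[[m]]] <- sq$position
    rm(sq)  # module rate matrices are large; free them eagerly
  }
  tn <- sim_tuning_module(n_mod, Tn, n_pres, p$presentation_spacing,
                          p$tuning_positions, p$n_stimuli, p$tuning_sd,
                          p$response_decay)
  act[rows[[3]], ] <- tn$rate
  truth[rows[[3]]] <- tn$position
  rm(tn)
  su <- sim_sustained_module(n_mod, Tn, p$n_timescales,
                             p$sustained_isi_decay, p$sustained_isi_min)
  act[rows[[4]], ] <- su$rate
  truth[rows[[4]]] <- su$position
  rm(su)
  truth[rows[[5]]] <- x_pl[rows[[5]]]

  # power-law component, added to every neuron. The chunk loops are inlined
  # here (not helper calls) so that subassignment into `act` stays in place:
  # a second live reference would force a full copy of a matrix that is
  # 2.4 GB at scale 1.
  pl <- sim_powerlaw_factors(x_pl, Tn, p$powerlaw_exponent,
                             K = min(p$powerlaw_K, Tn %/% 2, n_total),
                             density = p$powerlaw_density,
                             tau = p$powerlaw_tau)
  alpha <- powerlaw_rate_scale(pl$U, pl$V, p$powerlaw_peak)
  w <- p$powerlaw_weight * alpha
  chunk <- 2000L
  for (c0 in seq(1L, Tn, by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, Tn)
    act[, cols] <- act[, cols, drop = FALSE] +
      w * pmax(pl$U %*% pl$V[, cols, drop = FALSE], 0)
  }
  pl <- NULL

  # per-neuron firing-rate diversity, conversion to spikes per bin
  # (rate_peak = peak spike count of a unit-amplitude response), Poisson
  # spiking and additive Poisson noise, all in one in-place pass
  rate_gain <- p$rate_peak * stats::rexp(n_total, rate = 1 / p$rate_scale_mean)
  for (c0 in seq(1L, Tn, by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, Tn)
    lam <- act[, cols, drop = FALSE] * rate_gain + p$noise_mean
    act[, cols] <- stats::rpois(length(lam), lam)
  }

  module_label <- factor(rep(c("sequence1", "sequence2", "tuning",
                               "sustained", "powerlaw"),
                             c(n_mod, n_mod, n_mod, n_mod, n_pl)),
                         levels = c("sequence1", "sequence2", "tuning",
                                    "sustained", "powerlaw"))
  structure(list(activity = act, module_label = module_label,
                 ground_truth_position = truth,
                 params = c(p, list(scale = scale, n_time = Tn,
                                    n_neurons = n_total)),
                 seed = seed),
            class = "sim_dataset")
}

# Sequence module: repeating traversals of a 1-D track with variable
# velocity, 350-700 timepoint repetitions, 100-200 timepoint gaps, and a
# 50% chance per repetition of a mid-sequence pause.
sim_sequence_module <- function(n, Tn, width = 0.015, vel_noise = 0.5,
                                rep_len = c(350L, 700L),
                                gap_len = c(100L, 200L),
                                break_prob = 0.5,
                                break_len = c(50L, 150L)) {
  grid <- (seq_len(10L * n) - 0.5) / (10L * n)
  position <- sample(grid, n)  # without replacement: distinct latents
  rate <- matrix(0, n, Tn)
  t0 <- 1L
  while (t0 <= Tn) {
    len <- sample(rep_len[1]:rep_len[2], 1L)
    vel <- 1 + vel_noise * gauss_smooth(stats::rnorm(len), 30)
    vel <- pmax(vel, 0.05)
    if (stats::runif(1) < break_prob && len > 2L * break_len[2]) {
      dur <- sample(break_len[1]:break_len[2], 1L)
      bstart <- sample.int(len - dur, 1L)
      vel[bstart:(bstart + dur - 1L)] <- 0
    }
    lat <- cumsum(vel)
    lat <- (lat - lat[1]) / (lat[len] - lat[1])
    keep <- seq_len(min(len, Tn - t0 + 1L))
    cols <- t0 + keep - 1L
    rate[, cols] <- exp(-outer(position, lat[keep], "-")^2 / (2 * width^2))
    t0 <- t0 + len + sample(gap_len[1]:gap_len[2], 1L)
  }
  list(rate = rate, position = position)
}

# Tuning-curve module: Gaussian tuning to discrete stimuli on a 1-D axis,
# responses decaying exponentially from each stimulus onset.
sim_tuning_module <- function(n, Tn, n_pres, spacing = 100L,
                              n_positions = 1500L, n_stimuli = 15L,
                              tuning_sd = 0.05, decay = 25) {
  pref <- sample.int(n_positions, n, replace = TRUE) / n_positions
  stim_pos <- (seq_len(n_stimuli) - 0.5) / n_stimuli
  amp <- exp(-outer(pref, stim_pos, "-")^2 / (2 * tuning_sd^2))
  stim_id <- sample.int(n_stimuli, n_pres, replace = TRUE)
  dec <- exp(-(seq_len(spacing) - 1L) / decay)
  rate <- matrix(0, n, Tn)
  for (pres in seq_len(n_pres)) {
    onset <- (pres - 1L) * spacing + 1L
    if (onset > Tn) break
    cols <- onset:min(onset + spacing - 1L, Tn)
    rate[, cols] <- rate[, cols] +
      outer(amp[, stim_id[pres]], dec[seq_along(cols)])
  }
  list(rate = rate, position = pref)
}

# Sustained module: difference-of-exponentials responses to a single
# stimulus; 100 timescale pairs interpolate geometrically between (25, 5)
# and (304, 61) timepoints.
sim_sustained_module <- function(n, Tn, n_timescales = 100L,
                                 isi_decay = 750, isi_min = 2000) {
  frac <- (seq_len(n_timescales) - 1L) / (n_timescales - 1L)
  tau_slow <- 25 * (304 / 25)^frac
  tau_fast <- 5 * (61 / 5)^frac
  ks <- sample.int(n_timescales, n, replace = TRUE)
  onsets <- integer(0)
  t0 <- 0
  repeat {
    t0 <- t0 + isi_min + stats::rexp(1, rate = 1 / isi_decay)
    if (t0 > Tn) break
    onsets <- c(onsets, round(t0))
  }
  impulse <- numeric(Tn)
  impulse[onsets] <- 1
  rate <- matrix(0, n, Tn)
  for (k in sort(unique(ks))) {
    len <- min(Tn, ceiling(6 * tau_slow[k]))
    h <- exp(-(seq_len(len) - 1L) / tau_slow[k]) -
      exp(-(seq_len(len) - 1L) / tau_fast[k])
    h <- h / max(h)
    resp <- if (length(onsets) > 0L) conv_causal(impulse, h) else numeric(Tn)
    rate[which(ks == k), ] <- rep(pmax(resp, 0), each = sum(ks == k))
  }
  list(rate = rate, position = (ks - 0.5) / n_timescales)
}

# Power-law factors: left singular vectors are cosines of increasing
# frequency in each neuron's latent x, right singular vectors a sparse
# Boolean sequence filtered with a 25-timepoint exponential; component k
# carries singular value k^(-exponent/2), so the covariance eigenvalues
# decay as k^(-exponent).
sim_powerlaw_factors <- function(x, Tn, exponent, K, density = 0.005,
                                 tau = 25) {
  K <- as.integer(K)
  U <- cos(pi * outer(x, seq_len(K)))
  U <- U / rep(sqrt(colSums(U^2)), each = length(x))
  U <- U * rep(seq_len(K)^(-exponent / 2), each = length(x))
  B <- matrix(stats::rbinom(K * Tn, 1L, density), K, Tn)
  h <- exp_filter(tau)
  V <- t(apply(B, 1L, conv_causal, h = h))
  vn <- sqrt(rowSums(V^2))
  vn[vn < 1e-300] <- 1
  V <- V / vn
  list(U = U, V = V)
}

# Scale factor bringing the mean per-row maximum of clip(U V, 0) to
# `target`, so the power-law rates share the unit peak scale of the module
# responses. Computed on time chunks.
powerlaw_rate_scale <- function(U, V, target, chunk = 4000L) {
  Tn <- ncol(V)
  rmax <- rep(0, nrow(U))
  for (c0 in seq(1L, Tn, by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, Tn)
    R <- U %*% V[, cols, drop = FALSE]
    rmax <- pmax(rmax, apply(R, 1L, max))
  }
  m <- mean(rmax[rmax > 0])
  if (!is.finite(m) || m <= 0) return(1)
  target / m
}

#' Power-law population rates (before spiking)
#'
#' Builds the noiseless rate matrix of the power-law module alone:
#' `clip(U S V, 0)` with cosine left singular vectors in each neuron's
#' latent `x` and covariance eigenvalues decaying as `k^(-exponent)`.
#' Useful for inspecting the eigenspectrum of the construction.
#'
#' @param seed integer seed.
#' @param n_items,n_time matrix size.
#' @param exponent eigenvalue decay exponent (1.5 in the multi-module
#'   benchmark, 1 in the power-law-only benchmark).
#' @param K number of components.
#' @param density density of the Boolean temporal factors.
#' @return list with `rates` (clipped, unscaled), `x` (latent per neuron).
#' @export
simulate_powerlaw_rates <- function(seed, n_items, n_time, exponent = 1,
                                    K = 200L, density = 0.03) {
  set.seed(as.integer(seed))
  x <- stats::runif(n_items)
  pl <- sim_powerlaw_factors(x, n_time, exponent,
                             K = min(K, n_time %/% 2, n_items),
                             density = density)
  list(rates = pmax(pl$U %*% pl$V, 0), x = x)
}

#' Power-law-only benchmark simulation
#'
#' A population driven by a single power-law module with covariance
#' eigenvalues `e_k = 1/k` (full scale: 6,000 neurons). Each neuron's rate
#' trace is scaled by an exponential draw and spikes are Poisson. The
#' ground-truth 1-D latent is each neuron's `x`, so a recovered sorting
#' can be compared to the truth by rank correlation
#' ([groundtruth_correlation()]).
#'
#' @param seed integer seed.
#' @param n_items number of neurons (>= 100).
#' @param n_time number of timepoints.
#' @param params list of overrides: `powerlaw_K`, `powerlaw_density`,
#'   `powerlaw_peak`, `rate_scale_mean`.
#' @return a `sim_dataset` (see [generate_benchmark_simulation()]).
#' @export
generate_powerlaw_simulation <- function(seed, n_items = 6000L,
                                         n_time = 10000L, params = list()) {
  if (n_items < 100L) stop_param("n_items must be >= 100")
  p <- utils::modifyList(list(powerlaw_K = 200L, powerlaw_density = 0.03,
                              powerlaw_peak = 1.0, rate_peak = 6.0,
                              rate_scale_mean = 1.0), params)
  set.seed(as.integer(seed))
  x <- stats::runif(n_items)
  pl <- sim_powerlaw_factors(x, n_time, exponent = 1,
                             K = min(p$powerlaw_K, n_time %/% 2, n_items),
                             density = p$powerlaw_density)
  alpha <- powerlaw_rate_scale(pl$U, pl$V, p$powerlaw_peak)
  act <- matrix(0, n_items, n_time)
  gain <- p$rate_peak * stats::rexp(n_items, rate = 1 / p$rate_scale_mean)
  chunk <- 2000L
  for (c0 in seq(1L, n_time, by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, n_time)
    lam <- gain * alpha * pmax(pl$U %*% pl$V[, cols, drop = FALSE], 0)
    act[, cols] <- stats::rpois(length(lam), lam)
  }
  structure(list(activity = act,
                 module_label = factor(rep("powerlaw", n_items)),
                 ground_truth_position = x,
                 params = c(p, list(n_items = n_items, n_time = n_time)),
                 seed = seed),
            class = "sim_dataset")
}

#' Two-dimensional place-field simulation
#'
#' A population whose intrinsic dimensionality is 2: each neuron gets a
#' random `(x, y)` in the unit square, the left singular vectors are the
#' 900 products `cos(pi kx x) cos(pi ky y)` over a 30 x 30 frequency grid,
#' singular values are `(kx^2 + ky^2)^(-0.5)`, temporal factors are white
#' Gaussian noise, and Gaussian observation noise scaled by `5e-3` is
#' added. No Poisson step: the activity is real-valued. Any 1-D embedding
#' of this population must follow a space-filling curve through the square,
#' making it a stress test for 1-D sortings; split-and-resort refinement
#' improves small-neighborhood preservation here.
#'
#' @param seed integer seed.
#' @param n_items number of neurons (>= 100; full scale 30,000).
#' @param n_time number of timepoints (full scale 20,000).
#' @param noise_sd observation noise scale (default `5e-3`).
#' @param k_max frequency grid extent per axis (default 30).
#' @return a `sim_dataset`; `ground_truth_position` is an n x 2 matrix of
#'   `(x, y)`.
#' @export
generate_2d_simulation <- function(seed, n_items = 30000L, n_time = 20000L,
                                   noise_sd = 5e-3, k_max = 30L) {
  if (n_items < 100L) stop_param("n_items must be >= 100")
  set.seed(as.integer(seed))
  x <- stats::runif(n_items)
  y <- stats::runif(n_items)
  grid <- expand.grid(kx = seq_len(k_max), ky = seq_len(k_max))
  s <- (grid$kx^2 + grid$ky^2)^(-0.5)
  Cx <- cos(pi * outer(x, seq_len(k_max)))
  Cy <- cos(pi * outer(y, seq_len(k_max)))
  U <- Cx[, grid$kx, drop = FALSE] * Cy[, grid$ky, drop = FALSE]
  V <- matrix(stats::rnorm(nrow(grid) * n_time), nrow(grid), n_time)
  act <- U %*% (V * s)
  act <- act + noise_sd * matrix(stats::rnorm(length(act)), nrow(act))
  structure(list(activity = act,
                 module_label = factor(rep("place2d", n_items)),
                 ground_truth_position = cbind(x = x, y = y),
                 params = list(n_items = n_items, n_time = n_time,
                               noise_sd = noise_sd, k_max = k_max),
                 seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("simulated dataset:", nrow(x$activity), "neurons x",
      ncol(x$activity), "timepoints\n")
  cat("modules:", paste(sprintf("%s (%d)", levels(x$module_label),
                                table(x$module_label)), collapse = ", "),
      "\n")
  cat("seed:", x$seed, "\n")
  invisible(x)
}
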
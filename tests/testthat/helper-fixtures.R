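# Shared fixture builders; everything is generated in code, no stored data.

# z-scored random traces with optional 1-D latent structure
make_traces <- function(n, Tn, seed = 1, latent = FALSE) {
  set.seed(seed)
  x <- matrix(rnorm(n * Tn), n)
  if (latent) {
    pos <- sort(runif(n))
    base <- matrix(rnorm(6 * Tn), 6)
    for (i in seq_len(n))
      x[i, ] <- x[i, ] + 3 * base[1 + floor(pos[i] * 5.999), ]
    attr(x, "pos") <- pos
  }
  out <- rastermapr:::zscore_rows(x)
  attr(out, "pos") <- attr(x, "pos")
  out
}

# random strictly-upper-triangular matching matrix
make_random_M <- function(n, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  M[lower.tri(M, diag = TRUE)] <- 0
  M
}

naive_score <- function(S, M, perm) {
  n <- nrow(S)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + M[i, j] * S[perm[i], perm[j]]
  s
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
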
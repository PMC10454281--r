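# Deterministic small electrode layouts and epoch fixtures used across tests.

# n roughly uniform points on the upper hemisphere (golden-angle spiral);
# deterministic, no RNG.
make_test_layout <- function(n, labels = paste0("T", seq_len(n))) {
  k <- seq_len(n)
  z <- 1 - (k - 0.5) / n * 0.9          # keep off the equator rim
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(1 - z^2)
  eeg_layout(labels, cbind(r * cos(phi), r * sin(phi), z))
}

# Epochs holding one sinusoid per trial with per-trial phases.
make_sine_epochs <- function(phases, freq = 8, srate = 256,
                             window_ms = c(-1000, 1000), amplitude = 1,
                             n_channels = 1) {
  k <- ceiling(window_ms[1] * srate / 1000):(ceiling(window_ms[2] * srate / 1000) - 1)
  tms <- k * 1000 / srate
  ntr <- length(phases)
  dat <- array(0, dim = c(ntr, n_channels, length(tms)))
  for (i in seq_len(ntr)) {
    x <- amplitude * cos(2 * pi * freq * tms / 1000 + phases[i])
    for (ch in seq_len(n_channels)) dat[i, ch, ] <- x
  }
  eeg_epochs(dat, tms, srate)
}

# Minimal tf_decomp built directly from a complex coefficient array,
# for algebraic tests of the estimators downstream of the CWT.
make_tf <- function(coef, freqs, times, srate = 256) {
  tf_decomposition(coef, freqs, times, srate)
}

# Least-squares amplitude of a sinusoid at freq (Hz) in samples x (vector).
fitted_amplitude <- function(x, freq, srate) {
  t <- seq_along(x) / srate
  X <- cbind(cos(2 * pi * freq * t), sin(2 * pi * freq * t))
  cf <- stats::lm.fit(X, x)$coefficients
  sqrt(sum(cf^2))
}

# Brute-force all-pairs shortest paths (Floyd-Warshall) on a length matrix.
fw_shortest_paths <- function(L) {
  n <- nrow(L)
  d <- L
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Independent brute-force weighted graph metrics (oracles).
oracle_global_efficiency <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  d <- fw_shortest_paths(L)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- W[nb, nb, drop = FALSE]
    Lsub <- ifelse(sub > 0, (1 / sub)^(1 / 3), Inf)
    d <- fw_shortest_paths(Lsub)
    acc <- 0
    for (j in seq_len(k))
      for (h in seq_len(k))
        if (j != h && is.finite(d[j, h]) && d[j, h] > 0)
          acc <- acc + (W[i, nb[j]] * W[i, nb[h]])^(1 / 3) / d[j, h]
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# Random symmetric weight matrix with zero diagonal and edge density p.
random_weight_matrix <- function(n, p = 0.6) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on_edges <- stats::runif(length(ut)) < p
  W[ut[on_edges]] <- stats::runif(sum(on_edges))
  W + t(W)
}
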
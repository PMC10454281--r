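# Half-open sample-window selection on a ms time axis. Tolerance guards
# against floating-point drift of the uniform grid.
time_window_indices <- function(times, window_ms) {
  eps <- 1e-6
  idx <- which(times >= window_ms[1] - eps & times < window_ms[2] - eps)
  if (length(idx) == 0L)
    stop("window [", window_ms[1], ", ", window_ms[2],
         ") ms contains no samples")
  idx
}

#' Per-trial mean baseline power
#'
#' \eqn{\mu'_B(f,k) = \frac{1}{m}\sum_{t' \in B} |F_k(f,t')|^2}: the mean of
#' the Morlet power over the `m` samples of the half-open baseline window,
#' separately for every trial, channel and frequency. The default window
#' (-3500..-3000 ms) precedes movement preparation.
#'
#' @param tf a `tf_decomp`.
#' @param window_ms baseline window `(start, end)` in ms.
#' @return Numeric array trials x channels x frequencies.
#' @export
baseline_mean_power <- function(tf, window_ms = c(-3500, -3000)) {
  stopifnot(inherits(tf, "tf_decomp"))
  idx <- time_window_indices(tf$times, window_ms)
  if (window_ms[2] > 0)
    message("note: baseline window extends past the locking event")
  pw <- Mod(tf$coef[, , , idx, drop = FALSE])^2
  d <- dim(pw)
  array(rowMeans(matrix(pw, nrow = prod(d[1:3]))), dim = d[1:3])
}

#' Single-trial gain
#'
#' \eqn{P_k^{\%}(f,t) = |F_k(f,t)|^2 / \mu'_B(f,k)}: each trial's power
#' divided by that same trial's mean baseline power at the same channel and
#' frequency. Cells whose baseline is exactly zero are flagged `NA` and
#' excluded from the across-trial ERSP mean (a count is messaged).
#'
#' @param tf a `tf_decomp`.
#' @param base baseline array from [baseline_mean_power()].
#' @return Numeric array trials x channels x frequencies x samples.
#' @export
single_trial_gain <- function(tf, base) {
  stopifnot(inherits(tf, "tf_decomp"))
  d <- dim(tf$coef)
  if (!identical(dim(base), d[1:3]))
    stop("baseline dimensions do not match the decomposition")
  zero <- base == 0
  if (any(zero)) {
    message(sum(zero), " trial-channel-frequency cell(s) with zero baseline ",
            "power excluded from the gain model")
    base[zero] <- NA_real_
  }
  Mod(tf$coef)^2 / as.vector(base)      # baseline recycles over samples
}

#' Event-related spectral perturbation (single-trial gain model)
#'
#' \eqn{\mathrm{ERSP}(f,t) = 10 \log_{10}\big(\frac{1}{n}\sum_k
#' P_k^{\%}(f,t)\big)} in dB.
#'
#' @param P gain array from [single_trial_gain()] (trials x channels x
#'   frequencies x samples).
#' @param grid,times the generating `freq_grid` and time axis (carried into
#'   the map; taken from `tf` when supplied).
#' @param tf optional `tf_decomp` the gains came from (supplies grid, times,
#'   labels).
#' @return A `cft_map` (channels x frequencies x samples) of kind
#'   `"ERSP_dB"`.
#' @export
ersp <- function(P, tf = NULL, grid = NULL, times = NULL) {
  d <- dim(P)
  if (length(d) != 4L) stop("P must be trials x channels x freqs x samples")
  if (d[1] < 1L) stop("need at least one trial")
  mean_gain <- colMeans(P, na.rm = TRUE, dims = 1)
  vals <- 10 * log10(mean_gain)
  cft_map(vals, kind = "ERSP_dB", tf = tf, grid = grid, times = times,
          n_trials = d[1])
}

#' Inter-trial coherence
#'
#' \eqn{\mathrm{ITC}(c,f,t) = \big|\frac{1}{n}\sum_k e^{i\varphi_k(c,f,t)}
#' \big|} with \eqn{\varphi_k = \arg F_k}: the resultant length of the
#' across-trial unit phase vectors. 0 = random phases, 1 = identical phases
#' in every trial. Cells where a trial's coefficient is exactly zero (phase
#' undefined) contribute a zero vector for that trial.
#'
#' @param tf a `tf_decomp` with at least 2 trials.
#' @return A `cft_map` of kind `"ITC"`, values in \[0, 1\].
#' @export
itc <- function(tf) {
  stopifnot(inherits(tf, "tf_decomp"))
  d <- dim(tf$coef)
  if (d[1] < 2L) stop("ITC requires at least 2 trials")
  mag <- Mod(tf$coef)
  ph <- tf$coef
  nz <- mag > 0
  ph[nz] <- ph[nz] / mag[nz]
  vals <- Mod(colMeans(ph, dims = 1))
  cft_map(vals, kind = "ITC", tf = tf, n_trials = d[1])
}

# Channel x frequency x time map container shared by ERSP and ITC.
cft_map <- function(values, kind, tf = NULL, grid = NULL, times = NULL,
                    labels = NULL, n_trials = NA_integer_) {
  if (!is.null(tf)) {
    grid <- tf$grid; times <- tf$times; labels <- tf$labels
  }
  structure(list(values = values, kind = kind, grid = grid, times = times,
                 labels = labels, n_trials = n_trials),
            class = "cft_map")
}

#' @export
print.cft_map <- function(x, ...) {
  d <- dim(x$values)
  cat("<cft_map:", x$kind, "> ", d[1], " channels x ", d[2],
      " frequencies x ", d[3], " samples (n = ", x$n_trials, " trials)\n",
      sep = "")
  invisible(x)
}

#' Band- and window-averaged map values
#'
#' Averages a channel x frequency x time map over the grid frequencies in a
#' half-open band `[low, high)` and the samples in a half-open time window
#' `[start, end)`; one value per channel.
#'
#' @param map a `cft_map`.
#' @param band band name or `c(low, high)` in Hz.
#' @param window_ms time window `(start, end)` in ms; default the 300 ms
#'   analysis interval centered on the button press.
#' @return A list with `values` (named per-channel means) and `n_cells`
#'   (number of frequency-time cells averaged).
#' @export
band_window_average <- function(map, band, window_ms = c(-150, 150)) {
  stopifnot(inherits(map, "cft_map"))
  fi <- band_indices(map$grid, band)
  ti <- time_window_indices(map$times, window_ms)
  sub <- map$values[, fi, ti, drop = FALSE]
  vals <- apply(sub, 1, mean)
  names(vals) <- map$labels
  list(values = vals, n_cells = length(fi) * length(ti))
}
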
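#' Logarithmic frequency grid
#'
#' Frequencies `fmin * ratio^k` for `k = 0..K`, `K = floor(log(fmax/fmin) /
#' log(ratio))`. The defaults reproduce the analysis grid: range
#' 0.32-73 Hz with step ratio f(n)/f(n-1) = 1.1 (57 frequencies).
#'
#' @param fmin lowest frequency (Hz).
#' @param fmax upper bound (Hz); the last grid point is the largest
#'   `fmin * ratio^k` not exceeding it.
#' @param ratio multiplicative step, > 1.
#' @return An object of class `freq_grid` with elements `freqs`, `ratio`,
#'   `bands`.
#' @export
make_frequency_grid <- function(fmin = 0.32, fmax = 73, ratio = 1.1) {
  if (!(0 < fmin && fmin < fmax)) stop("need 0 < fmin < fmax")
  if (ratio <= 1) stop("step ratio must be > 1")
  K <- floor(log(fmax / fmin) / log(ratio) + 1e-12)
  structure(list(freqs = fmin * ratio^(0:K), ratio = ratio,
                 bands = eeg_bands()),
            class = "freq_grid")
}

#' @export
print.freq_grid <- function(x, ...) {
  f <- x$freqs
  cat("<freq_grid> ", length(f), " frequencies, ",
      signif(f[1], 4), " .. ", signif(f[length(f)], 4),
      " Hz, ratio ", x$ratio, "\n", sep = "")
  invisible(x)
}

#' Canonical EEG band edges
#'
#' Delta 1-4, theta 4-8, alpha 8-15, beta 15-30, gamma 30-70 Hz. Band
#' membership is half-open `[low, high)` so shared edges are not counted
#' twice.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 15),
       beta = c(15, 30), gamma = c(30, 70))
}

#' Indices of grid frequencies inside a band
#'
#' @param grid a `freq_grid`.
#' @param band band name (see [eeg_bands()]) or a numeric `c(low, high)`.
#' @return Integer indices into `grid$freqs`.
#' @export
band_indices <- function(grid, band) {
  edges <- if (is.character(band)) {
    b <- grid$bands[[band]]
    if (is.null(b)) stop("unknown band: ", band)
    b
  } else as.numeric(band)
  idx <- which(grid$freqs >= edges[1] & grid$freqs < edges[2])
  if (length(idx) == 0L)
    stop("band [", edges[1], ", ", edges[2], ") Hz contains no grid frequency")
  idx
}

#' Complex Morlet continuous wavelet transform
#'
#' FFT-based convolution of every trial and channel with scaled analytic
#' Morlet wavelets \eqn{\psi(t) = (\pi B)^{-1/2} e^{-t^2/B} e^{i 2\pi C t}}
#' ('cmor1-1': bandwidth B = 1 s², center frequency C = 1 Hz at scale 1;
#' the scale for target frequency f is s = C/f seconds). L1 normalization:
#' a pure sinusoid of amplitude A yields coefficients of magnitude A at its
#' own frequency, and the coefficient phase at time t equals the sinusoid's
#' instantaneous phase (analytic-signal convention).
#'
#' @param ep an [eeg_epochs].
#' @param grid a `freq_grid`; all frequencies must be below Nyquist.
#' @param bandwidth Morlet bandwidth parameter B (s²), default 1.
#' @param center_freq Morlet center frequency C (Hz at scale 1), default 1.
#' @param channels optional channel labels/indices to restrict to.
#' @return An object of class `tf_decomp`: complex `coef` array (trials x
#'   channels x frequencies x samples), `grid`, `times`, `srate`, `labels`,
#'   `bandwidth`, `center_freq`, and `coi` (frequencies x samples logical
#'   mask, TRUE where within one envelope e-folding time of an epoch edge).
#' @export
morlet_cwt <- function(ep, grid, bandwidth = 1, center_freq = 1,
                       channels = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(grid, "freq_grid"))
  fs <- ep$srate
  if (max(grid$freqs) >= fs / 2)
    stop("grid contains frequencies at or above Nyquist")
  if (is.character(channels)) channels <- match(channels, ep$labels)
  if (is.null(channels)) channels <- seq_along(ep$labels)
  d <- dim(ep$data)
  ntr <- d[1]; nch <- length(channels); nt <- d[3]
  nf <- length(grid$freqs)

  # epoch must cover at least one e-folding of the slowest wavelet
  te_max <- sqrt(bandwidth) * center_freq / grid$freqs[1]
  if (nt / fs < te_max)
    warning("epoch shorter than the lowest-frequency wavelet e-folding; ",
            "low-frequency coefficients are fully edge-contaminated")

  nfft <- stats::nextn(2L * nt, 2)
  fax <- (0:(nfft - 1)) / nfft * fs               # FFT bin frequencies
  pos <- fax > 0 & fax <= fs / 2                  # analytic one-sided factor
  sig <- matrix(0, nfft, ntr * nch)
  sig[1:nt, ] <- matrix(aperm(ep$data[, channels, , drop = FALSE],
                              c(3, 1, 2)), nrow = nt)
  SP <- stats::mvfft(sig)

  coef <- array(complex(real = 0), dim = c(ntr, nch, nf, nt))
  for (fi in seq_len(nf)) {
    f <- grid$freqs[fi]
    W <- exp(-pi^2 * bandwidth * center_freq^2 * (fax / f - 1)^2)
    W[!pos] <- 0
    W[pos] <- 2 * W[pos]
    Y <- stats::mvfft(SP * W, inverse = TRUE) / nfft
    coef[, , fi, ] <- aperm(array(Y[1:nt, ], dim = c(nt, ntr, nch)),
                            c(2, 3, 1))
  }

  te <- sqrt(bandwidth) * center_freq / grid$freqs  # e-folding time (s)
  tsec <- (ep$times - ep$times[1]) / 1000
  total <- (nt - 1) / fs
  coi <- outer(te, tsec, function(e, t) t < e | (total - t) < e)
  structure(list(coef = coef, grid = grid, times = ep$times, srate = fs,
                 labels = ep$labels[channels], bandwidth = bandwidth,
                 center_freq = center_freq, coi = coi,
                 metadata = ep$metadata),
            class = "tf_decomp")
}

#' @export
print.tf_decomp <- function(x, ...) {
  d <- dim(x$coef)
  cat("<tf_decomp> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " frequencies x ", d[4], " samples (Morlet B=", x$bandwidth,
      ", C=", x$center_freq, ")\n", sep = "")
  invisible(x)
}

#' Power and phase accessors
#'
#' `tf_power` returns |F|² and `tf_phase` the argument of the complex
#' Morlet coefficients, with the decomposition's dimensions.
#'
#' @param tf a `tf_decomp`.
#' @return Numeric array trials x channels x frequencies x samples.
#' @export
tf_power <- function(tf) {
  stopifnot(inherits(tf, "tf_decomp"))
  Mod(tf$coef)^2
}

#' @rdname tf_power
#' @export
tf_phase <- function(tf) {
  stopifnot(inherits(tf, "tf_decomp"))
  Arg(tf$coef)
}

#' Construct a time-frequency decomposition from coefficients
#'
#' Builds a `tf_decomp` directly from a complex coefficient array, for
#' analyses of externally computed or analytically constructed
#' coefficients (the estimators downstream — ERSP, ITC, dwPLI — only need
#' the coefficients, the grid and the time axis).
#'
#' @param coef complex array, trials x channels x frequencies x samples.
#' @param freqs frequency axis in Hz (length = dim 3).
#' @param times time axis in ms (length = dim 4).
#' @param srate sampling rate in Hz.
#' @param labels optional channel labels.
#' @return A `tf_decomp`.
#' @export
tf_decomposition <- function(coef, freqs, times, srate = 256,
                             labels = NULL) {
  if (length(dim(coef)) != 4L)
    stop("coef must be trials x channels x frequencies x samples")
  if (dim(coef)[3] != length(freqs) || dim(coef)[4] != length(times))
    stop("freqs/times lengths do not match the coefficient array")
  if (!is.complex(coef)) coef <- coef + 0i
  if (is.null(labels)) labels <- paste0("Ch", seq_len(dim(coef)[2]))
  grid <- structure(list(freqs = as.numeric(freqs), ratio = NA_real_,
                         bands = eeg_bands()),
                    class = "freq_grid")
  structure(list(coef = coef, grid = grid, times = as.numeric(times),
                 srate = srate, labels = labels,
                 bandwidth = NA_real_, center_freq = NA_real_,
                 coi = matrix(FALSE, length(freqs), length(times)),
                 metadata = NULL),
            class = "tf_decomp")
}
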
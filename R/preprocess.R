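#' Zero-phase band-pass filtering
#'
#' Cascaded high-pass and low-pass Butterworth filters applied
#' forward-backward (zero phase delay, effective order doubled), with odd
#' reflection padding. Defaults: 0.5-70 Hz, 4th order.
#'
#' @param rec an [eeg_raw].
#' @param low high-pass corner frequency (Hz).
#' @param high low-pass corner frequency (Hz).
#' @param order Butterworth order of each one-pass filter.
#' @return Filtered [eeg_raw].
#' @export
bandpass_zero_phase <- function(rec, low = 0.5, high = 70, order = 4) {
  stopifnot(inherits(rec, "eeg_raw"))
  nyq <- rec$srate / 2
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("low-pass corner at or above Nyquist (", nyq, " Hz)")
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    x <- filtfilt_refl(hp$b, hp$a, rec$data[ch, ])
    out$data[ch, ] <- filtfilt_refl(lp$b, lp$a, x)
  }
  out
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (constrained biquad with an exact zero at the
#' center frequency), applied forward-backward. Defaults target 50 Hz power
#' line noise with quality factor 45.
#'
#' @param rec an [eeg_raw].
#' @param center notch center frequency (Hz).
#' @param q quality factor (center / -3 dB bandwidth).
#' @return Filtered [eeg_raw].
#' @export
notch_filter <- function(rec, center = 50, q = 45) {
  stopifnot(inherits(rec, "eeg_raw"))
  nyq <- rec$srate / 2
  if (center <= 0 || center >= nyq) stop("notch center must be in (0, Nyquist)")
  if (q <= 0) stop("quality factor must be > 0")
  w0 <- 2 * pi * center / rec$srate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- filtfilt_refl(b, a, rec$data[ch, ])
  out
}

# Forward-backward IIR filtering with odd reflection padding of
# 3 x (filter length - 1) samples at each end.
filtfilt_refl <- function(b, a, x) {
  n <- length(x)
  pad <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= pad) stop("signal shorter than the filter padding length")
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(front, x, back)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Extract response-locked epochs
#'
#' Cuts a half-open window `[start, end)` (in ms relative to each event)
#' out of a continuous recording. Events whose window does not fit inside
#' the record are dropped with a message.
#'
#' @param rec an [eeg_raw].
#' @param window_ms length-2 numeric `(start, end)` in ms, with
#'   `start < 0 < end`; default the full response-locked epoch
#'   `c(-4500, 2500)`.
#' @param events optional events data.frame (default: `rec$events`).
#' @param metadata optional data.frame, one row per event, carried into the
#'   epochs of the surviving trials.
#' @return An [eeg_epochs].
#' @export
extract_epochs <- function(rec, window_ms = c(-4500, 2500), events = NULL,
                           metadata = NULL) {
  stopifnot(inherits(rec, "eeg_raw"))
  if (is.null(events)) events <- rec$events
  if (nrow(events) == 0L) stop("no events to epoch around")
  if (!(window_ms[1] < 0 && 0 < window_ms[2]))
    stop("window must satisfy start < 0 < end")
  fs <- rec$srate
  k_lo <- ceiling(window_ms[1] * fs / 1000 - 1e-9)
  k_hi <- ceiling(window_ms[2] * fs / 1000 - 1e-9) - 1L
  offs <- k_lo:k_hi
  nsamp <- ncol(rec$data)
  ok <- (events$sample + k_lo >= 1L) & (events$sample + k_hi <= nsamp)
  if (any(!ok))
    message(sum(!ok), " trial(s) dropped: epoch window outside the record")
  if (!any(ok)) stop("no complete epochs: all windows fall outside the record")
  keep <- which(ok)
  dat <- array(0, dim = c(length(keep), nrow(rec$data), length(offs)))
  for (i in seq_along(keep))
    dat[i, , ] <- rec$data[, events$sample[keep[i]] + offs, drop = FALSE]
  md <- if (is.null(metadata)) data.frame(event_code = events$code[keep])
        else metadata[keep, , drop = FALSE]
  eeg_epochs(dat, times = offs * 1000 / fs, srate = fs,
             labels = rec$labels, metadata = md)
}

#' Resample epochs
#'
#' Band-limited (FFT) resampling of each trial and channel to a lower rate.
#' The new sample count is `round(n * target / current)` and the time axis
#' is recomputed so that 0 ms stays on the sample grid.
#'
#' @param ep an [eeg_epochs].
#' @param target_rate new sampling rate (Hz), at most the current rate.
#' @return An [eeg_epochs] at `target_rate`.
#' @export
resample_epochs <- function(ep, target_rate) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (target_rate <= 0) stop("target rate must be positive")
  if (target_rate == ep$srate) return(ep)
  if (target_rate > ep$srate) stop("upsampling is not supported")
  n <- dim(ep$data)[3]
  m <- round(n * target_rate / ep$srate)
  k0_new <- ep$times[1] * target_rate / 1000
  if (abs(k0_new - round(k0_new)) > 1e-6)
    stop("0 ms would fall off the resampled grid; choose a commensurate rate")
  dat <- array(0, dim = c(dim(ep$data)[1], dim(ep$data)[2], m))
  for (tr in seq_len(dim(ep$data)[1]))
    for (ch in seq_len(dim(ep$data)[2]))
      dat[tr, ch, ] <- fft_resample(ep$data[tr, ch, ], m)
  eeg_epochs(dat, times = ep$times[1] + (0:(m - 1)) * 1000 / target_rate,
             srate = target_rate, labels = ep$labels,
             metadata = ep$metadata, csd = ep$csd)
}

# FFT-based resampling of a real vector to m samples (m <= length(x)).
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  half <- m %/% 2
  Y[1] <- X[1]
  if (half > 1) {
    Y[2:half] <- X[2:half]
    Y[(m - half + 2):m] <- X[(n - half + 2):n]
  }
  if (m %% 2 == 0) {
    Y[half + 1] <- X[half + 1] + X[n - half + 1]   # fold +/- Nyquist (real)
  } else if (half >= 1) {
    Y[half + 1] <- X[half + 1]
    Y[m - half + 1] <- X[n - half + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed channels' time series with the Perrin spherical-spline
#' interpolant fitted, sample by sample, on the remaining good channels.
#'
#' @param ep an [eeg_epochs].
#' @param bad channel labels or indices to replace.
#' @param layout the matching [eeg_layout].
#' @param m spline flexibility (default 4).
#' @param lambda smoothing constant (default 1e-5).
#' @param max_degree Legendre series truncation (default 10).
#' @return An [eeg_epochs] with the bad channels replaced.
#' @export
interpolate_bad_channels <- function(ep, bad, layout, m = 4, lambda = 1e-5,
                                     max_degree = 10) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(layout, "eeg_layout"))
  if (!identical(ep$labels, layout$labels))
    stop("epoch channels do not match the layout")
  if (is.character(bad)) bad <- match(bad, ep$labels)
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) == 0L) {
    warning("empty bad-channel set: returning input unchanged")
    return(ep)
  }
  if (anyNA(bad) || any(bad < 1L) || any(bad > length(ep$labels)))
    stop("bad channels not found among epoch channels")
  good <- setdiff(seq_along(ep$labels), bad)
  if (length(good) < 4L) stop("need at least 4 good channels to interpolate")
  A <- spline_interpolation_matrix(layout$positions, good, bad,
                                   m = m, lambda = lambda,
                                   max_degree = max_degree)
  out <- ep
  for (tr in seq_len(dim(ep$data)[1]))
    out$data[tr, bad, ] <- A %*% ep$data[tr, good, ]
  out
}
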
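#' Configuration for the synthetic two-group cohort generator
#'
#' Defaults emulate the study conditions: 22 subjects per group, 113
#' (young) / 88 (old) response-locked trials per hand, [-4500, 2500] ms
#' epochs at 256 Hz over the 128-channel ABC layout. Three ground-truth
#' components ride on spatially mixed 1/f background noise:
#' \itemize{
#'  \item a delta-band phase-locked burst (Gaussian envelope, per-trial
#'    phase drawn von Mises with group-specific concentration kappa — higher
#'    in the old group, so old-group ITC is higher);
#'  \item an alpha-band induced oscillation whose amplitude is multiplied by
#'    a group-specific gain g inside the event window (g < 1: event-related
#'    desynchronization; the default gains reproduce the printed group-mean
#'    ERSP values, -0.55 dB young and -2.389 dB old);
#'  \item theta- and delta-band lagged coupling: a common oscillation
#'    injected into channel pairs with a pi/2 phase lag and group-specific
#'    amplitude (stronger in the old group).
#' }
#'
#' @param layout an [eeg_layout] (default the packaged 128-channel ABC
#'   layout; tests use smaller layouts).
#' @param n_subjects subjects per group.
#' @param trials named list/vector: trials per subject for `young` and
#'   `old`.
#' @param srate sampling rate (Hz) of the generated epochs.
#' @param epoch_ms epoch window `(start, end)` ms, half-open on the sample
#'   grid.
#' @param noise list: `gamma` (1/f exponent), `amplitude` (per-channel SD,
#'   µV), `mix` (spatially mix the channel noise through a smooth Gaussian
#'   spatial kernel to mimic zero-lag volume conduction; width set by
#'   `mix_width`, chord distance on the unit sphere, default 0.6). Smooth
#'   zero-lag mixing is what the surface Laplacian and dwPLI are designed
#'   to reject, so it exercises both.
#' @param phase_locked list: `freq` (Hz), `amplitude`, `sigma_ms` (Gaussian
#'   envelope SD), `center_ms`, `mu` (mean phase), `kappa` (named per-group
#'   von Mises concentration), `channels` (target labels/indices; NULL =
#'   the 8 most posterior channels), optional `weights` (per-target-channel
#'   amplitude multipliers; a spatially peaked profile survives the
#'   surface Laplacian, a flat patch is attenuated by it).
#' @param induced list: `freq`, `amplitude` (baseline), `gain` (named
#'   per-group amplitude gain inside the window), `window_ms`, `channels`
#'   (NULL = all), optional `weights` as above.
#' @param coupling list of components, each with `freq`, `amplitude`
#'   (named per group), `dphi` (phase lag, radians in (0, pi)), `pairs`
#'   (2-column matrix of channel indices; NULL = consecutive pairs of the
#'   phase-locked target channels).
#' @param equalize_trials subsample both groups to the smaller trial count
#'   (ITC is upward-biased at small n; off by default).
#' @return A `cohort_config`.
#' @export
synthetic_config <- function(layout = biosemi128_layout(),
                             n_subjects = 22,
                             trials = list(young = 113, old = 88),
                             srate = 256,
                             epoch_ms = c(-4500, 2500),
                             noise = list(gamma = 1, amplitude = 1,
                                          mix = TRUE),
                             phase_locked = list(
                               freq = 3, amplitude = 2, sigma_ms = 150,
                               center_ms = 0, mu = 0,
                               kappa = c(young = 1, old = 4),
                               channels = NULL),
                             induced = list(
                               freq = 10, amplitude = 2,
                               gain = c(young = 10^(-0.55 / 20),
                                        old = 10^(-2.389 / 20)),
                               window_ms = c(-400, 400), channels = NULL),
                             coupling = NULL,
                             equalize_trials = FALSE) {
  stopifnot(inherits(layout, "eeg_layout"))
  if (any(unlist(trials) < 2)) stop("need at least 2 trials per subject")
  if (any(phase_locked$kappa < 0)) stop("kappa must be >= 0")
  if (any(induced$gain <= 0)) stop("induced gain must be > 0")
  if (is.null(phase_locked$channels))
    phase_locked$channels <- posterior_channels(layout, 8)
  else if (is.character(phase_locked$channels))
    phase_locked$channels <- match(phase_locked$channels, layout$labels)
  if (length(phase_locked$channels) == 0 && phase_locked$amplitude > 0)
    stop("empty target channel set with nonzero phase-locked amplitude")
  if (is.null(induced$channels))
    induced$channels <- seq_along(layout$labels)
  else if (is.character(induced$channels))
    induced$channels <- match(induced$channels, layout$labels)
  if (is.null(coupling)) {
    tgt <- phase_locked$channels
    prs <- default_pairs(tgt)
    coupling <- list(
      list(freq = 3, amplitude = c(young = 0.5, old = 1.5),
           dphi = pi / 2, pairs = prs),
      list(freq = 6, amplitude = c(young = 0.5, old = 1.5),
           dphi = pi / 2, pairs = prs))
  }
  for (cmp in coupling) {
    if (any(cmp$amplitude > 0) && (cmp$dphi <= 0 || cmp$dphi >= pi))
      stop("coupling phase lag must lie in (0, pi)")
  }
  fs <- srate
  k_lo <- ceiling(epoch_ms[1] * fs / 1000 - 1e-9)
  k_hi <- ceiling(epoch_ms[2] * fs / 1000 - 1e-9) - 1
  cfg <- list(layout = layout, n_subjects = n_subjects, trials = trials,
              srate = srate, epoch_ms = epoch_ms,
              times = (k_lo:k_hi) * 1000 / fs,
              noise = noise, phase_locked = phase_locked,
              induced = induced, coupling = coupling,
              equalize_trials = equalize_trials)
  win_chk <- function(w, nm) {
    if (w[1] < cfg$times[1] || w[2] > cfg$times[length(cfg$times)] + 1)
      stop(nm, " window lies outside the epoch")
  }
  win_chk(induced$window_ms, "induced")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_subjects, " subjects/group, trials ",
      x$trials$young, "/", x$trials$old, " (young/old), ",
      length(x$layout$labels), " channels @ ", x$srate, " Hz\n", sep = "")
  invisible(x)
}

# The k channels with the most posterior (most negative y) positions.
posterior_channels <- function(layout, k) {
  utils::head(order(layout$positions[, "y"]), k)
}

default_pairs <- function(chans) {
  n <- 2 * (length(chans) %/% 2)
  if (n < 2) stop("need at least 2 target channels for coupling pairs")
  matrix(chans[seq_len(n)], ncol = 2, byrow = TRUE)
}

#' Theoretical inter-trial coherence of a von Mises phase distribution
#'
#' The population resultant length \eqn{I_1(\kappa)/I_0(\kappa)} (ratio of
#' modified Bessel functions): the value the sample ITC estimates when
#' trial phases are von Mises distributed with concentration kappa.
#'
#' @param kappa concentration parameter(s), >= 0.
#' @return Resultant length(s) in \[0, 1\].
#' @export
theoretical_itc <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  # scaled Bessel functions underflow near kappa ~ 1e6; switch to the
  # large-kappa asymptotic expansion of the ratio there
  asym <- 1 - 1 / (2 * kappa) - 1 / (8 * kappa^2)
  exact <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  out <- ifelse(kappa > 1e5, asym, exact)
  out[kappa == 0] <- 0
  out
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; kappa = 0 reduces to the uniform circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return Angles in (-pi, pi\].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-9) {
    th <- stats::runif(n, -pi, pi) + mu
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u <- stats::runif(3)
        z <- cos(pi * u[1])
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
          th[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f))) + mu
          break
        }
      }
    }
  }
  ((th + pi) %% (2 * pi)) - pi
}

# 1/f^gamma noise: columns of white Gaussian noise spectrally shaped and
# rescaled to unit SD.
one_over_f_noise <- function(ns, ncol_, gamma) {
  w <- matrix(stats::rnorm(ns * ncol_), ns, ncol_)
  if (gamma == 0) return(w)
  X <- stats::mvfft(w)
  k <- c(1, pmin(1:(ns - 1), ns - 1:(ns - 1)))   # symmetric bin index
  shape <- 1 / k^(gamma / 2)
  shape[1] <- 0                                   # drop DC
  x <- Re(stats::mvfft(X * shape, inverse = TRUE)) / ns
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

#' Generate one synthetic subject
#'
#' Deterministic given `(config, subject_seed, group)`: spatially mixed
#' 1/f noise, plus the phase-locked burst (per-trial von Mises phase),
#' the induced oscillation (uniform phase, windowed amplitude gain), and
#' the lagged coupling components.
#'
#' @param config a `cohort_config`.
#' @param subject_seed integer seed for this subject.
#' @param group `"young"` or `"old"`.
#' @param subject_id identifier stored in the trial metadata.
#' @return An [eeg_epochs].
#' @export
generate_subject <- function(config, subject_seed, group = c("young", "old"),
                             subject_id = NA_character_) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  ntr <- config$trials[[group]]
  nch <- length(config$layout$labels)
  tms <- config$times
  ns <- length(tms)
  tsec <- tms / 1000
  fs <- config$srate

  dat <- with_seed(subject_seed, {
    arr <- array(0, dim = c(ntr, nch, ns))
    mix <- if (isTRUE(config$noise$mix)) {
      w <- config$noise$mix_width
      if (is.null(w)) w <- 0.6
      D <- as.matrix(stats::dist(config$layout$positions))
      M <- exp(-D^2 / (2 * w^2))
      M / sqrt(rowSums(M^2))              # keep per-channel noise SD
    } else diag(nch)
    for (tr in seq_len(ntr)) {
      nz <- t(one_over_f_noise(ns, nch, config$noise$gamma)) *
        config$noise$amplitude
      arr[tr, , ] <- mix %*% nz
    }

    pl <- config$phase_locked
    if (pl$amplitude > 0) {
      wts <- if (is.null(pl$weights)) rep(1, length(pl$channels))
             else pl$weights
      env <- pl$amplitude * exp(-(tms - pl$center_ms)^2 / (2 * pl$sigma_ms^2))
      th <- rvonmises(ntr, pl$mu, pl$kappa[[group]])
      for (tr in seq_len(ntr)) {
        burst <- env * cos(2 * pi * pl$freq * tsec + th[tr])
        arr[tr, pl$channels, ] <-
          arr[tr, pl$channels, , drop = FALSE] +
          as.vector(outer(wts, burst))
      }
    }

    ind <- config$induced
    if (ind$amplitude > 0) {
      wts <- if (is.null(ind$weights)) rep(1, length(ind$channels))
             else ind$weights
      g <- ind$gain[[group]]
      inwin <- tms >= ind$window_ms[1] & tms < ind$window_ms[2]
      amp <- ind$amplitude * ifelse(inwin, g, 1)
      for (tr in seq_len(ntr)) {
        phi <- stats::runif(1, -pi, pi)
        osc <- amp * cos(2 * pi * ind$freq * tsec + phi)
        arr[tr, ind$channels, ] <-
          arr[tr, ind$channels, , drop = FALSE] +
          as.vector(outer(wts, osc))
      }
    }

    for (cmp in config$coupling) {
      a <- cmp$amplitude[[group]]
      if (a <= 0) next
      for (pr in seq_len(nrow(cmp$pairs))) {
        ca <- cmp$pairs[pr, 1]; cb <- cmp$pairs[pr, 2]
        for (tr in seq_len(ntr)) {
          psi <- stats::runif(1, -pi, pi)
          arr[tr, ca, ] <- arr[tr, ca, ] +
            a * cos(2 * pi * cmp$freq * tsec + psi)
          arr[tr, cb, ] <- arr[tr, cb, ] +
            a * cos(2 * pi * cmp$freq * tsec + psi - cmp$dphi)
        }
      }
    }
    arr
  })

  eeg_epochs(dat, tms, fs, config$layout$labels,
             metadata = data.frame(trial = seq_len(ntr),
                                   subject = subject_id, group = group,
                                   hand = "right"))
}

#' Generate a two-group cohort with ground truth
#'
#' Per-subject seeds are derived deterministically from the master seed.
#' The old group uses its parameter set (higher kappa, stronger coupling,
#' lower induced gain), so the analysis pipeline should recover the
#' study's direction of effects.
#'
#' @param config a `cohort_config`.
#' @param seed master seed.
#' @return A list with `young` and `old` (lists of [eeg_epochs]) and
#'   `ground_truth` (theoretical ITC per group at the phase-locked
#'   frequency, theoretical ERSP in dB per group, coupled pairs and lag).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_subjects < 2) stop("need at least 2 subjects per group")
  subj_seed <- function(g, i)
    as.integer((as.numeric(seed) * 10007 + ifelse(g == "old", 5000, 0) + i)
               %% 2147483646) + 1L
  gen_group <- function(g) {
    lapply(seq_len(config$n_subjects), function(i) {
      ep <- generate_subject(config, subj_seed(g, i), g,
                             subject_id = paste0(substr(g, 1, 1), i))
      if (config$equalize_trials) {
        nmin <- min(unlist(config$trials))
        keep <- with_seed(subj_seed(g, i) + 1L,
                          sort(sample.int(n_trials(ep), nmin)))
        ep$data <- ep$data[keep, , , drop = FALSE]
        ep$metadata <- ep$metadata[keep, , drop = FALSE]
      }
      ep
    })
  }
  young <- gen_group("young")
  old <- gen_group("old")
  gt <- list(
    itc = vapply(c(young = "young", old = "old"), function(g)
      theoretical_itc(config$phase_locked$kappa[[g]]), 0),
    itc_freq = config$phase_locked$freq,
    itc_channels = config$phase_locked$channels,
    ersp_db = vapply(c(young = "young", old = "old"), function(g)
      20 * log10(config$induced$gain[[g]]), 0),
    ersp_freq = config$induced$freq,
    coupling = lapply(config$coupling, function(cmp)
      list(freq = cmp$freq, pairs = cmp$pairs, dphi = cmp$dphi,
           amplitude = cmp$amplitude))
  )
  list(young = young, old = old, ground_truth = gt)
}
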
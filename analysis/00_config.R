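# Shared configuration for the analysis drivers.
#
# Desk-scale study: 16 posterior-weighted channels of the ABC layout
# geometry, 6 subjects per group, 60 trials per subject, [-2000, 1000] ms
# epochs at 256 Hz. The old group has higher phase-locking concentration
# (kappa 4 vs 0.5), a stronger alpha desynchronization (gains anchored to
# the group-mean ERSP of the full study design), and stronger pi/2-lag
# delta/theta coupling. These sizes keep every driver in the minutes range
# on one core; all stages scale to the full 128-channel geometry.

suppressPackageStartupMessages(library(motoreeg))

RESULTS_DIR <- "results"
COHORT_DIR <- file.path(RESULTS_DIR, "cohort")
MASTER_SEED <- 20240521L

analysis_layout <- function() {
  full <- biosemi128_layout()
  # 16 channels spanning the scalp, weighted toward posterior sites
  post <- order(full$positions[, "y"])[seq(1, 64, by = 8)]
  ant <- order(full$positions[, "y"], decreasing = TRUE)[seq(1, 64, by = 8)]
  idx <- sort(unique(c(post, ant)))
  eeg_layout(full$labels[idx], full$positions[idx, ])
}

analysis_config <- function() {
  lay <- analysis_layout()
  posterior <- utils::head(order(lay$positions[, "y"]), 4)
  # spatially peaked burst profile and a graded induced profile: smooth but
  # non-constant patterns survive the surface Laplacian, a flat patch would
  # be strongly attenuated by it
  dpost <- sqrt(rowSums((lay$positions[posterior, , drop = FALSE] -
                           matrix(lay$positions[posterior[1], ],
                                  length(posterior), 3, byrow = TRUE))^2))
  synthetic_config(
    layout = lay, n_subjects = 6,
    trials = list(young = 60, old = 60),
    epoch_ms = c(-2000, 1000),
    noise = list(gamma = 1, amplitude = 0.6, mix = TRUE),
    phase_locked = list(freq = 3, amplitude = 3, sigma_ms = 150,
                        center_ms = 0, mu = 0,
                        kappa = c(young = 0.5, old = 4),
                        channels = posterior,
                        weights = exp(-dpost^2 / (2 * 0.35^2))),
    induced = list(freq = 10, amplitude = 1.5,
                   gain = c(young = 10^(-0.55 / 20),
                            old = 10^(-2.389 / 20)),
                   window_ms = c(-400, 400), channels = NULL,
                   weights = 1 + lay$positions[, "z"]),
    coupling = list(
      list(freq = 3, amplitude = c(young = 0.3, old = 1.2), dphi = pi / 2,
           pairs = matrix(posterior, ncol = 2)),
      list(freq = 6, amplitude = c(young = 0.3, old = 1.2), dphi = pi / 2,
           pairs = matrix(posterior, ncol = 2))))
}

analysis_grid <- function() make_frequency_grid(1.5, 12, 1.22)

BASELINE_MS <- c(-1900, -1400)
ANALYSIS_MS <- c(-150, 150)
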
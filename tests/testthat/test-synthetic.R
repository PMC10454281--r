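# Small desk-scale config used throughout: few channels, short-ish epochs.
small_config <- function(n_channels = 6, trials = 30, kappa = c(young = 1,
                                                                old = 4),
                         noise_amp = 0.3, coupling_amp = c(young = 0,
                                                           old = 0),
                         n_subjects = 2, ...) {
  lay <- make_test_layout(n_channels)
  synthetic_config(
    layout = lay, n_subjects = n_subjects,
    trials = list(young = trials, old = trials),
    epoch_ms = c(-1000, 1000),
    noise = list(gamma = 1, amplitude = noise_amp, mix = TRUE),
    phase_locked = list(freq = 8, amplitude = 2, sigma_ms = 150,
                        center_ms = 0, mu = 0, kappa = kappa,
                        channels = 1:2),
    induced = list(freq = 20, amplitude = 0,
                   gain = c(young = 1, old = 1),
                   window_ms = c(-400, 400), channels = NULL),
    coupling = list(list(freq = 6, amplitude = coupling_amp, dphi = pi / 2,
                         pairs = matrix(c(3, 4), ncol = 2))),
    ...)
}

itc_at_event <- function(ep, freq, channel = 1) {
  g <- make_frequency_grid(freq * 0.8, freq * 1.25, 1.1)
  tf <- morlet_cwt(ep, g, channels = channel)
  m <- itc(tf)
  fi <- which.min(abs(g$freqs - freq))
  i0 <- which(tf$times == 0)
  m$values[1, fi, i0]
}

test_that("generation is deterministic given (config, seed)", {
  cfg <- small_config()
  a <- generate_subject(cfg, 123, "old")
  b <- generate_subject(cfg, 123, "old")
  expect_identical(a$data, b$data)
  c <- generate_subject(cfg, 124, "old")
  expect_false(identical(a$data, c$data))
  # group label and trial metadata are recorded
  expect_equal(unique(a$metadata$group), "old")
  expect_equal(nrow(a$metadata), 30)
})

test_that("ITC at the phase-locked frequency tracks the kappa limits", {
  # kappa -> infinity: identical phases, ITC ~ 1
  cfg_hi <- small_config(trials = 50, kappa = c(young = 1e6, old = 1e6),
                         noise_amp = 0.05)
  ep <- generate_subject(cfg_hi, 1, "old")
  expect_gte(itc_at_event(ep, 8), 0.99)

  # kappa = 0: uniform phases, E[R] ~ 1/sqrt(n)
  cfg_lo <- small_config(trials = 100, kappa = c(young = 0, old = 0),
                         noise_amp = 0.05)
  ep0 <- generate_subject(cfg_lo, 2, "old")
  expect_lt(itc_at_event(ep0, 8), 0.2)
})

test_that("theoretical ITC is the Bessel ratio of the concentration", {
  expect_equal(theoretical_itc(0), 0)
  expect_gt(theoretical_itc(1e8), 1 - 1e-6)
  expect_equal(theoretical_itc(2), besselI(2, 1) / besselI(2, 0))
  expect_equal(round(theoretical_itc(2), 4), 0.6978)
  expect_error(theoretical_itc(-1), "kappa")
  # monotone in kappa
  expect_true(all(diff(theoretical_itc(c(0, 0.5, 1, 2, 4, 8))) > 0))
})

test_that("the von Mises sampler matches its target resultant length", {
  set.seed(77)
  for (kappa in c(0.5, 2, 8)) {
    th <- rvonmises(4000, mu = 0.4, kappa = kappa)
    R <- Mod(mean(exp(1i * th)))
    expect_lt(abs(R - theoretical_itc(kappa)), 0.03)
    mu_hat <- Arg(mean(exp(1i * th)))
    expect_lt(abs(mu_hat - 0.4), 0.1)
  }
  expect_true(all(abs(rvonmises(100, 0, 0)) <= pi))
})

test_that("higher kappa in the old group orders the group-mean ITC", {
  wins <- 0
  for (s in 1:8) {
    cfg <- small_config(trials = 40, n_subjects = 2)
    coh <- generate_cohort(cfg, seed = s)
    itc_o <- mean(vapply(coh$old, itc_at_event, 0, freq = 8))
    itc_y <- mean(vapply(coh$young, itc_at_event, 0, freq = 8))
    wins <- wins + (itc_o > itc_y)
  }
  expect_gte(wins, 7)
  # and the theoretical ordering is strict
  gt <- generate_cohort(small_config(), 1)$ground_truth
  expect_gt(gt$itc[["old"]], gt$itc[["young"]])
  expect_equal(gt$ersp_db[["young"]], 20 * log10(1))
})

test_that("without coupling, dwPLI stays small everywhere", {
  cfg <- small_config(trials = 100, kappa = c(young = 0, old = 0),
                      coupling_amp = c(young = 0, old = 0))
  ep <- generate_subject(cfg, 5, "young")
  g <- make_frequency_grid(4, 10, 1.1)
  tf <- morlet_cwt(ep, g)
  conn <- dwpli_matrix(tf, c(4, 10), window_ms = c(-150, 150))
  expect_lt(max(conn$W), 0.3)
})

test_that("pi/2-lag coupling separates coupled from uncoupled pairs", {
  cfg <- small_config(trials = 100, kappa = c(young = 0, old = 0),
                      coupling_amp = c(young = 0, old = 1))
  ep <- generate_subject(cfg, 9, "old")
  g <- make_frequency_grid(5, 7.5, 1.1)
  tf <- morlet_cwt(ep, g)
  conn <- dwpli_matrix(tf, c(5, 7.5), window_ms = c(-150, 150))
  coupled <- conn$W[3, 4]
  others <- conn$W[upper.tri(conn$W)]
  others <- others[others != coupled]
  expect_gt(coupled, max(others))
  expect_gt(coupled, 0.5)
})

test_that("trial-count equalization subsamples to the smaller group", {
  lay <- make_test_layout(4)
  cfg <- synthetic_config(
    layout = lay, n_subjects = 2,
    trials = list(young = 20, old = 12),
    epoch_ms = c(-500, 500),
    noise = list(gamma = 1, amplitude = 1, mix = FALSE),
    phase_locked = list(freq = 8, amplitude = 0, sigma_ms = 150,
                        center_ms = 0, mu = 0,
                        kappa = c(young = 1, old = 1), channels = 1:2),
    induced = list(freq = 10, amplitude = 0, gain = c(young = 1, old = 1),
                   window_ms = c(-200, 200), channels = NULL),
    coupling = list(list(freq = 6, amplitude = c(young = 0, old = 0),
                         dphi = pi / 2, pairs = matrix(1:2, ncol = 2))),
    equalize_trials = TRUE)
  coh <- generate_cohort(cfg, 3)
  expect_equal(dim(coh$young[[1]]$data)[1], 12)
  expect_equal(dim(coh$old[[1]]$data)[1], 12)
})

test_that("configuration invariants are enforced", {
  lay <- make_test_layout(4)
  expect_error(small_config(kappa = c(young = -1, old = 1)), "kappa")
  expect_error(synthetic_config(layout = lay,
                                trials = list(young = 1, old = 5)),
               "at least 2 trials")
  cfg <- small_config()
  expect_error(generate_cohort(structure(modifyList(unclass(cfg),
                                                    list(n_subjects = 1)),
                                         class = "cohort_config")),
               "at least 2 subjects")
})
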
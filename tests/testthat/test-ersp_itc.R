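# Build a tf_decomp with prescribed per-cell complex coefficients:
# coef[trial, channel, freq, time].
tf_from_values <- function(vals, freqs = NULL, srate = 256,
                           window_ms = c(-3600, 200)) {
  if (is.null(freqs)) freqs <- seq(4, by = 1, length.out = dim(vals)[3])
  k <- ceiling(window_ms[1] * srate / 1000):(ceiling(window_ms[2] * srate / 1000) - 1)
  times <- k * 1000 / srate
  d <- dim(vals)
  stopifnot(length(d) == 3)           # trials x channels x freqs; constant in t
  coef <- array(complex(real = 0), c(d, length(times)))
  for (tt in seq_along(times)) coef[, , , tt] <- vals
  make_tf(coef, freqs, times, srate)
}

test_that("baseline mean power is the arithmetic mean over the window", {
  # constant |F|^2 = 4
  tf <- tf_from_values(array(2 + 0i, c(3, 2, 2)))
  base <- baseline_mean_power(tf, c(-3500, -3000))
  expect_equal(unname(base[1, 1, 1]), 4)
  expect_equal(dim(base), c(3, 2, 2))

  # two samples with powers 2 and 6 -> mean 4
  times <- c(-3500, -3500 + 1000 / 256)
  coef <- array(complex(real = 0), c(1, 1, 1, 2))
  coef[1, 1, 1, 1] <- sqrt(2)
  coef[1, 1, 1, 2] <- sqrt(6)
  tf2 <- make_tf(coef, 4, times)
  expect_equal(as.numeric(baseline_mean_power(tf2, c(-3500, -3480))), 4)

  # half-open window at 256 Hz: 128 samples in [-3500, -3000)
  tf3 <- tf_from_values(array(1 + 0i, c(1, 1, 1)), window_ms = c(-4500, 0))
  idx <- motoreeg:::time_window_indices(tf3$times, c(-3500, -3000))
  expect_length(idx, 128)
  expect_error(baseline_mean_power(tf3, c(-9000, -8000)), "no samples")
})

test_that("the single-trial gain model divides by each trial's own baseline", {
  # trial power equal to its baseline -> gain 1 everywhere
  tf <- tf_from_values(array(3 + 0i, c(4, 2, 2)))
  base <- baseline_mean_power(tf)
  P <- single_trial_gain(tf, base)
  expect_equal(range(P), c(1, 1))

  # power 40 over baseline 4 -> 10
  srate <- 256
  k <- ceiling(-3600 * srate / 1000):(-1)
  times <- k * 1000 / srate
  coef <- array(complex(real = 2), c(1, 1, 1, length(times)))  # power 4
  coef[1, 1, 1, length(times)] <- sqrt(40)
  tf40 <- make_tf(coef, 4, times)
  b40 <- baseline_mean_power(tf40, c(-3500, -3000))
  P40 <- single_trial_gain(tf40, b40)
  expect_equal(unname(P40[1, 1, 1, length(times)]), 10)

  # trials with different baselines but equal gains give identical maps
  v <- array(0 + 0i, c(2, 1, 1))
  v[1, 1, 1] <- 1; v[2, 1, 1] <- 5
  tfs <- tf_from_values(v)
  Ps <- single_trial_gain(tfs, baseline_mean_power(tfs))
  expect_equal(Ps[1, 1, 1, ], Ps[2, 1, 1, ])

  # zero-baseline cells are excluded, not infinite
  vz <- array(0 + 0i, c(2, 1, 1)); vz[1, 1, 1] <- 1
  tfz <- tf_from_values(vz)
  expect_message(Pz <- single_trial_gain(tfz, baseline_mean_power(tfz)),
                 "zero baseline")
  expect_true(all(is.na(Pz[2, , , ])))
  e <- ersp(Pz)
  expect_true(all(is.finite(e$values)))
})

test_that("ERSP is the dB-scaled across-trial mean gain", {
  P1 <- array(1, c(5, 1, 1, 3))
  expect_equal(unname(ersp(P1)$values[1, 1, ]), rep(0, 3))
  P2 <- array(10, c(1, 1, 1, 2))
  expect_equal(unname(ersp(P2)$values[1, 1, 1]), 10)
  P3 <- array(c(1, 100), c(2, 1, 1, 1))
  expect_equal(unname(ersp(P3)$values[1, 1, 1]), 10 * log10(50.5))
})

test_that("ITC follows the circular resultant formula", {
  lattice_tf <- function(phases) {
    coef <- array(complex(argument = phases, modulus = 1),
                  c(length(phases), 1, 1, 1))
    make_tf(coef, 4, 0)
  }
  # identical phases in all trials -> 1
  expect_equal(as.numeric(itc(lattice_tf(rep(1.1, 50)))$values), 1,
               tolerance = 1e-12)
  # uniform lattice of phases -> exactly 0
  n <- 8
  expect_lt(as.numeric(itc(lattice_tf(2 * pi * (0:(n - 1)) / n))$values),
            1e-12)
  # {0, pi/2} -> sqrt(2)/2
  expect_equal(as.numeric(itc(lattice_tf(c(0, pi / 2)))$values),
               sqrt(2) / 2)
  expect_error(itc(lattice_tf(0)), "at least 2")
})

test_that("ITC ignores amplitude and ERSP ignores global rescaling", {
  set.seed(21)
  ph <- runif(12, -pi, pi)
  amp <- runif(12, 0.5, 4)
  coef1 <- array(complex(modulus = 1, argument = ph), c(12, 1, 1, 1))
  coef2 <- array(complex(modulus = amp, argument = ph), c(12, 1, 1, 1))
  t1 <- make_tf(coef1, 4, 0)
  t2 <- make_tf(coef2, 4, 0)
  expect_equal(itc(t1)$values, itc(t2)$values, tolerance = 1e-12)
  expect_true(all(itc(t2)$values >= 0 & itc(t2)$values <= 1))

  ep <- make_sine_epochs(runif(6, -pi, pi), freq = 8,
                         window_ms = c(-3600, 200))
  g <- make_frequency_grid(4, 16, 1.1)
  tf_a <- morlet_cwt(ep, g)
  ep$data <- ep$data * 3.7
  tf_b <- morlet_cwt(ep, g)
  ea <- ersp(single_trial_gain(tf_a, baseline_mean_power(tf_a)), tf = tf_a)
  eb <- ersp(single_trial_gain(tf_b, baseline_mean_power(tf_b)), tf = tf_b)
  expect_equal(ea$values, eb$values, tolerance = 1e-9)
})

test_that("band-window averaging matches a brute-force cell scan", {
  g <- make_frequency_grid(0.32, 73, 1.1)
  srate <- 256
  k <- ceiling(-500 * srate / 1000):(ceiling(500 * srate / 1000) - 1)
  times <- k * 1000 / srate
  set.seed(9)
  vals <- array(runif(2 * length(g$freqs) * length(times)),
                c(2, length(g$freqs), length(times)))
  map <- motoreeg:::cft_map(vals, "ITC", grid = g, times = times,
                            labels = c("a", "b"))
  out <- band_window_average(map, "theta", c(-150, 150))
  fi <- which(g$freqs >= 4 & g$freqs < 8)
  ti <- which(times >= -150 & times < 150)
  expect_equal(unname(out$values[1]), mean(vals[1, fi, ti]))
  expect_equal(out$n_cells, length(fi) * length(ti))
  # the +/-150 ms half-open window at 256 Hz holds 77 on-grid samples
  expect_length(ti, 77)

  cmap <- motoreeg:::cft_map(array(0.5, dim(vals)), "ITC", grid = g,
                             times = times, labels = c("a", "b"))
  expect_equal(unname(band_window_average(cmap, "alpha")$values),
               c(0.5, 0.5))
})
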
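# tf_decomp with prescribed complex coefficients at a single in-band cell.
tf_single_cell <- function(coef_ab) {
  # coef_ab: trials x channels complex matrix
  d <- dim(coef_ab)
  coef <- array(complex(real = 0), c(d[1], d[2], 1, 1))
  coef[, , 1, 1] <- coef_ab
  make_tf(coef, freqs = 5, times = 0)
}

test_that("dwPLI algebra matches hand evaluation of the estimator", {
  # constant positive imaginary cross-spectrum -> 1
  n <- 6
  Fa <- rep(complex(real = 1), n)
  Fb <- rep(complex(imaginary = -1), n)        # Im(Fa * Conj(Fb)) = +1
  conn <- dwpli_matrix(tf_single_cell(cbind(Fa, Fb)), "theta",
                       window_ms = c(-1, 1))
  expect_equal(unname(conn$W[1, 2]), 1)
  expect_equal(unname(diag(conn$W)), c(0, 0))

  # all-zero imaginary part (zero-lag / volume conduction) -> 0
  connz <- dwpli_matrix(tf_single_cell(cbind(Fa, Fa)), "theta",
                        window_ms = c(-1, 1))
  expect_equal(unname(connz$W[1, 2]), 0)

  # I = {+c, +c, -c, -c}: raw (0 - 4c^2)/((4c)^2 - 4c^2) = -1/3, clamped 0
  c0 <- 0.8
  Fa4 <- rep(complex(real = 1), 4)
  Fb4 <- complex(imaginary = c(-c0, -c0, c0, c0))
  raw <- dwpli_matrix(tf_single_cell(cbind(Fa4, Fb4)), "theta",
                      window_ms = c(-1, 1), clamp_negative = FALSE)
  expect_equal(unname(raw$W[1, 2]), -1 / 3)
  clamped <- dwpli_matrix(tf_single_cell(cbind(Fa4, Fb4)), "theta",
                          window_ms = c(-1, 1))
  expect_equal(unname(clamped$W[1, 2]), 0)
  expect_true(clamped$any_clamped)

  expect_error(dwpli_matrix(tf_single_cell(cbind(Fa[1], Fb[1])), "theta",
                            window_ms = c(-1, 1)), "at least 2")
})

test_that("dwPLI is invariant to amplitude scaling and zero-lag additions", {
  set.seed(13)
  n <- 60
  ph <- runif(n, -pi, pi)
  Fa <- complex(modulus = 1, argument = ph)
  Fb <- complex(modulus = 1, argument = ph - pi / 2)
  base <- dwpli_matrix(tf_single_cell(cbind(Fa, Fb)), "theta",
                       window_ms = c(-1, 1), clamp_negative = FALSE)
  # per-trial global scaling
  sc <- runif(n, 0.1, 5)
  scaled <- dwpli_matrix(tf_single_cell(cbind(sc * Fa, sc * Fb)), "theta",
                         window_ms = c(-1, 1), clamp_negative = FALSE)
  expect_equal(scaled$W, base$W, tolerance = 1e-12)
  expect_equal(unname(base$W[1, 2]), 1)        # pure pi/2 lag is maximal

  # adding a common zero-lag component to both channels does not create
  # spurious symmetric-about-zero imaginary parts that survive debiasing
  common <- complex(modulus = runif(n, 0, 2), argument = runif(n, -pi, pi))
  only_common <- dwpli_matrix(tf_single_cell(cbind(common, common)), "theta",
                              window_ms = c(-1, 1), clamp_negative = FALSE)
  expect_equal(unname(only_common$W[1, 2]), 0)
})

test_that("node strength sums edge weights", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.2
  W[1, 3] <- W[3, 1] <- 0.3
  conn <- band_connectivity(W, "delta")
  expect_equal(unname(node_strength(conn)), c(0.5, 0.2, 0.3))
  expect_equal(unname(node_strength(band_connectivity(matrix(0, 4, 4)))),
               rep(0, 4))
  set.seed(2)
  Wr <- random_weight_matrix(7)
  expect_equal(sum(node_strength(band_connectivity(Wr))),
               2 * sum(Wr[upper.tri(Wr)]))
})

test_that("global efficiency matches hand-run shortest paths", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 0.5
  conn <- band_connectivity(W)
  # d12 = 1, d13 = 2, d23 = 3 -> E = (1 + 1/2 + 1/3)/3
  expect_equal(global_efficiency(conn), (1 + 0.5 + 1 / 3) / 3)
  K <- matrix(1, 4, 4); diag(K) <- 0
  expect_equal(global_efficiency(band_connectivity(K)), 1)
  expect_equal(global_efficiency(band_connectivity(matrix(0, 5, 5))), 0)
})

test_that("local efficiency handles complete and star graphs", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(unname(local_efficiency(band_connectivity(K3))), rep(1, 3))
  star <- matrix(0, 3, 3)
  star[1, 2] <- star[2, 1] <- 1
  star[1, 3] <- star[3, 1] <- 1
  expect_equal(unname(local_efficiency(band_connectivity(star))), rep(0, 3))
})

test_that("efficiencies agree with brute-force oracles on random graphs", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    W <- random_weight_matrix(n, p = runif(1, 0.3, 0.9))
    conn <- band_connectivity(W)
    expect_equal(global_efficiency(conn), oracle_global_efficiency(W),
                 tolerance = 1e-12)
    expect_equal(unname(local_efficiency(conn)),
                 oracle_local_efficiency(W), tolerance = 1e-12)
    s <- node_strength(conn)
    expect_true(all(s >= 0))
    expect_true(all(local_efficiency(conn) >= 0 &
                      local_efficiency(conn) <= 1 + 1e-12))
  }
})

test_that("channel permutation permutes all metrics consistently", {
  set.seed(17)
  W <- random_weight_matrix(8)
  p <- sample(8)
  Wp <- W[p, p]
  c1 <- band_connectivity(W); c2 <- band_connectivity(Wp)
  expect_equal(unname(node_strength(c2)), unname(node_strength(c1))[p])
  expect_equal(unname(local_efficiency(c2)),
               unname(local_efficiency(c1))[p])
  expect_equal(global_efficiency(c2), global_efficiency(c1))
})

test_that("proportional thresholding keeps the stated edge count with ties", {
  # 128 nodes at 2%: 0.02 * 8128 = 162.56 -> 163 edges kept
  set.seed(4)
  W <- random_weight_matrix(128, p = 1)
  thr <- proportional_threshold(band_connectivity(W), 0.02)
  expect_equal(sum(thr$W[upper.tri(thr$W)] > 0), 163)
  # kept edges are exactly the 163 largest
  expect_equal(sort(thr$W[upper.tri(thr$W)], decreasing = TRUE)[1:163],
               sort(W[upper.tri(W)], decreasing = TRUE)[1:163])

  # proportion 1 is the identity
  full <- proportional_threshold(band_connectivity(W), 1)
  expect_equal(unname(full$W), W)

  # all-equal weights: deterministic tie-break keeps exactly half
  Weq <- matrix(1, 6, 6); diag(Weq) <- 0
  half <- proportional_threshold(band_connectivity(Weq), 0.5)
  expect_equal(sum(half$W[upper.tri(half$W)]), 8)   # ceil-half-up of 15 = 8
  ut <- which(upper.tri(Weq), arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  kept <- half$W[upper.tri(half$W)][ord] > 0
  expect_equal(which(kept), 1:8)                    # first by (i, j) order
  expect_error(proportional_threshold(band_connectivity(Weq), 0),
               "proportion")
})
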
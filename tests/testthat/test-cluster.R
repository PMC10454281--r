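grid_adjacency <- function(nch) {
  # simple chain adjacency over channels, deterministic
  lay <- make_test_layout(nch)
  build_adjacency(lay, 0.45)
}

# k channels forming a connected subgraph of the adjacency (BFS from `from`)
connected_channels <- function(adj, k, from = 1L) {
  seen <- from
  queue <- from
  while (length(seen) < k && length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    new <- setdiff(adj$neighbors[[cur]], seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  sort(seen[seq_len(k)])
}

test_that("identical arrays yield a flat t-map and no clusters", {
  adj <- grid_adjacency(6)
  cfg <- cluster_test_config(adj, cluster_alpha = 0.05,
                             n_permutations = 100, seed = 1)
  set.seed(1)
  x <- array(rnorm(8 * 6 * 4 * 5), c(8, 6, 4, 5))
  res <- paired_cluster_test(x, x, cfg)
  expect_equal(max(abs(res$t_map)), 0)
  expect_length(res$clusters, 0)
})

test_that("a planted block is detected and localized by the paired test", {
  set.seed(42)
  nsub <- 12; nch <- 16; nf <- 10; nt <- 20
  adj <- grid_adjacency(nch)
  cfg <- cluster_test_config(adj, cluster_alpha = 0.001,
                             n_permutations = 200, seed = 7)
  base <- array(rnorm(nsub * nch * nf * nt), c(nsub, nch, nf, nt))
  vals <- base + array(rnorm(nsub * nch * nf * nt), c(nsub, nch, nf, nt))
  block_ch <- connected_channels(adj, 5); block_f <- 4:6
  vals[, block_ch, block_f, ] <- vals[, block_ch, block_f, ] + 10
  res <- paired_cluster_test(vals, base, cfg)
  sig <- Filter(function(c) c$significant, res$clusters)
  expect_length(sig, 1)
  expect_gt(sig[[1]]$mass, 0)
  # members cover >= 90% of the injected block
  blk <- expand.grid(channel = block_ch, freq = block_f, time = 1:nt)
  mem <- as.data.frame(sig[[1]]$members)
  covered <- merge(blk, mem)
  expect_gte(nrow(covered) / nrow(blk), 0.9)
  expect_equal(sig[[1]]$p, 1 / 201)
})

test_that("a negative planted effect yields a negative cluster", {
  set.seed(11)
  nsub <- 10; nch <- 8; nf <- 5; nt <- 8
  adj <- grid_adjacency(nch)
  cfg <- cluster_test_config(adj, cluster_alpha = 0.001,
                             n_permutations = 150, seed = 3)
  base <- array(rnorm(nsub * nch * nf * nt), c(nsub, nch, nf, nt))
  vals <- base + rnorm(length(base))
  blk <- connected_channels(adj, 3)
  vals[, blk, 2:3, ] <- vals[, blk, 2:3, ] - 8
  res <- paired_cluster_test(vals, base, cfg)
  sig <- Filter(function(c) c$significant, res$clusters)
  expect_length(sig, 1)
  expect_equal(sig[[1]]$sign, -1)
  expect_lt(sig[[1]]$mass, 0)
})

test_that("the observed statistic lies inside the permutation null under exchange", {
  set.seed(5)
  nch <- 6
  adj <- grid_adjacency(nch)
  cfg <- cluster_test_config(adj, cluster_alpha = 0.05,
                             n_permutations = 200, seed = 9)
  a <- array(rnorm(6 * nch * 3 * 4), c(6, nch, 3, 4))
  b <- a[c(2, 1, 3, 4, 5, 6), , , ]     # one exchange of the same data
  res <- independent_cluster_test(a, b, cfg)
  if (length(res$clusters) > 0) {
    obs <- max(vapply(res$clusters, function(c) abs(c$mass), 0))
    expect_gte(obs, min(res$null_max))
    expect_lte(obs, max(res$null_max))
    expect_gt(min(vapply(res$clusters, function(c) c$p, 0)), 0.05)
  }
  expect_true(all(res$null_max >= 0))
})

test_that("between-group planted effects are recovered by the independent test", {
  set.seed(23)
  nch <- 12; nf <- 6; nt <- 10
  adj <- grid_adjacency(nch)
  cfg <- cluster_test_config(adj, cluster_alpha = 0.001,
                             n_permutations = 200, seed = 13)
  a <- array(rnorm(9 * nch * nf * nt), c(9, nch, nf, nt))
  b <- array(rnorm(8 * nch * nf * nt), c(8, nch, nf, nt))
  blk <- connected_channels(adj, 4)
  a[, blk, 2:4, 3:8] <- a[, blk, 2:4, 3:8] + 6
  res <- independent_cluster_test(a, b, cfg)
  sig <- Filter(function(c) c$significant, res$clusters)
  expect_length(sig, 1)
  expect_setequal(intersect(sig[[1]]$channels, adj$labels[blk]),
                  adj$labels[blk])
})

test_that("Monte-Carlo p-values respect the permutation floor and determinism", {
  set.seed(2)
  nch <- 5
  adj <- grid_adjacency(nch)
  cfg <- cluster_test_config(adj, cluster_alpha = 0.01,
                             n_permutations = 199, seed = 21)
  base <- array(rnorm(8 * nch * 3 * 3), c(8, nch, 3, 3))
  vals <- base + 50
  r1 <- paired_cluster_test(vals, base, cfg)
  r2 <- paired_cluster_test(vals, base, cfg)
  # p can never undercut the +1-corrected floor; here only the rare
  # all-equal-sign permutations tie the observed mass
  expect_gte(r1$clusters[[1]]$p, 1 / 200)
  expect_lt(r1$clusters[[1]]$p, cfg$alpha)
  expect_identical(r1$clusters[[1]]$p, r2$clusters[[1]]$p)
  expect_identical(r1$null_max, r2$null_max)
})

test_that("consistent channel relabeling leaves p-values unchanged", {
  set.seed(8)
  nch <- 8
  lay <- make_test_layout(nch)
  adj <- build_adjacency(lay, 0.45)
  cfg <- cluster_test_config(adj, cluster_alpha = 0.01,
                             n_permutations = 150, seed = 5)
  base <- array(rnorm(7 * nch * 4 * 4), c(7, nch, 4, 4))
  vals <- base
  vals[, 2:3, 2:3, ] <- vals[, 2:3, 2:3, ] + 7
  res1 <- paired_cluster_test(vals, base, cfg)

  # relabel: channel i of the permuted data is original channel perm[i]
  perm <- sample(nch)
  lay2 <- eeg_layout(lay$labels, lay$positions[perm, ])
  adj2 <- build_adjacency(lay2, 0.45)
  cfg2 <- cluster_test_config(adj2, cluster_alpha = 0.01,
                              n_permutations = 150, seed = 5)
  res2 <- paired_cluster_test(vals[, perm, , , drop = FALSE],
                              base[, perm, , , drop = FALSE], cfg2)
  p1 <- sort(vapply(res1$clusters, function(c) c$p, 0))
  p2 <- sort(vapply(res2$clusters, function(c) c$p, 0))
  expect_equal(p1, p2)
})

test_that("the scalar permutation test matches exhaustive enumeration", {
  # identical groups -> p = 1
  expect_equal(permutation_mean_test(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # {0 x5} vs {10 x5}: only the identity and its complement reach |diff| 10
  res <- permutation_mean_test(rep(0, 5), rep(10, 5), exhaustive = TRUE)
  expect_equal(res$p, 2 / choose(10, 5))
  expect_true(res$exhaustive)

  # determinism of the Monte Carlo path
  set.seed(99)
  a <- rnorm(12); b <- rnorm(12) + 0.8
  r1 <- permutation_mean_test(a, b, n_perm = 500, seed = 4,
                              exhaustive = FALSE)
  r2 <- permutation_mean_test(a, b, n_perm = 500, seed = 4,
                              exhaustive = FALSE)
  expect_identical(r1$p, r2$p)

  # Monte Carlo converges to the exhaustive answer within 2 MC SE
  a2 <- c(0.1, 0.5, 1.1, 1.9, 0.4)
  b2 <- c(1.2, 2.1, 1.8, 2.5, 1.4)
  pe <- permutation_mean_test(a2, b2, exhaustive = TRUE)$p
  pm <- permutation_mean_test(a2, b2, n_perm = 4000, seed = 6,
                              exhaustive = FALSE)$p
  se <- sqrt(pe * (1 - pe) / 4000)
  expect_lt(abs(pm - pe), 2 * se + 1 / 4001)
  expect_error(permutation_mean_test(1, c(1, 2)), "at least 2")
})
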
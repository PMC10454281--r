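#' Configuration for cluster-based permutation tests
#'
#' @param adjacency an `eeg_adjacency` for the channels of the data arrays.
#' @param cluster_alpha sample-level two-sided threshold used to form
#'   candidate clusters (default 0.001).
#' @param n_permutations Monte Carlo randomizations (default 10000).
#' @param alpha final cluster-level significance threshold (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return A `cluster_test_config` list.
#' @export
cluster_test_config <- function(adjacency, cluster_alpha = 0.001,
                                n_permutations = 10000, alpha = 0.05,
                                seed = 1) {
  stopifnot(inherits(adjacency, "eeg_adjacency"))
  if (!(cluster_alpha > 0 && cluster_alpha < 1))
    stop("cluster_alpha must be in (0, 1)")
  if (n_permutations < 100) stop("use at least 100 permutations")
  structure(list(adjacency = adjacency, cluster_alpha = cluster_alpha,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = as.integer(seed)),
            class = "cluster_test_config")
}

# Evaluate code with a local RNG stream; the caller's .Random.seed is
# restored afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# One-sample / paired t statistics per column given column means and the
# (permutation-invariant) column sums of squares.
t_from_moments <- function(m, ss, n) {
  v <- (ss - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tt <- m / sqrt(v / n)
  tt[m == 0 & !is.finite(tt)] <- 0
  tt[is.infinite(tt)] <- sign(tt[is.infinite(tt)]) * 1e9
  tt[is.nan(tt)] <- 0
  tt
}

# Connected components of the suprathreshold cells of a channel x freq x
# time t-map. Cells connect across time +/-1 sample, frequency +/-1 grid
# step, and spatially adjacent channels, within the same sign. Returns a
# list of clusters (linear cell indices, sign, mass = sum of t).
find_tmap_clusters <- function(tvals, dims, threshold, nb) {
  nch <- dims[1]; nf <- dims[2]; nt <- dims[3]
  res <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tvals > threshold else tvals < -threshold
    if (!any(mask)) next
    seen <- logical(length(tvals))
    cells <- which(mask)
    for (start in cells) {
      if (seen[start]) next
      stack <- start
      seen[start] <- TRUE
      members <- integer(0)
      while (length(stack)) {
        cur <- stack[length(stack)]
        stack <- stack[-length(stack)]
        members <- c(members, cur)
        z <- cur - 1L
        ch <- z %% nch + 1L
        r <- z %/% nch
        f <- r %% nf + 1L
        tt <- r %/% nf + 1L
        cand <- integer(0)
        if (f > 1L) cand <- c(cand, cur - nch)
        if (f < nf) cand <- c(cand, cur + nch)
        if (tt > 1L) cand <- c(cand, cur - nch * nf)
        if (tt < nt) cand <- c(cand, cur + nch * nf)
        sp <- nb[[ch]]
        if (length(sp)) cand <- c(cand, cur - ch + sp)
        cand <- cand[mask[cand] & !seen[cand]]
        if (length(cand)) {
          seen[cand] <- TRUE
          stack <- c(stack, cand)
        }
      }
      res[[length(res) + 1L]] <-
        list(cells = members, sign = sgn, mass = sum(tvals[members]))
    }
  }
  res
}

max_cluster_mass <- function(tvals, dims, threshold, nb) {
  cl <- find_tmap_clusters(tvals, dims, threshold, nb)
  if (length(cl) == 0L) return(0)
  max(vapply(cl, function(x) abs(x$mass), 0))
}

finish_cluster_test <- function(t_obs, dims, threshold, nb, null_max, cfg,
                                labels) {
  clusters <- find_tmap_clusters(t_obs, dims, threshold, nb)
  nperm <- length(null_max)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    cl$p <- (1 + sum(null_max >= abs(cl$mass))) / (nperm + 1)
    cl$significant <- cl$p <= cfg$alpha
    z <- cl$cells - 1L
    cl$members <- cbind(channel = z %% dims[1] + 1L,
                        freq = (z %/% dims[1]) %% dims[2] + 1L,
                        time = z %/% (dims[1] * dims[2]) + 1L)
    cl$channels <- sort(unique(labels[cl$members[, "channel"]]))
    clusters[[i]] <- cl
  }
  ord <- order(vapply(clusters, function(x) x$p, 0))
  structure(list(clusters = clusters[ord],
                 t_map = array(t_obs, dim = dims),
                 threshold = threshold, null_max = null_max,
                 cluster_alpha = cfg$cluster_alpha, alpha = cfg$alpha,
                 n_permutations = cfg$n_permutations, seed = cfg$seed,
                 labels = labels),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  nsig <- sum(vapply(x$clusters, function(c) c$significant, TRUE))
  cat("<cluster_test_result> ", length(x$clusters), " cluster(s), ",
      nsig, " significant at alpha = ", x$alpha, " (",
      x$n_permutations, " permutations)\n", sep = "")
  for (cl in x$clusters[seq_len(min(5, length(x$clusters)))])
    cat(sprintf("  %s cluster: %d cells, mass %.1f, p = %.4g%s\n",
                if (cl$sign > 0) "positive" else "negative",
                length(cl$cells), cl$mass, cl$p,
                if (cl$significant) " *" else ""))
  invisible(x)
}

check_cluster_inputs <- function(x, cfg) {
  d <- dim(x)
  if (length(d) != 4L)
    stop("data must be subjects x channels x frequencies x times")
  if (!all(is.finite(x))) stop("non-finite values in test data")
  if (d[2] != length(cfg$adjacency$labels))
    stop("adjacency channel count does not match the data")
  d
}

#' Paired (within-group) cluster-based permutation test
#'
#' Pointwise paired t statistics across subjects on `values - baseline`;
#' cells exceeding the two-sided t quantile at `cluster_alpha` form
#' same-sign clusters connected over time (+/-1 sample), frequency (+/-1
#' grid step) and spatially adjacent channels. Cluster mass is the sum of
#' member t values; the Monte Carlo null is the maximum absolute cluster
#' mass over random sign flips of the subject-level differences, and each
#' observed cluster gets p = (1 + #\{null >= |mass|\}) / (n_perm + 1).
#'
#' @param values,baseline numeric arrays, subjects x channels x frequencies
#'   x times.
#' @param cfg a [cluster_test_config()].
#' @param labels optional channel labels (default from the adjacency).
#' @return A `cluster_test_result`.
#' @export
paired_cluster_test <- function(values, baseline, cfg, labels = NULL) {
  stopifnot(inherits(cfg, "cluster_test_config"))
  d <- check_cluster_inputs(values, cfg)
  if (!identical(dim(baseline), d)) stop("values/baseline shape mismatch")
  n <- d[1]
  if (n < 2L) stop("paired test requires at least 2 subjects")
  if (is.null(labels)) labels <- cfg$adjacency$labels
  dims <- d[2:4]
  D <- matrix(values - baseline, nrow = n)
  ss <- colSums(D^2)                       # invariant under sign flips
  t_obs <- t_from_moments(colMeans(D), ss, n)
  threshold <- stats::qt(1 - cfg$cluster_alpha / 2, df = n - 1)
  nb <- cfg$adjacency$neighbors
  null_max <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(p) {
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      m <- as.numeric(crossprod(sgn, D)) / n
      max_cluster_mass(t_from_moments(m, ss, n), dims, threshold, nb)
    }, 0)
  })
  finish_cluster_test(t_obs, dims, threshold, nb, null_max, cfg, labels)
}

#' Independent-samples (between-group) cluster-based permutation test
#'
#' As [paired_cluster_test()] but with pointwise two-sample pooled-variance
#' t statistics, and a null built by randomly reassigning subjects to the
#' two groups while preserving group sizes.
#'
#' @param group_a,group_b numeric arrays, subjects x channels x frequencies
#'   x times (subject counts may differ).
#' @param cfg a [cluster_test_config()].
#' @param labels optional channel labels.
#' @return A `cluster_test_result`.
#' @export
independent_cluster_test <- function(group_a, group_b, cfg, labels = NULL) {
  stopifnot(inherits(cfg, "cluster_test_config"))
  da <- check_cluster_inputs(group_a, cfg)
  db <- check_cluster_inputs(group_b, cfg)
  if (!identical(da[2:4], db[2:4])) stop("group shapes differ")
  n1 <- da[1]; n2 <- db[1]
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  if (is.null(labels)) labels <- cfg$adjacency$labels
  dims <- da[2:4]
  X <- rbind(matrix(group_a, nrow = n1), matrix(group_b, nrow = n2))
  X2 <- X^2
  s_tot <- colSums(X)
  q_tot <- colSums(X2)
  N <- n1 + n2
  t_two_sample <- function(ing_a) {
    sA <- as.numeric(crossprod(ing_a, X))
    qA <- as.numeric(crossprod(ing_a, X2))
    mA <- sA / n1
    mB <- (s_tot - sA) / n2
    sp2 <- (qA - n1 * mA^2 + (q_tot - qA) - n2 * mB^2) / (N - 2)
    sp2[sp2 < 0] <- 0
    tt <- (mA - mB) / sqrt(sp2 * (1 / n1 + 1 / n2))
    tt[(mA - mB) == 0 & !is.finite(tt)] <- 0
    tt[is.infinite(tt)] <- sign(tt[is.infinite(tt)]) * 1e9
    tt[is.nan(tt)] <- 0
    tt
  }
  obs_ind <- c(rep(1, n1), rep(0, n2))
  t_obs <- t_two_sample(obs_ind)
  threshold <- stats::qt(1 - cfg$cluster_alpha / 2, df = N - 2)
  nb <- cfg$adjacency$neighbors
  null_max <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(p) {
      ind <- numeric(N)
      ind[sample.int(N, n1)] <- 1
      max_cluster_mass(t_two_sample(ind), dims, threshold, nb)
    }, 0)
  })
  finish_cluster_test(t_obs, dims, threshold, nb, null_max, cfg, labels)
}

#' Permutation test on group means of scalar metrics
#'
#' Two-sided nonparametric test of the absolute difference of group means
#' under random relabeling. With `exhaustive = TRUE` (or "auto" and a small
#' enough problem) every group assignment is enumerated and
#' p = #\{|null| >= |observed|\} / n_assignments; otherwise Monte Carlo with
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param metric_a,metric_b numeric vectors of per-subject values.
#' @param n_perm Monte Carlo permutations (default 10000).
#' @param seed RNG seed.
#' @param exhaustive TRUE, FALSE or "auto" (exhaustive when the number of
#'   assignments is at most 200000).
#' @return List with `p`, `observed` (mean(a) - mean(b)), `null`
#'   (permutation distribution of |mean difference|), `exhaustive`.
#' @export
permutation_mean_test <- function(metric_a, metric_b, n_perm = 10000,
                                  seed = 1, exhaustive = "auto") {
  a <- as.numeric(metric_a); b <- as.numeric(metric_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per group")
  pool <- c(a, b)
  n1 <- length(a); N <- length(pool)
  obs <- mean(a) - mean(b)
  tol <- 1e-12 * (abs(obs) + 1)
  n_comb <- choose(N, n1)
  do_ex <- isTRUE(exhaustive) ||
    (identical(exhaustive, "auto") && n_comb <= 2e5)
  if (do_ex) {
    idx <- utils::combn(N, n1)
    null <- apply(idx, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
    p <- sum(null >= abs(obs) - tol) / ncol(idx)
  } else {
    null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        i <- sample.int(N, n1)
        abs(mean(pool[i]) - mean(pool[-i]))
      }, 0)
    })
    p <- (1 + sum(null >= abs(obs) - tol)) / (n_perm + 1)
  }
  list(p = p, observed = obs, null = null, exhaustive = do_ex)
}
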
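#' Debiased weighted phase lag index association matrix
#'
#' For each channel pair (a, b) and each frequency-time cell in
#' band x window, with the per-trial cross-spectrum
#' \eqn{X_k = F_k(a,f,t)\,\overline{F_k(b,f,t)}} and its imaginary part
#' \eqn{I_k},
#' \deqn{\mathrm{dwPLI}(f,t) = \frac{(\sum_k I_k)^2 - \sum_k I_k^2}
#'  {(\sum_k |I_k|)^2 - \sum_k I_k^2},}
#' defined as 0 when the denominator vanishes (all \eqn{I_k = 0}; pure
#' zero-lag coupling). Cellwise values are averaged over the band x window
#' cells. The estimator is insensitive to zero-phase (volume-conducted)
#' coupling and debiased for finite trial counts; single-cell estimates can
#' therefore be negative, and the averaged matrix is clamped at 0 by default
#' so it can feed nonnegative-weight graph metrics.
#'
#' @param tf a `tf_decomp` with >= 2 trials.
#' @param band band name or `c(low, high)` Hz.
#' @param window_ms time window in ms; default the 300 ms interval centered
#'   on the button press.
#' @param clamp_negative zero out negative averaged entries (default TRUE);
#'   set FALSE to inspect the raw signed matrix.
#' @return An object of class `band_connectivity`: symmetric `W` (channels x
#'   channels, zero diagonal), `band`, `window_ms`, `n_trials`, `clamped`,
#'   `labels`.
#' @export
dwpli_matrix <- function(tf, band, window_ms = c(-150, 150),
                         clamp_negative = TRUE) {
  stopifnot(inherits(tf, "tf_decomp"))
  d <- dim(tf$coef)
  if (d[1] < 2L) stop("dwPLI debiasing requires at least 2 trials")
  fi <- band_indices(tf$grid, band)
  ti <- time_window_indices(tf$times, window_ms)
  nch <- d[2]
  acc <- matrix(0, nch, nch)
  for (f in fi) {
    for (t in ti) {
      Fc <- tf$coef[, , f, t, drop = TRUE]
      if (is.null(dim(Fc))) Fc <- matrix(Fc, nrow = d[1])
      A <- Re(Fc); B <- Im(Fc)                       # trials x channels
      S1 <- crossprod(B, A) - crossprod(A, B)        # sum_k I_k
      S2 <- crossprod(B^2, A^2) - 2 * crossprod(A * B, A * B) +
        crossprod(A^2, B^2)                          # sum_k I_k^2
      S3 <- matrix(0, nch, nch)                      # sum_k |I_k|
      for (k in seq_len(d[1]))
        S3 <- S3 + abs(outer(B[k, ], A[k, ]) - outer(A[k, ], B[k, ]))
      num <- S1^2 - S2
      den <- S3^2 - S2
      cell <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
      acc <- acc + cell
    }
  }
  W <- acc / (length(fi) * length(ti))
  W <- (W + t(W)) / 2
  diag(W) <- 0
  clamped <- FALSE
  if (clamp_negative && any(W < 0)) {
    W[W < 0] <- 0
    clamped <- TRUE
  }
  dimnames(W) <- list(tf$labels, tf$labels)
  structure(list(W = W, band = band, window_ms = window_ms,
                 n_trials = d[1], clamped = clamp_negative,
                 any_clamped = clamped, labels = tf$labels),
            class = "band_connectivity")
}

#' Construct a band_connectivity from a weight matrix
#'
#' Convenience constructor (used for graph-metric computation on externally
#' built matrices); validates symmetry and the zero diagonal.
#'
#' @param W symmetric numeric matrix with zero diagonal.
#' @param band band label.
#' @return A `band_connectivity`.
#' @export
band_connectivity <- function(W, band = NA_character_) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-10)
    stop("W must be square and symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("Ch", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  structure(list(W = W, band = band, window_ms = NULL,
                 n_trials = NA_integer_, clamped = FALSE,
                 any_clamped = FALSE, labels = labels),
            class = "band_connectivity")
}

#' @export
print.band_connectivity <- function(x, ...) {
  cat("<band_connectivity> ", nrow(x$W), " channels, band ",
      paste(x$band, collapse = "-"), ", mean weight ",
      signif(mean(x$W[upper.tri(x$W)]), 4), "\n", sep = "")
  invisible(x)
}

check_nonnegative <- function(conn) {
  if (any(conn$W < 0))
    stop("graph metrics require nonnegative weights; ",
         "rebuild the matrix with clamp_negative = TRUE")
  conn$W
}

#' Node strength
#'
#' Sum of all edge weights attached to each node, \eqn{s_i = \sum_j W_{ij}}.
#'
#' @param conn a `band_connectivity`.
#' @return Named numeric vector, one strength per channel.
#' @export
node_strength <- function(conn) {
  stopifnot(inherits(conn, "band_connectivity"))
  s <- rowSums(conn$W)
  names(s) <- conn$labels
  s
}

# igraph graph on lengths 1/w for shortest-path computations.
length_distances <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(W), nrow(W))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Global efficiency
#'
#' Weights map to lengths \eqn{L_{ij} = 1/W_{ij}}; with \eqn{d_{ij}} the
#' all-pairs shortest path lengths, \eqn{E_{glob} = \frac{1}{n(n-1)}
#' \sum_{i \ne j} 1/d_{ij}} (unreachable pairs contribute 0). Lies in
#' \[0, 1\] for weights in \[0, 1\].
#'
#' @param conn a `band_connectivity` with nonnegative weights.
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(conn) {
  stopifnot(inherits(conn, "band_connectivity"))
  W <- check_nonnegative(conn)
  n <- nrow(W)
  if (n < 2L) return(0)
  d <- length_distances(W)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' For node i with neighbourhood \eqn{N(i) = \{j : W_{ij} > 0\}} of size
#' \eqn{k_i},
#' \deqn{E_{loc}(i) = \frac{\sum_{j \ne h \in N(i)}
#'  (W_{ij} W_{ih})^{1/3} / d_{jh}(N_i)}{k_i (k_i - 1)},}
#' where \eqn{d_{jh}(N_i)} is the shortest path between j and h inside the
#' neighbourhood subgraph on cube-root-transformed lengths
#' \eqn{(1/W)^{1/3}} (the Brain Connectivity Toolbox weighted definition).
#' Nodes with fewer than 2 neighbours score 0.
#'
#' @param conn a `band_connectivity` with nonnegative weights.
#' @return Named numeric vector of local efficiencies.
#' @export
local_efficiency <- function(conn) {
  stopifnot(inherits(conn, "band_connectivity"))
  W <- check_nonnegative(conn)
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    sub <- W[nb, nb, drop = FALSE]
    gs <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    dsub <- if (igraph::ecount(gs) > 0)
      igraph::distances(gs, weights = (1 / igraph::E(gs)$weight)^(1 / 3))
    else matrix(Inf, k, k)
    e <- 1 / dsub
    e[!is.finite(e)] <- 0
    diag(e) <- 0
    sw <- W[i, nb]^(1 / 3)
    out[i] <- sum(outer(sw, sw) * e) / (k * (k - 1))
  }
  names(out) <- conn$labels
  out
}

#' Proportional edge thresholding
#'
#' Keeps the `round-half-up(proportion * n(n-1)/2)` largest off-diagonal
#' weights and zeroes the rest. Ties at the cutoff are broken
#' deterministically by lower channel index, then lower partner index.
#'
#' @param conn a `band_connectivity`.
#' @param proportion fraction of edges to keep, in (0, 1\]; 0.02 keeps the
#'   strongest 2%.
#' @return A `band_connectivity` with the pruned weight matrix.
#' @export
proportional_threshold <- function(conn, proportion = 0.02) {
  stopifnot(inherits(conn, "band_connectivity"))
  if (proportion <= 0 || proportion > 1)
    stop("proportion must be in (0, 1]")
  W <- conn$W
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  m <- floor(proportion * n * (n - 1) / 2 + 0.5)
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(m, length(ord)))]
  W2 <- matrix(0, n, n, dimnames = dimnames(W))
  W2[cbind(ut[keep, 1], ut[keep, 2])] <- w[keep]
  W2 <- W2 + t(W2)
  out <- conn
  out$W <- W2
  out
}
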
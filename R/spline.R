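#' Spherical-spline operators (Perrin method)
#'
#' Builds the interpolation kernel matrix G and Laplacian kernel matrix H on
#' the unit sphere,
#' \deqn{G(x) = \frac{1}{4\pi}\sum_{n=1}^{N} \frac{2n+1}{(n(n+1))^m} P_n(x),
#'  \qquad
#'  H(x) = \frac{1}{4\pi}\sum_{n=1}^{N} \frac{2n+1}{(n(n+1))^{m-1}} P_n(x),}
#' with \eqn{P_n} the Legendre polynomials and \eqn{x = \cos\theta_{ij}} the
#' cosine of the inter-electrode angle. The composite current-source-density
#' transform matrix (identical for every time sample) is precomputed.
#'
#' @param layout an [eeg_layout].
#' @param m spline flexibility (default 4).
#' @param lambda smoothing constant added to G's diagonal in the fit
#'   (default 1e-5).
#' @param max_degree Legendre series truncation N (default 10).
#' @return An object of class `spline_operator` with elements `G`, `H`,
#'   `csd_transform` (channels x channels), `m`, `lambda`, `max_degree`,
#'   `labels`, `positions`.
#' @export
build_spline_operator <- function(layout, m = 4, lambda = 1e-5,
                                  max_degree = 10) {
  stopifnot(inherits(layout, "eeg_layout"))
  if (m < 2) stop("spline flexibility m must be >= 2")
  if (lambda < 0) stop("smoothing constant must be >= 0")
  if (max_degree < 1) stop("max_degree must be >= 1")
  pos <- layout$positions
  cosang <- clamp_cos(tcrossprod(pos))
  off <- cosang[upper.tri(cosang)]
  if (any(off > 1 - 1e-10))
    warning("coincident electrodes: kernel still finite (truncated series)")
  G <- spline_kernel(cosang, m = m, max_degree = max_degree)
  H <- spline_kernel(cosang, m = m - 1, max_degree = max_degree)
  n <- nrow(G)
  S <- G + diag(lambda, n)
  Sinv <- solve(S)
  s1 <- Sinv %*% rep(1, n)                      # S^-1 1
  denom <- sum(s1)
  # CSD = H c, c = S^-1 (v - c0 1), c0 = (1' S^-1 v) / (1' S^-1 1)
  Tm <- H %*% Sinv - (H %*% s1) %*% (t(s1) / denom)
  dimnames(G) <- dimnames(H) <- dimnames(Tm) <-
    list(layout$labels, layout$labels)
  structure(list(G = G, H = H, csd_transform = Tm, m = m, lambda = lambda,
                 max_degree = max_degree, labels = layout$labels,
                 positions = pos),
            class = "spline_operator")
}

#' @export
print.spline_operator <- function(x, ...) {
  cat("<spline_operator> ", length(x$labels), " channels, m = ", x$m,
      ", lambda = ", format(x$lambda), ", N = ", x$max_degree, "\n", sep = "")
  invisible(x)
}

# Clamp cosines into [-1, 1] without disturbing dim attributes.
clamp_cos <- function(x) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

# Kernel g_m(x) = (1/4pi) sum_{n=1}^{N} (2n+1) / (n(n+1))^m * P_n(x),
# evaluated for a matrix/vector of cos(angle) values.
spline_kernel <- function(x, m, max_degree) {
  dims <- dim(x)
  xv <- as.vector(x)
  out <- numeric(length(xv))
  p_prev <- rep(1, length(xv))     # P_0
  p_cur <- xv                      # P_1
  for (n in seq_len(max_degree)) {
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_cur
    # Bonnet: (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
    p_next <- ((2 * n + 1) * xv * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  out <- out / (4 * pi)
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Fit a spherical spline to per-electrode values
#'
#' Solves the Perrin system \eqn{(G + \lambda I) c + c_0 \mathbf{1} = v}
#' subject to \eqn{\sum_i c_i = 0}.
#'
#' @param v numeric vector, one value per electrode of the operator.
#' @param op a `spline_operator`.
#' @return A list with `c0` (scalar) and `c` (coefficient vector summing
#'   to 0).
#' @export
fit_spline <- function(v, op) {
  stopifnot(inherits(op, "spline_operator"))
  n <- length(op$labels)
  if (length(v) != n) stop("value vector length does not match operator")
  if (!all(is.finite(v))) stop("non-finite electrode values")
  S <- op$G + diag(op$lambda, n)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("near-singular spline system; adding ridge regularization")
    solve(S + diag(1e-10, n))
  })
  s1 <- Sinv %*% rep(1, n)
  c0 <- sum(Sinv %*% v) / sum(s1)
  cc <- as.numeric(Sinv %*% (v - c0))
  list(c0 = c0, c = cc)
}

# Linear map taking values at `good` electrodes to spherical-spline
# interpolated values at `bad` electrodes. Positions are unit-norm rows.
spline_interpolation_matrix <- function(positions, good, bad, m = 4,
                                        lambda = 1e-5, max_degree = 10) {
  pg <- positions[good, , drop = FALSE]
  pb <- positions[bad, , drop = FALSE]
  Ggg <- spline_kernel(clamp_cos(tcrossprod(pg)), m, max_degree)
  Gbg <- spline_kernel(clamp_cos(tcrossprod(pb, pg)), m, max_degree)
  ng <- length(good)
  Sinv <- solve(Ggg + diag(lambda, ng))
  s1 <- Sinv %*% rep(1, ng)
  denom <- sum(s1)
  P <- Sinv - (s1 %*% t(s1)) / denom            # v -> c  (c = P v)
  # v_bad = c0 1 + Gbg c,  c0 = (s1' v)/denom
  Gbg %*% P + matrix(1, length(bad), 1) %*% (t(s1) / denom)
}

#' Surface Laplacian (current source density) transform
#'
#' Applies the precomputed spherical-spline CSD transform to every trial and
#' sample. A spatially constant potential maps to zero everywhere; the
#' output is flagged as CSD (units µV/m² on the unit-radius head).
#'
#' @param ep an [eeg_epochs].
#' @param op a `spline_operator` built on the same channel set.
#' @return An [eeg_epochs] in CSD units.
#' @export
surface_laplacian <- function(ep, op) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(op, "spline_operator"))
  if (!identical(ep$labels, op$labels))
    stop("epoch channels do not match the spline operator")
  d <- dim(ep$data)
  # channels x (trials*samples) unfolding; one matrix product for all samples
  flat <- matrix(aperm(ep$data, c(2, 1, 3)), nrow = d[2])
  res <- op$csd_transform %*% flat
  out <- aperm(array(res, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  eeg_epochs(out, ep$times, ep$srate, ep$labels, ep$metadata, csd = TRUE)
}
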
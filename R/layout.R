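#' Electrode layouts
#'
#' An `eeg_layout` holds ordered channel labels and 3D electrode positions
#' normalized to the unit sphere. Positions drive the spherical-spline
#' machinery (interpolation, surface Laplacian) and the spatial channel
#' adjacency used by the cluster statistics.
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix, one row per channel, columns x, y, z
#'   (head-centered; any overall scale — rows are renormalized).
#' @return An object of class `eeg_layout` with elements `labels` and
#'   `positions` (rows unit-norm).
#' @export
eeg_layout <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (length(labels) != nrow(positions))
    stop("number of labels does not match number of positions")
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (ncol(positions) != 3L || !all(is.finite(positions)))
    stop("positions must be a finite n x 3 matrix")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm < 1e-12))
    stop("zero-norm electrode position")
  positions <- positions / nrm
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, positions = positions),
            class = "eeg_layout")
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat("<eeg_layout> ", length(x$labels), " channels (",
      x$labels[1], " .. ", x$labels[length(x$labels)],
      "), unit-sphere positions\n", sep = "")
  invisible(x)
}

#' Read an electrode layout from a CSV/SFP-style table
#'
#' Expects columns `label`, `x`, `y`, `z` (header optional for 4-column
#' whitespace-separated SFP files). Positions are projected onto the unit
#' sphere; normalization is idempotent.
#'
#' @param path path to a text file with one electrode per row.
#' @return An [eeg_layout].
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("layout CSV must have columns label,x,y,z")
    tab <- tab[, need]
  } else {
    tab <- utils::read.table(path, stringsAsFactors = FALSE,
                             col.names = c("label", "x", "y", "z"))
  }
  coords <- as.matrix(tab[, c("x", "y", "z")])
  if (!is.numeric(coords) || anyNA(coords))
    stop("non-numeric coordinates in layout file")
  eeg_layout(tab$label, coords)
}

#' The packaged 128-channel Biosemi ABC layout
#'
#' Labels follow the Biosemi ABC convention (A1..A32, B1..B32, C1..C32,
#' D1..D32); unit-sphere positions correspond to the vendor's published
#' electrode coordinates. In this frame +x is right, +y anterior, +z vertex,
#' so posterior channels have negative y.
#'
#' @return An [eeg_layout] with 128 channels.
#' @export
biosemi128_layout <- function() {
  path <- system.file("extdata", "biosemi128_layout.csv",
                      package = "motoreeg", mustWork = TRUE)
  load_layout(path)
}

#' Build the spatial channel adjacency
#'
#' Channel neighbourhoods combine (union) a distance rule — pairs closer
#' than `distance_threshold` in 3D Euclidean distance on the unit sphere —
#' and the edge set of the Delaunay triangulation of the electrode positions
#' after azimuthal-equidistant projection to the plane. The result is
#' symmetric and irreflexive.
#'
#' @param layout an [eeg_layout].
#' @param distance_threshold Euclidean distance cutoff on the normalized
#'   (unit-radius) head; default 0.4.
#' @param use_triangulation include Delaunay edges (default TRUE).
#' @param use_distance include distance-rule edges (default TRUE).
#' @return An object of class `eeg_adjacency`: a list with `neighbors`
#'   (list of integer neighbour indices per channel), `matrix` (logical
#'   adjacency matrix) and `labels`.
#' @export
build_adjacency <- function(layout, distance_threshold = 0.4,
                            use_triangulation = TRUE, use_distance = TRUE) {
  stopifnot(inherits(layout, "eeg_layout"))
  if (distance_threshold <= 0) stop("distance_threshold must be > 0")
  n <- length(layout$labels)
  adj <- matrix(FALSE, n, n)
  if (use_distance) {
    d <- as.matrix(stats::dist(layout$positions))
    adj <- adj | (d < distance_threshold)
  }
  if (use_triangulation) {
    if (n < 3L) stop("triangulation requires at least 3 electrodes")
    xy <- azimuthal_projection(layout$positions)
    tri <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
    e <- tri$delsgs
    for (k in seq_len(nrow(e))) {
      i <- e$ind1[k]; j <- e$ind2[k]
      adj[i, j] <- TRUE; adj[j, i] <- TRUE
    }
  }
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  dimnames(adj) <- list(layout$labels, layout$labels)
  structure(list(
    neighbors = lapply(seq_len(n), function(i) unname(which(adj[i, ]))),
    matrix = adj,
    labels = layout$labels
  ), class = "eeg_adjacency")
}

#' @export
print.eeg_adjacency <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat("<eeg_adjacency> ", length(x$labels), " channels, mean degree ",
      round(mean(deg), 2), "\n", sep = "")
  invisible(x)
}

# Azimuthal-equidistant projection about +z: polar angle becomes the planar
# radius, azimuth is preserved. Deterministic and standard for scalp maps.
azimuthal_projection <- function(pos) {
  theta <- acos(pmin(1, pmax(-1, pos[, 3])))
  phi <- atan2(pos[, 2], pos[, 1])
  cbind(theta * cos(phi), theta * sin(phi))
}
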
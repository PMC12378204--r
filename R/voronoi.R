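# Planar Voronoi cells, nearest-neighbour queries and DBSCAN for
# localization tables. Cells are built by clipping a bounding frame with
# perpendicular-bisector half-planes of candidate neighbours, with a
# security-radius guard that enlarges the candidate set until the cell is
# provably correct (every excluded point is at least twice as far as the
# farthest cell vertex).

# k-nearest-neighbour indices (excluding self), ordered by distance
# (compiled brute force; fine for the 1e3-1e4 points of one nucleus).
knn_index <- function(xy, k) {
  kn <- cpp_knn(as.matrix(xy), as.integer(k))
  list(idx = kn$idx, dist = kn$dist)
}

# Median nearest-neighbour distance (used for scale-free eps/alpha
# defaults).
median_nn_dist <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(NA_real_)
  stats::median(cpp_knn(as.matrix(xy), 1L)$dist[, 1])
}

# Clip convex polygon `poly` (two-column matrix, counter-clockwise) by the
# half-plane of points closer to `site` than to `other`.
clip_bisector <- function(poly, site, other) {
  m <- (site + other) / 2
  u <- other - site # keep x with (x - m) . u <= 0
  s <- (poly[, 1] - m[1]) * u[1] + (poly[, 2] - m[2]) * u[2]
  inside <- s <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  nv <- nrow(poly)
  out <- matrix(0, nv + 4, 2)
  cnt <- 0L
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    if (inside[i]) {
      cnt <- cnt + 1L; out[cnt, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      cnt <- cnt + 1L
      out[cnt, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Voronoi cell areas of a planar point set
#'
#' Computes, for every point, the area of its Voronoi polygon clipped to a
#' rectangular frame slightly larger than the point cloud, and flags cells
#' that are unbounded in the unclipped tessellation (cells touching the
#' frame, plus convex-hull members) as edge cells.
#'
#' @param xy Two-column matrix of coordinates (nm).
#' @param k0 Initial number of bisector candidates per cell; enlarged
#'   automatically whenever the security-radius criterion fails.
#' @param frame Optional `c(xmin, xmax, ymin, ymax)` clipping frame.
#' @return A tibble with `area` (nm^2), `edge` (logical) and `n_clip`
#'   (candidates actually used); the Voronoi adjacency (neighbour indices
#'   per cell) is attached as the `adjacency` attribute.
#' @export
voronoi_cells <- function(xy, k0 = 24L, frame = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 4) stop("need at least 4 localizations to tessellate",
                  call. = FALSE)
  if (is.null(frame)) {
    rx <- range(xy[, 1]); ry <- range(xy[, 2])
    mar <- 0.05 * max(diff(rx), diff(ry)) + 1e-9
    frame <- c(rx[1] - mar, rx[2] + mar, ry[1] - mar, ry[2] + mar)
  }
  k0 <- min(k0, n - 1L)
  out <- cpp_voronoi_areas(xy, as.numeric(frame), as.integer(k0))
  hull <- rep(FALSE, n)
  hull[grDevices::chull(xy)] <- TRUE
  res <- tibble::tibble(area = as.numeric(out$area),
                        edge = hull | as.logical(out$edge),
                        n_clip = as.integer(out$n_clip))
  attr(res, "adjacency") <- out$adjacency
  res
}

#' Density-based spatial clustering (DBSCAN) of localizations
#'
#' Standard DBSCAN: points with at least `min_pts` neighbours within
#' `eps` (self included) are core points; clusters are the connected
#' components of core points under eps-reachability, with non-core points
#' attached to the first reachable cluster; everything else is noise
#' (label 0). Neighbour queries use an eps-sized grid of bins.
#'
#' @param xy Two-column coordinate matrix (nm).
#' @param eps Neighbourhood radius (nm), strictly positive.
#' @param min_pts Minimum neighbourhood size for a core point (default 3,
#'   so no cluster can have fewer than three localizations).
#' @return Integer cluster labels (0 = noise).
#' @export
dbscan_points <- function(xy, eps, min_pts = 3L) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  xy <- as.matrix(xy)
  n <- nrow(xy)
  gx <- floor(xy[, 1] / eps); gy <- floor(xy[, 2] / eps)
  key <- paste(gx, gy)
  bins <- split(seq_len(n), key)
  bin_of <- match(key, names(bins))
  nbrs <- vector("list", n)
  eps2 <- eps^2
  for (i in seq_len(n)) {
    cand <- unlist(bins[paste(rep(gx[i] + (-1:1), each = 3),
                              rep(gy[i] + (-1:1), 3))],
                   use.names = FALSE)
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    nbrs[[i]] <- cand[d2 <= eps2]
  }
  core <- lengths(nbrs) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nbrs[[j]][labels[nbrs[[j]]] == 0L])
      }
    }
  }
  labels
}
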
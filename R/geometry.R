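#' Lattice geometry of a simulated nucleus
#'
#' Builds the discrete nuclear domain a simulation runs on: a boolean mask
#' over a rectangular lattice, the closed boundary polyline, the
#' distance-to-lamina map `d(x)`, the nuclear area and the effective
#' radius `R_nuc = sqrt(A/pi)`. The lattice is centred on the origin.
#'
#' @param shape `"circle"` or `"ellipse"`.
#' @param radii Radius in nm (circle) or the two semi-axes `c(a, b)` in nm
#'   (ellipse).
#' @param h Lattice spacing (nm).
#' @param l_int Optional interface width (nm); if given and `h > l_int/2`
#'   a warning notes that interfaces will be under-resolved.
#' @param pad Number of empty lattice cells around the nucleus.
#' @return An object of class `nucleus_geometry`: list with `h`, `mask`,
#'   `x`, `y` (cell-centre coordinates), `boundary` (two-column matrix of
#'   ordered boundary points, nm), `dist` (distance-to-boundary matrix,
#'   nm), `nearest_b` (index of the nearest boundary point per cell),
#'   `arc` (arc-length position of each boundary point, nm), `perimeter`,
#'   `area` and `R_nuc`.
#' @examples
#' g <- make_geometry("circle", 500, h = 10)
#' abs(g$area / (pi * 500^2) - 1) < 0.02
#' @export
make_geometry <- function(shape = c("circle", "ellipse"), radii, h,
                          l_int = NULL, pad = 2L) {
  shape <- match.arg(shape)
  if (shape == "circle") radii <- rep(radii[1], 2)
  if (length(radii) != 2 || any(!is.finite(radii)) || any(radii <= 0)) {
    stop("degenerate radii", call. = FALSE)
  }
  if (any(radii < 10 * h)) {
    stop("degenerate radii: radii must be much larger than `h`",
         call. = FALSE)
  }
  if (!is.null(l_int) && h > l_int / 2) {
    warning(sprintf(
      "h = %g nm exceeds l_int/2 = %g nm; interfaces are under-resolved",
      h, l_int / 2))
  }
  a <- radii[1]; b <- radii[2]
  nx <- 2L * (ceiling(a / h) + pad)
  ny <- 2L * (ceiling(b / h) + pad)
  x <- (seq_len(nx) - (nx + 1) / 2) * h
  y <- (seq_len(ny) - (ny + 1) / 2) * h
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  mask <- (X / a)^2 + (Y / b)^2 <= 1
  # boundary polyline sampled at roughly one point per lattice cell
  npts <- max(64L, ceiling(pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b))) / h))
  th <- seq(0, 2 * pi, length.out = npts + 1)[-(npts + 1)]
  boundary <- cbind(x = a * cos(th), y = b * sin(th))
  geom <- build_geometry(mask, boundary, h, x, y)
  geom$shape <- shape
  geom$radii <- radii
  geom
}

# Shared constructor used by make_geometry() and estimate_boundary():
# fills distance map, nearest-boundary assignment and arc lengths.
build_geometry <- function(mask, boundary, h, x, y) {
  nx <- nrow(mask); ny <- ncol(mask)
  cells <- which(mask)
  ci <- ((cells - 1) %% nx) + 1
  cj <- ((cells - 1) %/% nx) + 1
  px <- x[ci]; py <- y[cj]
  nb <- integer(length(cells))
  dmin <- numeric(length(cells))
  bx <- boundary[, 1]; by <- boundary[, 2]
  chunk <- max(1L, floor(4e6 / length(bx)))
  for (s in seq(1, length(cells), by = chunk)) {
    e <- min(s + chunk - 1, length(cells))
    d2 <- outer(px[s:e], bx, "-")^2 + outer(py[s:e], by, "-")^2
    nb[s:e] <- max.col(-d2, ties.method = "first")
    dmin[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1), nb[s:e])])
  }
  dist <- matrix(NA_real_, nx, ny)
  dist[cells] <- dmin
  nearest_b <- matrix(NA_integer_, nx, ny)
  nearest_b[cells] <- nb
  seg <- sqrt(diff(c(bx, bx[1]))^2 + diff(c(by, by[1]))^2)
  arc <- c(0, cumsum(seg))[seq_along(bx)]
  area <- sum(mask) * h^2
  structure(list(
    h = h, mask = mask, x = x, y = y, boundary = boundary,
    dist = dist, nearest_b = nearest_b, arc = arc,
    perimeter = sum(seg), area = area, R_nuc = sqrt(area / pi)
  ), class = "nucleus_geometry")
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat("<nucleus_geometry>\n")
  cat(sprintf("  lattice %d x %d at h = %g nm; %d cells in mask\n",
              nrow(x$mask), ncol(x$mask), x$h, sum(x$mask)))
  cat(sprintf("  area = %.3g nm^2, R_nuc = %.1f nm, perimeter = %.1f nm\n",
              x$area, x$R_nuc, x$perimeter))
  invisible(x)
}

#' Distance from points to a closed boundary polyline
#'
#' Minimum Euclidean distance from each point to any segment of the
#' (closed) polyline. Used to classify localizations and clusters by their
#' proximity to the nuclear envelope.
#'
#' @param pts Two-column matrix of point coordinates (nm).
#' @param boundary Two-column matrix of ordered boundary points (nm).
#' @return A list with `dist` (nm) and `seg` (index of the nearest
#'   boundary segment per point) and `t` (position along that segment in
#'   `[0, 1]`).
#' @export
dist_to_boundary <- function(pts, boundary) {
  pts <- as.matrix(pts)
  b1 <- boundary
  b2 <- boundary[c(2:nrow(boundary), 1), , drop = FALSE]
  ex <- b2[, 1] - b1[, 1]; ey <- b2[, 2] - b1[, 2]
  len2 <- pmax(ex^2 + ey^2, 1e-300)
  n <- nrow(pts); m <- nrow(b1)
  best <- rep(Inf, n); bseg <- integer(n); bt <- numeric(n)
  chunk <- max(1L, floor(4e6 / m))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    dx <- outer(pts[s:e, 1], b1[, 1], "-")
    dy <- outer(pts[s:e, 2], b1[, 2], "-")
    tt <- sweep(sweep(dx, 2, ex, "*") + sweep(dy, 2, ey, "*"), 2, len2, "/")
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    qx <- dx - sweep(tt, 2, ex, "*")
    qy <- dy - sweep(tt, 2, ey, "*")
    d2 <- qx^2 + qy^2
    j <- max.col(-d2, ties.method = "first")
    idx <- cbind(seq_len(e - s + 1), j)
    best[s:e] <- sqrt(d2[idx])
    bseg[s:e] <- j
    bt[s:e] <- tt[idx]
  }
  list(dist = best, seg = bseg, t = bt)
}

#' Partition a closed boundary into equal-arc-length segments
#'
#' @param geom A `nucleus_geometry`.
#' @param n Number of segments (at least 4).
#' @return A tibble with one row per segment: `segment_idx`, `arc_start`,
#'   `arc_end`, `length_nm`.
#' @export
boundary_segments <- function(geom, n = 50) {
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  P <- geom$perimeter
  breaks <- seq(0, P, length.out = n + 1)
  tibble::tibble(
    segment_idx = seq_len(n),
    arc_start = breaks[-(n + 1)],
    arc_end = breaks[-1],
    length_nm = diff(breaks)
  )
}

# Arc-length position (nm, in [0, perimeter)) of the projection of points
# onto the boundary, given the output of dist_to_boundary().
arc_position <- function(geom, proj) {
  b1 <- geom$boundary
  b2 <- b1[c(2:nrow(b1), 1), , drop = FALSE]
  seglen <- sqrt(rowSums((b2 - b1)^2))
  (geom$arc[proj$seg] + proj$t * seglen[proj$seg]) %% geom$perimeter
}
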
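#' Read a localization table from CSV
#'
#' Expects columns `x_nm`, `y_nm` and optionally `nucleus_id` and `frame`.
#' One file may hold several nuclei. Exact duplicate coordinates within a
#' nucleus are jittered by less than 0.01 nm (a tessellation degeneracy
#' guard) with the seed recorded in the `jitter_seed` attribute.
#'
#' @param path CSV file path.
#' @param jitter_seed Seed for the degeneracy jitter.
#' @return A tibble of class `localization_table` with columns
#'   `nucleus_id`, `x_nm`, `y_nm` (and `frame` if present).
#' @export
read_localizations <- function(path, jitter_seed = 1L) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("x_nm", "y_nm"), names(tab))
  if (length(missing)) {
    stop("schema error: missing column(s) ",
         paste0("`", missing, "`", collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(tab$x_nm) || !is.numeric(tab$y_nm)) {
    stop("schema error: `x_nm`/`y_nm` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(tab$x_nm)) || any(!is.finite(tab$y_nm))) {
    stop("schema error: non-numeric or non-finite coordinate rows",
         call. = FALSE)
  }
  if (!"nucleus_id" %in% names(tab)) tab$nucleus_id <- 1L
  as_localization_table(tab, jitter_seed = jitter_seed)
}

#' @rdname read_localizations
#' @param tab A data frame with `x_nm`, `y_nm` and optionally
#'   `nucleus_id`.
#' @export
as_localization_table <- function(tab, jitter_seed = 1L) {
  tab <- tibble::as_tibble(tab)
  if (!"nucleus_id" %in% names(tab)) tab$nucleus_id <- 1L
  counts <- table(tab$nucleus_id)
  if (any(counts < 4)) {
    stop("each nucleus needs at least 4 localizations; nucleus ",
         paste(names(counts)[counts < 4], collapse = ", "), " has fewer",
         call. = FALSE)
  }
  dup <- duplicated(tab[, c("nucleus_id", "x_nm", "y_nm")])
  n_jittered <- sum(dup)
  if (n_jittered) {
    old <- local_seed(jitter_seed)
    on.exit(restore_seed(old), add = TRUE)
    tab$x_nm[dup] <- tab$x_nm[dup] + stats::runif(n_jittered, -5e-3, 5e-3)
    tab$y_nm[dup] <- tab$y_nm[dup] + stats::runif(n_jittered, -5e-3, 5e-3)
    message(sprintf(
      "jittered %d duplicate localization(s) by < 0.01 nm (seed %d)",
      n_jittered, jitter_seed))
  }
  tab <- dplyr::select(tab, "nucleus_id", "x_nm", "y_nm",
                       dplyr::any_of("frame"), dplyr::everything())
  class(tab) <- c("localization_table", class(tab))
  attr(tab, "jitter_seed") <- jitter_seed
  attr(tab, "n_jittered") <- n_jittered
  tab
}

#' Voronoi density annotation of a localization table
#'
#' Tessellates each nucleus, marks hull-touching/unbounded polygons as
#' edge polygons, and computes each localization's reduced Voronoi
#' density: the nucleus mean non-edge polygon area divided by the
#' polygon's own area, so a value of 1 is the nucleus-average density and
#' larger values are denser chromatin. The nuclear area estimate is the
#' sum of the non-edge polygon areas.
#'
#' @param tab A `localization_table`.
#' @return A list: `table` (the input annotated with `voronoi_area_nm2`,
#'   `edge`, `reduced_density`) and `summary` (per nucleus: localization
#'   count, edge count, mean non-edge polygon area, nuclear area
#'   estimate).
#' @export
voronoi_density <- function(tab) {
  stopifnot(inherits(tab, "data.frame"))
  out <- tab |>
    dplyr::group_by(.data$nucleus_id) |>
    dplyr::group_modify(function(df, key) {
      vc <- voronoi_cells(cbind(df$x_nm, df$y_nm))
      if (all(vc$edge)) {
        stop("pathological input: every polygon is an edge polygon ",
             "(collinear localizations?)", call. = FALSE)
      }
      abar <- mean(vc$area[!vc$edge])
      df$voronoi_area_nm2 <- vc$area
      df$edge <- vc$edge
      df$reduced_density <- ifelse(vc$edge, NA_real_, abar / vc$area)
      df$vor_neighbors <- attr(vc, "adjacency")
      df
    }) |>
    dplyr::ungroup()
  summary <- out |>
    dplyr::group_by(.data$nucleus_id) |>
    dplyr::summarise(
      n_locs = dplyr::n(),
      n_edge = sum(.data$edge),
      mean_area_nm2 = mean(.data$voronoi_area_nm2[!.data$edge]),
      nuclear_area_nm2 = sum(.data$voronoi_area_nm2[!.data$edge]),
      .groups = "drop"
    )
  list(table = out, summary = summary)
}

#' Percentile density classes over a pooled set of nuclei
#'
#' Pools the reduced Voronoi densities of every non-edge localization in
#' the supplied table (across nuclei and conditions, as passed in one
#' invocation) and classifies: at or below the 30th percentile is sparse
#' chromatin, between the 30th and 70th is dense, above the 70th is
#' ultradense; edge polygons keep the class `edge`.
#'
#' @param tab An annotated table from [voronoi_density()] (the `table`
#'   element), possibly concatenating several nuclei/conditions.
#' @return The table with a `density_class` factor column; the pooled
#'   thresholds are stored in the `density_thresholds` attribute.
#' @export
classify_density <- function(tab) {
  vals <- tab$reduced_density[!tab$edge]
  if (!length(vals)) stop("empty density pool", call. = FALSE)
  p <- stats::quantile(vals, c(0.3, 0.7), names = FALSE)
  if (p[1] == p[2]) {
    warning("degenerate density distribution: all localizations classed dense")
    cls <- ifelse(tab$edge, "edge", "dense")
  } else {
    cls <- dplyr::case_when(
      tab$edge ~ "edge",
      tab$reduced_density <= p[1] ~ "sparse",
      tab$reduced_density <= p[2] ~ "dense",
      TRUE ~ "ultradense"
    )
  }
  tab$density_class <- factor(cls,
    levels = c("sparse", "dense", "ultradense", "edge"))
  attr(tab, "density_thresholds") <- c(p30 = p[1], p70 = p[2])
  tab
}

#' Cluster dense localizations into heterochromatin domains
#'
#' Runs DBSCAN on the clustering mask (by default the dense plus
#' ultradense classes; `dense_band = "31:70"` restricts to the literal
#' dense band) of each nucleus. At least `min_pts` localizations are
#' required per cluster; unclustered mask points are labelled noise (0)
#' and off-mask points `NA`.
#'
#' @param tab A density-classified table ([classify_density()]).
#' @param eps DBSCAN radius (nm); default per nucleus is four times the
#'   median nearest-neighbour distance among that nucleus's mask
#'   localizations (large enough that a homogeneous cluster of mask
#'   density percolates into one domain, small enough not to bridge
#'   distinct domains).
#' @param min_pts DBSCAN core threshold (default 3).
#' @param dense_band `"31:100"` (default; dense and ultradense) or
#'   `"31:70"` (dense only).
#' @return The table with `cluster_id` (DBSCAN label), `eps_nm` (the
#'   radius used) and `area_cluster_id` columns. `area_cluster_id` extends
#'   each cluster, for area bookkeeping only, to unclustered non-edge
#'   localizations lying within `eps` of a member, so that sparse holes
#'   enclosed by a domain count towards the area the domain covers.
#' @export
cluster_domains <- function(tab, eps = NULL, min_pts = 3L,
                            dense_band = c("31:100", "31:70")) {
  dense_band <- match.arg(dense_band)
  classes <- if (dense_band == "31:70") "dense" else c("dense", "ultradense")
  tab |>
    dplyr::group_by(.data$nucleus_id) |>
    dplyr::group_modify(function(df, key) {
      sel <- df$density_class %in% classes
      df$cluster_id <- NA_integer_
      df$eps_nm <- NA_real_
      if (sum(sel) >= min_pts) {
        xy <- cbind(df$x_nm[sel], df$y_nm[sel])
        e <- eps %||% (4 * median_nn_dist(xy))
        df$cluster_id[sel] <- dbscan_points(xy, e, min_pts)
        df$eps_nm <- e
      } else if (any(sel)) {
        df$cluster_id[sel] <- 0L
      }
      df$area_cluster_id <- df$cluster_id
      df$area_contrib_nm2 <- ifelse(!is.na(df$cluster_id) &
                                      df$cluster_id > 0L & !df$edge,
                                    df$voronoi_area_nm2, 0)
      if (any(!is.na(df$cluster_id) & df$cluster_id > 0L) &&
          "vor_neighbors" %in% names(df)) {
        df$area_cluster_id <- fill_enclosed(df$area_cluster_id,
                                            df$vor_neighbors, df$edge,
                                            df$voronoi_area_nm2)
        memb <- !is.na(df$cluster_id) & df$cluster_id > 0L & !df$edge
        mean_member <- tapply(df$voronoi_area_nm2[memb],
                              df$cluster_id[memb], mean)
        filled <- !is.na(df$area_cluster_id) & df$area_cluster_id > 0L &
          (is.na(df$cluster_id) | df$cluster_id == 0L) & !df$edge
        # a filled gap contributes at most a few member-scale polygons:
        # its polygon may bleed far outside the domain
        cap <- 3 * mean_member[as.character(df$area_cluster_id[filled])]
        df$area_contrib_nm2[filled] <- pmin(df$voronoi_area_nm2[filled],
                                            cap)
      }
      df
    }) |>
    dplyr::ungroup()
}

# Attach unclustered polygons that are enclosed by a single domain:
# connected components of non-member, non-edge polygons in the Voronoi
# adjacency graph whose entire (non-edge) neighbourhood belongs to one
# cluster are sparse holes inside that domain, and their polygons count
# towards the area the domain covers. The open background fails the test
# because it borders many different clusters.
fill_enclosed <- function(labels, neighbors, edge, areas) {
  lab <- labels
  lab[is.na(lab)] <- 0L
  member_area <- tapply(areas[lab > 0L], lab[lab > 0L], sum)
  open <- which(lab == 0L & !edge)
  if (!length(open)) return(labels)
  pos <- match(seq_along(lab), open)
  ee <- do.call(rbind, lapply(open, function(i) {
    nb <- neighbors[[i]]
    nb <- nb[nb %in% open & nb > i]
    if (length(nb)) cbind(pos[i], pos[nb]) else NULL
  }))
  g <- igraph::make_graph(edges = if (is.null(ee)) integer(0) else
    as.vector(t(ee)), n = length(open), directed = FALSE)
  comp <- igraph::components(g)$membership
  for (cid in unique(comp)) {
    cells <- open[comp == cid]
    ext <- setdiff(unique(unlist(neighbors[cells])), cells)
    ext <- ext[!edge[ext]]
    ext_lab <- lab[ext]
    owners <- unique(ext_lab[ext_lab > 0L])
    if (length(owners) == 1 && all(ext_lab > 0L) && length(ext) >= 3) {
      # size guard: a genuine intra-domain gap is small relative to the
      # domain itself; a large enclosed region (a background bay wrapped
      # by a peripheral domain) is left out
      if (length(cells) <= 100 &&
          sum(areas[cells]) <= 0.25 * member_area[as.character(owners)]) {
        lab[cells] <- owners
      }
    }
  }
  lab[is.na(labels) & lab == 0L] <- NA_integer_
  lab
}

#' Estimate the nuclear boundary from a localization cloud
#'
#' Rasterises the localizations, closes the binary image with a disc of
#' radius `alpha`, fills interior holes and traces the outer contour,
#' giving a concave nuclear outline with resolvable indentations at the
#' `alpha` scale (small `alpha` follows the cloud tightly; large `alpha`
#' approaches the convex hull).
#'
#' @param tab Localizations of a single nucleus.
#' @param alpha Closing radius (nm); default five times the median
#'   nearest-neighbour distance.
#' @param bin Raster bin size (nm); default `alpha / 2`.
#' @return A `nucleus_geometry` whose mask lattice is the raster, with
#'   the boundary polyline, distance map, area and `R_nuc`.
#' @export
estimate_boundary <- function(tab, alpha = NULL, bin = NULL) {
  if (nrow(tab) < 10) {
    stop("need at least 10 localizations to estimate a boundary",
         call. = FALSE)
  }
  if (length(unique(tab$nucleus_id)) > 1) {
    stop("estimate_boundary() works on a single nucleus", call. = FALSE)
  }
  xy <- cbind(tab$x_nm, tab$y_nm)
  alpha <- alpha %||% (5 * median_nn_dist(xy))
  bin <- bin %||% (alpha / 2)
  pad <- ceiling(2 * alpha / bin) + 2
  x0 <- min(xy[, 1]) - pad * bin
  y0 <- min(xy[, 2]) - pad * bin
  nx <- ceiling((max(xy[, 1]) - x0) / bin) + pad
  ny <- ceiling((max(xy[, 2]) - y0) / bin) + pad
  img <- matrix(0, nx, ny)
  ii <- pmin(pmax(floor((xy[, 1] - x0) / bin) + 1, 1), nx)
  jj <- pmin(pmax(floor((xy[, 2] - y0) / bin) + 1, 1), ny)
  img[cbind(ii, jj)] <- 1
  brush <- EBImage::makeBrush(2 * round(alpha / bin) + 1, shape = "disc")
  closed <- EBImage::closing(img, brush)
  filled <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(filled)
  ncomp <- max(lab)
  if (ncomp > 1) {
    sizes <- tabulate(as.integer(lab[lab > 0]))
    if (sort(sizes, decreasing = TRUE)[2] > 0.05 * max(sizes)) {
      stop("disconnected hull: `alpha` too small for this cloud; ",
           "increase `alpha` (e.g. 10x the median NN distance)",
           call. = FALSE)
    }
    filled <- lab == which.max(sizes)
  }
  mask <- filled > 0
  # cell-centre coordinates of the raster
  xs <- x0 + (seq_len(nx) - 0.5) * bin
  ys <- y0 + (seq_len(ny) - 0.5) * bin
  cl <- grDevices::contourLines(xs, ys, mask * 1, levels = 0.5)
  if (!length(cl)) stop("boundary tracing failed", call. = FALSE)
  lens <- vapply(cl, function(c) length(c$x), numeric(1))
  bc <- cl[[which.max(lens)]]
  boundary <- cbind(x = bc$x, y = bc$y)
  if (all(boundary[1, ] == boundary[nrow(boundary), ])) {
    boundary <- boundary[-nrow(boundary), , drop = FALSE]
  }
  # the raster contour is an axis-aligned staircase whose teeth inflate
  # the perimeter (up to sqrt(2)x on diagonals) and skew arc-length
  # bookkeeping; resample at uniform arc spacing and average over ~2
  # alpha of arc, which flattens the teeth while keeping concave
  # features at the alpha scale
  boundary <- resample_closed_polyline(boundary, alpha / 4)
  win <- max(5L, 2L * 4L + 1L)
  boundary <- smooth_closed_polyline(boundary, win)
  geom <- build_geometry(mask, boundary, bin, xs, ys)
  # the polygon area is the better estimate (half-cell raster bias)
  geom$area <- polygon_area(boundary)
  geom$R_nuc <- sqrt(geom$area / pi)
  geom$shape <- "estimated"
  geom$alpha <- alpha
  geom
}

# resample a closed polyline at (approximately) uniform arc spacing
resample_closed_polyline <- function(poly, spacing) {
  seg <- sqrt(rowSums((poly[c(2:nrow(poly), 1), ] - poly)^2))
  arc <- c(0, cumsum(seg))
  per <- arc[length(arc)]
  n_out <- max(16L, ceiling(per / spacing))
  s_out <- seq(0, per, length.out = n_out + 1)[-(n_out + 1)]
  xs <- c(poly[, 1], poly[1, 1])
  ys <- c(poly[, 2], poly[1, 2])
  cbind(x = stats::approx(arc, xs, s_out)$y,
        y = stats::approx(arc, ys, s_out)$y)
}

# circular moving average of the vertices of a closed polyline
smooth_closed_polyline <- function(poly, win) {
  n <- nrow(poly)
  if (n <= win) return(poly)
  half <- win %/% 2
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1) %% n) + 1
  cbind(x = rowMeans(matrix(poly[idx, 1], n)),
        y = rowMeans(matrix(poly[idx, 2], n)))
}

#' Classify clusters as LADs or interior domains
#'
#' A cluster is a lamina-associated domain if any member localization
#' lies within `frac * R_nuc` of the nuclear boundary (inclusive);
#' otherwise it is an interior domain. Domain areas are the sums of the
#' member non-edge Voronoi polygon areas.
#'
#' @param tab A clustered, density-annotated table of one nucleus.
#' @param geom The nucleus geometry ([estimate_boundary()]).
#' @param frac Distance threshold as a fraction of `R_nuc` (default
#'   0.025).
#' @return A domain tibble: `nucleus_id`, `domain_id`, `type`, `n_locs`,
#'   `area_nm2`, `R_d_nm`, centroid coordinates, the mean member reduced
#'   density and `min_dist_to_boundary_nm`.
#' @export
classify_lads <- function(tab, geom, frac = 0.025) {
  if (missing(geom) || !inherits(geom, "nucleus_geometry")) {
    stop("missing geometry", call. = FALSE)
  }
  if (!"cluster_id" %in% names(tab)) {
    stop("run cluster_domains() first", call. = FALSE)
  }
  sel <- !is.na(tab$cluster_id) & tab$cluster_id > 0L
  if (!any(sel)) {
    return(tibble::tibble(
      nucleus_id = tab$nucleus_id[0], domain_id = integer(),
      type = character(), n_locs = integer(), area_nm2 = numeric(),
      R_d_nm = numeric(), min_dist_to_boundary_nm = numeric()
    ))
  }
  if (!"reduced_density" %in% names(tab)) {
    tab$reduced_density <- NA_real_
  }
  acol <- if ("area_cluster_id" %in% names(tab)) tab$area_cluster_id else
    tab$cluster_id
  avals <- if ("area_contrib_nm2" %in% names(tab)) tab$area_contrib_nm2 else
    tab$voronoi_area_nm2
  asel <- !is.na(acol) & acol > 0L & !tab$edge
  areas <- tapply(avals[asel], acol[asel], sum)
  sub <- tab[sel, ]
  proj <- dist_to_boundary(cbind(sub$x_nm, sub$y_nm), geom$boundary)
  sub$dist_b <- proj$dist
  sub |>
    dplyr::group_by(.data$nucleus_id, domain_id = .data$cluster_id) |>
    dplyr::summarise(
      n_locs = dplyr::n(),
      centroid_x_nm = mean(.data$x_nm),
      centroid_y_nm = mean(.data$y_nm),
      mean_reduced_density = mean(.data$reduced_density, na.rm = TRUE),
      min_dist_to_boundary_nm = min(.data$dist_b),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      area_nm2 = as.numeric(areas[as.character(.data$domain_id)])
    ) |>
    dplyr::mutate(
      R_d_nm = sqrt(.data$area_nm2 / pi),
      type = ifelse(.data$min_dist_to_boundary_nm <= frac * geom$R_nuc,
                    "LAD", "interior")
    ) |>
    dplyr::select("nucleus_id", "domain_id", "type", "n_locs", "area_nm2",
                  "R_d_nm", "centroid_x_nm", "centroid_y_nm",
                  "mean_reduced_density", "min_dist_to_boundary_nm")
}

#' LAD thickness profile from localization data
#'
#' Divides the nuclear boundary into `n_segments` equal-arc segments,
#' assigns every LAD localization's (non-edge) Voronoi polygon area to the
#' segment nearest its boundary projection, and converts the accumulated
#' area per segment into a local thickness. By default the conversion
#' inverts the annular-sector geometry (`area = dtheta * (R t - t^2/2)`)
#' so that a uniform band of true thickness `t` is recovered without the
#' curvature bias of a flat `area / length` ratio; `curvature_correct =
#' FALSE` gives the flat ratio.
#'
#' @param tab Clustered, annotated localizations of one nucleus.
#' @param domains The matching [classify_lads()] table.
#' @param geom The nucleus geometry.
#' @param n_segments Number of boundary segments (default 50; at least 4).
#' @param curvature_correct Invert the annular geometry (default `TRUE`).
#' @return A `lad_profile` (see [lad_thickness_from_mask()]).
#' @export
lad_thickness_profile <- function(tab, domains, geom, n_segments = 50,
                                  curvature_correct = TRUE) {
  segs <- boundary_segments(geom, n_segments)
  lad_ids <- domains$domain_id[domains$type == "LAD"]
  acol <- if ("area_cluster_id" %in% names(tab)) tab$area_cluster_id else
    tab$cluster_id
  avals <- if ("area_contrib_nm2" %in% names(tab)) tab$area_contrib_nm2 else
    tab$voronoi_area_nm2
  sel <- !is.na(acol) & acol %in% lad_ids & !tab$edge
  seg_area <- rep(0, n_segments)
  if (any(sel)) {
    proj <- dist_to_boundary(cbind(tab$x_nm[sel], tab$y_nm[sel]),
                             geom$boundary)
    arcs <- arc_position(geom, proj)
    idx <- pmin(findInterval(arcs, segs$arc_start), n_segments)
    acc <- tapply(avals[sel], idx, sum)
    seg_area[as.integer(names(acc))] <- acc
  }
  thick <- segment_thickness(seg_area, segs$length_nm, geom$R_nuc,
                             curvature_correct)
  prof <- dplyr::mutate(segs, lad_area_nm2 = seg_area,
                        thickness_nm = thick)
  total_hc <- sum(domains$area_nm2)
  structure(list(
    profile = dplyr::select(prof, "segment_idx", "arc_start", "arc_end",
                            "length_nm", "lad_area_nm2", "thickness_nm"),
    mean_T_LAD = mean(thick),
    median_T_LAD = stats::median(thick),
    total_lad_area_nm2 = sum(seg_area),
    peripheral_fraction = if (total_hc > 0) sum(seg_area) / total_hc else 0,
    n_segments = n_segments
  ), class = "lad_profile")
}

# Convert per-segment LAD area into a thickness. The curvature-corrected
# form solves area = dtheta * (R t - t^2 / 2) for t (an annular sector of
# outer radius R); the flat form is area / segment length.
segment_thickness <- function(seg_area, seg_len, R, curvature_correct) {
  if (!curvature_correct) return(seg_area / seg_len)
  dtheta <- seg_len / R
  disc <- pmax(R^2 - 2 * seg_area / dtheta, 0)
  R - sqrt(disc)
}
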
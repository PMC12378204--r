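#' Binarize a composition field into a heterochromatin mask
#'
#' Thresholds the heterochromatin fraction at the midpoint of the two
#' free-energy wells (`phi_h0 / 2`) by default, the level-set at which a
#' relaxed interface profile crosses over between the phases.
#'
#' @param field A [composition_field()].
#' @param threshold Threshold on `phi_h`, in `(0, phi_h0)`.
#' @param params [model_params()] supplying `phi_h0` when `threshold` is
#'   `NULL`.
#' @return A logical matrix (`FALSE` off the nucleus mask).
#' @export
binarize_heterochromatin <- function(field, threshold = NULL, params = NULL) {
  if (is.null(threshold)) {
    if (is.null(params)) {
      stop("supply `threshold` or `params`", call. = FALSE)
    }
    threshold <- params$phi_h0 / 2
  }
  if (!is.null(params) &&
      (threshold <= 0 || threshold >= params$phi_h0)) {
    stop("`threshold` must lie in (0, phi_h0)", call. = FALSE)
  }
  ph <- phi_h(field)
  out <- !is.na(ph) & ph >= threshold
  out
}

# 8-connected component labels over a logical matrix; returns an integer
# matrix (0 = background).
label_components <- function(bin) {
  nx <- nrow(bin); ny <- ncol(bin)
  cells <- which(bin)
  lab <- matrix(0L, nx, ny)
  if (!length(cells)) return(lab)
  id <- matrix(0L, nx, ny)
  id[cells] <- seq_along(cells)
  ci <- ((cells - 1) %% nx) + 1
  cj <- ((cells - 1) %/% nx) + 1
  edge_pairs <- function(di, dj) {
    ok <- ci + di >= 1 & ci + di <= nx & cj + dj >= 1 & cj + dj <= ny
    ii <- ci[ok] + di; jj <- cj[ok] + dj
    tgt <- id[cbind(ii, jj)]
    keep <- tgt > 0L
    cbind(id[cells[ok]][keep], tgt[keep])
  }
  e <- rbind(edge_pairs(1, 0), edge_pairs(0, 1),
             edge_pairs(1, 1), edge_pairs(1, -1))
  g <- igraph::make_graph(edges = as.vector(t(e)), n = length(cells),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[cells] <- as.integer(comp)
  lab
}

#' Label heterochromatin domains on a lattice
#'
#' Finds 8-connected components of a heterochromatin mask and classifies
#' each as a LAD (any member cell within `band` of the nuclear boundary)
#' or an interior domain, mirroring the imaging-side rule.
#'
#' @param mask Logical heterochromatin matrix (from
#'   [binarize_heterochromatin()]).
#' @param geom Matching [make_geometry()] object.
#' @param band Distance band in nm; default `0.025 * R_nuc`.
#' @return A tibble (one row per domain): `domain_id`, `type`
#'   (`"interior"`/`"LAD"`), `n_cells`, `area_nm2`, `R_d_nm`,
#'   `centroid_x_nm`, `centroid_y_nm`, `min_dist_to_boundary_nm`.
#' @export
label_domains <- function(mask, geom, band = NULL) {
  if (!all(dim(mask) == dim(geom$mask))) {
    stop("mask is not on the geometry lattice", call. = FALSE)
  }
  if (is.null(band)) band <- 0.025 * geom$R_nuc
  lab <- label_components(mask & geom$mask)
  cells <- which(lab > 0L)
  if (!length(cells)) {
    return(tibble::tibble(
      domain_id = integer(), type = character(), n_cells = integer(),
      area_nm2 = numeric(), R_d_nm = numeric(),
      centroid_x_nm = numeric(), centroid_y_nm = numeric(),
      min_dist_to_boundary_nm = numeric()
    ))
  }
  nx <- nrow(mask)
  ci <- ((cells - 1) %% nx) + 1
  cj <- ((cells - 1) %/% nx) + 1
  df <- tibble::tibble(
    domain_id = lab[cells],
    x = geom$x[ci], y = geom$y[cj],
    d = geom$dist[cells]
  )
  out <- df |>
    dplyr::group_by(.data$domain_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      area_nm2 = dplyr::n() * geom$h^2,
      centroid_x_nm = mean(.data$x),
      centroid_y_nm = mean(.data$y),
      min_dist_to_boundary_nm = min(.data$d),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      R_d_nm = sqrt(.data$area_nm2 / pi),
      type = ifelse(.data$min_dist_to_boundary_nm <= band,
                    "LAD", "interior")
    ) |>
    dplyr::select("domain_id", "type", "n_cells", "area_nm2", "R_d_nm",
                  "centroid_x_nm", "centroid_y_nm",
                  "min_dist_to_boundary_nm")
  out
}

#' LAD thickness profile from a lattice mask
#'
#' Partitions the nuclear boundary into `n_segments` equal-arc-length
#' segments and, for each, divides the cumulative LAD area assigned to it
#' (every LAD cell contributes `h^2` to the segment nearest its boundary
#' projection) by the segment length, giving a local thickness in nm.
#'
#' @param mask Logical heterochromatin matrix.
#' @param geom Matching geometry.
#' @param n_segments Number of boundary segments (default 50).
#' @param band LAD classification band (nm); default `0.025 * R_nuc`.
#' @param curvature_correct Invert the annular-sector geometry when
#'   converting segment area to thickness (default `TRUE`; see
#'   [lad_thickness_profile()]).
#' @return An object of class `lad_profile`: tibble `profile` with
#'   `segment_idx`, `arc_length_nm`, `lad_area_nm2`, `thickness_nm`, plus
#'   `mean_T_LAD`, `median_T_LAD`, `peripheral_fraction` (LAD area over
#'   total heterochromatin area) and `total_lad_area_nm2`.
#' @export
lad_thickness_from_mask <- function(mask, geom, n_segments = 50,
                                    band = NULL, curvature_correct = TRUE) {
  segs <- boundary_segments(geom, n_segments)
  dom <- label_domains(mask, geom, band = band)
  lab <- label_components(mask & geom$mask)
  lad_ids <- dom$domain_id[dom$type == "LAD"]
  lad_cells <- which(lab %in% lad_ids)
  seg_area <- rep(0, n_segments)
  if (length(lad_cells)) {
    arcs <- geom$arc[geom$nearest_b[lad_cells]]
    idx <- pmin(findInterval(arcs, segs$arc_start), n_segments)
    tab <- tapply(rep(geom$h^2, length(lad_cells)), idx, sum)
    seg_area[as.integer(names(tab))] <- tab
  }
  prof <- dplyr::mutate(segs,
    lad_area_nm2 = seg_area,
    thickness_nm = segment_thickness(seg_area, .data$length_nm,
                                     geom$R_nuc, curvature_correct)
  )
  total_hc <- sum(dom$area_nm2)
  structure(list(
    profile = dplyr::select(prof, "segment_idx", "arc_start", "arc_end",
                            length_nm = "length_nm",
                            "lad_area_nm2", "thickness_nm"),
    mean_T_LAD = mean(prof$thickness_nm),
    median_T_LAD = stats::median(prof$thickness_nm),
    total_lad_area_nm2 = sum(seg_area),
    peripheral_fraction = if (total_hc > 0) sum(seg_area) / total_hc else 0,
    n_segments = n_segments
  ), class = "lad_profile")
}

#' @export
print.lad_profile <- function(x, ...) {
  cat("<lad_profile>\n")
  cat(sprintf("  %d segments; mean T_LAD = %.1f nm, median = %.1f nm\n",
              x$n_segments, x$mean_T_LAD, x$median_T_LAD))
  cat(sprintf("  LAD area = %.3g nm^2 (peripheral fraction %.2f)\n",
              x$total_lad_area_nm2, x$peripheral_fraction))
  invisible(x)
}

#' Contact angle of a peripheral domain
#'
#' Fits a circular cap to a peripheral domain: the angle between the
#' domain's free interface and the local lamina follows from the cap
#' height `h_max` (maximum distance of domain cells from the boundary)
#' and the contact base `b` (arc extent of the cells adjacent to the
#' boundary) as `theta = 2 * atan(2 * h_max / b)`. A half-disk gives 90
#' degrees; spread lamellar caps give small angles.
#'
#' @param cell_idx Linear indices (into the lattice) of the domain cells.
#' @param geom Matching geometry.
#' @return Angle in degrees, or `NA` with a message for interior domains
#'   (no cells adjacent to the boundary).
#' @export
contact_angle <- function(cell_idx, geom) {
  if (!length(cell_idx)) return(NA_real_)
  d <- geom$dist[cell_idx]
  touch <- cell_idx[d <= 1.5 * geom$h]
  if (!length(touch)) {
    return(structure(NA_real_, reason = "interior domain"))
  }
  h_max <- max(d)
  arcs <- sort(geom$arc[geom$nearest_b[touch]])
  if (length(arcs) == 1) {
    base <- geom$h
  } else {
    gaps <- diff(c(arcs, arcs[1] + geom$perimeter))
    base <- geom$perimeter - max(gaps) + geom$h
  }
  2 * atan2(2 * h_max, base) * 180 / pi
}

#' Summaries of domain-size distributions across conditions
#'
#' @param tables Named list of domain tables ([label_domains()] /
#'   [classify_lads()] output), one per condition.
#' @param profiles Optional named list of `lad_profile` objects matching
#'   `tables`.
#' @return A list of class `size_distributions`: `summary` (per condition
#'   and metric: n, mean, median, q25, q75, sd) and `density` (smoothed
#'   density curves, per condition and metric).
#' @export
size_distributions <- function(tables, profiles = NULL) {
  if (!length(tables)) stop("no domain tables supplied", call. = FALSE)
  if (is.null(names(tables))) {
    names(tables) <- paste0("condition_", seq_along(tables))
  }
  vals <- purrr::imap_dfr(tables, function(tab, cond) {
    interior <- tab[tab$type == "interior", ]
    tibble::tibble(condition = cond, metric = "R_d_nm",
                   value = interior$R_d_nm)
  })
  if (!is.null(profiles)) {
    vals <- dplyr::bind_rows(vals, purrr::imap_dfr(profiles,
      function(pr, cond) {
        tibble::tibble(condition = cond, metric = "T_LAD_nm",
                       value = pr$profile$thickness_nm)
      }))
  }
  summ <- vals |>
    dplyr::group_by(.data$condition, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value),
      median = stats::median(.data$value),
      q25 = stats::quantile(.data$value, 0.25),
      q75 = stats::quantile(.data$value, 0.75),
      sd = stats::sd(.data$value), .groups = "drop"
    )
  dens <- vals |>
    dplyr::group_by(.data$condition, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2 || stats::sd(df$value) == 0) {
        return(tibble::tibble(x = df$value[1], y = Inf))
      }
      d <- stats::density(df$value)
      tibble::tibble(x = d$x, y = d$y)
    }) |>
    dplyr::ungroup()
  structure(list(summary = summ, density = dens),
            class = "size_distributions")
}

#' Percent change between two condition means
#'
#' @param reference,value Two numbers (e.g. condition means).
#' @return `100 * (value / reference - 1)`.
#' @export
percent_change <- function(reference, value) 100 * (value / reference - 1)
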
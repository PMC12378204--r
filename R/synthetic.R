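#' Specification of a synthetic STORM nucleus
#'
#' Describes the statistical structure of a single-nucleus localization
#' cloud: a closed nuclear boundary, a low-density euchromatin background,
#' interior heterochromatin clusters with a characteristic radius, and a
#' peripheral LAD band of controllable, possibly patchy thickness.
#' Intensities are localization densities per square micrometre.
#'
#' @param shape `"circle"` or `"ellipse"`.
#' @param radii Radius (nm) or semi-axes `c(a, b)`.
#' @param bg_intensity Background (euchromatin) localization intensity
#'   (per um^2).
#' @param n_clusters Number of interior heterochromatin clusters.
#' @param cluster_radius Mean cluster radius (nm).
#' @param cluster_radius_cv Coefficient of variation of cluster radii.
#' @param cluster_mult Within-cluster intensity multiplier over background.
#' @param lad_type `"constant"` (uniform band), `"patchy"` (alternating
#'   `0`/`t_max` blocks) or `"smooth"` (log of a smoothed noise profile).
#' @param lad_thickness Band thickness `t` (nm); for `"patchy"` this is
#'   `t_max` of the covered blocks.
#' @param lad_blocks Number of alternating blocks for `"patchy"` (even).
#' @param lad_cv Thickness CV for `"smooth"`.
#' @param lad_mult Band intensity multiplier over background.
#' @param jitter_sd Localization precision jitter (nm, Gaussian; default
#'   10 nm, the STORM precision scale).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = "circle", radii = 2000,
                           bg_intensity = 150, n_clusters = 30,
                           cluster_radius = 50, cluster_radius_cv = 0.2,
                           cluster_mult = 25,
                           lad_type = c("constant", "patchy", "smooth"),
                           lad_thickness = 200, lad_blocks = 12,
                           lad_cv = 0.3, lad_mult = 12,
                           jitter_sd = 10, seed = 1L) {
  lad_type <- match.arg(lad_type)
  if (bg_intensity <= 0 || cluster_mult <= 0 || lad_mult <= 0) {
    stop("intensities must be positive", call. = FALSE)
  }
  if (lad_thickness >= min(radii) / 2) {
    stop("LAD thickness must be below half the smallest radius",
         call. = FALSE)
  }
  if (lad_type == "patchy" && lad_blocks %% 2 != 0) {
    stop("`lad_blocks` must be even", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# thickness of the LAD band at boundary angle theta (radians)
band_thickness_at <- function(theta, spec, smooth_profile = NULL) {
  switch(spec$lad_type,
    constant = rep(spec$lad_thickness, length(theta)),
    patchy = {
      blk <- floor(theta / (2 * pi) * spec$lad_blocks) %% 2
      ifelse(blk == 0, spec$lad_thickness, 0)
    },
    smooth = {
      idx <- pmin(pmax(ceiling(theta / (2 * pi) *
                                 length(smooth_profile)), 1),
                  length(smooth_profile))
      smooth_profile[idx]
    })
}

#' Generate a synthetic nucleus with ground truth
#'
#' Draws a homogeneous Poisson background inside the boundary, interior
#' clusters as boosted-intensity disks at rejection-sampled
#' non-overlapping centres (minimum separation four mean radii, clear of
#' the LAD band), and a peripheral band whose local thickness follows the
#' spec. All positions receive Gaussian localization jitter.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `table` (a `localization_table` with a
#'   `compartment` column for diagnostics) and `truth` (cluster centres
#'   and radii, the per-angle band thickness at 360 samples, expected
#'   band thickness mean, and the spec).
#' @export
generate_nucleus <- function(spec) {
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  radii <- if (length(spec$radii) == 1) rep(spec$radii, 2) else spec$radii
  a <- radii[1]; b <- radii[2]
  area_um2 <- pi * a * b / 1e6
  smooth_profile <- NULL
  if (spec$lad_type == "smooth") {
    z <- grf1d(360, 30)
    smooth_profile <- pmax(spec$lad_thickness * (1 + spec$lad_cv * z), 0)
  }
  # background
  n_bg <- stats::rpois(1, spec$bg_intensity * area_um2)
  bg <- sample_in_ellipse(n_bg, a, b)
  # LAD band: sample candidates in the outer annulus at band intensity,
  # keep those within the local thickness of the boundary
  tmax <- switch(spec$lad_type,
                 constant = spec$lad_thickness,
                 patchy = spec$lad_thickness,
                 smooth = max(smooth_profile))
  lad <- matrix(numeric(0), 0, 2)
  if (tmax > 0) {
    # effective radial fraction of the band (sampling frame)
    frac <- 1 - (1 - tmax / min(a, b))^2
    n_cand <- stats::rpois(1, (spec$lad_mult - 1) * spec$bg_intensity *
                               area_um2 * frac * 1.2)
    cand <- sample_in_ellipse_annulus(n_cand, a, b, tmax * 1.2)
    if (nrow(cand)) {
      th <- atan2(cand[, 2] / b, cand[, 1] / a) %% (2 * pi)
      d <- dist_to_ellipse_edge(cand, a, b)
      keep <- d <= band_thickness_at(th, spec, smooth_profile)
      lad <- cand[keep, , drop = FALSE]
    }
  }
  # interior clusters
  centres <- matrix(numeric(0), 0, 2)
  radii_cl <- numeric(0)
  if (spec$n_clusters > 0) {
    sep <- 4 * spec$cluster_radius
    tries <- 0L
    while (nrow(centres) < spec$n_clusters) {
      tries <- tries + 1L
      if (tries > 200 * spec$n_clusters) {
        stop("infeasible packing: could not place the requested clusters",
             call. = FALSE)
      }
      p <- sample_in_ellipse(1, a, b)
      r <- max(stats::rnorm(1, spec$cluster_radius,
                            spec$cluster_radius_cv * spec$cluster_radius),
               10)
      d_edge <- dist_to_ellipse_edge(p, a, b)
      if (d_edge < tmax + r + 4 * spec$jitter_sd + 0.05 * min(a, b)) next
      if (nrow(centres) &&
          min(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2)) <
            sep) next
      centres <- rbind(centres, p)
      radii_cl <- c(radii_cl, r)
    }
  }
  cl_pts <- lapply(seq_len(nrow(centres)), function(i) {
    lam <- (spec$cluster_mult - 1) * spec$bg_intensity *
      pi * radii_cl[i]^2 / 1e6
    n <- stats::rpois(1, lam)
    if (!n) return(matrix(numeric(0), 0, 2))
    rr <- radii_cl[i] * sqrt(stats::runif(n))
    tt <- stats::runif(n, 0, 2 * pi)
    cbind(centres[i, 1] + rr * cos(tt), centres[i, 2] + rr * sin(tt))
  })
  cl <- do.call(rbind, c(list(matrix(numeric(0), 0, 2)), cl_pts))
  pts <- rbind(bg, lad, cl)
  compartment <- c(rep("background", nrow(bg)), rep("lad", nrow(lad)),
                   rep(paste0("cluster_",
                              rep(seq_len(nrow(centres)),
                                  vapply(cl_pts, nrow, numeric(1)))),
                       length.out = nrow(cl)))
  if (spec$jitter_sd > 0 && nrow(pts)) {
    pts <- pts + matrix(stats::rnorm(2 * nrow(pts), 0, spec$jitter_sd),
                        ncol = 2)
  }
  tab <- tibble::tibble(
    nucleus_id = 1L, x_nm = pts[, 1], y_nm = pts[, 2],
    compartment = compartment
  )
  tab <- as_localization_table(tab,
                               jitter_seed = stable_hash("dup", spec$seed))
  th360 <- seq(0, 2 * pi, length.out = 361)[-361]
  t_prof <- band_thickness_at(th360, spec, smooth_profile)
  list(
    table = tab,
    truth = list(
      centres = centres, cluster_radii = radii_cl,
      band_theta = th360, band_thickness = t_prof,
      band_mean = mean(t_prof),
      area_nm2 = pi * a * b, R_nuc = sqrt(a * b),
      spec = spec
    )
  )
}

sample_in_ellipse <- function(n, a, b) {
  if (!n) return(matrix(numeric(0), 0, 2))
  r <- sqrt(stats::runif(n)); t <- stats::runif(n, 0, 2 * pi)
  cbind(a * r * cos(t), b * r * sin(t))
}

# uniform sample in the band within `t` of the edge (in the normalised
# radial sense, exact for circles, adequate for mild ellipticity)
sample_in_ellipse_annulus <- function(n, a, b, t) {
  if (!n) return(matrix(numeric(0), 0, 2))
  s <- min(a, b)
  r0 <- 1 - t / s
  r <- sqrt(stats::runif(n, r0^2, 1)); tt <- stats::runif(n, 0, 2 * pi)
  cbind(a * r * cos(tt), b * r * sin(tt))
}

# distance to the ellipse edge: first-order normal distance
# (1 - rho) / |grad rho|, exact for circles
dist_to_ellipse_edge <- function(p, a, b) {
  p <- matrix(p, ncol = 2)
  rho <- sqrt((p[, 1] / a)^2 + (p[, 2] / b)^2)
  grad <- sqrt(p[, 1]^2 / a^4 + p[, 2]^2 / b^4) / pmax(rho, 1e-12)
  (1 - rho) / pmax(grad, 1e-12)
}

# expected localization counts of a spec: background, clusters, band
expected_counts <- function(spec) {
  radii <- if (length(spec$radii) == 1) rep(spec$radii, 2) else spec$radii
  A <- pi * radii[1] * radii[2] / 1e6
  n_bg <- spec$bg_intensity * A
  n_cl <- spec$n_clusters * pi * spec$cluster_radius^2 / 1e6 *
    (spec$cluster_mult - 1) * spec$bg_intensity
  R <- sqrt(radii[1] * radii[2])
  barea <- (2 * pi * R * spec$lad_thickness - pi * spec$lad_thickness^2) /
    1e6
  if (spec$lad_type == "patchy") barea <- barea / 2
  n_band <- max(barea, 0) * (spec$lad_mult - 1) * spec$bg_intensity
  list(bg = n_bg, structure = n_cl + n_band, area_um2 = A)
}

#' Generate a matched pair of synthetic conditions
#'
#' The perturbed condition scales the mean cluster radius by `dR_d`
#' percent and the band thickness by `dT_LAD` percent; everything else is
#' matched. In particular the expected localization *composition* is
#' held fixed: the background intensity is kept at the control value and
#' the within-structure intensities scale inversely with the structure
#' areas, so each structure keeps its expected localization count and
#' the pooled percentile thresholds see the same composition in both
#' conditions. (The pooled classifier anchors its sparse class at 30% of
#' the pool; letting the composition drift with structure size would
#' bias the measured sizes and contaminate the imposed effect.)
#'
#' @param spec Control [synthetic_spec()].
#' @param effect Named vector/list with `dR_d` and `dT_LAD` (percent,
#'   each > -100).
#' @param seeds Length-2 integer seeds for the two conditions.
#' @return A list with `control` and `perturbed` (each a
#'   [generate_nucleus()] result) and the applied `effect`.
#' @export
generate_condition_pair <- function(spec, effect, seeds = c(1L, 2L)) {
  effect <- as.list(effect)
  if (effect$dR_d <= -100 || effect$dT_LAD <= -100) {
    stop("effects must exceed -100%", call. = FALSE)
  }
  ctrl_spec <- spec
  ctrl_spec$seed <- seeds[1]
  pert_spec <- spec
  pert_spec$seed <- seeds[2]
  pert_spec$cluster_radius <- spec$cluster_radius * (1 + effect$dR_d / 100)
  pert_spec$lad_thickness <- spec$lad_thickness * (1 + effect$dT_LAD / 100)
  # hold the background intensity (hence the background polygon scale
  # and the bleed around structures) and the expected per-structure
  # localization counts fixed: within-structure intensities scale
  # inversely with the structure area, so the pooled composition and the
  # percentile thresholds are matched across the pair
  r_ratio2 <- (pert_spec$cluster_radius / spec$cluster_radius)^2
  if (r_ratio2 > 0) {
    pert_spec$cluster_mult <- 1 + (spec$cluster_mult - 1) / r_ratio2
  }
  t_c <- spec$lad_thickness; t_p <- pert_spec$lad_thickness
  if (t_p > 0 && t_c > 0) {
    R <- sqrt(prod(if (length(spec$radii) == 1) rep(spec$radii, 2) else
      spec$radii))
    band_ratio <- (2 * pi * R * t_p - pi * t_p^2) /
      (2 * pi * R * t_c - pi * t_c^2)
    pert_spec$lad_mult <- 1 + (spec$lad_mult - 1) / band_ratio
  }
  list(control = generate_nucleus(ctrl_spec),
       perturbed = generate_nucleus(pert_spec),
       effect = effect)
}
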
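#' Methylation rate from an interior domain radius
#'
#' Inverts the interior-domain size relation
#' `R_d = sqrt(3 * D_h * phi_h_star / Gamma_ac)`, where `phi_h_star` is
#' the far-field heterochromatin concentration maintained by the reaction
#' balance. With the default closure
#' `phi_h_star = s0 * Gamma_me / (Gamma_me + Gamma_ac)` the inversion is
#' closed-form: `Gamma_me = Gamma_ac * x / (s0 - x)` with
#' `x = R_d^2 * Gamma_ac / (3 * D_h)`. A custom monotone closure function
#' `closure(Gamma_me)` is inverted numerically.
#'
#' @param R_d Interior domain radius (nm); vectorised.
#' @param D_h Heterochromatin diffusivity (nm^2/s).
#' @param Gamma_ac Acetylation rate (1/s).
#' @param s0 Closure scale (dimensionless); see [calibrate_closure()].
#' @param closure Optional function `Gamma_me -> phi_h_star`, strictly
#'   increasing; overrides the default closure.
#' @return Methylation rate(s) (1/s).
#' @examples
#' infer_gamma_me(3, D_h = 6, Gamma_ac = 1, s0 = 1) # 1
#' @export
infer_gamma_me <- function(R_d, D_h, Gamma_ac, s0 = 1, closure = NULL) {
  stopifnot(all(R_d >= 0), D_h > 0, Gamma_ac > 0)
  x <- R_d^2 * Gamma_ac / (3 * D_h)
  if (is.null(closure)) {
    if (any(x >= s0)) {
      stop(sprintf(
        paste0("unreachable radius: R_d >= R_d_max = %.4g nm ",
               "under the default closure (s0 = %.4g)"),
        sqrt(3 * D_h * s0 / Gamma_ac), s0), call. = FALSE)
    }
    return(Gamma_ac * x / (s0 - x))
  }
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    f <- function(g) closure(g) - xi
    upper <- Gamma_ac
    while (f(upper) < 0 && upper < 1e12 * Gamma_ac) upper <- upper * 2
    if (f(upper) < 0) {
      stop("unreachable radius under the supplied closure", call. = FALSE)
    }
    stats::uniroot(f, c(0, upper), tol = 1e-12 * Gamma_ac)$root
  }, numeric(1))
}

#' Calibrate the far-field closure scale
#'
#' Fixes `s0` so that the control condition's mean interior radius maps to
#' the configured nominal methylation rate:
#' `s0 = x * (Gamma_me + Gamma_ac) / Gamma_me` with
#' `x = R_d^2 * Gamma_ac / (3 * D_h)`.
#'
#' @param R_d_control Mean control interior radius (nm).
#' @param Gamma_me_nominal Nominal control methylation rate (1/s).
#' @param D_h,Gamma_ac Fixed constants of the extraction.
#' @return The closure scale `s0`.
#' @export
calibrate_closure <- function(R_d_control, Gamma_me_nominal, D_h, Gamma_ac) {
  x <- R_d_control^2 * Gamma_ac / (3 * D_h)
  x * (Gamma_me_nominal + Gamma_ac) / Gamma_me_nominal
}

#' Build the LAD-thickness response surface by simulation
#'
#' Runs the phase-field model to steady state for every combination of a
#' methylation-rate grid and a chromatin-lamina affinity grid, measures
#' the mean LAD thickness of each steady state (averaging replicates) and
#' regularises each constant-`Gamma_me` row to be non-decreasing in the
#' affinity (isotonic regression). The resulting monotone map is what
#' [infer_vlad()] inverts; its first and last row values estimate the
#' regime-I and regime-III plateau levels.
#'
#' @param gamma_grid Ascending methylation-rate means (1/s).
#' @param vlad_grid Ascending affinity means (pN*nm/nm^2).
#' @param sim_config List of simulation settings: `geometry` (arguments to
#'   [make_geometry()]), `params` (a [model_params()] to use as the base),
#'   `phi_n_bar`, `cvs`, `xi`, and steady-state controls (`max_steps`,
#'   `check_every`, `tol`).
#' @param replicates Replicate steady states per cell (seeds fanned out).
#' @param seed Base seed.
#' @param cache_dir Optional directory; the surface is stored as JSON
#'   keyed by a hash of the configuration and re-loaded when present.
#' @return An object of class `response_surface`: `grid` (long tibble),
#'   `T` (matrix, rows = gamma, cols = vlad), `T_lo`, `T_hi` per row,
#'   `gamma_grid`, `vlad_grid`.
#' @export
build_response_surface <- function(gamma_grid, vlad_grid, sim_config,
                                   replicates = 1L, seed = 1L,
                                   cache_dir = NULL) {
  stopifnot(!is.unsorted(gamma_grid), !is.unsorted(vlad_grid),
            replicates >= 1)
  key <- stable_hash(paste(
    paste(signif(gamma_grid, 8), collapse = ","),
    paste(signif(vlad_grid, 8), collapse = ","),
    paste(deparse(sim_config[order(names(sim_config))]), collapse = ""),
    replicates, seed))
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir, sprintf("surface_%d.json", key))
    if (file.exists(cache_file)) {
      return(surface_from_cache(cache_file))
    }
  }
  geom <- do.call(make_geometry, sim_config$geometry)
  base <- sim_config$params
  Tmat <- matrix(NA_real_, length(gamma_grid), length(vlad_grid))
  disp <- matrix(NA_real_, length(gamma_grid), length(vlad_grid))
  for (gi in seq_along(gamma_grid)) {
    for (vi in seq_along(vlad_grid)) {
      vals <- numeric(0)
      for (r in seq_len(replicates)) {
        s <- stable_hash(sprintf("surface-%d-%d-%d", gi, vi, r), seed)
        res <- try(steady_for_means(
          geom, base, gamma_grid[gi], vlad_grid[vi],
          sim_config, seed = s), silent = TRUE)
        if (!inherits(res, "try-error")) vals <- c(vals, res)
      }
      if (length(vals)) {
        Tmat[gi, vi] <- mean(vals)
        disp[gi, vi] <- stats::sd(vals)
      }
    }
    bad <- is.na(Tmat[gi, ])
    if (any(bad)) {
      warning(sprintf("interpolating %d failed cell(s) in row %d",
                      sum(bad), gi))
      Tmat[gi, bad] <- stats::approx(vlad_grid[!bad], Tmat[gi, !bad],
                                     vlad_grid[bad], rule = 2)$y
    }
    Tmat[gi, ] <- stats::isoreg(vlad_grid, Tmat[gi, ])$yf
  }
  surf <- structure(list(
    grid = tidyr::expand_grid(Gamma_me = gamma_grid, V_LAD = vlad_grid) |>
      dplyr::mutate(T_LAD = as.vector(t(Tmat))),
    T = Tmat, dispersion = disp,
    T_lo = Tmat[, 1], T_hi = Tmat[, ncol(Tmat)],
    gamma_grid = gamma_grid, vlad_grid = vlad_grid,
    replicates = replicates, seed = seed
  ), class = "response_surface")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      gamma_grid = gamma_grid, vlad_grid = vlad_grid,
      T = Tmat, replicates = replicates, seed = seed
    ), cache_file, digits = NA, matrix = "rowmajor")
  }
  surf
}

surface_from_cache <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  Tmat <- matrix(as.numeric(d$T), length(d$gamma_grid),
                 length(d$vlad_grid), byrow = TRUE)
  structure(list(
    grid = tidyr::expand_grid(Gamma_me = d$gamma_grid,
                              V_LAD = d$vlad_grid) |>
      dplyr::mutate(T_LAD = as.vector(t(Tmat))),
    T = Tmat, dispersion = NULL,
    T_lo = Tmat[, 1], T_hi = Tmat[, ncol(Tmat)],
    gamma_grid = d$gamma_grid, vlad_grid = d$vlad_grid,
    replicates = d$replicates, seed = d$seed
  ), class = "response_surface")
}

# one steady-state run at given means; returns mean T_LAD
steady_for_means <- function(geom, base, gme_mean, vlad_mean, sim_config,
                             seed) {
  pf <- sample_parameter_fields(
    geom, means = list(Gamma_me = gme_mean, V_LAD = vlad_mean),
    cvs = sim_config$cvs %||% list(Gamma_me = 0.3, V_LAD = 0.3),
    xi = sim_config$xi %||% 200, seed = seed)
  ss <- run_to_steady_state(
    geom, pf, base,
    phi_n_bar = sim_config$phi_n_bar %||% 0.35,
    tol = sim_config$tol %||% 0.02,
    max_steps = sim_config$max_steps %||% 50000L,
    check_every = sim_config$check_every %||% 2000L,
    seed = seed)
  utils::tail(ss$trace$mean_T_LAD, 1)
}

#' @export
print.response_surface <- function(x, ...) {
  cat("<response_surface>\n")
  cat(sprintf("  %d Gamma_me x %d V_LAD cells; T_LAD range %.1f-%.1f nm\n",
              length(x$gamma_grid), length(x$vlad_grid),
              min(x$T, na.rm = TRUE), max(x$T, na.rm = TRUE)))
  invisible(x)
}

#' Chromatin-lamina affinity from a LAD thickness
#'
#' Inverts the monotone response surface at a given methylation rate.
#' Thicknesses at or below the regime-I plateau map to zero affinity;
#' thicknesses at or above the regime-III plateau map to the saturated
#' top of the affinity grid (flagged); in between, the unique interpolated
#' affinity is returned. Rows are interpolated linearly in `Gamma_me`
#' inside the grid; outside it the nearest row is used with a warning.
#'
#' @param T_LAD LAD thickness(es) (nm); vectorised.
#' @param Gamma_me Methylation rate (1/s), one value (recycled).
#' @param surf A [build_response_surface()] object.
#' @return A tibble with `T_LAD`, `V_LAD` and `regime`
#'   (`"low"`/`"mid"`/`"saturated"`).
#' @export
infer_vlad <- function(T_LAD, Gamma_me, surf) {
  g <- surf$gamma_grid
  if (Gamma_me < min(g) || Gamma_me > max(g)) {
    warning("Gamma_me outside the surface grid; using the nearest row")
    row <- surf$T[which.min(abs(g - Gamma_me)), ]
  } else if (length(g) == 1) {
    row <- surf$T[1, ]
  } else {
    i <- findInterval(Gamma_me, g, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(g) - 1)
    w <- (Gamma_me - g[i]) / (g[i + 1] - g[i])
    row <- (1 - w) * surf$T[i, ] + w * surf$T[i + 1, ]
  }
  v <- surf$vlad_grid
  t_lo <- row[1]; t_hi <- row[length(row)]
  out <- vapply(T_LAD, function(tt) {
    if (tt <= t_lo) return(c(0, 1))
    if (tt >= t_hi) return(c(v[length(v)], 3))
    # strictly increasing copy for interpolation
    rr <- row + seq_along(row) * 1e-12 * max(row, 1)
    c(stats::approx(rr, v, tt, rule = 2)$y, 2)
  }, numeric(2))
  tibble::tibble(
    T_LAD = T_LAD, V_LAD = out[1, ],
    regime = c("low", "mid", "saturated")[out[2, ]]
  )
}

#' Heterochromatin budget consistency check
#'
#' The total heterochromatin of the nucleus is shared between interior
#' domains and LADs. From the mean extracted rates, the expected total is
#' `phi_h_bar * A_nuc` with `phi_h_bar = Gamma_me / (Gamma_me +
#' Gamma_ac)`; the measured total is the summed area of all called
#' domains (interior + peripheral). The relative residual between the two
#' diagnoses closure miscalibration (flagged above `flag_at`).
#'
#' @param Gamma_me_mean Mean extracted methylation rate (1/s).
#' @param Gamma_ac Acetylation rate (1/s).
#' @param domains A domain table ([classify_lads()] / [label_domains()]).
#' @param geom The nucleus geometry (for `A_nuc`).
#' @param hc_capacity Area fraction a fully heterochromatic region
#'   contributes per unit `phi_h_bar` (1 for localization data; for
#'   simulated fields the chromatin content over `phi_h0`).
#' @param flag_at Residual threshold for the miscalibration flag.
#' @return A list: `total_hc_nm2`, `measured_hc_nm2`, `residual`,
#'   `flagged`.
#' @export
hc_budget_check <- function(Gamma_me_mean, Gamma_ac, domains, geom,
                            hc_capacity = 1, flag_at = 0.5) {
  phi_bar <- Gamma_me_mean / (Gamma_me_mean + Gamma_ac)
  total <- phi_bar * geom$area * hc_capacity
  measured <- sum(domains$area_nm2)
  residual <- abs(total - measured) / max(total, 1e-300)
  list(total_hc_nm2 = total, measured_hc_nm2 = measured,
       residual = residual, flagged = residual > flag_at)
}

#' Distribution summary with mode detection and plateau masses
#'
#' Summarises an extracted parameter sample: location and spread, a
#' kernel-density mode count (Silverman bandwidth; maxima below 5% of the
#' peak are ignored) and the fraction of mass sitting in the lowest and
#' saturated bins. The distribution is flagged bimodal when both plateau
#' masses exceed 10%, the signature of a periphery alternating between
#' lamina regions of vanishing and near-chromatin-strength affinity.
#'
#' @param values Numeric sample (at least 10 values).
#' @param kind `"gamma_me"` or `"vlad"` (labelling only).
#' @param lo_edge,hi_edge Bin edges for the plateau masses; defaults are
#'   5% above the minimum and 5% below the maximum of the sample range.
#' @return A list of class `distribution_summary`.
#' @export
summarize_distribution <- function(values, kind = c("gamma_me", "vlad"),
                                   lo_edge = NULL, hi_edge = NULL) {
  kind <- match.arg(kind)
  if (length(values) < 10) {
    stop("need at least 10 values to summarise a distribution",
         call. = FALSE)
  }
  rng <- range(values)
  span <- diff(rng)
  lo_edge <- lo_edge %||% (rng[1] + 0.05 * span)
  hi_edge <- hi_edge %||% (rng[2] - 0.05 * span)
  lo_mass <- mean(values <= lo_edge)
  hi_mass <- mean(values >= hi_edge)
  if (span == 0 || stats::sd(values) == 0) {
    modes <- rng[1]
  } else {
    d <- stats::density(values, bw = "nrd0")
    y <- d$y
    is_max <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf) &
                      y > 0.05 * max(y))
    modes <- d$x[is_max]
  }
  structure(list(
    kind = kind, n = length(values),
    mean = mean(values), median = stats::median(values),
    q25 = stats::quantile(values, 0.25, names = FALSE),
    q75 = stats::quantile(values, 0.75, names = FALSE),
    sd = stats::sd(values),
    modes = modes, n_modes = length(modes),
    lo_mass = lo_mass, hi_mass = hi_mass,
    bimodal = lo_mass > 0.1 && hi_mass > 0.1
  ), class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary: %s> n = %d\n", x$kind, x$n))
  cat(sprintf("  mean %.4g, median %.4g [%.4g, %.4g]\n",
              x$mean, x$median, x$q25, x$q75))
  cat(sprintf("  %d mode(s); plateau masses lo %.2f / hi %.2f%s\n",
              x$n_modes, x$lo_mass, x$hi_mass,
              if (x$bimodal) " (bimodal)" else ""))
  invisible(x)
}

#' Full parameter extraction for one nucleus
#'
#' The two-step extraction: interior domain radii map to per-domain
#' methylation rates through the interior-size relation, then each
#' boundary segment's LAD thickness maps to an affinity through the
#' response surface evaluated at the nucleus mean methylation rate.
#' Distribution summaries and the heterochromatin budget residual are
#' attached.
#'
#' @param domains Domain table of one nucleus.
#' @param profile The matching `lad_profile`.
#' @param surf A [build_response_surface()] object.
#' @param geom The nucleus geometry.
#' @param D_h,Gamma_ac Fixed extraction constants.
#' @param s0 Closure scale (see [calibrate_closure()]).
#' @param hc_capacity Passed to [hc_budget_check()].
#' @return An object of class `extraction_result`: tibbles `gamma_me`
#'   (per interior domain) and `vlad` (per boundary segment), summaries,
#'   the budget check and the closure metadata.
#' @export
extract_parameters <- function(domains, profile, surf, geom,
                               D_h, Gamma_ac, s0, hc_capacity = 1) {
  interior <- domains[domains$type == "interior", ]
  rmax <- sqrt(3 * D_h * s0 / Gamma_ac)
  usable <- interior$R_d_nm < 0.999 * rmax
  if (!all(usable)) {
    warning(sprintf("%d interior domain(s) above R_d_max dropped",
                    sum(!usable)))
  }
  gme <- infer_gamma_me(interior$R_d_nm[usable], D_h, Gamma_ac, s0 = s0)
  gamma_tab <- tibble::tibble(
    domain_id = interior$domain_id[usable],
    R_d_nm = interior$R_d_nm[usable],
    Gamma_me = gme
  )
  gme_mean <- if (length(gme)) mean(gme) else surf$gamma_grid[1]
  vl <- infer_vlad(profile$profile$thickness_nm, gme_mean, surf)
  vlad_tab <- tibble::tibble(
    segment_idx = profile$profile$segment_idx,
    T_LAD_nm = vl$T_LAD, V_LAD = vl$V_LAD, regime = vl$regime
  )
  budget <- hc_budget_check(gme_mean, Gamma_ac, domains, geom,
                            hc_capacity = hc_capacity)
  structure(list(
    gamma_me = gamma_tab, vlad = vlad_tab,
    gamma_summary = if (nrow(gamma_tab) >= 10) {
      summarize_distribution(gamma_tab$Gamma_me, "gamma_me")
    },
    vlad_summary = if (nrow(vlad_tab) >= 10) {
      summarize_distribution(vlad_tab$V_LAD, "vlad",
                             lo_edge = 0.05 * max(surf$vlad_grid),
                             hi_edge = 0.95 * max(surf$vlad_grid))
    },
    budget = budget,
    closure = list(D_h = D_h, Gamma_ac = Gamma_ac, s0 = s0)
  ), class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result>\n")
  cat(sprintf("  %d interior domains -> Gamma_me (mean %.4g /s)\n",
              nrow(x$gamma_me),
              if (nrow(x$gamma_me)) mean(x$gamma_me$Gamma_me) else NA))
  cat(sprintf("  %d boundary segments -> V_LAD (mean %.4g)\n",
              nrow(x$vlad), mean(x$vlad$V_LAD)))
  cat(sprintf("  budget residual %.3f%s\n", x$budget$residual,
              if (x$budget$flagged) " (FLAGGED)" else ""))
  invisible(x)
}
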
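# Shared fixtures: everything is generated in code at test time.

# report every failure rather than aborting at testthat's default cap
options(testthat.max_fails = Inf)

# memoised expensive objects shared across test files
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small simulation configuration used for scaled-down steady states in the
# test suite (same physics as the reference control, smaller nucleus and
# shorter horizon).
test_control <- function(R = 600, t_end = 400) {
  ctrl <- calibrated_control()
  ctrl$geometry$radii <- R
  dt <- 0.6 * ctrl$geometry$h^4 / (32 * ctrl$params$M_n * ctrl$params$kappa)
  ctrl$max_steps <- as.integer(round(t_end / dt))
  ctrl$check_every <- as.integer(ceiling(ctrl$max_steps / 8))
  ctrl
}

# one steady state at given mean parameters on the test geometry
test_steady <- function(gme_mean, vlad_mean, seed = 1, R = 500,
                        t_end = 300, cvs = list(Gamma_me = 0.2,
                                                V_LAD = 0.4)) {

  ctrl <- test_control(R = R, t_end = t_end)
  geom <- memo(sprintf("geom_%d", R),
               function() do.call(make_geometry, ctrl$geometry))
  pf <- sample_parameter_fields(
    geom, means = list(Gamma_me = gme_mean, V_LAD = vlad_mean),
    cvs = cvs, xi = ctrl$xi, seed = seed)
  run_to_steady_state(geom, pf, ctrl$params, phi_n_bar = ctrl$phi_n_bar,
                      tol = ctrl$tol, max_steps = ctrl$max_steps,
                      check_every = ctrl$check_every, seed = seed)
}

# response surface shared by the surface-shape and extraction tests;
# the methylation rows span the range where the peripheral layer is not
# yet budget-saturated, so the affinity response is visible
test_surface <- function() {
  memo("surface", function() {
    ctrl <- test_control(R = 500, t_end = 300)
    suppressWarnings(build_response_surface(
      gamma_grid = ctrl$gme_mean * c(0.4, 0.7, 1),
      vlad_grid = ctrl$vlad_mean * c(0, 0.05, 0.3, 1, 3),
      sim_config = list(
        geometry = ctrl$geometry, params = ctrl$params,
        phi_n_bar = ctrl$phi_n_bar, cvs = list(Gamma_me = 0.2, V_LAD = 0.4),
        xi = ctrl$xi, tol = ctrl$tol, max_steps = ctrl$max_steps,
        check_every = ctrl$check_every),
      replicates = 1L, seed = 42L))
  })
}

# brute-force DBSCAN oracle: full distance matrix, core points by row
# sums, clusters as connected components of the core-core eps graph,
# border points attached to any reachable core's cluster
dbscan_oracle <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_pts
  lab <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    cl <- cl + 1L
    members <- i
    repeat {
      grow <- which(core & lab == 0L &
                      apply(nbr[, members, drop = FALSE], 1, any))
      grow <- setdiff(grow, members)
      if (!length(grow)) break
      lab[grow] <- cl
      members <- c(members, grow)
    }
    lab[members] <- cl
  }
  for (i in which(!core & lab == 0L)) {
    reach <- which(core & nbr[i, ])
    if (length(reach)) lab[i] <- lab[reach[1]]
  }
  lab
}

# same clustering up to label permutation?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (any((a == 0) != (b == 0))) return(FALSE)
  ok <- a > 0
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# background intensity keeping the euchromatin share of localizations at
# ~30% for a given band thickness (the percentile classifier anchors the
# sparse class at 30% of the pool)
matched_bg_intensity <- function(spec) {
  radii <- if (length(spec$radii) == 1) rep(spec$radii, 2) else spec$radii
  A <- pi * radii[1] * radii[2] / 1e6
  n_cl <- spec$n_clusters * pi * spec$cluster_radius^2 / 1e6 *
    (spec$cluster_mult - 1) * 150
  band_area <- (2 * pi * sqrt(radii[1] * radii[2]) * spec$lad_thickness -
                  pi * spec$lad_thickness^2) / 1e6
  if (spec$lad_type == "patchy") band_area <- band_area / 2
  n_band <- band_area * (spec$lad_mult - 1) * 150
  (0.3 / 0.7) * (n_cl + n_band) / A
}
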
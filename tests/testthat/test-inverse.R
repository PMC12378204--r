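# a hand-built monotone response surface for testing the inversion logic
# independently of any simulation
fake_surface <- function() {
  gamma_grid <- c(0.05, 0.1, 0.2)
  vlad_grid <- c(0, 0.01, 0.02, 0.04, 0.08)
  Tmat <- outer(c(0.6, 1, 1.5),
                c(20, 20, 60, 140, 180)) # low plateau, rise, saturation
  structure(list(
    grid = tidyr::expand_grid(Gamma_me = gamma_grid, V_LAD = vlad_grid) |>
      dplyr::mutate(T_LAD = as.vector(t(Tmat))),
    T = Tmat, dispersion = NULL,
    T_lo = Tmat[, 1], T_hi = Tmat[, ncol(Tmat)],
    gamma_grid = gamma_grid, vlad_grid = vlad_grid,
    replicates = 1, seed = 1
  ), class = "response_surface")
}

test_that("interior-radius inversion is the closed-form inverse of the size law", {
  expect_equal(infer_gamma_me(3, D_h = 6, Gamma_ac = 1, s0 = 1), 1)
  expect_equal(infer_gamma_me(0, D_h = 6, Gamma_ac = 1, s0 = 1), 0)
  # forward-inverse round trip at many rates
  s0 <- 1.4; D <- 900; gac <- 0.12
  gme <- c(0.001, 0.05, 0.2, 1, 7)
  Rd <- sqrt(3 * D * s0 * gme / (gme + gac) / gac)
  expect_equal(infer_gamma_me(Rd, D, gac, s0 = s0), gme, tolerance = 1e-9)
  # unreachable radius carries the limiting R_d_max
  rmax <- sqrt(3 * D * s0 / gac)
  expect_error(infer_gamma_me(rmax * 1.01, D, gac, s0 = s0),
               "unreachable")
  expect_error(infer_gamma_me(rmax * 1.01, D, gac, s0 = s0),
               sprintf("%.4g", rmax))
  # custom closure solved numerically matches the analytic default
  cl <- function(g) 1.4 * g / (g + 0.12)
  expect_equal(infer_gamma_me(Rd, D, gac, closure = cl), gme,
               tolerance = 1e-6)
})

test_that("closure calibration maps the control radius to the nominal rate", {
  D <- 900; gac <- 0.12; gnom <- 0.08; Rc <- 70
  s0 <- calibrate_closure(Rc, gnom, D, gac)
  expect_equal(infer_gamma_me(Rc, D, gac, s0 = s0), gnom)
})

test_that("scale consistency: doubling D_h doubles the implied squared radius ceiling", {
  s0 <- 1; gac <- 0.1
  r1 <- sqrt(3 * 500 * s0 / gac)
  r2 <- sqrt(3 * 1000 * s0 / gac)
  expect_equal(r2^2 / r1^2, 2)
  # and the round trip stays intact
  gme <- 0.07
  Rd2 <- sqrt(3 * 1000 * s0 * gme / (gme + gac) / gac)
  expect_equal(infer_gamma_me(Rd2, 1000, gac, s0 = s0), gme,
               tolerance = 1e-9)
})

test_that("affinity inversion respects the three regimes", {
  surf <- fake_surface()
  # node round trip in mid-regime
  out <- infer_vlad(60, Gamma_me = 0.1, surf)
  expect_equal(out$V_LAD, 0.02, tolerance = 1e-6)
  expect_equal(out$regime, "mid")
  # regime I: at/below the low plateau maps to zero affinity
  lo <- infer_vlad(c(0, 10, 20), Gamma_me = 0.1, surf)
  expect_true(all(lo$V_LAD == 0))
  expect_true(all(lo$regime == "low"))
  # regime III: at/above the high plateau saturates at the grid top
  hi <- infer_vlad(c(180, 500), Gamma_me = 0.1, surf)
  expect_true(all(hi$V_LAD == max(surf$vlad_grid)))
  expect_true(all(hi$regime == "saturated"))
  # row interpolation between methylation levels
  mid <- infer_vlad(0.8 * 60, Gamma_me = 0.075, surf)
  expect_equal(mid$V_LAD, 0.02, tolerance = 0.05)
  # outside the grid: nearest row with a warning
  expect_warning(infer_vlad(60, Gamma_me = 1, surf), "nearest")
})

test_that("budget check flags inconsistent extractions", {
  g <- memo("geom_500", function() make_geometry("circle", 500, h = 10))
  # half the nucleus heterochromatic with balanced rates: residual ~ 0
  dom <- tibble::tibble(domain_id = 1L, type = "LAD",
                        area_nm2 = 0.5 * g$area)
  b <- hc_budget_check(1, 1, dom, g)
  expect_equal(b$total_hc_nm2, 0.5 * g$area)
  expect_lt(b$residual, 1e-9)
  expect_false(b$flagged)
  # zero measured domains with nonzero rates: residual ~ 1, flagged
  b0 <- hc_budget_check(1, 1, dom[0, ], g)
  expect_equal(b0$residual, 1)
  expect_true(b0$flagged)
})

test_that("distribution summaries count modes and plateau masses", {
  expect_error(summarize_distribution(1:5), "at least 10")
  s0 <- summarize_distribution(rep(3, 20), "gamma_me")
  expect_equal(s0$n_modes, 1)
  expect_equal(s0$sd, 0)
  s1 <- summarize_distribution(c(rep(0, 25), rep(1, 25)), "vlad")
  expect_true(s1$bimodal)
  expect_equal(s1$lo_mass, 0.5)
  expect_equal(s1$hi_mass, 0.5)
  # 6-sigma separated mixture: two modes in nearly all seeded draws
  found <- 0
  for (k in 1:40) {
    set.seed(k)
    x <- c(rnorm(30, 0, 1), rnorm(70, 6, 1))
    if (summarize_distribution(x, "gamma_me")$n_modes == 2) {
      found <- found + 1
    }
  }
  expect_gte(found / 40, 0.95)
})

test_that("extraction bundles rates, affinities and the budget residual", {
  surf <- fake_surface()
  g <- memo("geom_500", function() make_geometry("circle", 500, h = 10))
  dom <- tibble::tibble(
    domain_id = 1:12, type = c(rep("interior", 10), "LAD", "LAD"),
    n_cells = 50L, area_nm2 = c(pi * seq(40, 58, by = 2)^2, 4e5, 3e5),
    R_d_nm = NA_real_, centroid_x_nm = 0, centroid_y_nm = 0,
    min_dist_to_boundary_nm = c(rep(300, 10), 5, 5))
  dom$R_d_nm <- sqrt(dom$area_nm2 / pi)
  prof <- structure(list(
    profile = tibble::tibble(segment_idx = 1:50, arc_start = 0,
                             arc_end = 1, length_nm = g$perimeter / 50,
                             lad_area_nm2 = 1,
                             thickness_nm = rep(c(10, 200), 25)),
    mean_T_LAD = 80, median_T_LAD = 80, total_lad_area_nm2 = 7e5,
    peripheral_fraction = 0.5, n_segments = 50), class = "lad_profile")
  s0 <- calibrate_closure(mean(dom$R_d_nm[dom$type == "interior"]),
                          0.1, 800, 0.1)
  ex <- extract_parameters(dom, prof, surf, g, D_h = 800, Gamma_ac = 0.1,
                           s0 = s0)
  expect_equal(nrow(ex$gamma_me), 10)
  expect_equal(nrow(ex$vlad), 50)
  expect_equal(mean(ex$gamma_me$Gamma_me), 0.1, tolerance = 0.15)
  expect_true(all(ex$vlad$V_LAD >= 0 &
                    ex$vlad$V_LAD <= max(surf$vlad_grid)))
  expect_true(ex$vlad_summary$bimodal)
  gl <- glance(ex)
  expect_equal(gl$n_domains, 10)
  expect_equal(gl$s0, s0)
})
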
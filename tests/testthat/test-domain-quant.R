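# helper: composition field with a prescribed heterochromatin mask
field_from_mask <- function(mask, geom, phi_h0 = 0.8) {
  phi_n <- matrix(0.35, nrow(mask), ncol(mask))
  phi_n[mask] <- 1 - phi_h0
  phi_d <- matrix(-0.1, nrow(mask), ncol(mask))
  phi_d[mask] <- phi_h0
  composition_field(phi_n, phi_d, geom, validate = FALSE)
}

disk_mask <- function(geom, cx, cy, r) {
  dims <- dim(geom$mask)
  X <- matrix(geom$x, dims[1], dims[2])
  Y <- matrix(geom$y, dims[1], dims[2], byrow = TRUE)
  ((X - cx)^2 + (Y - cy)^2 <= r^2) & geom$mask
}

annulus_mask <- function(geom, t) {
  geom$mask & geom$dist <= t & !is.na(geom$dist)
}

test_that("binarization thresholds at the well midpoint", {
  p <- model_params()
  g <- memo("geom_300", function() make_geometry("circle", 300, h = 10))
  f0 <- uniform_field(g, 0.35, 0, 1, noise = 0) # all euchromatic
  expect_equal(sum(binarize_heterochromatin(f0, params = p)), 0)
  expect_error(binarize_heterochromatin(f0, threshold = 0.9, params = p),
               "threshold")
})

test_that("connected components classify interior disks and boundary annuli", {
  g <- memo("geom_500", function() make_geometry("circle", 500, h = 10))
  m <- disk_mask(g, 0, 0, 100)
  dom <- label_domains(m, g)
  expect_equal(nrow(dom), 1)
  expect_equal(dom$type, "interior")
  expect_lt(abs(dom$R_d_nm - 100), g$h)
  expect_equal(dom$R_d_nm, sqrt(dom$area_nm2 / pi))
  dom2 <- label_domains(annulus_mask(g, 100), g)
  expect_equal(nrow(dom2), 1)
  expect_equal(dom2$type, "LAD")
  empty <- label_domains(matrix(FALSE, nrow(g$mask), ncol(g$mask)), g)
  expect_equal(nrow(empty), 0)
  # 8-connectivity: diagonal necks stay one component
  m3 <- matrix(FALSE, nrow(g$mask), ncol(g$mask))
  ctr <- which.max(g$dist)
  i <- (ctr - 1) %% nrow(m3) + 1; j <- (ctr - 1) %/% nrow(m3) + 1
  m3[i, j] <- TRUE; m3[i + 1, j + 1] <- TRUE
  expect_equal(nrow(label_domains(m3, g)), 1)
})

test_that("annulus thickness identity holds for the mask estimator", {
  g <- memo("geom_1000", function() make_geometry("circle", 1000, h = 10))
  for (t in c(50, 100, 200, 400)) {
    prof <- lad_thickness_from_mask(annulus_mask(g, t), g)
    expect_lt(abs(prof$mean_T_LAD - t), max(10, 0.05 * t))
    # every segment close to t
    expect_lt(max(abs(prof$profile$thickness_nm - t)), max(16, 0.08 * t))
  }
  # no peripheral mask: zeros
  prof0 <- lad_thickness_from_mask(disk_mask(g, 0, 0, 100), g)
  expect_true(all(prof0$profile$thickness_nm == 0))
  expect_equal(prof0$mean_T_LAD, 0)
})

test_that("segment areas sum exactly to total LAD area", {
  g <- memo("geom_500", function() make_geometry("circle", 500, h = 10))
  m <- annulus_mask(g, 150)
  prof <- lad_thickness_from_mask(m, g)
  expect_equal(sum(prof$profile$lad_area_nm2), prof$total_lad_area_nm2)
  dom <- label_domains(m, g)
  expect_lt(abs(sum(prof$profile$lad_area_nm2) -
                  sum(dom$area_nm2[dom$type == "LAD"])) /
              sum(dom$area_nm2), 1e-6)
})

test_that("half-covered boundary gives half the mean thickness", {
  g <- memo("geom_1000", function() make_geometry("circle", 1000, h = 10))
  dims <- dim(g$mask)
  X <- matrix(g$x, dims[1], dims[2])
  m <- annulus_mask(g, 200) & (X > 0)
  prof <- lad_thickness_from_mask(m, g)
  expect_lt(abs(prof$mean_T_LAD - 100) / 100, 0.12)
})

test_that("contact angles recover constructed circular caps", {
  g <- memo("geom_1000", function() make_geometry("circle", 1000, h = 10))
  dims <- dim(g$mask)
  X <- matrix(g$x, dims[1], dims[2])
  Y <- matrix(g$y, dims[1], dims[2], byrow = TRUE)
  cap_mask <- function(theta_deg, hmax = 100) {
    # circular cap meeting the (locally flat) boundary at the east pole
    # with the prescribed contact angle: centre beyond the wall for
    # spread caps, on it for a half-disk
    th <- theta_deg * pi / 180
    Rc <- hmax / (1 - cos(th))
    cx <- 1000 + Rc * cos(th)
    ((X - cx)^2 + Y^2 <= Rc^2) & g$mask
  }
  for (th in c(60, 90)) {
    m <- cap_mask(th)
    cells <- which(m)
    ang <- contact_angle(cells, g)
    expect_lt(abs(ang - th), 7)
  }
  # thin wide lamella: wetting limit
  m <- annulus_mask(g, 60) & (abs(Y) < 600) & (X > 0)
  expect_lt(contact_angle(which(m), g), 30)
  # interior domain: not applicable
  ang0 <- contact_angle(which(disk_mask(g, 0, 0, 80)), g)
  expect_true(is.na(ang0))
})

test_that("size summaries report spread and recover constructed shifts", {
  doms <- list(
    a = tibble::tibble(domain_id = 1:20, type = "interior",
                       n_cells = 10L, area_nm2 = pi * rnorm(20, 50, 5)^2,
                       R_d_nm = NA, centroid_x_nm = 0, centroid_y_nm = 0,
                       min_dist_to_boundary_nm = 500),
    b = NULL
  )
  doms$a$R_d_nm <- sqrt(doms$a$area_nm2 / pi)
  doms$b <- doms$a
  doms$b$area_nm2 <- doms$a$area_nm2 * 1.21
  doms$b$R_d_nm <- sqrt(doms$b$area_nm2 / pi)
  sd <- size_distributions(doms)
  s <- sd$summary
  shift <- percent_change(s$mean[s$condition == "a"],
                          s$mean[s$condition == "b"])
  expect_lt(abs(shift - 10), 1e-6)
  one <- size_distributions(list(
    x = doms$a[1, ]
  ))
  expect_equal(one$summary$sd, NA_real_)
  expect_equal(one$summary$mean, doms$a$R_d_nm[1])
})

test_that("mask radii are robust to threshold choice within the interface width", {
  # a relaxed droplet's measured radius moves less than 2 l_int across a
  # 0.4-0.6 phi_h0 threshold sweep
  p <- model_params(Gamma_ac = 0)
  g <- memo("geom_300", function() make_geometry("circle", 300, h = 10))
  m <- disk_mask(g, 0, 0, 120)
  f <- field_from_mask(m, g, p$phi_h0)
  ev <- evolve(f, g, NULL, p, n_steps = 2000, record_every = 2000)
  radii <- sapply(c(0.4, 0.5, 0.6) * p$phi_h0, function(thr) {
    dom <- label_domains(binarize_heterochromatin(ev$field, thr), g,
                         band = 0)
    max(dom$R_d_nm)
  })
  # bound: twice the lattice-broadened interface width (~1.5 l_int at
  # h = l_int; see the methods vignette on interface resolution)
  expect_lt(diff(range(radii)), 3 * p$l_int)
})
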
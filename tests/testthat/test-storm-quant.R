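test_that("localization tables validate their schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    x_nm = c(0, 100, 0, 100), y_nm = c(0, 0, 100, 100)), path)
  tab <- read_localizations(path)
  expect_s3_class(tab, "localization_table")
  expect_equal(nrow(tab), 4)
  expect_equal(unique(tab$nucleus_id), 1L)

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(x_nm = 1:5, z = 1:5), bad)
  expect_error(read_localizations(bad), "y_nm")

  few <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(x_nm = 1:3, y_nm = 1:3), few)
  expect_error(read_localizations(few), "at least 4")
})

test_that("duplicate coordinates are retained with sub-0.01 nm jitter", {
  tab <- tibble::tibble(x_nm = c(0, 0, 50, 80, 90),
                        y_nm = c(0, 0, 50, 10, 20))
  expect_message(out <- as_localization_table(tab, jitter_seed = 4),
                 "jittered 1 duplicate")
  expect_equal(nrow(out), 5)
  expect_false(any(duplicated(out[, c("x_nm", "y_nm")])))
  expect_lt(abs(out$x_nm[2]), 0.01)
  # determinism of the jitter
  out2 <- suppressMessages(as_localization_table(tab, jitter_seed = 4))
  expect_identical(out$x_nm, out2$x_nm)
})

test_that("voronoi areas match an independent tessellation oracle", {
  # oracle: scipy's Qhull-based tessellation (independent route)
  skip_if_not(nzchar(Sys.which("python")), "python not on PATH")
  set.seed(13)
  xy <- cbind(runif(25, 0, 1000), runif(25, 0, 1000))
  vc <- voronoi_cells(xy)
  dir <- withr::local_tempdir()
  fin <- file.path(dir, "pts.csv"); fout <- file.path(dir, "areas.csv")
  utils::write.csv(data.frame(x = xy[, 1], y = xy[, 2]), fin,
                   row.names = FALSE)
  script <- file.path(dir, "vor.py")
  writeLines(c(
    "import sys, numpy as np, pandas as pd",
    "from scipy.spatial import Voronoi",
    "d = pd.read_csv(sys.argv[1]); pts = d[['x','y']].values",
    "vor = Voronoi(pts)",
    "rows = []",
    "for i in range(len(pts)):",
    "    reg = vor.regions[vor.point_region[i]]",
    "    if -1 in reg or len(reg) == 0:",
    "        rows.append((i, -1.0)); continue",
    "    p = vor.vertices[reg]; x, y = p[:,0], p[:,1]",
    "    A = 0.5*abs(np.dot(x, np.roll(y,1)) - np.dot(y, np.roll(x,1)))",
    "    rows.append((i, A))",
    "pd.DataFrame(rows, columns=['i','area']).to_csv(sys.argv[2], index=False)"
  ), script)
  status <- system2("python", c(script, fin, fout))
  skip_if(status != 0, "scipy oracle unavailable")
  orc <- utils::read.csv(fout)
  for (i in seq_len(25)) {
    if (orc$area[i] < 0) {
      expect_true(vc$edge[i]) # unbounded cells must be edge-flagged
    } else if (!vc$edge[i]) {
      expect_lt(abs(vc$area[i] - orc$area[i]) / orc$area[i], 1e-6)
    }
  }
})

test_that("uniform grids give unit reduced density away from edges", {
  gpts <- as.matrix(expand.grid(x = seq(0, 1000, 50), y = seq(0, 1000, 50)))
  tab <- as_localization_table(tibble::tibble(x_nm = gpts[, 1],
                                              y_nm = gpts[, 2]))
  vd <- voronoi_density(tab)
  inner <- !vd$table$edge
  expect_lt(max(abs(vd$table$reduced_density[inner] - 1)), 1e-9)
  # nuclear area = sum of non-edge polygon areas by construction
  expect_equal(vd$summary$nuclear_area_nm2,
               sum(vd$table$voronoi_area_nm2[inner]))
  # tight cluster in sparse background ranks far denser
  set.seed(5)
  mix <- rbind(cbind(runif(60, 0, 2000), runif(60, 0, 2000)),
               cbind(rnorm(40, 1000, 15), rnorm(40, 1000, 15)))
  tmix <- as_localization_table(tibble::tibble(x_nm = mix[, 1],
                                               y_nm = mix[, 2]))
  vm <- voronoi_density(tmix)$table
  expect_gt(min(vm$reduced_density[61:100], na.rm = TRUE),
            max(vm$reduced_density[1:60][!vm$edge[1:60]], na.rm = TRUE) / 2)
  expect_gt(mean(vm$reduced_density[61:100], na.rm = TRUE),
            5 * mean(vm$reduced_density[1:60], na.rm = TRUE))
})

test_that("percentile classes follow the pooled 30/70 thresholds", {
  tab <- tibble::tibble(
    nucleus_id = 1L, x_nm = 0, y_nm = 0,
    voronoi_area_nm2 = 1, edge = FALSE,
    reduced_density = 1:100
  )
  out <- classify_density(tab)
  expect_equal(as.integer(table(out$density_class)[c("sparse", "dense",
                                                     "ultradense")]),
               c(30, 40, 30))
  # all equal: degenerate, everything dense, warning
  tab2 <- tab; tab2$reduced_density <- rep(2, 100)
  expect_warning(out2 <- classify_density(tab2), "degenerate")
  expect_true(all(out2$density_class == "dense"))
  # two-component mixture: all high-component points above P30
  tab3 <- tab; tab3$reduced_density <- rep(c(0.5, 5), each = 50)
  out3 <- classify_density(tab3)
  expect_true(all(out3$density_class[51:100] != "sparse"))
  expect_error(classify_density(tab[0, ]), "empty")
})

test_that("dbscan agrees with a brute-force oracle on small point sets", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(5:20, 1)
    xy <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    eps <- runif(1, 20, 80)
    lab <- dbscan_points(xy, eps, 3)
    orc <- dbscan_oracle(xy, eps, 3)
    expect_true(same_partition(lab, orc))
    expect_true(all(tabulate(lab[lab > 0]) >= 3 |
                      tabulate(lab[lab > 0]) == 0))
  }
  # two points can never form a cluster
  expect_equal(dbscan_points(cbind(c(0, 5), c(0, 0)), eps = 50, 3),
               c(0L, 0L))
  # two well-separated blobs resolve into exactly two clusters
  set.seed(22)
  blobs <- rbind(cbind(rnorm(40, 0, 25), rnorm(40, 0, 25)),
                 cbind(rnorm(40, 1000, 25), rnorm(40, 1000, 25)))
  lb <- dbscan_points(blobs, eps = 50, 3)
  expect_equal(length(setdiff(unique(lb), 0L)), 2)
  expect_error(dbscan_points(blobs, eps = -1), "eps")
})

test_that("boundary estimation recovers disks and respects concavity", {
  set.seed(31)
  r <- 1000 * sqrt(runif(3000)); th <- runif(3000, 0, 2 * pi)
  tab <- as_localization_table(tibble::tibble(
    x_nm = r * cos(th), y_nm = r * sin(th)))
  geom <- estimate_boundary(tab)
  expect_lt(abs(geom$R_nuc - 1000) / 1000, 0.03)
  d <- dist_to_boundary(cbind(1000, 0), geom$boundary)
  expect_lt(d$dist, 40) # a boundary point sits at ~zero distance
  # C-shaped cloud: concave outline smaller than the convex hull
  keep <- !(abs(th - pi) < 0.8 & r > 300)
  ctab <- as_localization_table(tibble::tibble(
    x_nm = (r * cos(th))[keep], y_nm = (r * sin(th))[keep]))
  cgeom <- estimate_boundary(ctab, alpha = 120)
  hull_pts <- cbind(ctab$x_nm, ctab$y_nm)
  hull_area <- ladscape:::polygon_area(
    hull_pts[grDevices::chull(hull_pts), ])
  expect_lt(cgeom$area, 0.93 * hull_area)
  expect_error(estimate_boundary(tab[1:8, ]), "at least 10")
})

test_that("LAD classification uses the inclusive 2.5 percent rule", {
  # constructed nucleus: boundary from a dense disk, synthetic clusters
  set.seed(41)
  r <- 1000 * sqrt(runif(4000)); th <- runif(4000, 0, 2 * pi)
  tab <- tibble::tibble(x_nm = r * cos(th), y_nm = r * sin(th))
  tab <- as_localization_table(tab)
  geom <- estimate_boundary(tab)
  R <- geom$R_nuc
  tab$voronoi_area_nm2 <- 100
  tab$edge <- FALSE
  tab$cluster_id <- NA_integer_
  # cluster 1 at the centre; cluster 2 with one point at 0.025 R
  tab$cluster_id[1:10] <- 1L
  tab$x_nm[1:10] <- rnorm(10, 0, 30); tab$y_nm[1:10] <- rnorm(10, 0, 30)
  tab$cluster_id[11:20] <- 2L
  # place point 11 exactly at the threshold distance
  tab$x_nm[11:20] <- R - 200; tab$y_nm[11:20] <- seq(-50, 40, by = 10)
  tab$x_nm[11] <- (R - 0.025 * R) # on the x-axis: distance ~ 0.025 R
  tab$y_nm[11] <- 0
  dom <- classify_lads(tab, geom)
  expect_equal(dom$type[dom$domain_id == 1], "interior")
  expect_equal(dom$type[dom$domain_id == 2], "LAD")
  # frac = 0: only boundary-touching clusters qualify
  dom0 <- classify_lads(tab, geom, frac = 0)
  expect_true(all(dom0$type == "interior"))
  expect_error(classify_lads(tab, NULL), "geometry")
})

test_that("profile of a constructed uniform band recovers its thickness", {
  # dense band rendered directly as clustered localizations on a disk of
  # background, bypassing the stochastic class/cluster stages. Polygon
  # sums overshoot a band's area by about half the background
  # nearest-neighbour spacing on each border (bleed into the sparse
  # surroundings), so the recovery tolerance is set by that spacing
  # (~26 nm here), not by the band sampling density.
  set.seed(51)
  n_band <- 12000
  rr <- sqrt(runif(n_band, (800 / 1000)^2, 1)) * 1000
  th <- runif(n_band, 0, 2 * pi)
  bg_r <- 1000 * sqrt(runif(3000)); bg_t <- runif(3000, 0, 2 * pi)
  tab <- as_localization_table(tibble::tibble(
    x_nm = c(rr * cos(th), 790 * bg_r / 1000 * cos(bg_t)),
    y_nm = c(rr * sin(th), 790 * bg_r / 1000 * sin(bg_t))))
  vd <- voronoi_density(tab)
  tab <- vd$table
  tab$cluster_id <- c(rep(1L, n_band), rep(NA_integer_, 3000))
  tab$area_cluster_id <- tab$cluster_id
  geom <- estimate_boundary(tab)
  dom <- classify_lads(tab, geom)
  prof <- lad_thickness_profile(tab, dom, geom, n_segments = 50)
  expect_lt(abs(prof$mean_T_LAD - 200), 40)
  expect_gt(mean(abs(prof$profile$thickness_nm - 200) < 60), 0.8)
  # n = 50 versus n = 100 changes the mean by < 5%
  prof100 <- lad_thickness_profile(tab, dom, geom, n_segments = 100)
  expect_lt(abs(prof100$mean_T_LAD / prof$mean_T_LAD - 1), 0.05)
  # no LADs: all zeros
  tabn <- tab
  tabn$cluster_id <- NA_integer_; tabn$area_cluster_id <- NA_integer_
  prof0 <- lad_thickness_profile(tabn, dom[0, ], geom)
  expect_true(all(prof0$profile$thickness_nm == 0))
})
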
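test_that("composition bookkeeping maps state to fractions summing to one", {
  expect_equal(composition_from_state(1, 0), list(phi_h = 0, phi_e = 0))
  expect_equal(composition_from_state(0.4, 0.2),
               list(phi_h = 0.4, phi_e = 0.2))
  expect_equal(composition_from_state(0, 1), list(phi_h = 1, phi_e = 0))
  cc <- composition_from_state(0.3, -0.1)
  expect_equal(cc$phi_h + cc$phi_e + 0.3, 1)
  expect_error(composition_from_state(0.5, 0.8), "composition domain")
  expect_error(composition_from_state(1.5, 0), "composition domain")
})

test_that("bulk double well vanishes exactly at the two chromatin phases", {
  p <- model_params()
  expect_equal(bulk_free_energy_density(0, 0, p), 0)
  expect_equal(bulk_free_energy_density(p$phi_h0, 0, p), 0)
  p2 <- model_params(c = 2, phi_h0 = 1)
  expect_equal(bulk_free_energy_density(0.5, 0, p2), 0.0625)
  # grid search at 1e-3 resolution: zeros only at the two wells
  ph <- rep(seq(0, 1, by = 1e-3), each = 51)
  pe <- rep(seq(0, 1, by = 0.02), times = 1001)
  ok <- ph + pe <= 1
  f <- bulk_free_energy_density(ph[ok], pe[ok], p)
  zero <- which(f < 1e-15)
  wells <- unique(cbind(ph[ok][zero], pe[ok][zero]))
  expect_equal(nrow(wells), 2)
  expect_true(all(wells[, 2] == 0))
  expect_setequal(wells[, 1], c(0, p$phi_h0))
  expect_true(all(f >= 0))
})

test_that("lamina adhesion decays exponentially and respects the anchors", {
  p <- model_params(V_HC = 1, V_EC = 0, d0 = 2.5, phi_h0 = 1)
  expect_equal(lamina_energy_density(1, 0, p), -0.4)
  expect_equal(lamina_energy_density(0, 0, p), 0)
  expect_lt(abs(lamina_energy_density(1, 100, p)), 1e-17)
  d <- seq(0, 50, by = 5)
  expect_true(all(diff(abs(lamina_energy_density(1, d, p))) < 0))
  expect_error(lamina_energy_density(0.5, -1, p), "geometry")
})

test_that("reaction term balances at the rate ratio", {
  expect_equal(reaction_rate(0.2, 0.2, 1, 1), 0)
  expect_equal(reaction_rate(0, 0.3, 1, 5), 0.6)
  expect_equal(reaction_rate(0.2, 0, 7, 1), -0.4)
  # zero iff phi_h / phi_e = Gamma_me / Gamma_ac
  expect_equal(reaction_rate(0.6, 0.2, 3, 1), 0)
  expect_error(reaction_rate(0.1, 0.1, -1, 1), "non-negative")
})

test_that("composite rate composes harmonically and is dominated by the slow step", {
  expect_equal(composite_rate(1, 1), 0.5)
  expect_equal(composite_rate(2, 2), 1)
  expect_equal(composite_rate(Inf, 3), 3)
  expect_error(composite_rate(0, 0), "undefined")
  set.seed(1)
  a <- runif(50, 0.01, 10); b <- runif(50, 0.01, 10)
  expect_equal(composite_rate(a, b), composite_rate(b, a))
  expect_true(all(composite_rate(a, b) <= pmin(a, b)))
  # monotone in each argument
  expect_true(all(composite_rate(a * 2, b) > composite_rate(a, b)))
})

test_that("model_params validates inputs and derives l_int and V_LAD", {
  p <- model_params(c = 8e-3, kappa = 0.8)
  expect_equal(p$l_int, 10)
  expect_equal(model_params(V_EC = 0.01, V_HC = 0.05)$V_LAD, 0.04)
  expect_error(model_params(c = -1), "strictly positive")
  expect_error(model_params(phi_h0 = 1.2), "phi_h0")
  # harmonic component rates populate Gamma_me
  p2 <- model_params(Gamma_HDAC = 0.2, Gamma_HMT = 0.2)
  expect_equal(p2$Gamma_me, 0.1)
  expect_error(model_params(Gamma_HDAC = 0.2, Gamma_HMT = 0.3,
                            Gamma_me = 0.2), "disagrees")
})

test_that("total free energy reduces to closed forms on uniform fields", {
  p <- model_params()
  g <- make_geometry("circle", 200, h = 10)
  f <- uniform_field(g, 0.4, 1, 1, noise = 0)
  comp <- composition_from_state(0.4, f$phi_d[g$mask][1])
  expected <- g$area * bulk_free_energy_density(comp$phi_h, comp$phi_e, p) +
    sum(lamina_energy_density(comp$phi_h, g$dist[g$mask], p)) * g$h^2
  expect_equal(total_free_energy(f, g, p), expected)
  # gradient energy is a sum of squares
  set.seed(2)
  dims <- dim(g$mask)
  f2 <- composition_field(
    matrix(0.4 + 0.02 * runif(prod(dims)), dims[1], dims[2]),
    matrix(0.05 * runif(prod(dims)), dims[1], dims[2]), g)
  p0 <- model_params() # V = 0: isolate bulk+gradient
  bulk_only <- sum(bulk_free_energy_density(
    phi_h(f2)[g$mask], phi_e(f2)[g$mask], p0)) * g$h^2 +
    sum(lamina_energy_density(phi_h(f2)[g$mask], g$dist[g$mask], p0)) *
      g$h^2
  expect_gte(total_free_energy(f2, g, p0), bulk_only)
  gbad <- make_geometry("circle", 150, h = 10)
  expect_error(total_free_energy(f2, gbad, p), "lattice mismatch")
})

test_that("chemical potentials are the discrete variational derivatives", {
  # central-difference perturbation oracle on random small fields
  p <- model_params(V_HC = 0.05)
  g <- make_geometry("circle", 120, h = 10)
  set.seed(42)
  dims <- dim(g$mask)
  for (rep in 1:3) {
    f <- composition_field(
      matrix(runif(prod(dims), 0.3, 0.5), dims[1], dims[2]),
      matrix(runif(prod(dims), -0.2, 0.2), dims[1], dims[2]), g)
    mu <- chemical_potentials(f, g, p)
    cells <- sample(which(g$mask), 4)
    for (cc in cells) {
      d <- 1e-6
      for (var in c("phi_n", "phi_d")) {
        fp <- f; fp[[var]][cc] <- fp[[var]][cc] + d
        fm <- f; fm[[var]][cc] <- fm[[var]][cc] - d
        num <- (total_free_energy(fp, g, p) -
                  total_free_energy(fm, g, p)) / (2 * d) / g$h^2
        ana <- if (var == "phi_n") mu$mu_n[cc] else mu$mu_d[cc]
        expect_lt(abs(num - ana) / max(abs(ana), 1e-8), 1e-4)
      }
    }
  }
  # uniform field at a well with no lamina term: mu_d of bulk vanishes
  f0 <- uniform_field(g, 1 - model_params()$phi_h0, 1, 0, noise = 0)
  mu0 <- chemical_potentials(f0, g, model_params())
  expect_lt(max(abs(mu0$mu_d[g$mask])), 1e-12)
})

test_that("relaxed 1D interface width sits between the analytic bracket", {
  # l_int = sqrt(kappa/c) is the lower scale estimate; the equal-well
  # kink along the straight two-field path (phi_e = 0, effective
  # gradient stiffness 2*kappa) gives the upper one,
  # delta = (2/phi_h0) * sqrt(2*kappa/c). The relaxed profile must land
  # between half the former and 1.5x the latter.
  p <- model_params(Gamma_ac = 0)
  g <- make_geometry("circle", 150, h = 5)
  dims <- dim(g$mask)
  x <- matrix(g$x, dims[1], dims[2])
  q <- p$phi_h0
  phi_n <- matrix(ifelse(x < 0, 1 - q, 1), dims[1], dims[2])
  phi_d <- matrix(ifelse(x < 0, q, 0), dims[1], dims[2])
  f <- composition_field(phi_n, phi_d, g)
  ev <- evolve(f, g, NULL, p, n_steps = 12000, record_every = 12000)
  mid <- ceiling(dims[2] / 2)
  prof <- phi_h(ev$field)[, mid]
  keep <- !is.na(prof)
  xx <- g$x[keep]; yy <- prof[keep]
  fit <- stats::nls(yy ~ q / 2 * (1 + tanh((x0 - xx) / w)),
                    start = list(x0 = 0, w = 10),
                    control = list(warnOnly = TRUE))
  w <- abs(coef(fit)[["w"]])
  delta_path <- (2 / q) * sqrt(2 * p$kappa / p$c)
  expect_gt(w, p$l_int / 2)
  expect_lt(w, 1.5 * delta_path)
})

test_that("nondimensional groups scale as the intrinsic units dictate", {
  p <- model_params(Gamma_ac = 0.1, V_HC = 0.04)
  nd <- nondimensionalize(p)
  expect_equal(nd$l_int, 10)
  expect_equal(nd$Gamma_ac_tilde, 0.1 * 100 / (p$M_n * p$c))
  expect_equal(nd$v_lad_tilde, 0.04 / (p$c * 10))
  expect_equal(nd$d0_tilde, 0.25)
})
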
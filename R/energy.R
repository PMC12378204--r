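#' Bulk (chromatin-chromatin) free-energy density
#'
#' The double-well landscape
#' `f = (c/2) * (phi_e^2 + phi_h^2 * (phi_h0 - phi_h)^2)` whose two zeros
#' on the physical simplex are the euchromatic well at
#' `(phi_h, phi_e) = (0, 0)` (water-rich: the loosely packed phase is
#' mostly nucleoplasm) and the heterochromatic well at `(phi_h0, 0)`
#' (water-poor, compacted chromatin).
#'
#' @param phi_h,phi_e Volume fractions.
#' @param params A [model_params()] object.
#' @return Energy density (pN/nm^2), non-negative, zero exactly at the
#'   two wells.
#' @export
bulk_free_energy_density <- function(phi_h, phi_e, params) {
  (params$c / 2) *
    (phi_e^2 + phi_h^2 * (params$phi_h0 - phi_h)^2)
}

# partial derivatives of the bulk density wrt phi_h and phi_e
bulk_deriv <- function(phi_h, phi_e, params) {
  q <- params$phi_h0
  list(
    f_h = params$c * phi_h * (q - phi_h) * (q - 2 * phi_h),
    f_e = params$c * phi_e
  )
}

#' Chromatin-lamina adhesion energy density
#'
#' `-V(phi_h)/d0 * exp(-d/d0)`: an attraction (for positive affinity)
#' confined to a layer of width `d0` against the nuclear envelope. The
#' affinity interpolation `V(phi_h)` is [lamina_affinity()].
#'
#' @param phi_h Heterochromatin fraction(s).
#' @param d Distance(s) to the lamina (nm, non-negative).
#' @param params A [model_params()] object.
#' @return Energy density (pN/nm^2); magnitude decays exponentially in `d`.
#' @export
lamina_energy_density <- function(phi_h, d, params) {
  if (any(d < 0, na.rm = TRUE)) {
    stop("geometry error: negative distance to lamina", call. = FALSE)
  }
  -lamina_affinity(phi_h, params) / params$d0 * exp(-d / params$d0)
}

#' Reaction kinetics of the order parameter
#'
#' The epigenetic interconversion term of the order-parameter equation:
#' `d(phi_d)/dt = 2 * (Gamma_me * phi_e - Gamma_ac * phi_h)`. Methylation
#' converts euchromatin into heterochromatin (raising `phi_d` by the
#' factor 2 because one converted unit moves between the two fractions),
#' acetylation the reverse. It vanishes exactly at the balance
#' `phi_h / phi_e = Gamma_me / Gamma_ac`.
#'
#' @param phi_h,phi_e Volume fractions.
#' @param Gamma_me,Gamma_ac Non-negative rates (1/s).
#' @return Rate of change of `phi_d` (1/s).
#' @export
reaction_rate <- function(phi_h, phi_e, Gamma_me, Gamma_ac) {
  if (any(Gamma_me < 0) || any(Gamma_ac < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  2 * (Gamma_me * phi_e - Gamma_ac * phi_h)
}

# Masked 5-point Laplacian with mirror (no-flux) closure: a missing
# neighbour contributes zero flux. `phi` may hold NAs outside the mask.
lap_masked <- function(phi, mask, h) {
  nx <- nrow(phi); ny <- ncol(phi)
  p <- phi
  p[!mask] <- 0
  acc <- matrix(0, nx, ny)
  # left neighbour
  nb <- rbind(p[1, ], p[-nx, ]); nbm <- rbind(mask[1, ], mask[-nx, ])
  acc <- acc + ifelse(nbm, nb, p) - p
  # right
  nb <- rbind(p[-1, ], p[nx, ]); nbm <- rbind(mask[-1, ], mask[nx, ])
  acc <- acc + ifelse(nbm, nb, p) - p
  # down
  nb <- cbind(p[, 1], p[, -ny]); nbm <- cbind(mask[, 1], mask[, -ny])
  acc <- acc + ifelse(nbm, nb, p) - p
  # up
  nb <- cbind(p[, -1], p[, ny]); nbm <- cbind(mask[, -1], mask[, ny])
  acc <- acc + ifelse(nbm, nb, p) - p
  acc <- acc / h^2
  acc[!mask] <- NA_real_
  acc
}

# Sum over lattice edges of (phi_j - phi_i)^2 within the mask (the
# discrete gradient energy integral, up to the kappa/2 factor).
edge_sq_sum <- function(phi, mask) {
  p <- phi; p[!mask] <- 0
  nx <- nrow(p); ny <- ncol(p)
  dx <- (p[-1, , drop = FALSE] - p[-nx, , drop = FALSE])^2 *
    (mask[-1, , drop = FALSE] & mask[-nx, , drop = FALSE])
  dy <- (p[, -1, drop = FALSE] - p[, -ny, drop = FALSE])^2 *
    (mask[, -1, drop = FALSE] & mask[, -ny, drop = FALSE])
  sum(dx) + sum(dy)
}

#' Total free energy of a composition field
#'
#' Discrete integral over the nucleus mask of the bulk double-well
#' density, the interfacial energy
#' `(kappa/2)(|grad phi_n|^2 + |grad phi_d|^2)` and the chromatin-lamina
#' adhesion, per unit depth. Gradients use the lattice edge sum with
#' no-flux closure, so uniform fields contribute zero interfacial energy.
#'
#' @param field A [composition_field()].
#' @param geom The matching [make_geometry()] object.
#' @param params A [model_params()] object.
#' @return Scalar energy (pN*nm per unit depth).
#' @export
total_free_energy <- function(field, geom, params) {
  if (!all(dim(field$phi_n) == dim(geom$mask)) || field$h != geom$h) {
    stop("lattice mismatch between field and geometry", call. = FALSE)
  }
  m <- geom$mask
  ph <- phi_h(field); pe <- phi_e(field)
  e_bulk <- sum(bulk_free_energy_density(ph[m], pe[m], params)) * geom$h^2
  e_lam <- sum(lamina_energy_density(ph[m], geom$dist[m], params)) * geom$h^2
  e_grad <- (params$kappa / 2) *
    (edge_sq_sum(field$phi_n, m) + edge_sq_sum(field$phi_d, m))
  e_bulk + e_grad + e_lam
}

#' Chemical potentials of the two state variables
#'
#' The discrete variational derivatives `mu_n = dF/dphi_n` and
#' `mu_d = dF/dphi_d` of [total_free_energy()] per unit volume: chain rule
#' of the bulk and lamina densities through `phi_h`, `phi_e`, plus the
#' interfacial contribution `-kappa * lap(phi)` for each variable.
#'
#' @inheritParams total_free_energy
#' @return A list of matrices `mu_n`, `mu_d` (pN/nm^2), `NA` off the mask.
#' @export
chemical_potentials <- function(field, geom, params) {
  m <- geom$mask
  ph <- phi_h(field); pe <- phi_e(field)
  dv <- bulk_deriv(ph, pe, params)
  lam <- -lamina_affinity_deriv(ph, params) / params$d0 * exp(-geom$dist / params$d0)
  # d phi_h/d phi_n = -1/2, d phi_e/d phi_n = -1/2
  # d phi_h/d phi_d = +1/2, d phi_e/d phi_d = -1/2
  mu_n <- -(dv$f_h + dv$f_e) / 2 - lam / 2 -
    params$kappa * lap_masked(field$phi_n, m, geom$h)
  mu_d <- (dv$f_h - dv$f_e) / 2 + lam / 2 -
    params$kappa * lap_masked(field$phi_d, m, geom$h)
  mu_n[!m] <- NA_real_
  mu_d[!m] <- NA_real_
  list(mu_n = mu_n, mu_d = mu_d)
}
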
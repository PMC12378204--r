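#' Model parameters for the chromatin phase-field model
#'
#' Bundles the thermodynamic and kinetic constants of the
#' heterochromatin/euchromatin phase-field model: chromatin-chromatin
#' interaction strength, interfacial penalty, well composition,
#' chromatin-lamina affinities with their exponential decay length, the
#' mobilities of nucleoplasm and epigenetic marks, the acetylation rate and
#' the effective heterochromatin diffusivity. Units are nm, s and pN
#' throughout.
#'
#' The composite methylation rate can alternatively be supplied through its
#' two enzymatic sub-steps (`Gamma_HDAC`, `Gamma_HMT`), which compose
#' harmonically (see [composite_rate()]); the same applies to the
#' acetylation pathway (`Gamma_HDM`, `Gamma_HAT`).
#'
#' @param c Chromatin-chromatin interaction strength per unit volume
#'   (pN/nm^2). Sets the depth of the two free-energy wells.
#' @param kappa Interfacial penalty (pN); the energy cost of composition
#'   gradients. Together with `c` it fixes the interface width
#'   `l_int = sqrt(kappa/c)`.
#' @param phi_h0 Heterochromatin-well composition, in (0, 1]. The
#'   heterochromatic phase sits at `phi_h = phi_h0`.
#' @param d0 Decay length of the chromatin-lamina interaction (nm),
#'   comparable to the size of the anchoring proteins.
#' @param V_EC,V_HC Lamina affinity per unit lamina area (pN*nm/nm^2) of the
#'   euchromatic (`phi_h = 0`) and heterochromatic (`phi_h = phi_h0`)
#'   phases. The preferential affinity is `V_LAD = V_HC - V_EC`.
#' @param M_n,M_d Mobilities of nucleoplasm and of epigenetic marks
#'   (nm^2 (pN/nm^2)^-1 s^-1).
#' @param Gamma_ac Acetylation rate (1/s).
#' @param Gamma_me Methylation rate (1/s); optional here because spatially
#'   varying rate fields are usually supplied at simulation time. If
#'   `Gamma_HDAC` and `Gamma_HMT` are both given, `Gamma_me` is derived
#'   harmonically and must agree if also supplied.
#' @param D_h Effective heterochromatin diffusivity (nm^2/s), used by the
#'   interior-domain size relation. Defaults to `M_d * c`, the diffusivity
#'   scale implied by the mark mobility and the well curvature.
#' @param Gamma_HDAC,Gamma_HMT,Gamma_HDM,Gamma_HAT Optional component rates
#'   (1/s) of the two-step methylation/acetylation pathways.
#' @param V_fn Optional affinity interpolation `V(phi_h)`. Defaults to the
#'   linear ramp between `V_EC` and `V_HC` over `[0, phi_h0]`. Must accept
#'   `(phi_h, params)` and be monotone between the two anchors.
#'
#' @return An object of class `model_params` (a named list) with derived
#'   fields `l_int` (interface width, nm) and `V_LAD`.
#' @examples
#' p <- model_params()
#' p$l_int   # sqrt(0.8 / 8e-3) = 10 nm
#' @export
model_params <- function(c = 8e-3, kappa = 0.8, phi_h0 = 0.8, d0 = 2.5,
                         V_EC = 0, V_HC = 0,
                         M_n = 1.25e5, M_d = 1.25e5,
                         Gamma_ac = 0.2, Gamma_me = NULL,
                         D_h = NULL,
                         Gamma_HDAC = NULL, Gamma_HMT = NULL,
                         Gamma_HDM = NULL, Gamma_HAT = NULL,
                         V_fn = NULL) {
  stopifnot(is.numeric(c), is.numeric(kappa), is.numeric(phi_h0))
  for (nm in c("c", "kappa", "d0", "M_n", "M_d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single strictly positive number", nm),
           call. = FALSE)
    }
  }
  # Gamma_ac = 0 is admitted for reaction-free (pure Cahn-Hilliard) runs
  if (!is.numeric(Gamma_ac) || length(Gamma_ac) != 1L || Gamma_ac < 0) {
    stop("`Gamma_ac` must be a single non-negative number", call. = FALSE)
  }
  if (phi_h0 <= 0 || phi_h0 > 1) {
    stop("`phi_h0` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(Gamma_HDAC) || !is.null(Gamma_HMT)) {
    if (is.null(Gamma_HDAC) || is.null(Gamma_HMT)) {
      stop("supply both `Gamma_HDAC` and `Gamma_HMT`, or neither",
           call. = FALSE)
    }
    gme <- composite_rate(Gamma_HDAC, Gamma_HMT)
    if (!is.null(Gamma_me) &&
        abs(Gamma_me - gme) > 1e-8 * max(Gamma_me, gme)) {
      stop("`Gamma_me` disagrees with the harmonic composition of ",
           "`Gamma_HDAC` and `Gamma_HMT`", call. = FALSE)
    }
    Gamma_me <- gme
  }
  if (!is.null(Gamma_HDM) || !is.null(Gamma_HAT)) {
    if (is.null(Gamma_HDM) || is.null(Gamma_HAT)) {
      stop("supply both `Gamma_HDM` and `Gamma_HAT`, or neither",
           call. = FALSE)
    }
    gac <- composite_rate(Gamma_HDM, Gamma_HAT)
    Gamma_ac <- gac
  }
  if (is.null(D_h)) D_h <- M_d * c
  if (D_h <= 0) stop("`D_h` must be strictly positive", call. = FALSE)
  p <- structure(list(
    c = c, kappa = kappa, phi_h0 = phi_h0, d0 = d0,
    V_EC = V_EC, V_HC = V_HC, M_n = M_n, M_d = M_d,
    Gamma_ac = Gamma_ac, Gamma_me = Gamma_me, D_h = D_h,
    Gamma_HDAC = Gamma_HDAC, Gamma_HMT = Gamma_HMT,
    Gamma_HDM = Gamma_HDM, Gamma_HAT = Gamma_HAT,
    V_fn = V_fn
  ), class = "model_params")
  p$l_int <- sqrt(kappa / c)
  p$V_LAD <- V_HC - V_EC
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  c = %g pN/nm^2, kappa = %g pN  (l_int = %g nm)\n",
              x$c, x$kappa, x$l_int))
  cat(sprintf("  phi_h0 = %g, d0 = %g nm\n", x$phi_h0, x$d0))
  cat(sprintf("  V_EC = %g, V_HC = %g  (V_LAD = %g pN*nm/nm^2)\n",
              x$V_EC, x$V_HC, x$V_LAD))
  cat(sprintf("  M_n = %g, M_d = %g, Gamma_ac = %g /s, D_h = %g nm^2/s\n",
              x$M_n, x$M_d, x$Gamma_ac, x$D_h))
  if (!is.null(x$Gamma_me)) cat(sprintf("  Gamma_me = %g /s\n", x$Gamma_me))
  invisible(x)
}

#' Harmonic composition of two sequential first-order rates
#'
#' A two-step conversion whose steps proceed at rates `Gamma_a` and
#' `Gamma_b` has overall rate `1/Gamma = 1/Gamma_a + 1/Gamma_b`. This is
#' how deacetylation (HDAC) and methyltransferase (HMT) activity combine
#' into the effective methylation rate, and demethylase/acetyltransferase
#' activity into the effective acetylation rate.
#'
#' @param Gamma_a,Gamma_b Non-negative rates (1/s); `Inf` is allowed and
#'   recovers the other rate (an infinitely fast step is never limiting).
#' @return The composed rate, `<= min(Gamma_a, Gamma_b)`.
#' @examples
#' composite_rate(1, 1)   # 0.5
#' composite_rate(Inf, 3) # 3
#' @export
composite_rate <- function(Gamma_a, Gamma_b) {
  if (any(Gamma_a < 0) || any(Gamma_b < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  if (any(Gamma_a == 0 & Gamma_b == 0)) {
    stop("undefined rate: both component rates are zero", call. = FALSE)
  }
  1 / (1 / Gamma_a + 1 / Gamma_b)
}

#' Chromatin-lamina affinity as a function of local composition
#'
#' Evaluates the affinity interpolation `V(phi_h)` between the euchromatic
#' anchor `V_EC = V(0)` and the heterochromatic anchor `V_HC = V(phi_h0)`.
#' The default is a linear ramp clipped to `[0, phi_h0]`; a custom
#' interpolation can be plugged in through `model_params(V_fn = )` since
#' only the two anchors are physically constrained.
#'
#' @param phi_h Heterochromatin volume fraction(s).
#' @param params A [model_params()] object.
#' @return Affinity values (pN*nm/nm^2), same shape as `phi_h`.
#' @export
lamina_affinity <- function(phi_h, params) {
  if (!is.null(params$V_fn)) return(params$V_fn(phi_h, params))
  s <- pmin(pmax(phi_h / params$phi_h0, 0), 1)
  params$V_EC + (params$V_HC - params$V_EC) * s
}

# derivative dV/dphi_h of the default (or a user) interpolation; numerical
# for user-supplied forms.
lamina_affinity_deriv <- function(phi_h, params) {
  if (is.null(params$V_fn)) {
    slope <- (params$V_HC - params$V_EC) / params$phi_h0
    ifelse(phi_h > 0 & phi_h < params$phi_h0, slope, 0)
  } else {
    eps <- 1e-6
    (params$V_fn(phi_h + eps, params) - params$V_fn(phi_h - eps, params)) /
      (2 * eps)
  }
}

#' Rescale parameters to intrinsic units
#'
#' Expresses a parameter set in the model's intrinsic scales: lengths in
#' units of the interface width `l_int = sqrt(kappa/c)`, times in units of
#' `l_int^2 / (M_n c)` (the nucleoplasm diffusion time across one
#' interface width) and energy densities in units of `c`. Useful for
#' reasoning about regimes; simulations themselves run in raw nm/s/pN
#' units.
#'
#' @param params A [model_params()] object.
#' @return A named list of dimensionless groups: `Gamma_ac_tilde`,
#'   `Gamma_me_tilde` (if present), `D_h_tilde`, `M_ratio`,
#'   `v_lad_tilde = V_LAD / (c * l_int)` and `d0_tilde`.
#' @export
nondimensionalize <- function(params) {
  tau <- params$l_int^2 / (params$M_n * params$c)
  list(
    l_int = params$l_int,
    tau = tau,
    Gamma_ac_tilde = params$Gamma_ac * tau,
    Gamma_me_tilde = if (!is.null(params$Gamma_me)) params$Gamma_me * tau,
    D_h_tilde = params$D_h * tau / params$l_int^2,
    M_ratio = params$M_d / params$M_n,
    v_lad_tilde = params$V_LAD / (params$c * params$l_int),
    d0_tilde = params$d0 / params$l_int
  )
}
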
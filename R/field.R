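#' Composition of the three nuclear constituents from the state variables
#'
#' The model tracks the nucleoplasm fraction `phi_n` and the order
#' parameter `phi_d = phi_h - phi_e`; heterochromatin and euchromatin
#' fractions follow as `phi_h = (1 - phi_n + phi_d)/2` and
#' `phi_e = (1 - phi_n - phi_d)/2`, so the three fractions sum to one by
#' construction.
#'
#' @param phi_n Nucleoplasm volume fraction(s), in `[0, 1]`.
#' @param phi_d Order parameter(s); must satisfy
#'   `|phi_d| <= 1 - phi_n + tol`.
#' @param tol Numerical tolerance for range checks (default `1e-6`).
#' @return A list with components `phi_h` and `phi_e`.
#' @examples
#' composition_from_state(0.4, 0.2) # phi_h = 0.4, phi_e = 0.2
#' @export
composition_from_state <- function(phi_n, phi_d, tol = 1e-6) {
  if (any(phi_n < -tol | phi_n > 1 + tol)) {
    stop("composition domain error: `phi_n` outside [0, 1]", call. = FALSE)
  }
  if (any(abs(phi_d) > 1 - phi_n + tol)) {
    stop("composition domain error: |phi_d| exceeds 1 - phi_n",
         call. = FALSE)
  }
  list(phi_h = (1 - phi_n + phi_d) / 2,
       phi_e = (1 - phi_n - phi_d) / 2)
}

#' Gridded composition state of one simulated nucleus
#'
#' A `composition_field` holds the two state arrays `phi_n` and `phi_d`
#' on a rectangular lattice restricted to a nucleus mask. Values outside
#' the mask are `NA` and never enter any computation.
#'
#' @param phi_n,phi_d Numeric matrices of equal dimension.
#' @param geom A nucleus geometry from [make_geometry()] (supplies the
#'   lattice spacing and mask).
#' @param tol Tolerance for the composition range checks.
#' @param validate Set `FALSE` to skip range checks (used internally on
#'   mid-evolution states where transient interfacial overshoot beyond the
#'   construction tolerance is expected).
#' @return An object of class `composition_field`.
#' @export
composition_field <- function(phi_n, phi_d, geom, tol = 1e-6,
                              validate = TRUE) {
  stopifnot(is.matrix(phi_n), is.matrix(phi_d),
            all(dim(phi_n) == dim(phi_d)))
  if (!all(dim(phi_n) == dim(geom$mask))) {
    stop("lattice mismatch between field and geometry", call. = FALSE)
  }
  m <- geom$mask
  phi_n[!m] <- NA_real_
  phi_d[!m] <- NA_real_
  if (validate) {
    comp <- composition_from_state(phi_n[m], phi_d[m], tol = tol)
    if (any(comp$phi_h < -tol | comp$phi_h > 1 + tol) ||
        any(comp$phi_e < -tol | comp$phi_e > 1 + tol)) {
      stop("composition domain error: phi_h/phi_e outside [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(phi_n = phi_n, phi_d = phi_d, h = geom$h, mask = m),
            class = "composition_field")
}

#' @rdname composition_field
#' @param field A `composition_field`.
#' @export
phi_h <- function(field) (1 - field$phi_n + field$phi_d) / 2

#' @rdname composition_field
#' @export
phi_e <- function(field) (1 - field$phi_n - field$phi_d) / 2

#' Spatially uniform composition field
#'
#' Builds the homogeneous state used to initialise simulations: nucleoplasm
#' fraction `phi_n_bar` everywhere and the chromatin split between
#' methylated and acetylated marks set by the reaction balance,
#' `phi_h / (phi_h + phi_e) = Gamma_me / (Gamma_me + Gamma_ac)`.
#'
#' @param geom Nucleus geometry.
#' @param phi_n_bar Mean nucleoplasm fraction (1 minus the chromatin
#'   content of the nucleus).
#' @param Gamma_me,Gamma_ac Reaction rates fixing the methylated fraction.
#' @param noise Amplitude of i.i.d. uniform perturbations of `phi_d`
#'   seeding the phase separation (0 for none).
#' @param seed Optional integer seed making the noise reproducible.
#' @return A `composition_field`.
#' @export
uniform_field <- function(geom, phi_n_bar, Gamma_me, Gamma_ac,
                          noise = 0.01, seed = NULL) {
  stopifnot(phi_n_bar >= 0, phi_n_bar <= 1)
  r <- Gamma_me / (Gamma_me + Gamma_ac)
  chrom <- 1 - phi_n_bar
  phi_d0 <- chrom * (2 * r - 1)
  dims <- dim(geom$mask)
  phi_n <- matrix(phi_n_bar, dims[1], dims[2])
  phi_d <- matrix(phi_d0, dims[1], dims[2])
  if (noise > 0) {
    if (!is.null(seed)) {
      old <- local_seed(seed)
      on.exit(restore_seed(old), add = TRUE)
    }
    eta <- matrix(stats::runif(prod(dims), -noise, noise), dims[1], dims[2])
    # keep |phi_d| within the simplex even at the well edges
    phi_d <- pmin(pmax(phi_d + eta, -chrom), chrom)
  }
  composition_field(phi_n, phi_d, geom)
}

# Seed bookkeeping: set a seed while remembering the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed %% 2147483647))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Stable 31-bit integer hash used to fan a global seed out to stages.
stable_hash <- function(label, seed = 0) {
  codes <- utf8ToInt(as.character(label))
  acc <- as.numeric(seed) %% 2147483647
  for (k in codes) acc <- (acc * 131 + k) %% 2147483647
  as.integer(acc)
}
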
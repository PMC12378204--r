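#' Tidy a steady-state simulation into its domain table
#'
#' @param x A `steady_state`.
#' @param ... Unused.
#' @return The domain tibble of the final field (see [label_domains()]).
#' @method tidy steady_state
#' @export
tidy.steady_state <- function(x, ...) {
  mask <- binarize_heterochromatin(x$field, params = x$params)
  label_domains(mask, x$geom)
}

#' @rdname tidy.steady_state
#' @return For `glance()`: a one-row tibble with the convergence metrics.
#' @method glance steady_state
#' @export
glance.steady_state <- function(x, ...) {
  n <- nrow(x$trace)
  tibble::tibble(
    steps = x$steps, dt = x$dt, converged = x$converged,
    mean_R_d = x$trace$mean_R_d[n], mean_T_LAD = x$trace$mean_T_LAD[n],
    energy = x$trace$energy[n]
  )
}

#' Tidy an extraction result
#'
#' @param x An `extraction_result`.
#' @param which `"gamma_me"` (per interior domain) or `"vlad"` (per
#'   boundary segment).
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy extraction_result
#' @export
tidy.extraction_result <- function(x, which = c("gamma_me", "vlad"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname tidy.extraction_result
#' @method glance extraction_result
#' @export
glance.extraction_result <- function(x, ...) {
  tibble::tibble(
    n_domains = nrow(x$gamma_me),
    n_segments = nrow(x$vlad),
    gamma_me_mean = if (nrow(x$gamma_me)) mean(x$gamma_me$Gamma_me) else
      NA_real_,
    vlad_mean = mean(x$vlad$V_LAD),
    vlad_bimodal = if (!is.null(x$vlad_summary)) x$vlad_summary$bimodal
      else NA,
    budget_residual = x$budget$residual,
    s0 = x$closure$s0, D_h = x$closure$D_h, Gamma_ac = x$closure$Gamma_ac
  )
}

#' @method tidy response_surface
#' @export
tidy.response_surface <- function(x, ...) x$grid

#' @method glance response_surface
#' @export
glance.response_surface <- function(x, ...) {
  tibble::tibble(
    n_gamma = length(x$gamma_grid), n_vlad = length(x$vlad_grid),
    T_min = min(x$T, na.rm = TRUE), T_max = max(x$T, na.rm = TRUE),
    replicates = x$replicates
  )
}

#' @method tidy lad_profile
#' @export
tidy.lad_profile <- function(x, ...) x$profile

#' @method glance lad_profile
#' @export
glance.lad_profile <- function(x, ...) {
  tibble::tibble(
    n_segments = x$n_segments, mean_T_LAD = x$mean_T_LAD,
    median_T_LAD = x$median_T_LAD,
    total_lad_area_nm2 = x$total_lad_area_nm2,
    peripheral_fraction = x$peripheral_fraction
  )
}

#' @method tidy perturbation_panel
#' @export
tidy.perturbation_panel <- function(x, ...) x$contrasts

#' @method glance perturbation_panel
#' @export
glance.perturbation_panel <- function(x, ...) {
  tibble::tibble(n_conditions = nrow(x$contrasts) - 1L,
                 n_seeds = x$n_seeds, seed = x$seed)
}
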
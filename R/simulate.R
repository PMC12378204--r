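#' Sample spatially heterogeneous parameter fields
#'
#' Draws the local methylation-rate map `Gamma_me(x)` over the nucleus and
#' the chromatin-lamina affinity `V_LAD(s)` along the boundary as Gaussian
#' random fields with prescribed pointwise mean, coefficient of variation
#' and correlation length `xi`, truncated at zero. Spatial correlation is
#' produced by Gaussian-kernel smoothing of white noise (2D over the
#' lattice for the rate map, circular 1D over arc length for the boundary
#' affinity), normalised so the pointwise standard deviation equals
#' `cv * mean`. With `cv = 0` the fields are exactly constant. The same
#' seed reproduces the fields bit-identically.
#'
#' @param geom A [make_geometry()] object.
#' @param means Named list with `Gamma_me` (1/s) and `V_LAD`
#'   (pN*nm/nm^2): the field means.
#' @param cvs Named list with coefficients of variation `Gamma_me`,
#'   `V_LAD` (defaults 0.3 each).
#' @param xi Correlation length (nm); default 200 nm, the LAD scale.
#' @param seed Integer seed.
#' @return An object of class `parameter_fields`: `Gamma_me` (matrix over
#'   the lattice, NA off-mask), `V_b` (affinity per boundary point) and
#'   the sampling metadata.
#' @export
sample_parameter_fields <- function(geom, means,
                                    cvs = list(Gamma_me = 0.3, V_LAD = 0.3),
                                    xi = 200, seed = 1L) {
  stopifnot(means$Gamma_me >= 0, means$V_LAD >= -1e-12)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  dims <- dim(geom$mask)
  if (is.null(cvs$Gamma_me)) cvs$Gamma_me <- 0
  if (is.null(cvs$V_LAD)) cvs$V_LAD <- 0
  gme <- matrix(means$Gamma_me, dims[1], dims[2])
  if (cvs$Gamma_me > 0 && means$Gamma_me > 0) {
    z <- grf2d(dims, xi / geom$h)
    gme <- means$Gamma_me * (1 + cvs$Gamma_me * z)
  }
  gme[gme < 0] <- 0
  gme[!geom$mask] <- NA_real_
  nb <- nrow(geom$boundary)
  vb <- rep(means$V_LAD, nb)
  if (cvs$V_LAD > 0 && means$V_LAD > 0) {
    spacing <- geom$perimeter / nb
    z1 <- grf1d(nb, xi / spacing)
    vb <- means$V_LAD * (1 + cvs$V_LAD * z1)
  }
  vb[vb < 0] <- 0
  structure(list(
    Gamma_me = gme, V_b = vb,
    means = means, cvs = cvs, xi = xi, seed = seed
  ), class = "parameter_fields")
}

# 2D standard Gaussian random field with Gaussian correlation kernel of
# width `sigma` lattice units (periodic FFT smoothing of white noise,
# renormalised to unit pointwise variance).
grf2d <- function(dims, sigma) {
  if (sigma < 0.5) {
    return(matrix(stats::rnorm(prod(dims)), dims[1], dims[2]))
  }
  nx <- dims[1]; ny <- dims[2]
  kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) # signed lattice offsets
  ky <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  kern <- exp(-outer(kx^2, ky^2, "+") / (2 * sigma^2))
  kern <- kern / sum(kern)
  w <- stats::rnorm(nx * ny)
  W <- matrix(w, nx, ny)
  sm <- Re(stats::fft(stats::fft(W) * stats::fft(kern), inverse = TRUE)) /
    (nx * ny)
  sm / sqrt(sum(kern^2))
}

# 1D circular analogue for boundary fields.
grf1d <- function(n, sigma) {
  if (sigma < 0.5) return(stats::rnorm(n))
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  kern <- exp(-k^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  w <- stats::rnorm(n)
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(kern), inverse = TRUE)) / n
  sm / sqrt(sum(kern^2))
}

# Build the compact-cell representation used by the C++ kernel: cell list,
# neighbour table (self-index closure off the mask) and per-cell copies of
# the heterogeneous coefficients.
compact_state <- function(field, geom, pf, params) {
  mask <- geom$mask
  nx <- nrow(mask); ny <- ncol(mask)
  id <- matrix(NA_integer_, nx, ny)
  cells <- which(mask)
  id[cells] <- seq_along(cells)
  ci <- ((cells - 1) %% nx) + 1
  cj <- ((cells - 1) %/% nx) + 1
  nbr_of <- function(di, dj) {
    ii <- pmin(pmax(ci + di, 1), nx)
    jj <- pmin(pmax(cj + dj, 1), ny)
    v <- id[cbind(ii, jj)]
    ifelse(is.na(v), seq_along(cells), v)
  }
  nbr <- cbind(nbr_of(-1, 0), nbr_of(1, 0), nbr_of(0, -1), nbr_of(0, 1)) - 1L
  gme <- if (is.null(pf)) rep(0, length(cells)) else pf$Gamma_me[cells]
  gme[is.na(gme)] <- 0
  vb <- if (is.null(pf)) rep(params$V_LAD, nrow(geom$boundary)) else pf$V_b
  vhc <- params$V_EC + vb[geom$nearest_b[cells]]
  decay <- exp(-geom$dist[cells] / params$d0) / params$d0
  list(cells = cells, nbr = nbr, gme = gme, vhc = vhc, decay = decay)
}

#' Integrate the chromatin evolution equations
#'
#' Advances the coupled conserved dynamics of `phi_n` (nucleoplasm
#' diffusion down its chemical-potential gradient) and `phi_d` (mark
#' diffusion plus epigenetic reaction kinetics) by `n_steps` explicit
#' steps of size `dt`, recording diagnostics every `record_every` steps.
#' No-flux boundaries make the total nucleoplasm exactly conserved; the
#' total order parameter is conserved when the reactions are off or
#' balanced pointwise.
#'
#' @param field Initial [composition_field()].
#' @param geom Matching geometry.
#' @param pf Optional [sample_parameter_fields()] object; `NULL` uses the
#'   homogeneous `params$Gamma_me` (0 if unset) and `params$V_LAD`.
#' @param params [model_params()].
#' @param dt Time step (s). The explicit scheme requires
#'   `dt < ~ h^4/(32 M kappa)`; the default uses 60% of that bound.
#' @param n_steps Number of steps.
#' @param record_every Diagnostic recording interval (steps).
#' @param clip_tol Simplex excursion tolerance before projection.
#' @return A list of class `evolution`: final `field`, `trace` tibble
#'   (step, time, energy, total phi_n / phi_d, cumulative clips) and the
#'   settings used.
#' @export
evolve <- function(field, geom, pf = NULL, params, dt = NULL,
                   n_steps = 1000, record_every = 250, clip_tol = 0.05) {
  if (is.null(dt)) dt <- stable_dt(geom, params)
  cs <- compact_state(field, geom, pf, params)
  if (is.null(pf) && !is.null(params$Gamma_me)) {
    cs$gme <- rep(params$Gamma_me, length(cs$cells))
  }
  pn <- field$phi_n[cs$cells]
  pd <- field$phi_d[cs$cells]
  traces <- list()
  done <- 0L; clips <- 0
  while (done < n_steps) {
    todo <- min(record_every, n_steps - done)
    out <- cpp_evolve(pn, pd, cs$nbr, cs$gme, params$Gamma_ac,
                      cs$vhc, params$V_EC, cs$decay,
                      params$phi_h0, params$c, params$kappa,
                      params$M_n, params$M_d, geom$h, dt,
                      as.integer(todo), clip_tol)
    if (isTRUE(out$diverged)) {
      stop(sprintf(
        "integration error: non-finite field at step %d (dt = %g too large?)",
        done + out$steps, dt), call. = FALSE)
    }
    pn <- out$phi_n; pd <- out$phi_d
    done <- done + out$steps
    clips <- clips + out$clips
    f <- expand_field(pn, pd, cs$cells, geom)
    traces[[length(traces) + 1]] <- tibble::tibble(
      step = done, time = done * dt,
      energy = total_free_energy(f, geom, params),
      total_phi_n = sum(pn) * geom$h^2,
      total_phi_d = sum(pd) * geom$h^2,
      clips = clips
    )
  }
  structure(list(
    field = expand_field(pn, pd, cs$cells, geom),
    trace = dplyr::bind_rows(traces),
    dt = dt, params = params, pf = pf
  ), class = "evolution")
}

expand_field <- function(pn, pd, cells, geom) {
  dims <- dim(geom$mask)
  mn <- matrix(NA_real_, dims[1], dims[2]); mn[cells] <- pn
  md <- matrix(NA_real_, dims[1], dims[2]); md[cells] <- pd
  composition_field(mn, md, geom, validate = FALSE)
}

# Explicit stability bound for the biharmonic term, with a safety margin.
stable_dt <- function(geom, params, safety = 0.6) {
  mmax <- max(params$M_n, params$M_d)
  safety * geom$h^4 / (32 * mmax * params$kappa)
}

#' Run the simulation to a morphological steady state
#'
#' Starts from the uniform reaction-balanced composition plus small seeded
#' noise and integrates until the interior domain radius and the mean LAD
#' thickness plateau: the run stops when the relative change of both
#' metrics across a window of consecutive checks stays below `tol`.
#'
#' @param geom Geometry from [make_geometry()].
#' @param pf Parameter fields from [sample_parameter_fields()] (or `NULL`
#'   for homogeneous parameters taken from `params`).
#' @param params [model_params()]; `params$Gamma_me` is used for the
#'   initial composition when `pf` is `NULL`.
#' @param phi_n_bar Mean nucleoplasm fraction of the initial state.
#' @param tol Relative plateau tolerance (default 0.02).
#' @param max_steps Step budget; reaching it raises a warning and returns
#'   the partial state.
#' @param seed Seed for the initial noise.
#' @param dt,check_every,window,min_checks Integration and plateau
#'   controls; `check_every` steps between metric evaluations, plateau
#'   judged over `window` checks after at least `min_checks`.
#' @param noise Initial noise amplitude.
#' @return A list of class `steady_state`: `field`, `geom`, `trace`
#'   (metric trace tibble), `converged`, `steps`.
#' @export
run_to_steady_state <- function(geom, pf = NULL, params,
                                phi_n_bar = 0.35, tol = 0.02,
                                max_steps = 50000L, seed = 1L,
                                dt = NULL, check_every = 2000L,
                                window = 4L, min_checks = 6L,
                                noise = 0.01) {
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  gme_mean <- if (!is.null(pf)) pf$means$Gamma_me else
    (params$Gamma_me %||% 0)
  field <- uniform_field(geom, phi_n_bar, gme_mean, params$Gamma_ac,
                         noise = noise, seed = seed)
  if (is.null(dt)) dt <- stable_dt(geom, params)
  state <- field
  metrics <- list()
  steps <- 0L
  converged <- FALSE
  ev <- NULL
  while (steps < max_steps) {
    todo <- min(check_every, max_steps - steps)
    ev <- evolve(state, geom, pf, params, dt = dt, n_steps = todo,
                 record_every = todo)
    state <- ev$field
    steps <- steps + todo
    met <- steady_metrics(state, geom, params)
    metrics[[length(metrics) + 1]] <- tibble::tibble(
      step = steps, time = steps * dt,
      mean_R_d = met$mean_R_d, mean_T_LAD = met$mean_T_LAD,
      energy = ev$trace$energy[nrow(ev$trace)]
    )
    k <- length(metrics)
    if (k >= max(min_checks, window + 1)) {
      tr <- dplyr::bind_rows(metrics)
      recent <- tr[(k - window):k, ]
      relspan <- function(v) {
        (max(v) - min(v)) / max(mean(v), geom$h)
      }
      if (relspan(recent$mean_R_d) < tol &&
          relspan(recent$mean_T_LAD) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning(sprintf("steady state not reached within %d steps", max_steps))
  }
  structure(list(
    field = state, geom = geom, params = params, pf = pf,
    trace = dplyr::bind_rows(metrics), converged = converged,
    steps = steps, dt = dt, seed = seed
  ), class = "steady_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Interior-radius and LAD-thickness summary used by the plateau criterion.
steady_metrics <- function(field, geom, params) {
  mask <- binarize_heterochromatin(field, params = params)
  dom <- label_domains(mask, geom)
  interior <- dom[dom$type == "interior", ]
  prof <- lad_thickness_from_mask(mask, geom, n_segments = 50)
  list(
    mean_R_d = if (nrow(interior)) mean(interior$R_d_nm) else 0,
    mean_T_LAD = prof$mean_T_LAD
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>\n")
  cat(sprintf("  %d steps (dt = %.3g s), converged: %s\n",
              x$steps, x$dt, x$converged))
  n <- nrow(x$trace)
  if (n) {
    cat(sprintf("  mean R_d = %.1f nm, mean T_LAD = %.1f nm\n",
                x$trace$mean_R_d[n], x$trace$mean_T_LAD[n]))
  }
  invisible(x)
}
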
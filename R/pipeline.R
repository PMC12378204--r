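#' Frozen control-condition simulation configuration
#'
#' The reference simulation the perturbation protocol compares against:
#' geometry, thermodynamic parameters and heterogeneity settings chosen
#' once so that the control steady state exhibits interior domains of
#' roughly 50 nm mean radius and a LAD layer of roughly 200 nm mean
#' thickness at desk scale. Perturbed conditions are derived from it by
#' proportionate changes of the mean methylation rate and mean
#' chromatin-lamina affinity, holding the coefficients of variation,
#' correlation length and geometry fixed.
#'
#' @param h Lattice spacing (nm).
#' @param R_nuc Nucleus radius (nm).
#' @return A list with `geometry` (arguments for [make_geometry()]),
#'   `params` ([model_params()]), `gme_mean`, `vlad_mean`, `phi_n_bar`,
#'   `cvs`, `xi` and steady-state controls.
#' @export
calibrated_control <- function(h = 10, R_nuc = 900) {
  params <- model_params(
    c = 8e-3, kappa = 0.8, phi_h0 = 0.8, d0 = 2.5,
    M_n = 1.25e5, M_d = 1.25e5, Gamma_ac = 0.08
  )
  list(
    geometry = list(shape = "circle", radii = R_nuc, h = h),
    params = params,
    gme_mean = 0.095,
    vlad_mean = 0.035,
    phi_n_bar = 0.30,
    cvs = list(Gamma_me = 0.25, V_LAD = 0.5),
    xi = 100,
    tol = 0.025, max_steps = 210000L, check_every = 30000L
  )
}

#' Simulate a panel of perturbed conditions against a control
#'
#' Runs the control configuration and each perturbed condition (a
#' proportionate scaling of the mean methylation rate and/or mean
#' chromatin-lamina affinity) to steady state over a common set of seeds,
#' and reports the percent change in the mean interior domain radius and
#' the mean LAD thickness relative to control. Heterogeneity CVs,
#' correlation length, geometry and seeds are matched across conditions,
#' so the contrasts isolate the parameter changes.
#'
#' @param conditions A named list; each element is
#'   `list(gme_scale = , vlad_scale = )`.
#' @param control A [calibrated_control()]-style list.
#' @param n_seeds Number of replicate seeds per condition (>= 3 for the
#'   stochastic contrasts).
#' @param seed Base seed fanned out to replicates.
#' @return A list of class `perturbation_panel`: `results` tibble (per
#'   condition and seed: `mean_R_d`, `mean_T_LAD`), `contrasts` tibble
#'   (per condition: seed-averaged means and `pct_R_d`, `pct_T_LAD`
#'   versus control).
#' @export
perturbation_panel <- function(conditions, control = calibrated_control(),
                               n_seeds = 3L, seed = 1L) {
  geom <- do.call(make_geometry, control$geometry)
  all_conditions <- c(list(control = list(gme_scale = 1, vlad_scale = 1)),
                      conditions)
  rows <- list()
  for (cname in names(all_conditions)) {
    cond <- all_conditions[[cname]]
    for (k in seq_len(n_seeds)) {
      s <- stable_hash(paste0("panel-", k), seed)
      pf <- sample_parameter_fields(
        geom,
        means = list(Gamma_me = control$gme_mean * cond$gme_scale,
                     V_LAD = control$vlad_mean * cond$vlad_scale),
        cvs = control$cvs, xi = control$xi, seed = s)
      ss <- run_to_steady_state(
        geom, pf, control$params, phi_n_bar = control$phi_n_bar,
        tol = control$tol, max_steps = control$max_steps,
        check_every = control$check_every, seed = s)
      n <- nrow(ss$trace)
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = cname, seed_idx = k,
        mean_R_d = ss$trace$mean_R_d[n],
        mean_T_LAD = ss$trace$mean_T_LAD[n],
        converged = ss$converged, steps = ss$steps
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  means <- results |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_R_d = mean(.data$mean_R_d),
                     mean_T_LAD = mean(.data$mean_T_LAD),
                     .groups = "drop")
  ctrl <- means[means$condition == "control", ]
  contrasts <- means |>
    dplyr::mutate(
      pct_R_d = percent_change(ctrl$mean_R_d, .data$mean_R_d),
      pct_T_LAD = percent_change(ctrl$mean_T_LAD, .data$mean_T_LAD)
    )
  structure(list(results = results, contrasts = contrasts,
                 control = control, n_seeds = n_seeds, seed = seed),
            class = "perturbation_panel")
}

#' @export
print.perturbation_panel <- function(x, ...) {
  cat("<perturbation_panel>\n")
  print(as.data.frame(x$contrasts), digits = 4)
  invisible(x)
}

# ---- configuration / dispatch --------------------------------------------

config_schema <- list(
  top = c("command", "stages", "input", "output", "seed", "log_level",
          "model", "simulate", "quantify", "extract", "synth"),
  model = c("c", "kappa", "phi_h0", "d0", "V_EC", "V_HC", "M_n", "M_d",
            "Gamma_ac", "Gamma_me", "D_h", "Gamma_HDAC", "Gamma_HMT",
            "Gamma_HDM", "Gamma_HAT"),
  simulate = c("shape", "radii", "h", "phi_n_bar", "gme_mean", "vlad_mean",
               "gme_scale", "vlad_scale", "cv_gamma", "cv_vlad", "xi",
               "tol", "max_steps", "check_every"),
  quantify = c("n_segments", "frac", "min_pts", "eps", "alpha",
               "dense_band"),
  extract = c("D_h", "Gamma_ac", "s0", "gamma_grid", "vlad_grid",
              "replicates", "surface_cache"),
  synth = c("shape", "radii", "bg_intensity", "n_clusters",
            "cluster_radius", "cluster_radius_cv", "cluster_mult",
            "lad_type", "lad_thickness", "lad_blocks", "lad_cv",
            "lad_mult", "jitter_sd")
)

config_defaults <- list(
  quantify = list(n_segments = 50, frac = 0.025, min_pts = 3,
                  dense_band = "31:100"),
  seed = 1L, log_level = "info"
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys (naming the
#' offender), checks basic types and fills documented defaults
#' (`n_segments = 50`, `frac = 0.025`, `min_pts = 3`).
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("missing required path: `", path, "`", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_schema$top)
  if (length(unknown)) {
    stop("unknown configuration key `", unknown[1], "`", call. = FALSE)
  }
  for (sec in intersect(names(cfg), names(config_schema)[-1])) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      stop("unknown configuration key `", sec, ".", bad[1], "`",
           call. = FALSE)
    }
  }
  for (nm in names(config_defaults$quantify)) {
    if (is.null(cfg$quantify[[nm]])) {
      cfg$quantify[[nm]] <- config_defaults$quantify[[nm]]
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- config_defaults$seed
  if (!is.numeric(cfg$seed)) {
    stop("type mismatch for key `seed`: expected integer", call. = FALSE)
  }
  if (is.null(cfg$log_level)) cfg$log_level <- config_defaults$log_level
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf(...))
}

write_manifest <- function(cfg, out_dir, stage_seeds, artifacts) {
  manifest <- list(
    package = "ladscape",
    version = as.character(utils::packageVersion("ladscape")),
    config_hash = stable_hash(paste(deparse(unclass(cfg)), collapse = "")),
    seed = cfg$seed,
    stage_seeds = stage_seeds,
    artifacts = artifacts,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the analysis pipeline described by a configuration
#'
#' Dispatches the requested stages (`synth`, `quantify`, `surface`,
#' `extract`, `simulate`) with each stage's outputs feeding the next;
#' partial pipelines are allowed. Every run writes a manifest (config
#' hash, fanned-out stage seeds, package version) beside its outputs. A
#' stage failure halts the run, naming the stage and listing the
#' artifacts already produced.
#'
#' @param cfg A [load_config()] object (or a list shaped like one).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stages <- cfg$stages %||% cfg$command
  if (is.null(stages)) stop("config names no stages", call. = FALSE)
  out_dir <- cfg$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- stats::setNames(
    lapply(stages, function(s) stable_hash(s, cfg$seed)), stages)
  artifacts <- list()
  env <- new.env()
  for (stage in stages) {
    res <- tryCatch(
      run_stage(stage, cfg, env, out_dir, stage_seeds[[stage]]),
      error = function(e) {
        stop(sprintf(
          "stage '%s' failed: %s [completed artifacts: %s]",
          stage, conditionMessage(e),
          if (length(artifacts)) {
            paste(unlist(artifacts), collapse = ", ")
          } else "none"), call. = FALSE)
      })
    artifacts[[stage]] <- res
  }
  write_manifest(cfg, out_dir, stage_seeds, artifacts)
  invisible(artifacts)
}

run_stage <- function(stage, cfg, env, out_dir, seed) {
  switch(stage,
    synth = {
      sy <- cfg$synth %||% list()
      sy$seed <- seed
      spec <- do.call(synthetic_spec, sy)
      gen <- generate_nucleus(spec)
      env$table <- gen$table
      env$truth <- gen$truth
      path <- file.path(out_dir, "localizations.csv")
      readr::write_csv(gen$table, path)
      tp <- file.path(out_dir, "ground_truth.json")
      jsonlite::write_json(list(
        cluster_x = gen$truth$centres[, 1],
        cluster_y = gen$truth$centres[, 2],
        cluster_radii = gen$truth$cluster_radii,
        band_mean = gen$truth$band_mean
      ), tp, digits = NA)
      c(path, tp)
    },
    quantify = {
      q <- cfg$quantify
      tab <- env$table %||% read_localizations(cfg$input)
      res <- quantify_nuclei(tab, n_segments = q$n_segments,
                             frac = q$frac, min_pts = q$min_pts,
                             eps = q$eps, alpha = q$alpha,
                             dense_band = if (identical(q$dense_band,
                                                        "31:70")) {
                               "31:70"
                             } else "31:100")
      env$quant <- res
      dp <- file.path(out_dir, "domains.csv")
      pp <- file.path(out_dir, "lad_profile.csv")
      vs <- file.path(out_dir, "voronoi_summary.json")
      readr::write_csv(res$domains, dp)
      readr::write_csv(
        dplyr::bind_rows(lapply(names(res$profiles), function(id) {
          dplyr::mutate(res$profiles[[id]]$profile, nucleus_id = id,
                        .before = 1)
        })), pp)
      jsonlite::write_json(res$summary, vs, digits = NA)
      c(dp, pp, vs)
    },
    surface = {
      ex <- cfg$extract %||% list()
      sim <- sim_config_from(cfg)
      surf <- build_response_surface(
        gamma_grid = ex$gamma_grid %||%
          (calibrated_control()$gme_mean * c(0.5, 1, 2)),
        vlad_grid = ex$vlad_grid %||%
          (calibrated_control()$vlad_mean * c(0, 0.5, 1, 2, 4)),
        sim_config = sim, replicates = ex$replicates %||% 1L,
        seed = seed, cache_dir = ex$surface_cache %||% out_dir)
      env$surface <- surf
      sp <- file.path(out_dir, "response_surface.csv")
      readr::write_csv(surf$grid, sp)
      sp
    },
    extract = {
      if (is.null(env$surface)) {
        pipeline_log(cfg, "no cached surface; building it first")
        run_stage("surface", cfg, env, out_dir,
                  stable_hash("surface", cfg$seed))
      }
      if (is.null(env$quant)) stop("run `quantify` before `extract`")
      ex <- cfg$extract %||% list()
      ctrl <- calibrated_control()
      D_h <- ex$D_h %||% ctrl$params$D_h
      gac <- ex$Gamma_ac %||% ctrl$params$Gamma_ac
      ids <- names(env$quant$profiles)
      outs <- lapply(ids, function(id) {
        dom <- env$quant$domains[env$quant$domains$nucleus_id == id, ]
        s0 <- ex$s0 %||% calibrate_closure(
          mean(dom$R_d_nm[dom$type == "interior"]), ctrl$gme_mean,
          D_h, gac)
        extract_parameters(dom, env$quant$profiles[[id]],
                           env$surface, env$quant$geoms[[id]],
                           D_h = D_h, Gamma_ac = gac, s0 = s0)
      })
      names(outs) <- ids
      env$extraction <- outs
      gp <- file.path(out_dir, "gamma_me.csv")
      vp <- file.path(out_dir, "vlad.csv")
      readr::write_csv(dplyr::bind_rows(lapply(ids, function(id) {
        dplyr::mutate(outs[[id]]$gamma_me, nucleus_id = id, .before = 1)
      })), gp)
      readr::write_csv(dplyr::bind_rows(lapply(ids, function(id) {
        dplyr::mutate(outs[[id]]$vlad, nucleus_id = id, .before = 1)
      })), vp)
      sj <- file.path(out_dir, "extraction_summary.json")
      jsonlite::write_json(lapply(outs, function(o) list(
        gamma_me_mean = mean(o$gamma_me$Gamma_me),
        vlad_mean = mean(o$vlad$V_LAD),
        vlad_bimodal = if (!is.null(o$vlad_summary)) {
          o$vlad_summary$bimodal
        } else NA,
        budget_residual = o$budget$residual
      )), sj, auto_unbox = TRUE, digits = NA)
      c(gp, vp, sj)
    },
    simulate = {
      sim <- cfg$simulate %||% list()
      ctrl <- calibrated_control()
      for (nm in c("h", "radii")) {
        if (!is.null(sim[[nm]])) ctrl$geometry[[nm]] <- sim[[nm]]
      }
      for (nm in c("phi_n_bar", "gme_mean", "vlad_mean", "xi", "tol",
                   "max_steps", "check_every")) {
        if (!is.null(sim[[nm]])) ctrl[[nm]] <- sim[[nm]]
      }
      if (!is.null(sim$cv_gamma)) ctrl$cvs$Gamma_me <- sim$cv_gamma
      if (!is.null(sim$cv_vlad)) ctrl$cvs$V_LAD <- sim$cv_vlad
      conds <- list(perturbed = list(
        gme_scale = sim$gme_scale %||% 1,
        vlad_scale = sim$vlad_scale %||% 1))
      panel <- perturbation_panel(conds, control = ctrl,
                                  n_seeds = 3L, seed = seed)
      env$panel <- panel
      rp <- file.path(out_dir, "perturbation_report.csv")
      readr::write_csv(panel$contrasts, rp)
      rp
    },
    stop(sprintf("unknown stage '%s'", stage))
  )
}

sim_config_from <- function(cfg) {
  ctrl <- calibrated_control()
  sim <- cfg$simulate %||% list()
  list(
    geometry = list(shape = sim$shape %||% ctrl$geometry$shape,
                    radii = sim$radii %||% ctrl$geometry$radii,
                    h = sim$h %||% ctrl$geometry$h),
    params = ctrl$params,
    phi_n_bar = sim$phi_n_bar %||% ctrl$phi_n_bar,
    cvs = list(Gamma_me = sim$cv_gamma %||% ctrl$cvs$Gamma_me,
               V_LAD = sim$cv_vlad %||% ctrl$cvs$V_LAD),
    xi = sim$xi %||% ctrl$xi,
    tol = sim$tol %||% ctrl$tol,
    max_steps = sim$max_steps %||% ctrl$max_steps,
    check_every = sim$check_every %||% ctrl$check_every
  )
}

#' Quantify one or many nuclei from a localization table
#'
#' Convenience wrapper chaining the full imaging pipeline per nucleus:
#' Voronoi density annotation, pooled percentile classification, DBSCAN
#' domain calling, boundary estimation, LAD classification and the
#' thickness profile.
#'
#' @param tab A `localization_table` (one or more nuclei; percentile
#'   pooling spans everything in the table).
#' @param n_segments,frac,min_pts,eps,alpha,dense_band Stage parameters
#'   (see the individual functions).
#' @return A list: `table` (fully annotated), `domains` (bound domain
#'   table), `profiles`, `geoms` (named by nucleus id), `summary`.
#' @export
quantify_nuclei <- function(tab, n_segments = 50, frac = 0.025,
                            min_pts = 3L, eps = NULL, alpha = NULL,
                            dense_band = "31:100") {
  vd <- voronoi_density(tab)
  ann <- classify_density(vd$table)
  ann <- cluster_domains(ann, eps = eps, min_pts = min_pts,
                         dense_band = dense_band)
  ids <- unique(ann$nucleus_id)
  geoms <- list(); profiles <- list(); doms <- list()
  for (id in ids) {
    sub <- ann[ann$nucleus_id == id, ]
    geom <- estimate_boundary(sub, alpha = alpha)
    dom <- classify_lads(sub, geom, frac = frac)
    prof <- lad_thickness_profile(sub, dom, geom, n_segments = n_segments)
    key <- as.character(id)
    geoms[[key]] <- geom
    profiles[[key]] <- prof
    doms[[key]] <- dom
  }
  list(table = ann, domains = dplyr::bind_rows(doms),
       profiles = profiles, geoms = geoms, summary = vd$summary)
}
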
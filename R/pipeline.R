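#' Default run configuration
#'
#' @return Nested list with `geometry`, `flow`, `tracking` and `light` blocks
#'   mirroring the config-file schema (see [run_pipeline()]).
#' @export
default_run_config <- function() {
  list(
    geometry = list(),
    flow = list(aeration_vvm = 0.02, baffled = c(TRUE, FALSE),
                turbulence_intensity = 0.10, eddy_time_s = 0.5),
    tracking = list(n_particles = 1000L, dt_s = 0.004, record_dt_s = 0.1,
                    t_max_s = 60, seed = 1L),
    light = list(I0 = 530, I_crit = 96.84,
                 calibration = data.frame(concentration_g_per_L = c(0.28, 1.7),
                                          critical_depth_cm = c(5, 1)),
                 concentration_g_per_L = 0.85)
  )
}

# FNV-1a over the canonical deparse of an object; stable fingerprint used to
# refuse comparisons across different geometries/configs.
fingerprint <- function(obj) {
  bytes <- as.integer(charToRaw(paste(deparse(obj), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  base <- default_run_config()
  for (block in names(base)) {
    if (is.null(config[[block]])) config[[block]] <- list()
    for (key in names(base[[block]])) {
      if (is.null(config[[block]][[key]])) {
        config[[block]][[key]] <- base[[block]][[key]]
      }
    }
  }
  config
}

validate_run_config <- function(config) {
  tr <- config$tracking
  if (tr$n_particles < 1) stop("tracking.n_particles must be >= 1")
  if (tr$dt_s <= 0 || tr$record_dt_s <= 0 || tr$t_max_s <= 0) {
    stop("tracking time settings must be positive")
  }
  spr <- tr$record_dt_s / tr$dt_s
  if (abs(spr - round(spr)) > 1e-9) {
    stop("tracking.record_dt_s must be an integer multiple of tracking.dt_s")
  }
  fl <- config$flow
  if (fl$aeration_vvm <= 0) stop("flow.aeration_vvm must be positive")
  if (fl$turbulence_intensity < 0 || fl$turbulence_intensity >= 1) {
    stop("flow.turbulence_intensity must be in [0, 1)")
  }
  li <- config$light
  if (any(li$concentration_g_per_L <= 0)) stop("light concentration must be positive")
  invisible(config)
}

#' Run the end-to-end flashing-light pipeline
#'
#' Executes calibrate -> track -> binarize -> population summary -> velocity
#' metrics for every requested regime, and produces a comparison table when
#' two or more regimes are run at matched aeration and concentration. The run
#' is fully reproducible from the config and master seed.
#'
#' The config is a nested list (or path to a JSON file) with blocks:
#' `geometry` (see [build_geometry()]), `flow` (`aeration_vvm`, `baffled`
#' logical scalar or vector, `turbulence_intensity`, `eddy_time_s`),
#' `tracking` (`n_particles`, `dt_s`, `record_dt_s`, `t_max_s`, `seed`) and
#' `light` (`I0`, `I_crit`, `sigma_a` or `calibration` pairs,
#' `concentration_g_per_L`).
#'
#' @param config Nested list or JSON file path; missing keys take defaults
#'   from [default_run_config()].
#' @param out_dir Optional output directory; when given, per-regime trajectory
#'   CSVs, summary JSONs and the comparison table CSV are written there.
#' @param verbose Print stage progress (default FALSE).
#' @return A list with one entry per regime (each holding `field` metrics,
#'   `summary`, `trajectories`) plus `comparison`, `config` and `config_hash`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         verbose = FALSE) {
  config <- validate_run_config(read_run_config(config))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  geom <- build_geometry(config$geometry)
  # the unbaffled regime is the same panel without the baffle solids
  gcfg0 <- config$geometry
  gcfg0$baffle_count <- 0L
  gcfg0$baffle_centers <- NULL
  geom0 <- build_geometry(gcfg0)
  # comparisons are refused across different panels, not across baffle
  # layouts of the same panel (that contrast is the point of the pipeline)
  geom_hash <- fingerprint(list(geom$x_extent, geom$z_extent, geom$depth_y,
                                geom$port_positions, geom$illuminated_face))
  cfg_hash <- fingerprint(config)

  li <- config$light
  model <- if (!is.null(li$sigma_a)) {
    light_model(li$sigma_a, li$I0, li$I_crit, geom$illuminated_face)
  } else {
    fit_attenuation(as.data.frame(li$calibration), li$I0, li$I_crit,
                    geom$illuminated_face)
  }
  C <- li$concentration_g_per_L[1]

  tr <- config$tracking
  fl <- config$flow
  runs <- list()
  for (i in seq_along(fl$baffled)) {
    baffled <- fl$baffled[i]
    label <- if (baffled) "baffled" else "unbaffled"
    geom_i <- if (baffled) geom else geom0
    say("stage calibrate_field [%s, %g vvm]", label, fl$aeration_vvm)
    field <- stage("calibrate_field",
                   calibrate_field(geom_i, fl$aeration_vvm, baffled,
                                   turbulence_intensity = fl$turbulence_intensity,
                                   eddy_time = fl$eddy_time_s))
    say("stage track [%s] n=%d", label, tr$n_particles)
    traj <- stage("track",
                  track(field, geom_i, n = tr$n_particles, dt = tr$dt_s,
                        record_dt = tr$record_dt_s, t_max = tr$t_max_s,
                        seed = tr$seed + (i - 1L)))
    say("stage ld_stats [%s]", label)
    summary <- stage("ld_stats",
                     population_summary(binarize(traj, model, geom_i, C)))
    runs[[label]] <- list(
      label = label,
      regime = label,
      aeration_vvm = fl$aeration_vvm,
      concentration_g_per_L = C,
      vz_cm_s = vertical_velocity(field, geom_i),
      vx_cm_s = horizontal_velocity(field, geom_i),
      t_av_p_s = summary$t_av_p_s,
      mean_light_fraction = summary$mean_light_fraction,
      p_bin_5_10 = bin_probability(summary, 5, 10),
      summary = summary,
      trajectories = traj,
      geometry_hash = geom_hash
    )
  }

  comparison <- if (length(runs) >= 2L) comparison_table(runs) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in runs) {
      write_trajectories(r$trajectories,
                         file.path(out_dir, paste0("trajectories_", r$label, ".csv")))
      write_ld_summary(r$summary,
                       file.path(out_dir, paste0("summary_", r$label, ".json")),
                       file.path(out_dir, paste0("per_particle_", r$label, ".csv")))
    }
    if (!is.null(comparison)) {
      utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(config_hash = cfg_hash, geometry_hash = geom_hash,
           seed = tr$seed, r_version = as.character(getRversion())),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE
    )
  }

  list(runs = runs, comparison = comparison, config = config,
       config_hash = cfg_hash, geometry_hash = geom_hash)
}

#' Comparison table across runs
#'
#' Rows are metrics (population L/D period, mean light fraction, line-averaged
#' velocities, the \[5, 10) s histogram bin probability); columns are runs,
#' plus a signed percent-change column for each non-reference run against the
#' first (reference) run. Runs with differing geometry fingerprints are
#' refused.
#'
#' @param runs List of per-run metric lists as produced by [run_pipeline()]
#'   (fields `label`, `t_av_p_s`, `mean_light_fraction`, `vz_cm_s`,
#'   `vx_cm_s`, `p_bin_5_10`, optional `geometry_hash`).
#' @return Data frame, one row per metric.
#' @export
comparison_table <- function(runs) {
  stopifnot(length(runs) >= 2L)
  hashes <- unlist(lapply(runs, function(r) r$geometry_hash %||% NA_character_))
  hashes <- hashes[!is.na(hashes)]
  if (length(unique(hashes)) > 1L) {
    stop("refusing to compare runs with different geometry fingerprints")
  }
  metrics <- c(t_av_p_s = "t_av_p_s",
               mean_light_fraction = "mean_light_fraction",
               vz_cm_s = "vz_cm_s", vx_cm_s = "vx_cm_s",
               p_bin_5_10 = "p_bin_5_10")
  out <- data.frame(metric = names(metrics))
  ref <- runs[[1]]
  for (r in runs) {
    out[[r$label]] <- vapply(metrics, function(m) r[[m]] %||% NA_real_, numeric(1))
  }
  for (r in runs[-1]) {
    out[[paste0("pct_change_", r$label)]] <- vapply(metrics, function(m) {
      a <- ref[[m]]; b <- r[[m]]
      if (is.null(a) || is.null(b) || is.na(a) || is.na(b) || a == 0) NA_real_
      else percent_change(a, b)
    }, numeric(1))
  }
  out
}
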
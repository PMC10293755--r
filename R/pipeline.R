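# Pipeline orchestration: simulate -> analyze -> report with a JSON run
# config, per-stage logging and reproducible run directories.
#
# The config file is the single source of truth; CLI flags override single
# fields and the override is recorded in the resolved copy written into the
# run directory. Each invocation gets a fresh run directory (suffix
# counter), never overwriting an earlier one. Reruns with the same config
# are bit-identical except for the timing log.

#' Default run configuration
#'
#' @param base_seed Integer base seed for all stochastic stages.
#' @return Nested list understood by [run_full()] / [validate_config()]:
#'   `cohort` (see [cohort_config()]), `tissue`, `sensor`, `solver`
#'   (`dt_s`, `t_extra_s`, `snapshot_every_s`), `threshold_c`,
#'   `calibration` (`from_fiducial` or explicit `mm_per_pixel`),
#'   `out_dir`, `write_sequences`.
#' @export
default_run_config <- function(base_seed = 1L) {
  list(
    cohort = list(n_per_group = 16L, base_seed = as.integer(base_seed),
                  jitter = list(diffusivity = 0.15, coupling = 0.15,
                                contact_area = 0.15),
                  dropout_rate = 0, macro_sd = 0.1,
                  groups = list(c(30, 2), c(30, 4), c(60, 2), c(60, 4))),
    tissue = list(size_mm = c(30, 30, 20), voxel_mm = 0.5,
                  diffusivity_mm2_s = 0.14, rho_c_J_mm3K = 3.6e-3,
                  ambient_c = 37, surface_h = 0, boundary = "insulated"),
    sensor = list(array_shape = c(60, 80), frame_rate_hz = 10, netd_c = 0.1,
                  bias_c = 0, scene_mm_per_pixel = 1.0, saturation_c = 150),
    solver = list(dt_s = 0.05, t_extra_s = 4, snapshot_every_s = 0.1),
    threshold_c = 60,
    calibration = list(from_fiducial = TRUE),
    out_dir = "runs",
    write_sequences = FALSE
  )
}

#' Read a run configuration from a JSON file
#'
#' Missing fields fall back to [default_run_config()].
#'
#' @param path JSON file.
#' @return A run-config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_value("config not found: ", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  merge_config(default_run_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(user[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

config_objects <- function(cfg) {
  tissue <- do.call(tissue_model, cfg$tissue)
  sensor <- do.call(sensor_model, cfg$sensor)
  groups <- lapply(cfg$cohort$groups, function(g) as.numeric(unlist(g)))
  cohort <- cohort_config(n_per_group = cfg$cohort$n_per_group,
                          base_seed = cfg$cohort$base_seed,
                          jitter = cfg$cohort$jitter,
                          dropout_rate = cfg$cohort$dropout_rate,
                          macro_sd = cfg$cohort$macro_sd,
                          groups = groups)
  list(tissue = tissue, sensor = sensor, cohort = cohort)
}

#' Validate a run configuration
#'
#' Checks every module's preconditions without raising; problems come back
#' as messages.
#'
#' @param cfg A run-config list (see [default_run_config()]).
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  obj <- tryCatch(config_objects(cfg), error = function(e) {
    add(conditionMessage(e)); NULL
  })
  if (is.null(obj)) return(problems)
  dt_max <- max_stable_dt(obj$tissue)
  if (cfg$solver$dt_s > dt_max + 1e-12) {
    add(sprintf("solver dt_s = %g s violates stability; maximal admissible dt is %g s",
                cfg$solver$dt_s, dt_max))
  }
  if (cfg$threshold_c <= obj$tissue$ambient_c || cfg$threshold_c >= 400) {
    add(sprintf("threshold_c = %g degC must lie in (ambient = %g, 400)",
                cfg$threshold_c, obj$tissue$ambient_c))
  }
  for (g in obj$cohort$groups) {
    app <- tryCatch(cautery_application(g[1], g[2]), error = function(e) NULL)
    if (is.null(app)) { add(sprintf("invalid group setting (%g W, %g s)", g[1], g[2])); next }
    ok <- tryCatch({ footprint_mask(obj$tissue, app); TRUE }, error = function(e) FALSE)
    if (!ok) add("cautery footprint extends outside the tissue block")
    k <- g[2] / cfg$solver$dt_s
    if (abs(k - round(k)) > 1e-6) {
      add(sprintf("application duration %g s is not a multiple of dt_s = %g s", g[2], cfg$solver$dt_s))
    }
  }
  k <- cfg$solver$snapshot_every_s / cfg$solver$dt_s
  if (abs(k - round(k)) > 1e-6) add("snapshot_every_s must be a multiple of dt_s")
  b <- cfg$sensor$scene_mm_per_pixel / cfg$tissue$voxel_mm
  if (abs(b - round(b)) > 1e-9 || b < 1) {
    add("scene_mm_per_pixel must be a positive integer multiple of voxel_mm")
  }
  if (is.null(cfg$calibration$from_fiducial) || !isTRUE(cfg$calibration$from_fiducial)) {
    ok <- tryCatch({ calibration_from_config(cfg$calibration); TRUE },
                   error = function(e) { add(conditionMessage(e)); FALSE })
  }
  problems
}

next_run_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  i <- 1L
  repeat {
    d <- file.path(out_dir, sprintf("run_%03d", i))
    if (!dir.exists(d)) { dir.create(d); return(d) }
    i <- i + 1L
  }
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full simulate -> analyze -> report pipeline
#'
#' @param cfg A run-config list (see [default_run_config()],
#'   [read_run_config()]). Validated first; a marker file
#'   `FAILED_<stage>` is left behind if a stage aborts.
#' @param out_dir Override for `cfg$out_dir`.
#' @return Path of the run directory, containing `resolved_config.json`,
#'   `manifest.csv`, per-sample spread results (`spread_results.csv`),
#'   `group_summary.csv`, `pairwise_tests.csv`, `correlations.csv`,
#'   `regressions.csv` and `log.txt` (per-stage timings; the only
#'   non-reproducible file).
#' @export
run_full <- function(cfg = default_run_config(), out_dir = NULL) {
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  problems <- validate_config(cfg)
  if (length(problems)) {
    stop_value("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  run_dir <- next_run_dir(cfg$out_dir)
  log_file <- file.path(run_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_file, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      writeLines(paste(name, conditionMessage(e)), file.path(run_dir, paste0("FAILED_", name)))
      stop_value("stage '", name, "' failed: ", conditionMessage(e))
    })
    log_line("stage %s: %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }
  jsonlite::write_json(cfg, file.path(run_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  obj <- config_objects(cfg)

  cohort <- stage("simulate", {
    co <- generate_cohort(obj$cohort, obj$tissue, obj$sensor,
                          t_extra_s = cfg$solver$t_extra_s,
                          dt_s = cfg$solver$dt_s,
                          snapshot_every_s = cfg$solver$snapshot_every_s,
                          keep_sequences = TRUE)
    write_csv(co$manifest, file.path(run_dir, "manifest.csv"))
    if (isTRUE(cfg$write_sequences)) {
      seq_dir <- file.path(run_dir, "sequences")
      dir.create(seq_dir)
      for (s in co$samples) {
        write_sequence(s$sequence, file.path(seq_dir, paste0(s$sample_id, ".tiff")),
                       format = "tiff_stack")
      }
    }
    co
  })

  results <- stage("analyze", {
    cal <- if (isTRUE(cfg$calibration$from_fiducial)) {
      compute_pixel_size(cohort$fiducial$p1, cohort$fiducial$p2,
                         cohort$fiducial$known_length_mm)
    } else {
      calibration_from_config(cfg$calibration)
    }
    rows <- lapply(cohort$samples, function(s) {
      sr <- analyze_spread(s$sequence, threshold_c = cfg$threshold_c, cal = cal)
      data.frame(sample_id = s$sample_id, power_w = s$group[["power_w"]],
                 duration_s = s$group[["duration_s"]], dropped = s$dropped,
                 threshold_c = cfg$threshold_c,
                 cumulative_area_mm2 = sr$cumulative_area_mm2,
                 peak_temperature_c = sr$peak_temperature_c,
                 macro_area_mm2 = s$macro_area_mm2,
                 truth_area_mm2 = s$truth$surface_area_mm2,
                 truth_depth_mm = s$truth$max_depth_mm)
    })
    df <- do.call(rbind, rows)
    write_csv(df, file.path(run_dir, "spread_results.csv"))
    df
  })

  stage("report", {
    df <- results
    df$spread_area_mm2 <- df$cumulative_area_mm2
    write_csv(group_summary_table(df), file.path(run_dir, "group_summary.csv"))
    write_csv(pairwise_test_table(df), file.path(run_dir, "pairwise_tests.csv"))
    write_csv(correlation_table(df), file.path(run_dir, "correlations.csv"))
    write_csv(regression_table(df), file.path(run_dir, "regressions.csv"))
    NULL
  })
  run_dir
}
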
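# Camera observation model and synthetic-cohort generation.
#
# The observation model emulates a compact uncooled microbolometer camera
# (60 x 80 array, 10 Hz, NETD < 0.1 degC, absolute accuracy within +/-2
# degC) looking straight down at the tissue top surface. Camera-to-scene
# mapping is axis-aligned block averaging: one camera pixel integrates a
# b x b block of surface voxels, where b = scene_mm_per_pixel / voxel_mm.
# At the defaults (1 mm camera pixel over 0.5 mm voxels) this yields the
# ~1 mm^2 effective pixel area of the physical setup. The full sensor array
# sees more than the 30 x 30 mm block, so cohort rendering uses the
# tissue-registered sub-window of the array; the mapped window must lie
# inside the scene.

#' Describe the thermal camera
#'
#' @param array_shape Detector window rendered, c(rows, cols); default
#'   60 x 80 (the full microbolometer array).
#' @param frame_rate_hz Acquisition rate, Hz (default 10).
#' @param netd_c Per-pixel Gaussian noise SD in degC (default 0.1, the
#'   sensor's thermal-sensitivity floor).
#' @param bias_c Systematic radiometric offset in degC (default 0;
#'   admissible within the +/-2 degC accuracy class).
#' @param scene_mm_per_pixel Width of scene covered by one camera pixel, mm
#'   (default 1.0, giving ~1 mm^2 pixels at the tissue plane).
#' @param saturation_c Upper measurement-range limit in degC (default 150,
#'   typical for a compact uncooled camera); hotter scenes read as
#'   saturated pixels. Well above the 60 degC segmentation threshold, so
#'   spread areas are unaffected.
#' @return Object of class `sensor_model`.
#' @export
sensor_model <- function(array_shape = c(60, 80), frame_rate_hz = 10,
                         netd_c = 0.1, bias_c = 0, scene_mm_per_pixel = 1.0,
                         saturation_c = 150) {
  stopifnot(length(array_shape) == 2L, all(array_shape >= 1),
            frame_rate_hz > 0, netd_c >= 0, scene_mm_per_pixel > 0,
            saturation_c > 60)
  if (abs(bias_c) > 2) stop_value("bias_c outside the +/-2 degC accuracy class")
  structure(list(array_shape = as.integer(array_shape),
                 frame_rate_hz = frame_rate_hz, netd_c = netd_c,
                 bias_c = bias_c, scene_mm_per_pixel = scene_mm_per_pixel,
                 saturation_c = saturation_c),
            class = "sensor_model")
}

# block-average a matrix by integer factor b (internal)
block_average <- function(m, b) {
  if (b == 1L) return(m)
  nr <- nrow(m) %/% b; nc <- ncol(m) %/% b
  m <- m[seq_len(nr * b), seq_len(nc * b), drop = FALSE]
  # average rows within blocks, then columns
  a <- array(m, c(b, nr, nc * b))
  m2 <- matrix(colMeans(a), nr, nc * b)
  a <- array(t(m2), c(b, nc, nr))
  t(matrix(colMeans(a), nc, nr))
}

#' Render a simulated field through the camera model
#'
#' Samples the field's stored surface snapshots at the camera frame times
#' (nearest snapshot), block-averages the surface to the camera grid, then
#' adds the systematic bias and i.i.d. Gaussian NETD noise. Output values
#' are digitized to float32 precision. Deterministic for a fixed seed.
#'
#' @param field A `temperature_field` from [simulate_field()].
#' @param sensor A [sensor_model()].
#' @param seed Integer seed for the noise realization.
#' @return A [thermogram_sequence()] at the sensor frame rate.
#' @export
render_thermograms <- function(field, sensor = sensor_model(), seed = 1L) {
  stopifnot(inherits(field, "temperature_field"), inherits(sensor, "sensor_model"))
  voxel <- field$tissue$voxel_mm
  b <- sensor$scene_mm_per_pixel / voxel
  if (abs(b - round(b)) > 1e-9 || b < 1) {
    stop_value("scene_mm_per_pixel must be a positive integer multiple of voxel_mm")
  }
  b <- as.integer(round(b))
  d <- field$tissue$dims
  need <- sensor$array_shape * b
  if (need[1] > d[1] || need[2] > d[2]) {
    stop_value(sprintf(
      "camera grid (%d x %d px at %g mm/px) is larger than the scene (%g x %g mm)",
      sensor$array_shape[1], sensor$array_shape[2], sensor$scene_mm_per_pixel,
      d[1] * voxel, d[2] * voxel))
  }
  off <- (d[1:2] - need) %/% 2L  # centered window
  snap_times <- field$times
  t_end <- snap_times[length(snap_times)]
  frame_times <- seq(0, t_end, by = 1 / sensor$frame_rate_hz)
  pick <- vapply(frame_times, function(t) which.min(abs(snap_times - t)), integer(1))

  frames <- with_seed(seed, {
    lapply(seq_along(frame_times), function(k) {
      surf <- field$snapshots[off[1] + seq_len(need[1]),
                              off[2] + seq_len(need[2]), 1, pick[k]]
      px <- block_average(surf, b) + sensor$bias_c
      if (sensor$netd_c > 0) {
        px <- px + matrix(stats::rnorm(length(px), 0, sensor$netd_c),
                          nrow(px), ncol(px))
      }
      as_float32(pmin(px, sensor$saturation_c))
    })
  })
  frames <- lapply(seq_along(frames), function(k) {
    thermogram_frame(frames[[k]], timestamp = (k - 1) / sensor$frame_rate_hz)
  })
  thermogram_sequence(frames, frame_rate_hz = sensor$frame_rate_hz,
                      meta = list(ambient_c = field$tissue$ambient_c,
                                  pressure_mmhg = 12,
                                  source = "thermospread synthetic render"))
}

#' Emulate a manual macrophotography delineation of the necrosis area
#'
#' Applies a lognormal multiplicative error with median 1 to the
#' ground-truth surface damage area, modelling operator variability in
#' manual delineation of the necrotic region.
#'
#' @param truth A `damage_truth` from [ground_truth_damage()].
#' @param seed Integer seed.
#' @param relative_sd Relative SD of the multiplicative error (default 0.1).
#' @return Emulated delineated area in mm^2 (non-negative).
#' @export
emulate_macro_area <- function(truth, seed = 1L, relative_sd = 0.1) {
  stopifnot(inherits(truth, "damage_truth"), relative_sd >= 0)
  if (relative_sd == 0) return(truth$surface_area_mm2)
  sdlog <- sqrt(log(1 + relative_sd^2))
  factor <- with_seed(seed, stats::rlnorm(1, meanlog = 0, sdlog = sdlog))
  truth$surface_area_mm2 * factor
}

#' Configure a synthetic cohort
#'
#' Defaults mirror the study design: four groups (30/60 W crossed with
#' 2/4 s) of 16 sessions each, with between-sample variability entering
#' through jittered physical parameters rather than ad-hoc area noise
#' (tissue composition, scalpel pressure/orientation and prong contact vary
#' between sessions).
#'
#' @param n_per_group Sessions per group (default 16).
#' @param base_seed Integer; per-sample seed is `base_seed XOR sample index`.
#' @param jitter Named relative SDs of lognormal (median-1) multiplicative
#'   jitter: `diffusivity`, `coupling`, `contact_area` (defaults 0.15 each).
#' @param dropout_rate Probability a session is flagged as rejected
#'   (default 0; emulates recording-workflow failures).
#' @param macro_sd Relative SD of the emulated macrophotography delineation
#'   (default 0.1).
#' @param groups List of `c(power_w, duration_s)` settings; default the full
#'   2 x 2 study grid.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 16L, base_seed = 1L,
                          jitter = list(diffusivity = 0.15, coupling = 0.15,
                                        contact_area = 0.15),
                          dropout_rate = 0, macro_sd = 0.1,
                          groups = list(c(30, 2), c(30, 4), c(60, 2), c(60, 4))) {
  stopifnot(n_per_group >= 1, dropout_rate >= 0, dropout_rate < 1,
            length(groups) >= 1)
  for (nm in c("diffusivity", "coupling", "contact_area")) {
    if (is.null(jitter[[nm]])) jitter[[nm]] <- 0.15
    stopifnot(jitter[[nm]] >= 0)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 base_seed = as.integer(base_seed), jitter = jitter,
                 dropout_rate = dropout_rate, macro_sd = macro_sd,
                 groups = groups),
            class = "cohort_config")
}

lognormal_jitter <- function(relative_sd) {
  if (relative_sd == 0) return(1)
  stats::rlnorm(1, meanlog = 0, sdlog = sqrt(log(1 + relative_sd^2)))
}

#' Generate a synthetic cohort of cautery sessions
#'
#' For each group x replicate: jitters the physical parameters, simulates
#' the temperature field, renders it through the camera, and computes the
#' ground-truth damage plus an emulated macrophotography area. The whole
#' cohort is a pure function of its configuration.
#'
#' @param cfg A [cohort_config()].
#' @param tissue Baseline [tissue_model()] (jitter applies on top).
#' @param sensor A [sensor_model()]; `array_shape` is clipped to the
#'   tissue-registered window when the full array would overhang the block.
#' @param t_extra_s Simulated cool-down after the source switches off, s
#'   (default 4).
#' @param dt_s,snapshot_every_s Solver controls (see [simulate_field()]).
#' @param keep_sequences Keep rendered sequences in the returned samples
#'   (default TRUE; set FALSE to save memory when only areas are needed).
#' @return List with `samples` (list of `cohort_sample`: `sample_id`,
#'   `group`, `seed`, `dropped`, `params`, `sequence`, `truth`,
#'   `macro_area_mm2`, `fiducial`) and `manifest` (one data.frame row per
#'   sample, every parameter recorded).
#' @export
generate_cohort <- function(cfg = cohort_config(), tissue = tissue_model(),
                            sensor = sensor_model(), t_extra_s = 4,
                            dt_s = 0.05, snapshot_every_s = 0.1,
                            keep_sequences = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(tissue, "tissue_model"),
            inherits(sensor, "sensor_model"))
  voxel <- tissue$voxel_mm
  b <- as.integer(round(sensor$scene_mm_per_pixel / voxel))
  max_px <- tissue$dims[1:2] %/% b
  window <- pmin(sensor$array_shape, max_px)
  sensor_win <- sensor
  sensor_win$array_shape <- as.integer(window)
  # fiducial the simulator "places in scene": 10 camera px of known length
  fid_px <- min(10L, window[2] - 1L)
  fiducial <- list(p1 = c(0, 0), p2 = c(0, fid_px),
                   known_length_mm = fid_px * sensor$scene_mm_per_pixel)

  samples <- list()
  rows <- list()
  idx <- 0L
  for (g in cfg$groups) {
    for (rep in seq_len(cfg$n_per_group)) {
      idx <- idx + 1L
      seed_i <- derive_seed(cfg$base_seed, idx)
      draws <- with_seed(seed_i, list(
        alpha_f = lognormal_jitter(cfg$jitter$diffusivity),
        coupling_f = lognormal_jitter(cfg$jitter$coupling),
        area_f = lognormal_jitter(cfg$jitter$contact_area),
        dropped = stats::runif(1) < cfg$dropout_rate
      ))
      tis <- tissue
      tis$diffusivity_mm2_s <- tissue$diffusivity_mm2_s * draws$alpha_f
      app <- cautery_application(
        power_w = g[1], duration_s = g[2],
        coupling_efficiency = min(1, 0.15 * draws$coupling_f),
        prong_mm = c(1, 4) * sqrt(draws$area_f))
      field <- tryCatch(
        simulate_field(tis, app, t_end_s = g[2] + t_extra_s, dt_s = dt_s,
                       snapshot_every_s = snapshot_every_s),
        error = function(e) stop_value("simulation failed for sample ", idx, ": ",
                                       conditionMessage(e)))
      truth <- ground_truth_damage(field, threshold_c = 60)
      macro <- emulate_macro_area(truth, seed = derive_seed(seed_i, 7919L),
                                  relative_sd = cfg$macro_sd)
      seq <- render_thermograms(field, sensor_win, seed = seed_i)
      cal <- compute_pixel_size(fiducial$p1, fiducial$p2, fiducial$known_length_mm)
      spread <- analyze_spread(seq, threshold_c = 60, cal = cal)
      samp <- structure(list(
        sample_id = sprintf("S%03d", idx),
        group = c(power_w = g[1], duration_s = g[2]),
        seed = seed_i, dropped = draws$dropped,
        params = list(diffusivity_mm2_s = tis$diffusivity_mm2_s,
                      coupling_efficiency = app$coupling_efficiency,
                      prong_mm = app$prong_mm),
        sequence = if (keep_sequences) seq else NULL,
        truth = truth, macro_area_mm2 = macro,
        fiducial = fiducial
      ), class = "cohort_sample")
      samples[[idx]] <- samp
      rows[[idx]] <- data.frame(
        sample_id = samp$sample_id, power_w = g[1], duration_s = g[2],
        seed = seed_i, dropped = draws$dropped,
        diffusivity_mm2_s = tis$diffusivity_mm2_s,
        coupling_efficiency = app$coupling_efficiency,
        prong_w_mm = app$prong_mm[1], prong_l_mm = app$prong_mm[2],
        truth_area_mm2 = truth$surface_area_mm2,
        truth_depth_mm = truth$max_depth_mm,
        macro_area_mm2 = macro,
        spread_area_mm2 = spread$cumulative_area_mm2,
        peak_c = spread$peak_temperature_c,
        stringsAsFactors = FALSE
      )
      rm(field)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$mm_per_pixel <- fiducial$known_length_mm /
    sqrt(sum((fiducial$p1 - fiducial$p2)^2))
  list(samples = samples, manifest = manifest, fiducial = fiducial)
}
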
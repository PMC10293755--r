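# Finite-difference bioheat simulation of an ex-vivo tissue block under a
# bipolar-cautery source.
#
# Model: 3-D heat equation dT/dt = alpha lap(T) + q/(rho c) on a regular
# voxel grid, explicit forward Euler, with a uniform volumetric source
# inside the two forceps-prong footprints while the source is on. The
# samples are inanimate, so there is no perfusion term (the Pennes perfusion
# sink is identically zero; adding it back is an extension hook). Phase
# change and temperature-dependent properties are omitted; temperatures may
# exceed 100 degC and are reported as-is.
#
# Geometry: z = 0 is the top (heated and observed) surface; x and y span the
# surface. Voxel centers sit at (i + 0.5) * voxel_mm, i 0-based.

#' Describe a tissue block
#'
#' @param size_mm Physical block size (x, y, z) in mm. Default 30 x 30 x 20
#'   (a ~3 x 3 x 2 cm ex-vivo sample).
#' @param voxel_mm Isotropic voxel edge in mm (default 0.5). Each dimension
#'   must resolve to at least 4 voxels.
#' @param diffusivity_mm2_s Thermal diffusivity alpha in mm^2/s (default
#'   0.14, literature muscle value).
#' @param rho_c_J_mm3K Volumetric heat capacity rho*c in J/(mm^3 K)
#'   (default 3.6e-3, literature muscle value).
#' @param ambient_c Ambient / initial temperature in degC (default 37, the
#'   controlled chamber temperature).
#' @param surface_h Convective coefficient on the top face in W/(mm^2 K);
#'   default 0 (still CO2 atmosphere at tissue temperature).
#' @param boundary `"insulated"` (zero-flux, default) or `"fixed_ambient"`.
#' @return Object of class `tissue_model`.
#' @export
tissue_model <- function(size_mm = c(30, 30, 20), voxel_mm = 0.5,
                         diffusivity_mm2_s = 0.14, rho_c_J_mm3K = 3.6e-3,
                         ambient_c = 37, surface_h = 0,
                         boundary = c("insulated", "fixed_ambient")) {
  boundary <- match.arg(boundary)
  stopifnot(length(size_mm) == 3L, all(size_mm > 0), voxel_mm > 0,
            diffusivity_mm2_s > 0, rho_c_J_mm3K > 0, surface_h >= 0)
  dims <- as.integer(round(size_mm / voxel_mm))
  if (any(dims < 4L)) stop_value("each dimension must be at least 4 voxels")
  structure(list(dims = dims, voxel_mm = voxel_mm,
                 diffusivity_mm2_s = diffusivity_mm2_s,
                 rho_c_J_mm3K = rho_c_J_mm3K, ambient_c = ambient_c,
                 surface_h = surface_h, boundary = boundary),
            class = "tissue_model")
}

#' Describe a bipolar cautery application
#'
#' The source is modelled as uniform volumetric heating inside two
#' rectangular prong footprints (the forceps jaws) extending
#' `deposition_depth_mm` into the tissue, centered on the top surface with
#' prongs separated along x and elongated along y.
#'
#' @param power_w Generator power setting in W (study grid: 30 or 60).
#' @param duration_s Application time in s (study grid: 2 or 4).
#' @param coupling_efficiency Fraction of electrical power deposited as heat
#'   (default 0.15; a tuning default, not a measured value).
#' @param prong_mm Contact footprint of one prong, c(width_x, length_y) in
#'   mm (default 1 x 4: the gripping portion of a Maryland-forceps jaw tip).
#' @param gap_mm Gap between the prongs in mm (default 2).
#' @param deposition_depth_mm Depth over which power is distributed
#'   (default 1).
#' @return Object of class `cautery_application`.
#' @export
cautery_application <- function(power_w, duration_s, coupling_efficiency = 0.15,
                                prong_mm = c(1, 4), gap_mm = 2,
                                deposition_depth_mm = 1) {
  stopifnot(power_w >= 0, duration_s > 0, length(prong_mm) == 2L,
            all(prong_mm > 0), gap_mm >= 0, deposition_depth_mm > 0)
  if (coupling_efficiency <= 0 || coupling_efficiency > 1) {
    stop_value("coupling_efficiency must be in (0, 1]")
  }
  structure(list(power_w = power_w, duration_s = duration_s,
                 coupling_efficiency = coupling_efficiency,
                 prong_mm = prong_mm, gap_mm = gap_mm,
                 deposition_depth_mm = deposition_depth_mm),
            class = "cautery_application")
}

#' Largest stable time step for the explicit scheme
#'
#' @param tissue A [tissue_model()].
#' @return `voxel_mm^2 / (6 * alpha)` in seconds; explicit forward Euler on
#'   the 7-point stencil is stable iff `dt_s` does not exceed this.
#' @export
max_stable_dt <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_model"))
  tissue$voxel_mm^2 / (6 * tissue$diffusivity_mm2_s)
}

# logical voxel mask of the two prong footprints (internal)
footprint_mask <- function(tissue, app) {
  v <- tissue$voxel_mm
  d <- tissue$dims
  cx <- d[1] * v / 2; cy <- d[2] * v / 2
  xc <- (seq_len(d[1]) - 0.5) * v
  yc <- (seq_len(d[2]) - 0.5) * v
  zc <- (seq_len(d[3]) - 0.5) * v
  half_gap <- app$gap_mm / 2
  in_x <- (xc >= cx - half_gap - app$prong_mm[1] & xc <= cx - half_gap) |
          (xc >= cx + half_gap & xc <= cx + half_gap + app$prong_mm[1])
  in_y <- yc >= cy - app$prong_mm[2] / 2 & yc <= cy + app$prong_mm[2] / 2
  in_z <- zc <= app$deposition_depth_mm
  x_lo <- cx - half_gap - app$prong_mm[1]
  x_hi <- cx + half_gap + app$prong_mm[1]
  if (x_lo < 0 || x_hi > d[1] * v || app$prong_mm[2] > d[2] * v ||
      app$deposition_depth_mm > d[3] * v) {
    stop_value("cautery footprint extends outside the tissue block")
  }
  xy <- outer(in_x, in_y, `&`)
  mask <- array(FALSE, d)
  for (k in which(in_z)) mask[, , k] <- xy
  mask
}

#' Simulate the temperature field of a cautery application
#'
#' Explicit forward-Euler solution of the heat equation with a uniform
#' volumetric source inside the prong footprints while `t <= duration_s`.
#'
#' @param tissue A [tissue_model()].
#' @param app A [cautery_application()].
#' @param t_end_s Total simulated time, s (must cover `app$duration_s`).
#' @param dt_s Solver step, s. Must satisfy the stability bound
#'   [max_stable_dt()] and divide both `snapshot_every_s` and
#'   `app$duration_s`.
#' @param snapshot_every_s Interval between stored snapshots, s.
#' @return Object of class `temperature_field`: `snapshots` (4-D array
#'   nx x ny x nz x n_snapshots, degC), `times` (s), `dt_s`, `tissue`,
#'   `app`.
#' @export
simulate_field <- function(tissue, app, t_end_s, dt_s = 0.05,
                           snapshot_every_s = 0.1) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(app, "cautery_application"))
  dt_max <- max_stable_dt(tissue)
  if (dt_s > dt_max + 1e-12) {
    stop_value(sprintf(
      "unstable explicit step: dt_s = %g s exceeds the maximal admissible dt of %g s (voxel^2 / (6 alpha))",
      dt_s, dt_max))
  }
  if (t_end_s < app$duration_s) stop_value("t_end_s must cover the application duration")
  for (nm in c("snapshot_every_s", "duration")) {
    val <- if (nm == "duration") app$duration_s else snapshot_every_s
    k <- val / dt_s
    if (abs(k - round(k)) > 1e-6) {
      stop_value(nm, " must be an integer multiple of dt_s")
    }
  }
  n_steps <- as.integer(round(t_end_s / dt_s))
  src_steps <- as.integer(round(app$duration_s / dt_s))
  snap_every <- as.integer(round(snapshot_every_s / dt_s))

  heat_rate <- array(0, tissue$dims)
  if (app$power_w > 0) {
    fp <- footprint_mask(tissue, app)
    vol_mm3 <- sum(fp) * tissue$voxel_mm^3
    heat_rate[fp] <- app$power_w * app$coupling_efficiency /
      (vol_mm3 * tissue$rho_c_J_mm3K)  # K/s
  }
  T0 <- array(tissue$ambient_c, tissue$dims)
  sol <- fd_heat_solve_cpp(T0, tissue$diffusivity_mm2_s, tissue$voxel_mm,
                           dt_s, n_steps, heat_rate, src_steps,
                           tissue$surface_h, tissue$ambient_c,
                           tissue$rho_c_J_mm3K, snap_every,
                           tissue$boundary == "fixed_ambient")
  structure(list(snapshots = sol$snapshots, times = sol$times, dt_s = dt_s,
                 tissue = tissue, app = app),
            class = "temperature_field")
}

#' Low-level access to the finite-difference stepper
#'
#' Runs the solver from an arbitrary initial field with an arbitrary
#' volumetric heating-rate array. Used for physics verification (energy
#' conservation, analytic diffusion checks); [simulate_field()] is the
#' user-facing entry point.
#'
#' @param tissue A [tissue_model()] (provides alpha, voxel, boundary,
#'   convection).
#' @param T0 Initial temperature array matching `tissue$dims`.
#' @param heat_rate_k_s Volumetric heating rate array, K/s (default all 0).
#' @param n_steps Number of Euler steps.
#' @param dt_s Step size, s (stability-checked).
#' @param source_steps Steps during which the source is applied.
#' @param snap_every Store every k-th step (default: only first and last
#'   reachable multiples).
#' @return A `temperature_field` (with `app = NULL`).
#' @export
evolve_field <- function(tissue, T0, heat_rate_k_s = NULL, n_steps, dt_s,
                         source_steps = 0L, snap_every = n_steps) {
  stopifnot(inherits(tissue, "tissue_model"))
  if (!identical(dim(T0), as.integer(tissue$dims))) {
    stop_value("T0 must match tissue$dims")
  }
  dt_max <- max_stable_dt(tissue)
  if (dt_s > dt_max + 1e-12) {
    stop_value(sprintf("dt_s exceeds the maximal admissible dt of %g s", dt_max))
  }
  if (is.null(heat_rate_k_s)) heat_rate_k_s <- array(0, tissue$dims)
  sol <- fd_heat_solve_cpp(T0, tissue$diffusivity_mm2_s, tissue$voxel_mm,
                           dt_s, as.integer(n_steps), heat_rate_k_s,
                           as.integer(source_steps), tissue$surface_h,
                           tissue$ambient_c, tissue$rho_c_J_mm3K,
                           as.integer(snap_every),
                           tissue$boundary == "fixed_ambient")
  structure(list(snapshots = sol$snapshots, times = sol$times, dt_s = dt_s,
                 tissue = tissue, app = NULL),
            class = "temperature_field")
}

#' Top-surface temperature maps of a simulated field
#'
#' @param field A `temperature_field`.
#' @return List of nx x ny matrices (degC), one per stored snapshot: the
#'   z = 0 (top) layer that a surface-mounted thermal camera can observe.
#' @export
surface_slice <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  n <- dim(field$snapshots)[4]
  lapply(seq_len(n), function(k) field$snapshots[, , 1, k])
}

#' Ground-truth thermal damage of a simulated field
#'
#' @param field A `temperature_field`.
#' @param threshold_c Damage threshold in degC (default 60; strict ">").
#' @return List of class `damage_truth`: `surface_area_mm2` (top-layer
#'   voxels whose peak-over-time temperature exceeds the threshold, times
#'   voxel area) and `max_depth_mm` (depth of the deepest ever-exceeding
#'   voxel center, `(z + 0.5) * voxel_mm` with 0-based layer index z; 0 when
#'   no voxel exceeds).
#' @export
ground_truth_damage <- function(field, threshold_c = 60) {
  stopifnot(inherits(field, "temperature_field"))
  n_snap <- dim(field$snapshots)[4]
  peak <- field$snapshots[, , , 1]
  for (k in seq_len(n_snap)[-1]) peak <- pmax(peak, field$snapshots[, , , k])
  voxel <- field$tissue$voxel_mm
  exceed <- peak > threshold_c
  surface_area <- sum(exceed[, , 1]) * voxel^2
  z_any <- which(apply(exceed, 3, any))
  max_depth <- if (length(z_any)) (max(z_any) - 0.5) * voxel else 0
  structure(list(surface_area_mm2 = surface_area, max_depth_mm = max_depth,
                 threshold_c = threshold_c),
            class = "damage_truth")
}
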
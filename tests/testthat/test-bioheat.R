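# gaussian bump initial field centered in a cube (shared by several tests)
gaussian_field <- function(tissue, sigma_mm, amplitude = 30) {
  d <- tissue$dims; v <- tissue$voxel_mm
  ctr <- d * v / 2
  xc <- (seq_len(d[1]) - 0.5) * v - ctr[1]
  yc <- (seq_len(d[2]) - 0.5) * v - ctr[2]
  zc <- (seq_len(d[3]) - 0.5) * v - ctr[3]
  r2 <- outer(outer(xc^2, yc^2, `+`), zc^2, `+`)
  tissue$ambient_c + amplitude * exp(-r2 / (2 * sigma_mm^2))
}

axis_variance <- function(T, tissue, axis) {
  w <- T - tissue$ambient_c
  coord <- (seq_len(dim(T)[axis]) - 0.5) * tissue$voxel_mm
  wa <- apply(w, axis, sum)
  mu <- sum(wa * coord) / sum(wa)
  sum(wa * (coord - mu)^2) / sum(wa)
}

test_that("zero power leaves the field at ambient", {
  tis <- tiny_tissue()
  f <- simulate_field(tis, cautery_application(0, 1), t_end_s = 2,
                      dt_s = 0.1, snapshot_every_s = 0.5)
  expect_true(all(f$snapshots == 37))
  expect_equal(f$times, c(0, 0.5, 1, 1.5, 2))
})

test_that("insulated no-source evolution conserves excess heat", {
  tis <- tissue_model(size_mm = c(10, 10, 10), voxel_mm = 0.5)
  T0 <- gaussian_field(tis, sigma_mm = 1.5)
  f <- evolve_field(tis, T0, n_steps = 100, dt_s = 0.05, snap_every = 100)
  s0 <- sum(T0 - 37)
  s1 <- sum(f$snapshots[, , , 2] - 37)
  expect_lt(abs(s1 - s0) / s0, 1e-6)
})

test_that("maximum principle holds without a source", {
  tis <- tissue_model(size_mm = c(10, 10, 10), voxel_mm = 0.5)
  T0 <- gaussian_field(tis, sigma_mm = 1.5)
  f <- evolve_field(tis, T0, n_steps = 60, dt_s = 0.05, snap_every = 10)
  maxima <- apply(f$snapshots, 4, max)
  minima <- apply(f$snapshots, 4, min)
  expect_true(all(diff(maxima) <= 1e-12))
  expect_true(all(diff(minima) >= -1e-12))
})

test_that("a gaussian bump diffuses with variance growth 2*alpha*t", {
  tis <- tissue_model(size_mm = c(20, 20, 20), voxel_mm = 0.5)
  T0 <- gaussian_field(tis, sigma_mm = 2)
  f <- evolve_field(tis, T0, n_steps = 100, dt_s = 0.05, snap_every = 100) # 5 s
  T5 <- f$snapshots[, , , 2]
  for (axis in 1:3) {
    expect_equal(axis_variance(T0, tis, axis), 4, tolerance = 0.01)
    expect_equal(axis_variance(T5, tis, axis), 4 + 2 * 0.14 * 5, tolerance = 0.01)
  }
})

test_that("heating is linear in the source", {
  tis <- tiny_tissue()
  q <- array(0, tis$dims); q[5:8, 5:8, 1:2] <- 3
  T0 <- array(37, tis$dims)
  f1 <- evolve_field(tis, T0, q, n_steps = 20, dt_s = 0.1, source_steps = 10,
                     snap_every = 20)
  f2 <- evolve_field(tis, T0, 2 * q, n_steps = 20, dt_s = 0.1, source_steps = 10,
                     snap_every = 20)
  expect_equal(f2$snapshots[, , , 2] - 37, 2 * (f1$snapshots[, , , 2] - 37),
               tolerance = 1e-12)
})

test_that("stability violations are rejected naming the admissible dt", {
  tis <- tiny_tissue() # dt_max = 1 / (6 * 0.14)
  dt_max <- max_stable_dt(tis)
  expect_equal(dt_max, 1 / (6 * 0.14))
  expect_error(simulate_field(tis, cautery_application(30, 2), t_end_s = 4,
                              dt_s = 2, snapshot_every_s = 2),
               "admissible dt.*1\\.19")
  expect_error(
    simulate_field(tis, cautery_application(30, 2, prong_mm = c(20, 4)),
                   t_end_s = 4, dt_s = 0.1, snapshot_every_s = 0.1),
    "outside the tissue block")
})

test_that("surface_slice returns the top layer by direct indexing", {
  tis <- tiny_tissue()
  f <- simulate_field(tis, cautery_application(30, 2), t_end_s = 3,
                      dt_s = 0.1, snapshot_every_s = 0.5)
  sl <- surface_slice(f)
  expect_length(sl, dim(f$snapshots)[4])
  for (k in seq_along(sl)) {
    expect_identical(sl[[k]], f$snapshots[, , 1, k])
    expect_lte(max(sl[[k]]), max(f$snapshots[, , , k]))
  }
})

test_that("ground_truth_damage follows the voxel-center depth convention", {
  tis <- tissue_model(size_mm = c(6, 6, 4), voxel_mm = 1)
  snaps <- array(37, c(tis$dims, 2))
  snaps[2:3, 2:3, 1, 2] <- 80   # 4 top voxels
  snaps[2, 2, 2, 2] <- 70       # one voxel in layer 2
  snaps[4, 4, 1, 1] <- 61       # exceeds only in the FIRST snapshot
  f <- structure(list(snapshots = snaps, times = c(0, 1), dt_s = 1,
                      tissue = tis, app = NULL), class = "temperature_field")
  tr <- ground_truth_damage(f, 60)
  expect_equal(tr$surface_area_mm2, 5)   # ever-exceeding top voxels
  expect_equal(tr$max_depth_mm, 1.5)     # layer index 1 (0-based) -> (1+0.5)*1
  cold <- f; cold$snapshots[] <- 37
  tr0 <- ground_truth_damage(cold, 60)
  expect_equal(tr0$surface_area_mm2, 0)
  expect_equal(tr0$max_depth_mm, 0)
})

test_that("longer heating never shrinks damage", {
  tis <- tiny_tissue()
  f2 <- simulate_field(tis, cautery_application(30, 2), t_end_s = 5,
                       dt_s = 0.1, snapshot_every_s = 0.1)
  f4 <- simulate_field(tis, cautery_application(30, 4), t_end_s = 7,
                       dt_s = 0.1, snapshot_every_s = 0.1)
  t2 <- ground_truth_damage(f2); t4 <- ground_truth_damage(f4)
  expect_gte(t4$surface_area_mm2, t2$surface_area_mm2)
  expect_gte(t4$max_depth_mm, t2$max_depth_mm)
})

test_that("ground-truth area is grid-consistent under refinement", {
  app <- cautery_application(30, 2)
  coarse <- ground_truth_damage(simulate_field(
    tissue_model(voxel_mm = 1), app, t_end_s = 6, dt_s = 0.1,
    snapshot_every_s = 0.1))
  fine <- ground_truth_damage(simulate_field(
    tissue_model(voxel_mm = 0.5), app, t_end_s = 6, dt_s = 0.05,
    snapshot_every_s = 0.1))
  expect_lt(abs(coarse$surface_area_mm2 - fine$surface_area_mm2) /
              fine$surface_area_mm2, 0.10)
})
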
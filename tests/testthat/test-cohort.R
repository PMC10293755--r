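test_that("noise-free 1:1 rendering reproduces the surface slices", {
  tis <- tiny_tissue()
  f <- simulate_field(tis, cautery_application(30, 2), t_end_s = 2,
                      dt_s = 0.1, snapshot_every_s = 0.1)
  sen <- sensor_model(array_shape = tis$dims[1:2], netd_c = 0, bias_c = 0,
                      scene_mm_per_pixel = 1)
  seq <- render_thermograms(f, sen, seed = 3)
  sl <- surface_slice(f)
  for (k in seq_along(seq$frames)) {
    expect_equal(seq$frames[[k]]$values, float32(pmin(sl[[k]], 150)),
                 tolerance = 1e-12)
  }
})

test_that("rendering is deterministic per seed and distinct across seeds", {
  tis <- tiny_tissue()
  f <- simulate_field(tis, cautery_application(30, 2), t_end_s = 2,
                      dt_s = 0.1, snapshot_every_s = 0.1)
  sen <- sensor_model(array_shape = c(12, 12), scene_mm_per_pixel = 1)
  a <- render_thermograms(f, sen, seed = 5)
  b <- render_thermograms(f, sen, seed = 5)
  c <- render_thermograms(f, sen, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$frames[[1]]$values, c$frames[[1]]$values))
})

test_that("bias shifts and saturation clips the rendered temperatures", {
  tis <- tiny_tissue()
  f <- simulate_field(tis, cautery_application(0, 1), t_end_s = 1,
                      dt_s = 0.1, snapshot_every_s = 0.5)
  sen <- sensor_model(array_shape = c(12, 12), netd_c = 0, bias_c = 1.5,
                      scene_mm_per_pixel = 1)
  seq <- render_thermograms(f, sen, seed = 1)
  expect_equal(seq$frames[[1]]$values, float32(matrix(38.5, 12, 12)))
  expect_error(sensor_model(bias_c = 3), "accuracy class")
  hot <- f; hot$snapshots[] <- 200
  seqh <- render_thermograms(hot, sen, seed = 1)
  expect_true(all(seqh$frames[[1]]$values == 150))
})

test_that("an oversized camera window is a config error", {
  tis <- tiny_tissue()
  f <- simulate_field(tis, cautery_application(0, 1), t_end_s = 1,
                      dt_s = 0.1, snapshot_every_s = 0.5)
  expect_error(render_thermograms(f, sensor_model(array_shape = c(60, 80),
                                                  scene_mm_per_pixel = 1)),
               "larger than the scene")
})

test_that("noise averages out at the standard-error rate", {
  tis <- tissue_model(size_mm = c(8, 8, 4), voxel_mm = 1, ambient_c = 37)
  snaps <- array(50, c(tis$dims, 101))
  f <- structure(list(snapshots = snaps, times = seq(0, 10, 0.1), dt_s = 0.1,
                      tissue = tis, app = NULL), class = "temperature_field")
  sen <- sensor_model(array_shape = c(8, 8), netd_c = 0.1, scene_mm_per_pixel = 1)
  seq <- render_thermograms(f, sen, seed = 42) # 101 frames
  n <- length(seq$frames)
  means <- Reduce(`+`, lapply(seq$frames, `[[`, "values")) / n
  se <- 0.1 / sqrt(n)
  # 3*SE bounds a single pixel's mean; the max over all 64 pixels needs the
  # joint (Bonferroni) bound
  expect_lt(abs(means[4, 4] - 50), 3 * se)
  expect_lt(abs(mean(means) - 50), 3 * se / sqrt(length(means)))
  expect_lt(max(abs(means - 50)), 4.5 * se)
})

test_that("macro-area emulation has median one and is reproducible", {
  tr <- structure(list(surface_area_mm2 = 20, max_depth_mm = 1, threshold_c = 60),
                  class = "damage_truth")
  expect_equal(emulate_macro_area(tr, seed = 1, relative_sd = 0), 20)
  expect_equal(emulate_macro_area(tr, seed = 9), emulate_macro_area(tr, seed = 9))
  draws <- vapply(1:1000, function(s) emulate_macro_area(tr, seed = s, relative_sd = 0.1),
                  numeric(1))
  expect_lt(abs(median(draws) - 20) / 20, 0.03)
  expect_true(all(draws >= 0))
})

test_that("generate_cohort covers the group grid deterministically", {
  tis <- tiny_tissue()
  sen <- sensor_model(scene_mm_per_pixel = 1)
  cfg <- cohort_config(n_per_group = 1, base_seed = 2)
  co <- generate_cohort(cfg, tis, sen, t_extra_s = 2, dt_s = 0.1)
  expect_length(co$samples, 4)
  expect_equal(nrow(co$manifest), 4)
  got <- paste(co$manifest$power_w, co$manifest$duration_s)
  expect_setequal(got, c("30 2", "30 4", "60 2", "60 4"))
  expect_false(any(co$manifest$dropped))
  # pure function of config
  co2 <- generate_cohort(cfg, tis, sen, t_extra_s = 2, dt_s = 0.1)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$samples[[1]]$sequence, co2$samples[[1]]$sequence)
  # jitter actually varies the physical parameters between samples
  expect_gt(length(unique(co$manifest$coupling_efficiency)), 1)
  # manifest traceability: one row per sample id, params recorded
  expect_setequal(co$manifest$sample_id, vapply(co$samples, `[[`, "", "sample_id"))
  expect_true(all(c("diffusivity_mm2_s", "coupling_efficiency", "seed",
                    "truth_area_mm2", "macro_area_mm2") %in% names(co$manifest)))
})

test_that("dropout flags sessions without changing their seeds", {
  tis <- tiny_tissue()
  sen <- sensor_model(scene_mm_per_pixel = 1)
  base <- generate_cohort(cohort_config(n_per_group = 2, base_seed = 3,
                                        groups = list(c(30, 2))),
                          tis, sen, t_extra_s = 1, dt_s = 0.1)
  drop <- generate_cohort(cohort_config(n_per_group = 2, base_seed = 3,
                                        dropout_rate = 0.99,
                                        groups = list(c(30, 2))),
                          tis, sen, t_extra_s = 1, dt_s = 0.1)
  expect_true(all(drop$manifest$dropped))
  expect_equal(drop$manifest$seed, base$manifest$seed)
  expect_equal(drop$manifest$truth_area_mm2, base$manifest$truth_area_mm2)
})
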
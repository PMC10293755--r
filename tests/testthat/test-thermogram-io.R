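test_that("frame and sequence invariants are enforced", {
  expect_error(thermogram_frame(matrix(c(1, NA, 3, 4), 2, 2)), "non-finite")
  expect_error(thermogram_frame(matrix(500, 2, 2)), "unit error")
  expect_error(thermogram_frame(matrix(-100, 2, 2)), "unit error")
  expect_error(thermogram_frame(matrix(37, 2, 2), timestamp = -1), "non-negative")

  expect_error(thermogram_sequence(list()), "at least 1 frame")
  expect_error(
    thermogram_sequence(list(matrix(37, 2, 2), matrix(37, 3, 2)), frame_rate_hz = 10),
    "constant")
  f1 <- thermogram_frame(matrix(37, 2, 2), 0)
  f2 <- thermogram_frame(matrix(37, 2, 2), 0)
  expect_error(thermogram_sequence(list(f1, f2)), "strictly increasing")
  # timestamp / frame-rate disagreement beyond 1 ms
  f2$timestamp <- 0.2
  expect_error(thermogram_sequence(list(f1, f2), frame_rate_hz = 10), "1 ms")
})

test_that("bare matrices get timestamps index/frame_rate", {
  seq <- thermogram_sequence(replicate(3, matrix(37, 2, 2), simplify = FALSE),
                             frame_rate_hz = 10)
  expect_equal(sequence_timestamps <- vapply(seq$frames, `[[`, numeric(1), "timestamp"),
               c(0, 0.1, 0.2))
})

test_that("csv_dir round trip preserves values to the written precision", {
  seq <- random_sequence(42, n_frames = 3)
  dir <- tempfile("csvdir")
  write_sequence(seq, dir, "csv_dir", decimals = 3)
  back <- read_sequence(dir, "csv_dir")
  expect_length(back$frames, 3)
  for (i in 1:3) {
    expect_lt(max(abs(back$frames[[i]]$values - seq$frames[[i]]$values)), 0.005)
  }
  expect_equal(back$frame_rate_hz, 10) # from the meta.yaml sidecar
})

test_that("TIFF round trip is bit-exact and order-stable for rendered data", {
  tis <- tiny_tissue()
  field <- simulate_field(tis, cautery_application(30, 2), t_end_s = 2,
                          dt_s = 0.1, snapshot_every_s = 0.1)
  seq <- render_thermograms(field, sensor_model(array_shape = c(12, 12),
                                                scene_mm_per_pixel = 1), seed = 1)
  expect_length(seq$frames, 21)
  path <- tempfile(fileext = ".tiff")
  write_sequence(seq, path, "tiff_stack")
  back <- read_sequence(path, "tiff_stack")
  expect_length(back$frames, length(seq$frames))
  for (i in seq_along(seq$frames)) {
    expect_identical(back$frames[[i]]$values, seq$frames[[i]]$values)
  }
  # CSV at 3 decimals: error below 0.005 degC
  dir <- tempfile("csvdir")
  write_sequence(seq, dir, "csv_dir", decimals = 3)
  back_csv <- read_sequence(dir, "csv_dir")
  err <- max(vapply(seq_along(seq$frames), function(i) {
    max(abs(back_csv$frames[[i]]$values - seq$frames[[i]]$values))
  }, numeric(1)))
  expect_lte(err, 0.005)
  # order stability: distinct per-frame signatures survive the round trip
  sig <- function(s) vapply(s$frames, function(f) f$values[1, 1], numeric(1))
  expect_identical(sig(back), sig(seq))
})

test_that("reader errors are informative", {
  expect_error(read_sequence(tempfile(), "csv_dir"), "does not exist")
  dir <- tempfile("bad"); dir.create(dir)
  writeLines(c("1,2", "3"), file.path(dir, "frame_0001.csv"))
  expect_error(read_sequence(dir, "csv_dir", frame_rate_hz = 10),
               "ragged.*frame_0001.*row 2")
  writeLines(c("1,2", "3,x"), file.path(dir, "frame_0001.csv"))
  expect_error(read_sequence(dir, "csv_dir", frame_rate_hz = 10),
               "non-numeric cell.*row 2, col 2")
  # frame rate is required metadata when no sidecar exists
  writeLines(c("37,37", "37,37"), file.path(dir, "frame_0001.csv"))
  expect_error(read_sequence(dir, "csv_dir"), "frame_rate_hz is required")
  # unit-error rejection: a hot reading recorded in Kelvin exceeds 400
  writeLines(c("510,510", "510,510"), file.path(dir, "frame_0001.csv"))
  expect_error(read_sequence(dir, "csv_dir", frame_rate_hz = 10), "unit error")
})

test_that("empty or invalid sequences cannot be written", {
  expect_error(write_sequence(list(frames = list()), tempfile(), "csv_dir"))
  seq <- random_sequence(1, n_frames = 1)
  dir <- tempfile()
  write_sequence(seq, dir, "csv_dir")
  expect_identical(list.files(dir, pattern = "csv$"), "frame_0001.csv")
})

test_that("frame_stats matches direct summation", {
  m <- matrix(c(61, 60, 59.9, 62), 2, 2, byrow = TRUE)
  seq <- thermogram_sequence(list(matrix(37, 2, 2), m), frame_rate_hz = 10)
  fs <- frame_stats(seq)
  expect_equal(fs$min_c, c(37, 59.9))
  expect_equal(fs$max_c, c(37, 62))
  expect_equal(fs$mean_c[2], sum(m) / length(m))
  expect_true(all(fs$max_c >= fs$mean_c & fs$mean_c >= fs$min_c))
})
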
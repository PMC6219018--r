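test_that("moving average matches the arithmetic-mean oracle, warm-up included", {
  grid <- pressure_grid()
  set.seed(2)
  frames <- replicate(15, matrix(runif(160, 0, 5), 16, 10), simplify = FALSE)
  seq <- frame_sequence(frames, grid = grid)
  for (t in c(0L, 3L, 9L, 14L)) {
    sm <- moving_average(seq, 10L, t)
    lo <- max(0L, t - 9L)
    expected <- Reduce(`+`, frames[(lo + 1):(t + 1)]) / (t - lo + 1)
    expect_equal(sm$values, expected, tolerance = 0)
  }
})

test_that("moving average handles constants, single-cell ramps and N = 1", {
  expect_true(all(moving_average(const_seq(3, 12), 7L, 11L)$values == 3))

  grid <- grid_spec(1, 1, "pressure")
  ramp <- frame_sequence(lapply(1:10, function(v) matrix(v, 1, 1)),
                         grid = grid)
  expect_equal(moving_average(ramp, 10L, 9L)$values[1, 1], mean(1:10)) # 5.5

  set.seed(3)
  frames <- replicate(4, matrix(runif(64, 20, 30), 8, 8), simplify = FALSE)
  seq <- frame_sequence(frames, grid = thermal_grid())
  expect_identical(moving_average(seq, 1L, 2L)$values, frames[[3]])

  expect_error(moving_average(seq, 10L, 4L), "out of range")
  expect_error(moving_average(seq, 0L, 1L), "N must be")
})

test_that("moving average is linear, shift-equivariant and per-cell", {
  set.seed(4)
  grid <- thermal_grid()
  fa <- replicate(8, matrix(runif(64), 8, 8), simplify = FALSE)
  fb <- replicate(8, matrix(runif(64), 8, 8), simplify = FALSE)
  sa <- frame_sequence(fa, grid = grid)
  sb <- frame_sequence(fb, grid = grid)
  sab <- frame_sequence(mapply(function(a, b) 2 * a + 3 * b, fa, fb,
                               SIMPLIFY = FALSE), grid = grid)
  expect_equal(moving_average(sab, 5L, 6L)$values,
               2 * moving_average(sa, 5L, 6L)$values +
                 3 * moving_average(sb, 5L, 6L)$values)

  # shift equivariance: dropping the first frame shifts t by one
  shifted <- frame_sequence(fa[-1], grid = grid)
  expect_equal(moving_average(sa, 3L, 5L)$values,
               moving_average(shifted, 3L, 4L)$values)

  # a fixed permutation of cells applied to every frame commutes with MAF
  perm <- sample(64)
  pa <- lapply(fa, function(m) matrix(as.vector(m)[perm], 8, 8))
  sp <- frame_sequence(pa, grid = grid)
  expect_equal(as.vector(moving_average(sp, 4L, 7L)$values),
               as.vector(moving_average(sa, 4L, 7L)$values)[perm])
})

test_that("thresholding is strict and monotone", {
  grid <- grid_spec(2, 2, "pressure")
  fr <- structure(list(grid = grid,
                       values = matrix(c(1, 7, 5, 2), 2, 2), t = 0L),
                  class = "smoothed_frame")
  expect_identical(threshold_frame(fr, 4)$cells,
                   matrix(c(0L, 1L, 1L, 0L), 2, 2))

  # exact equality is NOT a sensed point
  eq <- structure(list(grid = grid, values = matrix(4, 2, 2), t = 0L),
                  class = "smoothed_frame")
  expect_true(all(threshold_frame(eq, 4)$cells == 0))
  expect_true(all(threshold_frame(eq, 3.999)$cells == 1))

  # monotone: raising tau can only turn cells off
  set.seed(5)
  v <- structure(list(grid = thermal_grid(),
                      values = matrix(runif(64, 0, 10), 8, 8), t = 0L),
                 class = "smoothed_frame")
  for (tau in c(2, 5, 8)) {
    lo <- threshold_frame(v, tau)$cells
    hi <- threshold_frame(v, tau + 1)$cells
    expect_true(all(hi <= lo))
  }
  expect_error(threshold_frame(v, Inf), "finite")
})

test_that("preprocessing recovers the contact masks of noiseless recordings", {
  cfg <- run_config()
  rec <- generate_frame("supine", body_model("medium"), zero_jitter(),
                        n_frames = 3)
  maps <- preprocess_recording(rec$pressure, rec$thermal, cfg)
  expect_identical(maps$pressure$cells, rec$truth$pressure_mask)
  expect_identical(maps$thermal$cells, rec$truth$thermal_mask)
  expect_false(maps$partial)
})

test_that("uniform ambient temperature yields an empty thermal map", {
  cfg <- run_config()
  amb <- const_seq(22, 12, thermal_grid())
  maps <- preprocess_recording(NULL, amb, cfg)
  expect_true(all(maps$thermal$cells == 0))
  expect_true(maps$partial)
  expect_null(maps$pressure)
  expect_error(preprocess_recording(NULL, NULL, cfg), "both streams")
})

test_that("small-amplitude noise is rejected by the averaging filter", {
  cfg <- run_config()
  clean <- generate_frame("prone", body_model("heavy"), zero_jitter(),
                          n_frames = 10)
  noisy <- generate_frame("prone", body_model("heavy"),
                          jitter_spec(translate_rows = 0, translate_cols = 0,
                                      rotate_deg = 0,
                                      noise_sd_pressure = 0.05,
                                      noise_sd_thermal = 0.1,
                                      ghost_rate = 0, seed = 11L),
                          n_frames = 10)
  m_clean <- preprocess_recording(clean$pressure, clean$thermal, cfg)
  m_noisy <- preprocess_recording(noisy$pressure, noisy$thermal, cfg)
  expect_identical(m_noisy$pressure$cells, m_clean$pressure$cells)
  expect_identical(m_noisy$thermal$cells, m_clean$thermal$cells)
})
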
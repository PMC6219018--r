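test_that("histogram projections count sensed points conservatively", {
  grid <- pressure_grid()
  zero <- binary_map(matrix(0L, 16, 10), grid)
  expect_true(all(project_histogram(zero, "horizontal")$counts == 0))

  cells <- matrix(0L, 16, 10)
  cells[4, 8] <- 1L  # 0-based (3, 7)
  one <- binary_map(cells, grid)
  h <- project_histogram(one, "horizontal")
  expect_identical(h$counts, as.integer(replace(rep(0, 10), 8, 1)))
  v <- project_histogram(one, "vertical")
  expect_identical(v$counts, as.integer(replace(rep(0, 16), 4, 1)))

  set.seed(6)
  for (i in 1:5) {
    bm <- random_binary_map(grid)
    total <- sum(bm$cells)
    expect_equal(sum(project_histogram(bm, "horizontal")$counts), total)
    expect_equal(sum(project_histogram(bm, "vertical")$counts), total)
  }
})

test_that("single-cluster FCM is the coordinate-wise mean", {
  set.seed(7)
  pts <- cbind(sample(0:15, 8), sample(1:9, 8, replace = TRUE))
  fit <- fcm_cluster(pts, c = 1)
  expect_equal(as.vector(fit$centers), colMeans(pts))
  expect_true(all(fit$U == 1))
})

test_that("well-separated groups converge to group means with a non-increasing objective", {
  set.seed(8)
  g1 <- cbind(rnorm(10, 2, 0.01), rnorm(10, 3, 0.01))
  g2 <- cbind(rnorm(10, 12, 0.01), rnorm(10, 9, 0.01))
  fit <- fcm_cluster(rbind(g1, g2), c = 2, epsilon = 1e-10, max_iter = 500)
  ctr <- fit$centers[order(fit$centers[, 1]), ]
  expect_equal(as.vector(ctr[1, ]), colMeans(g1), tolerance = 1e-3)
  expect_equal(as.vector(ctr[2, ]), colMeans(g2), tolerance = 1e-3)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
})

test_that("a point equidistant between symmetric clusters splits its membership", {
  pts <- rbind(c(0, 0), c(10, 0), c(5, 0))
  fit <- fcm_cluster(pts, c = 2, m = 2,
                     centers = rbind(c(0, 0), c(10, 0)), max_iter = 1)
  expect_equal(fit$U[3, ], c(0.5, 0.5))
  # coincident point takes membership 1 by the singularity guard
  expect_equal(fit$U[1, ], c(1, 0))
})

test_that("fcm agrees with a brute-force alternating-minimization oracle", {
  set.seed(9)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    cc <- sample(2:3, 1)
    pts <- cbind(sample(0:15, n), sample(0:12, n, replace = TRUE))
    init_pos <- seq(min(pts[, 1]), max(pts[, 1]), length.out = cc)
    init <- cbind(init_pos, pts[sapply(init_pos, function(p)
      which.min(abs(pts[, 1] - p))), 2])
    fit <- fcm_cluster(pts, c = cc, m = 2, epsilon = 1e-8, max_iter = 300,
                       centers = init)
    ref <- fcm_oracle(pts, cc, 2, 1e-8, 300, init)
    expect_lt(abs(fit$objective_trace[length(fit$objective_trace)] -
                  ref$objective), 1e-6)
    expect_lt(fit$membership_dev, 1e-12)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("fcm validates its preconditions", {
  pts <- cbind(1:2, 1:2)
  expect_error(fcm_cluster(pts, c = 3), "at least")
  expect_error(fcm_cluster(pts, c = 1, m = 1), "m must be")
  expect_error(fcm_cluster(pts, c = 1, epsilon = 0), "epsilon")
})

test_that("the middle axis of a symmetric unimodal projection is its centre", {
  counts <- c(0, 1, 2, 4, 7, 9, 7, 4, 2, 1, 0)
  proj <- structure(list(axis = "horizontal", index = 0:10,
                         counts = as.integer(counts)),
                    class = "projection")
  expect_equal(find_middle_axis(proj, run_config())$axis, 5L)
})

test_that("degenerate projections reduce the cluster count totally", {
  cfg <- run_config()
  # single occupied column: argmax-count index comes straight back
  proj <- structure(list(axis = "horizontal", index = 0:7,
                         counts = as.integer(c(0, 0, 0, 6, 0, 0, 0, 0))),
                    class = "projection")
  res <- find_middle_axis(proj, cfg)
  expect_equal(res$axis, 3L)
  expect_null(res$clustering)

  empty <- structure(list(axis = "vertical", index = 0:7,
                          counts = integer(8)), class = "projection")
  expect_error(find_middle_axis(empty, cfg), "no sensed points")
})

test_that("trunk cross point is recovered exactly on noiseless frames", {
  cfg <- run_config()
  rec <- generate_frame("supine", body_model("medium"), zero_jitter(),
                        n_frames = 2)
  maps <- preprocess_recording(rec$pressure, rec$thermal, cfg)
  axes <- find_trunk_middle_point(maps$pressure, cfg)
  expect_identical(unname(axes$cross_point), c(8L, 4L))
  expect_identical(axes$cross_point[["row"]], axes$vertical_axis)
  expect_identical(axes$cross_point[["col"]], axes$horizontal_axis)
})

test_that("middle axes mirror and translate with the map", {
  cfg <- run_config()
  rec <- generate_frame("left_fetus", body_model("heavy"), zero_jitter(),
                        n_frames = 2)
  maps <- preprocess_recording(rec$pressure, rec$thermal, cfg)
  axes <- find_trunk_middle_point(maps$pressure, cfg)

  mirrored <- find_trunk_middle_point(mirror_lr(maps$pressure), cfg)
  expect_equal(mirrored$horizontal_axis, 9L - axes$horizontal_axis)
  expect_equal(mirrored$vertical_axis, axes$vertical_axis)

  # shift every sensed point one column toward the subject's left
  shifted <- cbind(matrix(0L, 16, 1), maps$pressure$cells[, 1:9])
  ax_shift <- find_trunk_middle_point(binary_map(shifted, pressure_grid()),
                                      cfg)
  expect_equal(ax_shift$horizontal_axis, axes$horizontal_axis + 1L)

  leg <- find_leg_middle_axis(maps$thermal, cfg)
  leg_m <- find_leg_middle_axis(mirror_lr(maps$thermal), cfg)
  expect_equal(leg_m$axis, 7L - leg$axis)
})

test_that("leg middle axis handles log templates and single-column masses", {
  cfg <- run_config()
  rec <- generate_frame("right_log", body_model("light"), zero_jitter(),
                        n_frames = 2)
  maps <- preprocess_recording(rec$pressure, rec$thermal, cfg)
  expect_equal(find_leg_middle_axis(maps$thermal, cfg)$axis,
               rec$truth$leg_axis)

  cells <- matrix(0L, 8, 8)
  cells[, 6] <- 1L
  one_col <- binary_map(cells, thermal_grid())
  expect_equal(find_leg_middle_axis(one_col, cfg)$axis, 5L)
})
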
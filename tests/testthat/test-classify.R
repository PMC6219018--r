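test_that("k-NN handles leaves, coincident queries and validates input", {
  ex <- rbind(c(1, 1))
  res <- knn_classify(c(5, 5), ex, "supine", k = 1)
  expect_equal(res$label, "supine")
  expect_equal(unname(res$scores), 1)

  ex <- rbind(c(0, 0), c(3, 3), c(10, 10))
  labs <- c("a", "b", "c")
  hit <- knn_classify(c(3, 3), ex, labs, k = 3)
  expect_equal(hit$label, "b")
  expect_equal(unname(hit$scores["b"]), 1)

  expect_error(knn_classify(c(0, 0), ex[0, , drop = FALSE], character(0), 1),
               "empty")
  expect_error(knn_classify(c(0, 0), ex, labs, k = 4), "outside")
  expect_error(knn_classify(c(NA, 0), ex, labs, k = 1), "finite")
})

test_that("k-NN equals the exhaustive weighted-vote oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    ex <- cbind(runif(n, -10, 10), runif(n, -10, 10))
    labs <- sample(c("log", "fetus"), n, replace = TRUE)
    if (length(unique(labs)) < 2) labs[1:2] <- c("log", "fetus")
    k <- sample(1:n, 1)
    x <- runif(2, -10, 10)
    got <- knn_classify(x, ex, labs, k = k, weight_exponent = 2)
    ref <- knn_oracle(x, ex, labs, k = k, p = 2)
    expect_equal(got$label, ref$label)
    expect_equal(got$scores[names(ref$scores)], ref$scores)
  }
})

test_that("duplicated exemplars leave the vote unchanged after renormalization", {
  ex <- rbind(c(0, 0), c(4, 0), c(8, 0))
  labs <- c("a", "a", "b")
  base <- knn_classify(c(3, 1), ex, labs, k = 3)
  dup <- knn_classify(c(3, 1), rbind(ex, ex), c(labs, labs), k = 6)
  expect_equal(dup$label, base$label)
  expect_equal(dup$scores, base$scores)
})

test_that("reference model construction validates class support", {
  cfg <- run_config()
  ds <- generate_dataset(6, seed = 21)
  feats <- dataset_features(ds, cfg)
  model <- build_reference_model(feats, k = 5)
  expect_s3_class(model, "reference_model")
  expect_gte(min(table(model$trunk_labels)), 5)
  expect_gte(min(table(model$leg_labels)), 5)

  no_prone <- feats[feats$label != "prone", ]
  expect_error(build_reference_model(no_prone, k = 5), "prone")
  expect_error(build_reference_model(feats[0, ], k = 1), "supine")
})

test_that("trunk stage follows the geometry of the symmetry feature space", {
  model <- default_reference_model(run_config(), n_per_class = 30L)
  mk <- function(trl, tch) {
    structure(list(T_D_RL = trl, T_D_CH = tch, L_D_RL = 0L, L_MAC = 8L),
              class = "posture_features")
  }
  expect_equal(classify_trunk(mk(0L, 0L), model)$label, "supine")
  expect_equal(classify_trunk(mk(-12L, 1L), model)$label, "left_lateral")
  expect_equal(classify_trunk(mk(12L, 1L), model)$label, "right_lateral")
  expect_equal(classify_trunk(mk(0L, -14L), model)$label, "prone")
})

test_that("leg stage separates straight from curled legs", {
  model <- default_reference_model(run_config(), n_per_class = 30L)
  mk <- function(lrl, lmac) {
    structure(list(T_D_RL = -10L, T_D_CH = 0L, L_D_RL = lrl, L_MAC = lmac),
              class = "posture_features")
  }
  expect_equal(classify_legs(mk(6L, 1L), model)$label, "fetus")
  expect_equal(classify_legs(mk(0L, 8L), model)$label, "log")
})

test_that("the decision tree composes stages into the six postures", {
  model <- default_reference_model(run_config(), n_per_class = 30L)
  f <- structure(list(T_D_RL = -12L, T_D_CH = 0L, L_D_RL = 6L, L_MAC = 1L),
                 class = "posture_features")
  out <- classify_posture(f, model)
  expect_equal(out$label, "left_fetus")
  expect_equal(out$trunk$label, "left_lateral")
  expect_equal(out$legs$label, "fetus")

  sup <- structure(list(T_D_RL = 0L, T_D_CH = 1L, L_D_RL = 6L, L_MAC = 1L),
                   class = "posture_features")
  out <- classify_posture(sup, model)
  expect_equal(out$label, "supine")
  expect_null(out$legs)

  # lateral trunk with missing leg features degrades to a flagged result
  part <- structure(list(T_D_RL = -12L, T_D_CH = 0L, L_D_RL = NA_integer_,
                         L_MAC = NA_integer_), class = "posture_features")
  out <- classify_posture(part, model)
  expect_equal(out$label, "left_lateral")
  expect_true(out$partial)
})

test_that("noiseless templates of all six postures classify correctly", {
  cfg <- run_config()
  model <- default_reference_model(cfg, n_per_class = 30L)
  for (p in SLEEP_POSTURES) {
    for (w in c("light", "medium", "heavy")) {
      rec <- generate_frame(p, body_model(w), zero_jitter(), n_frames = 2)
      out <- classify_recording(rec$pressure, rec$thermal, model, cfg)
      expect_equal(out$label, p)
      expect_false(out$partial)
    }
  }
})

test_that("a missing thermal stream yields a flagged trunk-level result", {
  cfg <- run_config()
  model <- default_reference_model(cfg, n_per_class = 30L)
  rec <- generate_frame("right_log", body_model("medium"), zero_jitter(),
                        n_frames = 2)
  out <- classify_recording(rec$pressure, NULL, model, cfg)
  expect_true(out$partial)
  expect_equal(out$label, "right_lateral")
})

test_that("mirroring inputs swaps lateral labels under a mirror-symmetric model", {
  cfg <- run_config()
  model <- symmetric_model(cfg)
  swap <- c(right_log = "left_log", left_log = "right_log",
            right_fetus = "left_fetus", left_fetus = "right_fetus",
            supine = "supine", prone = "prone")
  set.seed(15)
  for (i in 1:12) {
    p <- sample(SLEEP_POSTURES, 1)
    rec <- generate_frame(p, body_model(sample(c("light", "medium", "heavy"),
                                               1)),
                          jitter_spec(seed = sample.int(10000, 1)),
                          n_frames = 12)
    out <- classify_recording(rec$pressure, rec$thermal, model, cfg)
    out_m <- classify_recording(mirror_lr(rec$pressure),
                                mirror_lr(rec$thermal), model, cfg)
    expect_equal(out_m$label, unname(swap[out$label]))
  }
})
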
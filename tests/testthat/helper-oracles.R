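# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation: plain loops,
# no vectorized shortcuts.

# Brute-force fuzzy c-means: explicit alternating minimization with the
# same update schedule (memberships from current centers, objective, then
# center update) so that runs with a shared initialization are comparable.
fcm_oracle <- function(points, n_clusters, m, epsilon, max_iter, centers) {
  n <- nrow(points)
  trace <- c()
  a_prev <- Inf
  u <- matrix(0, n, n_clusters)
  for (iter in 1:max_iter) {
    d <- matrix(0, n, n_clusters)
    for (i in 1:n) for (k in 1:n_clusters) {
      d[i, k] <- sqrt((points[i, 1] - centers[k, 1])^2 +
                      (points[i, 2] - centers[k, 2])^2)
    }
    for (i in 1:n) {
      if (any(d[i, ] == 0)) {
        u[i, ] <- ifelse(d[i, ] == 0, 1 / sum(d[i, ] == 0), 0)
      } else {
        for (k in 1:n_clusters) {
          acc <- 0
          for (l in 1:n_clusters)
            acc <- acc + (d[i, k] / d[i, l])^(2 / (m - 1))
          u[i, k] <- 1 / acc
        }
      }
    }
    a <- 0
    for (i in 1:n) for (k in 1:n_clusters)
      a <- a + u[i, k]^m * d[i, k]^2
    trace <- c(trace, a)
    if (abs(a_prev - a) < epsilon) break
    a_prev <- a
    for (k in 1:n_clusters) {
      num <- c(0, 0); den <- 0
      for (i in 1:n) {
        w <- u[i, k]^m
        num <- num + w * points[i, ]
        den <- den + w
      }
      centers[k, ] <- num / den
    }
  }
  list(objective = trace[length(trace)], trace = trace, U = u,
       centers = centers)
}

# Exhaustive distance-weighted vote.
knn_oracle <- function(x, exemplars, labels, k, p) {
  d <- numeric(nrow(exemplars))
  for (i in seq_along(d))
    d[i] <- sqrt(sum((exemplars[i, ] - x)^2))
  if (any(d == 0)) {
    lab <- labels[which(d == 0)[1]]
    scores <- sapply(unique(labels), function(cl) as.numeric(cl == lab))
    return(list(label = lab, scores = scores))
  }
  nn <- order(d)[1:k]
  scores <- sapply(unique(labels), function(cl) {
    s <- 0
    for (i in nn) if (labels[i] == cl) s <- s + 1 / d[i]^p
    s
  })
  scores <- scores / sum(scores)
  list(label = names(scores)[which.max(scores)], scores = scores)
}

# Monte-Carlo estimate of the largest circle centred in a square sensing
# grid cell that avoids the four corner sensor disks: rejection sampling of
# circle placements over the cell, radius capped by the corner constraint.
mc_max_circle_area_cm2 <- function(pitch, sensor_radius, n = 200000L) {
  corners <- rbind(c(0, 0), c(0, pitch), c(pitch, 0), c(pitch, pitch))
  best <- 0
  xs <- runif(n, 0, pitch)
  ys <- runif(n, 0, pitch)
  for (i in seq_len(n)) {
    dmin <- min(sqrt((corners[, 1] - xs[i])^2 + (corners[, 2] - ys[i])^2))
    r <- dmin - sensor_radius
    if (r > 0) best <- max(best, pi * r^2)
  }
  best * 1e4
}

# Direct cell-enumeration of trunk quadrants and leg partitions.
quadrant_oracle <- function(cells, waist_row, trunk_col) {
  counts <- c(C_R = 0, C_L = 0, H_R = 0, H_L = 0, on_axis = 0)
  for (r in seq_len(nrow(cells))) for (cc in seq_len(ncol(cells))) {
    if (cells[r, cc] != 1) next
    r0 <- r - 1; c0 <- cc - 1
    if (r0 == waist_row || c0 == trunk_col) {
      counts["on_axis"] <- counts["on_axis"] + 1
    } else if (r0 < waist_row && c0 < trunk_col) {
      counts["C_R"] <- counts["C_R"] + 1
    } else if (r0 < waist_row && c0 > trunk_col) {
      counts["C_L"] <- counts["C_L"] + 1
    } else if (r0 > waist_row && c0 < trunk_col) {
      counts["H_R"] <- counts["H_R"] + 1
    } else {
      counts["H_L"] <- counts["H_L"] + 1
    }
  }
  counts
}

leg_oracle <- function(cells, axis) {
  counts <- c(L_R = 0, L_L = 0, L_MAC = 0)
  for (r in seq_len(nrow(cells))) for (cc in seq_len(ncol(cells))) {
    if (cells[r, cc] != 1) next
    c0 <- cc - 1
    if (c0 < axis) counts["L_R"] <- counts["L_R"] + 1
    else if (c0 > axis) counts["L_L"] <- counts["L_L"] + 1
    else counts["L_MAC"] <- counts["L_MAC"] + 1
  }
  counts
}

# Small builders shared across tests.
const_seq <- function(value, n, grid = pressure_grid()) {
  frame_sequence(replicate(n, matrix(value, grid$rows, grid$cols),
                           simplify = FALSE), grid = grid)
}

random_binary_map <- function(grid, p = 0.3) {
  binary_map(matrix(runif(grid$rows * grid$cols) < p,
                    grid$rows, grid$cols), grid)
}

# Reference model whose exemplar set is mirror-symmetric by construction:
# every exemplar is paired with its left-right mirror image.
symmetric_model <- function(cfg = run_config(), n_per_class = 30L,
                            seed = 99L) {
  ds <- generate_dataset(n_per_class = n_per_class, seed = seed)
  feats <- dataset_features(ds, cfg)
  mirrored <- feats
  mirrored$T_D_RL <- -feats$T_D_RL
  swap <- c(right_log = "left_log", left_log = "right_log",
            right_fetus = "left_fetus", left_fetus = "right_fetus",
            supine = "supine", prone = "prone")
  mirrored$label <- unname(swap[feats$label])
  build_reference_model(rbind(feats, mirrored), k = cfg$knn$k,
                        weight_exponent = cfg$knn$weight_exponent)
}
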
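#' Histogram projection of a binary map
#'
#' Counts sensed points per positioning index along one direction: the
#' horizontal projection gives one count per column, the vertical projection
#' one count per row. The sum over indices always equals the number of
#' sensed points in the map.
#'
#' @param bm A [binary_map()].
#' @param axis `"horizontal"` (per-column counts) or `"vertical"` (per-row
#'   counts).
#' @return An object of class `projection` with elements `axis`, `index`
#'   (0-based positioning indices) and `counts`.
#' @export
project_histogram <- function(bm, axis = c("horizontal", "vertical")) {
  stopifnot(inherits(bm, "binary_map"))
  axis <- match.arg(axis)
  counts <- if (axis == "horizontal") colSums(bm$cells) else rowSums(bm$cells)
  structure(
    list(axis = axis, index = seq_along(counts) - 1L,
         counts = as.integer(counts)),
    class = "projection"
  )
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection> %s, %d indices, %d sensed point(s)\n",
              x$axis, length(x$counts), sum(x$counts)))
  invisible(x)
}

# Pairwise Euclidean distances between n x d points and c x d centers.
fcm_distances <- function(points, centers) {
  n <- nrow(points)
  cc <- nrow(centers)
  D <- matrix(0, n, cc)
  for (k in seq_len(cc)) {
    D[, k] <- sqrt(rowSums((points - matrix(centers[k, ], n, ncol(points),
                                            byrow = TRUE))^2))
  }
  D
}

# Membership update: u_ik = 1 / sum_l (d_ik / d_il)^(2/(m-1)), with the
# standard singularity guard: a point at zero distance from one or more
# centers takes membership split over those centers and 0 elsewhere.
fcm_memberships <- function(D, m) {
  n <- nrow(D)
  cc <- ncol(D)
  U <- matrix(0, n, cc)
  p <- 2 / (m - 1)
  for (i in seq_len(n)) {
    zero <- D[i, ] == 0
    if (any(zero)) {
      U[i, zero] <- 1 / sum(zero)
    } else {
      inv <- D[i, ]^(-p)
      U[i, ] <- inv / sum(inv)
    }
  }
  U
}

#' Fuzzy c-means clustering of projection points
#'
#' Soft clustering of `(positioning index, sensed count)` pairs minimizing
#' the weighted within-cluster sum of squares
#' `A = sum_i sum_k u_ik^m * ||x_i - c_k||^2`, where the distance between a
#' point and a center is the 2-D Euclidean distance over the position and
#' count coordinates. The algorithm alternates the membership update
#' (inverse-distance-ratio rule raised to `2/(m-1)`) with the weighted-mean
#' center update, and stops when the objective changes by less than
#' `epsilon` between consecutive iterations, or after `max_iter` iterations.
#'
#' Initialization is deterministic by default: the `c` initial center
#' positions are evenly spaced over the range of the supplied point
#' positions, and each initial center count is the count of the nearest
#' point. A run is fully determined by its initialization.
#'
#' @param points `n x 2` numeric matrix (columns: position, count) with
#'   `n >= c`.
#' @param c Number of clusters (>= 1).
#' @param m Fuzzifier (> 1).
#' @param epsilon Stop tolerance on the change of the objective (> 0).
#' @param max_iter Iteration cap.
#' @param centers Optional `c x 2` matrix of initial centers, overriding the
#'   deterministic initializer.
#' @return An object of class `axis_clustering`: `centers` (`c x 2`), `U`
#'   (`n x c` memberships, rows summing to 1), `objective_trace`
#'   (non-increasing after the first iterate), `labels` (0-based defuzzified
#'   cluster per point, ties to the lowest cluster), `iterations`,
#'   `membership_dev` (largest deviation of any row sum of `U` from 1 seen
#'   at any iteration), plus the call parameters.
#' @examples
#' pts <- cbind(c(0, 1, 2, 7, 8, 9), c(2, 3, 2, 4, 5, 4))
#' fit <- fcm_cluster(pts, c = 2)
#' fit$centers
#' @export
fcm_cluster <- function(points, c, m = 2, epsilon = 1e-5, max_iter = 200L,
                        centers = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("fcm_cluster: points must be an n x 2 matrix", call. = FALSE)
  n <- nrow(points)
  c <- as.integer(c)
  if (c < 1L) stop("fcm_cluster: c must be >= 1", call. = FALSE)
  if (n < c)
    stop(sprintf("fcm_cluster: need at least c=%d points, got %d", c, n),
         call. = FALSE)
  if (m <= 1) stop("fcm_cluster: m must be > 1", call. = FALSE)
  if (epsilon <= 0) stop("fcm_cluster: epsilon must be > 0", call. = FALSE)

  if (is.null(centers)) {
    pos <- points[, 1L]
    init_pos <- if (c == 1L) mean(range(pos)) else
      seq(min(pos), max(pos), length.out = c)
    nearest <- vapply(init_pos, function(p) which.min(abs(pos - p)),
                      integer(1L))
    centers <- cbind(init_pos, points[nearest, 2L])
  }
  centers <- as.matrix(centers)
  if (nrow(centers) != c || ncol(centers) != 2L)
    stop("fcm_cluster: centers must be a c x 2 matrix", call. = FALSE)
  dimnames(centers) <- list(NULL, c("position", "count"))

  trace <- numeric(0)
  A_prev <- Inf
  U <- NULL
  mdev <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- fcm_distances(points, centers)
    U <- fcm_memberships(D, m)
    mdev <- max(mdev, abs(rowSums(U) - 1))
    A <- sum(U^m * D^2)
    trace <- c(trace, A)
    if (abs(A_prev - A) < epsilon || iter >= max_iter) break
    A_prev <- A
    W <- U^m
    centers <- (t(W) %*% points) / colSums(W)
    dimnames(centers) <- list(NULL, c("position", "count"))
  }

  labels <- apply(U, 1L, which.max) - 1L  # which.max ties -> lowest cluster
  structure(
    list(c = c, m = m, centers = centers, U = U,
         objective_trace = trace, labels = as.integer(labels),
         iterations = iter, membership_dev = mdev,
         points = points, epsilon = epsilon),
    class = "axis_clustering"
  )
}

#' @export
print.axis_clustering <- function(x, ...) {
  cat(sprintf("<axis_clustering> c=%d, m=%.3g, %d point(s), %d iteration(s), A=%.6g\n",
              x$c, x$m, nrow(x$points), x$iterations,
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Find the middle axis of a projection
#'
#' Implements the foreground-selection step of the middle-point procedure.
#' Only occupied positioning indices (count > 0) enter the clustering, so
#' the flanking background clusters sit at the edges of the body's support.
#' The clusters are ordered by center position; the middle one (median
#' center position) is the foreground cluster -- the trunk on a horizontal
#' projection, the waist on a vertical projection -- and the occupied index
#' with the maximum membership in that cluster is the middle axis. Ties in
#' membership break to the lower index, and ties in center position to the
#' lower position, so the result is deterministic.
#'
#' Degenerate support is handled totally: when fewer occupied indices exist
#' than the configured cluster count, the cluster count is reduced to the
#' number of occupied indices (for an even reduced count the lower of the
#' two central clusters is taken as the middle); with a single occupied
#' cluster the argmax-count index is returned directly.
#'
#' @param proj A `projection` from [project_histogram()].
#' @param cfg A [run_config()]; `cfg$fcm` supplies c, m, epsilon, max_iter.
#' @return A list with `axis` (0-based positioning index) and `clustering`
#'   (an `axis_clustering`, or `NULL` in the single-cluster degenerate
#'   case).
#' @export
find_middle_axis <- function(proj, cfg = run_config()) {
  stopifnot(inherits(proj, "projection"))
  occ <- proj$counts > 0L
  n_occ <- sum(occ)
  if (n_occ == 0L)
    stop(sprintf("find_middle_axis: %s projection has no sensed points",
                 proj$axis), call. = FALSE)
  c_use <- min(cfg$fcm$n_clusters, n_occ)
  idx <- proj$index[occ]
  cnt <- proj$counts[occ]
  if (c_use == 1L) {
    return(list(axis = idx[which.max(cnt)], clustering = NULL))
  }
  fit <- fcm_cluster(cbind(idx, cnt), c = c_use, m = cfg$fcm$m,
                     epsilon = cfg$fcm$epsilon, max_iter = cfg$fcm$max_iter)
  ord <- order(fit$centers[, 1L])          # stable: position ties keep order
  middle <- ord[(c_use + 1L) %/% 2L]       # median center; lower of two mid
  u_mid <- fit$U[, middle]
  axis <- idx[which.max(u_mid)]            # ties -> lowest index
  list(axis = axis, clustering = fit, middle_cluster = middle)
}

#' Locate the trunk middle point on the pressure map
#'
#' Runs [find_middle_axis()] on both projections of the pressure binary
#' map. On the horizontal projection the foreground (middle) cluster maps
#' to the trunk and yields the trunk middle column; on the vertical
#' projection the middle cluster maps to the waist -- the chest cluster lies
#' above it (toward the head end) and the hip cluster below -- and yields
#' the waist row. Their crossing is the trunk middle point used to cut the
#' trunk into four sub-regions.
#'
#' @param bm Pressure [binary_map()].
#' @param cfg A [run_config()].
#' @return An object of class `middle_axes`: `horizontal_axis` (trunk
#'   middle column), `vertical_axis` (waist row), `cross_point`
#'   (`c(row, col)`), and the two clusterings.
#' @export
find_trunk_middle_point <- function(bm, cfg = run_config()) {
  stopifnot(inherits(bm, "binary_map"))
  h <- find_middle_axis(project_histogram(bm, "horizontal"), cfg)
  v <- find_middle_axis(project_histogram(bm, "vertical"), cfg)
  structure(
    list(horizontal_axis = h$axis, vertical_axis = v$axis,
         cross_point = c(row = v$axis, col = h$axis),
         horizontal_clustering = h$clustering,
         vertical_clustering = v$clustering),
    class = "middle_axes"
  )
}

#' @export
print.middle_axes <- function(x, ...) {
  cat(sprintf("<middle_axes> trunk column %d, waist row %d, cross point (%d, %d)\n",
              x$horizontal_axis, x$vertical_axis,
              x$cross_point[1L], x$cross_point[2L]))
  invisible(x)
}

#' Locate the leg middle axis on the thermal map
#'
#' The horizontal projection of the thermal binary map is clustered exactly
#' as for the trunk; the middle-cluster argmax-membership column is the leg
#' middle axis separating the left- and right-leg sub-regions.
#'
#' @param bm Thermal [binary_map()].
#' @param cfg A [run_config()].
#' @return A list with `axis` (0-based column) and `clustering`.
#' @export
find_leg_middle_axis <- function(bm, cfg = run_config()) {
  stopifnot(inherits(bm, "binary_map"))
  find_middle_axis(project_histogram(bm, "horizontal"), cfg)
}
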
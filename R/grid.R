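#' Sensor grid specification
#'
#' Describes one of the two sensing arrays: the force-sensing resistor (FSR)
#' pressure array under the upper body, or the infrared thermal array imaging
#' the lower body. The grid fixes the coordinate convention used by every
#' stage of the pipeline: row 0 is the head end of the bed, and column 0 is
#' the subject's right side (the image left, viewing the bed from above with
#' the subject supine). All indices reported by the package are 0-based.
#'
#' @param rows Number of sensor rows (positive integer).
#' @param cols Number of sensor columns (positive integer).
#' @param role Either `"pressure"` (values in kg/cm2, full scale 10) or
#'   `"thermal"` (values in degrees Celsius).
#' @return An object of class `grid_spec`.
#' @examples
#' pressure_grid()
#' thermal_grid()
#' @export
grid_spec <- function(rows, cols, role = c("pressure", "thermal")) {
  role <- match.arg(role)
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (length(rows) != 1L || is.na(rows) || rows < 1L)
    stop("grid_spec: 'rows' must be a positive integer", call. = FALSE)
  if (length(cols) != 1L || is.na(cols) || cols < 1L)
    stop("grid_spec: 'cols' must be a positive integer", call. = FALSE)
  structure(
    list(rows = rows, cols = cols, role = role,
         row0_at = "head end", col0_at = "subject right"),
    class = "grid_spec"
  )
}

#' @rdname grid_spec
#' @export
pressure_grid <- function() grid_spec(16L, 10L, "pressure")

#' @rdname grid_spec
#' @export
thermal_grid <- function() grid_spec(8L, 8L, "thermal")

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s %dx%d (row 0 = %s, col 0 = %s)\n",
              x$role, x$rows, x$cols, x$row0_at, x$col0_at))
  invisible(x)
}

same_grid <- function(a, b) {
  a$rows == b$rows && a$cols == b$cols && a$role == b$role
}

check_matrix_shape <- function(values, grid, what = "values") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  if (nrow(values) != grid$rows || ncol(values) != grid$cols)
    stop(sprintf("%s is %dx%d but grid is %dx%d", what,
                 nrow(values), ncol(values), grid$rows, grid$cols),
         call. = FALSE)
  invisible(values)
}

#' Single sensor frame
#'
#' One time-stamped matrix of raw readings from either array. Pressure
#' readings are clamped by the sensor to the 0--10 kg/cm2 full scale, which
#' is validated here.
#'
#' @param values `rows x cols` numeric matrix of readings.
#' @param grid A [grid_spec()].
#' @param t Sample index (integer, >= 0). Sampling is treated as an abstract
#'   index, not wall-clock time.
#' @return An object of class `sensor_frame`.
#' @export
sensor_frame <- function(values, grid, t = 0L) {
  check_matrix_shape(values, grid)
  t <- as.integer(t)
  if (is.na(t) || t < 0L) stop("sensor_frame: t must be >= 0", call. = FALSE)
  if (grid$role == "pressure" &&
      (min(values) < 0 || max(values) > 10))
    stop("sensor_frame: pressure values must lie in [0, 10] kg/cm2",
         call. = FALSE)
  structure(list(grid = grid, t = t, values = values), class = "sensor_frame")
}

#' Ordered sequence of frames from one array
#'
#' Temporal container consumed by the moving-average filter. All frames share
#' one grid and carry strictly increasing sample indices.
#'
#' @param frames List of `rows x cols` numeric matrices, or of
#'   [sensor_frame()] objects.
#' @param grid A [grid_spec()] (required when `frames` are bare matrices).
#' @param t Integer vector of sample indices; defaults to `0:(n-1)`.
#' @return An object of class `frame_sequence` with elements `grid`, `frames`
#'   (list of matrices) and `t`.
#' @export
frame_sequence <- function(frames, grid = NULL, t = NULL) {
  if (length(frames) < 1L)
    stop("frame_sequence: need at least one frame", call. = FALSE)
  if (inherits(frames[[1L]], "sensor_frame")) {
    if (is.null(grid)) grid <- frames[[1L]]$grid
    if (is.null(t)) t <- vapply(frames, function(f) f$t, integer(1L))
    frames <- lapply(frames, function(f) f$values)
  }
  if (is.null(grid)) stop("frame_sequence: 'grid' is required", call. = FALSE)
  if (is.null(t)) t <- seq_along(frames) - 1L
  t <- as.integer(t)
  if (length(t) != length(frames) || anyNA(t) || any(diff(t) <= 0L) || t[1L] < 0L)
    stop("frame_sequence: t must be strictly increasing, non-negative",
         call. = FALSE)
  for (i in seq_along(frames)) check_matrix_shape(frames[[i]], grid,
                                                  sprintf("frame %d", i - 1L))
  structure(list(grid = grid, frames = frames, t = t),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d %s frame(s) of %dx%d, t = %d..%d\n",
              length(x$frames), x$grid$role, x$grid$rows, x$grid$cols,
              x$t[1L], x$t[length(x$t)]))
  invisible(x)
}

#' Binary map of sensed points
#'
#' The unit of all downstream computation: a 0/1 matrix marking which sensor
#' cells exceeded the detection threshold after smoothing ("sensed points").
#'
#' @param cells `rows x cols` matrix with entries 0 or 1 (logical accepted).
#' @param grid A [grid_spec()].
#' @return An object of class `binary_map`.
#' @export
binary_map <- function(cells, grid) {
  if (is.logical(cells)) cells <- cells + 0L
  storage.mode(cells) <- "integer"
  check_matrix_shape(cells + 0, grid, "cells")
  if (!all(cells %in% c(0L, 1L)))
    stop("binary_map: cells must contain only 0 and 1", call. = FALSE)
  structure(list(grid = grid, cells = cells), class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %s %dx%d, %d sensed point(s)\n",
              x$grid$role, x$grid$rows, x$grid$cols, sum(x$cells)))
  invisible(x)
}

#' Mirror a binary map or frame sequence left--right
#'
#' Reverses the column order, i.e. swaps the subject's left and right sides.
#' Used throughout the tests to assert mirror equivariance of the pipeline.
#'
#' @param x A `binary_map` or `frame_sequence`.
#' @return The mirrored object of the same class.
#' @export
mirror_lr <- function(x) {
  flip <- function(m) m[, ncol(m):1L, drop = FALSE]
  if (inherits(x, "binary_map")) {
    binary_map(flip(x$cells), x$grid)
  } else if (inherits(x, "frame_sequence")) {
    frame_sequence(lapply(x$frames, flip), grid = x$grid, t = x$t)
  } else {
    stop("mirror_lr: unsupported type", call. = FALSE)
  }
}
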
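#' Segment the trunk pressure map into four sub-regions
#'
#' The trunk middle point splits the pressure map into right-chest, left-
#' chest, right-hip and left-hip quadrants. Chest rows lie strictly above
#' the waist row (toward the head end, row 0); the subject's right is the
#' side of column 0. Cells lying exactly on either middle axis belong to no
#' quadrant, which makes the four counts plus the on-axis cells an
#' exhaustive partition of the sensed points.
#'
#' @param bm Pressure [binary_map()].
#' @param axes A `middle_axes` object from [find_trunk_middle_point()].
#' @return An object of class `quadrant_counts` with integer fields `C_R`,
#'   `C_L`, `H_R`, `H_L` and `on_axis`.
#' @export
segment_trunk <- function(bm, axes) {
  stopifnot(inherits(bm, "binary_map"))
  waist <- axes$vertical_axis
  trunkcol <- axes$horizontal_axis
  if (waist < 0L || waist >= bm$grid$rows ||
      trunkcol < 0L || trunkcol >= bm$grid$cols)
    stop("segment_trunk: cross point outside grid", call. = FALSE)
  r <- row(bm$cells) - 1L
  cl <- col(bm$cells) - 1L
  s <- bm$cells == 1L
  structure(
    list(C_R = sum(s & r < waist & cl < trunkcol),
         C_L = sum(s & r < waist & cl > trunkcol),
         H_R = sum(s & r > waist & cl < trunkcol),
         H_L = sum(s & r > waist & cl > trunkcol),
         on_axis = sum(s & (r == waist | cl == trunkcol))),
    class = "quadrant_counts"
  )
}

#' Segment the leg thermal map into left, right and on-axis counts
#'
#' Columns on the column-0 side of the leg middle axis are the subject's
#' right leg region, columns on the other side the left leg region, and
#' cells in the axis column itself are counted separately (`L_MAC`). The
#' three counts always sum to the total number of sensed points.
#'
#' @param bm Thermal [binary_map()].
#' @param axis Leg middle-axis column (0-based).
#' @return An object of class `leg_counts` with integer fields `L_R`, `L_L`
#'   and `L_MAC`.
#' @export
segment_legs <- function(bm, axis) {
  stopifnot(inherits(bm, "binary_map"))
  axis <- as.integer(axis)
  if (axis < 0L || axis >= bm$grid$cols)
    stop("segment_legs: axis outside grid", call. = FALSE)
  cl <- col(bm$cells) - 1L
  s <- bm$cells == 1L
  structure(
    list(L_R = sum(s & cl < axis),
         L_L = sum(s & cl > axis),
         L_MAC = sum(s & cl == axis)),
    class = "leg_counts"
  )
}

#' Compute the symmetry features of a posture
#'
#' Four scalars summarize left--right and chest--hip balance:
#' \itemize{
#'   \item `T_D_RL = (C_R + H_R) - (C_L + H_L)`: trunk right-minus-left
#'     sensed-point difference. Near zero for supine and prone; positive
#'     for right-lateral and negative for left-lateral postures.
#'   \item `T_D_CH = (C_R + C_L) - (H_R + H_L)`: trunk chest-minus-hip
#'     difference. Near zero for supine and lateral postures; negative
#'     (hip-dominant) for prone.
#'   \item `L_D_RL = |L_R - L_L|`: absolute left--right leg imbalance.
#'     Small for straight (log) legs, large for curled (fetus) legs.
#'   \item `L_MAC`: sensed points on the leg middle axis. Large for log,
#'     small for fetus.
#' }
#'
#' @param q A `quadrant_counts` from [segment_trunk()], or `NULL` when the
#'   pressure stream is missing.
#' @param l A `leg_counts` from [segment_legs()], or `NULL` when the thermal
#'   stream is missing.
#' @return An object of class `posture_features` with fields `T_D_RL`,
#'   `T_D_CH`, `L_D_RL`, `L_MAC` (missing stream gives `NA`) and the raw
#'   counts.
#' @export
compute_features <- function(q, l) {
  structure(
    list(
      T_D_RL = if (is.null(q)) NA_integer_ else
        as.integer((q$C_R + q$H_R) - (q$C_L + q$H_L)),
      T_D_CH = if (is.null(q)) NA_integer_ else
        as.integer((q$C_R + q$C_L) - (q$H_R + q$H_L)),
      L_D_RL = if (is.null(l)) NA_integer_ else as.integer(abs(l$L_R - l$L_L)),
      L_MAC = if (is.null(l)) NA_integer_ else as.integer(l$L_MAC),
      quadrants = q, legs = l
    ),
    class = "posture_features"
  )
}

#' @export
print.posture_features <- function(x, ...) {
  cat(sprintf("<posture_features> T_D_RL=%s T_D_CH=%s L_D_RL=%s L_MAC=%s\n",
              x$T_D_RL, x$T_D_CH, x$L_D_RL, x$L_MAC))
  invisible(x)
}

#' Extract posture features from preprocessed binary maps
#'
#' Convenience wrapper chaining middle-point localization and segmentation:
#' trunk middle point and quadrant counts from the pressure map, leg middle
#' axis and leg counts from the thermal map, then [compute_features()].
#' Either map may be `NULL` (partial recording); the corresponding features
#' come back `NA`.
#'
#' @param bm_pressure Pressure [binary_map()] or `NULL`.
#' @param bm_thermal Thermal [binary_map()] or `NULL`.
#' @param cfg A [run_config()].
#' @return A `posture_features` object, with attributes `axes` (the trunk
#'   `middle_axes`) and `leg_axis` attached when available.
#' @export
extract_features <- function(bm_pressure, bm_thermal, cfg = run_config()) {
  q <- NULL
  l <- NULL
  axes <- NULL
  leg_axis <- NULL
  if (!is.null(bm_pressure)) {
    axes <- find_trunk_middle_point(bm_pressure, cfg)
    q <- segment_trunk(bm_pressure, axes)
  }
  if (!is.null(bm_thermal)) {
    la <- find_leg_middle_axis(bm_thermal, cfg)
    leg_axis <- la$axis
    l <- segment_legs(bm_thermal, leg_axis)
  }
  f <- compute_features(q, l)
  attr(f, "axes") <- axes
  attr(f, "leg_axis") <- leg_axis
  f
}
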
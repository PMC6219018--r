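#' Moving-average filter over a frame sequence
#'
#' Smooths each sensor cell independently with an N-point moving average,
#' the standard way to suppress random temporal noise (and, for the pressure
#' array, noise arising from mattress compliance) before thresholding. Cell
#' `(i, j)` of the output is the arithmetic mean of that cell over the last
#' `N` samples ending at sample `t`; during warm-up (`t < N - 1`) the mean
#' runs over the `t + 1` samples available so far, so the filter is defined
#' from the first frame on.
#'
#' @param seq A [frame_sequence()].
#' @param N Window length (integer >= 1). `N = 1` returns the raw frame.
#' @param t Positional sample index, 0-based: `0 <= t < length(seq)`.
#' @return An object of class `smoothed_frame` with elements `grid`,
#'   `values` and `t`.
#' @export
moving_average <- function(seq, N, t) {
  stopifnot(inherits(seq, "frame_sequence"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L)
    stop("moving_average: N must be an integer >= 1", call. = FALSE)
  t <- as.integer(t)
  if (is.na(t) || t < 0L || t >= length(seq$frames))
    stop(sprintf("moving_average: t=%d out of range 0..%d", t,
                 length(seq$frames) - 1L), call. = FALSE)
  lo <- max(0L, t - N + 1L)
  window <- seq$frames[(lo + 1L):(t + 1L)]
  values <- Reduce(`+`, window) / length(window)
  structure(list(grid = seq$grid, values = values, t = t),
            class = "smoothed_frame")
}

#' Threshold a smoothed frame into a binary sensed-point map
#'
#' A cell becomes a sensed point (1) when its smoothed value is strictly
#' greater than the threshold `tau`; a value exactly equal to the threshold
#' is not sensed.
#'
#' @param frame A `smoothed_frame` (or any list with `grid` and `values`).
#' @param tau Finite threshold in the frame's units (kg/cm2 or degrees C).
#' @return A [binary_map()].
#' @export
threshold_frame <- function(frame, tau) {
  if (!is.finite(tau))
    stop("threshold_frame: tau must be finite", call. = FALSE)
  binary_map(frame$values > tau, frame$grid)
}

#' Ambient-relative thermal threshold
#'
#' The thermal threshold is the per-frame median of the (smoothed) thermal
#' frame -- taken as the ambient temperature, since the body occupies a
#' minority of the 8x8 field of view -- plus a fixed offset. This keeps
#' thermal detection independent of room temperature.
#'
#' @param frame A smoothed thermal frame.
#' @param offset Offset above ambient in degrees C.
#' @return The threshold in degrees C.
#' @export
thermal_threshold <- function(frame, offset = 2.0) {
  stats::median(frame$values) + offset
}

#' Preprocess one time point of a two-stream recording
#'
#' Applies the moving-average filter and thresholding to the pressure and
#' thermal streams, each with its own threshold (fixed for pressure,
#' ambient-relative for thermal). Either stream may be `NULL`, in which case
#' the available half is processed and the result is flagged partial.
#'
#' @param pressure Pressure [frame_sequence()] or `NULL`.
#' @param thermal Thermal [frame_sequence()] or `NULL`.
#' @param cfg A [run_config()].
#' @param t Positional sample index; defaults to the last sample of the
#'   longest available stream.
#' @return A list with `pressure` and `thermal` [binary_map()]s (either may
#'   be `NULL`) and a logical `partial`.
#' @export
preprocess_recording <- function(pressure, thermal, cfg = run_config(),
                                 t = NULL) {
  if (is.null(pressure) && is.null(thermal))
    stop("preprocess_recording: both streams missing", call. = FALSE)
  if (is.null(t)) {
    n <- max(if (is.null(pressure)) 0L else length(pressure$frames),
             if (is.null(thermal)) 0L else length(thermal$frames))
    t <- n - 1L
  }
  bm_p <- NULL
  bm_t <- NULL
  if (!is.null(pressure)) {
    sm <- moving_average(pressure, cfg$maf_window, t)
    bm_p <- threshold_frame(sm, cfg$pressure_threshold)
  }
  if (!is.null(thermal)) {
    sm <- if (cfg$smooth_thermal) {
      moving_average(thermal, cfg$maf_window, t)
    } else {
      structure(list(grid = thermal$grid, values = thermal$frames[[t + 1L]],
                     t = t), class = "smoothed_frame")
    }
    bm_t <- threshold_frame(sm, thermal_threshold(sm, cfg$thermal_offset))
  }
  list(pressure = bm_p, thermal = bm_t,
       partial = is.null(bm_p) || is.null(bm_t))
}
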
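#' Sensor-deployment geometry specification
#'
#' Describes a deployed sensing array for the geometry analytics: a square
#' lattice of round pressure sensors on the bedsheet, or the overhead
#' infrared array whose pixels tile the coverage with no gap. Distances are
#' in metres; the pitch is `coverage_w / n_cols` and must exceed the sensor
#' diameter.
#'
#' @param n_rows,n_cols Sensor (or pixel) counts along each side.
#' @param coverage_w,coverage_h Sensing coverage in metres.
#' @param sensor_radius Radius of each round pressure sensor in metres
#'   (ignored for the infrared kind).
#' @param kind `"pressure_lattice"` or `"infrared_array"`.
#' @return An object of class `deployment_spec`.
#' @examples
#' fsr_7x7_deployment()
#' grid_eye_deployment()
#' @export
deployment_spec <- function(n_rows, n_cols, coverage_w, coverage_h,
                            sensor_radius = 0,
                            kind = c("pressure_lattice", "infrared_array")) {
  kind <- match.arg(kind)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L)
    stop("deployment_spec: sensor counts must be >= 1", call. = FALSE)
  if (coverage_w <= 0 || coverage_h <= 0)
    stop("deployment_spec: coverage must be > 0", call. = FALSE)
  if (sensor_radius < 0)
    stop("deployment_spec: sensor_radius must be >= 0", call. = FALSE)
  pitch <- coverage_w / n_cols
  if (kind == "pressure_lattice" && pitch <= 2 * sensor_radius)
    stop("deployment_spec: pitch must exceed the sensor diameter",
         call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         coverage_w = coverage_w, coverage_h = coverage_h,
         sensor_radius = sensor_radius, pitch = pitch, kind = kind),
    class = "deployment_spec"
  )
}

#' Reference deployments compared in the leg area
#'
#' `fsr_7x7_deployment()` is the typical sparse bedsheet layout: 7 x 7
#' round pressure sensors over 0.875 m x 0.875 m (pitch 0.125 m, sensor
#' radius 0.0125 m, giving the 0.1 m sensing gap). `grid_eye_deployment()`
#' is the overhead 8 x 8 infrared array covering 1 m x 1 m.
#'
#' @rdname deployment_spec
#' @export
fsr_7x7_deployment <- function() {
  deployment_spec(7L, 7L, 0.875, 0.875, sensor_radius = 0.0125,
                  kind = "pressure_lattice")
}

#' @rdname deployment_spec
#' @export
grid_eye_deployment <- function() {
  deployment_spec(8L, 8L, 1, 1, kind = "infrared_array")
}

#' Largest undetectable body-part area of the infrared array
#'
#' Empirical constant, in cm2: a shank was undetectable over one-fifth
#' (20 cm2) of an infrared sensing grid but detectable over one-quarter
#' (25 cm2), and two fingers (18 cm2) went undetected while three
#' (27 cm2) were seen; 25 cm2 is taken as the array's signal detection
#' threshold. This is a measurement, not a computed geometry.
#'
#' @export
INFRARED_DETECTION_THRESHOLD_CM2 <- 25

#' Spatial sensing resolution of a deployment
#'
#' Number of sensing points (or pixels) per square metre of coverage:
#' `(n_rows * n_cols) / (coverage_w * coverage_h)`.
#'
#' @param spec A [deployment_spec()].
#' @return Sensing points per m2.
#' @examples
#' spatial_resolution(fsr_7x7_deployment())  # 64
#' spatial_resolution(grid_eye_deployment()) # 64
#' @export
spatial_resolution <- function(spec) {
  stopifnot(inherits(spec, "deployment_spec"))
  (spec$n_rows * spec$n_cols) / (spec$coverage_w * spec$coverage_h)
}

#' Sensing gap of a pressure lattice
#'
#' Edge-to-edge distance between adjacent sensor disks:
#' `pitch - 2 * sensor_radius`. The infrared array has no sensing gap
#' (adjacent and diagonal pixel grids adjoin), so it returns `NA` with an
#' explanatory attribute.
#'
#' @param spec A [deployment_spec()].
#' @return Gap in metres, or `NA` for the infrared kind.
#' @export
sensing_gap <- function(spec) {
  stopifnot(inherits(spec, "deployment_spec"))
  if (spec$kind == "infrared_array") {
    out <- NA_real_
    attr(out, "reason") <- "no sensing gap in a contiguous pixel array"
    return(out)
  }
  spec$pitch - 2 * spec$sensor_radius
}

#' Signal detection threshold of a pressure lattice: max undetectable area
#'
#' The worst case for a sparse pressure lattice is a round body part
#' centred in a sensing grid cell, grown until it touches -- but does not
#' overlap -- the four corner sensor disks. Its radius is the centre-to-
#' corner distance `pitch * sqrt(2) / 2` minus the sensor radius, and the
#' threshold is the area of that circle, reported in cm2:
#' `pi_value * (pitch * sqrt(2)/2 - sensor_radius)^2 * 1e4`.
#'
#' @param spec A [deployment_spec()] of kind `pressure_lattice`.
#' @param pi_value Value used for pi. Defaults to `base::pi`; `3.14`
#'   reproduces the two-decimal rounded constant commonly quoted for the
#'   7 x 7 reference deployment (180.83 cm2 instead of 180.93 cm2).
#' @return Area in cm2.
#' @examples
#' max_undetectable_area(fsr_7x7_deployment(), pi_value = 3.14)  # 180.83
#' @export
max_undetectable_area <- function(spec, pi_value = pi) {
  stopifnot(inherits(spec, "deployment_spec"))
  if (spec$kind != "pressure_lattice")
    stop("max_undetectable_area: defined for pressure lattices only; the infrared array threshold is the empirical constant INFRARED_DETECTION_THRESHOLD_CM2",
         call. = FALSE)
  r <- spec$pitch * sqrt(2) / 2 - spec$sensor_radius
  if (r <= 0)
    stop("max_undetectable_area: sensors overlap the cell diagonal",
         call. = FALSE)
  pi_value * r^2 * 1e4
}

#' Side-by-side comparison of two deployments
#'
#' Tabulates sensor count, spatial resolution, sensing gap and signal
#' detection threshold for two deployments, and names the deployment with
#' the smaller threshold as the better one (smaller undetectable area is
#' better).
#'
#' @param a,b [deployment_spec()]s.
#' @param pi_value Passed to [max_undetectable_area()].
#' @return An object of class `deployment_comparison` (a data frame with
#'   one row per deployment) with attribute `better`.
#' @export
compare_deployments <- function(a, b, pi_value = pi) {
  one <- function(spec, name) {
    gap <- sensing_gap(spec)
    thr <- if (spec$kind == "pressure_lattice")
      max_undetectable_area(spec, pi_value) else
      INFRARED_DETECTION_THRESHOLD_CM2
    data.frame(deployment = name, kind = spec$kind,
               n_sensors = spec$n_rows * spec$n_cols,
               resolution_per_m2 = spatial_resolution(spec),
               sensing_gap_m = as.numeric(gap),
               max_undetectable_cm2 = thr,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(a, "a"), one(b, "b"))
  attr(out, "better") <- out$deployment[which.min(out$max_undetectable_cm2)]
  class(out) <- c("deployment_comparison", class(out))
  out
}

#' @export
print.deployment_comparison <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  df$sensing_gap_m <- ifelse(is.na(df$sensing_gap_m), "N/A",
                             format(df$sensing_gap_m))
  print(df, row.names = FALSE)
  cat(sprintf("better (smaller max undetectable area): %s\n",
              attr(x, "better")))
  invisible(x)
}
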
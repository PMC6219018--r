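#' Run configuration
#'
#' Assembles the tunable parameters of the whole pipeline with validated
#' defaults. Every stage reads its parameters from this one object.
#'
#' Defaults: the moving-average window is `N = 10` samples; the pressure
#' detection threshold is 0.5 kg/cm2; the thermal threshold is the per-frame
#' median of the smoothed thermal frame (taken as ambient temperature) plus
#' `thermal_offset` = 2 degrees C, which keeps thermal detection scale-free
#' with respect to room temperature; fuzzy c-means uses 3 clusters per
#' projection, fuzzifier `m = 2`, stop tolerance `1e-5` on the change of the
#' objective, and at most 200 iterations; the classifier uses distance-
#' weighted k-NN with `k = 5` and weight `1/d^2`.
#'
#' @param maf_window Moving-average window length N (integer >= 1).
#' @param pressure_threshold Detection threshold for smoothed pressure values
#'   (kg/cm2).
#' @param thermal_offset Thermal detection threshold above the per-frame
#'   ambient (median) temperature, in degrees C.
#' @param smooth_thermal Apply the moving-average filter to the thermal
#'   stream as well (both streams are thresholded either way).
#' @param fcm List with `n_clusters`, `m` (> 1), `epsilon` (> 0), `max_iter`.
#' @param knn List with `k` (>= 1) and `weight_exponent` (> 0).
#' @param seed Integer seed for operations that use randomness.
#' @return An object of class `run_config`.
#' @examples
#' cfg <- run_config()
#' cfg$fcm$m
#' @export
run_config <- function(maf_window = 10L,
                       pressure_threshold = 0.5,
                       thermal_offset = 2.0,
                       smooth_thermal = TRUE,
                       fcm = list(),
                       knn = list(),
                       seed = 0L) {
  fcm_def <- list(n_clusters = 3L, m = 2, epsilon = 1e-5, max_iter = 200L)
  knn_def <- list(k = 5L, weight_exponent = 2)
  fcm <- utils::modifyList(fcm_def, fcm)
  knn <- utils::modifyList(knn_def, knn)

  maf_window <- as.integer(maf_window)
  if (is.na(maf_window) || maf_window < 1L)
    stop("run_config: 'maf_window' must be an integer >= 1", call. = FALSE)
  if (!is.finite(pressure_threshold))
    stop("run_config: 'pressure_threshold' must be finite", call. = FALSE)
  if (!is.finite(thermal_offset))
    stop("run_config: 'thermal_offset' must be finite", call. = FALSE)
  if (!is.finite(fcm$m) || fcm$m <= 1)
    stop("run_config: 'fcm$m' must be > 1", call. = FALSE)
  if (!is.finite(fcm$epsilon) || fcm$epsilon <= 0)
    stop("run_config: 'fcm$epsilon' must be > 0", call. = FALSE)
  fcm$n_clusters <- as.integer(fcm$n_clusters)
  fcm$max_iter <- as.integer(fcm$max_iter)
  if (is.na(fcm$n_clusters) || fcm$n_clusters < 1L)
    stop("run_config: 'fcm$n_clusters' must be >= 1", call. = FALSE)
  if (is.na(fcm$max_iter) || fcm$max_iter < 1L)
    stop("run_config: 'fcm$max_iter' must be >= 1", call. = FALSE)
  knn$k <- as.integer(knn$k)
  if (is.na(knn$k) || knn$k < 1L)
    stop("run_config: 'knn$k' must be an integer >= 1", call. = FALSE)
  if (!is.finite(knn$weight_exponent) || knn$weight_exponent <= 0)
    stop("run_config: 'knn$weight_exponent' must be > 0", call. = FALSE)

  structure(
    list(maf_window = maf_window,
         pressure_threshold = pressure_threshold,
         thermal_offset = thermal_offset,
         smooth_thermal = isTRUE(smooth_thermal),
         fcm = fcm, knn = knn, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML or JSON file
#'
#' Unspecified fields fall back to the [run_config()] defaults; nested lists
#' (`fcm`, `knn`) are merged field by field. Validation errors name the
#' offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` document, or `NULL` for
#'   all defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  if (!file.exists(path))
    stop(sprintf("load_config: no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop(sprintf("load_config: unsupported config format '.%s'", ext),
         call. = FALSE)
  }
  if (is.null(doc)) doc <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0L)
    stop(sprintf("load_config: unknown field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(run_config, doc)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<run_config> N=%d, tau_p=%.3g kg/cm2, tau_t=ambient+%.3g C\n",
    "  fcm: c=%d, m=%.3g, eps=%.1e, max_iter=%d\n",
    "  knn: k=%d, weight 1/d^%.3g; seed=%d\n"),
    x$maf_window, x$pressure_threshold, x$thermal_offset,
    x$fcm$n_clusters, x$fcm$m, x$fcm$epsilon, x$fcm$max_iter,
    x$knn$k, x$knn$weight_exponent, x$seed))
  invisible(x)
}

log_stage <- function(level, stage, msg, ...) {
  message(sprintf("[%s] %s: %s", toupper(level), stage, sprintf(msg, ...)))
}
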
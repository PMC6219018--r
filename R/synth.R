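#' Body model for the synthetic frame simulator
#'
#' Parametrizes the simulated sleeper. The upper body is rendered on the
#' pressure grid as a sum of 2-D Gaussian contact footprints (chest, hips,
#' a waist bridge and arm lobes); cells whose summed pressure falls below a
#' contact floor are zeroed, so every contact cell clears the detection
#' threshold at zero noise. The lower body is rendered on the thermal grid
#' as per-leg polyline traces at a fixed temperature elevation above
#' ambient. The three weight classes (around 40, 60 and 80 kg) scale both
#' the peak pressure and the footprint spread, so heavier bodies press
#' harder and cover more cells.
#'
#' @param weight_class `"light"` (around 40 kg), `"medium"` (around 60 kg)
#'   or `"heavy"` (around 80 kg).
#' @return An object of class `body_model`.
#' @export
body_model <- function(weight_class = c("medium", "light", "heavy")) {
  weight_class <- match.arg(weight_class)
  amp_scale <- switch(weight_class, light = 0.80, medium = 1.0, heavy = 1.20)
  spread_scale <- switch(weight_class, light = 0.90, medium = 1.0,
                         heavy = 1.12)
  structure(
    list(weight_class = weight_class,
         peak_pressure = 4.0 * amp_scale,   # kg/cm2 at the chest centre
         spread_scale = spread_scale,
         contact_floor = 1.0,               # kg/cm2; below this, no contact
         ambient_c = 22.0,                  # deg C
         leg_delta_c = 7.0),                # leg elevation above ambient
    class = "body_model"
  )
}

#' Jitter specification for the simulator
#'
#' Emulates the position and orientation differences between subjects and
#' nights that the middle-point procedure is designed to absorb, plus
#' sensor noise: a whole-recording integer translation and small rotation
#' of the body on each grid, per-frame additive Gaussian noise, and
#' spurious single-cell "ghost" activations.
#'
#' @param translate_rows,translate_cols Maximum absolute translation on the
#'   pressure grid, in cells (integers drawn uniformly from the range).
#'   The thermal grid uses at most 1 cell in each direction.
#' @param rotate_deg Maximum absolute body rotation in degrees.
#' @param noise_sd_pressure Per-cell, per-frame Gaussian noise sd (kg/cm2).
#' @param noise_sd_thermal Per-cell, per-frame Gaussian noise sd (deg C).
#' @param ghost_rate Probability that any cell carries a spurious
#'   activation in any single frame.
#' @param seed Optional integer; when given, generation is seeded locally
#'   so that repeated calls reproduce identical sequences.
#' @return An object of class `jitter_spec`.
#' @export
jitter_spec <- function(translate_rows = 2L, translate_cols = 1L,
                        rotate_deg = 5, noise_sd_pressure = 0.15,
                        noise_sd_thermal = 0.4, ghost_rate = 0.02,
                        seed = NULL) {
  if (translate_rows < 0 || translate_cols < 0 || rotate_deg < 0 ||
      noise_sd_pressure < 0 || noise_sd_thermal < 0)
    stop("jitter_spec: ranges must be >= 0", call. = FALSE)
  if (ghost_rate < 0 || ghost_rate > 1)
    stop("jitter_spec: ghost_rate must be in [0, 1]", call. = FALSE)
  structure(
    list(translate_rows = as.integer(translate_rows),
         translate_cols = as.integer(translate_cols),
         rotate_deg = rotate_deg,
         noise_sd_pressure = noise_sd_pressure,
         noise_sd_thermal = noise_sd_thermal,
         ghost_rate = ghost_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "jitter_spec"
  )
}

#' @rdname jitter_spec
#' @export
zero_jitter <- function() {
  jitter_spec(translate_rows = 0L, translate_cols = 0L, rotate_deg = 0,
              noise_sd_pressure = 0, noise_sd_thermal = 0, ghost_rate = 0)
}

add_blob <- function(mat, r0, c0, sr, sc, amp) {
  r <- row(mat) - 1L
  cl <- col(mat) - 1L
  mat + amp * exp(-0.5 * ((r - r0) / sr)^2 - 0.5 * ((cl - c0) / sc)^2)
}

mirror_template <- function(m) m[, ncol(m):1L, drop = FALSE]

# Upper-body pressure template on the 16x10 grid, 0-based coords, centre
# column 4, waist row 8. Fields sum Gaussian footprints; cells below the
# contact floor are zeroed so the contact mask equals (template > 0).
trunk_template <- function(kind = c("supine", "prone", "right_lateral"),
                           body) {
  kind <- match.arg(kind)
  s <- body$spread_scale
  A <- body$peak_pressure
  m <- matrix(0, 16L, 10L)
  if (kind == "supine") {
    m <- add_blob(m, 3.5, 4, 1.6 * s, 1.8 * s, A)          # chest/shoulders
    m <- add_blob(m, 12.5, 4, 1.6 * s, 2.0 * s, 1.05 * A)  # hips
    m <- add_blob(m, 8, 4, 1.0 * s, 1.2 * s, 0.85 * A)     # waist bridge
    m <- add_blob(m, 4.5, 1, 0.85 * s, 0.55 * s, 0.60 * A)  # right arm
    m <- add_blob(m, 4.5, 7, 0.85 * s, 0.55 * s, 0.60 * A)  # left arm
  } else if (kind == "prone") {
    m <- add_blob(m, 3.5, 4, 1.3 * s, 1.3 * s, 0.85 * A)   # raised chest
    m <- add_blob(m, 13, 4, 1.3 * s, 2.4 * s, 1.20 * A)    # hips take load
    m <- add_blob(m, 8, 4, 1.0 * s, 1.2 * s, 0.95 * A)
    m <- add_blob(m, 4.5, 1, 0.85 * s, 0.55 * s, 0.60 * A)
    m <- add_blob(m, 4.5, 7, 0.85 * s, 0.55 * s, 0.60 * A)
  } else {
    # Lying on the right side: a narrow shoulder-to-hip contact line pinned
    # to the centre column, folded arms and knees pressing on the subject's
    # right (low columns) clear of the waist rows, and a light trailing-arm
    # contact on the left.
    m <- add_blob(m, 3.5, 4, 1.6 * s, 0.9 * s, 1.15 * A)   # shoulder
    m <- add_blob(m, 12.5, 4, 1.6 * s, 0.9 * s, 1.15 * A)  # hip
    m <- add_blob(m, 8, 4, 1.0 * s, 0.55 * s, 0.90 * A)    # flank/waist
    m <- add_blob(m, 5, 1.5, 0.9 * s, 0.8 * s, 0.75 * A)   # folded arms
    m <- add_blob(m, 11.5, 1.5, 0.9 * s, 0.8 * s, 0.70 * A) # knees
    m <- add_blob(m, 4.5, 7, 0.9 * s, 0.5 * s, 0.55 * A)   # trailing arm
  }
  m[m < body$contact_floor] <- 0
  pmin(m, 10)
}

# Lower-body thermal template (temperature elevation over ambient) on the
# 8x8 grid. Legs are polyline cell traces at a fixed elevation.
leg_template <- function(kind = c("straight", "log_right", "fetus_right"),
                         body) {
  kind <- match.arg(kind)
  m <- matrix(0, 8L, 8L)
  set_cells <- function(m, rows, cols) { m[rows + 1L, cols + 1L] <- body$leg_delta_c; m }
  if (kind == "straight") {
    # supine/prone: both legs straight down the middle of the field of view
    m <- set_cells(m, 0:7, 3:4)
  } else if (kind == "log_right") {
    # side-lying, straight legs: a compact 3-column band centred on col 3
    m <- set_cells(m, 0:7, 2:4)
  } else {
    # side-lying, curled legs: thighs along cols 2-3, shanks folded toward
    # the subject's front (high columns)
    m <- set_cells(m, 0:4, 2:3)
    m <- set_cells(m, 5:6, 4:7)
  }
  m
}

# Six-posture template table. Left-side postures are exact mirrors of the
# right-side constructions; ground truth carries the designed centreline
# column, waist row and leg middle axis (0-based, before jitter).
posture_template <- function(posture, body) {
  if (!posture %in% SLEEP_POSTURES)
    stop(sprintf("unknown posture '%s'", posture), call. = FALSE)
  right <- switch(posture,
    supine = list(p = trunk_template("supine", body),
                  t = leg_template("straight", body),
                  leg_axis = 3L),
    prone = list(p = trunk_template("prone", body),
                 t = leg_template("straight", body),
                 leg_axis = 3L),
    right_log = , left_log =
      list(p = trunk_template("right_lateral", body),
           t = leg_template("log_right", body), leg_axis = 3L),
    right_fetus = , left_fetus =
      list(p = trunk_template("right_lateral", body),
           t = leg_template("fetus_right", body), leg_axis = 4L)
  )
  out <- list(pressure = right$p, thermal = right$t,
              center_col = 4L, waist_row = 8L, leg_axis = right$leg_axis)
  if (startsWith(posture, "left_")) {
    out$pressure <- mirror_template(out$pressure)
    out$thermal <- mirror_template(out$thermal)
    out$center_col <- 9L - out$center_col
    out$leg_axis <- 7L - out$leg_axis
  }
  out
}

# Nearest-cell resampling of a template under translation (integer cells)
# and rotation (degrees, about the given 0-based pivot). Sub-cell rendering
# would be overkill at 16x10 / 8x8 resolution.
transform_template <- function(m, dr, dc, theta_deg, pivot) {
  if (dr == 0 && dc == 0 && theta_deg == 0) return(m)
  th <- theta_deg * pi / 180
  out <- matrix(0, nrow(m), ncol(m))
  r <- as.vector(row(out)) - 1
  cl <- as.vector(col(out)) - 1
  # inverse map: undo translation, then rotate back about the pivot
  rr <- r - dr - pivot[1L]
  cc <- cl - dc - pivot[2L]
  sr <- round(cos(th) * rr + sin(th) * cc + pivot[1L])
  sc <- round(-sin(th) * rr + cos(th) * cc + pivot[2L])
  ok <- sr >= 0 & sr < nrow(m) & sc >= 0 & sc < ncol(m)
  out[cbind(r[ok] + 1, cl[ok] + 1)] <- m[cbind(sr[ok] + 1, sc[ok] + 1)]
  out
}

#' Generate one labelled synthetic recording
#'
#' Renders the posture's deterministic body template, applies one
#' whole-recording positional/orientation jitter, and emits `n_frames`
#' frames with per-frame Gaussian sensor noise and ghost activations. The
#' returned ground truth carries everything the pipeline is supposed to
#' recover: the label, the body centreline column and waist row on the
#' pressure grid, the leg middle axis on the thermal grid, and the
#' zero-noise contact masks of both arrays.
#'
#' @param posture One of the six [SLEEP_POSTURES].
#' @param body A [body_model()].
#' @param jitter A [jitter_spec()]; use [zero_jitter()] for noiseless
#'   template recordings.
#' @param n_frames Frames per stream (>= 1).
#' @return A list with `pressure` and `thermal` [frame_sequence()]s and
#'   `truth` (a list with `label`, `weight_class`, `center_col`,
#'   `waist_row`, `leg_axis`, `pressure_mask`, `thermal_mask`).
#' @export
generate_frame <- function(posture, body = body_model(),
                           jitter = jitter_spec(), n_frames = 12L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L)
    stop("generate_frame: n_frames must be >= 1", call. = FALSE)
  if (!is.null(jitter$seed)) set.seed(jitter$seed)

  tpl <- posture_template(posture, body)

  runif_int <- function(range) {
    if (range == 0L) 0L else sample.int(2L * range + 1L, 1L) - range - 1L
  }
  dr <- runif_int(jitter$translate_rows)
  dc <- runif_int(jitter$translate_cols)
  theta <- if (jitter$rotate_deg == 0) 0 else
    stats::runif(1L, -jitter$rotate_deg, jitter$rotate_deg)
  dr_t <- runif_int(min(1L, jitter$translate_rows))
  dc_t <- runif_int(min(1L, jitter$translate_cols))

  p_tpl <- transform_template(tpl$pressure, dr, dc, theta,
                              pivot = c(tpl$waist_row, tpl$center_col))
  t_tpl <- transform_template(tpl$thermal, dr_t, dc_t, theta,
                              pivot = c(3.5, tpl$leg_axis))
  if (sum(p_tpl > 0) == 0L || sum(t_tpl > 0) == 0L)
    stop("generate_frame: jitter pushed the body off the grid",
         call. = FALSE)

  truth <- list(label = posture, weight_class = body$weight_class,
                center_col = tpl$center_col + dc,
                waist_row = tpl$waist_row + dr,
                leg_axis = tpl$leg_axis + dc_t,
                pressure_mask = (p_tpl > 0) + 0L,
                thermal_mask = (t_tpl > 0) + 0L)

  pg <- pressure_grid()
  tg <- thermal_grid()
  p_frames <- vector("list", n_frames)
  t_frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    pf <- p_tpl
    if (jitter$noise_sd_pressure > 0)
      pf <- pf + matrix(stats::rnorm(160L, 0, jitter$noise_sd_pressure),
                        16L, 10L)
    if (jitter$ghost_rate > 0) {
      g <- matrix(stats::runif(160L) < jitter$ghost_rate, 16L, 10L)
      pf[g] <- pf[g] + stats::runif(sum(g), 0.8, 2.0)
    }
    p_frames[[i]] <- pmin(pmax(pf, 0), 10)

    tf <- body$ambient_c + t_tpl
    if (jitter$noise_sd_thermal > 0)
      tf <- tf + matrix(stats::rnorm(64L, 0, jitter$noise_sd_thermal),
                        8L, 8L)
    if (jitter$ghost_rate > 0) {
      g <- matrix(stats::runif(64L) < jitter$ghost_rate, 8L, 8L)
      tf[g] <- tf[g] + stats::runif(sum(g), 3, 6)
    }
    t_frames[[i]] <- tf
  }
  list(pressure = frame_sequence(p_frames, grid = pg),
       thermal = frame_sequence(t_frames, grid = tg),
       truth = truth)
}

#' Generate a labelled, class-balanced synthetic dataset
#'
#' Produces `n_per_class` recordings for each of the six postures, cycling
#' the weight classes, under one jitter specification and one seed. With a
#' directory given, recordings are written as frame files alongside a CSV
#' labels manifest; otherwise the dataset stays in memory.
#'
#' @param n_per_class Recordings per posture (>= 1).
#' @param weights Weight classes to cycle through.
#' @param jitter A [jitter_spec()].
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @param n_frames Frames per recording.
#' @param dir Optional output directory for frame files and
#'   `manifest.csv`.
#' @return An object of class `synthetic_dataset`: a list with
#'   `recordings` (each as returned by [generate_frame()], plus `id`) and
#'   `manifest` (data frame).
#' @export
generate_dataset <- function(n_per_class, weights = c("light", "medium",
                                                      "heavy"),
                             jitter = jitter_spec(), seed = 0L,
                             n_frames = 12L, dir = NULL) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L)
    stop("generate_dataset: n_per_class must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  jitter$seed <- NULL  # one stream for the whole dataset

  recordings <- list()
  rows <- list()
  idx <- 0L
  for (posture in SLEEP_POSTURES) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      wc <- weights[((i - 1L) %% length(weights)) + 1L]
      rec <- generate_frame(posture, body_model(wc), jitter, n_frames)
      rec$id <- sprintf("rec%04d", idx)
      p_file <- ""
      t_file <- ""
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        p_file <- sprintf("%s_pressure.txt", rec$id)
        t_file <- sprintf("%s_thermal.txt", rec$id)
        write_frame_sequence(rec$pressure, file.path(dir, p_file))
        write_frame_sequence(rec$thermal, file.path(dir, t_file))
      }
      recordings[[idx]] <- rec
      rows[[idx]] <- data.frame(id = rec$id, label = posture,
                                weight_class = wc,
                                pressure_file = p_file,
                                thermal_file = t_file,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.csv"))
  structure(list(recordings = recordings, manifest = manifest,
                 jitter = jitter, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d recording(s), seed %d\n",
              length(x$recordings), x$seed))
  invisible(x)
}

#' Extract posture features for every recording of a dataset
#'
#' Runs the preprocessing and feature-extraction pipeline on each
#' recording and returns one feature row per recording.
#'
#' @param ds A `synthetic_dataset` (or list with `recordings`).
#' @param cfg A [run_config()].
#' @return Data frame with columns `id`, `T_D_RL`, `T_D_CH`, `L_D_RL`,
#'   `L_MAC`, `label`, `weight_class`.
#' @export
dataset_features <- function(ds, cfg = run_config()) {
  rows <- lapply(ds$recordings, function(rec) {
    maps <- preprocess_recording(rec$pressure, rec$thermal, cfg)
    f <- extract_features(maps$pressure, maps$thermal, cfg)
    data.frame(id = rec$id %||% NA_character_,
               T_D_RL = f$T_D_RL, T_D_CH = f$T_D_CH,
               L_D_RL = f$L_D_RL, L_MAC = f$L_MAC,
               label = rec$truth$label,
               weight_class = rec$truth$weight_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
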
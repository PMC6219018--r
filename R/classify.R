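#' Six-class and four-class posture label sets
#'
#' The six sleeping postures are the cross of trunk orientation and leg
#' shape on the lateral side: `right_log`, `right_fetus`, `supine`,
#' `prone`, `left_fetus`, `left_log`. The trunk stage distinguishes
#' `supine`, `prone`, `left_lateral`, `right_lateral`; the leg stage
#' distinguishes `log` from `fetus`.
#'
#' @name posture_labels
#' @export
SLEEP_POSTURES <- c("right_log", "right_fetus", "supine", "prone",
                    "left_fetus", "left_log")

#' @rdname posture_labels
#' @export
TRUNK_POSTURES <- c("supine", "prone", "left_lateral", "right_lateral")

#' @rdname posture_labels
#' @export
LEG_POSTURES <- c("log", "fetus")

trunk_label_of <- function(label) {
  switch(label,
         supine = "supine", prone = "prone",
         left_log = , left_fetus = "left_lateral",
         right_log = , right_fetus = "right_lateral",
         stop(sprintf("unknown posture label '%s'", label), call. = FALSE))
}

leg_label_of <- function(label) {
  switch(label,
         left_log = , right_log = "log",
         left_fetus = , right_fetus = "fetus",
         NA_character_)
}

#' Distance-weighted k-nearest-neighbour classification
#'
#' Votes among the `k` exemplars nearest to the query in Euclidean
#' distance, each weighted by `1 / d^weight_exponent`. A zero-distance
#' neighbour dominates: the query takes its label outright with score 1.
#' Class scores are normalized to sum to 1. All ties are deterministic:
#' equal distances rank by exemplar order, and an exact score tie goes to
#' the class of the lowest-indexed exemplar among the neighbours.
#'
#' @param x Numeric feature vector (length 2 here, but any dimension works).
#' @param exemplars `n x d` numeric matrix of exemplar features.
#' @param labels Character vector of exemplar labels (length `n`).
#' @param k Number of neighbours (`1 <= k <= n`).
#' @param weight_exponent Positive exponent of the inverse-distance weight.
#' @return A list with `label` and `scores` (named numeric vector over the
#'   classes present in `labels`, summing to 1).
#' @export
knn_classify <- function(x, exemplars, labels, k = 5L, weight_exponent = 2) {
  exemplars <- as.matrix(exemplars)
  n <- nrow(exemplars)
  if (n == 0L) stop("knn_classify: empty exemplar set", call. = FALSE)
  if (length(labels) != n)
    stop("knn_classify: labels must match exemplar rows", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > n)
    stop(sprintf("knn_classify: k=%d outside 1..%d", k, n), call. = FALSE)
  if (!all(is.finite(x)))
    stop("knn_classify: query features must be finite", call. = FALSE)

  classes <- unique(labels)
  d <- sqrt(colSums((t(exemplars) - as.numeric(x))^2))
  scores <- stats::setNames(numeric(length(classes)), classes)

  zero <- which(d == 0)
  if (length(zero) > 0L) {
    lab <- labels[zero[1L]]
    scores[lab] <- 1
    return(list(label = lab, scores = scores))
  }

  ord <- order(d)[seq_len(k)]          # stable: distance ties keep row order
  w <- 1 / d[ord]^weight_exponent
  for (i in seq_len(k)) scores[labels[ord[i]]] <- scores[labels[ord[i]]] + w[i]
  scores <- scores / sum(scores)

  top <- max(scores)
  tied <- names(scores)[scores >= top - 1e-12]
  lab <- if (length(tied) == 1L) tied else {
    # tie: the class of the lowest-indexed exemplar among the neighbours
    labels[ord][match(TRUE, labels[ord] %in% tied)]
  }
  list(label = lab, scores = scores)
}

#' Reference model for the two-stage posture classifier
#'
#' Stores the labelled exemplars of both k-NN stages. Trunk exemplars live
#' in the `(T_D_RL, T_D_CH)` trunk-symmetry space with the four trunk
#' labels (the lateral six-class labels pool into `left_lateral` /
#' `right_lateral`); leg exemplars live in the `(L_D_RL, L_MAC)`
#' leg-symmetry space with labels `log` / `fetus` (drawn from the four
#' lateral classes only).
#'
#' @param dataset Data frame with numeric columns `T_D_RL`, `T_D_CH`,
#'   `L_D_RL`, `L_MAC` and a character `label` column of six-class labels.
#' @param k Neighbour count used by both stages.
#' @param weight_exponent Distance-weight exponent.
#' @return An object of class `reference_model`.
#' @export
build_reference_model <- function(dataset, k = 5L, weight_exponent = 2) {
  need <- c("T_D_RL", "T_D_CH", "L_D_RL", "L_MAC", "label")
  if (!all(need %in% names(dataset)))
    stop(sprintf("build_reference_model: dataset needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!all(dataset$label %in% SLEEP_POSTURES))
    stop("build_reference_model: unknown posture label(s)", call. = FALSE)
  ok <- stats::complete.cases(dataset[, need[1:4]])
  dataset <- dataset[ok, , drop = FALSE]

  trunk_lab <- vapply(dataset$label, trunk_label_of, character(1L),
                      USE.NAMES = FALSE)
  leg_lab <- vapply(dataset$label, leg_label_of, character(1L),
                    USE.NAMES = FALSE)
  lateral <- !is.na(leg_lab)

  k <- as.integer(k)
  for (cls in TRUNK_POSTURES) {
    if (sum(trunk_lab == cls) < k)
      stop(sprintf("build_reference_model: trunk class '%s' has %d exemplar(s), need >= k=%d",
                   cls, sum(trunk_lab == cls), k), call. = FALSE)
  }
  for (cls in LEG_POSTURES) {
    if (sum(leg_lab[lateral] == cls) < k)
      stop(sprintf("build_reference_model: leg class '%s' has %d exemplar(s), need >= k=%d",
                   cls, sum(leg_lab[lateral] == cls), k), call. = FALSE)
  }
  structure(
    list(trunk_features = as.matrix(dataset[, c("T_D_RL", "T_D_CH")]),
         trunk_labels = trunk_lab,
         leg_features = as.matrix(dataset[lateral, c("L_D_RL", "L_MAC")]),
         leg_labels = leg_lab[lateral],
         k = k, weight_exponent = weight_exponent),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> %d trunk / %d leg exemplar(s), k=%d, weight 1/d^%.3g\n",
              nrow(x$trunk_features), nrow(x$leg_features), x$k,
              x$weight_exponent))
  invisible(x)
}

#' Classify the trunk posture
#'
#' k-NN in the trunk-symmetry feature space `(T_D_RL, T_D_CH)`. Supine sits
#' near the origin, prone has negative `T_D_CH`, left lateral negative
#' `T_D_RL`, right lateral positive `T_D_RL`.
#'
#' @param f A `posture_features` object.
#' @param model A [build_reference_model()] model.
#' @return A list with `label` (one of the four trunk postures) and
#'   `scores`.
#' @export
classify_trunk <- function(f, model) {
  knn_classify(c(f$T_D_RL, f$T_D_CH), model$trunk_features,
               model$trunk_labels, model$k, model$weight_exponent)
}

#' Classify the leg posture of a lateral sleeper
#'
#' k-NN in the leg-symmetry feature space `(L_D_RL, L_MAC)`: log (straight
#' legs) shows small `L_D_RL` and large `L_MAC`; fetus (curled legs) the
#' opposite.
#'
#' @inheritParams classify_trunk
#' @return A list with `label` (`"log"` or `"fetus"`) and `scores`.
#' @export
classify_legs <- function(f, model) {
  knn_classify(c(f$L_D_RL, f$L_MAC), model$leg_features,
               model$leg_labels, model$k, model$weight_exponent)
}

#' Two-stage decision-tree posture classification
#'
#' The trunk stage runs first. Supine and prone are leaves and return
#' directly; a lateral trunk result descends into the leg stage, and the
#' side is combined with the leg shape into one of `left_log`,
#' `left_fetus`, `right_log`, `right_fetus`. With leg features missing
#' (partial recording) a lateral result is returned at the trunk level and
#' flagged.
#'
#' @inheritParams classify_trunk
#' @return A list with `label` (six-class, or a trunk-level lateral label
#'   when partial), `trunk` and `legs` stage results, and `partial`.
#' @export
classify_posture <- function(f, model) {
  if (is.na(f$T_D_RL))
    stop("classify_posture: trunk features missing (no pressure stream)",
         call. = FALSE)
  trunk <- classify_trunk(f, model)
  if (trunk$label %in% c("supine", "prone"))
    return(list(label = trunk$label, trunk = trunk, legs = NULL,
                partial = FALSE))
  if (is.na(f$L_D_RL))
    return(list(label = trunk$label, trunk = trunk, legs = NULL,
                partial = TRUE))
  legs <- classify_legs(f, model)
  side <- if (trunk$label == "left_lateral") "left" else "right"
  list(label = paste(side, legs$label, sep = "_"),
       trunk = trunk, legs = legs, partial = FALSE)
}

#' Classify a two-stream recording end to end
#'
#' Full pipeline for one recording: moving-average smoothing, thresholding,
#' middle-point localization, feature extraction and two-stage
#' classification.
#'
#' @param pressure Pressure [frame_sequence()] or `NULL`.
#' @param thermal Thermal [frame_sequence()] or `NULL`.
#' @param model A `reference_model`.
#' @param cfg A [run_config()].
#' @param t Sample index to classify at; defaults to the last sample.
#' @return As [classify_posture()], plus `features`.
#' @export
classify_recording <- function(pressure, thermal, model,
                               cfg = run_config(), t = NULL) {
  maps <- preprocess_recording(pressure, thermal, cfg, t)
  f <- extract_features(maps$pressure, maps$thermal, cfg)
  out <- classify_posture(f, model)
  out$features <- f
  out$partial <- out$partial || maps$partial
  out
}

.model_cache <- new.env(parent = emptyenv())

#' Default reference model from the synthetic simulator
#'
#' No training recordings are shipped with the package; the default model
#' is built at first use from the synthetic generator: `n_per_class`
#' recordings per posture at default jitter, weight classes cycled, pushed
#' through the full pipeline to features. The build is deterministic for a
#' given seed and cached for the session.
#'
#' @param cfg A [run_config()].
#' @param n_per_class Exemplar recordings per posture class.
#' @param seed Generator seed.
#' @return A `reference_model`.
#' @export
default_reference_model <- function(cfg = run_config(), n_per_class = 50L,
                                    seed = 20181106L) {
  key <- sprintf("m_%d_%d_%d_%g", n_per_class, seed, cfg$knn$k,
                 cfg$knn$weight_exponent)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  ds <- generate_dataset(n_per_class = n_per_class, seed = seed)
  feats <- dataset_features(ds, cfg)
  model <- build_reference_model(feats, k = cfg$knn$k,
                                 weight_exponent = cfg$knn$weight_exponent)
  .model_cache[[key]] <- model
  model
}
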
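---
title: "Sleeping-posture recognition from dual sensor arrays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleeping-posture recognition from dual sensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnopose)
```

## The problem

Bed-bound and ambulatory patients alike benefit from unobtrusive sleeping-
posture monitoring: posture drives pressure-ulcer risk, interacts with sleep
apnea and reflux, and is a component of sleep-quality assessment. Cameras
raise privacy concerns and dense pressure mats are expensive, so a practical
compromise instruments the bed with a modest 16×10 force-sensing resistor
(FSR) array under the upper body (pressure in kg/cm², full scale 10) and a
single overhead 8×8 infrared thermal array (Grid-EYE) imaging the lower
body in °C. The legs contribute almost no pressure signal, which is exactly
why the thermal array replaces thousands of extra pressure sensors there.

`somnopose` implements the full recognition pipeline for this sensor pair,
a simulator that generates labelled recordings with the statistical
structure the method assumes, and the deployment-geometry analytics used to
justify the sensor layout.

## Pipeline

### Preprocessing

Each cell of each array is smoothed with an N-point moving-average filter
(default N = 10 samples) and then binarized: a cell is a *sensed point* when
its smoothed value is **strictly greater** than the detection threshold.
The pressure threshold defaults to 0.5 kg/cm²; the thermal threshold is the
per-frame median of the smoothed thermal frame — the ambient temperature,
since the body occupies a minority of the 64 pixels — plus 2 °C, which
makes thermal detection independent of room temperature. During filter
warm-up (t < N−1) the mean runs over the samples available so far; the
filter is therefore total on every frame index, a choice documented here
because the N-point definition is silent about start-up.

### Middle point and middle axis by fuzzy c-means

Subjects do not lie where you want them to. To absorb position and
orientation differences, the trunk is located from the data: the binary map
is projected into per-column (horizontal) and per-row (vertical) sensed-
point histograms, and the occupied positioning indices of each projection
are soft-clustered into three clusters by fuzzy c-means (FCM) over
(position, count) pairs. FCM minimizes

$$A = \sum_{i=1}^{n}\sum_{k=1}^{c} u_{ik}^m \lVert x_i - c_k\rVert^2,$$

with memberships `u_ik` given by the inverse-distance-ratio rule with
exponent 2/(m−1), fuzzifier m = 2 by default, and the 2-D Euclidean
distance over the position and count coordinates. (The per-point distance
is the only reading that makes the objective, the distance and the
membership rule mutually consistent.) Iteration stops when the objective
changes by less than ε = 10⁻⁵, with a cap of 200 iterations.

On a horizontal projection the flanking clusters are background and the
middle cluster (median center position) is the trunk; the occupied index
with maximal membership in that cluster is the *middle axis*. On a vertical
projection the middle cluster is the waist, between the chest cluster
(toward the head end, row 0) and the hip cluster. The trunk middle point is
the crossing of the trunk column and the waist row. The same horizontal
procedure applied to the thermal map gives the leg middle axis.

Numerical choices, all made for determinism: initialization places the c
centers evenly over the occupied index range with counts taken from the
nearest point (a seeded random initializer can be substituted); a point
coincident with a center takes membership 1 there (split across coincident
centers); membership ties defuzzify to the lowest cluster; maximum-
membership ties break to the lowest index; center-position ties to the
lowest position. Degenerate support is handled totally: fewer occupied
indices than clusters reduces c to the occupied count, and a single
occupied cluster returns its argmax-count index directly.

### Symmetry features and the two-stage classifier

The cross point cuts the trunk map into right-chest, left-chest, right-hip
and left-hip quadrants (`C_R`, `C_L`, `H_R`, `H_L`; cells on an axis belong
to no quadrant, making the partition exhaustive), and the leg axis splits
the thermal map into `L_R`, `L_L` and the on-axis count `L_MAC`. Four
scalars carry the posture signal:

* `T_D_RL = (C_R + H_R) − (C_L + H_L)` — trunk left–right balance;
* `T_D_CH = (C_R + C_L) − (H_R + H_L)` — chest–hip balance;
* `L_D_RL = |L_R − L_L|` — leg left–right imbalance;
* `L_MAC` — on-axis leg mass.

Supine sits near the origin of the (T_D_RL, T_D_CH) space; prone is
hip-dominant (T_D_CH < 0); laterals carry the sign of T_D_RL. Straight
(log) legs give small L_D_RL and large L_MAC; curled (fetus) legs the
opposite. A two-stage decision tree exploits this: a distance-weighted
k-nearest-neighbour vote (k = 5, weight 1/d², both configurable; a
zero-distance neighbour wins outright; all ties deterministic) first picks
the trunk class; supine and prone are leaves, and lateral results descend
into a second k-NN in the (L_D_RL, L_MAC) space whose log/fetus answer is
combined with the side into the six-class label. Features enter the k-NN
in raw units — positions and counts on these small grids are the same
order of magnitude, and the feature spaces are used as plotted, without
standardization.

No reference recordings are deposited anywhere, so the default exemplar
model is built from the simulator (50 recordings per posture, fixed seed,
weight classes cycled) at first use; user-supplied labelled datasets can
replace it via `build_reference_model()`.

## The simulator, and what it does and does not emulate

`generate_frame()` renders a posture-specific body template and emits
frames with per-recording positional jitter and per-frame noise. The upper
body is a sum of 2-D Gaussian contact footprints — chest, hips, a waist
bridge, and arm/knee lobes — clipped at a 1 kg/cm² contact floor so every
contact cell clears the detection threshold at zero noise; the three weight
classes (around 40, 60 and 80 kg) scale peak pressure (3.2/4.0/4.8 kg/cm²)
and footprint spread (×0.9/1.0/1.12). The lower body is a set of leg
polyline traces 7 °C above a 22 °C ambient. Lateral templates place a
narrow shoulder-to-hip contact line on the center column with folded
arms/knees pressing on the facing side; prone is encoded as hip-dominant
contact, matching the feature-space semantics the classifier relies on.
Left-side postures are exact mirrors of right-side constructions, which
the mirror-equivariance tests exploit.

Jitter defaults were chosen once as plausible study conditions: whole-
recording translation up to ±2 rows and ±1 column (±1 cell on the thermal
grid), rotation up to ±5° (nearest-cell resampling — sub-cell rendering is
overkill at 16×10 and 8×8), Gaussian sensor noise of 0.15 kg/cm² and
0.4 °C per cell per frame, and spurious single-frame "ghost" activations
at rate 0.02, which exist specifically to exercise the moving-average
filter. Recordings default to 12 frames so the 10-point window is full.

The simulator reproduces the *geometry* the method depends on — six
posture classes, three weight classes, placement variation, additive
noise — not real bodies. It does not model mattress force diffusion,
limb-position variety within a posture class, breathing or movement within
a recording, or sensor-to-sensor calibration differences. Passing tests
therefore demonstrate that the pipeline recovers what the generative model
encodes under realistic perturbation; they cannot certify accuracy on
human subjects, and the published real-subject accuracies are not
reproducible at a desk for the same reason.

## Deployment geometry

For a square lattice of round pressure sensors, `spatial_resolution()` is
sensors per m² of coverage, and `sensing_gap()` the edge-to-edge distance
`pitch − 2·radius`. The reference sparse layout (7×7 sensors over
0.875 m × 0.875 m) and the 8×8 infrared array over 1 m × 1 m both resolve
64 points/m², making the comparison fair. The sensor radius of that layout
is never printed anywhere; it is recovered as (pitch − gap)/2 =
(0.875/7 − 0.1)/2 = 0.0125 m, the only value consistent with the printed
pitch and the printed 0.1 m gap.

The *signal detection threshold* is the area of the largest round body
part that can evade every sensor: a circle centred in the sensing cell
touching the four corner sensor disks, of radius `pitch·√2/2 − radius`,
i.e. `max(A_u) = π·(pitch·√2/2 − radius)²`. With π ≈ 3.14 this is
180.83 cm² for the reference layout — the two-decimal constant usually
quoted — and 180.93 cm² with full π; `max_undetectable_area()` exposes
`pi_value` so both readings are available, and the test suite checks the
exact version against a Monte-Carlo rejection-sampling oracle. Which
rounding produced the published constant is not stated in the source; the
3.14 reading reproduces it to the last digit. The infrared array has no
sensing gap (adjacent pixel grids adjoin), and its 25 cm² threshold is an
empirical constant from shank/finger detectability measurements, stored as
`INFRARED_DETECTION_THRESHOLD_CM2`, never computed.

## Evaluation

`evaluate_dataset()` reports a six-class confusion matrix, per-class and
per-weight-class accuracies, the overall accuracy (trace over total) and
the headline average, which is the **unweighted mean of the per-weight-
class accuracies** rounded to two decimals — the convention under which
groups at 90, 85.83 and 88.33 percent average to 88.05. The acceptance
script re-derives that rule on those published group values and also runs
the full synthetic experiment: 600 recordings (100 per posture) at default
jitter, plus 300 jittered trials scoring how often the trunk column is
recovered within one cell. Problem sizes (600 and 300, 12 frames each)
keep each experiment in a few seconds while leaving binomial noise on the
reported rates well under the margins being tested.

```{r example, eval = FALSE}
cfg <- run_config()
model <- default_reference_model(cfg)
rec <- generate_frame("left_fetus", body_model("medium"),
                      jitter_spec(seed = 1), n_frames = 12)
classify_recording(rec$pressure, rec$thermal, model, cfg)$label
#> [1] "left_fetus"
```

## Known limitations

* The middle-axis rule (maximum membership in the middle cluster) follows
  the fuzzy centroid of the foreground, so on a projection whose central
  plateau is strongly peaked *and* weakly supported the argmax can land one
  index off the peak; real bodies (and the simulator) produce plateau-like
  trunk profiles for which the rule is stable, and the jittered recovery
  rate is measured rather than assumed.
* Raw-unit FCM mixes cell indices with counts; on much larger grids the
  count dimension would dominate and the optional min–max scaling flag
  would become necessary.
* The two k-NN stages are only as good as their exemplars; the shipped
  default model inherits every assumption of the simulator above.
* Sampling is an abstract index; no wall-clock timing, streaming, or
  hardware acquisition is modelled.
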
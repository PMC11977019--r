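---
title: "Methods: background elimination, tracking and evaluation in cagewatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background elimination, tracking and evaluation in cagewatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagewatch)
```

`cagewatch` provides a training-free detector for home-cage primate
video, a Kalman/Hungarian tracking layer, an IoU-based evaluation
harness, and nonparametric model-comparison statistics, all exercised on
a seeded synthetic scene generator. This vignette explains the models,
the parameters that matter, the numerical choices, and what the
synthetic tests do and do not establish.

## Background elimination

The detector assumes a **static camera** and a scene in which the
animals are the dominant moving element. Under that assumption the
static background can be recovered from the video itself:

1. sample every `stride`-th frame (default 10);
2. resize to `target_size` (default 1280×720) and blur slightly
   (Gaussian, 5×5 kernel, OpenCV-style σ = 1.1) to suppress sensor
   noise;
3. partition the samples into consecutive groups of `group_size`
   (default 120 ≈ 80 s of video at 15 fps and stride 10); within each
   group take the per-pixel, per-channel **70th percentile** to form a
   sub-background;
4. take the per-pixel median across sub-backgrounds and round to 8-bit.

The 70th percentile (rather than the median) biases each pixel towards
its brighter, scene-typical value and rejects an animal that occupies a
pixel in under roughly 30% of a group's frames. A final partial group is
kept: discarding the tail of a short video would silently change its
background. Percentiles use the *lower-value* rule (the largest data
value at or below the requested rank, index `floor((n−1)·q) + 1` into
the sorted sample) so 8-bit intensities are never interpolated; shuffling
frames within a group cannot change the result.

Foreground extraction compares each frame against a per-pixel Gaussian
whose mean is the synthesized background colour and whose variance is
**frozen** at `var_init` (default 15, intensity² units): a pixel is
foreground when its squared RGB distance exceeds
`var_threshold × var_init` (default threshold multiplier 16). Freezing
the model (learning rate 0) is a deliberate reading of the pipeline: the
background is synthesized once from the whole video, so per-frame
adaptation would only re-absorb slow-moving animals. A pixel that passes
the foreground test but looks like a darkened copy of the background —
brightness ratio in `[0.5, 1]` with small colour distortion — is
classified as shadow and mapped back to background.

Mask refinement applies morphological closing (2 iterations) then
opening (1 iteration) with a 5×5 elliptical kernel, labels 8-connected
components, fills each component's convex hull, and merges hulls that
share any pixel, iterating to a fixpoint. Clusters below `min_area`
(default 2000 px² at 1280×720, about 0.2% of the frame; scale it with
the working resolution, e.g. 125 px² at 320×180) are dropped and a tight
box is placed around each survivor. Merging overlapping hulls
reproduces a known failure mode of this detector class on purpose: two
animals in contact fuse into a single detection. The other known
failure — a motionless animal absorbed into the background — is likewise
inherent to the approach, and the test suite asserts both behaviours
rather than hiding them.

## Tracking

Each track carries a 4-dimensional constant-velocity state
(centroid `cx, cy` in px, velocity `vx, vy` in px/frame), a 4×4
covariance, the box size of its last matched detection, and a coast
counter. Per frame:

1. predict all live tracks one step (`F` = constant-velocity transition;
   process noise `Q` = discrete white-noise-acceleration form scaled by
   `process_noise`, default 1 px/frame²);
2. associate predictions to detection centroids by the Hungarian
   algorithm on Euclidean distance; assigned pairs farther apart than
   `gate_distance` (default 150 px at 1280×720) are treated as unmatched;
3. matched tracks take a Kalman measurement update
   (`measurement_noise` = 10 px standard deviation) and refresh their
   box size and score;
4. unmatched tracks **coast**: the predicted centroid is emitted with
   the carried box size, flagged `coasted`, for at most `coast_limit`
   (default 20) consecutive frames, after which the track dies;
5. unmatched detections found new tracks immediately (zero initial
   velocity, inflated velocity variance — no confirmation window, to
   keep the pipeline simple and transparent).

Coasted boxes keep the score of the last matched detection so that a
downstream confidence threshold does not silently delete fill-ins, and
they are included in scored output: the point of coasting is to repair
recall across detection gaps, which is measurable only if coasted boxes
are scored. The same mechanism propagates a vanished false positive for
up to 20 frames — the documented cost of gap-filling, asserted in the
tests. Tracking state is per-video; identities never cross videos.

## Evaluation

Scoring follows detection-benchmark convention: detections are visited
in decreasing confidence order and each claims the highest-IoU
still-unclaimed ground-truth box at IoU ≥ 0.50 (ties on IoU go to the
lower ground-truth index; greedy score-ordered matching is standard,
deterministic, and matcher choice is second-order at this IoU
threshold). Ground truth for an animal in a neighbouring cage carries an
`ignore` flag: a detection whose best remaining overlap is with an
ignored instance is discarded — neither credit nor penalty — and an
undetected ignored instance is not a false negative.

Counts are **micro-aggregated**: TP/FP/FN are summed over all frames of
a video before precision/recall/F1 are computed once, because per-frame
metrics are undefined on frames with no ground truth and averaging them
would bias the result. A 0/0 ratio (e.g. precision with no detections)
is *undefined*, propagates as `NA`, and is excluded from medians — never
coerced to 0 or 1. Per-individual scoring restricts TP/FN to that
individual while charging only globally-unmatched detections as false
positives (a detection matched to the cagemate is that animal's true
positive, not this animal's false positive).

The confidence sweep evaluates thresholds 0.50–0.95 in 0.05 steps and
selects the **arg-max of median F1** (ties to the lower threshold).
"Maximise precision and recall" needs a scalarisation; median F1 is the
natural single-number choice and coincides with the intent of reading
the knee of a median precision-versus-recall curve. Detectors without
confidences (background elimination emits score 1.0) pass every
threshold unchanged.

## Statistics

Model comparison treats videos (or individuals) as subjects and is fully
nonparametric: performance metrics on video data are bounded, skewed and
heteroscedastic, so rank procedures are the defensible default.

* **Friedman test** for k ≥ 3 models: classical statistic
  `χ² = 12/(n·k·(k+1)) · ΣRⱼ² − 3n(k+1)` on within-subject ranks
  (average ranks on ties), referred to χ² with k−1 degrees of freedom.
  The χ² reference is accurate in the rejection region at the suite's
  sizes; the tests calibrate it against a permutation null there.
* **Wilcoxon signed-rank** for pairs: zero differences dropped, average
  ranks on ties, statistic `T⁺` = rank sum of positive differences of
  (first − second), so `T⁺ = 0` means the first-listed model never
  exceeded the second. The two-sided p is **exact** up to n = 25 —
  computed by dynamic programming over the observed rank multiset, which
  equals full 2ⁿ sign-pattern enumeration and remains exact under ties —
  and a normal approximation with tie and continuity corrections beyond.
* **Benjamini–Hochberg** correction is applied within each metric's
  family of pairwise comparisons (all model pairs for one metric in one
  report), the narrowest family that reflects how the comparisons are
  read; the family composition is visible in the output table.

Subjects with an undefined metric under any model are dropped listwise
with a warning, keeping the design paired.

## The synthetic scene generator

`render_scene()` produces frames with *exact* ground truth, emulating
the challenges of real home-cage footage: textured deformable subjects
(two overlapping ellipses with phase-varying eccentricity, filled with
filtered noise so colour thresholding cannot work), waypoint motion with
optional stationary episodes, railing-bar and enrichment occlusion,
global overexposure episodes, a semi-transparent reflection overlay, a
moving non-focal animal inside a marked ignore region, and ±2-level
sensor noise. Ground-truth boxes are the tight bounds of the subject
mask *before* occluders are drawn, matching the annotation convention
that boxes include all body parts even when occluded. Scene defaults
mirror the recording conditions the toolkit targets (1280×720 at
15 fps); the fixture suite renders at 320×180 — a scale-preserving
quarter resolution — so the full test suite runs in minutes, and states
that resolution explicitly.

What the generator does **not** emulate: photorealistic appearance, fur
texture against realistic enclosures, camera repositioning or zoom,
compression artefacts, and multi-animal contact deformation. Passing
tests therefore establish algorithmic correctness — background recovery
under partial occupancy, coasting geometry, scoring rules — not
field performance on real video; absolute performance on real footage
must be measured on real, annotated recordings via the same harness.

`corrupt_detections()` turns ground truth into an imperfect detector
stream: independent dropout, uniform positional jitter, calibrated
scores (true boxes uniform on [0.72, 1.00], injected false positives on
[0.50, 0.68], giving a known separation at 0.70 for sweep tests), and
Poisson-rate false-positive injection. Neighbour (ignored) boxes are
included — a real detector sees them too, which is what makes the ignore
rule worth testing.

The canonical fixtures (`standard_fixture_suite()`) pin the study
conditions used by the end-to-end tests: `single_clean` (300 frames, one
moving subject), `single_static_subject` (motionless for the whole
video, hence absorbed), `single_overexposed`, `paired_overlap`,
`neighbour_ignore`, `dropout_gap5` (frames 50–54 deleted) and
`dropout_gap25` (frames 40–64 deleted, exceeding the 20-frame coast
limit). The static-subject fixture disables the shape-deformation phase
entirely: its purpose is a truly motionless animal (e.g. sleeping), and
edge flutter from a pulsating outline would leak motion into the
background model.

## Numerical and engineering choices

* Coordinates are 0-based, half-open (`[x_min, x_max) × [y_min, y_max)`),
  matching array indexing; a VIA rectangle `(x, y, w, h)` maps to
  `(x, y, x+w, y+h)`. Readers validate every box and refuse inverted or
  non-finite geometry rather than clamping silently.
* The detections interchange format is a diffable CSV, one row per
  detection, floats written at 6-decimal fidelity so a
  write–read–write cycle is byte-stable. Tracker fill-ins extend the
  schema with a `coasted` column that unaware readers can ignore.
* Videos are in-memory frame stacks or PNG frame directories; frame
  indices always refer to the original video positions, so
  stride-sampled frames remember where they came from.
* Hull merging is implemented by rasterising filled hulls onto a shared
  canvas and re-labelling, iterated to a fixpoint — hulls that share any
  pixel merge, which is the pixel-level reading of "overlapping hulls".
* Kalman noise defaults (`process_noise` 1 px/frame²,
  `measurement_noise` 10 px) favour smooth constant-velocity coasting on
  the spatial scales of a 1280×720 cage view; both are exposed in
  `tracker_config()` and scale with resolution.
* Degenerate inputs are defined, not accidental: empty masks refine to
  empty cluster lists, empty detection streams track to empty outputs,
  all-zero difference vectors give a degenerate Wilcoxon result
  (p = 1) with a warning, and a sweep point with no surviving detections
  is undefined and excluded from medians.

## Problem sizes

The test suite renders its scenes at 320×180: 300 frames for the
background-elimination behaviour checks, 120 frames for the tracking-gap
fixtures, 30–120 frames for unit tests. Property checks use 1000 random
box pairs against a pixel-enumeration IoU oracle, 200 random cost
matrices up to 6×6 against a brute-force assignment oracle, and 100
random Wilcoxon fixtures (n ≤ 12) against full sign-pattern enumeration.
These sizes were chosen so the whole suite completes in a few minutes on
one CPU while still exercising every qualitative behaviour the toolkit
claims.

## Known limitations

* Background elimination presumes a fixed camera and fails by design on
  motionless animals and merged nearby animals; it outputs no
  confidence, so it cannot benefit from threshold sweeps.
* The tracker has no appearance model: after a long occlusion or an
  identity swap during contact, continuity of `track_id` is not
  guaranteed and re-identification is out of scope.
* Evaluation is box-level only; mask-level IoU is deliberately not
  implemented because cross-detector comparison requires the common
  denominator of boxes.
* The scene generator's subjects are geometric, not photorealistic;
  conclusions about real-world accuracy require real annotated video.
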
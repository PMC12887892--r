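---
title: "Measuring cognitive–motor speed from foot-landmark video streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cognitive–motor speed from foot-landmark video streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepmetrics)
```

## The measurement model

The package scores a floor-target psychomotor test from two inputs: a
per-frame stream of foot landmarks (heel, ankle, foot index per foot, in
image pixels with a visibility score) and a stimulus log. Everything is
referenced to a one-frame calibration of the scene: the nine circular floor
targets as image-space polygons plus a planar homography between the floor
plane (meters, origin at the central marker) and the image (pixels, 0-based,
x right, y down).

The core assumption is planarity: the feet are scored where they meet the
floor, so a single 3×3 projective map suffices and no depth signal is
required. The price is that vertical motion is only observed through its
image-space signature, which drives several detector choices below.

Per stimulus–response cycle the pipeline measures:

* **movement onset** — the first frame after stimulus presentation at which
  the attacking foot's footprint no longer intersects the central-zone
  polygon. Requiring both suprathreshold displacement and footprint–center
  separation reconciles "completely lift the foot off the circle" with a
  2D-only view: a genuine lift reads as a fast apparent translation of the
  foot keypoints, whereas jitter in place never empties the intersection.
* **zone arrival** — the earliest stable contact of either foot whose
  footprint overlaps a peripheral zone by at least `min_overlap` of the
  footprint area, strictly between onset and the next stimulus. Contacts
  grounded to the central zone are not arrivals: stepping back onto the
  center belongs to the return phase.
* **outcome** — `correct` iff the arrival zone equals the stimulus-defined
  target; `no_response` iff no validated arrival occurs in the window.

Session metrics are VMRS (onset − presentation, seconds), DS (arrival −
onset), RC (percent correct over all scenarios; no-response counts in the
denominator but never in the VMRS/DS means) and the exploratory composite
CMS = VMRS + DS, unweighted since both terms share units.

## Calibration

Automatic region finding is a deliberately simple contrast pipeline: global
Otsu threshold (taking the sparser polarity as foreground), connected
components, then filters on circularity `4πA/P² ≥ 0.6` and area within
[0.25×, 4×] of the expected marker area. Candidate contours are replaced by
their convex hulls: the markers are circular discs, and convex zone
polygons keep the footprint–zone clipping exact (the clipper is
Sutherland–Hodgman, which requires a convex polygon on one side; the
package always clips with the convex footprint).

Labeling nine candidates is under-determined by geometry alone: the layout
has 8-fold rotational symmetry, and a floor-plane rotation composes with
any homography into an equally valid homography, so all sixteen
rotation/reflection labelings reproject exactly. Labels are therefore
anchored by a camera-orientation convention — the camera hangs upright above
the display, so P1 (floor +x) is the peripheral to the image right of the
center and P3 (floor +y, toward the display) points toward the image top.
Within that convention, assignment is minimal-total-distance (exact
branch-and-bound, ties broken in zone index order, invariant to candidate
order).

The semiautomatic fallback takes at least six clicked near-field centers
with explicit zone ids (a file/API input; the package has no GUI), fits the
homography to those, projects the remaining centers, and re-centers each
synthesized polygon onto the nearest detected region within 1.5 projected
marker radii. Homographies are estimated by the normalized DLT solved by
SVD over all correspondences — deterministic, no iteration, with the RMS
reprojection residual attached.

## Detector parameters

All pixel thresholds are defined at 1080p and scale linearly with image
height (`scale_detector_params()`).

| parameter | default | unit | role |
|---|---|---|---|
| `move_threshold` | 2 | px/frame | stillness bound on smoothed displacement |
| `stability_window` | 3 | frames | minimum still-run length |
| `retro_window` | 5 | frames | deceleration-to-rest check before a run |
| `retro_slack_px` | 0.5 | px/frame | tolerated non-monotonicity from jitter |
| `bounding_radius` | 6 | px | compactness of the still positions |
| `min_overlap` | 0.20 | fraction | footprint–zone validation floor |
| smoothing `window` | 3 | frames | centered moving average ("light" smoothing) |
| `dilation_px` | 10 | px | footprint growth around the keypoint hull |

The representative foot point is the centroid of the three landmarks —
stable against single-landmark jitter, and no landmark is privileged.
Landmarks under 0.5 visibility are dropouts; gaps of at most 5 frames are
interpolated linearly, longer gaps invalidate the affected span. The
retrospective-deceleration heuristic is operationalized as monotone
non-increasing displacement within `retro_slack_px`; with slack 0 strict
monotonicity is recovered, but under any landmark noise a strict check
rejects essentially every true stop. Two nearby still runs separated by a
single moving frame are merged before the length test.

One property worth stating precisely: the still/moving *classification* is
monotone in `move_threshold`, but the *number of events* is not — raising
the threshold can close the moving gap between two runs and merge them.
Tests assert the form that holds.

## What the simulator emulates — and what it does not

`simulate_session()` generates the study conditions end to end: a seeded
16-scenario schedule (8 offensive / 8 defensive, 1 s configuration + 2 s
visualization + 2 s response window, 80 s per sequence), an athlete standing
with the attacking foot on the central marker and the support foot 0.2 m
aside, per-trial reaction latencies and displacement durations, execution of
the intended zone with probability `accuracy_prob` (otherwise a uniformly
wrong peripheral or, with probability 0.1 within the error branch, no
movement at all), Gaussian landmark jitter and optional visibility
dropouts. Group presets carry the reported professional/university values:
reaction 0.77 ± 0.12 vs 0.96 ± 0.12 s, displacement 0.76 ± 0.11 vs
0.64 ± 0.06 s, accuracies 0.97 and 0.9375 (placing the group RC medians at
100% and 93.75%).

The ± SDs are treated as **between-athlete** dispersions: each athlete draws
a latent mean from the group distribution (truncated normal) and individual
trials scatter with within-athlete SDs of 0.08 s (reaction) and 0.06 s
(displacement). Reaction distributions in real populations are
right-skewed; the truncated normal is a declared simplification.

Kinematics are built for observability at 30 fps:

* the floor path is a minimum-jerk ease-in/ease-out translation, which
  produces exactly the deceleration-to-rest signature the retrospective
  heuristic expects;
* the airborne foot carries an image-space lift that reaches full height
  within the first tenth of the flight — the way toe-off reads on video —
  so the footprint clears the central circle within about one frame of
  movement start, and touches down at 75% of the flight so the final
  approach is governed by the horizontal deceleration alone (a symmetric
  lift profile provably breaks the monotone-deceleration heuristic: the
  last-frame drop spikes the displacement right before the still run);
* the minimum-jerk tail is truncated so the foot lands with a constant
  0.35 m/s impact velocity. An untruncated profile creeps over its last few
  pixels for several frames, leaving no observable landing frame at all;
* flight timing accounts for the measurement chain's half-window delay: a
  centered 3-frame smoother reads a sharp stop one frame late, so flights
  end one frame before `presentation + reaction + displacement` and the
  observed stop lands on the nominal instant. Ground truth records the
  physical landing frame; the exact clearance frame is recorded by running
  the footprint-versus-center geometry on the noise-free trajectory.

The simulator does **not** emulate: photorealistic appearance or a pose
model (it emits landmarks directly, so pose-estimation error enters only as
configurable jitter/dropout), gait dynamics of the support foot (it stands
still), anticipatory or corrective movements, occlusions, rolling shutter,
or lens distortion. Passing tests therefore demonstrate the correctness of
the measurement chain given landmarks of stated quality — not the quality
of any particular pose backend on real video.

## Numerical and statistical choices

* Homography estimation normalizes points (Hartley conditioning) and
  refuses configurations whose design matrix drops below rank 8.
* Polygon areas use the shoelace formula; footprint buffering is the convex
  hull of per-vertex circle samples (12 per vertex).
* The Mann–Whitney U statistic uses midranks; Z carries the tie-corrected
  variance and a continuity correction, its sign following the group order
  as passed. The two-tailed p is exact — full enumeration of the U null
  distribution via dynamic programming — for pooled samples up to 12
  without ties, and the normal approximation otherwise. `wilcox.test` is
  used in the test suite as an independent oracle, never as the
  implementation.
* Cohen's d uses the pooled SD. The d values printed alongside the
  reference group summaries (0.79, −0.71) are not reproducible from those
  summaries under this (standard) formula, which yields ≈1.58 and ≈1.34;
  the package computes the standard quantity and documents the discrepancy
  rather than matching the printed numbers. The printed parametric CIs
  differ similarly from t-based CIs computed from the printed summaries.
* Bonferroni adjustment uses m = 3 (VMRS, DS, RC; α = 0.05/3 ≈ 0.0167);
  CMS is exploratory and compared at the unadjusted level. Assumption
  gates (Shapiro–Wilk per group, Levene centered on the mean) act at 0.05;
  `force_test_mapping = TRUE` pins the fixed mapping (t for VMRS/DS,
  Mann–Whitney for RC/CMS) regardless.
* Median CIs are seeded bootstrap percentile intervals (default 10,000
  replicates) — reproducible and distribution-free.
* Degenerate inputs are values, not crashes, wherever the field expects it:
  a flat calibration frame yields zero candidates, a constant group fails
  the normality gate with a flag, a missing arrival is a `no_response`
  trial, a degenerate footprint grounds to no zone.

## Problem sizes in the test suite

The property suites run at sizes chosen to make their statistical bands
meaningful: exact Mann–Whitney agreement over every untied two-group
partition up to 6+6; contact-frame recovery over 208 simulated trials at
1 px jitter (and noise-free); type-I error of the gated pipeline over 1,000
null cohorts (3,000 primary-variable tests) against a binomial band around
α = 0.0167; and parameter recovery on a full 15 + 14 athlete cohort at the
preset group distributions, within two standard errors of the configured
means. A two-standard-error band is by construction a ~95% check per
comparison; the suite fixes its seeds and states this rather than widening
the band.

## Known limitations

* Arrival timing inherits a one-frame quantization from the smoothing
  window; on fast flights toward the near field (local scale up to
  ~225 px/m against thresholds calibrated at 1080p) about 1% of simulated
  contacts are reported two frames late.
* Zone grounding normalizes overlap by footprint area; very large
  footprints (heavy dilation at low resolution) can dilute the overlap of a
  15 cm marker below `min_overlap`.
* The onset definition requires footprint–center separation and therefore
  reads a slow foot drag later than a true lift-off would be read from a
  side view; without depth this is the conservative choice.
* A single calibration is assumed valid for the whole session (fixed
  camera); there is no drift detection.
* Lens distortion and multi-camera setups are out of scope; clicked centers
  are file inputs, not an interactive tool.
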
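---
title: "lanecam: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lanecam: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanecam)
```

lanecam re-creates, end to end and without hardware, an automated system
for collecting top-view depth images of dairy cows walking through a
narrow one-way lane: a downward-facing RGB-D sensor above the lane, a
point-of-interest (POI) trigger that starts and stops capture, a
depth-image segmentation chain, top-view morphometrics, and the
success-rate and storage accounting used to compare capture strategies.
This vignette explains the models behind each stage, the parameters that
matter, and the choices made where the design was genuinely open.

## The scene simulator

### Geometry

The camera is a pinhole looking straight down from
`height_above_ground` (default 2.75 m) above the lane floor, with an
87° × 58° field of view imaged onto 1280 × 720 pixels at 30 frames per
second. The image x-axis (columns) is the travel axis; a frame therefore
captures the head-to-tail extent of the animal along its 1280-pixel
dimension. Depth is the distance from the camera to the nearest surface,
stored as integer millimeters; a cell with no reading is an explicit `NA`
in memory and 0 in the 16-bit PNG frame store, so "no reading" can never
be confused with a zero distance.

A plane at distance $d$ from the camera is imaged at

$$\mathrm{mpp}(d) = \frac{2\,d\tan(\mathrm{fov}/2)}{\text{axis pixels}}$$

meters per pixel, strictly increasing in $d$ — the scale every metric
computation in the package uses.

The lane runs along world x from `entrance_x` (0 by convention) to
`exit_x`, with the camera above the midpoint and the centerline at
y = 0. Fence rails run along the lane edges at `rail_height` (default
1.2 m); because they sit closer to the camera they project *farther*
from the image center than their floor positions suggest, which is why
the default crop computes the rail band at the rail plane.

### The body model

A cow is a half-ellipsoid standing on the floor: length along the travel
axis, width across the lane, height peaking at `body_height` on the
topline. Legs are not modeled — the ground-truth mask is the body
footprint, which is all that the trigger, the segmentation chain and the
morphometrics ever see from above. The animal walks the centerline at
constant `speed`; it is rendered while its body center is between
entrance and exit, clipped to the lane window.

Pixels over the body read
$d = \text{floor} - 1000\,h(x,y)$ with
$h(x,y) = \text{height}\sqrt{1 - u^2 - v^2}$ the half-ellipsoid profile.
The silhouette is projected at the body's **mean back plane**, i.e. at
distance $\text{camera height} - \tfrac{2}{3}\,\text{body height}$ (the
mean surface height of a half-ellipsoid over its footprint). This is a
deliberate flat-plane approximation of the perspective silhouette, chosen
because it makes the simulator and the measurement model exactly
consistent with one another:

* the mean valid in-mask depth of a rendered animal equals the plane the
  footprint was projected at, so bounding-box extents × `mpp(mean back
  depth)` recover the configured length and width to within a few
  percent;
* a body at floor level occupies `length / mpp(floor)` pixels along the
  travel axis (±1 px), so the projection obeys the obvious floor-plane
  check;
* reported length is invariant (±2 %) to camera-height changes that keep
  the animal in frame.

An exact ray-traced ellipsoid silhouette breaks the first of these
badly (the tangent silhouette lives at depth $\sqrt{H^2 - c^2}$, not at
the mean back depth, giving a ~25 % length bias for a 1.45 m cow under a
2.75 m camera), while adding nothing the downstream stages care about.

### The noise model

Two processes are emulated, both driven by one integer seed from which
every frame derives a sub-seed deterministically:

* **Gaussian jitter** — zero-mean noise with `gaussian_sigma`
  millimeters added to every valid reading and rounded back to integer
  millimeters.
* **Dropout** — overexposed patches with no depth reading, the dominant
  failure mode on light coats under ambient light. Circular blobs
  (`dropout_blob_radius_px`) are stamped inside the animal mask, at seed
  pixels drawn from a single random permutation of the mask, until the
  lost fraction reaches `dropout_base_rate × coat_lightness`, scaled by
  `ir_cut_factor` (< 1) when the infrared cut lens is fitted. Floor
  pixels are never dropped.

Drawing blob seeds from one permutation has a property the evaluation
relies on: at equal seeds, the dropout pattern at a lower effective rate
is a *subset* of the pattern at a higher rate, so lens-on and lens-off
runs are coupled pixel by pixel and their comparison is paired in the
strongest sense.

What the simulator does **not** emulate: photorealistic RGB or infrared
dot-pattern physics, stereo-matching artifacts, legs, tails, head
posture, lateral wander within the lane, reflective wet floors, or
multiple partially overlapping animals with distinct geometry. Passing
the package's tests therefore demonstrates that the *mechanics* —
triggering, capture policies, the segmentation chain, the measurement
arithmetic and the accounting — are correct; it does not certify
segmentation accuracy on real farm imagery.

## The trigger and the capture modes

A POI is a single pixel whose depth is monitored. From the
camera-to-floor baseline (configured, or calibrated as the median of
valid readings over a stream prefix), a valid reading that drops by at
least `trigger_delta` (default 600 mm — an object at least 0.6 m tall
over the POI) fires the trigger; a valid reading back within
`release_tolerance` of the floor releases it.

Three choices here were open and are worth recording:

* **One onset rule for both modes.** The 0.6 m onset rule is stated for
  video capture; picture capture reuses it, so there is one trigger
  semantic and two capture policies.
* **`release_tolerance` = 50 mm.** "Returned to the floor distance"
  cannot mean exact equality under sensor noise; 50 mm is comfortably
  above jitter and far below any animal. It is configurable and logged
  with every run.
* **Missing readings are state-neutral**, so dropout at the POI can
  neither fire nor release the trigger. To keep a dead pixel from
  deadlocking an active recording, a watchdog force-releases after 2 s
  (configurable) of consecutive missing readings and flags the event
  truncated.

**Picture mode** captures the onset frame and schedules the remaining
`n_pictures - 1` at the configured `interval` (3 at 0.75 s or 10 at
0.15 s in the standard settings), each taken as the stream frame nearest
its scheduled time, ties toward the earlier frame. Whether the interval
is onset-to-first-picture or first-picture-immediately was not decidable
from the system description; lanecam captures at onset and spaces from
there, which is flagged here rather than asserted as the original
intent. After the set completes the mode locks out until release, so a
lingering animal produces exactly one event. **Video mode** records
every frame from onset to release, optionally capped by `max_duration`
(a 5 s cap bounds recordings of stationary animals; the cap is exact
frame arithmetic: 5 s × 30 fps = 150 frames).

## The segmentation chain

`segment_frame()` runs crop → colorize → hue threshold → largest
contour → morphological closing, with every intermediate retrievable.

* **Crop.** The primary rail exclusion and out-of-view boundary: rows
  strictly between the rail bands (computed at the rail plane), columns
  bounded by the lane footprint at floor level.
* **Colorize.** Depth maps linearly onto hue 0–240° over
  `depth_range` (default 400 mm to the floor distance) at full
  saturation/value; sentinel pixels get value 0. The ramp is strictly
  monotone, hence invertible on valid pixels.
* **Hue threshold.** Because the package owns the colorization, the hue
  band is derived from a physically meaningful *height band* (default:
  objects 0.35–2.0 m above the floor) through the ramp. Thresholding hue
  on `[h(a), h(b)]` is provably identical to thresholding depth on
  `[a, b]` for valid pixels, and the test suite asserts this equivalence
  by brute force. The exact band is configuration, tuned only on the
  simulator.
* **Largest contour.** 8-connected components; the largest is kept
  (ties broken toward the earliest component in column-major scan
  order), its boundary traced clockwise by Moore neighbor tracing.
* **Closing.** Dilation then the paired erosion with a 10 × 10 square,
  computed on a background-padded domain so the pair is exact at the
  borders; closing is extensive and fills interior holes smaller than
  the element. These binary primitives are implemented in C++ and
  verified against independent brute-force oracles because available
  labeling routines are 4-connected and even-sized structuring elements
  are handled inconsistently by general-purpose morphology functions.

Residual rail pixels inside the crop are deliberately *not* erased; rail
contamination is a grading category, not a segmentation fix-up.

## Morphometrics

Height is camera height minus the minimum valid in-mask depth (apex at
the argmin, scan-order tie-break). Length and width are the mask's
axis-aligned bounding-box extents converted with `mpp(mean valid in-mask
depth)` — the animal's surface, not the floor, is the measured plane,
and the scale depth is recorded in the output. The lane constrains travel
to the image x-axis, so a rotated box would add complexity without
information. A metric is flagged not determinable when the mask touches
the crop boundary on its axis (animal partly out of view) or when fewer
than `min_valid_frac` (default 0.5) of mask pixels carry valid depth.

## Grading and evaluation

Each image falls into exactly one of six categories — successful, failed
on quality, animal not fully in view, rail separation, quality + rail,
multiple animals — via a deterministic cascade evaluated in that
priority order (multiple-animal detection first, using the
pre-retention component statistics, since the retained mask deliberately
keeps one component). The thresholds (`component_area_floor`,
`rail_overlap_floor` 200 px, `quality_floor` 0.25 in-mask invalid
fraction, optional `min_mask_area`) are calibration-free defaults
expressed in pixels of the full-resolution camera; scaled-down test
cameras scale them accordingly. `min_mask_area` exists because heavy
dropout tends to *fragment* the threshold image rather than raise the
in-mask invalid fraction: the retained fragment looks clean but its
extents are far from the animal's, which is precisely a
"dimensions cannot be determined" failure.

Per-animal success is ambiguous in the source description ("at least two
images captured" vs "the post-segmentation image sufficient to determine
height, width and length"). lanecam adopts the conjunctive reading — at
least two images captured *and* at least one successful image — as the
default `cow_success()` rule, with the alternative readings available as
documented switches.

Percentages are rounded half-up to two decimals (`100·165/237 → 69.62`).
Storage averages print at two decimals below 5 MB and one decimal at or
above, reproducing the mixed precision such figures are conventionally
reported at (2.01 MB/cow from 476.47 MB over 237; 6.7 MB/cow from
1.35 GB over 202). One published rate (81 successful of 88) is printed at
integer precision (92 %); at two decimals the count implies 92.05, and
that is what `success_rate()` returns.

## Numerical conventions

* Integer millimeter depths everywhere; `NA` sentinel in memory, 0 on
  disk; 16-bit grayscale PNG + JSON manifest as the interchange format
  (lossless for 1–65535 mm, verified by round-trip property tests).
* 1-based inclusive pixel rectangles and indices, the native R
  convention, throughout.
* Frame file names derive from the run epoch plus the frame timestamp at
  millisecond resolution, so lexicographic order is temporal order.
* One integer seed per simulation; per-frame sub-seeds derived by a
  fixed affine map; the caller's RNG state is never disturbed.

## Problem sizes used by the tests

The test-suite and the acceptance script run entirely on simulated
scenes at reduced camera resolutions (64 × 36 to 320 × 180 pixels, 10–30
fps), which the pinhole geometry makes equivalent to full resolution up
to pixel quantization: capture-count runs use 237 and 202 passes at
64 × 36, parameter recovery uses 50 animals at 320 × 180, and the paired
lens experiment uses 100 replicate batches of 5 animals at 96 × 54.

The lens experiment deserves its own note, since its design is the one
place the package takes a position on study conditions. It uses video
capture over a 5 m lane with the POI 1.5 m from the entrance and a
light-coated herd (`coat_lightness` 0.55–0.95). Each choice has a
reason: video capture, because picture placement interacts with trigger
timing (heavier dropout delays onset, which *moves the pictures*,
confounding a paired comparison — and the published per-cow rates
themselves show the lens direction only for the 10-picture and video
settings); a 5 m lane, so the camera cone rather than the lane gate
bounds visibility and out-of-view gradings arise the way they do in a
deployed system; a deep POI, the deployment's own proposed improvement,
so the recording window overlaps the fully-in-view window; and light
coats, because the lens exists to fix overexposure on light coats — on a
dark herd there is no effect to detect and the comparison measures pure
edge noise.

## Known limitations

* The simulator's animals are rigid half-ellipsoids on a centerline;
  real top-view silhouettes (head, neck, tail, gait) are substantially
  less regular, so hue-band and grading thresholds tuned here should be
  re-tuned on real imagery before any field use.
* The half-ellipsoid apex is a single point; real topline height
  estimates need spatial smoothing against jitter (the simulator's
  jitter is small enough that the raw minimum suffices).
* Storage accounting uses actual PNG sizes when frames are persisted and
  a configurable bytes-per-frame estimate (default 0.67 MB, a typical
  compressed single-frameset size for a 1280 × 720 depth sensor)
  otherwise.
* Multi-animal frames are detected and graded, never instance-separated.
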
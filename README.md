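# lanecam

Automated top-view depth-image acquisition and morphometrics for
walk-through livestock lanes — hardware-free and fully testable.

Collecting overhead depth images of dairy cows as they walk under a
ceiling-mounted RGB-D sensor is a standard route to non-invasive body
measurements (height, width, length, and downstream traits such as body
weight and condition score). The hard part is rarely the camera: it is
the *acquisition logic* — detecting that an animal is under the sensor,
triggering capture, stopping again, and doing so unattended for hundreds
of animals a day without recording continuously — and the *evaluation* of
what fraction of animals yielded usable images at what storage cost.

lanecam implements that whole system as an R package driven by a
synthetic depth-scene simulator (or replayed frame stores), so every
stage can be developed, tested and benchmarked without a barn:

* **Scene simulation** — a pinhole camera (default 2.75 m above the
  floor, 87° × 58° field of view, 1280 × 720 px, 30 fps) over a lane
  with fence rails; cows as half-ellipsoid bodies walking at
  0.8–2.0 m/s; sensor noise as Gaussian jitter plus dropout blobs on
  light coats, with an infrared-cut-lens option that scales the dropout
  rate down. Ground truth (mask, bounding box) accompanies every frame.
* **Acquisition** — a point-of-interest (POI) trigger: a monitored pixel
  fires when its depth drops by ≥ 0.6 m (an animal has entered) and
  releases when it returns to the floor distance. Two capture policies:
  *picture mode* (3 pictures at 0.75 s or 10 at 0.15 s per trigger, then
  lock-out until release) and *video mode* (every frame from onset to
  release, optionally capped at 5 s).
* **Segmentation** — crop to the walk-through area → colorize depth into
  an HSV image over a documented monotone hue ramp → threshold on a hue
  band (equivalently, a height band above the floor) → keep the largest
  8-connected contour → morphological closing with a 10 × 10 square.
* **Morphometrics** — height = camera height − min in-mask depth;
  length/width = mask bounding-box extents × meters-per-pixel at the
  animal's mean back depth,
  `mpp(d) = 2 d tan(fov/2) / axis_px`.
* **Evaluation** — every image graded into six categories (successful;
  failed on quality; not fully in view; rail separation; quality + rail;
  multiple animals), per-cow success (≥ 2 images captured and ≥ 1
  successful), success-rate tables by lens × method, and storage
  accounting.

Depth frames persist as 16-bit grayscale PNGs (integer millimeters,
0 = no reading) with a JSON manifest; the round trip is bit-exact.

## Worked example

Simulate five cows through a 5 m lane, run three-picture capture, grade
every image and summarize:

```r
library(lanecam)

cfg <- run_config(
  camera     = list(width_px = 160L, height_px = 90L, fps = 15),
  lane       = list(exit_x = 5),
  picture    = list(n_pictures = 3, interval = 0.75),
  simulation = list(n_cows = 5, gap = 2),
  grading    = list(component_area_floor = 200),
  seed       = 11
)
res <- run_pipeline(cfg)
res$summary
#>      lens   method cows_tested n_success n_fail pct_success images_total
#> 1 without picture3           5         5      0         100           15
#>   images_success pct_images_success total_mb avg_mb_per_cow
#> 1              7              46.67    10.05           2.01
```

Five passes produced five capture events of three pictures each
(15 images). Every cow was a per-cow success (≥ 2 images captured, ≥ 1
graded successful); 7 of 15 individual images were successful — the rest
mostly catch the animal partly out of view at the start or end of the
pass, which is why multiple pictures per pass matter. Storage is
accounted at the configured 0.67 MB per persisted frame.

Individual stages are ordinary functions on ordinary objects:

```r
ev <- res$events[[1]]
ev
#> <capture_event #1> picture mode, onset t = 1.600 s, 3 frame(s), 2.01 MB

sm <- segment_frame(ev$frames[[2]], cfg$seg)
measure_body(sm$stages$cropped, sm$mask, cfg$camera)
#> <body_metrics> height 1.510 m, length 1.473 m, width 0.713 m
#>                (determinable: height, length, width)
```

This cow was simulated with height 1.51 m, length 1.54 m, width 0.75 m:
height is recovered to the millimeter; length and width land within ~5 %
(the hue band keeps surfaces at least 0.35 m above the floor, which trims
a thin low rim off the silhouette).

A thin command-line wrapper for shell use lives at
`inst/cli/lanecam.R` (`simulate`, `run`, `validate` subcommands over a
YAML config).

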
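---
title: "Methods: the trigger engine, its background model, and the synthetic benthic scene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the trigger engine, its background model, and the synthetic benthic scene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octotrigger)
```

`octotrigger` re-implements the acquisition engine of a motion-triggered
underwater camera trap as ordinary, testable R (with one compiled kernel),
decoupled from camera, strobe and power hardware behind small functional
contracts. This vignette is the package's account of the science inside it:
the detection model and its assumptions, the parameters that matter, what
the synthetic scene generator does and does not emulate, and the design
decisions taken where the design was genuinely open.

## 1. The triggered-acquisition model

A deployment is one power-up-to-shutdown run. After an initial wait the
engine either captures on a fixed interval (intervalometer mode) or senses:
every `motion_detect_interval` seconds it takes a 320 x 240 monochrome
trigger-evaluation image (TEI) and runs

> blur (5 x 5 Gaussian) → crop to `trigger_roi` → per-pixel
> mixture-of-Gaussians classification at `foreground_threshold` →
> morphological closing (3 x 3) → trigger rule,

firing a full-resolution capture and then resting `post_detection_rest`
minutes when the rule is met. Both trigger rules are strict inequalities:
*pixel_total* fires when the post-closing foreground count exceeds
`min_pixel_count`; *object_size* fires when any 8-connected component
exceeds `min_object_size` pixels. Closing is applied before **both** rules
(the foreground count is taken on the closed mask) so that the two rules
see the same mask and a logged decision can be re-derived from the stored
TEI with no hidden state.

Blur is applied to the full TEI and the crop taken afterwards; with
reflected borders and the ROI inset from the frame edge the result is
identical to cropping first with a 2-pixel apron, so the order is a
presentation choice, not a numerical one.

### The mixture-of-Gaussians background

Each ROI pixel carries K = 3 Gaussian components (weight w, mean, variance
in grey² ). Components are ranked by w/σ; the background set is the
smallest prefix of that ranking whose cumulative weight reaches the
background ratio T = 0.9 (the component that crosses T is included — with a
single component of weight 1 the background set must not be empty, or a
static scene could never converge). A pixel is background iff it matches a
background component, where the matching band is

> max(`foreground_threshold`, 2.5 σ) grey levels.

The configured threshold is printed in grey levels (0-255), so it is
honoured literally as a floor under the conventional 2.5 σ band: raising it
makes the engine strictly less sensitive, and the band never collapses
below the configured sensitivity as variances shrink. Classification uses
the pre-update model — a target must not suppress its own detection — then
the frame is absorbed: the matched component moves toward the sample at
rate α = 1/`frame_history` and its weight grows, unmatched pixels replace
their weakest component with a wide (σ² = 15²) low-weight (0.05) component
centred on the sample, and weights are renormalised. Variances are floored
at 4 grey² so bands cannot degenerate. The per-pixel sweep is a small C++
kernel; an independent scalar R oracle replicates the rules step by step in
the test suite and the two are compared to 1e-12.

K, T, the initial/replacement variance, the variance floor and the
replacement weight are not part of the engine's printed configuration;
they follow common choices in the mixture-background literature and are
surfaced as arguments of `mog_init()` for experimentation.

### Absorption dynamics, and what "recovery" can mean

With the stock history of 25 frames (α = 0.04) and T = 0.9, an occluded
pixel's background component falls out of the T-prefix after roughly
log(0.95/0.9)/α ≈ 1.3 unmatched frames: a pixel statically covered for
more than ~2-3 evaluations is absorbed into the background. This is a
property of the stock parameters, not a defect — a 25-frame memory is
*meant* to adapt within seconds, which is what keeps a drifting,
current-swept scene from saturating the trigger. Two consequences shape
the package's validation fixtures:

* a persistent step change clears well within 3 x `frame_history` frames
  (the absorption guarantee the tests pin);
* per-pixel recovery of a target mask is only meaningful for a target in
  motion, whose pixels are freshly occluded. The package's standard
  recovery fixture is therefore a transiting ellipse (20 x 10 px,
  contrast +50, 20 px/frame) over a low-noise static background; the
  engine recovers it at a mean per-frame Jaccard ≈ 0.99 (the acceptance
  suite requires ≥ 0.95). A slow or dwelling target is detected on its
  first appearance — which is what the trigger needs — but its interior
  mask dissolves as it is absorbed.

For the same reason, end-to-end trigger fixtures have targets *appear* in
the field of view (an animal swimming into frame between two 1 s
evaluations, or emerging under the camera) rather than inching in from the
frame edge: a 20 x 10 ellipse creeping in at 2 px/frame never exposes more
than ~40 fresh pixels per evaluation and legitimately stays below a 500 px
object threshold.

## 2. Configuration

`settings.cfg` is INI text with four sections (`general_settings`,
`intervalometer_settings`, `motion_detection_settings`,
`camera_configuration`). Keys are unique across sections; enum values parse
case-insensitively and are stored lower-case (files get edited on boats).
Unknown keys warn and are ignored; invalid values raise a structured
validation error naming the key and its allowed options. `write_settings()`
∘ `parse_settings()` is the identity on valid configurations (doubles are
serialized with the shortest representation that round-trips exactly).
Defaults worth calling out:

| parameter | default | units / note |
|---|---|---|
| `motion_detect_interval` | 1 | s between TEI evaluations |
| `post_detection_rest` | 5 | min of suspended sensing after a trigger |
| `max_runtime` | 60 | min; read as minutes of acquisition time (its unit is not printed anywhere authoritative; minutes matches the neighbouring rest/wait parameters) |
| `foreground_threshold` | 8 | grey levels, floor of the matching band |
| `trigger_roi` | [20, 20, 280, 200] | (left, bottom, width, height) on the 320 x 240 TEI, bottom-left origin |
| `frame_history` | 25 | frames of background memory (α = 1/25) |
| `min_object_size` / `min_pixel_count` | 500 / 10,000 | px, strict `>` |
| `low_voltage_cutoff` | 11 | V, strict `<`, checked before each cycle |
| `image_quality` | 95 | JPEG 70-100; if `image_type = png` the default becomes compression level 3 (0-9) |

The deployment layout is `<DMMDDYYYY-Thhmmss>/{settings.cfg, log.csv,
full/, tei/}`; the name comes from the simulated calendar clock at boot.
Every evaluated TEI is stored with its logged decision so trigger
performance can be rescored offline, and the battery voltage is logged with
every capture. The log alone suffices to replay the state trace
(`replay_deployment()`), which the suite verifies by replaying and
comparing. The configuration file name is standardized as `settings.cfg`
throughout (one engine description also mentions a `setup.cfg`; a single
name keeps snapshots unambiguous). The Wi-Fi power-down flag is recorded in
the boot log entry but is a no-op here, it describes a power-saving
hardware action; likewise `shutdown_at_end = false` simply returns control
to the caller (bench use).

Exit conditions are evaluated in a fixed priority order — `low_voltage`,
`disk_full` (free space under one worst-case image), `max_runtime`
(triggered mode), `max_images` (intervalometer mode) — so a log never shows
a capture after the battery crossed the cutoff. The ROI applies to the TEI
path only; full-resolution captures are stored uncropped, since the crop
exists to focus *evaluation*, not to discard image area.

## 3. Image operators

All 2-D operators are implemented in the package and checked against
independent oracles (brute-force convolution, scalar flood fill, a
reference CLAHE):

* **Gaussian blur** — separable, σ = 0.3((k−1)/2 − 1) + 0.8 for kernel
  side k (the convention imaging toolkits use when only a kernel size is
  given), symmetric-reflect borders, rounded back to 0-255. Exact on
  constants; within ±1 grey level of the brute-force oracle (rounding).
* **ROI crop** — bottom-left configuration coordinates mapped to the
  internal top-left row-major storage (`row = H − bottom − height + 1`).
* **Closing** — dilation then erosion, 3 x 3 square element, with neutral
  paddings (outside is background for dilation, foreground for erosion) so
  the all-zero and all-one masks are fixed points and closing is
  idempotent.
* **Connected components** — 8-connected (diagonal fragments of one animal
  should merge, consistent with why the mask is closed first), labelled in
  column-major first-pixel order, with sizes and bounding boxes.
* **CLAHE** — tile-wise (8 x 8) histogram equalization with clipping at
  `clip_limit` times the uniform bin height, even redistribution of the
  excess, and bilinear interpolation between tile mappings; applied to
  full-resolution captures when `auto_contrast` is on. On a constant frame
  every tile shares one mapping, so the output is spatially constant
  (though clipping may relocate the grey level).

## 4. The synthetic benthic scene

The simulator stands in for footage from a high-current seafloor site. A
scene is: a static smooth texture field (amplitude 10 grey levels) over
mean grey 120; a sinusoidal luminance drift, amplitude 6 grey levels with
an hour-scale period (3600 s) — the short end of tidal variation, fast
enough to exercise background adaptation across a 5-minute rest without
forging false triggers; and per-frame additive Gaussian sensor noise
(sd 2 grey levels), clipped to [0, 255]. Targets are hard-edged ellipses
at an exact signed contrast against the local background — no
anti-aliasing, so truth masks are exact and thresholding the noise-free
render at half contrast reproduces them bit for bit. Rendering is
deterministic: each frame draws from its own seed-derived stream, so
frames can be rendered in any order (the engine skips frames during rests)
and never disturb the session RNG.

What the simulator deliberately does **not** emulate: moving texture
(swaying kelp, sediment transport), heavy-tailed or multiplicative sensor
noise, illumination flicker, partial occlusion, and anti-aliased or
deforming target silhouettes. Passing tests therefore show that the engine
implements its model faithfully and detects clean transients at the stated
contrasts; they do not bound false-trigger rates on real footage, where
texture motion is the dominant nuisance. The generator's parameters exist
precisely so harsher regimes can be added without API changes.

## 5. Scoring

Ground truth collapses per-frame target presence into maximal windows;
walking forward in time, a window wholly inside the rest shadow cast by the
previous detectable window is flagged unmatchable and leaves the
sensitivity denominator (the engine is asleep by design, not failing).
Triggers are matched one-to-one to windows by overlap within ± one
`motion_detect_interval` (the engine's sampling granularity), greedily in
time order against the earliest-ending available window — optimal for
interval overlap, and verified against a brute-force assignment oracle.
Unmatched triggers are false; the rate is reported per deployment hour,
alongside the intervalometer-equivalent image count
`floor(hours · 3600 / interval)` that anchors the capture-economics
comparison (785 h at 2 s → 1,413,000 frames).

## 6. Problem sizes and numerical choices

The test suite runs everything at desk scale, chosen so the full suite
finishes in a few minutes: operator oracles on 16 x 16 - 32 x 32 grids
(200 seeded masks for the component oracle), mixture checks on 20 x 20
scenes and single-pixel sequences, deployment checks on 2-15 simulated
minutes, and one full 2-simulated-hour triggered deployment with five
target passes (sensitivity 1.0, ≤ 1 false trigger, at stock settings with
the runtime cap raised to cover the 2 h scene). Determinism is pinned to
the byte: two runs of the same seeded deployment must produce identical
logs and identical image files.

Numerical conventions, in one place: pixel values are stored as doubles
but always rounded and clamped to 0-255 at frame boundaries; mixture
weights are renormalised every update and checked to 1e-9; all strict
inequalities ("exceeds", "below cutoff") are implemented as printed and
pinned by boundary tests; ties in component fitness resolve to the lowest
component index, and the replacement slot prefers dead components. The
only compiled code is the per-pixel mixture sweep, where per-pixel R
vectorisation is the bottleneck of a 7,000-frame deployment.

## 7. Known limitations

* The camera, strobe and voltage models are functional stubs; exposure
  metering, gain and the "camera"-driven double-flash strobe mode are out
  of scope (the latter is hardware-specific).
* The mixture model has no shadow handling and a fixed K; fast-adapting
  stock parameters absorb dwelling animals within seconds of stillness, so
  dwell-time estimation needs the stored TEI sequence, not the live masks.
* Simulator realism is bounded as described in §4.
* `max_runtime`'s unit is asserted as minutes by analogy, not by a printed
  authority; deployments that depend on it should pin it explicitly.
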
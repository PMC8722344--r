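---
title: "Tracking-via-segmentation for row-crop monitoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking-via-segmentation for row-crop monitoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(croptrack)
```

## The problem

A monitoring robot traverses a crop row filming RGB-D at a fixed rate while
logging wheel odometry. An instance-segmentation detector marks every plant
or fruit in every frame with a super-class (plant / sweet pepper), a
fine-grained sub-class (weed species, or ripeness color), and a confidence.
The quantity a grower needs is not per-frame detections but a **per-row
summary**: how many objects of each sub-class are in the row, and how large
each one is. That requires associating detections of the same physical
object across frames — tracking-via-segmentation — plus depth-based
filtering and sizing.

Because consecutive frames of a slow row traverse are nearly static, a
full-blown tracker (Kalman filters, appearance embeddings, global
assignment) is unnecessary; the pipeline instead relies on geometric overlap
or proximity between consecutive frames, optionally compensating platform
motion explicitly through odometry.

## The tracking model

Per processed frame the tracker:

1. obtains the frame's masks from the detector interface;
2. drops masks failing the **depth window**: a mask is kept only if the
   percentage `q` of its valid-depth pixels with depth in `[τ_l, τ_h]`
   exceeds a threshold (default `q > 50`);
3. drops masks only partially visible (bounding box touching the image
   border, or inside a margin-wide entry/exit zone along the travel axis);
4. computes an affinity between every active tracklet and every surviving
   mask — pixel IoU (criterion `"iou"`), or negative centroid distance gated
   by the tracklet's **dynamic radius** (criterion `"dr"`); when
   reprojection is on, each tracklet's last mask is first warped into the
   current frame;
5. matches greedily: repeatedly take the global affinity maximum while it
   exceeds the threshold γ, record the pair, and zero that row *and* column
   (one-to-one assignment);
6. matched tracklets absorb the detection; unmatched detections spawn new
   tracklets; tracklets idle for more than α processed frames close.

The yield report then drops tracklets with fewer than `min_track_length`
matches, votes a sub-class per tracklet, and reports each tracklet's maximum
per-frame area.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `gamma` | 0.1 | IoU | published matching threshold; small because consecutive-frame overlap of moving unconstrained shapes is weak |
| `alpha` | 5 | processed frames | published keep-alive; bridges detector dropouts |
| `min_track_length` | 10 (3 when striding) | matches | published validity threshold; striding shortens an object's time on screen, hence the reduction |
| `dr_weight` | 1.0 | — | weight on the bounding-box extent; 1.0 was found optimal among 0.5 / 0.75 / 1.0 |
| `depth_window` | off; protocol sweep τ_h ∈ {1.0, 1.4, ∞}, τ_l = 0.4 m | m | 1.0 m approximates the glasshouse heat-rail distance (~1.05 m); `q > 50` |
| `fov_margin` | 20 | px | entry/exit zones; the source protocol cites prior work without numbers — 20 px is small relative to object sizes at both datasets' resolutions |
| `frame_stride` | 1 (5 for the skip protocol) | frames | emulates faster platforms / dropped frames |

### Decisions the published description leaves open

These are the package's own choices; each is exercised by tests.

* **Zeroing the matched pair.** The published pseudo-code zeroes "the
  matched set's IoU values". Zeroing only the tracklet row would let one
  detection be absorbed by two tracklets; we zero the row *and* the column,
  which is what one-to-one counting requires.
* **DR conflicts.** Nearest-inside-radius matching is described per
  tracklet. When one detection is nearest to two tracklets we resolve
  greedily by smallest distance globally — the same engine as the IoU loop
  with affinity = −distance gated by the radius.
* **Tie-breaking.** Equal affinities resolve to the lowest tracklet id,
  then the lowest candidate index, making runs bit-reproducible.
* **Tracklet reference.** Matching uses the geometry of the tracklet's most
  recent matched mask (reprojected when enabled), not a running average —
  "the last mask" semantics.
* **α counts processed frames.** Under stride 5 the skip protocol only
  reduces `min_track_length`, implying the keep-alive is interpreted in
  processed-frame units.
* **Sub-class vote.** Majority over the tracklet's history, ties to the
  most recent label; `"last"` and confidence-weighted voting are available
  (`subclass_vote`).
* **Depth filtering applies to detections, not tracklets**, so objects
  beyond the row are never allowed to seed identity.
* **W_ij convention.** The relative odometry transform is taken as
  `W_j⁻¹ W_i` (frame i expressed in frame j), so
  `H_ij = E⁻¹ W_ij E` maps old-frame camera points into the new frame —
  what tracklet reprojection needs. If real platform logs are ever
  ingested, this is the first convention to re-verify.
* **"Minimum of 10 segmentation matches"** is read as matched detections,
  not frames spanned.

## Geometry and numerics

Pixels are 0-based, `(u, v) = (column, row)`, continuous coordinates at
pixel centers. Projection is the pure pinhole model (no lens distortion —
out of scope). Reprojection back-projects every valid-depth mask pixel with
its own depth, applies the rigid transform, re-projects, and rounds to the
nearest pixel (R's round-half-to-even; the source never states a rounding
rule, and nearest minimizes drift). Pixels with invalid (zero) depth are
*skipped, not inpainted* — registered stereo depth has holes and inpainting
would invent geometry. Reprojected masks are not morphologically closed:
rounding can open 1-px holes, but both matching criteria tolerate them and
the operator stays pure. Degenerate outputs (all pixels dropped) are
returned as empty masks, which simply fail to match.

Area estimation sums `d_i²/(f_x f_y)` over mask pixels; invalid-depth
pixels contribute zero, so depth holes bias the estimate low rather than
fabricating surface. The inlier percentage `q` likewise uses valid-depth
pixels as its denominator; a mask with no valid depth gets `q = 0`
(conservatively treated as outside the window).

Bounding-box extents are inclusive pixel counts (a 1-pixel object has
extent 1), so the dynamic radius of a 1-pixel object is `dr_weight`, not 0.

## Metrics

Detection F1 is reported at the operating point where precision equals
recall; since threshold sweeps are discrete the crossing is found by linear
interpolation between adjacent operating points. Confusion matrices include
only IoU-matched pairs (≥ 0.4), which **excludes false and missed
detections and therefore inflates apparent sub-class accuracy** — read it
together with detection P/R. The instance-protocol foreground IoU averages
over the union of predicted and ground-truth instances with false/missed
detections scoring zero, which reproduces the published gap to the semantic
protocol (collapse both sides to binary maps, compute pixel-wise FG/BG
IoU). R² of counts is, by default, the coefficient of determination of the
OLS fit of predictions on ground truth; an identity-line variant is
provided because the published convention is not stated.

## The synthetic world

The simulator is first-class, tested code: it renders what the real
recordings provide (per-frame instance masks, registered depth, odometry,
intrinsics) with exact ground truth, in the two scene shapes that matter:

* **field** — ground plane at 0.8 m below a downward camera, many small
  objects, sub-class frequencies defaulting to the sugar-beet training
  distribution (heavily skewed: SB/Th/Pe dominant, Cy/An rare);
* **wall** — crop wall at 0.7 m before a sideways camera plus a
  **distractor layer** at 1.3 m (beyond the ~1.05 m heat-rail boundary)
  and background at 3 m, frequencies defaulting to the sweet-pepper
  distribution (green-dominant).

Objects are randomized ellipses with known pixel count, so each object's
true area `n_px · d²/(f_x f_y)` is exact by construction. The traverse
default (6.7 mm/frame ≈ 0.2 m/s at 30 fps) and odometry noise (2 mm/frame
std on the recorded pose; the rendered geometry stays exact) are fixed
choices of the stated world, not tuning knobs. Masks are clipped to visible
surfaces (nearer layers occlude), matching what a detector could see.
Detector corruption (dropout, centroid jitter, dilation/erosion, spurious
blobs, label flips) degrades only the detection stream, never the manifest.

**What a green test does not establish:** the simulator has no photometric
content, no plant-like silhouettes, no correlated detector failures
(occlusion-driven misses cluster in reality), no depth noise beyond i.i.d.
holes, and no odometry drift. Recovery of exact counts on clean renders
validates the *machinery* — assignment, lifecycle, reprojection algebra,
depth gating — not detector-limited field accuracy. The published
field-scale numbers (μNAE ≈ 0.047, R² ≈ 0.9 on real glasshouse rows) depend
on unreleased recordings and a trained network and are deliberately not
reproduced here; the acceptance suite instead checks the worked examples
recomputable from printed tables plus the qualitative orderings (IoU
fragments small fast objects where DR does not; under frame skips the
reprojected variants strictly dominate; the depth window removes exactly
the distractor layer).

## On-disk formats

COCO-style annotation JSON (uncompressed column-major RLE, or polygons
decoded by the even-odd rule); depth as 16-bit binary PGM in millimeters
with 0 = invalid (PGM rather than PNG because no pre-installed writer
produces 16-bit PNG; the in-memory contract is a matrix of meters);
odometry as JSONL of 4×4 row-major world-from-body transforms; calibration
as YAML; ground-truth manifests and visual count tables as validated CSV.
RGB is not rendered — nothing in the pipeline consumes it and photorealism
is a non-goal.

## Known limitations

* DR matches the nearest centroid within the radius in any direction — it
  can switch to a neighbor moving through the stored region (the published
  failure mode under clutter); direction-of-travel gating is deliberately
  not implemented.
* Greedy assignment is order-dependent by design (it mirrors the published
  algorithm); Hungarian matching is out of scope.
* Sub-class counting inherits detector label noise: per-sub-class μNAE is
  substantially worse than total μNAE in the published results, and the
  majority vote only partially mitigates it.
* The annotation loader accepts polygons but the writer always emits RLE;
  self-intersecting polygons decode with a warning.
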
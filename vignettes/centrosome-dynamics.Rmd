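---
title: "Quantifying centrosome dynamics in time-lapse movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centrosome dynamics in time-lapse movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrotrack)
```

## The measurement problem

Before mitosis the duplicated centrosomes of an adherent cell separate,
driven by the kinesin Eg5, and move along the nuclear surface until they
face each other across the nuclear diameter, roughly 10 µm apart. When Eg5
is inhibited, separated centrosomes *congress* back toward the nuclear
centroid. Flat cultured cells have a "fried egg" geometry — a thin
cytoplasmic skirt around a disk-shaped nucleus — so the whole process is
effectively two-dimensional and can be measured from 2D projections of
spinning-disk time-lapse movies taken at 5-minute intervals.

`centrotrack` turns such movies into per-cell numbers: the
inter-centrosome distance over time, separation onset and time of first
contact, per-centrosome speeds and mean-squared displacement (MSD), the
angle the two centrosomes subtend at the nuclear centroid, the alignment
of the pair's midpoint with the nucleus, nuclear-envelope (NE) contact
phases, qualitative position classes, spindle-axis rotation, EB3 comet
statistics, and line-profile quantification of perinuclear actin. A
synthetic movie generator with exact ground truth makes every stage
testable without microscopy data.

## Detection

Centrosome spots are diffraction-limited (~3 px across at 0.2 µm/px). The
detector band-passes each frame with a difference of Gaussians (sigmas
1.5 and 4.5 px, bracketing the spot scale), thresholds the filtered image
to define the background, grows candidate regions from local maxima, and
filters them by size and shape:

* **Background.** Otsu's rule (256-bin histogram; the between-class
  variance is maximized and, on plateaus, the lowest maximizing cut is
  taken) defines the background on the filtered image. Otsu presumes a
  bimodal histogram; on a frame that contains only background the rule
  would land inside the noise, so the threshold is floored at a robust
  noise level (median + 3 MAD of the filtered frame). The same floor
  (with 2 MAD) guards the DNA-channel threshold in segmentation.
* **Region growing.** Above-background pixels are partitioned among local
  maxima by a watershed on the filtered relief; maxima whose separating
  saddle is shallower than 20% of the tallest peak are merged rather than
  split. The 20% fraction is scale-free (the filtered image has arbitrary
  units) and only matters for near-touching spots.
* **Minimum size.** Regions below 15 px are discarded. The minimum is
  applied after saddle splitting.
* **Peak prominence.** A region's peak must rise at least 5 robust SDs
  above the background threshold. Chance clusters of correlated noise can
  pass a pure size test; genuine spots exceed this floor even at peak
  SNR 5, where the band-passed spot response is still ~7 noise SDs high.
* **Circularity.** `4πA/P²` with the perimeter measured by tracing the
  8-connected boundary (axial steps 1, diagonal steps √2), clipped to 1.
  Regions below 0.7 — elongated detections — are discarded. A rasterized
  disk of radius 10 px scores ≈ 0.92; a 3:1 streak scores ≈ 0.64.

Sub-pixel positions are intensity-weighted centroids over the region's
above-background response; on noiseless frames they match the rendered
truth to well under half a pixel, and to ≈ 0.25 px at SNR 5.

EB3 comets are detected separately with a scale-normalized
Laplacian-of-Gaussian detector (no circularity filter — comets are
elongated), thresholded at median + 6 MAD of the response, with
non-maximum suppression within two sigma.

## Segmentation

Nuclei (DNA channel): global threshold → disk close/open (radius 2 px,
small enough to preserve nuclear shape at these scales) → Euclidean
distance transform → Gaussian blur (sigma 2 px) → watershed, which cuts
touching nuclei; labels under a configurable minimum area (default
200 px) are dropped. Two ellipses overlapping by ~20% of their minor axis
split into exactly two labels with centroid errors under 2 px.

The cell outline (tubulin channel) is segmented from Gabor texture
energy: a bank of 4 orientations × 2 wavelengths (4 and 8 px), quadrature
magnitudes summed and smoothed, thresholded by the same Otsu rule, then
the connected component containing the nucleus is kept, filled, and
united with the nucleus mask. A manually drawn polygon can replace the
automatic outline — the practical fallback when neighbouring cells touch.
Per-frame failures (no component contains the nucleus) are flagged, and
flagged frames are excluded from cell-centroid metrics rather than
aborting the run.

Nuclear masks are tracked over time with the same linking machinery used
for spots, so each cell keeps one identity across the movie.

## Tracking

Three motion models link detections frame to frame, all with greedy
mutual-nearest assignment (candidate pairs sorted by distance to the
predicted position; ties break on the lowest spot id, then track id, so
runs are deterministic):

* `nearest` — predict the last position;
* `drift` — last position plus the last per-frame displacement;
* `kalman` — constant-velocity state with innovation gating.

Unassigned spots seed new tracks. Gaps up to `max_gap` frames are closed
with the radius scaled by the gap length; gap-closed positions are *not*
interpolated — downstream metrics use actual time lags only. On instances
with at most 4 spots per frame and displacements well below the
inter-spot separation, the greedy links coincide with the
minimum-total-distance assignment (verified against exhaustive
permutation in the test suite).

The default per-frame search radius for centrosomes is 2.5 µm: centrosome
speeds of 0.1–0.5 µm/min at 5-minute frames give per-frame displacements
up to 2.5 µm, so a radius sized to the fast EB3 regime (3 px ≈ 0.6 µm,
appropriate at second-scale intervals) would shatter tracks during active
separation. The two longest tracks within the cell mask become the
centrosome pair; the brighter track at its first frame is C1, with ties
falling back to the lower track id.

## Metrics

All metrics are computed in 2D (x, y in µm, time in minutes); a z column
is carried through but unused, matching the flat-cell reduction.

* **Distance series** — Euclidean distance at frames common to both
  tracks. Two centrosomes closer than the optical resolution merge into a
  single detection, so a congressing pair's observed series ends just
  before contact; frames where exactly one track continues within the
  contact threshold of the other's last position are appended as
  unresolved-pair rows with distance 0, and only the contact call uses
  this extension.
* **Separation onset** — first time the distance exceeds 2.5 µm and stays
  above it for 2 frames. The threshold sits above the engaged-pair
  distance regime and is configurable. Frames are phased pre / active /
  post, with the active phase ending when the distance reaches 95% of its
  post-onset plateau; cells are aligned by onset for cohort overlays.
* **Contact** — first time the distance drops below 1.5 µm for 2
  consecutive frames. 1.5 µm is roughly where two diffraction-limited
  spots become unresolvable, i.e. where "joined" is an observable
  statement; both threshold and dwell are configurable. Percent
  congression is the cumulative fraction of cells with contact by each
  time, monotone by construction.
* **Speed** — path length over elapsed time (per track), or summed
  absolute distance change over time (the approximation velocity of a
  pair); optionally restricted to a frame window such as the active
  phase. The per-centrosome separation speed is measured over the active
  window plus the arrival frame.
* **MSD** — time-averaged over all overlapping pairs at each frame lag,
  with lags capped at one third of the track length (the usual
  bias/variance compromise). Stationary tracks give identically 0;
  ballistic tracks give (vτ)² to machine precision on truth coordinates
  and within a few percent through the rendered pipeline; random walks
  recover the diffusive slope 2σ²/Δt.
* **High/low displacement grouping** — per cell, the centrosome with the
  larger MSD at the reference lag (largest common lag, capped at ⅓ track
  length) is "high"; exact ties go to C1. Cohort curves are pointwise
  mean ± SD per group.
* **Angles** — the centroid angle is the angle at the nuclear centroid
  between the vectors to each centrosome (0–180°); axis rotation is the
  acute angle between undirected axes (0–90°), e.g. the centrosome axis
  at nuclear envelope breakdown versus the spindle-pole axis at
  metaphase. Both are invariant to global translation and rotation.
* **NE contact phases** — contact is the first frame within 1 µm of the
  nucleus boundary (boundary distance is measured to the nearest boundary
  pixel of the mask); speeds are reported for the approach, the 0–20 min
  pause window after contact, and beyond.
* **Position classes** — deterministic rules standing in for visual
  scoring: detached (both beyond 3 µm from the NE, outside), diametric
  under the nucleus (angle ≥ 150° and both inside the nuclear
  projection), NE-border (both within 1 µm of the boundary, tolerance
  inclusive), else side-of-nucleus.

## Perinuclear profiles and the ring score

Line ROIs crossing the NE are sampled by bilinear interpolation (101
samples), normalized so each line's maximum is exactly 100%, registered
at the recorded NE crossing and aggregated as pointwise mean ± SD. Ring
presence is made reproducible by a prominence score: the mean intensity
in a ±1 µm annulus straddling the nucleus boundary divided by the mean in
a 2–4 µm cytoplasmic band outside it. A flat image scores ~1, and the
score is invariant to global intensity scaling; a ring is called present
above 1.5 — comfortably between the flat-image score and the ≈ 3.9
scored by the default rendered ring.

## The synthetic generator

`scene_config()` + `make_scene()` build a flat cell: an elliptical
nucleus (default semi-axes 8 × 6 µm) inside an elliptical (or polygonal)
cell outline, at 0.2 µm/px on a 120 × 120 px field, 5-minute frames.
`trajectory_program()` scripts the pair kinematics — separation to a
target distance/angle about the nuclear centroid (default 10 µm at 180°),
congression to the centroid, a stall at the NE with a programmable dwell,
stationary, or detachment — with per-centrosome speeds (asymmetric speeds
are the norm in real cells) and optional Gaussian positional jitter.
Endpoints are placed so motion toward them is radial from the start
positions; target angle θ and distance d fix the endpoint radius
d / (2 sin(θ/2)).

`render_movie()` rasterizes Gaussian spots (PSF sigma 1.5 px, consistent
with "size 3 px" spots), a DNA channel filling the nucleus, a band-pass
textured tubulin channel, optional EB3 comets nucleated at the
centrosomes moving radially outward, and an optional perinuclear actin
annulus. Poisson shot noise and Gaussian read noise are applied and
values are rounded to integer camera counts in [0, 65535] — which is also
what makes 16-bit TIFF round-trips bit-exact. Default amplitudes give
peak SNR ≈ 15 at the spots; the amplitude is the SNR knob (52 counts over
the default background ≈ SNR 5). Identical configuration and seed give
bit-identical stacks.

EB3 comets move at 15 µm/min (0.25 µm/s, the physiological plus-end
growth rate). At 5-minute frames this is unresolvable motion, exactly as
in real imaging, so EB3 scenes use second-scale intervals (e.g. 2 s =
1/30 min), keeping per-frame displacements within the 3-px comet linking
radius.

What the generator does **not** emulate: photobleaching, focus drift,
cell migration and shape change, 3D PSFs, overlapping neighbour cells,
cytoplasmic autofluorescence texture in the spot channel, and
force-based (motor-level) motion. Passing tests therefore demonstrate
correctness of the measurement pipeline under controlled imaging physics,
not robustness to every artifact of live-cell data; the configuration
surface (thresholds, radii, morphology sizes) is the intended adaptation
point for real movies.

## Problem sizes and reproducibility

The test suite and the acceptance script run cohorts sized for a single
CPU: 50-frame detection fidelity runs, 100-instance tracking-oracle and
random-walk batches, and full-pipeline cohorts of ~20 rendered movies of
22–25 frames at 120 × 120 px. Every stochastic step is seeded; the
pipeline writes a manifest (configuration hash, seed, package version,
stage counts) and identical inputs give byte-identical outputs.

## Known limitations

* The FindFoci-style detector implements the background / minimum-size /
  circularity / prominence recipe only, not the full parameter space of
  the original tool.
* Congression contact relies on the merge-extension convention described
  above; a pair that merges with a third bright object nearby could be
  mis-called (not represented in the generator).
* Gabor cell segmentation assumes textured cytoplasm over a flat
  background; it fails (and flags) on texture-free frames.
* Tracking is single-hypothesis; merge/split events beyond the
  two-centrosome merge convention are out of scope.
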
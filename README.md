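# centrotrack

Quantification of centrosome dynamics in multi-channel time-lapse
fluorescence movies of flat adherent cells, for cell biologists studying
centrosome separation, congression and nuclear positioning before
mitosis.

Before nuclear envelope breakdown the duplicated centrosomes separate
along the nuclear surface to a stable position across the nuclear
diameter (~10 µm apart, subtending close to 180° at the nuclear
centroid); after Eg5 inhibition they congress back toward the nuclear
centroid. `centrotrack` measures this from movies:

* **Detection** — difference-of-Gaussians band-pass (σ = 1.5/4.5 px) →
  Otsu background with a robust noise floor → maxima-seeded region
  growing with highest-saddle splitting → 15-px minimum size →
  circularity filter (4πA/P² ≥ 0.7); Laplacian-of-Gaussian detection for
  EB3 comets.
* **Segmentation** — threshold/morphology/distance-transform/watershed
  nuclei; Gabor-texture cell outlines with a manual-polygon override;
  centroids as reference points.
* **Tracking** — nearest-neighbour, drift, or constant-velocity Kalman
  linking with gap closing; per-cell centrosome-pair assignment.
* **Metrics** — distance d(t), separation onset and time of first
  contact, percent congression, speeds (path/Δt), time-averaged MSD with
  high/low displacement grouping, centroid angle, midpoint alignment,
  distances to nuclear/cellular centroids, NE contact phases
  (outside / 0–20 min pause / after), position classes, spindle-axis
  rotation, EB3 comet speed and MSD.
* **Profiles** — NE-crossing line profiles normalized to 100% of the
  line maximum, registered aggregation, and a reproducible perinuclear
  ring-prominence score.
* **Synthetic data** — a movie generator (scene geometry, trajectory
  programs, camera noise) with exact ground-truth tables, so every stage
  is verifiable without microscopy data.

## A worked example

Simulate one separating cell, render it, and run the full pipeline:

```r
library(centrotrack)

cfg   <- scene_config(seed = 11L)            # 120x120 px, 0.2 um/px, 5-min frames
scene <- make_scene(cfg)
prog  <- trajectory_program("separation", speeds = c(0.3, 0.3),
                            target_distance = 10, target_angle = 180)
truth <- simulate_pair(prog, scene, n_frames = 25, seed = 5)
stack <- render_movie(scene, truth, cfg)

res <- run_pipeline(stack, pipeline_config())
res$summary
#>   n_spots n_tracks analyzable final_distance_um final_angle_deg congressed contact_t_min
#> 1      49        2       TRUE          10.00133        179.8742      FALSE            NA
```

The pipeline detected 49 spots (the pair is unresolvable in frame 1,
when the centrosomes sit 1 µm apart), linked them into the two
centrosome tracks, and measured a final separation of 10.0 µm at 179.9°
— the programmed endpoint, recovered through rendering, detection,
segmentation and tracking. `res$metrics` holds the full bundle
(distance series, onset, MSDs, active-phase speeds ≈ 0.30 µm/min, ...).

A command-line driver wrapping the same functions is installed at
`inst/cli/centrotrack` (subcommands `simulate`, `detect`, `segment`,
`track`, `metrics`, `profile`, `run`).

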
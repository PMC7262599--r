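mk_track <- function(frames, x, y) data.frame(frame = frames, x = x, y = y)

test_that("distance series is symmetric and follows Pythagoras", {
  a <- mk_track(1:5, 1:5, rep(0, 5))
  expect_true(all(distance_series(a, a)$d_um == 0))
  b <- mk_track(1:5, 1:5 + 3, rep(4, 5))
  d <- distance_series(a, b)
  expect_true(all(d$d_um == 5))
  expect_identical(distance_series(a, b)$d_um, distance_series(b, a)$d_um)
  # programmed relative speed 0.2 um/min at 5-min frames: 1 um per frame
  c2 <- mk_track(1:6, 1 + (0:5), rep(0, 6))
  c1 <- mk_track(1:6, rep(1, 6), rep(0, 6))
  expect_equal(diff(distance_series(c1, c2)$d_um), rep(1, 5))
})

test_that("separation onset requires persistence above threshold", {
  d <- c(0.5, 0.5, 0.6, 0.5, 0.5, 3, 3.2, 3.4, 3.5, 3.5)
  on <- detect_separation_onset(d, onset_threshold = 2.5, persistence = 2)
  expect_equal(on$onset_frame, 6)
  expect_equal(on$phase[1:5], rep("pre", 5))
  none <- detect_separation_onset(rep(1, 10), 2.5, 2)
  expect_true(is.na(none$onset_frame))
  # a single-frame spike is not an onset
  spike <- detect_separation_onset(c(0.5, 3, 0.5, 0.5), 2.5, 2)
  expect_true(is.na(spike$onset_frame))
})

test_that("contact calls respect the dwell requirement", {
  d <- c(8, 6, 4, 2.5, 1.2, 1.1, 1.0)
  ct <- time_of_first_contact(d, contact_threshold = 1.5, dwell = 2)
  expect_equal(ct$contact_frame, 5)
  expect_true(ct$congressed)
  dip <- time_of_first_contact(c(8, 1.2, 8, 8), 1.5, 2)
  expect_false(dip$congressed)
})

test_that("percent congression is exact and monotone", {
  contacts <- c(rep(10, 5), rep(25, 9), rep(NA, 6))  # 14/20 congress
  pc <- percent_congression(contacts, times = seq(0, 60, 5))
  expect_true(all(diff(pc$percent) >= 0))
  expect_equal(max(pc$percent), 70)
  expect_equal(pc$percent[pc$t_min == 10], 25)
  none <- percent_congression(rep(NA_real_, 5), times = c(0, 10))
  expect_true(all(none$percent == 0))
  all3 <- percent_congression(rep(10, 3), times = c(10, 20))
  expect_true(all(all3$percent == 100))
})

test_that("speed is path length over time, with window restriction", {
  tr <- mk_track(1:11, c(seq(0, 8, 2), rep(8, 6)), 0)  # 0.4 um/min then 0
  expect_equal(speed(tr, frame_interval = 5), 8 / 50)
  expect_equal(speed(tr, frame_interval = 5, frames = 1:5), 0.4)
  expect_equal(speed(mk_track(1:5, 2, 3), 5), 0)
  expect_true(is.na(speed(mk_track(1, 0, 0), 5)))
})

test_that("MSD matches closed forms for stationary and ballistic motion", {
  still <- mk_track(1:20, 4, 7)
  expect_true(all(msd(still)$msd_um2 == 0))
  v <- 0.25; dt <- 5
  bal <- mk_track(1:30, v * dt * (0:29), 0)
  m <- msd(bal, max_lag = 10, frame_interval = dt)
  expect_equal(m$msd_um2, (v * m$tau_min)^2, tolerance = 1e-12)
  expect_equal(m$msd_um2[m$lag == 0], 0)
})

test_that("MSD of 2D random walks recovers the diffusive slope", {
  set.seed(21)
  sig <- 0.3
  slopes <- replicate(100, {
    n <- 80
    tr <- mk_track(1:n, cumsum(rnorm(n, sd = sig)), cumsum(rnorm(n, sd = sig)))
    m <- msd(tr, max_lag = 8, frame_interval = 1)
    stats::coef(stats::lm(msd_um2 ~ 0 + lag, data = m[m$lag > 0, ]))
  })
  expect_lt(abs(mean(slopes) - 2 * sig^2) / (2 * sig^2), 0.15)
})

test_that("displacement grouping separates mover from stayer and breaks ties", {
  mover <- msd(mk_track(1:20, (1:20) * 0.5, 0), max_lag = 6)
  stayer <- msd(mk_track(1:20, 3, 1), max_lag = 6)
  g <- displacement_grouping(list(list(c1 = stayer, c2 = mover, cell_id = 1)))
  expect_equal(g$assignment$high, "c2")
  tie <- displacement_grouping(list(list(c1 = mover, c2 = mover, cell_id = 2)))
  expect_equal(tie$assignment$high, "c1")
  hi <- g$curves[g$curves$group == "high", ]
  lo <- g$curves[g$curves$group == "low", ]
  expect_true(all(hi$mean_msd[hi$lag > 0] > lo$mean_msd[lo$lag > 0]))
})

test_that("cohorts with a 3:1 speed ratio separate into MSD groups", {
  set.seed(3)
  cells <- lapply(1:8, function(k) {
    fast <- mk_track(1:25, cumsum(rnorm(25, 0.45, 0.05)), 0)
    slow <- mk_track(1:25, cumsum(rnorm(25, 0.15, 0.05)), 0)
    if (k %% 2) list(c1 = fast, c2 = slow, cell_id = k)
    else list(c1 = slow, c2 = fast, cell_id = k)
  })
  cells <- lapply(cells, function(cl)
    list(c1 = msd(cl$c1, max_lag = 8), c2 = msd(cl$c2, max_lag = 8),
         cell_id = cl$cell_id))
  g <- displacement_grouping(cells)
  hi <- g$curves[g$curves$group == "high" & g$curves$lag > 0, ]
  lo <- g$curves[g$curves$group == "low" & g$curves$lag > 0, ]
  expect_true(all(hi$mean_msd > lo$mean_msd))
})

test_that("centroid angle handles canonical placements and invariances", {
  expect_equal(centroid_angle(c(5, 0), c(-5, 0), c(0, 0)), 180)
  expect_equal(centroid_angle(c(1, 0), c(0, 1), c(0, 0)), 90)
  # invariant under global translation and rotation
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p1 <- c(3, 1); p2 <- c(-2, 2); ctr <- c(0.5, 0.5)
  base <- centroid_angle(p1, p2, ctr)
  shift <- c(11, -4)
  expect_equal(centroid_angle(p1 + shift, p2 + shift, ctr + shift), base)
  expect_equal(centroid_angle(as.numeric(R %*% p1), as.numeric(R %*% p2),
                              as.numeric(R %*% ctr)), base)
  expect_error(centroid_angle(c(0, 0), c(1, 1), c(0, 0)), "coincides")
})

test_that("midpoint alignment distance follows vector arithmetic", {
  expect_equal(alignment_midpoint_distance(c(8, 0), c(0, 0), c(0, 0)), 4)
  expect_equal(alignment_midpoint_distance(c(5, 5), c(-5, -5), c(0, 0)), 0)
  p <- c(3, 4)
  expect_equal(alignment_midpoint_distance(p, p, c(0, 0)), 5)
})

test_that("axis rotation is the acute angle between undirected axes", {
  expect_equal(axis_rotation(c(0, 0), c(1, 0), c(5, 5), c(9, 5)), 0)
  expect_equal(axis_rotation(c(0, 0), c(1, 0), c(0, 0), c(0, 2)), 90)
  th <- 30 * pi / 180
  expect_equal(axis_rotation(c(0, 0), c(1, 0),
                             c(0, 0), c(cos(th), sin(th))), 30,
               tolerance = 1e-9)
  # undirected: flipping one axis changes nothing
  expect_equal(axis_rotation(c(0, 0), c(1, 0), c(cos(th), sin(th)), c(0, 0)),
               30, tolerance = 1e-9)
})

test_that("centroid distance series uses per-frame geometry", {
  geom <- data.frame(frame = 1:5, nuc_x_um = 0, nuc_y_um = 0,
                     cell_x_um = 2, cell_y_um = 0)
  tr <- mk_track(1:5, c(0, 1, 2, 3, 4), 0)
  cd <- centroid_distance_series(tr, geom)
  expect_equal(cd$d_nuclear_um, c(0, 1, 2, 3, 4))
  expect_equal(cd$d_cellular_um, c(2, 1, 0, 1, 2))
})

test_that("NE contact phases split speeds around the pause", {
  cfg <- test_scene_config()
  scene <- make_scene(cfg)
  prog <- trajectory_program("stall_at_NE", speeds = c(0.3, 0.3),
                             dwell_min = 20)
  tt <- simulate_pair(prog, scene, n_frames = 25, seed = 5)
  t1 <- tt[tt$centrosome_id == 1, ]
  ph <- ne_contact_phases(mk_track(t1$frame, t1$x_um, t1$y_um),
                          scene$nucleus_mask, cfg$pixel_size)
  expect_false(is.na(ph$contact_frame))
  expect_lt(ph$speeds["pause"], 0.1 * ph$speeds["outside"])
  # track never reaching the nucleus: outside speed only
  far <- mk_track(1:10, seq(0.2, 2, 0.2), 0.2)
  ph2 <- ne_contact_phases(far, scene$nucleus_mask, cfg$pixel_size)
  expect_true(is.na(ph2$contact_frame))
  expect_true(is.na(ph2$speeds["pause"]))
  # contact at the first frame: no outside phase
  ctr <- scene$nuclear_centroid
  bnd <- mk_track(1:6, unname(ctr[1] + 7.9), unname(seq(ctr[2], ctr[2] + 1, 0.2)))
  ph3 <- ne_contact_phases(bnd, scene$nucleus_mask, cfg$pixel_size)
  expect_equal(ph3$contact_frame, 1)
  expect_true(is.na(ph3$speeds["outside"]))
})

test_that("position classes follow the stated rules", {
  cfg <- test_scene_config()
  scene <- make_scene(cfg)
  ctr <- scene$nuclear_centroid
  psz <- cfg$pixel_size
  # diametric under the nucleus (angle 180, both inside projection)
  expect_equal(classify_position(ctr + c(5, 0), ctr - c(5, 0),
                                 scene$nucleus_mask, psz),
               "diametric-under-nucleus")
  # both far outside the nucleus: detached
  expect_equal(classify_position(ctr + c(11, 4), ctr + c(11, -4),
                                 scene$nucleus_mask, psz),
               "detached")
  # both within NE tolerance at a narrow angle: NE-border
  expect_equal(classify_position(ctr + c(7.8, 1), ctr + c(7.8, -1),
                                 scene$nucleus_mask, psz),
               "NE-border")
  # inside but narrow angle, away from the rim: side of nucleus
  expect_equal(classify_position(ctr + c(4, 1.5), ctr + c(4, -1.5),
                                 scene$nucleus_mask, psz),
               "side-of-nucleus")
})

test_that("merged detections extend the distance series for contact calls", {
  # pair converges then collapses into a single surviving track
  c1 <- mk_track(1:6, c(5, 4, 3, 2.2, 1.6, 1.2), 0)
  c2 <- mk_track(1:8, c(0, 0.4, 0.9, 1.0, 1.1, 1.15, 1.18, 1.2), 0)
  dm <- merge_extended_distance(c1, c2, merge_radius = 1.5)
  expect_true(all(dm$merged[dm$frame > 6]))
  expect_equal(dm$d_um[dm$frame > 6], c(0, 0))
  ct <- time_of_first_contact(dm, 1.5, 2)
  expect_true(ct$congressed)
})

test_that("comet statistics recover programmed radial speeds", {
  set.seed(8)
  tracks <- do.call(rbind, lapply(1:10, function(id) {
    n <- 8
    ang <- runif(1, 0, 2 * pi)
    step <- 0.5  # um per frame
    data.frame(track_id = id, frame = 1:n,
               x = 10 + cos(ang) * step * (1:n),
               y = 10 + sin(ang) * step * (1:n),
               spot_id = 1:n)
  }))
  cs <- comet_stats(tracks, frame_interval = 1 / 30, min_length = 4)
  expect_equal(cs$mean_speed, 0.5 * 30, tolerance = 1e-9)
  expect_equal(unname(cs$track_lengths), rep(8L, 10))
  expect_equal(cs$msd$msd_um2[cs$msd$lag == 2], (2 * 0.5)^2, tolerance = 1e-9)
})
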
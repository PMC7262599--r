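# Derived statistics on centrosome-pair tracks: distance and speed series,
# separation onset and first contact, congression percentages, MSD with
# high/low displacement grouping, angles at the nuclear centroid,
# midpoint alignment, nuclear-envelope contact phases, position classes and
# spindle-axis rotation. All metrics are 2D (x, y in um): the flat "fried
# egg" geometry of adherent cells reduces the system to two dimensions, and
# any z column is carried but unused here.

common_frames <- function(a, b) sort(intersect(a$frame, b$frame))

#' Inter-centrosome distance over time
#'
#' Euclidean distance (um) at the frames common to both tracks.
#'
#' @param track_a,track_b data.frames with `frame`, `x`, `y` in um.
#' @param frame_interval minutes per frame (for the time column).
#' @return data.frame: `frame`, `t_min`, `d_um`.
#' @export
distance_series <- function(track_a, track_b, frame_interval = 5) {
  fr <- common_frames(track_a, track_b)
  a <- track_a[match(fr, track_a$frame), ]
  b <- track_b[match(fr, track_b$frame), ]
  data.frame(frame = fr, t_min = (fr - 1) * frame_interval,
             d_um = sqrt((a$x - b$x)^2 + (a$y - b$y)^2))
}

#' Distance series extended with spot-merge events
#'
#' Two centrosomes closer than the optical resolution collapse into a
#' single detection, so a congressing pair's observed distance series ends
#' just before contact. Frames at which exactly one of the two tracks has a
#' point, with that point lying within `merge_radius` of the other track's
#' nearest observation, are appended as unresolved-pair rows with distance
#' 0 (`merged = TRUE`). Only contact calls should use the extended series;
#' MSD and speed metrics use observed positions only.
#'
#' @param track_a,track_b the assigned pair, data.frames with `frame`,
#'   `x`, `y` in um.
#' @param frame_interval minutes per frame.
#' @param merge_radius um; how close the surviving spot must be to the
#'   vanished track to count as a merge.
#' @return data.frame: `frame`, `t_min`, `d_um`, `merged`.
#' @export
merge_extended_distance <- function(track_a, track_b, frame_interval = 5,
                                    merge_radius = 1.5) {
  d <- distance_series(track_a, track_b, frame_interval)
  d$merged <- FALSE
  only <- union(setdiff(track_a$frame, track_b$frame),
                setdiff(track_b$frame, track_a$frame))
  only <- only[only > min(d$frame %||% Inf)]
  for (f in sort(only)) {
    pres <- if (f %in% track_a$frame) track_a else track_b
    miss <- if (f %in% track_a$frame) track_b else track_a
    p <- pres[match(f, pres$frame), ]
    i <- which.min(abs(miss$frame - f))
    q <- miss[i, ]
    if (sqrt((p$x - q$x)^2 + (p$y - q$y)^2) <= merge_radius)
      d <- rbind(d, data.frame(frame = f, t_min = (f - 1) * frame_interval,
                               d_um = 0, merged = TRUE))
  }
  d <- d[order(d$frame), ]
  rownames(d) <- NULL
  d
}

#' Detect the onset of centrosome separation
#'
#' Onset is the first frame at which the inter-centrosome distance exceeds
#' `onset_threshold` and stays above it for `persistence` consecutive
#' observations. Frames are phased `pre` before onset, `active` while the
#' distance still climbs toward its post-separation plateau (95% of the
#' maximum reached after onset) and `post` thereafter; this is the
#' alignment point for overlaying separation tracks from different cells.
#'
#' @param d a [distance_series()] data.frame (or numeric vector of
#'   distances).
#' @param onset_threshold um.
#' @param persistence consecutive observations required above threshold.
#' @return list: `onset_frame` (NA if never exceeded), `onset_t_min`,
#'   `phase` (character vector along the series).
#' @export
detect_separation_onset <- function(d, onset_threshold = 2.5,
                                    persistence = 2) {
  dv <- if (is.data.frame(d)) d$d_um else d
  n <- length(dv)
  above <- dv > onset_threshold
  onset <- NA_integer_
  for (i in seq_len(n - persistence + 1)) {
    if (all(above[i:(i + persistence - 1)])) { onset <- i; break }
  }
  phase <- rep("pre", n)
  if (!is.na(onset)) {
    plateau <- max(dv[onset:n])
    post_start <- onset + which(dv[onset:n] >= 0.95 * plateau)[1] - 1L
    if (post_start > onset) phase[onset:(post_start - 1)] <- "active"
    phase[post_start:n] <- "post"
  }
  fr <- if (is.data.frame(d)) d$frame else seq_len(n)
  tm <- if (is.data.frame(d) && "t_min" %in% names(d)) d$t_min else fr - 1
  list(onset_frame = if (is.na(onset)) NA_integer_ else fr[onset],
       onset_t_min = if (is.na(onset)) NA_real_ else tm[onset],
       phase = phase)
}

#' Time of first centrosome contact
#'
#' First frame at which the inter-centrosome distance drops below
#' `contact_threshold` and remains below it for `dwell` consecutive
#' observations; a pair that makes contact within the observation window is
#' scored as congressed.
#'
#' @param d a [distance_series()] data.frame or numeric vector.
#' @param contact_threshold um; below this the centrosomes are considered
#'   joined.
#' @param dwell consecutive observations required below threshold.
#' @return list: `contact_frame` (NA if none), `contact_t_min`,
#'   `congressed`.
#' @export
time_of_first_contact <- function(d, contact_threshold = 1.5, dwell = 2) {
  dv <- if (is.data.frame(d)) d$d_um else d
  n <- length(dv)
  below <- dv < contact_threshold
  hit <- NA_integer_
  for (i in seq_len(max(n - dwell + 1, 0))) {
    if (all(below[i:(i + dwell - 1)])) { hit <- i; break }
  }
  fr <- if (is.data.frame(d)) d$frame else seq_len(n)
  tm <- if (is.data.frame(d) && "t_min" %in% names(d)) d$t_min else fr - 1
  list(contact_frame = if (is.na(hit)) NA_integer_ else fr[hit],
       contact_t_min = if (is.na(hit)) NA_real_ else tm[hit],
       congressed = !is.na(hit))
}

#' Cumulative percentage of congressed cells over time
#'
#' At each evaluation time, 100 x (cells with first contact at or before
#' t) / (cells analyzed). Monotone nondecreasing by construction.
#'
#' @param contact_times numeric vector of first-contact times (minutes),
#'   NA for cells that never congress. Length = cells analyzed.
#' @param times evaluation grid (minutes); defaults to the sorted observed
#'   contact times.
#' @return data.frame: `t_min`, `percent`.
#' @export
percent_congression <- function(contact_times, times = NULL) {
  n <- length(contact_times)
  if (n == 0L) stop("no cells in cohort", call. = FALSE)
  times <- times %||% sort(unique(contact_times[!is.na(contact_times)]))
  data.frame(t_min = times,
             percent = vapply(times, function(t)
               100 * sum(!is.na(contact_times) & contact_times <= t) / n,
               numeric(1)))
}

#' Speed as distance over time
#'
#' For a track, the traversed path length divided by the elapsed time; for
#' a distance series, the summed absolute distance change over elapsed time
#' (the approximation velocity of a closing pair). An optional frame window
#' restricts the computation, e.g. to the active separation phase.
#'
#' @param x a track data.frame (`frame`, `x`, `y`) or a
#'   [distance_series()] data.frame.
#' @param frame_interval minutes per frame.
#' @param frames optional vector of frames to restrict to.
#' @return speed in um/min (NA with fewer than two points).
#' @export
speed <- function(x, frame_interval = 5, frames = NULL) {
  if (!is.null(frames)) x <- x[x$frame %in% frames, ]
  if (nrow(x) < 2L) return(NA_real_)
  x <- x[order(x$frame), ]
  dt <- diff(x$frame) * frame_interval
  path <- if ("d_um" %in% names(x) && !("x" %in% names(x)))
    sum(abs(diff(x$d_um))) else sum(sqrt(diff(x$x)^2 + diff(x$y)^2))
  path / sum(dt)
}

#' Time-averaged mean squared displacement
#'
#' MSD(tau) averaged over all overlapping point pairs separated by each
#' frame lag, using actual frame differences so gap-closed tracks
#' contribute only real observations. Lags default to one third of the
#' track length, the usual bias/variance compromise for single-particle
#' tracks.
#'
#' @param track data.frame with `frame`, `x`, `y` in um.
#' @param max_lag maximum lag in frames.
#' @param frame_interval minutes per frame.
#' @return data.frame: `lag` (frames), `tau_min`, `msd_um2`, `n_pairs`;
#'   includes the trivial lag-0 row with MSD 0.
#' @export
msd <- function(track, max_lag = NULL, frame_interval = 5) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  span <- if (n > 1) max(track$frame) - min(track$frame) else 0
  max_lag <- max_lag %||% max(1L, floor(span / 3))
  lags <- 0:max_lag
  rows <- lapply(lags, function(k) {
    if (k == 0L)
      return(data.frame(lag = 0L, tau_min = 0, msd_um2 = 0, n_pairs = n))
    i <- match(track$frame + k, track$frame)
    ok <- !is.na(i)
    if (!any(ok))
      return(data.frame(lag = k, tau_min = k * frame_interval,
                        msd_um2 = NA_real_, n_pairs = 0L))
    d2 <- (track$x[i[ok]] - track$x[ok])^2 + (track$y[i[ok]] - track$y[ok])^2
    data.frame(lag = k, tau_min = k * frame_interval,
               msd_um2 = mean(d2), n_pairs = sum(ok))
  })
  do.call(rbind, rows)
}

#' Group centrosomes into high and low displacement
#'
#' Within each cell the centrosome with the larger MSD at the reference lag
#' (the largest lag common to both curves, itself capped at one third of
#' the track) is assigned to the high-displacement group, the other to the
#' low group; exact ties go to C1. Cohort curves are the pointwise mean and
#' SD of the per-centrosome MSD curves in each group.
#'
#' @param cells list of cells, each a list with `c1` and `c2` [msd()]
#'   curves and optionally `cell_id`.
#' @return list: `assignment` (data.frame cell_id, high in {"c1","c2"}),
#'   `curves` (data.frame group, lag, tau_min, mean_msd, sd_msd).
#' @export
displacement_grouping <- function(cells) {
  assignment <- data.frame(cell_id = integer(), high = character())
  per_group <- list(high = list(), low = list())
  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    id <- cell$cell_id %||% k
    lag_ref <- min(max(cell$c1$lag), max(cell$c2$lag))
    m1 <- cell$c1$msd_um2[match(lag_ref, cell$c1$lag)]
    m2 <- cell$c2$msd_um2[match(lag_ref, cell$c2$lag)]
    high <- if (m2 > m1) "c2" else "c1"
    assignment <- rbind(assignment, data.frame(cell_id = id, high = high))
    per_group$high[[length(per_group$high) + 1L]] <-
      if (high == "c1") cell$c1 else cell$c2
    per_group$low[[length(per_group$low) + 1L]] <-
      if (high == "c1") cell$c2 else cell$c1
  }
  curves <- do.call(rbind, lapply(names(per_group), function(g) {
    all <- do.call(rbind, per_group[[g]])
    agg_m <- stats::aggregate(msd_um2 ~ lag + tau_min, all, mean)
    agg_s <- stats::aggregate(msd_um2 ~ lag + tau_min, all,
                              function(v) stats::sd(v))
    data.frame(group = g, lag = agg_m$lag, tau_min = agg_m$tau_min,
               mean_msd = agg_m$msd_um2, sd_msd = agg_s$msd_um2)
  }))
  list(assignment = assignment, curves = curves[order(curves$group, curves$lag), ])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Angle at the nuclear centroid between the two centrosomes
#'
#' The angle between the vectors from the nuclear centroid to each
#' centrosome, in degrees in \[0, 180\]. 180 means diametric placement
#' across the nucleus.
#'
#' @param c1,c2 centrosome positions, `c(x, y)` in um.
#' @param centroid nuclear centroid, `c(x, y)` in um.
#' @return angle in degrees.
#' @export
centroid_angle <- function(c1, c2, centroid) {
  v1 <- c1[1:2] - centroid[1:2]
  v2 <- c2[1:2] - centroid[1:2]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("centrosome coincides with the centroid: angle undefined",
         call. = FALSE)
  acos(clamp(sum(v1 * v2) / (n1 * n2), -1, 1)) * 180 / pi
}

#' Distance from the centrosome-pair midpoint to the nuclear centroid
#'
#' @param c1,c2 centrosome positions, `c(x, y)` in um.
#' @param centroid nuclear centroid in um.
#' @return distance in um; 0 means the separation axis is centred on the
#'   nucleus.
#' @export
alignment_midpoint_distance <- function(c1, c2, centroid) {
  mid <- (c1[1:2] + c2[1:2]) / 2
  sqrt(sum((mid - centroid[1:2])^2))
}

#' Distances of a centrosome to the nuclear and cellular centroids over time
#'
#' @param track data.frame with `frame`, `x`, `y` in um.
#' @param geometry per-frame geometry (columns `frame`, `nuc_x_um`,
#'   `nuc_y_um`, `cell_x_um`, `cell_y_um`), e.g. from [segment_stack()].
#' @return data.frame: `frame`, `d_nuclear_um`, `d_cellular_um` (NA where a
#'   centroid is unavailable).
#' @export
centroid_distance_series <- function(track, geometry) {
  g <- geometry[match(track$frame, geometry$frame), ]
  data.frame(frame = track$frame,
             d_nuclear_um = sqrt((track$x - g$nuc_x_um)^2 +
                                 (track$y - g$nuc_y_um)^2),
             d_cellular_um = sqrt((track$x - g$cell_x_um)^2 +
                                  (track$y - g$cell_y_um)^2))
}

#' Nuclear-envelope contact phases of a centrosome track
#'
#' The NE-contact time is the first frame at which the centrosome comes
#' within `contact_tol` of the nucleus boundary. Phase speeds are then
#' reported for the approach (outside, before contact), the pause (0 to
#' `pause_window` minutes after contact) and the after-pause window
#' (beyond `pause_window`); tracks from different cells can be aligned by
#' their contact times.
#'
#' @param track data.frame with `frame`, `x`, `y` in um.
#' @param nucleus_mask logical matrix.
#' @param pixel_size um/px.
#' @param contact_tol um; boundary distance at or below it counts as
#'   contact.
#' @param pause_window minutes after contact treated as the pause phase.
#' @param frame_interval minutes per frame.
#' @return list: `contact_frame` (NA if never in contact), `contact_t_min`,
#'   `speeds` (named: outside, pause, after; um/min, NA for absent phases).
#' @export
ne_contact_phases <- function(track, nucleus_mask, pixel_size,
                              contact_tol = 1, pause_window = 20,
                              frame_interval = 5) {
  track <- track[order(track$frame), ]
  db <- boundary_distance(track$x, track$y, nucleus_mask, pixel_size)
  hit <- which(db <= contact_tol)[1]
  if (is.na(hit))
    return(list(contact_frame = NA_integer_, contact_t_min = NA_real_,
                speeds = c(outside = speed(track, frame_interval),
                           pause = NA_real_, after = NA_real_)))
  t0 <- (track$frame[hit] - track$frame[1]) * frame_interval
  rel_t <- (track$frame - track$frame[hit]) * frame_interval
  win <- list(outside = track$frame[rel_t <= 0],
              pause = track$frame[rel_t >= 0 & rel_t <= pause_window],
              after = track$frame[rel_t >= pause_window])
  sp <- vapply(win, function(fr)
    if (length(fr) >= 2) speed(track, frame_interval, frames = fr)
    else NA_real_, numeric(1))
  list(contact_frame = track$frame[hit],
       contact_t_min = (track$frame[hit] - 1) * frame_interval,
       speeds = sp)
}

#' Classify the position of a centrosome pair
#'
#' Deterministic rules standing in for visual scoring: pairs far from the
#' nucleus are `detached`; pairs under the nuclear projection at a wide
#' angle are `diametric-under-nucleus`; pairs hugging the envelope (within
#' `ne_tol` of the boundary, inclusive) are `NE-border`; everything else is
#' `side-of-nucleus`.
#'
#' @param c1,c2 centrosome positions `c(x, y)` in um.
#' @param nucleus_mask logical matrix.
#' @param pixel_size um/px.
#' @param nuclear_centroid `c(x, y)` um; computed from the mask if missing.
#' @param angle_min degrees; at or above this the pair counts as diametric.
#' @param ne_tol um; inclusive boundary tolerance for `NE-border`.
#' @param detach_threshold um; boundary distance beyond which a pair
#'   outside the nucleus counts as detached.
#' @return one of `"diametric-under-nucleus"`, `"NE-border"`,
#'   `"side-of-nucleus"`, `"detached"`.
#' @export
classify_position <- function(c1, c2, nucleus_mask, pixel_size,
                              nuclear_centroid = NULL,
                              angle_min = 150, ne_tol = 1,
                              detach_threshold = 3) {
  ctr <- nuclear_centroid %||% mask_centroid(nucleus_mask, pixel_size)
  pts <- rbind(c1[1:2], c2[1:2])
  db <- boundary_distance(pts[, 1], pts[, 2], nucleus_mask, pixel_size)
  rr <- clamp(round(um_to_px(pts[, 2], pixel_size)), 1, nrow(nucleus_mask))
  cc <- clamp(round(um_to_px(pts[, 1], pixel_size)), 1, ncol(nucleus_mask))
  inside <- nucleus_mask[cbind(rr, cc)]
  ang <- centroid_angle(c1, c2, ctr)
  if (all(!inside & db > detach_threshold)) return("detached")
  if (ang >= angle_min && all(inside)) return("diametric-under-nucleus")
  if (all(db <= ne_tol)) return("NE-border")
  "side-of-nucleus"
}

#' Rotation between two centrosome/spindle axes
#'
#' The acute angle between the undirected axes defined by two point pairs,
#' e.g. the centrosome axis at NEBD versus the spindle-pole axis at
#' metaphase. Degrees in \[0, 90\].
#'
#' @param a1,a2 endpoints of the first axis (`c(x, y)` um).
#' @param b1,b2 endpoints of the second axis.
#' @return rotation angle in degrees.
#' @export
axis_rotation <- function(a1, a2, b1, b2) {
  v1 <- a2[1:2] - a1[1:2]
  v2 <- b2[1:2] - b1[1:2]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("degenerate axis", call. = FALSE)
  acos(clamp(abs(sum(v1 * v2)) / (n1 * n2), 0, 1)) * 180 / pi
}

#' Summary statistics of EB3 comet tracks
#'
#' Per-track path speed (path length over duration), the per-cell mean
#' speed, the pooled MSD (per-lag average over tracks weighted by the
#' number of contributing pairs) and the track-length distribution.
#'
#' @param tracks data.frame from [link_spots()] with coordinates in um.
#' @param frame_interval minutes per frame.
#' @param min_length shortest track (points) entering the statistics.
#' @return list: `mean_speed` (um/min), `speeds` (per track),
#'   `track_lengths`, `msd` (pooled curve).
#' @export
comet_stats <- function(tracks, frame_interval = 5, min_length = 3) {
  tracks <- filter_tracks(tracks, min_length = min_length)
  by_track <- split(tracks, tracks$track_id)
  if (!length(by_track))
    return(list(mean_speed = NA_real_, speeds = numeric(),
                track_lengths = integer(), msd = NULL))
  speeds <- vapply(by_track, speed, numeric(1),
                   frame_interval = frame_interval)
  msds <- lapply(by_track, msd, frame_interval = frame_interval)
  all <- do.call(rbind, msds)
  all <- all[!is.na(all$msd_um2), ]
  pooled <- do.call(rbind, lapply(split(all, all$lag), function(g)
    data.frame(lag = g$lag[1], tau_min = g$tau_min[1],
               msd_um2 = sum(g$msd_um2 * g$n_pairs) / sum(g$n_pairs),
               n_pairs = sum(g$n_pairs))))
  list(mean_speed = mean(speeds), speeds = speeds,
       track_lengths = vapply(by_track, nrow, integer(1)),
       msd = pooled[order(pooled$lag), ])
}

#' All pair metrics for one cell
#'
#' Convenience wrapper computing the full per-cell metric bundle from an
#' assigned centrosome pair and (optionally) the per-frame geometry.
#'
#' @param pair list with `c1`, `c2` from [assign_pair()].
#' @param geometry optional per-frame geometry data.frame (see
#'   [centroid_distance_series()]).
#' @param nucleus_mask,pixel_size optional, for NE phases and position
#'   class.
#' @param frame_interval minutes per frame.
#' @param contact_threshold,onset_threshold,dwell,persistence thresholds
#'   for contact and onset calls (um / frames).
#' @return list with the distance series, onset, contact, per-centrosome
#'   speeds and MSDs, endpoint angle, midpoint alignment and (when masks
#'   are given) the position class.
#' @export
pair_metrics <- function(pair, geometry = NULL, nucleus_mask = NULL,
                         pixel_size = NULL, frame_interval = 5,
                         contact_threshold = 1.5, onset_threshold = 2.5,
                         dwell = 2, persistence = 2) {
  stopifnot(isTRUE(pair$ok))
  d <- distance_series(pair$c1, pair$c2, frame_interval)
  onset <- detect_separation_onset(d, onset_threshold, persistence)
  dext <- merge_extended_distance(pair$c1, pair$c2, frame_interval,
                                  merge_radius = contact_threshold)
  contact <- time_of_first_contact(dext, contact_threshold, dwell)
  out <- list(
    distance = d,
    onset = onset,
    contact = contact,
    speed_c1 = speed(pair$c1, frame_interval),
    speed_c2 = speed(pair$c2, frame_interval),
    approach_speed = speed(d, frame_interval),
    msd_c1 = msd(pair$c1, frame_interval = frame_interval),
    msd_c2 = msd(pair$c2, frame_interval = frame_interval))
  act <- d$frame[onset$phase == "active"]
  if (length(act)) {
    # the moving window: active frames plus the arrival frame
    nxt <- d$frame[d$frame > max(act)]
    win <- c(act, if (length(nxt)) min(nxt))
    out$separation_speed_c1 <- speed(pair$c1, frame_interval, frames = win)
    out$separation_speed_c2 <- speed(pair$c2, frame_interval, frames = win)
    out$separation_rate <- speed(d, frame_interval, frames = win)
  }
  if (!is.null(geometry)) {
    last <- max(d$frame)
    g <- geometry[match(last, geometry$frame), ]
    p1 <- c(pair$c1$x[match(last, pair$c1$frame)],
            pair$c1$y[match(last, pair$c1$frame)])
    p2 <- c(pair$c2$x[match(last, pair$c2$frame)],
            pair$c2$y[match(last, pair$c2$frame)])
    ctr <- c(g$nuc_x_um, g$nuc_y_um)
    out$final_distance <- d$d_um[nrow(d)]
    out$final_angle <- centroid_angle(p1, p2, ctr)
    out$midpoint_distance <- alignment_midpoint_distance(p1, p2, ctr)
    out$centroid_distances_c1 <- centroid_distance_series(pair$c1, geometry)
    out$centroid_distances_c2 <- centroid_distance_series(pair$c2, geometry)
    if (!is.null(nucleus_mask) && !is.null(pixel_size))
      out$position_class <- classify_position(p1, p2, nucleus_mask,
                                              pixel_size,
                                              nuclear_centroid = ctr)
  }
  out
}
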
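# Frame-to-frame particle linking with three motion models: plain nearest
# neighbour, drift prediction (nearest velocity) and a constant-velocity
# Kalman filter with innovation gating. Gaps up to `max_gap` frames are
# closed by linking across missing frames with the search radius scaled by
# the gap length. Gap-closed positions are never interpolated: downstream
# distance/MSD computations use the actual time lags.

new_track_state <- function(id, frame, x, y, mode) {
  list(id = id, last_frame = frame, pos = c(x, y), disp = c(0, 0),
       has_disp = FALSE,
       kf = if (mode == "kalman")
         list(s = c(x, y, 0, 0),
              P = diag(c(1, 1, 25, 25))) else NULL)
}

kf_predict <- function(kf, dt, q) {
  FF <- diag(4); FF[1, 3] <- dt; FF[2, 4] <- dt
  G <- c(dt^2 / 2, dt^2 / 2, dt, dt)  # white-acceleration process noise
  list(s = as.numeric(FF %*% kf$s),
       P = FF %*% kf$P %*% t(FF) + q^2 * diag(G^2))
}

kf_update <- function(kf, z, r) {
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  S <- H %*% kf$P %*% t(H) + r^2 * diag(2)
  K <- kf$P %*% t(H) %*% solve(S)
  s <- kf$s + as.numeric(K %*% (z - kf$s[1:2]))
  P <- (diag(4) - K %*% H) %*% kf$P
  list(s = s, P = P)
}

#' Link detections across frames into tracks
#'
#' Greedy mutual-nearest assignment per frame: all (track, spot) pairs
#' within the (gap-scaled) search radius are sorted by predicted-position
#' distance and assigned greedily; equidistant candidates break ties on the
#' lowest spot id, then the lowest track id, so linking is deterministic.
#' Unassigned spots seed new tracks.
#'
#' @param spots data.frame with columns `frame`, `x`, `y`, `spot_id` and
#'   optionally `intensity`; coordinates in any consistent unit (the search
#'   radius uses the same unit).
#' @param mode `"nearest"` (predict = last position), `"drift"` (predict =
#'   last position + last per-frame displacement) or `"kalman"`
#'   (constant-velocity state with innovation gating).
#' @param search_radius maximum link distance per frame step; > 0.
#' @param max_gap frames a track may go undetected and still be continued;
#'   the radius for a link across `g` missing frames scales to
#'   `search_radius * (g + 1)`.
#' @param q,r Kalman process/measurement noise (kalman mode).
#' @return data.frame: `track_id`, `frame`, `x`, `y`, `spot_id`, ordered by
#'   track then frame. Frames are strictly increasing within a track and no
#'   link exceeds its scaled radius.
#' @export
link_spots <- function(spots, mode = c("nearest", "drift", "kalman"),
                       search_radius = 5, max_gap = 1, q = 1, r = 0.5) {
  mode <- match.arg(mode)
  if (!is.numeric(search_radius) || search_radius <= 0)
    stop("search_radius must be > 0", call. = FALSE)
  if (nrow(spots) == 0L)
    return(data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), spot_id = integer()))
  spots <- spots[order(spots$frame, spots$spot_id), ]
  frames <- sort(unique(spots$frame))
  active <- list()
  next_id <- 1L
  links <- list()

  for (f in frames) {
    sf <- spots[spots$frame == f, ]
    cand <- list()
    preds <- list()
    for (ti in seq_along(active)) {
      tr <- active[[ti]]
      dt <- f - tr$last_frame
      if (dt > max_gap + 1L) next
      pred <- switch(mode,
        nearest = tr$pos,
        drift = tr$pos + tr$disp * dt,
        kalman = kf_predict(tr$kf, dt, q)$s[1:2])
      rad <- search_radius * dt
      d <- sqrt((sf$x - pred[1])^2 + (sf$y - pred[2])^2)
      ok <- which(d <= rad)
      if (length(ok))
        cand[[length(cand) + 1L]] <- data.frame(
          ti = ti, si = ok, d = d[ok],
          spot_id = sf$spot_id[ok], track_id = tr$id)
      preds[[as.character(ti)]] <- pred
    }
    used_t <- integer(); used_s <- integer()
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$d, cand$spot_id, cand$track_id), ]
      for (k in seq_len(nrow(cand))) {
        ti <- cand$ti[k]; si <- cand$si[k]
        if (ti %in% used_t || si %in% used_s) next
        used_t <- c(used_t, ti); used_s <- c(used_s, si)
        tr <- active[[ti]]
        dt <- f - tr$last_frame
        z <- c(sf$x[si], sf$y[si])
        tr$disp <- (z - tr$pos) / dt
        tr$has_disp <- TRUE
        tr$pos <- z
        tr$last_frame <- f
        if (mode == "kalman") tr$kf <- kf_update(kf_predict(tr$kf, dt, q), z, r)
        active[[ti]] <- tr
        links[[length(links) + 1L]] <- data.frame(
          track_id = tr$id, frame = f, x = z[1], y = z[2],
          spot_id = sf$spot_id[si])
      }
    }
    for (si in setdiff(seq_len(nrow(sf)), used_s)) {
      tr <- new_track_state(next_id, f, sf$x[si], sf$y[si], mode)
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <- tr
      links[[length(links) + 1L]] <- data.frame(
        track_id = tr$id, frame = f, x = sf$x[si], y = sf$y[si],
        spot_id = sf$spot_id[si])
    }
  }
  out <- do.call(rbind, links)
  out[order(out$track_id, out$frame), ]
}

#' Filter tracks on length and gap criteria
#'
#' Retains tracks with at least `min_length` points and at most `max_gaps`
#' gap events (frame steps larger than one). Idempotent and
#' order-deterministic.
#'
#' @param tracks output of [link_spots()].
#' @param min_length minimum number of points.
#' @param max_gaps maximum number of gap events.
#' @return filtered tracks, ordered by track then frame.
#' @export
filter_tracks <- function(tracks, min_length = 5, max_gaps = Inf) {
  if (nrow(tracks) == 0L) return(tracks)
  keep <- vapply(split(tracks$frame, tracks$track_id), function(fr) {
    length(fr) >= min_length && sum(diff(sort(fr)) > 1) <= max_gaps
  }, logical(1))
  out <- tracks[tracks$track_id %in% as.integer(names(keep))[keep], ]
  out[order(out$track_id, out$frame), ]
}

#' Assign the two centrosome tracks of a cell
#'
#' Among the tracks whose points fall within the cell mask (at least half
#' of the points, to tolerate detections on the mask border), the two
#' longest become the cell's centrosome pair. The brighter track at its
#' first frame is labelled C1; ties fall back to the lower track id.
#'
#' @param tracks data.frame from [link_spots()] with coordinates in um and,
#'   ideally, an `intensity` column (joined from the spots table).
#' @param cell_mask optional logical matrix restricting candidate tracks.
#' @param pixel_size um/px (needed with `cell_mask`).
#' @return list with `c1`, `c2` (per-track data.frames ordered by frame)
#'   and `ok`; when fewer than two tracks qualify, `ok = FALSE` and the
#'   cell is unanalyzable.
#' @export
assign_pair <- function(tracks, cell_mask = NULL, pixel_size = NULL) {
  if (nrow(tracks) == 0L) return(list(c1 = NULL, c2 = NULL, ok = FALSE))
  by_track <- split(tracks, tracks$track_id)
  if (!is.null(cell_mask)) {
    if (is.null(pixel_size))
      stop("pixel_size is required with cell_mask", call. = FALSE)
    inside <- vapply(by_track, function(tr) {
      rr <- pmin(pmax(round(um_to_px(tr$y, pixel_size)), 1), nrow(cell_mask))
      cc <- pmin(pmax(round(um_to_px(tr$x, pixel_size)), 1), ncol(cell_mask))
      mean(cell_mask[cbind(rr, cc)]) >= 0.5
    }, logical(1))
    by_track <- by_track[inside]
  }
  if (length(by_track) < 2L) return(list(c1 = NULL, c2 = NULL, ok = FALSE))
  len <- vapply(by_track, nrow, integer(1))
  ids <- as.integer(names(by_track))
  ord <- order(-len, ids)
  a <- by_track[[ord[1]]]; b <- by_track[[ord[2]]]
  ia <- if ("intensity" %in% names(a)) a$intensity[1] else 0
  ib <- if ("intensity" %in% names(b)) b$intensity[1] else 0
  if (ib > ia || (ib == ia && b$track_id[1] < a$track_id[1])) {
    tmp <- a; a <- b; b <- tmp
  }
  list(c1 = a[order(a$frame), ], c2 = b[order(b$frame), ], ok = TRUE)
}
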
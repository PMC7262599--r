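# Centrosome trajectory programs. Each program describes the kinematics of a
# centrosome pair in one of the motion regimes observed in G2/prophase cells:
# Eg5-driven separation along the nuclear surface, congression of separated
# centrosomes toward the nuclear centroid after Eg5 inhibition, a pause at
# the nuclear envelope, stationary pairs and detachment from the nucleus.

#' Define a centrosome-pair trajectory program
#'
#' @param mode one of `"separation"`, `"congression"`, `"stall_at_NE"`,
#'   `"stationary"`, `"detach"`.
#' @param speeds per-centrosome speed in um/min (length 2; asymmetric speeds
#'   are the rule in live cells, where one centrosome displaces much more
#'   than the other).
#' @param start positions at frame 1, a 2 x 2 matrix (rows = centrosomes,
#'   columns = x, y in um). Defaults depend on the mode: separation starts
#'   both centrosomes 1 um apart near the nuclear centroid; congression
#'   starts them at the programmed endpoint geometry; stall_at_NE starts
#'   outside the nucleus.
#' @param target_distance endpoint inter-centrosome distance in um
#'   (separation mode). The ~10 um default matches the stable pre-NEBD
#'   position along the nuclear diameter.
#' @param target_angle endpoint angle at the nuclear centroid, degrees in
#'   (0, 180].
#' @param axis_angle orientation (degrees) of the separation axis bisector.
#' @param motion_noise isotropic Gaussian positional noise per frame (um).
#' @param contact_threshold inter-distance (um) below which congressing
#'   centrosomes are considered joined and stop.
#' @param dwell_min pause duration at the nuclear envelope (minutes,
#'   stall_at_NE mode).
#' @param start_frame frames of rest before motion begins (the "pre" phase).
#' @return An object of class `trajectory_program`.
#' @export
trajectory_program <- function(mode = c("separation", "congression",
                                        "stall_at_NE", "stationary", "detach"),
                               speeds = c(0.3, 0.3),
                               start = NULL,
                               target_distance = 10,
                               target_angle = 180,
                               axis_angle = 0,
                               motion_noise = 0,
                               contact_threshold = 1.5,
                               dwell_min = 20,
                               start_frame = 1L) {
  mode <- match.arg(mode)
  if (any(speeds < 0)) stop("speeds must be >= 0", call. = FALSE)
  if (target_angle <= 0 || target_angle > 180)
    stop("target_angle must be in (0, 180] degrees", call. = FALSE)
  if (target_distance < 0) stop("target_distance must be >= 0", call. = FALSE)
  prog <- list(mode = mode, speeds = as.numeric(speeds), start = start,
               target_distance = target_distance, target_angle = target_angle,
               axis_angle = axis_angle, motion_noise = motion_noise,
               contact_threshold = contact_threshold, dwell_min = dwell_min,
               start_frame = as.integer(start_frame))
  class(prog) <- "trajectory_program"
  prog
}

# Endpoint positions about the nuclear centroid: angle theta between the two
# radius vectors, inter-distance d => radius r = d / (2 sin(theta/2)). The
# two endpoints sit symmetrically about the perpendicular to `axis_angle`
# through the centroid, so at theta = 180 deg the pair axis runs along
# `axis_angle`.
endpoint_positions <- function(center, target_distance, target_angle,
                               axis_angle) {
  half <- target_angle / 2 * pi / 180
  r <- target_distance / (2 * sin(half))
  phi <- axis_angle * pi / 180 - pi / 2
  rbind(center + r * c(cos(phi + half), sin(phi + half)),
        center + r * c(cos(phi - half), sin(phi - half)))
}

default_start <- function(program, scene, goals) {
  ctr <- scene$nuclear_centroid
  phi <- program$axis_angle * pi / 180
  u <- c(cos(phi), sin(phi))
  unit_to <- function(g) {
    v <- g - ctr
    n <- sqrt(sum(v^2))
    if (n < 1e-12) u else v / n
  }
  switch(program$mode,
    # nudge each centrosome toward its own goal so active motion is radial
    separation = rbind(ctr + 0.5 * unit_to(goals[1, ]),
                       ctr + 0.5 * unit_to(goals[2, ])),
    congression = endpoint_positions(ctr, program$target_distance,
                                     program$target_angle,
                                     program$axis_angle),
    stall_at_NE = {
      # start outside the nucleus along the axis, just inside the cell edge
      a <- max(attr(scene, "cell_axes") %||% c(11.5, 10.5))
      rbind(ctr + (a - 0.5) * u, ctr - (a - 0.5) * u)
    },
    stationary = rbind(ctr + 2 * u, ctr - 2 * u),
    detach = endpoint_positions(ctr, program$target_distance,
                                program$target_angle, program$axis_angle)
  )
}

#' Simulate a centrosome pair under a trajectory program
#'
#' Generates the ground-truth table for one cell: per-frame true centrosome
#' positions, phase labels and the contact/congression bookkeeping used by
#' downstream metric tests. Motion is piecewise linear toward mode-specific
#' goals at the programmed speeds, with optional isotropic Gaussian noise;
#' the same seed always reproduces the same table.
#'
#' @param program a [trajectory_program()].
#' @param scene a `cell_geometry` from [make_scene()].
#' @param n_frames number of frames.
#' @param frame_interval minutes between frames.
#' @param seed RNG seed.
#' @param cell_id identifier written into the table.
#' @return A data.frame of class `ground_truth` with one row per
#'   (frame, centrosome): columns `cell_id`, `frame`, `t_min`,
#'   `centrosome_id`, `x_um`, `y_um`, `z_um` (constant 0), `phase`.
#'   Attributes: `program`, `congressed`, `time_first_contact` (minutes or
#'   NA), `target_reached` (FALSE flags an endpoint unreachable within
#'   `n_frames`), `nuclear_centroid`, `cellular_centroid`.
#' @export
simulate_pair <- function(program, scene, n_frames = 25,
                          frame_interval = 5, seed = 1L, cell_id = 1L) {
  stopifnot(inherits(program, "trajectory_program"),
            inherits(scene, "cell_geometry"))
  ctr <- scene$nuclear_centroid
  goals0 <- switch(program$mode,
    separation = endpoint_positions(ctr, program$target_distance,
                                    program$target_angle, program$axis_angle),
    congression = rbind(ctr, ctr),
    stall_at_NE = rbind(ctr, ctr),
    stationary = NULL,
    detach = NULL)
  start <- program$start %||% default_start(program, scene, goals0)
  if (!is.matrix(start) || !all(dim(start) == c(2, 2)))
    stop("start must be a 2 x 2 matrix (centrosomes x (x, y))", call. = FALSE)
  goals <- goals0 %||% switch(program$mode,
    stationary = start,
    detach = {
      u1 <- start[1, ] - ctr; u2 <- start[2, ] - ctr
      rbind(start[1, ] + 20 * u1 / max(sqrt(sum(u1^2)), 1e-9),
            start[2, ] + 20 * u2 / max(sqrt(sum(u2^2)), 1e-9))
    })

  dwell_frames <- ceiling(program$dwell_min / frame_interval)
  noise <- if (program$motion_noise > 0)
    with_seed(seed, matrix(stats::rnorm(2 * 2 * n_frames,
                                        sd = program$motion_noise),
                           ncol = 4)) else matrix(0, n_frames, 4)

  pos <- array(NA_real_, c(n_frames, 2, 2))  # frame x centrosome x (x, y)
  phase <- matrix("pre", n_frames, 2)
  cur <- start
  paused_since <- c(NA_integer_, NA_integer_)  # stall_at_NE bookkeeping
  contact_frame <- NA_integer_
  step_len <- program$speeds * frame_interval

  ne_state <- c("outside", "outside")  # stall_at_NE state machine
  for (f in seq_len(n_frames)) {
    if (f > program$start_frame) {
      for (i in 1:2) {
        if (program$mode == "stationary") { phase[f, i] <- "post"; next }
        if (program$mode == "stall_at_NE" && ne_state[i] == "pause") {
          # resume only after the full dwell has elapsed at the envelope
          if ((f - paused_since[i]) > dwell_frames) {
            ne_state[i] <- "inside"
          } else { phase[f, i] <- "pause"; next }
        }
        v <- goals[i, ] - cur[i, ]
        d <- sqrt(sum(v^2))
        arrived <- d <= step_len[i] || d < 1e-12
        cur[i, ] <- if (arrived) goals[i, ] else cur[i, ] + v / d * step_len[i]
        if (program$mode == "stall_at_NE") {
          if (ne_state[i] == "outside") {
            db <- boundary_distance(cur[i, 1], cur[i, 2],
                                    scene$nucleus_mask, scene$pixel_size)
            if (db <= 0.5) {
              ne_state[i] <- "pause"
              paused_since[i] <- f
              phase[f, i] <- "pause"
            } else phase[f, i] <- "outside"
          } else phase[f, i] <- "inside"
        } else {
          phase[f, i] <- if (arrived) "post" else "active"
        }
      }
    }
    obs <- cur + matrix(noise[f, ], 2, 2)
    pos[f, , ] <- obs
    if (program$mode == "congression" && is.na(contact_frame)) {
      if (sqrt(sum((cur[1, ] - cur[2, ])^2)) < program$contact_threshold)
        contact_frame <- f
    }
  }

  reached <- all(sqrt(rowSums((cur - goals)^2)) < 1e-6) ||
    program$mode == "stationary"
  if (!reached && program$mode != "stationary")
    warning(sprintf("cell %s: endpoint not reached within %d frames",
                    cell_id, n_frames), call. = FALSE)

  out <- data.frame(
    cell_id = cell_id,
    frame = rep(seq_len(n_frames), each = 2),
    t_min = rep((seq_len(n_frames) - 1) * frame_interval, each = 2),
    centrosome_id = rep(1:2, n_frames),
    x_um = as.vector(t(pos[, , 1])),
    y_um = as.vector(t(pos[, , 2])),
    z_um = 0,
    phase = as.vector(t(phase)))
  attr(out, "program") <- program
  attr(out, "congressed") <- !is.na(contact_frame)
  attr(out, "time_first_contact") <-
    if (is.na(contact_frame)) NA_real_ else (contact_frame - 1) * frame_interval
  attr(out, "target_reached") <- reached
  attr(out, "nuclear_centroid") <- scene$nuclear_centroid
  attr(out, "cellular_centroid") <- scene$cellular_centroid
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Simulate a cohort of cells
#'
#' Applies one trajectory program per cell (recycled if a single program is
#' given) with per-cell derived seeds, returning the row-bound ground-truth
#' table with per-cell attributes collected into a summary data.frame.
#'
#' @param programs a [trajectory_program()] or list of them, one per cell.
#' @param scene shared `cell_geometry`.
#' @param n_cells number of cells (defaults to `length(programs)`).
#' @param n_frames,frame_interval,seed as in [simulate_pair()].
#' @return list with `truth` (row-bound ground-truth table) and `cells`
#'   (data.frame: cell_id, congressed, time_first_contact, target_reached).
#' @export
simulate_cohort <- function(programs, scene, n_cells = NULL,
                            n_frames = 25, frame_interval = 5, seed = 1L) {
  if (inherits(programs, "trajectory_program")) programs <- list(programs)
  n_cells <- n_cells %||% length(programs)
  tabs <- vector("list", n_cells)
  cells <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    prog <- programs[[(k - 1) %% length(programs) + 1]]
    tabs[[k]] <- simulate_pair(prog, scene, n_frames, frame_interval,
                               seed = seed + 1009L * k, cell_id = k)
    cells[[k]] <- data.frame(
      cell_id = k,
      congressed = attr(tabs[[k]], "congressed"),
      time_first_contact = attr(tabs[[k]], "time_first_contact"),
      target_reached = attr(tabs[[k]], "target_reached"))
  }
  list(truth = do.call(rbind, tabs), cells = do.call(rbind, cells))
}
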
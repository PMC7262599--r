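# Synthetic movie rendering. Channels emulate a spinning-disk time-lapse of
# a flat adherent cell: diffraction-limited centrosome spots (RFP-PACT-like),
# a DNA channel filling the nucleus, a textured tubulin channel filling the
# cytoplasm, optional EB3 comets moving radially out from the centrosomes and
# an optional perinuclear actin annulus. Pixel values are integer camera
# counts in [0, 65535].

KNOWN_CHANNELS <- c("centrosome", "dna", "tubulin", "eb3", "actin")

# Add a 2D Gaussian of peak `amp` and sd `sigma_px` at (x_um, y_um) onto img.
add_gaussian_spot <- function(img, x_um, y_um, amp, sigma_px, pixel_size) {
  cx <- um_to_px(x_um, pixel_size)
  cy <- um_to_px(y_um, pixel_size)
  r <- ceiling(4 * sigma_px)
  cols <- max(1, floor(cx) - r):min(ncol(img), ceiling(cx) + r)
  rows <- max(1, floor(cy) - r):min(nrow(img), ceiling(cy) + r)
  if (!length(cols) || !length(rows)) return(img)
  gx <- exp(-(cols - cx)^2 / (2 * sigma_px^2))
  gy <- exp(-(rows - cy)^2 / (2 * sigma_px^2))
  img[rows, cols] <- img[rows, cols] + amp * outer(gy, gx)
  img
}

# Static band-pass texture for the tubulin channel, in [0, 1].
make_texture <- function(ny, nx, seed) {
  with_seed(seed, {
    n <- matrix(stats::rnorm(ny * nx), ny, nx)
    t <- EBImage::gblur(n, sigma = 1) - EBImage::gblur(n, sigma = 4)
    (t - min(t)) / (max(t) - min(t))
  })
}

# Deterministic EB3 comet book-keeping: comets nucleate at the centrosome
# positions, pick a random direction, and travel radially outward at
# `eb3_speed` until they leave the cell mask or exceed their lifetime.
simulate_comets <- function(config, scene, truth, lifetime_frames = 8) {
  n_frames <- max(truth$frame)
  with_seed(config$seed + 7L, {
    comets <- list(); out <- list(); next_id <- 1L
    for (f in seq_len(n_frames)) {
      tf <- truth[truth$frame == f, ]
      for (i in seq_len(nrow(tf))) {
        for (k in seq_len(config$eb3_rate)) {
          ang <- stats::runif(1, 0, 2 * pi)
          comets[[length(comets) + 1L]] <- list(
            id = next_id, born = f, origin = c(tf$x_um[i], tf$y_um[i]),
            dir = c(cos(ang), sin(ang)))
          next_id <- next_id + 1L
        }
      }
      keep <- logical(length(comets))
      for (j in seq_along(comets)) {
        cm <- comets[[j]]
        age <- f - cm$born
        p <- cm$origin + config$eb3_speed * age * config$frame_interval * cm$dir
        px <- round(um_to_px(p[1], config$pixel_size))
        py <- round(um_to_px(p[2], config$pixel_size))
        inside <- px >= 1 && px <= config$nx && py >= 1 && py <= config$ny &&
          scene$cell_mask[py, px]
        if (inside && age < lifetime_frames) {
          keep[j] <- TRUE
          out[[length(out) + 1L]] <- data.frame(
            comet_id = cm$id, frame = f, x_um = p[1], y_um = p[2])
        }
      }
      comets <- comets[keep]
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(comet_id = integer(), frame = integer(),
                 x_um = numeric(), y_um = numeric())
  })
}

apply_camera_noise <- function(img, config) {
  if (config$photon_scale > 0)
    img <- stats::rpois(length(img), pmax(img, 0) * config$photon_scale) /
      config$photon_scale
  if (config$read_sigma > 0)
    img <- img + stats::rnorm(length(img), sd = config$read_sigma)
  matrix(pmin(pmax(round(img), 0), 65535), config$ny, config$nx)
}

#' Render a synthetic multi-channel movie
#'
#' Rasterizes the ground-truth trajectories of [simulate_pair()] into an
#' image stack. The centrosome channel carries Gaussian spots of sigma
#' `config$psf_sigma` at the true positions; the DNA channel fills the
#' nucleus; the tubulin channel fills the cell with a static band-pass
#' texture; the EB3 channel (if its amplitude is positive) carries radially
#' moving comets nucleated at the centrosomes; the actin channel carries an
#' annulus hugging the nucleus boundary. Poisson shot noise and Gaussian
#' read noise are applied per pixel, and values are rounded to integer
#' camera counts. Identical (config, truth, seed) give bit-identical stacks.
#'
#' @param scene `cell_geometry` from [make_scene()].
#' @param truth `ground_truth` table from [simulate_pair()].
#' @param config the [scene_config()] (channels with amplitude > 0 are
#'   rendered as signal; amplitude 0 renders pure background).
#' @param channels character vector of channel roles to render; defaults to
#'   the names of `config$amplitudes`.
#' @return An `image_stack`: list with `data` (array T x C x Y x X of
#'   integer counts), `channels`, `pixel_size` (um/px) and `frame_interval`
#'   (min). EB3 ground truth, when rendered, is attached as attribute
#'   `comet_truth`.
#' @export
render_movie <- function(scene, truth, config, channels = NULL) {
  stopifnot(inherits(scene, "cell_geometry"), inherits(config, "scene_config"))
  channels <- channels %||% names(config$amplitudes)
  unknown <- setdiff(channels, KNOWN_CHANNELS)
  if (length(unknown))
    stop("unknown channel role(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  xmax <- px_to_um(config$nx, config$pixel_size)
  ymax <- px_to_um(config$ny, config$pixel_size)
  if (any(truth$x_um < 0 | truth$x_um > xmax |
          truth$y_um < 0 | truth$y_um > ymax))
    stop("ground-truth positions fall outside the image bounds", call. = FALSE)

  n_frames <- max(truth$frame)
  amp <- config$amplitudes
  texture <- if ("tubulin" %in% channels)
    make_texture(config$ny, config$nx, config$seed + 3L) else NULL
  ring <- if ("actin" %in% channels) {
    db <- abs(EBImage::distmap(scene$nucleus_mask) -
              0.5 / config$pixel_size) * config$pixel_size
    dbo <- EBImage::distmap(!scene$nucleus_mask) * config$pixel_size
    band <- (scene$nucleus_mask & db <= config$actin_ring_width) |
      (!scene$nucleus_mask & dbo <= config$actin_ring_width)
    EBImage::gblur(band * 1, sigma = 1)
  } else NULL
  comet_truth <- if ("eb3" %in% channels && amp[["eb3"]] > 0)
    simulate_comets(config, scene, truth) else NULL

  arr <- array(0, c(n_frames, length(channels), config$ny, config$nx))
  with_seed(config$seed, {
    for (f in seq_len(n_frames)) {
      tf <- truth[truth$frame == f, ]
      for (ci in seq_along(channels)) {
        ch <- channels[ci]
        a <- amp[[ch]] %||% 0
        img <- matrix(config$background, config$ny, config$nx)
        if (a > 0) {
          if (ch == "centrosome") {
            for (i in seq_len(nrow(tf)))
              img <- add_gaussian_spot(img, tf$x_um[i], tf$y_um[i], a,
                                       config$psf_sigma, config$pixel_size)
          } else if (ch == "dna") {
            img <- img + a * EBImage::gblur(scene$nucleus_mask * 1, sigma = 1)
          } else if (ch == "tubulin") {
            img <- img + a * (0.4 + 0.6 * texture) * scene$cell_mask
          } else if (ch == "eb3") {
            cf <- comet_truth[comet_truth$frame == f, ]
            for (i in seq_len(nrow(cf)))
              img <- add_gaussian_spot(img, cf$x_um[i], cf$y_um[i], a,
                                       config$psf_sigma, config$pixel_size)
          } else if (ch == "actin") {
            img <- img + a * ring
          }
        }
        arr[f, ci, , ] <- apply_camera_noise(img, config)
      }
    }
  })
  stack <- image_stack(arr, channels = channels,
                       pixel_size = config$pixel_size,
                       frame_interval = config$frame_interval)
  if (!is.null(comet_truth)) attr(stack, "comet_truth") <- comet_truth
  stack
}

#' Construct an image stack container
#'
#' @param data numeric array with dimensions T x C x Y x X.
#' @param channels character vector of channel roles, length = dim 2.
#' @param pixel_size um/px.
#' @param frame_interval minutes between frames.
#' @return list of class `image_stack`.
#' @export
image_stack <- function(data, channels, pixel_size, frame_interval) {
  stopifnot(length(dim(data)) == 4, dim(data)[2] == length(channels))
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  structure(list(data = data, channels = channels, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' Extract one frame of one channel from an image stack
#'
#' @param stack an `image_stack`.
#' @param frame frame index (1-based).
#' @param channel channel role name or index.
#' @return numeric matrix (Y x X).
#' @export
get_frame <- function(stack, frame, channel) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- if (is.character(channel)) match(channel, stack$channels) else channel
  if (is.na(ci)) stop("channel '", channel, "' not present", call. = FALSE)
  stack$data[frame, ci, , ]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames x %d channels (%s), %d x %d px, %.3g um/px, %.3g min/frame\n",
              d[1], d[2], paste(x$channels, collapse = ", "),
              d[3], d[4], x$pixel_size, x$frame_interval))
  invisible(x)
}
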
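# Synthetic scene geometry: the static "fried egg" cell used by the movie
# generator. Adherent interphase cells are flat, with an elliptical nucleus
# surrounded by a thin cytoplasmic skirt, so the whole geometry is treated
# in 2D; a constant z column is carried for 3D-capable consumers.

#' Configuration of a synthetic imaging scene
#'
#' Describes the static geometry and imaging parameters of one synthetic
#' cell: image size, calibration, nucleus and cell ellipses, background and
#' noise levels, and per-channel amplitudes. All physical lengths are in
#' micrometres; the pixel grid places pixel (1, 1) at (x, y) = (0, 0) um with
#' x along columns and y along rows.
#'
#' @param ny,nx image size in pixels (rows, columns).
#' @param pixel_size pixel size in um/px.
#' @param frame_interval time between frames in minutes.
#' @param n_frames number of frames to simulate.
#' @param nucleus_center nucleus ellipse centre (x, y) in um; defaults to the
#'   image centre.
#' @param nucleus_axes nucleus semi-axes (a, b) in um.
#' @param nucleus_theta nucleus orientation in radians (major axis vs +x).
#' @param cell_axes cell-outline ellipse semi-axes (a, b) in um, sharing the
#'   nucleus centre and orientation; must enclose the nucleus.
#' @param cell_polygon optional polygon (two-column matrix of x, y in um)
#'   overriding the elliptical cell outline.
#' @param background camera background level (counts).
#' @param read_sigma Gaussian read-noise standard deviation (counts).
#' @param photon_scale Poisson shot-noise scale; expected counts are drawn as
#'   `rpois(lambda * photon_scale) / photon_scale`. Set to 0 to disable shot
#'   noise.
#' @param psf_sigma point-spread-function sigma in pixels for rendered spots.
#' @param amplitudes named numeric vector of peak amplitudes above background
#'   per channel role. Channels with amplitude 0 render as pure background.
#' @param eb3_speed radial speed of EB3 comets in um/min. The default, 15
#'   um/min (0.25 um/s), is the typical microtubule plus-end growth rate;
#'   EB3 scenes should pair it with a second-scale `frame_interval` (e.g.
#'   1/30 min) so per-frame comet displacements stay within the 3-px
#'   linking radius used for comet tracking.
#' @param eb3_rate new comets nucleated per centrosome per frame.
#' @param actin_ring_width half-width of the perinuclear actin annulus (um).
#' @param seed RNG seed used by the renderer.
#'
#' @details Default amplitudes give a peak signal-to-noise ratio of roughly
#'   15 at the centrosome spots (amplitude 300 over Poisson background 100
#'   with read sigma 2); the detection stage is specified down to SNR 5, so
#'   lowering `amplitudes["centrosome"]` provides the SNR knob for stress
#'   tests.
#'
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(ny = 120, nx = 120,
                         pixel_size = 0.2,
                         frame_interval = 5,
                         n_frames = 25,
                         nucleus_center = NULL,
                         nucleus_axes = c(8, 6),
                         nucleus_theta = 0,
                         cell_axes = c(11.5, 10.5),
                         cell_polygon = NULL,
                         background = 100,
                         read_sigma = 2,
                         photon_scale = 1,
                         psf_sigma = 1.5,
                         amplitudes = c(centrosome = 300, dna = 300,
                                        tubulin = 150, eb3 = 250, actin = 0),
                         eb3_speed = 15,
                         eb3_rate = 2,
                         actin_ring_width = 1,
                         seed = 1L) {
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  if (any(nucleus_axes <= 0)) stop("nucleus semi-axes must be > 0", call. = FALSE)
  if (is.null(cell_polygon) && any(cell_axes <= 0))
    stop("cell semi-axes must be > 0", call. = FALSE)
  if (is.null(nucleus_center))
    nucleus_center <- c((nx - 1) / 2, (ny - 1) / 2) * pixel_size
  cfg <- list(ny = as.integer(ny), nx = as.integer(nx),
              pixel_size = pixel_size, frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              nucleus_center = as.numeric(nucleus_center),
              nucleus_axes = as.numeric(nucleus_axes),
              nucleus_theta = nucleus_theta,
              cell_axes = as.numeric(cell_axes),
              cell_polygon = cell_polygon,
              background = background, read_sigma = read_sigma,
              photon_scale = photon_scale, psf_sigma = psf_sigma,
              amplitudes = amplitudes,
              eb3_speed = eb3_speed, eb3_rate = eb3_rate,
              actin_ring_width = actin_ring_width,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

#' Rasterize an ellipse to a binary mask
#'
#' @param ny,nx mask size (rows, columns).
#' @param center ellipse centre (x, y) in um.
#' @param axes semi-axes (a, b) in um.
#' @param theta orientation in radians.
#' @param pixel_size um/px.
#' @return logical matrix of dimension `c(ny, nx)`.
#' @export
rasterize_ellipse <- function(ny, nx, center, axes, theta, pixel_size) {
  x <- px_to_um(col(matrix(0, ny, nx)), pixel_size) - center[1]
  y <- px_to_um(row(matrix(0, ny, nx)), pixel_size) - center[2]
  u <- (x * cos(theta) + y * sin(theta)) / axes[1]
  v <- (-x * sin(theta) + y * cos(theta)) / axes[2]
  u * u + v * v <= 1
}

#' Rasterize a polygon to a binary mask (even-odd rule)
#'
#' @param ny,nx mask size (rows, columns).
#' @param polygon two-column matrix of vertices (x, y) in um.
#' @param pixel_size um/px.
#' @return logical matrix of dimension `c(ny, nx)`.
#' @export
rasterize_polygon <- function(ny, nx, polygon, pixel_size) {
  if (!is.matrix(polygon) || ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("polygon must be a matrix with >= 3 rows of (x, y)", call. = FALSE)
  px <- px_to_um(seq_len(nx), pixel_size)
  py <- px_to_um(seq_len(ny), pixel_size)
  mask <- matrix(FALSE, ny, nx)
  n <- nrow(polygon)
  xs <- polygon[, 1]; ys <- polygon[, 2]
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j]; y2 <- ys[j]
    if (y1 == y2) next
    # for each mask row, does edge (i,j) cross the horizontal line at py?
    rows <- which((py >= pmin(y1, y2)) & (py < pmax(y1, y2)))
    if (!length(rows)) next
    xcross <- x1 + (py[rows] - y1) / (y2 - y1) * (x2 - x1)
    for (k in seq_along(rows)) {
      cols <- px < xcross[k]
      mask[rows[k], cols] <- !mask[rows[k], cols]
    }
  }
  mask
}

#' Build the static cell geometry of a scene
#'
#' Rasterizes the nucleus and cell outline of a [scene_config()] and returns
#' their masks together with the analytic centroids. The nucleus must lie
#' strictly inside the cell outline.
#'
#' @param config a [scene_config()].
#' @return A list of class `cell_geometry` with elements `nucleus_mask`,
#'   `cell_mask` (logical matrices), `nuclear_centroid`, `cellular_centroid`
#'   (x, y in um) and `pixel_size`.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nuc <- rasterize_ellipse(config$ny, config$nx, config$nucleus_center,
                           config$nucleus_axes, config$nucleus_theta,
                           config$pixel_size)
  cell <- if (!is.null(config$cell_polygon)) {
    rasterize_polygon(config$ny, config$nx, config$cell_polygon,
                      config$pixel_size)
  } else {
    rasterize_ellipse(config$ny, config$nx, config$nucleus_center,
                      config$cell_axes, config$nucleus_theta,
                      config$pixel_size)
  }
  if (any(nuc & !cell))
    stop("nucleus mask is not contained in the cell mask", call. = FALSE)
  geom <- list(nucleus_mask = nuc, cell_mask = cell,
               nuclear_centroid = mask_centroid(nuc, config$pixel_size),
               cellular_centroid = mask_centroid(cell, config$pixel_size),
               pixel_size = config$pixel_size)
  class(geom) <- "cell_geometry"
  geom
}

#' Unweighted centroid of a binary mask in micrometres
#'
#' Centre of mass of the mask pixels, reported as (x, y) in um under the
#' package's pixel-grid convention. This is the reference-point operation
#' behind all positional metrics.
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size um/px.
#' @return numeric vector `c(x, y)` in um.
#' @export
mask_centroid <- function(mask, pixel_size = 1) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid", call. = FALSE)
  c(x = px_to_um(mean(idx[, 2]), pixel_size),
    y = px_to_um(mean(idx[, 1]), pixel_size))
}

#' Distance from points to the boundary of a mask
#'
#' Unsigned Euclidean distance (um) from each query point to the nearest
#' boundary pixel of the mask. Used for nuclear-envelope contact calls.
#'
#' @param x,y query coordinates in um.
#' @param mask logical matrix.
#' @param pixel_size um/px.
#' @return numeric vector of distances in um.
#' @export
boundary_distance <- function(x, y, mask, pixel_size = 1) {
  bnd <- mask_boundary(mask)
  idx <- which(bnd, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(rep(NA_real_, length(x)))
  bx <- px_to_um(idx[, 2], pixel_size)
  by <- px_to_um(idx[, 1], pixel_size)
  vapply(seq_along(x), function(i)
    sqrt(min((bx - x[i])^2 + (by - y[i])^2)), numeric(1))
}

# Boundary pixels: mask pixels with at least one 4-neighbour outside.
mask_boundary <- function(mask) {
  m <- mask != 0
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  interior <- pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  m & !interior
}
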
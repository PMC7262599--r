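# Nucleus and cell segmentation. Nuclei: global threshold -> morphological
# close/open -> distance transform -> Gaussian blur -> watershed to cut
# merged nuclei. Cell outline: Gabor texture energy of the tubulin channel,
# thresholded, keeping the connected component that contains the nucleus; a
# manually drawn polygon can override the automatic outline.

#' Segment nuclei in a DNA-channel frame
#'
#' Otsu threshold, disk close then open, Euclidean distance transform,
#' Gaussian blur and a watershed seeded at the distance maxima to cut
#' merged nuclei. Labels below `min_area` are dropped and the rest
#' relabelled 1..n. A blank or constant frame yields zero labels rather
#' than an error.
#'
#' @param dna numeric matrix (Y x X).
#' @param min_area minimum nucleus area in px.
#' @param brush_radius disk radius (px) of the close/open structuring
#'   element.
#' @param blur_sigma Gaussian sigma (px) applied to the distance transform
#'   before the watershed.
#' @param tolerance watershed saddle tolerance in distance units (px).
#' @return integer label matrix; 0 is background.
#' @export
segment_nuclei <- function(dna, min_area = 200, brush_radius = 2,
                           blur_sigma = 2, tolerance = 1) {
  if (diff(range(dna)) == 0) return(matrix(0L, nrow(dna), ncol(dna)))
  # as in spot detection, the Otsu background is floored at a robust noise
  # level so a frame without nuclei does not split its own noise
  thr <- max(otsu_background(dna), stats::median(dna) + 2 * stats::mad(dna))
  mask <- dna > thr
  brush <- EBImage::makeBrush(2L * brush_radius + 1L, shape = "disc")
  mask <- EBImage::opening(EBImage::closing(mask, brush), brush) > 0
  if (!any(mask)) return(matrix(0L, nrow(dna), ncol(dna)))
  if (all(mask)) return(matrix(1L, nrow(dna), ncol(dna)))
  dm <- EBImage::distmap(mask)
  dmb <- EBImage::gblur(dm, sigma = blur_sigma)
  dmb[!mask] <- 0
  labels <- EBImage::imageData(
    EBImage::watershed(EBImage::Image(dmb), tolerance = tolerance, ext = 1))
  labels[!mask] <- 0L
  relabel_min_area(labels, min_area)
}

relabel_min_area <- function(labels, min_area) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 0L
  for (id in ids) {
    sel <- labels == id
    if (sum(sel) >= min_area) {
      nxt <- nxt + 1L
      out[sel] <- nxt
    }
  }
  out
}

# Even/odd Gabor kernel pair at wavelength lambda (px) and orientation theta.
gabor_kernel <- function(lambda, theta, sigma = 0.56 * lambda, gamma = 0.8) {
  half <- max(3L, ceiling(3 * sigma))
  g <- expand.grid(y = -half:half, x = -half:half)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  k <- 2L * half + 1L
  list(even = matrix(env * cos(2 * pi * xr / lambda), k, k),
       odd = matrix(env * sin(2 * pi * xr / lambda), k, k))
}

#' Gabor texture energy of a frame
#'
#' Summed quadrature magnitude over a bank of Gabor filters (default 4
#' orientations x 2 wavelengths), smoothed with a Gaussian. Textured
#' cytoplasm scores high, flat background low.
#'
#' @param image numeric matrix.
#' @param orientations filter orientations in radians.
#' @param wavelengths filter wavelengths in px.
#' @param smooth_sigma Gaussian sigma (px) applied to the summed energy.
#' @return energy matrix of the same size.
#' @export
gabor_energy <- function(image,
                         orientations = pi * (0:3) / 4,
                         wavelengths = c(4, 8),
                         smooth_sigma = 3) {
  energy <- matrix(0, nrow(image), ncol(image))
  for (lam in wavelengths) for (th in orientations) {
    kk <- gabor_kernel(lam, th)
    re <- EBImage::filter2(image, kk$even)
    im <- EBImage::filter2(image, kk$odd)
    energy <- energy + sqrt(re^2 + im^2)
  }
  EBImage::gblur(energy, sigma = smooth_sigma)
}

#' Segment the cell outline from the tubulin channel
#'
#' Thresholds the Gabor texture energy and keeps the connected component
#' containing (or maximally overlapping) the nucleus, filled and united
#' with the nucleus mask. When a manual polygon is supplied it is
#' rasterized and returned exactly, mirroring manual centroid estimation.
#' If no component overlaps the nucleus the returned mask is empty and
#' carries attribute `failed = TRUE`; callers should exclude the frame
#' rather than abort.
#'
#' @param tubulin numeric matrix.
#' @param nucleus_mask logical matrix of the cell's nucleus.
#' @param polygon optional manual outline, a two-column (x, y) matrix in um.
#' @param pixel_size um/px (needed for `polygon`).
#' @param ... passed to [gabor_energy()].
#' @return logical cell mask with attribute `failed`.
#' @export
segment_cell <- function(tubulin, nucleus_mask, polygon = NULL,
                         pixel_size = NULL, ...) {
  if (!is.null(polygon)) {
    if (is.null(pixel_size))
      stop("pixel_size is required to rasterize a manual polygon", call. = FALSE)
    mask <- rasterize_polygon(nrow(tubulin), ncol(tubulin), polygon, pixel_size)
    attr(mask, "failed") <- FALSE
    return(mask)
  }
  energy <- gabor_energy(tubulin, ...)
  thr <- tryCatch(otsu_background(energy), error = function(e) Inf)
  mask <- energy > thr
  mask <- EBImage::fillHull(mask) > 0
  labels <- EBImage::bwlabel(mask)
  overlap <- vapply(seq_len(max(labels)), function(id)
    sum(labels == id & nucleus_mask), numeric(1))
  if (!length(overlap) || max(overlap) == 0) {
    out <- matrix(FALSE, nrow(tubulin), ncol(tubulin))
    attr(out, "failed") <- TRUE
    return(out)
  }
  out <- (labels == which.max(overlap)) | nucleus_mask
  attr(out, "failed") <- FALSE
  out
}

#' Track labelled nucleus masks over time
#'
#' Computes per-label centroids in each frame and links them across frames
#' with the same machinery used for centrosomes (nearest-neighbour motion
#' model), so nuclear identities persist through the movie. A nucleus that
#' leaves the field terminates its identity; it is never reassigned.
#'
#' @param label_stack list of integer label matrices, one per frame.
#' @param pixel_size um/px.
#' @param search_radius_um linking radius in um per frame.
#' @param max_gap frames a nucleus may go missing and still be relinked.
#' @return data.frame: `cell_id` (persistent identity), `frame`, `label`
#'   (per-frame label), `x_um`, `y_um`.
#' @export
track_masks <- function(label_stack, pixel_size = 1,
                        search_radius_um = 2, max_gap = 1) {
  spots <- do.call(rbind, lapply(seq_along(label_stack), function(f) {
    labels <- label_stack[[f]]
    ids <- setdiff(sort(unique(as.integer(labels))), 0L)
    if (!length(ids)) return(NULL)
    ctr <- t(vapply(ids, function(id)
      mask_centroid(labels == id, pixel_size), numeric(2)))
    data.frame(frame = f, x = ctr[, 1], y = ctr[, 2],
               intensity = vapply(ids, function(id) sum(labels == id),
                                  numeric(1)),
               label = ids)
  }))
  if (is.null(spots))
    return(data.frame(cell_id = integer(), frame = integer(),
                      label = integer(), x_um = numeric(), y_um = numeric()))
  spots$spot_id <- seq_len(nrow(spots))
  tracks <- link_spots(spots, mode = "nearest",
                       search_radius = search_radius_um, max_gap = max_gap)
  m <- merge(tracks, spots[, c("spot_id", "label")], by = "spot_id")
  out <- data.frame(cell_id = m$track_id, frame = m$frame, label = m$label,
                    x_um = m$x, y_um = m$y)
  out[order(out$cell_id, out$frame), ]
}

#' Per-frame cell geometry from a multi-channel stack
#'
#' Segments nuclei (DNA channel) and the cell outline (tubulin channel, if
#' present) in every frame and returns the reference centroids used by the
#' positional metrics. Frames where cell segmentation fails are flagged and
#' should be excluded from cell-centroid metrics.
#'
#' @param stack an `image_stack` with a `dna` channel (and optionally
#'   `tubulin`).
#' @param ... passed to [segment_nuclei()].
#' @return list with `geometry` (data.frame: `cell_id`, `frame`,
#'   `nuc_x_um`, `nuc_y_um`, `cell_x_um`, `cell_y_um`, `cell_failed`),
#'   `nucleus_masks` and `cell_masks` (lists over frames).
#' @export
segment_stack <- function(stack, ...) {
  stopifnot(inherits(stack, "image_stack"))
  n_frames <- dim(stack$data)[1]
  psz <- stack$pixel_size
  nuc_masks <- lapply(seq_len(n_frames), function(f)
    segment_nuclei(get_frame(stack, f, "dna"), ...))
  ids <- track_masks(nuc_masks, psz)
  has_tub <- "tubulin" %in% stack$channels
  cell_masks <- vector("list", n_frames)
  rows <- list()
  for (f in seq_len(n_frames)) {
    labels <- nuc_masks[[f]]
    idf <- ids[ids$frame == f, ]
    for (k in seq_len(nrow(idf))) {
      nmask <- labels == idf$label[k]
      nc <- mask_centroid(nmask, psz)
      if (has_tub) {
        cmask <- segment_cell(get_frame(stack, f, "tubulin"), nmask)
        failed <- isTRUE(attr(cmask, "failed"))
        cc <- if (failed) c(NA_real_, NA_real_) else mask_centroid(cmask, psz)
        cell_masks[[f]] <- cmask
      } else {
        failed <- TRUE
        cc <- c(NA_real_, NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = idf$cell_id[k], frame = f,
        nuc_x_um = nc[1], nuc_y_um = nc[2],
        cell_x_um = cc[1], cell_y_um = cc[2], cell_failed = failed)
    }
  }
  list(geometry = if (length(rows)) do.call(rbind, rows) else
         data.frame(cell_id = integer(), frame = integer(),
                    nuc_x_um = numeric(), nuc_y_um = numeric(),
                    cell_x_um = numeric(), cell_y_um = numeric(),
                    cell_failed = logical()),
       nucleus_masks = nuc_masks, cell_masks = cell_masks)
}
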
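# Spot detection. The centrosome recipe is: difference-of-Gaussians
# band-pass -> Otsu threshold on the filtered image to define background ->
# maxima-seeded region growing above background with highest-saddle
# splitting -> minimum region size -> circularity filter. EB3 comets use a
# Laplacian-of-Gaussian blob detector without the circularity filter
# (comets are elongated by construction).

#' Difference-of-Gaussians band-pass filter
#'
#' Subtracts a wide Gaussian blur from a narrow one, enhancing features
#' between the two scales. The defaults (1.5 and 4.5 px) bracket
#' diffraction-limited spots of size ~3 px.
#'
#' @param image numeric matrix (Y x X).
#' @param r_small,r_large Gaussian sigmas in px, `r_small < r_large`.
#' @return filtered matrix, zero-mean on constant input.
#' @export
dog_filter <- function(image, r_small = 1.5, r_large = 4.5) {
  if (r_small >= r_large)
    stop("r_small must be < r_large", call. = FALSE)
  EBImage::gblur(image, sigma = r_small) - EBImage::gblur(image, sigma = r_large)
}

#' Otsu background threshold
#'
#' Histogram threshold maximizing the between-class variance, computed on a
#' 256-bin histogram spanning the image range. Pixels at or below the
#' returned value are background.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param n_bins number of histogram bins.
#' @return threshold on the intensity scale of `image`.
#' @export
otsu_background <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("constant image: Otsu threshold is undefined", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(v, breaks, all.inside = TRUE), n_bins),
                     nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[n_bins]; mtot <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  mu0 <- m[-n_bins] / w0
  mu1 <- (mtot - m[-n_bins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(bcv)
  breaks[k + 1]  # upper edge of the background class
}

# Moore-neighbour boundary tracing; returns perimeter with axial steps of
# length 1 and diagonal steps of sqrt(2). Regions of area <= 2 fall back to
# small closed-curve conventions (their circularity clips to 1 anyway).
trace_perimeter <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  a <- nrow(idx)
  if (a == 0L) stop("empty region", call. = FALSE)
  if (a == 1L) return(1)
  # clockwise from East
  dirs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1], ]
  inside <- function(p) {
    p[1] >= 1 && p[1] <= nrow(mask) && p[2] >= 1 && p[2] <= ncol(mask) &&
      mask[p[1], p[2]]
  }
  cur <- start
  back_dir <- 5L  # came from the West (outside, by scan order)
  per <- 0
  steps <- 0L
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- ((back_dir - 1L + k - 1L) %% 8L) + 1L
      cand <- cur + dirs[d, ]
      if (inside(cand)) {
        per <- per + if (sum(abs(dirs[d, ])) == 2) sqrt(2) else 1
        # new backtrack: direction pointing from cand to the last empty cell
        prev_d <- ((d - 2L) %% 8L) + 1L
        empty <- cur + dirs[prev_d, ]
        dd <- empty - cand
        back_dir <- which(dirs[, 1] == dd[1] & dirs[, 2] == dd[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) return(1)  # isolated pixel among diagonals
    steps <- steps + 1L
    if (all(cur == start) || steps > 8L * a + 8L) break
  }
  per
}

#' Circularity of a binary region
#'
#' `4 * pi * area / perimeter^2`, with the perimeter measured by
#' boundary-segment counting along the traced 8-connected boundary
#' (diagonal steps count sqrt(2)). Values are clipped to 1 to absorb
#' digitization overshoot; 1 is a disk, elongated shapes score lower.
#'
#' @param mask logical matrix with a single connected region of TRUE.
#' @return circularity in \[0, 1\].
#' @export
circularity <- function(mask) {
  area <- sum(mask)
  if (area == 0L) stop("region has zero area", call. = FALSE)
  if (area <= 2L) return(1)
  p <- trace_perimeter(mask)
  min(4 * pi * area / p^2, 1)
}

#' Grow candidate spot regions from local maxima
#'
#' Above-background pixels are partitioned among the local maxima of the
#' filtered image by a watershed on the inverted relief, so each region is
#' claimed by one maximum; touching maxima are merged when their saddle is
#' shallower than `split_tol_frac` of the tallest peak. Regions smaller
#' than `min_size` are removed.
#'
#' @param filtered DoG- (or LoG-) filtered matrix.
#' @param background_threshold background level from [otsu_background()].
#' @param min_size minimum region area in px.
#' @param split_tol_frac saddle tolerance as a fraction of the maximum
#'   above-background height; peaks separated by shallower saddles are
#'   merged rather than split.
#' @return data.frame with one row per retained region: `x_px`, `y_px`
#'   (intensity-weighted sub-pixel centroid, 1-based), `area_px`,
#'   `circularity`, `peak`, `total` (summed above-background intensity).
#'   The label matrix is attached as attribute `labels`.
#' @export
find_spot_regions <- function(filtered, background_threshold,
                              min_size = 15, split_tol_frac = 0.2) {
  h <- filtered - background_threshold
  h[h < 0] <- 0
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      area_px = integer(), circularity = numeric(),
                      peak = numeric(), total = numeric())
  if (all(h == 0)) { attr(empty, "labels") <- array(0L, dim(filtered)); return(empty) }
  labels <- EBImage::watershed(EBImage::Image(h),
                               tolerance = split_tol_frac * max(h), ext = 1)
  labels <- EBImage::imageData(labels)
  labels[h == 0] <- 0L
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  rows <- lapply(ids, function(id) {
    sel <- which(labels == id, arr.ind = TRUE)
    if (nrow(sel) < min_size) return(NULL)
    wts <- h[sel]
    region <- matrix(FALSE, nrow(filtered), ncol(filtered))
    region[sel] <- TRUE
    data.frame(x_px = sum(sel[, 2] * wts) / sum(wts),
               y_px = sum(sel[, 1] * wts) / sum(wts),
               area_px = nrow(sel),
               circularity = circularity(region),
               peak = max(filtered[sel]),
               total = sum(wts))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "labels") <- labels
  out
}

#' Detect centrosome spots in one frame
#'
#' The full recipe: DoG band-pass, Otsu background on the filtered image,
#' maxima-seeded region growing with a 15-px minimum size, then discarding
#' regions with circularity below 0.7 (elongated detections). Results are
#' sorted by descending peak intensity.
#'
#' @param image raw frame (Y x X matrix).
#' @param r_small,r_large DoG sigmas in px.
#' @param min_size minimum spot area in px.
#' @param circ_min circularity cutoff; regions below it are discarded.
#' @param min_peak_snr minimum peak prominence: a region's peak must rise
#'   at least this many robust SDs (MAD of the sub-threshold filtered
#'   pixels) above the background threshold. On a frame containing only
#'   background the Otsu threshold falls inside the noise distribution, so
#'   a pure size/shape filter would still admit chance clusters; the
#'   prominence requirement rejects them while leaving genuine
#'   diffraction-limited spots (whose band-pass response far exceeds the
#'   noise floor) untouched.
#' @param split_tol_frac see [find_spot_regions()].
#' @return data.frame of spot candidates (columns as in
#'   [find_spot_regions()]), possibly empty. A constant frame yields an
#'   empty result.
#' @export
detect_spots <- function(image, r_small = 1.5, r_large = 4.5,
                         min_size = 15, circ_min = 0.7,
                         min_peak_snr = 5, split_tol_frac = 0.2) {
  f <- dog_filter(image, r_small, r_large)
  if (diff(range(f)) == 0)
    return(find_spot_regions(f, Inf, min_size))  # constant: empty result
  # Otsu defines the background when the filtered histogram is bimodal
  # (background vs spots); on near-unimodal frames it can land inside the
  # noise, so the background never drops below a robust noise floor.
  thr <- max(otsu_background(f), stats::median(f) + 3 * stats::mad(f))
  cand <- find_spot_regions(f, thr, min_size, split_tol_frac)
  sigma_bg <- stats::mad(f[f <= thr])
  cand <- cand[cand$peak >= thr + min_peak_snr * sigma_bg &
                 cand$circularity >= circ_min, , drop = FALSE]
  cand[order(-cand$peak), , drop = FALSE]
}

#' Detect EB3 comets in one frame
#'
#' Laplacian-of-Gaussian blob detection at the comet scale. Local maxima of
#' the scale-normalized LoG response above a robust noise floor (median +
#' `k_mad` median absolute deviations) are reported with sub-pixel centroids
#' from a 3 x 3 intensity-weighted refinement. No circularity filter is
#' applied: comets are elongated.
#'
#' @param image raw frame.
#' @param sigma LoG scale in px.
#' @param k_mad response threshold in robust SDs above the median.
#' @return data.frame with `x_px`, `y_px`, `response` per comet.
#' @export
detect_comets <- function(image, sigma = 1.5, k_mad = 6) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- -sigma^2 * EBImage::filter2(EBImage::gblur(image, sigma), lap)
  thr <- stats::median(resp) + k_mad * stats::mad(resp)
  mx <- local_maxima(resp)
  mx <- mx[resp[mx] > thr, , drop = FALSE]
  if (nrow(mx) == 0L)
    return(data.frame(x_px = numeric(), y_px = numeric(), response = numeric()))
  # non-maximum suppression within 2*sigma
  o <- order(-resp[mx])
  mx <- mx[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(mx))
  for (i in seq_len(nrow(mx))) {
    if (!keep[i]) next
    if (i < nrow(mx)) {
      j <- (i + 1):nrow(mx)
      d2 <- (mx[j, 1] - mx[i, 1])^2 + (mx[j, 2] - mx[i, 2])^2
      keep[j][d2 <= (2 * sigma)^2] <- FALSE
    }
  }
  mx <- mx[keep, , drop = FALSE]
  ref <- t(apply(mx, 1, function(p) refine_centroid(resp, p[1], p[2])))
  data.frame(x_px = ref[, 1], y_px = ref[, 2], response = resp[mx])
}

# 3x3 intensity-weighted sub-pixel refinement around (row, col).
refine_centroid <- function(img, r, c) {
  rs <- max(1, r - 1):min(nrow(img), r + 1)
  cs <- max(1, c - 1):min(ncol(img), c + 1)
  w <- img[rs, cs, drop = FALSE]
  w <- w - min(w)
  if (sum(w) == 0) return(c(c, r))
  c(sum(rep(cs, each = length(rs)) * w) / sum(w),
    sum(rep(rs, length(cs)) * w) / sum(w))
}

# Strict-ish 8-neighbour local maxima as (row, col) index matrix.
local_maxima <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- img
  ok <- matrix(TRUE, ny, nx)
  greater <- matrix(FALSE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
    ok <- ok & (img >= nb)
    greater <- greater | (img > nb)
  }
  which(ok & greater, arr.ind = TRUE)
}

#' Detect spots across all frames of a stack channel
#'
#' Runs [detect_spots()] (or [detect_comets()] for the EB3 channel) on every
#' frame and returns a tidy table with pixel and micrometre coordinates.
#'
#' @param stack an `image_stack`.
#' @param channel channel role to process.
#' @param comet use the comet detector instead of the spot detector.
#' @param ... passed to the per-frame detector.
#' @return data.frame: `frame`, `t_min`, `channel`, `x_px`, `y_px`, `x_um`,
#'   `y_um`, plus the detector's shape/intensity columns and a per-frame
#'   `spot_id`.
#' @export
detect_stack <- function(stack, channel = "centrosome",
                         comet = identical(channel, "eb3"), ...) {
  stopifnot(inherits(stack, "image_stack"))
  n_frames <- dim(stack$data)[1]
  out <- lapply(seq_len(n_frames), function(f) {
    det <- if (comet) detect_comets(get_frame(stack, f, channel), ...)
           else detect_spots(get_frame(stack, f, channel), ...)
    if (nrow(det) == 0L) return(NULL)
    det$frame <- f
    det$t_min <- (f - 1) * stack$frame_interval
    det$channel <- channel
    det$x_um <- px_to_um(det$x_px, stack$pixel_size)
    det$y_um <- px_to_um(det$y_px, stack$pixel_size)
    det$spot_id <- seq_len(nrow(det))
    det
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(frame = integer(), t_min = numeric(),
                      channel = character(), x_px = numeric(),
                      y_px = numeric(), x_um = numeric(), y_um = numeric(),
                      spot_id = integer()))
  do.call(rbind, out)
}
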
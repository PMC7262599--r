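# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (dense loops, exhaustive search) so
# it stays independent of the package's optimized code paths.

# Exhaustive Otsu: try every histogram cut point, compute class means and
# between-class variance directly from the binned data.
otsu_bruteforce <- function(v, n_bins = 256) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(v, breaks, all.inside = TRUE), n_bins)
  best <- -Inf; best_k <- NA
  for (k in 1:(n_bins - 1)) {
    lo <- v[bin <= k]; hi <- v[bin > k]
    if (!length(lo) || !length(hi)) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  breaks[best_k + 1]
}

# Dense direct convolution with a normalized Gaussian kernel (no FFT).
dense_gaussian_blur <- function(img, sigma) {
  half <- ceiling(4 * sigma)
  ker <- outer(-half:half, -half:half,
               function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  ker <- ker / sum(ker)
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- min(max(i + di, 1), ny)  # replicate border
      jj <- min(max(j + dj, 1), nx)
      acc <- acc + img[ii, jj] * ker[di + half + 1, dj + half + 1]
    }
    out[i, j] <- acc
  }
  out
}

# Minimum-total-distance assignment by exhaustive permutation (n <= 5).
hungarian_bruteforce <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 5)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf; best_p <- NULL
  for (p in perms(seq_len(n))) {
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (tot < best) { best <- tot; best_p <- p }
  }
  list(assignment = best_p, cost = best)
}

# Small default scene used in many tests.
test_scene_config <- function(...) {
  scene_config(ny = 120, nx = 120, seed = 42L, ...)
}

# Render a single two-spot frame with known positions; returns list with
# the frame matrix, truth positions (um) and the config.
two_spot_frame <- function(amp = 300, noise = TRUE, seed = 1L,
                           pos = rbind(c(8, 9), c(16.2, 14.6))) {
  cfg <- scene_config(
    seed = seed,
    read_sigma = if (noise) 2 else 0,
    photon_scale = if (noise) 1 else 0,
    amplitudes = c(centrosome = amp, dna = 0, tubulin = 0, eb3 = 0,
                   actin = 0))
  scene <- make_scene(cfg)
  truth <- data.frame(cell_id = 1L, frame = 1L, t_min = 0,
                      centrosome_id = 1:2,
                      x_um = pos[, 1], y_um = pos[, 2], z_um = 0,
                      phase = "post")
  stack <- render_movie(scene, truth, cfg, channels = "centrosome")
  list(frame = stack$data[1, 1, , ], truth = truth, config = cfg,
       scene = scene)
}
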
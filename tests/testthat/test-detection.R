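test_that("DoG filter is zero-mean on constant input and validates radii", {
  img <- matrix(7, 40, 40)
  out <- dog_filter(img)
  expect_lt(max(abs(out)), 1e-8)
  expect_error(dog_filter(img, 4.5, 1.5), "r_small")
  expect_error(dog_filter(img, 2, 2), "r_small")
})

test_that("DoG argmax agrees with a dense direct-convolution oracle", {
  img <- matrix(0, 61, 61)
  gx <- outer((1:61) - 41, (1:61) - 41,
              function(a, b) exp(-(a^2 + b^2) / (2 * 1.5^2)))
  img <- img + 100 * gx  # spot at (row 41, col 41)
  fast <- dog_filter(img, 1.5, 4.5)
  oracle <- dense_gaussian_blur(img, 1.5) - dense_gaussian_blur(img, 4.5)
  expect_equal(which.max(fast), which.max(oracle))
  wm <- arrayInd(which.max(fast), dim(fast))
  expect_equal(as.integer(wm), c(41L, 41L))
  # central values agree between implementations
  expect_equal(fast[31:51, 31:51], oracle[31:51, 31:51], tolerance = 0.02)
})

test_that("Otsu threshold separates two equal-mass modes", {
  set.seed(1)
  v <- c(rnorm(5000, 10, 1), rnorm(5000, 200, 4))
  thr <- otsu_background(matrix(v, 100, 100))
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  # invariance to constant offset (up to that offset)
  thr2 <- otsu_background(matrix(v + 50, 100, 100))
  expect_equal(thr2, thr + 50, tolerance = 1e-9)
  expect_error(otsu_background(matrix(3, 10, 10)), "constant")
})

test_that("Otsu equals exhaustive between-class-variance maximization", {
  set.seed(99)
  for (k in 1:20) {
    n1 <- sample(200:2000, 1); n2 <- sample(200:2000, 1)
    v <- c(rnorm(n1, runif(1, 0, 50), runif(1, 0.5, 5)),
           rnorm(n2, runif(1, 60, 250), runif(1, 1, 10)))
    expect_equal(otsu_background(v), otsu_bruteforce(v), tolerance = 1e-12)
  }
})

test_that("regions smaller than the minimum spot size are removed", {
  img <- matrix(0, 50, 50)
  img[10:11, 10:14] <- 10   # 10 px region
  img[30:34, 30:34] <- 10   # 25 px region
  reg <- find_spot_regions(img, background_threshold = 5, min_size = 15)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$area_px, 25)
  # all-background frame: empty result, not an error
  empty <- find_spot_regions(matrix(0, 30, 30), 5)
  expect_equal(nrow(empty), 0)
})

test_that("two well-separated rendered spots give two regions at truth", {
  tw <- two_spot_frame(noise = FALSE)
  f <- dog_filter(tw$frame)
  reg <- find_spot_regions(f, otsu_background(f))
  expect_equal(nrow(reg), 2)
  reg <- reg[order(reg$x_px), ]
  tr <- tw$truth[order(tw$truth$x_um), ]
  expect_lt(max(abs(reg$x_px - um_to_px(tr$x_um, 0.2))), 1)
  expect_lt(max(abs(reg$y_px - um_to_px(tr$y_um, 0.2))), 1)
})

test_that("circularity follows the isoperimetric identity on known shapes", {
  disk <- matrix(FALSE, 40, 40)
  disk[(row(disk) - 20)^2 + (col(disk) - 20)^2 <= 100] <- TRUE
  expect_gte(circularity(disk), 0.85)
  line <- matrix(FALSE, 20, 30)
  line[10, 8:22] <- TRUE
  # oracle: area 15, traced perimeter 2 x 14 -> 4*pi*15/784
  expect_equal(circularity(line), 4 * pi * 15 / 28^2, tolerance = 1e-9)
  expect_lt(circularity(line), 0.3)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(circularity(one), 1)
  expect_error(circularity(matrix(FALSE, 5, 5)), "zero area")
})

test_that("elongated streaks with sufficient area are discarded", {
  img <- matrix(100, 60, 60)
  # 3:1 anisotropic Gaussian streak, bright and large
  y <- row(img) - 30; x <- col(img) - 30
  img <- img + 400 * exp(-(x^2 / (2 * 6^2) + y^2 / (2 * 2^2)))
  img <- round(img)
  f <- dog_filter(img)
  reg <- find_spot_regions(f, otsu_background(f), min_size = 15)
  expect_gte(nrow(reg), 1)          # the streak is a candidate by size...
  expect_lt(max(reg$circularity), 0.7)
  det <- detect_spots(img)          # ...but the circularity filter drops it
  expect_equal(nrow(det), 0)
})

test_that("detection recovers rendered spots and rejects pure noise", {
  tw <- two_spot_frame(amp = 102, noise = TRUE, seed = 3)
  det <- detect_spots(tw$frame)
  expect_equal(nrow(det), 2)
  det <- det[order(det$x_px), ]
  tr <- tw$truth[order(tw$truth$x_um), ]
  expect_lt(max(abs(det$x_px - um_to_px(tr$x_um, 0.2))), 1)
  set.seed(7)
  noise <- pmax(round(matrix(rpois(90 * 90, 100) + rnorm(8100, 0, 2),
                             90, 90)), 0)
  expect_equal(nrow(detect_spots(noise)), 0)
  # constant frame: empty, no error
  expect_equal(nrow(detect_spots(matrix(5, 40, 40))), 0)
})

test_that("raising min_size or the circularity cutoff never adds spots", {
  tw <- two_spot_frame(amp = 150, noise = TRUE, seed = 9)
  sizes <- c(5, 15, 30, 60)
  counts <- vapply(sizes, function(ms)
    nrow(detect_spots(tw$frame, min_size = ms)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  cuts <- c(0.3, 0.5, 0.7, 0.9, 0.99)
  counts2 <- vapply(cuts, function(cc)
    nrow(detect_spots(tw$frame, circ_min = cc)), numeric(1))
  expect_true(all(diff(counts2) <= 0))
})

test_that("comet detector finds rendered blobs and ignores flat frames", {
  img <- matrix(100, 80, 80)
  pts <- rbind(c(15, 20), c(55, 18), c(30, 60), c(66, 64), c(44, 40))
  for (k in seq_len(nrow(pts))) {
    y <- row(img) - pts[k, 1]; x <- col(img) - pts[k, 2]
    img <- img + 200 * exp(-(x^2 + y^2) / (2 * 1.5^2))
  }
  img <- round(img)
  det <- detect_comets(img)
  expect_equal(nrow(det), 5)
  for (k in seq_len(nrow(pts))) {
    d <- sqrt((det$y_px - pts[k, 1])^2 + (det$x_px - pts[k, 2])^2)
    expect_lte(min(d), 1)
  }
  expect_equal(nrow(detect_comets(matrix(50, 40, 40))), 0)
})

test_that("noiseless detection centroids match truth to half a pixel", {
  tw <- two_spot_frame(noise = FALSE, pos = rbind(c(8.13, 9.41), c(16.3, 14.57)))
  det <- detect_spots(tw$frame)
  det <- det[order(det$x_px), ]
  tr <- tw$truth[order(tw$truth$x_um), ]
  expect_lt(max(abs(det$x_px - um_to_px(tr$x_um, 0.2))), 0.5)
  expect_lt(max(abs(det$y_px - um_to_px(tr$y_um, 0.2))), 0.5)
})
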
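# FFT orientation index: spectrum normalization, binarization convention,
# equivalent-ellipse axes, analytic limits, invariances.

test_that("constant ROI gives an all-zero magnitude and degenerate flag", {
  mg <- fft_magnitude(matrix(4, 32, 32))
  expect_true(mg$degenerate)
  expect_true(all(mg$magnitude == 0))
  ax <- orientation_index(matrix(4, 32, 32))
  expect_true(ax$degenerate)
  expect_true(is.na(ax$oi))
})

test_that("non-finite pixels are rejected", {
  m <- matrix(1, 8, 8); m[3, 3] <- NA
  expect_error(fft_magnitude(m), "finite")
})

test_that("sinusoid spectrum peaks at the conjugate frequency pixels", {
  n <- 64
  x <- matrix(sin(2 * pi * (1:n) / 8), n, n, byrow = TRUE)  # varies along cols
  mg <- fft_magnitude(x, window = FALSE)$magnitude
  peaks <- which(mg >= 1 - 1e-9, arr.ind = TRUE)
  ctr <- n / 2 + 1
  expect_equal(nrow(peaks), 2)
  expect_true(all(peaks[, 1] == ctr))               # on the axis through DC
  expect_setequal(peaks[, 2], c(ctr - 8, ctr + 8))  # +/- n/8 = period-8 pair
})

test_that("magnitude is max-normalized for any non-constant input", {
  for (s in 1:5) {
    set.seed(s)
    mg <- fft_magnitude(matrix(runif(256), 16, 16))
    expect_equal(max(mg$magnitude), 1)
    expect_true(all(mg$magnitude >= 0 & mg$magnitude <= 1))
  }
})

test_that("binarization uses the inclusive >= convention and records the threshold", {
  m <- matrix(0, 4, 4); m[2, 2] <- 0.38; m[3, 3] <- 1
  sm <- binarize_spectrum(m, threshold = 0.38)
  expect_true(sm$mask[2, 2])   # boundary value included
  expect_equal(sum(sm$mask), 2)
  expect_equal(sm$threshold, 0.38)
  expect_error(binarize_spectrum(m, threshold = 0), "threshold")
  expect_error(binarize_spectrum(m, threshold = 1), "threshold")
  empty <- binarize_spectrum(list(magnitude = matrix(0, 4, 4),
                                  degenerate = TRUE))
  expect_true(empty$degenerate)
  expect_equal(sum(empty$mask), 0)
})

test_that("axis estimation matches analytic shapes", {
  n <- 201; ctr <- 101
  # disk: lambda1 = lambda2, OI = 0
  disk <- outer(1:n, 1:n, function(r, c) (r - ctr)^2 + (c - ctr)^2 <= 50^2)
  ax <- estimate_axes(disk)
  expect_equal(ax$oi, 0, tolerance = 1e-12)
  # single row: collinear, OI = 1
  row1 <- matrix(FALSE, 21, 21); row1[11, ] <- TRUE
  ax1 <- estimate_axes(row1)
  expect_equal(ax1$short_axis_px, 0)
  expect_equal(ax1$oi, 1)
  # 2:1 axis-aligned ellipse: OI = 0.5 within discretization
  ell <- outer(1:n, 1:n, function(r, c)
    ((r - ctr) / 30)^2 + ((c - ctr) / 60)^2 <= 1)
  expect_equal(estimate_axes(ell)$oi, 0.5, tolerance = 0.02)
  # empty mask errors; single pixel carries no anisotropy
  expect_error(estimate_axes(matrix(FALSE, 4, 4)), "degenerate")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(estimate_axes(one)$oi, 0)
})

test_that("radially symmetric image has OI = 0 to machine precision", {
  expect_equal(orientation_index(gaussian_spot(256, 15))$oi, 0,
               tolerance = 1e-6)
  expect_equal(orientation_index(gaussian_spot(128, 8),
                                 window = FALSE)$oi, 0, tolerance = 1e-6)
})

test_that("parallel fibers give OI >= 0.9, agreeing with the brute-force oracle", {
  sc <- generate_fiber_image(shape_px = c(512, 512), n_fibers = 40,
                             orientation_mean_deg = 30,
                             orientation_concentration = 1e6,
                             length_law = list(type = "uniform",
                                               min = 150, max = 450),
                             seed = 6)
  ax <- orientation_index(sc$image)
  expect_gte(ax$oi, 0.9)
  mask <- binarize_spectrum(fft_magnitude(sc$image$pixels))$mask
  expect_equal(ax$oi, naive_axis_oi(mask), tolerance = 1e-10)
})

test_that("OI is invariant under rotation within tolerance", {
  sc <- generate_fiber_image(shape_px = c(360, 360), n_fibers = 40,
                             orientation_mean_deg = 90,
                             orientation_concentration = 12,
                             length_law = list(type = "uniform",
                                               min = 100, max = 300),
                             noise_model = list(type = "none"),
                             seed = 14)
  img <- sc$image$pixels
  rot <- EBImage::rotate(img, 37, output.dim = c(360, 360),
                         bg.col = sc$truth$background)
  crop <- function(m) m[53:308, 53:308]
  oi0 <- orientation_index(crop(img))$oi
  oi1 <- orientation_index(crop(as.matrix(rot)))$oi
  expect_lt(abs(oi0 - oi1), 0.05)
})

test_that("OI is invariant under intensity scaling", {
  sc <- generate_fiber_image(shape_px = c(128, 128), n_fibers = 15, seed = 2)
  expect_equal(orientation_index(sc$image$pixels)$oi,
               orientation_index(3.7 * sc$image$pixels)$oi)
})

test_that("OI always lies in [0, 1] on random and structured inputs", {
  for (s in 1:10) {
    set.seed(s)
    oi <- orientation_index(matrix(runif(64 * 64), 64, 64))$oi
    expect_true(oi >= 0 && oi <= 1)
  }
})
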
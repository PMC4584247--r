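make_cube <- function(rows = 4, cols = 5, grid = c(400, 500, 600),
                      fill = function(n) seq_len(n)) {
  n <- rows * cols * length(grid)
  hypercube(array(fill(n), c(rows, cols, length(grid))), grid)
}

test_that("reflectance calibration identities hold", {
  white <- make_cube(fill = function(n) rep(2, n))
  dark <- make_cube(fill = function(n) rep(0.5, n))

  cal <- calibrate_reflectance(white, white, dark)
  expect_true(all(cal$values == 1))

  cal0 <- calibrate_reflectance(dark, white, dark)
  expect_true(all(cal0$values == 0))

  mid <- make_cube(fill = function(n) rep((2 + 0.5) / 2, n))
  expect_true(all(calibrate_reflectance(mid, white, dark)$values == 0.5))
})

test_that("calibration rejects mismatched or degenerate references", {
  white <- make_cube(fill = function(n) rep(2, n))
  dark <- make_cube(fill = function(n) rep(0.5, n))
  small <- hypercube(array(1, c(2, 2, 3)), c(400, 500, 600))
  expect_error(calibrate_reflectance(small, white, dark), "shape")
  expect_error(calibrate_reflectance(white, white, white), "degenerate")
  other_grid <- make_cube(grid = c(401, 500, 600), fill = function(n) rep(0.5, n))
  expect_error(calibrate_reflectance(white, white, other_grid), "grid")
})

test_that("band cropping keeps the closed interval", {
  cube <- make_cube()
  full <- crop_bands(cube, 400, 600)
  expect_identical(full$values, cube$values)

  part <- crop_bands(cube, 450, 1000)
  expect_equal(part$wavelength, c(500, 600))
  expect_equal(part$values, cube$values[, , 2:3])

  g512 <- make_wavelength_grid(512, 380, 1030)
  # brute-force oracle: count grid points inside the closed interval
  expect_equal(sum(g512 >= 420 & g512 <= 1000), 456)
  big <- hypercube(array(0, c(2, 2, 512)), g512)
  expect_equal(dim(crop_bands(big, 420, 1000))[3], 456)

  expect_error(crop_bands(cube, 601, 1000), "empty")
  expect_error(crop_bands(cube, 600, 400), "lo_nm")
})

test_that("band-difference masking thresholds at >= and is idempotent", {
  g <- c(569, 893)
  v <- array(0, c(2, 3, 2))
  v[, , 2] <- matrix(c(0.5, 0.39, 0.4, 0.0, 0.41, 0.8), 2, 3)
  cube <- hypercube(v, g)
  m <- build_mask(cube, 893, 569, threshold = 0.4)
  expect_identical(m$flags, v[, , 2] >= 0.4)

  # identical band images -> all background
  same <- hypercube(array(0.7, c(2, 3, 2)), g)
  expect_false(any(build_mask(same, 893, 569)$flags))

  # idempotent: re-thresholding the mask's own difference does not change it
  m2 <- build_mask(cube, 893, 569, threshold = 0.4)
  expect_identical(m$flags, m2$flags)

  expect_error(build_mask(cube, 1200, 569), "outside")
})

test_that("masks recover synthetic footprints at the default threshold", {
  cap <- tiny_capture(n_blobs = 4, n_bands = 128, seed = 31)
  refl <- calibrate_reflectance(cap$raw, cap$white, cap$dark)
  m <- build_mask(refl)
  fp <- unlist(cap$footprints)
  expect_gte(mean(m$flags[fp]), 0.99)
  expect_equal(sum(m$flags[-fp]), 0)
})

test_that("mean ROI spectra average foreground pixels per band", {
  g <- c(450, 550)
  v <- array(0, c(2, 2, 2))
  v[1, 1, ] <- c(1, 2); v[2, 1, ] <- c(3, 6)
  cube <- hypercube(v, g)

  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(extract_mean_spectrum(cube, one), c(1, 2))

  two <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(extract_mean_spectrum(cube, two), c(2, 4))

  expect_error(extract_mean_spectrum(cube, matrix(FALSE, 2, 2)), "empty ROI")
})

test_that("noisy blob means converge to the noise-free spectrum", {
  params <- spectral_model_params(noise_sd = 0.02, scatter_sd = 0,
                                  saturation_rate = 0)
  cap <- tiny_capture(n_blobs = 1, n_bands = 32, seed = 13, params = params)
  refl <- calibrate_reflectance(cap$raw, cap$white, cap$dark)
  fp <- cap$footprints[[1]]
  sel <- matrix(FALSE, 64, 64); sel[fp] <- TRUE
  got <- extract_mean_spectrum(refl, sel)
  want <- model_reflectance(cap$grid, cap$truth_tss[1], params)
  tol <- 4 * 0.02 * max(want) / sqrt(length(fp))
  expect_true(all(abs(got - want) < tol))
})

test_that("median filtering matches brute-force medians with reflection edges", {
  expect_identical(median_filter_image(matrix(3, 4, 4), 3), matrix(3, 4, 4))

  # single impulse wiped out by a 5x5 window
  img <- matrix(0, 7, 7); img[4, 4] <- 100
  expect_true(all(median_filter_image(img, 5) == 0))

  # centre of a 5x5 ramp is the 13th order statistic
  ramp <- matrix(1:25, 5, 5)
  expect_equal(median_filter_image(ramp, 5)[3, 3], 13)

  # brute-force oracle at every pixel, reflection padding computed literally
  set.seed(2)
  x <- matrix(rnorm(30), 5, 6)
  w <- 3; r <- 1
  pad <- rbind(x[2, ], x, x[4, ])
  pad <- cbind(pad[, 2], pad, pad[, 5])
  want <- x
  for (i in 1:5) for (j in 1:6) {
    want[i, j] <- median(pad[i:(i + 2 * r), j:(j + 2 * r)])
  }
  expect_equal(median_filter_image(x, w), want)

  # idempotent on piecewise-constant images with large features
  pc <- matrix(1, 8, 8); pc[1:4, ] <- 5
  once <- median_filter_image(pc, 3)
  expect_equal(median_filter_image(once, 3), once)

  expect_error(median_filter_image(x, 4), "odd")
})

test_that("calibrate-then-crop commutes with crop-then-calibrate", {
  cap <- tiny_capture(n_blobs = 2, n_bands = 32, seed = 17)
  a <- crop_bands(calibrate_reflectance(cap$raw, cap$white, cap$dark), 420, 1000)
  b <- calibrate_reflectance(crop_bands(cap$raw, 420, 1000),
                             crop_bands(cap$white, 420, 1000),
                             crop_bands(cap$dark, 420, 1000))
  expect_equal(a$values, b$values, tolerance = 1e-14)
  expect_equal(a$wavelength, b$wavelength)
})

test_that("connected-component labelling splits disjoint blobs", {
  flags <- matrix(FALSE, 6, 7)
  flags[1:2, 1:2] <- TRUE      # component 1
  flags[5:6, 6:7] <- TRUE      # component 2
  flags[4, 4] <- TRUE          # component 3 (single pixel)
  lab <- label_mask(flags)
  expect_equal(max(lab), 3)
  expect_true(all(lab[flags] > 0))
  expect_true(all(lab[!flags] == 0))
  expect_equal(length(unique(as.vector(lab[1:2, 1:2]))), 1)
  expect_equal(length(unique(as.vector(lab[5:6, 6:7]))), 1)
})
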
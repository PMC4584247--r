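test_that("unfold orders pixels row-major and folds back exactly", {
  v <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  cube <- hypercube(v, c(100, 200, 300))
  u <- unfold(cube)
  expect_equal(dim(u), c(4, 3))
  expect_equal(u[1, ], v[1, 1, ]) # pixel (1,1) first
  expect_equal(u[2, ], v[1, 2, ]) # then the rest of row 1
  expect_equal(u[3, ], v[2, 1, ])

  back <- fold_cube(u, wavelength = cube$wavelength)
  expect_identical(back$values, cube$values)

  one <- hypercube(array(rnorm(5), c(1, 1, 5)), 1:5)
  expect_equal(dim(unfold(one)), c(1, 5))

  # fold_map inverts the spatial part
  m <- fold_map(u[, 2], dim(v)[1:2])
  expect_equal(m, v[, , 2])
})

test_that("the published 23-coefficient model evaluates as printed", {
  m <- published_tss_model()
  expect_length(m$coefficients, 23)
  expect_length(m$wavelengths, 23)
  expect_equal(m$wavelengths[1:4], c(960, 929, 814, 849))

  expect_equal(evaluate_published_model(rep(0, 23), m), 16.207)

  probe <- rep(0, 23); probe[5] <- 1 # the 432 nm term, coefficient +0.007
  expect_equal(evaluate_published_model(probe, m), 16.214)

  # independent hand tally of the printed coefficients sums to -16.525
  expect_equal(evaluate_published_model(rep(1, 23), m), 16.207 - 16.525,
               tolerance = 1e-12)

  expect_error(evaluate_published_model(rep(0, 22), m), "23")
})

test_that("per-pixel maps agree with tabular predictions", {
  grid <- make_wavelength_grid(64, 380, 1030)
  s <- model_reflectance(grid, 7)
  v <- array(rep(s, each = 36), c(6, 6, 64))
  cube <- hypercube(v, grid)
  flags <- matrix(TRUE, 6, 6); flags[1, 1] <- FALSE

  tb <- linear_table(n = 30, p = 64, planted = c(10, 40), noise_sd = 0.05,
                     seed = 3)
  pm <- fit_plsr(tb$X, tb$y, n_lv = 2, wavelengths = grid)
  map <- predict_map(cube, flags, pm, denoise = FALSE)

  want <- predict(pm, matrix(s, 1))
  expect_true(all(abs(map$values[flags] - want) < 1e-10))
  expect_true(is.na(map$values[1, 1])) # background carries NA, never 0

  # single-pixel agreement
  expect_equal(map$values[3, 4], want)
})

test_that("a zero-reflectance cube maps to the published intercept", {
  m <- published_tss_model()
  grid <- make_wavelength_grid(512, 380, 1030)
  cube <- hypercube(array(0, c(4, 4, 512)), grid)
  map <- predict_map(cube, matrix(TRUE, 4, 4), m, denoise = FALSE)
  expect_true(all(map$values == 16.207))
})

test_that("footprint means of linear-model maps equal mean-spectrum predictions", {
  cap <- tiny_capture(n_blobs = 3, n_bands = 96, seed = 23)
  refl <- calibrate_reflectance(cap$raw, cap$white, cap$dark)
  mask <- build_mask(refl)
  tb <- linear_table(n = 30, p = 96, planted = c(20, 70), noise_sd = 0.05)
  pm <- fit_plsr(tb$X, tb$y, n_lv = 2, wavelengths = refl$wavelength)
  map <- predict_map(refl, mask, pm, denoise = FALSE)
  for (i in seq_along(cap$footprints)) {
    sel <- matrix(FALSE, 64, 64)
    sel[cap$footprints[[i]]] <- TRUE
    sel <- sel & mask$flags
    want <- predict(pm, matrix(extract_mean_spectrum(refl, sel), 1))
    expect_equal(mean(map$values[sel]), want, tolerance = 1e-8)
  }
})

test_that("saturated pixels are excluded from map statistics", {
  grid <- make_wavelength_grid(32, 380, 1030)
  v <- array(0.5, c(4, 4, 32))
  cube <- hypercube(v, grid)
  flags <- matrix(TRUE, 4, 4)
  sat <- matrix(FALSE, 4, 4); sat[2, 2] <- TRUE
  tb <- linear_table(n = 20, p = 32, planted = 5, noise_sd = 0.05)
  pm <- fit_plsr(tb$X, tb$y, n_lv = 1, wavelengths = grid)
  map <- predict_map(cube, flags, pm, denoise = FALSE, saturated = sat)
  s <- map_stats(map)
  expect_equal(unname(s["n_pixels"]), 15)
})

test_that("saturation flags fire on full-scale raw counts", {
  cap <- tiny_capture(n_blobs = 2, n_bands = 32, seed = 29,
                      params = spectral_model_params(saturation_rate = 0.1))
  sat <- saturation_flags(cap$raw, cap$full_scale)
  expect_identical(unname(sat), unname(cap$saturated))
})

test_that("pseudo-colour rendering is a linear blue-to-red ramp", {
  m <- matrix(c(3, 7, 11, NA), 2, 2)
  map <- structure(list(values = m, mask = !is.na(m),
                        saturated = matrix(FALSE, 2, 2)),
                   class = "chemical_map")
  rgb <- render_pseudocolour(map, lo = 3, hi = 11)
  expect_equal(rgb[1, 1, ], c(0, 0, 1)) # lo -> blue
  expect_equal(rgb[1, 2, ], c(1, 0, 0)) # hi -> red
  expect_equal(rgb[2, 1, ], c(0.5, 0, 0.5)) # midpoint of the ramp
  expect_equal(rgb[2, 2, ], rep(unname(grDevices::col2rgb("gray85")[1] / 255), 3))
  expect_error(render_pseudocolour(map, 5, 5), "lo")
})

test_that("median denoising before prediction changes only noisy maps", {
  grid <- make_wavelength_grid(32, 380, 1030)
  v <- array(0.4, c(8, 8, 32))
  cube <- hypercube(v, grid)
  tb <- linear_table(n = 20, p = 32, planted = 5, noise_sd = 0.05)
  pm <- fit_plsr(tb$X, tb$y, n_lv = 1, wavelengths = grid)
  m1 <- predict_map(cube, matrix(TRUE, 8, 8), pm, denoise = TRUE)
  m2 <- predict_map(cube, matrix(TRUE, 8, 8), pm, denoise = FALSE)
  expect_equal(m1$values, m2$values, tolerance = 1e-12) # constant image
})
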
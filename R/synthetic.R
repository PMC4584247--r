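# Seeded synthetic generator: raw/white/dark captures of dark-fruit blobs on
# a uniform background, with a known linear TSS -> reflectance coupling so
# every downstream stage (calibration, masking, partitioning, wavelength
# selection, modelling, mapping) can be tested against ground truth.

#' Evenly spaced wavelength grid
#'
#' @param n_bands number of bands (>= 2).
#' @param lo_nm,hi_nm wavelength range endpoints in nm, `lo_nm < hi_nm`.
#' @return strictly increasing numeric vector of length `n_bands` whose
#'   endpoints equal `lo_nm` and `hi_nm`.
#' @examples
#' make_wavelength_grid(512, 380, 1030)[1:5]
#' @export
make_wavelength_grid <- function(n_bands, lo_nm, hi_nm) {
  if (!is.numeric(n_bands) || length(n_bands) != 1L || n_bands < 2 ||
      n_bands != round(n_bands)) {
    stop_invalid("`n_bands` must be an integer >= 2")
  }
  if (!(lo_nm < hi_nm)) stop_invalid("`lo_nm` must be < `hi_nm`")
  seq(lo_nm, hi_nm, length.out = as.integer(n_bands))
}

#' Draw reference TSS values from a truncated normal
#'
#' Emulates a field-collected distribution of total soluble solids: normal
#' with the given mean/SD, truncated (by rejection) to `[lo, hi]`. Defaults
#' reproduce a ripe dark-fruit crop: mean 6.75, SD 1.55, range
#' 3.21-10.99 degrees Brix.
#'
#' @param n number of samples (> 0).
#' @param seed integer seed; the same seed yields the same vector.
#' @param mean,sd normal parameters in degrees Brix (`sd > 0`).
#' @param lo,hi truncation bounds in degrees Brix (`lo < hi`).
#' @return numeric vector of length `n`, all values in `[lo, hi]`.
#' @export
draw_tss_values <- function(n, seed, mean = 6.75, sd = 1.55,
                            lo = 3.21, hi = 10.99) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n)) {
    stop_invalid("`n` must be a positive integer")
  }
  if (!(lo < hi)) stop_invalid("`lo` must be < `hi`")
  if (!(sd > 0)) stop_invalid("`sd` must be positive")
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(max(2L * (n - length(out)), 16L), mean, sd)
      out <- c(out, draw[draw >= lo & draw <= hi])
    }
    out[seq_len(n)]
  })
}

#' Spectral model parameters for the synthetic generator
#'
#' The noise-free fruit reflectance at wavelength lambda for a fruit with
#' soluble-solids content `tss` is a sum of Gaussian shape components:
#' \deqn{R(\lambda; tss) = \sum_j (a_j + s_j \cdot tss)\,
#'       \exp(-((\lambda - c_j)/w_j)^2)}
#' where a non-finite width `w_j` denotes a flat (constant) component. The
#' defaults emulate a ripe dark fruit: low visible reflectance (< 0.10 over
#' 420-650 nm), a broad near-infrared peak at 850 nm, and a water/
#' carbohydrate absorption valley near 970 nm whose depth grows linearly
#' with TSS (so a linear calibration model is recoverable).
#'
#' @param centers,widths,amplitudes,tss_sensitivity per-component Gaussian
#'   centre (nm), width (nm, non-finite = flat), base amplitude
#'   (reflectance units) and TSS coupling (reflectance units per degree
#'   Brix).
#' @param noise_sd multiplicative per-pixel, per-band sensor noise SD.
#' @param scatter_sd SD of the per-pixel bumpy-surface scaling factor
#'   (one factor per pixel, shared across bands).
#' @param saturation_rate fraction of fruit pixels forced to sensor
#'   full-scale.
#' @param background_reflectance flat background reflectance; near-equal
#'   at all bands so the band-difference mask statistic is ~0 there.
#' @return an object of class `spectral_model_params`.
#' @export
spectral_model_params <- function(
    centers = c(700, 850, 970),
    widths = c(Inf, 120, 20),
    amplitudes = c(0.05, 0.55, -0.06),
    tss_sensitivity = c(0, 0, -0.012),
    noise_sd = 0.01,
    scatter_sd = 0.03,
    saturation_rate = 0.002,
    background_reflectance = 0.25) {
  k <- length(centers)
  if (length(widths) != k || length(amplitudes) != k ||
      length(tss_sensitivity) != k) {
    stop_invalid("component parameter vectors must share one length")
  }
  if (noise_sd < 0 || scatter_sd < 0 ||
      saturation_rate < 0 || saturation_rate > 1) {
    stop_invalid("noise_sd/scatter_sd must be >= 0, saturation_rate in [0,1]")
  }
  structure(list(centers = centers, widths = widths,
                 amplitudes = amplitudes, tss_sensitivity = tss_sensitivity,
                 noise_sd = noise_sd, scatter_sd = scatter_sd,
                 saturation_rate = saturation_rate,
                 background_reflectance = background_reflectance),
            class = "spectral_model_params")
}

#' Noise-free model reflectance spectrum
#'
#' @param grid wavelength grid in nm.
#' @param tss soluble-solids content, degrees Brix (scalar or vector).
#' @param params a [spectral_model_params()].
#' @return if `tss` is scalar, a numeric spectrum over `grid`; otherwise a
#'   `length(tss)` x `length(grid)` matrix (one spectrum per row).
#' @export
model_reflectance <- function(grid, tss, params = spectral_model_params()) {
  shapes <- vapply(seq_along(params$centers), function(j) {
    if (!is.finite(params$widths[j])) rep(1, length(grid))
    else exp(-((grid - params$centers[j]) / params$widths[j])^2)
  }, numeric(length(grid)))          # bands x components
  amp <- outer(params$tss_sensitivity, tss) + params$amplitudes # comp x n
  out <- t(shapes %*% amp)           # n x bands
  if (length(tss) == 1L) drop(out) else out
}

# Non-overlapping circular blob centres laid out on a lattice.
default_blob_centers <- function(n_blobs, rows, cols, radius) {
  per_row <- max(1L, floor(cols / (2 * radius + 3)))
  n_rows <- ceiling(n_blobs / per_row)
  if (n_rows * (2 * radius + 3) > rows) {
    stop_invalid("%d blobs of radius %d do not fit in a %d x %d image",
                 n_blobs, radius, rows, cols)
  }
  ys <- round(seq(radius + 2, rows - radius - 1, length.out = n_rows))
  xs <- round(seq(radius + 2, cols - radius - 1, length.out = per_row))
  g <- expand.grid(col = xs, row = ys)[seq_len(n_blobs), , drop = FALSE]
  cbind(row = g$row, col = g$col)
}

#' Capture geometry
#'
#' @param rows,cols image size in pixels.
#' @param blob_radius fruit blob radius in pixels.
#' @param centers optional n x 2 matrix (row, col) of blob centres; by
#'   default blobs are laid out on a lattice. Blobs must fit inside the
#'   image and must not overlap.
#' @param n_blobs number of blobs when `centers` is NULL.
#' @return an object of class `capture_geometry`.
#' @export
capture_geometry <- function(rows = 96, cols = 96, blob_radius = 7,
                             n_blobs = 6, centers = NULL) {
  if (is.null(centers)) {
    centers <- default_blob_centers(n_blobs, rows, cols, blob_radius)
  }
  centers <- as.matrix(centers)
  n <- nrow(centers)
  r <- blob_radius
  if (any(centers[, 1] - r < 1 | centers[, 1] + r > rows |
          centers[, 2] - r < 1 | centers[, 2] + r > cols)) {
    stop_invalid("blobs do not fit inside the %d x %d image", rows, cols)
  }
  if (n > 1) {
    d <- as.matrix(stats::dist(centers))
    diag(d) <- Inf
    if (any(d <= 2 * r)) stop_invalid("blobs overlap")
  }
  structure(list(rows = rows, cols = cols, blob_radius = r,
                 centers = centers),
            class = "capture_geometry")
}

blob_footprints <- function(geometry) {
  rows <- geometry$rows; cols <- geometry$cols; r <- geometry$blob_radius
  rc <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  lapply(seq_len(nrow(geometry$centers)), function(i) {
    c0 <- geometry$centers[i, ]
    inside <- (rc$row - c0[1])^2 + (rc$col - c0[2])^2 <= r^2
    which(inside) # linear indices, column-major over rows x cols
  })
}

#' Render a synthetic hyperspectral capture
#'
#' Builds raw, white-reference and dark-reference digital-count cubes for a
#' scene of circular fruit blobs on a flat background. Counts follow the
#' push-broom acquisition model
#' `raw = dark + (white - dark) * reflectance * scatter * noise`, clipped
#' to the sensor full-scale of 1.0 (white-normalized counts); a random
#' subset of fruit pixels is forced to full-scale to emulate saturation.
#'
#' @param tss degrees-Brix ground truth, one value per blob.
#' @param grid wavelength grid in nm.
#' @param geometry a [capture_geometry()]; blob count must match
#'   `length(tss)`.
#' @param params a [spectral_model_params()].
#' @param seed integer seed; identical inputs + seed give bit-identical
#'   captures.
#' @return an object of class `synthetic_capture`: list with `raw`, `white`,
#'   `dark` ([hypercube]s of digital counts), `truth_tss`, `footprints`
#'   (per-blob linear pixel indices), `saturated` (rows x cols logical),
#'   `reflectance` (the noise-free reflectance [hypercube]) and `grid`.
#' @export
render_capture <- function(tss, grid, geometry = capture_geometry(n_blobs = length(tss)),
                           params = spectral_model_params(), seed = 1L) {
  stopifnot(inherits(geometry, "capture_geometry"),
            inherits(params, "spectral_model_params"))
  if (nrow(geometry$centers) != length(tss)) {
    stop_invalid("geometry has %d blobs but %d TSS values supplied",
                 nrow(geometry$centers), length(tss))
  }
  rows <- geometry$rows; cols <- geometry$cols; nb <- length(grid)
  npx <- rows * cols
  foot <- blob_footprints(geometry)

  # per-pixel noise-free reflectance (pixels x bands), background first
  refl <- matrix(params$background_reflectance, npx, nb)
  fruit_spectra <- model_reflectance(grid, tss, params)
  if (length(tss) == 1L) fruit_spectra <- matrix(fruit_spectra, 1L)
  for (i in seq_along(foot)) {
    refl[foot[[i]], ] <- rep(fruit_spectra[i, ], each = length(foot[[i]]))
  }

  full_scale <- 1.0
  dark_level <- 0.02
  white_level <- 0.95
  dark <- array(dark_level, c(rows, cols, nb))
  white <- array(white_level, c(rows, cols, nb))

  capture <- with_seed(seed, {
    scatter <- 1 + stats::rnorm(npx, 0, params$scatter_sd)
    noise <- if (params$noise_sd > 0) {
      matrix(1 + stats::rnorm(npx * nb, 0, params$noise_sd), npx, nb)
    } else 1
    counts <- dark_level + (white_level - dark_level) * refl * scatter * noise
    counts <- pmin(pmax(counts, 0), full_scale)
    sat_idx <- integer(0)
    if (params$saturation_rate > 0) {
      fruit_px <- unlist(foot)
      k <- round(params$saturation_rate * length(fruit_px))
      if (k > 0) {
        sat_idx <- sample(fruit_px, k)
        counts[sat_idx, ] <- full_scale
      }
    }
    list(counts = counts, sat_idx = sat_idx)
  })
  saturated <- matrix(FALSE, rows, cols)
  saturated[capture$sat_idx] <- TRUE

  structure(list(
    raw = hypercube(array(capture$counts, c(rows, cols, nb)), grid),
    white = hypercube(white, grid),
    dark = hypercube(dark, grid),
    truth_tss = tss,
    footprints = foot,
    saturated = saturated,
    reflectance = hypercube(array(refl, c(rows, cols, nb)), grid),
    grid = grid,
    full_scale = full_scale,
    geometry = geometry,
    params = params
  ), class = "synthetic_capture")
}

#' @export
print.synthetic_capture <- function(x, ...) {
  cat(sprintf("<synthetic_capture> %d x %d pixels, %d bands, %d fruit blobs\n",
              dim(x$raw)[1], dim(x$raw)[2], dim(x$raw)[3],
              length(x$truth_tss)))
  invisible(x)
}

#' Simulate a spectra table of fruit samples
#'
#' Renders seeded synthetic captures in batches, calibrates them, recovers
#' the fruit masks by band-difference thresholding, and extracts one mean
#' ROI spectrum per blob — the full acquisition path, producing the
#' samples x bands matrix plus ground-truth TSS used by the calibration
#' stages.
#'
#' @param n_samples number of fruit samples.
#' @param grid wavelength grid in nm.
#' @param params a [spectral_model_params()].
#' @param seed integer master seed.
#' @param blobs_per_capture fruit blobs rendered per capture.
#' @param geometry geometry used for each capture (blob count taken from
#'   `blobs_per_capture`).
#' @param crop optional `c(lo, hi)` nm band-crop window applied after
#'   calibration (NULL = keep all bands).
#' @return a [spectra_table()] with ground-truth `y`.
#' @export
simulate_spectra_table <- function(n_samples, grid = make_wavelength_grid(512, 380, 1030),
                                   params = spectral_model_params(),
                                   seed = 1L, blobs_per_capture = 6L,
                                   geometry = capture_geometry(n_blobs = blobs_per_capture),
                                   crop = c(420, 1000)) {
  n_caps <- ceiling(n_samples / blobs_per_capture)
  seeds <- derive_seeds(seed, n_caps + 1L)
  tss_all <- draw_tss_values(n_samples, seeds[n_caps + 1L])
  X <- NULL
  out_grid <- NULL
  for (i in seq_len(n_caps)) {
    idx <- ((i - 1L) * blobs_per_capture + 1L):min(i * blobs_per_capture, n_samples)
    geo <- if (length(idx) == blobs_per_capture) geometry
           else capture_geometry(rows = geometry$rows, cols = geometry$cols,
                                 blob_radius = geometry$blob_radius,
                                 n_blobs = length(idx))
    cap <- render_capture(tss_all[idx], grid, geo, params, seed = seeds[i])
    refl <- calibrate_reflectance(cap$raw, cap$white, cap$dark)
    if (!is.null(crop)) refl <- crop_bands(refl, crop[1], crop[2])
    mask <- build_mask(refl)
    spectra <- t(vapply(cap$footprints, function(fp) {
      m <- mask$flags
      keep <- fp[m[fp] & !cap$saturated[fp]]
      if (length(keep) == 0) keep <- fp
      sub <- matrix(refl$values, ncol = dim(refl)[3])[keep, , drop = FALSE]
      colMeans(sub)
    }, numeric(dim(refl)[3])))
    X <- rbind(X, spectra)
    out_grid <- refl$wavelength
  }
  spectra_table(X, tss_all, grid = out_grid,
                sample_ids = sprintf("S%03d", seq_len(n_samples)))
}
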
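# Pixel-wise chemical mapping: unfold -> predict -> fold, the bundled
# published 23-wavelength multilinear TSS model, and pseudo-colour
# rendering.

#' Unfold a hypercube into a pixels x bands matrix
#'
#' Pixels are ordered row-major: pixel (1,1) first, then the rest of row 1
#' left to right, then row 2, and so on. The attached shape record allows
#' exact inversion by [fold_map()] / [fold_cube()].
#'
#' @param cube a [hypercube].
#' @return numeric matrix (rows*cols) x bands with attribute `cube_shape`
#'   = `c(rows, cols)`.
#' @export
unfold <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  m <- matrix(aperm(cube$values, c(2, 1, 3)), ncol = d[3])
  attr(m, "cube_shape") <- d[1:2]
  m
}

#' Fold a pixel vector back into an image
#'
#' Inverse of the spatial part of [unfold()]: a length rows*cols vector in
#' row-major pixel order becomes a rows x cols matrix.
#'
#' @param values numeric vector, row-major pixel order.
#' @param shape `c(rows, cols)` (or a matrix carrying a `cube_shape`
#'   attribute).
#' @return rows x cols matrix.
#' @export
fold_map <- function(values, shape) {
  if (is.matrix(shape) || !is.null(attr(shape, "cube_shape"))) {
    shape <- attr(shape, "cube_shape")
  }
  if (length(values) != prod(shape)) stop_invalid("length/shape mismatch")
  t(matrix(values, nrow = shape[2], ncol = shape[1]))
}

#' Fold an unfolded matrix back into a hypercube
#'
#' @param m pixels x bands matrix in row-major pixel order (as produced by
#'   [unfold()]), with shape given by `shape` or its `cube_shape`
#'   attribute.
#' @param shape `c(rows, cols)`.
#' @param wavelength band grid in nm.
#' @return a [hypercube].
#' @export
fold_cube <- function(m, shape = attr(m, "cube_shape"), wavelength) {
  if (is.null(shape)) stop_invalid("no shape record supplied")
  a <- array(m, dim = c(shape[2], shape[1], ncol(m)))
  hypercube(aperm(a, c(2, 1, 3)), wavelength)
}

# ---- published multilinear TSS model ---------------------------------------

#' The published 23-wavelength multilinear TSS model
#'
#' Loads the bundled reduced-wavelength multilinear prediction equation
#' for mulberry TSS: an intercept of 16.207 degrees Brix plus 23 signed
#' coefficients applied to the reflectance at 23 fixed wavelengths
#' (960, 929, 814, ... nm, in the fixed published order).
#'
#' @param path JSON file holding the model; defaults to the copy bundled
#'   with the package.
#' @return an object of class `published_tss_model` (also
#'   `multilinear_model`): list with `intercept`, `coefficients` and
#'   `wavelengths`.
#' @examples
#' m <- published_tss_model()
#' evaluate_published_model(rep(0, 23), m) # the intercept
#' @export
published_tss_model <- function(path = system.file("extdata", "eq12.json",
                                                   package = "hsitss")) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(spec$coefficients) != length(spec$wavelengths)) {
    stop_invalid("model file corrupt: coefficient/wavelength mismatch")
  }
  structure(list(intercept = spec$intercept,
                 coefficients = as.numeric(spec$coefficients),
                 wavelengths = as.numeric(spec$wavelengths)),
            class = c("published_tss_model", "multilinear_model"))
}

#' Evaluate the published TSS model on one spectrum
#'
#' @param spectrum exactly 23 reflectance values, ordered as the model's
#'   wavelength list (960, 929, 814, ... nm).
#' @param model a [published_tss_model()].
#' @return predicted TSS in degrees Brix:
#'   `intercept + sum(coefficients * spectrum)`.
#' @export
evaluate_published_model <- function(spectrum, model = published_tss_model()) {
  stopifnot(inherits(model, "multilinear_model"))
  if (length(spectrum) != length(model$coefficients)) {
    stop_invalid("spectrum has %d values, model expects %d",
                 length(spectrum), length(model$coefficients))
  }
  model$intercept + sum(model$coefficients * as.numeric(spectrum))
}

#' @export
predict.multilinear_model <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop_invalid("newdata has %d bands, model expects %d",
                 ncol(newdata), length(object$coefficients))
  }
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' @export
coef.multilinear_model <- function(object, ...) {
  stats::setNames(c(object$intercept, object$coefficients),
                  c("(Intercept)", paste0(object$wavelengths, "nm")))
}

#' @export
print.published_tss_model <- function(x, ...) {
  cat(sprintf("<published_tss_model> intercept %.3f + %d wavelength terms (%s ... nm)\n",
              x$intercept, length(x$coefficients),
              paste(x$wavelengths[1:3], collapse = ", ")))
  invisible(x)
}

# ---- mapping ----------------------------------------------------------------

model_wavelengths <- function(model) {
  if (!is.null(model$wavelengths)) return(model$wavelengths)
  NULL
}

#' Predict a per-pixel chemical map
#'
#' Applies a fitted model to every foreground pixel of a calibrated cube
#' via the unfold-predict-fold scheme: the cube is restricted to the
#' model's wavelengths (nearest-band lookup), optionally 5 x 5
#' median-filtered per band, unfolded to pixels x bands, predicted, and
#' folded back into an image. Background pixels carry NA; pixels flagged
#' saturated stay in the image but are excluded from summary statistics.
#'
#' @param cube a calibrated reflectance [hypercube].
#' @param mask a [build_mask()] result or logical matrix (foreground =
#'   TRUE).
#' @param model a `plsr_model`, `lssvm_model` or `multilinear_model`
#'   carrying `wavelengths`; any model whose `predict` accepts a pixels x
#'   bands matrix works if `wavelengths` is supplied.
#' @param denoise apply a 5 x 5 median filter to each band image before
#'   prediction.
#' @param saturated optional rows x cols logical matrix of saturated
#'   pixels (e.g. raw counts at sensor full-scale in any model band).
#' @param wavelengths model wavelengths (nm); defaults to
#'   `model$wavelengths`.
#' @param median_window window of the denoising median filter.
#' @return an object of class `chemical_map`: `values` (rows x cols,
#'   degrees Brix, NA on background), `mask`, `saturated` and
#'   `wavelengths_used` (band centres actually taken from the grid).
#' @export
predict_map <- function(cube, mask, model, denoise = TRUE,
                        saturated = NULL, wavelengths = model_wavelengths(model),
                        median_window = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  flags <- if (inherits(mask, "mask_image")) mask$flags else mask
  if (!identical(dim(flags), dim(cube$values)[1:2])) {
    stop_invalid("mask shape does not match cube")
  }
  if (is.null(wavelengths)) {
    stop_invalid("model carries no wavelengths and none were supplied")
  }
  grid <- cube$wavelength
  step <- if (length(grid) > 1) max(diff(grid)) else Inf
  idx <- nearest_band(grid, wavelengths)
  off <- abs(grid[idx] - wavelengths)
  if (any(off > step / 2 + 1e-9)) {
    stop(sprintf(
      "wavelength mismatch: %s nm missing from the grid (nearest band %.1f nm away)",
      paste(wavelengths[which.max(off)], collapse = ", "), max(off)),
      call. = FALSE)
  }
  sub <- cube$values[, , idx, drop = FALSE]
  if (denoise) {
    for (b in seq_len(dim(sub)[3])) {
      sub[, , b] <- median_filter_image(sub[, , b], median_window)
    }
  }
  subcube <- hypercube(sub, seq_along(idx)) # positional grid; order = model order
  px <- unfold(subcube)
  fg <- as.vector(t(flags)) # row-major, matching unfold ordering
  vals <- rep(NA_real_, length(fg))
  if (any(fg)) {
    vals[fg] <- predict(model, px[fg, , drop = FALSE])
  }
  if (is.null(saturated)) saturated <- matrix(FALSE, nrow(flags), ncol(flags))
  structure(list(values = fold_map(vals, dim(flags)),
                 mask = flags,
                 saturated = saturated,
                 wavelengths_used = grid[idx]),
            class = "chemical_map")
}

#' Saturation flags for a capture
#'
#' Flags pixels whose raw digital count sits at sensor full-scale in any
#' of the model wavelengths; such pixels carry no valid reflectance and
#' are excluded from map statistics.
#'
#' @param raw raw-count [hypercube].
#' @param full_scale sensor full-scale count.
#' @param wavelengths model wavelengths (nm); NULL = all bands.
#' @return rows x cols logical matrix.
#' @export
saturation_flags <- function(raw, full_scale = 1.0, wavelengths = NULL) {
  stopifnot(inherits(raw, "hypercube"))
  idx <- if (is.null(wavelengths)) seq_along(raw$wavelength)
         else nearest_band(raw$wavelength, wavelengths)
  apply(raw$values[, , idx, drop = FALSE] >= full_scale, c(1, 2), any)
}

#' @export
print.chemical_map <- function(x, ...) {
  s <- map_stats(x)
  cat(sprintf("<chemical_map> %d x %d, %d foreground px (%d saturated excluded)\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              sum(x$saturated & x$mask)))
  cat(sprintf("  TSS mean %.2f, range [%.2f, %.2f] degrees Brix\n",
              s["mean"], s["min"], s["max"]))
  invisible(x)
}

#' Summary statistics of a chemical map
#'
#' Mean/min/max over foreground, non-saturated pixels only.
#'
#' @param map a [predict_map()] result.
#' @param footprint optional logical matrix or linear pixel indices
#'   restricting the statistic to one sample.
#' @return named numeric vector `mean`, `min`, `max`, `n_pixels`.
#' @export
map_stats <- function(map, footprint = NULL) {
  stopifnot(inherits(map, "chemical_map"))
  keep <- map$mask & !map$saturated
  if (!is.null(footprint)) {
    sel <- matrix(FALSE, nrow(keep), ncol(keep))
    sel[footprint] <- TRUE
    keep <- keep & sel
  }
  v <- map$values[keep]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    return(c(mean = NA_real_, min = NA_real_, max = NA_real_, n_pixels = 0))
  }
  c(mean = mean(v), min = min(v), max = max(v), n_pixels = length(v))
}

#' Render a chemical map in pseudo-colour
#'
#' Linear colour scale from blue (`lo`) to red (`hi`): high concentrations
#' render red, low render blue. Background pixels render neutral gray.
#'
#' @param map a [predict_map()] result (or a plain numeric matrix).
#' @param lo,hi scale endpoints in degrees Brix (`lo < hi`); values
#'   outside are clamped.
#' @param ramp vector of colours interpolated linearly from `lo` to `hi`.
#' @param background colour of background/NA pixels.
#' @return rows x cols x 3 RGB array in [0, 1], with attributes `lo`, `hi`
#'   and `ramp` (colour-bar metadata).
#' @export
render_pseudocolour <- function(map, lo, hi,
                                ramp = c("blue", "red"),
                                background = "gray85") {
  if (!(lo < hi)) stop_invalid("`lo` must be < `hi`")
  values <- if (inherits(map, "chemical_map")) map$values else map
  ramp_fun <- grDevices::colorRamp(ramp)
  u <- (values - lo) / (hi - lo)
  u <- pmin(pmax(u, 0), 1)
  flat <- as.vector(u)
  rgb <- matrix(rep(grDevices::col2rgb(background) / 255, each = length(flat)),
                ncol = 3)
  ok <- !is.na(flat)
  if (any(ok)) rgb[ok, ] <- ramp_fun(flat[ok]) / 255
  out <- array(rgb, dim = c(nrow(values), ncol(values), 3))
  attr(out, "lo") <- lo
  attr(out, "hi") <- hi
  attr(out, "ramp") <- ramp
  out
}

#' Write an RGB array (or a mask) as PNG
#'
#' @param img rows x cols x 3 RGB array in [0,1] (from
#'   [render_pseudocolour()]) or a logical matrix (written as 0/255
#'   grayscale).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (is.logical(img)) img <- (img * 1.0)
  png::writePNG(img, path)
  invisible(path)
}
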
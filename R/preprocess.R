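# Calibration, band cropping, masking, ROI spectra and median denoising.

#' Reflectance calibration against white and dark references
#'
#' Element-wise `(raw - dark) / (white - dark)`. A white reference of ~99%
#' reflectance and a dark (~0%) reference correct for dark current and the
#' uneven lamp intensity across bands. No clipping is applied: values may
#' leave `[0, 1]` (e.g. specular highlights).
#'
#' @param raw,white,dark [hypercube]s of identical shape and grid.
#' @return a [hypercube] of relative reflectance.
#' @export
calibrate_reflectance <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"),
            inherits(dark, "hypercube"))
  if (!identical(dim(raw), dim(white)) || !identical(dim(raw), dim(dark))) {
    stop_invalid("raw/white/dark cubes must share one shape")
  }
  if (!isTRUE(all.equal(raw$wavelength, white$wavelength)) ||
      !isTRUE(all.equal(raw$wavelength, dark$wavelength))) {
    stop_invalid("raw/white/dark cubes must share one wavelength grid")
  }
  denom <- white$values - dark$values
  if (any(denom == 0)) {
    stop("degenerate reference: white == dark at some pixel/band",
         call. = FALSE)
  }
  hypercube((raw$values - dark$values) / denom, raw$wavelength)
}

#' Crop a hypercube to a closed wavelength interval
#'
#' Retains exactly the bands with `lo_nm <= lambda <= hi_nm`. Analyses
#' typically drop the noisy grid edges, e.g. keeping 420-1000 nm of a
#' 380-1030 nm acquisition.
#'
#' @param cube a [hypercube].
#' @param lo_nm,hi_nm closed interval endpoints in nm (`lo_nm <= hi_nm`).
#' @return the cropped [hypercube].
#' @export
crop_bands <- function(cube, lo_nm = 420, hi_nm = 1000) {
  stopifnot(inherits(cube, "hypercube"))
  if (lo_nm > hi_nm) stop_invalid("`lo_nm` must be <= `hi_nm`")
  keep <- cube$wavelength >= lo_nm & cube$wavelength <= hi_nm
  if (!any(keep)) {
    stop(sprintf("empty selection: no bands in [%g, %g] nm", lo_nm, hi_nm),
         call. = FALSE)
  }
  hypercube(cube$values[, , keep, drop = FALSE], cube$wavelength[keep])
}

#' Build a foreground mask by band-difference thresholding
#'
#' Subtracts the image at `band_b_nm` from the image at `band_a_nm`
#' (nearest-band lookup) and flags pixels whose difference is at least
#' `threshold` as foreground. With the defaults (893 minus 569 nm,
#' threshold 0.4) dark-skinned fruit — low visible, high near-infrared
#' reflectance — separates cleanly from a spectrally flat background.
#'
#' @param cube a reflectance [hypercube].
#' @param band_a_nm,band_b_nm wavelengths (nm) of the minuend and
#'   subtrahend bands; must lie inside the grid range.
#' @param threshold foreground decision level on the difference image.
#' @return an object of class `mask_image`: list with `flags` (rows x cols
#'   logical, foreground = TRUE), `threshold`, and `bands_nm` (the band
#'   centres actually used).
#' @export
build_mask <- function(cube, band_a_nm = 893, band_b_nm = 569,
                       threshold = 0.4) {
  a <- band_image(cube, band_a_nm)
  b <- band_image(cube, band_b_nm)
  flags <- (a - b) >= threshold
  structure(list(flags = unclass(flags),
                 threshold = threshold,
                 bands_nm = c(attr(a, "wavelength_nm"),
                              attr(b, "wavelength_nm"))),
            class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image> %d x %d, %d foreground px (bands %.1f - %.1f nm, threshold %g)\n",
              nrow(x$flags), ncol(x$flags), sum(x$flags),
              x$bands_nm[1], x$bands_nm[2], x$threshold))
  invisible(x)
}

#' Mean ROI spectrum
#'
#' Arithmetic mean over all foreground pixels, per band — the sample-level
#' spectrum used for calibration modelling.
#'
#' @param cube a [hypercube].
#' @param mask a [build_mask()] result (or a rows x cols logical matrix)
#'   with at least one foreground pixel.
#' @return numeric vector, one mean reflectance per band.
#' @export
extract_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  flags <- if (inherits(mask, "mask_image")) mask$flags else mask
  if (!identical(dim(flags), dim(cube$values)[1:2])) {
    stop_invalid("mask shape does not match cube")
  }
  if (!any(flags)) stop("empty ROI: mask has no foreground pixels",
                        call. = FALSE)
  px <- matrix(cube$values, ncol = dim(cube)[3])
  colMeans(px[as.vector(flags), , drop = FALSE])
}

#' 2-D median filter with reflection padding
#'
#' Sets every pixel to the median of the `window` x `window` neighbourhood
#' centred on it; edges are handled by reflecting the image across its
#' borders. A 5 x 5 median is the usual denoising step before per-pixel
#' prediction.
#'
#' @param img numeric matrix.
#' @param window odd window size (>= 1).
#' @return filtered matrix of the same shape.
#' @export
median_filter_image <- function(img, window = 5L) {
  if (!is.matrix(img)) stop_invalid("`img` must be a matrix")
  if (window < 1 || window %% 2 == 0) {
    stop_invalid("`window` must be odd and >= 1")
  }
  if (window == 1L) return(img)
  r <- (window - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  ridx <- reflect_index(n, r)
  cidx <- reflect_index(m, r)
  pad <- img[ridx, cidx, drop = FALSE]
  out <- img
  # gather the window x window shifted copies and take a running median
  stack <- array(NA_real_, c(n, m, window * window))
  k <- 0L
  for (dr in 0:(window - 1L)) {
    for (dc in 0:(window - 1L)) {
      k <- k + 1L
      stack[, , k] <- pad[dr + seq_len(n), dc + seq_len(m)]
    }
  }
  out[] <- apply(stack, c(1, 2), stats::median)
  out
}

# index vector 1..n padded by r reflected samples on each side
# (reflection without repeating the edge pixel; falls back to edge
# repetition when the image is smaller than the pad)
reflect_index <- function(n, r) {
  left <- rev(seq_len(min(r, n - 1)) + 1L)
  if (length(left) < r) left <- c(rep(1L, r - length(left)), left)
  right <- n - seq_len(min(r, n - 1))
  if (length(right) < r) right <- c(right, rep(n, r - length(right)))
  c(left, seq_len(n), right)
}

#' Label connected mask components
#'
#' 4-connectivity flood fill over the foreground of a mask; used to split a
#' multi-fruit mask into per-sample regions of interest.
#'
#' @param mask a `mask_image` or a logical matrix.
#' @return integer matrix of the same shape: 0 = background, 1..k = component
#'   labels, numbered in column-major order of first encounter.
#' @export
label_mask <- function(mask) {
  flags <- if (inherits(mask, "mask_image")) mask$flags else mask
  n <- nrow(flags); m <- ncol(flags)
  labels <- matrix(0L, n, m)
  lab <- 0L
  for (start in which(flags)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- ((p - 1L) %% n) + 1L
      pc <- ((p - 1L) %/% n) + 1L
      for (q in c(if (pr > 1L) p - 1L, if (pr < n) p + 1L,
                  if (pc > 1L) p - n, if (pc < m) p + n)) {
        if (flags[q] && labels[q] == 0L) {
          labels[q] <- lab
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}
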
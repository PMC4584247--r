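#' Hypercube container
#'
#' A hypercube is a 3-D block of hyperspectral data: two spatial dimensions
#' (rows x cols) by one wavelength dimension. Values are reflectance
#' (unitless) or raw digital counts; the wavelength grid (nm) must be
#' strictly increasing and match the third array dimension.
#'
#' @param values numeric array of dimension rows x cols x bands.
#' @param wavelength numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length equal to `dim(values)[3]`.
#' @return an object of class `hypercube`: a list with elements `values`
#'   and `wavelength`.
#' @examples
#' cube <- hypercube(array(runif(2 * 3 * 4), c(2, 3, 4)), c(450, 550, 650, 750))
#' dim(cube)
#' @export
hypercube <- function(values, wavelength) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_invalid("`values` must be a 3-D array (rows x cols x bands)")
  }
  wavelength <- as.numeric(wavelength)
  if (length(wavelength) != dim(values)[3]) {
    stop_invalid("wavelength grid length (%d) != band count (%d)",
                 length(wavelength), dim(values)[3])
  }
  if (length(wavelength) > 1 && any(diff(wavelength) <= 0)) {
    stop_invalid("wavelength grid must be strictly increasing")
  }
  structure(list(values = values, wavelength = wavelength),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Single-band image from a hypercube
#'
#' Extracts the 2-D image at the grid band nearest to `wavelength_nm`.
#'
#' @param cube a [hypercube].
#' @param wavelength_nm requested wavelength in nm; must fall inside the
#'   grid range.
#' @return a rows x cols numeric matrix with attribute `wavelength_nm`
#'   giving the band centre actually used.
#' @export
band_image <- function(cube, wavelength_nm) {
  stopifnot(inherits(cube, "hypercube"))
  g <- cube$wavelength
  if (wavelength_nm < min(g) || wavelength_nm > max(g)) {
    stop_invalid("wavelength %.1f nm outside grid range [%.1f, %.1f]",
                 wavelength_nm, min(g), max(g))
  }
  b <- nearest_band(g, wavelength_nm)
  structure(cube$values[, , b], wavelength_nm = g[b])
}

# ---- ENVI-style I/O ---------------------------------------------------------
# Minimal ENVI raster support: an ASCII .hdr with a mandatory `wavelength`
# list plus a raw binary block in BIL or BSQ interleave, IEEE float
# (data type 4 = float32, 5 = float64), byte order 0 (little-endian).

#' Write a hypercube as an ENVI cube
#'
#' @param cube a [hypercube].
#' @param path output path of the binary block; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bil"` or `"bsq"`.
#' @param data_type ENVI numeric type code: 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) {
    stop_invalid("unsupported ENVI data type %s (use 4 or 5)", data_type)
  }
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {hsitss hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelength, trim = TRUE, digits = 10),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # ENVI pixel order: BIL = line, band, sample; BSQ = band, line, sample.
  # R arrays are column-major (rows fastest); permute so `sample` varies
  # fastest within each line.
  v <- cube$values
  block <- if (interleave == "bil") {
    aperm(v, c(2, 3, 1)) # sample, band, line
  } else {
    aperm(v, c(2, 1, 3)) # sample, line, band
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(block), con,
           size = if (data_type == 4L) 4L else 8L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  # fold multi-line { ... } blocks onto one logical line
  repeat {
    folded <- gsub("(\\{[^}]*)\n", "\\1 ", txt)
    if (identical(folded, txt)) break
    txt <- folded
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  get_field <- function(name, numeric = TRUE) {
    pat <- sprintf("^[ \t]*%s[ \t]*=", name)
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) return(NULL)
    val <- sub("^[^=]*=[ \t]*", "", hit[1])
    val <- trimws(gsub("[{}]", "", val))
    if (numeric) as.numeric(strsplit(val, ",")[[1]]) else val
  }
  list(
    samples    = as.integer(get_field("samples")),
    lines      = as.integer(get_field("lines")),
    bands      = as.integer(get_field("bands")),
    data_type  = as.integer(get_field("data type")),
    interleave = tolower(get_field("interleave", numeric = FALSE)),
    byte_order = as.integer(get_field("byte order")),
    wavelength = get_field("wavelength")
  )
}

#' Read an ENVI cube
#'
#' Reads a BIL or BSQ float cube written by [write_envi()] or by other
#' software, requiring a `wavelength` list in the header.
#'
#' @param path path of the binary block; the header is looked up at
#'   `paste0(path, ".hdr")` (or `path` with its extension replaced by
#'   `.hdr`).
#' @return a [hypercube].
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  }
  if (!file.exists(hdr_path)) stop_invalid("ENVI header not found for %s", path)
  h <- parse_envi_header(hdr_path)
  if (is.null(h$wavelength)) stop_invalid("ENVI header lacks a wavelength list")
  if (!h$interleave %in% c("bil", "bsq")) {
    stop_invalid("unsupported interleave '%s'", h$interleave)
  }
  if (!h$data_type %in% c(4L, 5L)) {
    stop_invalid("unsupported ENVI data type %d", h$data_type)
  }
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = "numeric", n = n,
                      size = if (h$data_type == 4L) 4L else 8L,
                      endian = "little")
  if (length(raw_vals) != n) stop_invalid("ENVI block truncated")
  if (h$interleave == "bil") {
    a <- array(raw_vals, dim = c(h$samples, h$bands, h$lines))
    v <- aperm(a, c(3, 1, 2))
  } else {
    a <- array(raw_vals, dim = c(h$samples, h$lines, h$bands))
    v <- aperm(a, c(2, 1, 3))
  }
  hypercube(v, h$wavelength)
}
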
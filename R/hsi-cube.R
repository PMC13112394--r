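#' Evenly spaced wavelength grid
#'
#' Builds the vector of band centers for a spectral camera, evenly spaced and
#' inclusive of both endpoints. The two default acquisition ranges used
#' throughout the package are Vis-NIR (380-1010 nm, 440 bands, ~1.43 nm
#' spacing) and SWIR (1000-2000 nm, 146 bands).
#'
#' @param start_nm first band center (nm)
#' @param stop_nm last band center (nm); must exceed `start_nm`
#' @param n_bands number of bands (>= 2)
#' @return numeric vector of length `n_bands`, strictly increasing, with
#'   `values[1] == start_nm` and `values[n_bands] == stop_nm`
#' @examples
#' wl <- make_wavelength_grid(380, 1010, 440)
#' diff(wl)[1]  # ~1.435 nm
#' @export
make_wavelength_grid <- function(start_nm, stop_nm, n_bands) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(n_bands))
  if (n_bands < 2) stop("make_wavelength_grid: n_bands must be >= 2")
  if (stop_nm <= start_nm) stop("make_wavelength_grid: stop_nm must exceed start_nm")
  seq(start_nm, stop_nm, length.out = as.integer(n_bands))
}

#' Construct a hyperspectral cube
#'
#' A cube is a rows x cols x bands reflectance (or raw count) array with an
#' ascending wavelength vector. Axes follow the (row, col, band) convention,
#' 0 offset at the image top-left, independent of how the cube is stored on
#' disk (interleave is a storage property only).
#'
#' @param data numeric array, dim = c(rows, cols, bands)
#' @param wavelengths ascending numeric vector, length = bands
#' @param calibrated logical; `TRUE` once white/dark reflectance calibration
#'   has been applied
#' @param interleave storage interleave for ENVI output: "bsq", "bil" or "bip"
#' @return an object of class `hsi_cube`
#' @export
hsi_cube <- function(data, wavelengths, calibrated = FALSE, interleave = "bsq") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("hsi_cube: data must be a rows x cols x bands array")
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("hsi_cube: bands dimension must equal wavelength length")
  if (any(diff(wavelengths) <= 0))
    stop("hsi_cube: wavelengths must be strictly increasing")
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  if (isTRUE(calibrated) && !all(is.finite(data)))
    stop("hsi_cube: calibrated cube must contain only finite values")
  structure(
    list(data = data, wavelengths = wavelengths,
         calibrated = isTRUE(calibrated), interleave = interleave),
    class = "hsi_cube"
  )
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (x$calibrated) "calibrated reflectance" else "raw counts"))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' White/dark reference frames for reflectance calibration
#'
#' Line-scan systems record a white reference (near-100 % reflectance panel)
#' and a dark-current frame under the acquisition optics. Frames may be a
#' full rows x cols x bands array, a cols x bands matrix (per scan column,
#' the usual line-scan case), a per-band vector, or a scalar; all broadcast
#' against the raw cube.
#'
#' @param white white reference signal
#' @param dark dark current signal
#' @return an object of class `calibration_frames`
#' @export
calibration_frames <- function(white, dark) {
  structure(list(white = white, dark = dark), class = "calibration_frames")
}

# Broadcast a calibration frame to the full cube shape.
broadcast_frame <- function(frame, dims) {
  rows <- dims[1]; cols <- dims[2]; bands <- dims[3]
  if (length(frame) == 1L) return(array(frame, dims))
  if (is.null(dim(frame)) && length(frame) == bands)
    return(aperm(array(frame, c(bands, rows, cols)), c(2, 3, 1)))
  if (is.matrix(frame) && all(dim(frame) == c(cols, bands)))
    return(aperm(array(frame, c(cols, bands, rows)), c(3, 1, 2)))
  if (is.array(frame) && length(dim(frame)) == 3L && all(dim(frame) == dims))
    return(frame)
  stop("calibrate_reflectance: frame shape not broadcastable to cube shape")
}

#' Radiometric reflectance calibration
#'
#' Converts raw sensor counts to relative reflectance with the standard
#' white/dark correction
#' \deqn{R_{cal} = (R_{raw} - R_D) / (R_W - R_D)}
#' applied per pixel and band. Values are deliberately not clipped to
#' \[0, 1\]: sensor noise can exceed the white panel, and clamping is left as
#' an explicit downstream choice.
#'
#' @param raw an uncalibrated [hsi_cube]
#' @param frames a [calibration_frames] object; `white - dark` must be
#'   nonzero everywhere
#' @return a calibrated [hsi_cube]
#' @export
calibrate_reflectance <- function(raw, frames) {
  stopifnot(inherits(raw, "hsi_cube"), inherits(frames, "calibration_frames"))
  if (raw$calibrated) stop("calibrate_reflectance: cube is already calibrated")
  dims <- dim(raw$data)
  white <- broadcast_frame(frames$white, dims)
  dark <- broadcast_frame(frames$dark, dims)
  denom <- white - dark
  if (any(denom == 0)) {
    bad <- sort(unique(which(denom == 0, arr.ind = TRUE)[, 3]))
    stop(sprintf(
      "calibrate_reflectance: white == dark at %d element(s); affected band index(es): %s",
      sum(denom == 0), paste(utils::head(bad, 10), collapse = ", ")))
  }
  out <- (raw$data - dark) / denom
  hsi_cube(out, raw$wavelengths, calibrated = TRUE, interleave = raw$interleave)
}

#' Trim to a retained wavelength range
#'
#' Noisy bands at the spectral extremes are routinely discarded before
#' modeling; this keeps only bands whose centers fall inside `keep_range_nm`
#' (inclusive), preserving order. Works on a cube, on a plain spectrum
#' vector, or on an n x bands spectra matrix (with `wavelengths` supplied).
#'
#' @param x an [hsi_cube], a numeric vector, or an n x bands matrix
#' @param keep_range_nm length-2 numeric `c(lo, hi)`
#' @param wavelengths band centers, required when `x` is not a cube
#' @return the same kind of object restricted to the retained bands; matrices
#'   and vectors additionally carry the retained wavelengths in attribute
#'   `"wavelengths"`
#' @export
trim_bands <- function(x, keep_range_nm, wavelengths = NULL) {
  stopifnot(length(keep_range_nm) == 2L)
  lo <- min(keep_range_nm); hi <- max(keep_range_nm)
  wl <- if (inherits(x, "hsi_cube")) x$wavelengths else as.numeric(wavelengths)
  if (is.null(wl)) stop("trim_bands: wavelengths required for non-cube input")
  keep <- which(wl >= lo & wl <= hi)
  if (length(keep) == 0L)
    stop("trim_bands: no bands inside the requested range")
  if (inherits(x, "hsi_cube")) {
    return(hsi_cube(x$data[, , keep, drop = FALSE], wl[keep],
                    calibrated = x$calibrated, interleave = x$interleave))
  }
  out <- if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
  attr(out, "wavelengths") <- wl[keep]
  out
}

# Index of the band whose center is nearest target_nm; ties go to the
# lower index.
nearest_band_index <- function(wavelengths, target_nm) {
  which.min(abs(wavelengths - target_nm))
}
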
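#' Co-registered segmentation masks
#'
#' Holds the binary masks produced by the segmentation stage. The region of
#' interest is derived, never stored independently:
#' `roi = fruit & !achene & !leaf`.
#'
#' @param fruit,achene,leaf logical matrices of identical shape
#' @param source_wavelength_nm the band (nm) the fruit mask was derived from
#' @return an object of class `mask_set` with elements `fruit`, `achene`,
#'   `leaf`, `roi`, `source_wavelength_nm`
#' @export
mask_set <- function(fruit, achene, leaf, source_wavelength_nm = NA_real_) {
  fruit <- as.logical_mask(fruit); achene <- as.logical_mask(achene)
  leaf <- as.logical_mask(leaf)
  if (!all(dim(achene) == dim(fruit)) || !all(dim(leaf) == dim(fruit)))
    stop("mask_set: masks must share one shape")
  structure(
    list(fruit = fruit, achene = achene, leaf = leaf,
         roi = fruit & !achene & !leaf,
         source_wavelength_nm = source_wavelength_nm),
    class = "mask_set")
}

as.logical_mask <- function(m) {
  if (is.null(dim(m)) || length(dim(m)) != 2L)
    stop("mask_set: masks must be matrices")
  matrix(as.logical(m), nrow(m), ncol(m))
}

#' Extract the grayscale image at a target wavelength
#'
#' Returns the single band whose center is nearest `target_nm` (ties go to
#' the lower band index). The fruit mask is conventionally built at 647 nm,
#' where fruit/background contrast is strong and stable across bruise levels
#' and storage times.
#'
#' @param cube a calibrated [hsi_cube]
#' @param target_nm requested wavelength (nm)
#' @return numeric matrix (rows x cols)
#' @export
band_image <- function(cube, target_nm = 647) {
  stopifnot(inherits(cube, "hsi_cube"))
  idx <- nearest_band_index(cube$wavelengths, target_nm)
  d <- dim(cube$data)
  structure(matrix(cube$data[, , idx], d[1], d[2]),
            wavelength_nm = cube$wavelengths[idx])
}

#' Otsu threshold of a grayscale image
#'
#' Computes the threshold maximizing the between-class variance of a 256-bin
#' histogram spanning the image range; foreground is the brighter class
#' (`value > threshold`). Candidate thresholds are the bin edges; the
#' returned value is the edge with maximal between-class variance (lowest
#' edge among ties).
#'
#' @param image numeric matrix (or vector) with at least two distinct values
#' @param n_bins histogram resolution (default 256)
#' @return the scalar threshold
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("otsu_threshold: image is constant (degenerate input)")
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  p <- counts / sum(counts)
  centers <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  omega <- cumsum(p)                  # class-0 mass up to and incl. bin t
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  t_idx <- seq_len(n_bins - 1L)
  valid <- omega[t_idx] > 0 & omega[t_idx] < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * omega[t_idx][valid] - mu[t_idx][valid])^2 /
    (omega[t_idx][valid] * (1 - omega[t_idx][valid]))
  best <- which.max(sigma_b)          # lowest index among ties
  lo + best / n_bins * (hi - lo)      # upper edge of bin `best`
}

#' Morphological refinement of a binary mask
#'
#' Opening then closing with disk structuring elements, followed by keeping
#' the largest connected component and filling interior holes — the standard
#' cleanup applied to the thresholded fruit mask. Enclosed holes (dark
#' achene speckles fall below the fruit/background threshold) are filled
#' once before the opening as well, since opening can otherwise erode a
#' hole near the silhouette rim into an open bay that the final hole fill
#' cannot recover.
#'
#' @param mask logical matrix
#' @param open_radius,close_radius disk radii in pixels (0 skips the step)
#' @return refined logical matrix
#' @export
refine_mask <- function(mask, open_radius = 2, close_radius = 2) {
  m <- as.logical_mask(mask)
  img <- matrix(as.numeric(EBImage::fillHull(m)), nrow(m), ncol(m))
  if (open_radius > 0)
    img <- EBImage::opening(img, disk_brush(open_radius))
  if (close_radius > 0)
    img <- EBImage::closing(img, disk_brush(close_radius))
  lab <- EBImage::bwlabel(img > 0.5)
  if (max(lab) == 0) stop("refine_mask: mask is empty after refinement")
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  img <- EBImage::fillHull(lab == keep)
  matrix(as.numeric(img) > 0.5, nrow(m), ncol(m))
}

disk_brush <- function(radius) {
  EBImage::makeBrush(2L * ceiling(radius) + 1L, shape = "disc")
}

#' Black-hat achene mask
#'
#' The black-hat transform, closing(I) - I, responds to dark features
#' smaller than the structuring element — achenes appear as dark speckles on
#' the bright fruit at 647 nm. The mask is the response exceeding
#' `min_response`, restricted to `fruit` when given.
#'
#' @param image grayscale matrix in \[0, 1\]
#' @param se_radius disk structuring-element radius in pixels
#' @param min_response response threshold
#' @param fruit optional fruit mask to restrict to
#' @return logical matrix
#' @export
blackhat_achene_mask <- function(image, se_radius = 3, min_response = 0.1,
                                 fruit = NULL) {
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  response <- EBImage::closing(img, disk_brush(se_radius)) - img
  m <- response > min_response
  if (!is.null(fruit)) m <- m & as.logical_mask(fruit)
  matrix(m, nrow(image), ncol(image))
}

#' NDVI leaf mask
#'
#' Computes the normalized difference vegetation index
#' \eqn{(R_{NIR} - R_{red}) / (R_{NIR} + R_{red})} from the bands nearest
#' the requested wavelengths (classical pair 800/670 nm) and thresholds it.
#' Pixels with a zero denominator get NDVI 0 by convention (not leaf).
#'
#' @param cube a calibrated [hsi_cube]
#' @param nir_nm,red_nm band centers for the NIR and red channels
#' @param ndvi_threshold mask is `NDVI > ndvi_threshold`
#' @return logical matrix; the NDVI image is attached as attribute `"ndvi"`
#' @export
ndvi_leaf_mask <- function(cube, nir_nm = 800, red_nm = 670,
                           ndvi_threshold = 0.4) {
  nir <- band_image(cube, nir_nm)
  red <- band_image(cube, red_nm)
  denom <- nir + red
  ndvi <- ifelse(denom == 0, 0, (nir - red) / denom)
  structure(ndvi > ndvi_threshold, ndvi = ndvi,
            dim = dim(ndvi))
}

#' Build the full mask set for a cube
#'
#' Composition of the three segmentation steps: fruit by Otsu thresholding
#' of the 647 nm band image with morphological refinement, achene removal by
#' black-hat transform, leaf removal by NDVI thresholding. Deterministic:
#' the same cube and parameters always give the same masks.
#'
#' @param cube calibrated [hsi_cube]
#' @param params list of tunables; defaults from [segmentation_params()]
#' @return a [mask_set]
#' @export
build_maskset <- function(cube, params = segmentation_params()) {
  stopifnot(inherits(cube, "hsi_cube"))
  p <- utils::modifyList(segmentation_params(), params)
  gray <- band_image(cube, p$fruit_band_nm)
  thr <- tryCatch(otsu_threshold(gray, p$n_bins), error = function(e)
    stop("build_maskset: empty ROI (no contrast in the segmentation band)",
         call. = FALSE))
  fruit <- refine_mask(gray > thr, p$open_radius, p$close_radius)
  achene <- blackhat_achene_mask(gray, p$blackhat_radius, p$blackhat_min_response,
                                 fruit = fruit)
  leaf <- ndvi_leaf_mask(cube, p$ndvi_nir_nm, p$ndvi_red_nm, p$ndvi_threshold)
  leaf <- matrix(as.logical(leaf), nrow(leaf), ncol(leaf))
  mask_set(fruit = fruit, achene = achene, leaf = leaf,
           source_wavelength_nm = attr(gray, "wavelength_nm"))
}

#' @rdname build_maskset
#' @export
segmentation_params <- function() {
  list(fruit_band_nm = 647, n_bins = 256L,
       open_radius = 2, close_radius = 2,
       blackhat_radius = 3, blackhat_min_response = 0.1,
       ndvi_nir_nm = 800, ndvi_red_nm = 670, ndvi_threshold = 0.4)
}

#' Write a mask as a single-band PNG (0/255)
#' @param mask logical matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
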
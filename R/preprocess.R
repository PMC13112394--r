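#' Labeled spectral dataset
#'
#' Container for a matrix of per-sample spectra with class labels, the
#' wavelength grid, an optional calibration/validation split, and a record
#' of the preprocessing steps applied.
#'
#' @param spectra n x bands numeric matrix
#' @param labels length-n class labels (bruise level or storage hour)
#' @param wavelengths band centers, length = ncol(spectra)
#' @param storage_h optional per-row storage hours
#' @param split optional list(cal, val) of disjoint row indices covering all
#'   rows
#' @param preprocessing character vector naming the applied steps, in order
#' @return an object of class `spectral_dataset`
#' @export
spectral_dataset <- function(spectra, labels, wavelengths,
                             storage_h = NULL, split = NULL,
                             preprocessing = character()) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != length(labels))
    stop("spectral_dataset: labels length must equal nrow(spectra)")
  if (ncol(spectra) != length(wavelengths))
    stop("spectral_dataset: wavelengths length must equal ncol(spectra)")
  if (!is.null(split)) {
    if (length(intersect(split$cal, split$val)) > 0)
      stop("spectral_dataset: cal and val indices overlap")
    if (!setequal(c(split$cal, split$val), seq_len(nrow(spectra))))
      stop("spectral_dataset: split must cover all rows")
  }
  structure(
    list(spectra = spectra, labels = as.character(labels),
         wavelengths = as.numeric(wavelengths),
         storage_h = storage_h, split = split,
         preprocessing = preprocessing),
    class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d bands; classes: %s%s\n",
              nrow(x$spectra), ncol(x$spectra),
              paste(names(table(x$labels)), collapse = "/"),
              if (!is.null(x$split))
                sprintf("; split %d cal / %d val", length(x$split$cal),
                        length(x$split$val)) else ""))
  invisible(x)
}

#' Mean spectrum over the region of interest
#'
#' Per-band arithmetic mean of all pixel spectra inside the ROI
#' (fruit excluding achenes and leaves) — the per-fruit signature used for
#' model calibration.
#'
#' @param cube an [hsi_cube]
#' @param masks a [mask_set] (or a logical matrix used directly as ROI)
#' @return numeric vector of length `bands`
#' @export
mean_roi_spectrum <- function(cube, masks) {
  stopifnot(inherits(cube, "hsi_cube"))
  roi <- if (inherits(masks, "mask_set")) masks$roi else as.logical_mask(masks)
  if (!any(roi)) stop("mean_roi_spectrum: ROI is empty")
  flat <- matrix(cube$data, prod(dim(cube$data)[1:2]), dim(cube$data)[3])
  colMeans(flat[as.vector(roi), , drop = FALSE])
}

#' Moving-average smoothing
#'
#' Symmetric moving average with an odd window (default 5 points, the
#' standard chemometric choice). Edges use the truncated window so output
#' length equals input length; the value range can never grow.
#'
#' @param spectrum numeric vector, or n x bands matrix (rows smoothed
#'   independently)
#' @param window odd window size, at most the spectrum length
#' @return smoothed object of the same shape
#' @export
moving_average <- function(spectrum, window = 5L) {
  if (window %% 2 == 0) stop("moving_average: window must be odd")
  if (is.matrix(spectrum))
    return(t(apply(spectrum, 1, moving_average, window = window)))
  n <- length(spectrum)
  if (window > n) stop("moving_average: window exceeds spectrum length")
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, spectrum))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L); hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' First derivative with respect to wavelength
#'
#' Central differences at interior points,
#' \eqn{(s_{i+1} - s_{i-1}) / (\lambda_{i+1} - \lambda_{i-1})}, one-sided
#' differences at the two ends; output length equals input length. Removes
#' additive baseline offsets exactly.
#'
#' @param spectrum numeric vector, or n x bands matrix
#' @param wavelengths strictly monotone band centers
#' @return derivative of the same shape (units: reflectance per nm)
#' @export
first_derivative <- function(spectrum, wavelengths) {
  wl <- as.numeric(wavelengths)
  if (length(wl) < 3) stop("first_derivative: need at least 3 bands")
  d <- diff(wl)
  if (!(all(d > 0) || all(d < 0)))
    stop("first_derivative: wavelengths must be strictly monotone")
  deriv1 <- function(s) {
    n <- length(s)
    out <- numeric(n)
    out[1] <- (s[2] - s[1]) / (wl[2] - wl[1])
    out[n] <- (s[n] - s[n - 1]) / (wl[n] - wl[n - 1])
    i <- 2:(n - 1)
    out[i] <- (s[i + 1] - s[i - 1]) / (wl[i + 1] - wl[i - 1])
    out
  }
  if (is.matrix(spectrum)) t(apply(spectrum, 1, deriv1)) else deriv1(spectrum)
}

#' Standard spectral preprocessing pipeline
#'
#' Band trimming to the retained range, 5-point moving-average smoothing,
#' then first-derivative transformation — applied in that order, matching
#' the chemometric protocol used before model construction.
#'
#' @param spectra numeric vector or n x bands matrix
#' @param wavelengths band centers
#' @param keep_range_nm retained wavelength range; `NULL` keeps all bands
#' @param window moving-average window
#' @return list with `spectra` (same kind as input), `wavelengths`
#'   (retained) and `steps` (character record)
#' @export
preprocess_pipeline <- function(spectra, wavelengths,
                                keep_range_nm = NULL, window = 5L) {
  steps <- character()
  wl <- as.numeric(wavelengths)
  x <- spectra
  if (!is.null(keep_range_nm)) {
    x <- trim_bands(x, keep_range_nm, wl)
    wl <- attr(x, "wavelengths")
    attr(x, "wavelengths") <- NULL
    steps <- c(steps, sprintf("trim[%g,%g]", min(keep_range_nm),
                              max(keep_range_nm)))
  }
  x <- moving_average(x, window)
  steps <- c(steps, sprintf("moving_average(%d)", as.integer(window)))
  x <- first_derivative(x, wl)
  steps <- c(steps, "first_derivative")
  list(spectra = x, wavelengths = wl, steps = steps)
}

#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min-distance sample selection: the first two picks are
#' a maximally distant pair (Euclidean); each further pick maximizes its
#' minimum distance to the already-selected set. Ties always go to the
#' lowest row index, so the split is bit-stable. By default the algorithm
#' runs independently within each class (keeping the classes balanced
#' across the two sets); set `per_class = FALSE` to pool.
#'
#' @param spectra n x bands matrix
#' @param cal_fraction fraction assigned to calibration (default 2/3,
#'   the conventional 2:1 split); cal size per group = `round(n * fraction)`
#' @param labels class labels; required when `per_class = TRUE`
#' @param per_class run the selection within each class
#' @return list with sorted integer vectors `cal` and `val`
#' @export
kennard_stone_split <- function(spectra, cal_fraction = 2 / 3,
                                labels = NULL, per_class = !is.null(labels)) {
  x <- as.matrix(spectra)
  n <- nrow(x)
  if (n < 2) stop("kennard_stone_split: need at least 2 samples")
  if (cal_fraction <= 0 || cal_fraction >= 1)
    stop("kennard_stone_split: cal_fraction must be in (0, 1)")
  if (per_class) {
    if (is.null(labels)) stop("kennard_stone_split: labels required per class")
    cal <- integer()
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) == 1L) { cal <- c(cal, idx); next }
      sub <- kennard_stone_core(x[idx, , drop = FALSE],
                                round(length(idx) * cal_fraction))
      cal <- c(cal, idx[sub])
    }
  } else {
    cal <- kennard_stone_core(x, round(n * cal_fraction))
  }
  cal <- sort(cal)
  list(cal = cal, val = setdiff(seq_len(n), cal))
}

# Greedy max-min selection of n_cal rows; ties resolved to the lowest index.
kennard_stone_core <- function(x, n_cal) {
  n <- nrow(x)
  n_cal <- max(1L, min(as.integer(n_cal), n))
  d <- as.matrix(stats::dist(x))
  # maximally distant pair, lowest-index pair among ties
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  if (nrow(best) == 0L) best <- matrix(c(1L, 2L), 1)  # all points identical
  ord <- order(best[, 1], best[, 2])
  sel <- as.integer(best[ord[1], ])
  while (length(sel) < n_cal) {
    remaining <- setdiff(seq_len(n), sel)
    mind <- apply(d[remaining, sel, drop = FALSE], 1, min)
    sel <- c(sel, remaining[which.max(mind)])  # which.max: lowest index on tie
  }
  sort(sel)
}

#' Attach a Kennard-Stone split to a dataset
#'
#' Convenience wrapper running [kennard_stone_split] on a
#' [spectral_dataset]'s spectra and storing the result in `$split`.
#'
#' @param dataset a [spectral_dataset]
#' @param cal_fraction calibration fraction
#' @param per_class split within classes (default) or pooled
#' @return the dataset with `$split` set
#' @export
split_dataset <- function(dataset, cal_fraction = 2 / 3, per_class = TRUE) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  dataset$split <- kennard_stone_split(dataset$spectra, cal_fraction,
                                       labels = if (per_class) dataset$labels,
                                       per_class = per_class)
  dataset
}

#' Apply the preprocessing pipeline to a dataset
#'
#' @param dataset a [spectral_dataset] of raw reflectance spectra
#' @param keep_range_nm retained range (`NULL` keeps all bands)
#' @param window moving-average window
#' @return a new [spectral_dataset] of preprocessed spectra
#' @export
preprocess_dataset <- function(dataset, keep_range_nm = NULL, window = 5L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  out <- preprocess_pipeline(dataset$spectra, dataset$wavelengths,
                             keep_range_nm, window)
  spectral_dataset(out$spectra, dataset$labels, out$wavelengths,
                   storage_h = dataset$storage_h, split = dataset$split,
                   preprocessing = c(dataset$preprocessing, out$steps))
}

#' Read/write spectra tables
#'
#' CSV layout: first column `label`, optional `storage_h`, then one column
#' per band named by wavelength (`wl_<nm>`).
#'
#' @param dataset a [spectral_dataset]
#' @param path CSV path
#' @return `write_spectra_csv`: `path` invisibly; `read_spectra_csv`: a
#'   [spectral_dataset]
#' @export
write_spectra_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  df <- data.frame(label = dataset$labels, check.names = FALSE)
  if (!is.null(dataset$storage_h)) df$storage_h <- dataset$storage_h
  sp <- as.data.frame(dataset$spectra)
  names(sp) <- sprintf("wl_%.2f", dataset$wavelengths)
  utils::write.csv(cbind(df, sp), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  if (length(wl_cols) == 0) stop("read_spectra_csv: no wl_ band columns")
  spectral_dataset(
    as.matrix(df[, wl_cols, drop = FALSE]),
    labels = df$label,
    wavelengths = as.numeric(sub("^wl_", "", names(df)[wl_cols])),
    storage_h = if ("storage_h" %in% names(df)) df$storage_h else NULL)
}
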
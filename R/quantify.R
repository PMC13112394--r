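#' Impact energy of a dropped steel ball
#'
#' \eqn{E_i = m g h}: the potential energy converted at impact. With the
#' standard 32.6 g ball this gives approximately 0, 0.06 and 0.19 J for drop
#' heights 0, 0.2 and 0.6 m — the three bruising treatments (Intact,
#' Bruised I, Bruised II).
#'
#' @param mass_kg ball mass (kg)
#' @param height_m drop height (m)
#' @param gravity gravitational acceleration (m/s^2), default 9.8
#' @return energy in joules
#' @export
impact_energy <- function(mass_kg, height_m, gravity = 9.8) {
  if (any(c(mass_kg, height_m, gravity) < 0))
    stop("impact_energy: arguments must be nonnegative")
  mass_kg * gravity * height_m
}

#' Area of an ellipse
#'
#' \eqn{S = \pi a b} for semi-major axis `a` and semi-minor axis `b`; used
#' for the elliptical bruise footprints measured on fruit and for the
#' phantom's ground-truth bookkeeping.
#'
#' @param a,b semi-axes (any consistent length unit)
#' @return area in squared units
#' @export
ellipse_area <- function(a, b) {
  if (any(c(a, b) < 0)) stop("ellipse_area: semi-axes must be nonnegative")
  pi * a * b
}

#' Per-pixel bruise map of a cube
#'
#' Classifies every ROI pixel of a calibrated cube with a trained spectral
#' model, after pushing each pixel spectrum through the identical
#' preprocessing pipeline used at training time (trim, 5-point smoothing,
#' first derivative along the spectral axis). Both bruise severities map to
#' `"bruised"`; achene and leaf pixels are `"excluded"`; off-fruit pixels
#' are `"background"`.
#'
#' @param cube calibrated [hsi_cube]
#' @param masks a [mask_set]
#' @param model a trained [train_model] (or [baseline_train]) result
#' @param keep_range_nm preprocessing trim range (must reproduce training)
#' @param window moving-average window
#' @param intact_classes labels counted as intact; all other predicted
#'   classes count as bruised
#' @return an object of class `bruise_map`: `class_map` (character matrix
#'   over {"intact","bruised","excluded","background"}), `bruised_ratio`
#'   (percent), `n_fruit_pixels`, `n_bruised_pixels`
#' @export
pixel_classify_map <- function(cube, masks, model,
                               keep_range_nm = NULL, window = 5L,
                               intact_classes = "Intact") {
  stopifnot(inherits(cube, "hsi_cube"), inherits(masks, "mask_set"))
  if (!any(masks$roi)) stop("pixel_classify_map: ROI is empty")
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  roi_idx <- which(as.vector(masks$roi))
  pp <- preprocess_pipeline(flat[roi_idx, , drop = FALSE], cube$wavelengths,
                            keep_range_nm, window)
  input_len <- if (inherits(model, "e1d_model")) model$config$input_length
               else ncol(pp$spectra)
  if (ncol(pp$spectra) != input_len)
    stop(sprintf(
      "pixel_classify_map: %d preprocessed bands but the model expects %d",
      ncol(pp$spectra), input_len))
  pred <- if (inherits(model, "e1d_model")) predict(model, pp$spectra)$labels
          else predict_baseline(model, pp$spectra)$labels
  class_map <- matrix("background", d[1], d[2])
  class_map[masks$fruit] <- "excluded"   # achene/leaf-covered fruit pixels
  class_map[as.vector(masks$leaf)] <- "excluded"
  class_map[roi_idx] <- ifelse(pred %in% intact_classes, "intact", "bruised")
  bruise_map(class_map)
}

#' Construct a bruise map from a class matrix
#'
#' @param class_map character matrix over
#'   {"intact","bruised","excluded","background"}
#' @return an object of class `bruise_map`
#' @export
bruise_map <- function(class_map) {
  stopifnot(is.matrix(class_map))
  bad <- setdiff(unique(as.vector(class_map)),
                 c("intact", "bruised", "excluded", "background"))
  if (length(bad) > 0)
    stop("bruise_map: unknown class label(s): ", paste(bad, collapse = ", "))
  n_bruised <- sum(class_map == "bruised")
  n_intact <- sum(class_map == "intact")
  structure(
    list(class_map = class_map,
         n_fruit_pixels = n_bruised + n_intact,
         n_bruised_pixels = n_bruised,
         bruised_ratio = if (n_bruised + n_intact > 0)
           100 * n_bruised / (n_bruised + n_intact) else NA_real_),
    class = "bruise_map")
}

#' Bruised-area ratio of a map
#'
#' Percent of classified fruit pixels labeled bruised. By default the
#' denominator is intact + bruised pixels only (excluded seed/leaf pixels
#' are outside the classification); set `include_excluded = TRUE` to count
#' them in the denominator instead.
#'
#' @param map a [bruise_map]
#' @param include_excluded include excluded pixels in the denominator
#' @return percent in \[0, 100\]
#' @export
bruised_area_ratio <- function(map, include_excluded = FALSE) {
  stopifnot(inherits(map, "bruise_map"))
  denom <- map$n_fruit_pixels +
    if (include_excluded) sum(map$class_map == "excluded") else 0L
  if (denom == 0) stop("bruised_area_ratio: no fruit pixels")
  100 * map$n_bruised_pixels / denom
}

#' Classification accuracy and confusion matrix
#'
#' Overall accuracy (correct / n) together with the K x K confusion matrix
#' (rows = truth, columns = prediction). For binary problems this reduces to
#' \eqn{(TP + TN) / (TP + FP + TN + FN)}.
#'
#' @param y_true,y_pred equal-length label vectors
#' @return list with `accuracy`, `confusion`, `n`
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("classification_metrics: length mismatch")
  if (length(y_true) == 0) stop("classification_metrics: empty input")
  lev <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  confusion <- table(factor(y_true, levels = lev),
                     factor(y_pred, levels = lev), dnn = c("true", "pred"))
  list(accuracy = mean(as.character(y_true) == as.character(y_pred)),
       confusion = unclass(confusion), n = length(y_true))
}

#' Mean absolute and root-mean-squared error
#'
#' \eqn{MAE = \frac{1}{n}\sum |y_{true,i} - y_{pred,i}|},
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum (y_{true,i} - y_{pred,i})^2}} — the
#' agreement metrics between measured and pixel-counted bruised-area ratios.
#' MAE <= RMSE always.
#'
#' @param true_values,est_values equal-length numeric vectors (length >= 1)
#' @return named vector `c(mae, rmse)`
#' @export
area_error_metrics <- function(true_values, est_values) {
  if (length(true_values) != length(est_values))
    stop("area_error_metrics: length mismatch")
  if (length(true_values) == 0) stop("area_error_metrics: empty input")
  d <- true_values - est_values
  c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

bruise_palette <- function() {
  rbind(bruised = c(0.13, 0.30, 0.85),   # blue
        intact = c(0.95, 0.45, 0.10),    # orange
        excluded = c(0.15, 0.65, 0.20),  # green
        background = c(0, 0, 0))         # black
}

#' Render a bruise map as a color image
#'
#' Color-codes the per-pixel classes — blue for bruised tissue, orange for
#' intact flesh, green for excluded non-target regions (seeds/leaves),
#' black background — as an rows x cols x 3 RGB array. The palette is
#' exactly one color per class, so the class map can be recovered from the
#' image by inverse palette lookup.
#'
#' @param map a [bruise_map]
#' @param path optional PNG output path; when given, a sidecar
#'   `<path>.json` with pixel counts and the ratio is written as well
#' @return RGB array (invisibly when `path` is given); attribute
#'   `"caption"` carries the ratio legend text
#' @export
render_map <- function(map, path = NULL) {
  stopifnot(inherits(map, "bruise_map"))
  pal <- bruise_palette()
  d <- dim(map$class_map)
  idx <- match(as.vector(map$class_map), rownames(pal))
  img <- array(pal[idx, ], c(d[1], d[2], 3))
  attr(img, "caption") <- sprintf(
    "bruised area: %.2f%% (%d / %d fruit pixels)",
    map$bruised_ratio, map$n_bruised_pixels, map$n_fruit_pixels)
  if (!is.null(path)) {
    png::writePNG(img, path)
    jsonlite::write_json(
      list(n_fruit_pixels = map$n_fruit_pixels,
           n_bruised_pixels = map$n_bruised_pixels,
           bruised_ratio = map$bruised_ratio,
           palette = as.list(stats::setNames(
             apply(round(pal * 255), 1, paste, collapse = ","),
             rownames(pal)))),
      paste0(path, ".json"), auto_unbox = TRUE)
    return(invisible(img))
  }
  img
}

#' Recover the class map from a rendered image
#'
#' Inverse palette lookup for [render_map] output.
#'
#' @param img rows x cols x 3 RGB array
#' @return character class matrix
#' @export
decode_map <- function(img) {
  pal <- bruise_palette()
  d <- dim(img)
  flat <- matrix(img, d[1] * d[2], 3)
  dist2 <- sapply(seq_len(nrow(pal)), function(i)
    rowSums(sweep(flat, 2, pal[i, ])^2))
  matrix(rownames(pal)[max.col(-dist2, ties.method = "first")], d[1], d[2])
}
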
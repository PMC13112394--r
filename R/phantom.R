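#' Spectral class model for the strawberry phantom
#'
#' Defines the generative model used by the synthetic phantom: a smooth
#' reflectance baseline shared by all classes, Gaussian absorption features
#' whose depths grow with bruise severity and storage time, a multiplicative
#' per-class reflectance depression, and a simple chemometric noise
#' decomposition (additive per-band noise plus a per-spectrum multiplicative
#' scatter factor). The default absorption centers place features at 675 nm
#' (pigment degradation), 970 nm and 1191 nm (water O-H overtones) and
#' 1873 nm (water combination band), the regions where bruised tissue shows
#' its strongest reflectance loss.
#'
#' @param baseline_knots 2-column matrix (wavelength nm, reflectance) of
#'   control points for the monotone-smooth baseline; reflectances in \[0,1\]
#' @param absorption_bands data.frame with columns `center_nm`, `sigma_nm`,
#'   `depth` (depth shared by all classes) and `bruise_gain` (extra depth per
#'   bruise severity step; BruisedI adds 1x, BruisedII adds 2x)
#' @param class_depression named multiplicative reflectance factors in (0,1],
#'   ordered Intact >= BruisedI >= BruisedII. The default steps are
#'   deliberately unequal (damage accelerates with impact energy), which
#'   also keeps the three class prototypes affinely independent rather than
#'   collinear
#' @param storage_gain additional fractional depression per stored hour
#'   applied to bruised classes (severity-scaled)
#' @param noise_sd additive Gaussian noise sd per band
#' @param scatter_sd sd of the per-spectrum multiplicative scatter factor
#' @return an object of class `spectral_class_model`
#' @export
spectral_class_model <- function(
    baseline_knots = default_baseline_knots(),
    absorption_bands = default_absorption_bands(),
    class_depression = c(Intact = 1.0, BruisedI = 0.93, BruisedII = 0.8),
    storage_gain = 0.0015,
    noise_sd = 0.01,
    scatter_sd = 0.01) {
  stopifnot(is.matrix(baseline_knots) || is.data.frame(baseline_knots))
  baseline_knots <- as.matrix(baseline_knots)
  absorption_bands <- as.data.frame(absorption_bands)
  stopifnot(all(c("center_nm", "sigma_nm", "depth", "bruise_gain") %in%
                  names(absorption_bands)))
  if (any(absorption_bands$depth < 0) || any(absorption_bands$bruise_gain < 0))
    stop("spectral_class_model: absorption depths must be >= 0")
  if (any(class_depression <= 0) || any(class_depression > 1))
    stop("spectral_class_model: class_depression must lie in (0, 1]")
  stopifnot(noise_sd >= 0, scatter_sd >= 0, storage_gain >= 0)
  structure(
    list(baseline_knots = baseline_knots,
         absorption_bands = absorption_bands,
         class_depression = class_depression,
         storage_gain = storage_gain,
         noise_sd = noise_sd, scatter_sd = scatter_sd),
    class = "spectral_class_model")
}

#' @rdname spectral_class_model
#' @export
default_baseline_knots <- function() {
  # Low reflectance below 500 nm, a mild 675 nm pigment valley, a broad NIR
  # plateau, gentle decline through the SWIR water bands.
  cbind(wavelength = c(380, 450, 550, 620, 675, 760, 900, 1010, 1400, 2000),
        reflectance = c(0.08, 0.10, 0.22, 0.46, 0.40, 0.58, 0.62, 0.58,
                        0.45, 0.30))
}

#' @rdname spectral_class_model
#' @export
default_absorption_bands <- function() {
  data.frame(
    center_nm = c(675, 970, 1191, 1873),
    sigma_nm = c(14, 28, 35, 45),
    depth = c(0.02, 0.03, 0.02, 0.05),
    bruise_gain = c(0.03, 0.035, 0.025, 0.03))
}

phantom_classes <- c("Intact", "BruisedI", "BruisedII")
phantom_storage_hours <- c(0, 12, 24, 48)

# Smooth monotone-in-shape baseline through the knots (natural spline,
# clamped to [0, 1]).
eval_baseline <- function(model, grid) {
  kn <- model$baseline_knots
  f <- stats::splinefun(kn[, 1], kn[, 2], method = "monoH.FC")
  pmin(pmax(f(grid), 0), 1)
}

# Deterministic expected spectrum for a class at a storage time (no noise).
# Shared absorption valleys are part of every class's spectrum; bruised
# classes additionally lose reflectance through a global multiplicative
# depression and severity-scaled extra absorption depth, both of which
# deepen linearly with storage hours.
class_prototype <- function(model, class_label, storage_h, grid) {
  if (!class_label %in% phantom_classes)
    stop("unknown class label '", class_label, "'")
  severity <- match(class_label, phantom_classes) - 1L  # 0, 1, 2
  base <- eval_baseline(model, grid)
  ab <- model$absorption_bands
  gauss <- matrix(0, length(grid), max(nrow(ab), 1L))
  for (i in seq_len(nrow(ab)))
    gauss[, i] <- exp(-(grid - ab$center_nm[i])^2 / (2 * ab$sigma_nm[i]^2))
  if (nrow(ab) == 0L) ab <- data.frame(depth = 0, bruise_gain = 0)
  shared <- pmin(pmax(base - as.vector(gauss %*% ab$depth), 0), 1)
  depress <- model$class_depression[[class_label]] -
    model$storage_gain * storage_h * severity
  depress <- max(depress, 0)
  extra <- severity * (1 + model$storage_gain * storage_h * 10) *
    as.vector(gauss %*% ab$bruise_gain)
  pmin(pmax(shared * depress - extra, 0), 1)
}

#' Simulate a single reflectance spectrum
#'
#' Draws one spectrum from the phantom class model: the class prototype
#' (baseline x class depression minus severity-scaled absorption features)
#' perturbed by a multiplicative scatter factor and additive band noise,
#' clipped to \[0, 1\]. With all noise at zero the expectation ordering
#' BruisedII <= BruisedI <= Intact holds at every band.
#'
#' @param model a [spectral_class_model]
#' @param class_label one of `"Intact"`, `"BruisedI"`, `"BruisedII"`
#' @param storage_h storage time in hours (0, 12, 24 or 48 in the standard
#'   design; any nonnegative value is accepted)
#' @param grid wavelength vector from [make_wavelength_grid]
#' @param seed integer seed; all randomness flows through it
#' @return reflectance vector on `grid`, values in \[0, 1\]
#' @export
simulate_spectrum <- function(model, class_label, storage_h, grid, seed = 0L) {
  proto <- class_prototype(model, class_label, storage_h, grid)
  if (model$noise_sd == 0 && model$scatter_sd == 0) return(proto)
  rng <- local_rng(seed)
  scatter <- 1 + rng$norm(1, sd = model$scatter_sd)
  noise <- rng$norm(length(grid), sd = model$noise_sd)
  pmin(pmax(proto * scatter + noise, 0), 1)
}

# Small closure-based RNG so no simulation touches the global random state.
local_rng <- function(seed) {
  env <- new.env()
  assign("state", {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }, env)
  draw <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", get("state", env), envir = globalenv())
    out <- fn()
    assign("state", get(".Random.seed", globalenv()), env)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) draw(function() stats::rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1) draw(function() stats::runif(n, min, max)),
    sample = function(x, size = NULL, replace = FALSE)
      draw(function() if (is.null(size)) sample(x, replace = replace)
           else sample(x, size, replace = replace)),
    integer = function(n, max) draw(function() sample.int(max, n, replace = TRUE))
  )
}

#' Describe a phantom scene
#'
#' Geometry of one synthetic strawberry image: an elliptical fruit, an
#' optional elliptical bruise fully contained in the fruit, achene speckles
#' scattered over the fruit, and an optional rectangular leaf region outside
#' the fruit. When `target_bruise_ratio` is given the bruise semi-axes are
#' derived from the analytic ellipse-area ratio
#' \eqn{S = \pi a b} so that the bruised fraction of fruit pixels matches the
#' target (up to rasterization).
#'
#' @param image_shape `c(rows, cols)`
#' @param fruit_center,fruit_axes ellipse center (row, col) and semi-axes
#'   (a, b) in pixels
#' @param bruise_center,bruise_axes bruise ellipse, or `NULL` for an intact
#'   fruit; must lie inside the fruit
#' @param target_bruise_ratio percent of fruit pixels to bruise; when given,
#'   overrides `bruise_axes` with axes scaled from the fruit's
#' @param bruise_class class of the bruised region (`"BruisedI"` or
#'   `"BruisedII"`)
#' @param storage_h storage hours for the whole scene
#' @param n_achenes number of achene speckles
#' @param achene_radius speckle radius in pixels
#' @param leaf_rect `c(row0, col0, row1, col1)` leaf rectangle or `NULL`
#' @param seed integer seed controlling achene placement and pixel noise
#' @return an object of class `phantom_scene`
#' @export
phantom_scene <- function(image_shape = c(72, 72),
                          fruit_center = NULL,
                          fruit_axes = c(26, 20),
                          bruise_center = NULL,
                          bruise_axes = NULL,
                          target_bruise_ratio = NULL,
                          bruise_class = "BruisedII",
                          storage_h = 0,
                          n_achenes = 25,
                          achene_radius = 1,
                          leaf_rect = NULL,
                          seed = 0L) {
  if (is.null(fruit_center)) fruit_center <- (image_shape + 1) / 2
  if (!is.null(target_bruise_ratio)) {
    # pi*a_b*b_b / (pi*a_f*b_f) = r/100 with the bruise shaped like the fruit
    s <- sqrt(target_bruise_ratio / 100)
    bruise_axes <- fruit_axes * s
  }
  has_bruise <- !is.null(bruise_axes)
  if (has_bruise && is.null(bruise_center)) {
    # offset toward the upper-left so the bruise is not concentric by default
    off <- pmax(fruit_axes - bruise_axes, 0) * 0.3
    bruise_center <- fruit_center - off
  }
  if (has_bruise) {
    if (!ellipse_inside(bruise_center, bruise_axes, fruit_center, fruit_axes))
      stop("phantom_scene: bruise ellipse escapes the fruit ellipse")
    if (!bruise_class %in% c("BruisedI", "BruisedII"))
      stop("phantom_scene: bruise_class must be BruisedI or BruisedII")
  }
  structure(
    list(image_shape = as.integer(image_shape),
         fruit_center = fruit_center, fruit_axes = fruit_axes,
         bruise_center = if (has_bruise) bruise_center else NULL,
         bruise_axes = if (has_bruise) bruise_axes else NULL,
         target_bruise_ratio = target_bruise_ratio,
         bruise_class = bruise_class, storage_h = storage_h,
         n_achenes = as.integer(n_achenes), achene_radius = achene_radius,
         leaf_rect = leaf_rect, seed = as.integer(seed)),
    class = "phantom_scene")
}

# Conservative containment check: sample the inner ellipse boundary and
# require every point inside the outer one.
ellipse_inside <- function(ci, ai, co, ao) {
  th <- seq(0, 2 * pi, length.out = 128)
  pr <- ci[1] + ai[1] * cos(th)
  pc <- ci[2] + ai[2] * sin(th)
  all(((pr - co[1]) / ao[1])^2 + ((pc - co[2]) / ao[2])^2 <= 1 + 1e-9)
}

ellipse_mask <- function(shape, center, axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
}

#' Simulate a hyperspectral phantom cube with ground truth
#'
#' Rasterizes a [phantom_scene] and fills each pixel with a spectrum drawn
#' from the pixel's ground-truth class: fruit pixels from the Intact
#' prototype, bruise pixels from the scene's bruise class, achene pixels
#' from a dark spectrum (0.3 x the fruit baseline), leaf pixels from a
#' chlorophyll-like spectrum constructed with NDVI > 0.6, and background
#' pixels near zero. Returns the cube, the ground-truth mask set, and the
#' realized bruised-area ratio (bruised / fruit pixels x 100).
#'
#' @param scene a [phantom_scene]
#' @param model a [spectral_class_model]
#' @param grid wavelength vector
#' @return list with elements `cube` ([hsi_cube]), `masks` ([mask_set]) and
#'   `true_ratio` (percent)
#' @export
simulate_cube <- function(scene, model = spectral_class_model(),
                          grid = make_wavelength_grid(380, 1010, 440)) {
  stopifnot(inherits(scene, "phantom_scene"))
  shape <- scene$image_shape
  nb <- length(grid)
  rng <- local_rng(scene$seed)

  fruit <- ellipse_mask(shape, scene$fruit_center, scene$fruit_axes)
  bruise <- if (!is.null(scene$bruise_axes))
    ellipse_mask(shape, scene$bruise_center, scene$bruise_axes) & fruit
  else matrix(FALSE, shape[1], shape[2])

  # achene speckles: small discs scattered over the imaged fruit face.
  # Centers are drawn from the fruit interior (axes shrunk by the speckle
  # radius + 2 px) so speckles do not straddle the silhouette rim.
  achene <- matrix(FALSE, shape[1], shape[2])
  if (scene$n_achenes > 0) {
    inner <- ellipse_mask(shape, scene$fruit_center,
                          pmax(scene$fruit_axes - (scene$achene_radius + 2), 1))
    fruit_idx <- which(fruit & inner)
    pick <- fruit_idx[rng$integer(scene$n_achenes, length(fruit_idx))]
    pr <- (pick - 1) %% shape[1] + 1
    pc <- (pick - 1) %/% shape[1] + 1
    rad <- max(scene$achene_radius, 0)
    for (i in seq_along(pick)) {
      rr <- max(1, pr[i] - ceiling(rad)):min(shape[1], pr[i] + ceiling(rad))
      cc <- max(1, pc[i] - ceiling(rad)):min(shape[2], pc[i] + ceiling(rad))
      for (a in rr) for (b in cc)
        if ((a - pr[i])^2 + (b - pc[i])^2 <= rad^2) achene[a, b] <- TRUE
    }
    achene <- achene & fruit
  }

  leaf <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(scene$leaf_rect)) {
    lr <- scene$leaf_rect
    leaf[lr[1]:lr[3], lr[2]:lr[4]] <- TRUE
    if (any(leaf & fruit))
      stop("simulate_cube: leaf region must not overlap the fruit")
  }

  protos <- rbind(
    intact = class_prototype(model, "Intact", scene$storage_h, grid),
    bruise = class_prototype(model, scene$bruise_class, scene$storage_h, grid),
    achene = 0.3 * eval_baseline(model, grid),
    leaf = leaf_prototype(grid),
    background = rep(0.02, nb))

  labels <- matrix("background", shape[1], shape[2])
  labels[fruit] <- "intact"
  labels[bruise] <- "bruise"
  labels[achene] <- "achene"
  labels[leaf] <- "leaf"

  npix <- prod(shape)
  flat <- protos[match(as.vector(labels),
                       c("intact", "bruise", "achene", "leaf", "background")), ,
                 drop = FALSE]
  if (model$scatter_sd > 0)
    flat <- flat * (1 + rng$norm(npix, sd = model$scatter_sd))
  if (model$noise_sd > 0)
    flat <- flat + matrix(rng$norm(npix * nb, sd = model$noise_sd), npix, nb)
  flat <- pmin(pmax(flat, 0), 1)
  data <- array(flat, c(shape[1], shape[2], nb))

  masks <- mask_set(fruit = fruit, achene = achene, leaf = leaf,
                    source_wavelength_nm = NA_real_)
  gt_bruised <- sum(bruise & !achene)
  gt_fruit <- sum(fruit & !achene)
  true_ratio <- if (gt_fruit > 0) 100 * gt_bruised / gt_fruit else 0
  list(cube = hsi_cube(data, grid, calibrated = TRUE),
       masks = masks, true_ratio = true_ratio,
       label_map = labels)
}

# Leaf spectrum: low red (660-680 nm), high NIR plateau, so NDVI at the
# conventional 670/800 nm pair is ~0.8 (> the 0.6 construction floor).
leaf_prototype <- function(grid) {
  red <- 0.06 + 0.02 * exp(-(grid - 550)^2 / (2 * 30^2))
  nir <- 0.55 / (1 + exp(-(grid - 715) / 12))
  pmin(red + nir, 1)
}

#' Simulate a labeled mean-spectrum dataset
#'
#' Draws `n_per_class` spectra per class at each requested storage time,
#' emulating the per-fruit mean ROI spectra that feed the classifiers. Rows
#' are ordered class-major (all Intact first), storage-minor; the order is
#' stable and two calls with the same seed are identical.
#'
#' @param model a [spectral_class_model]
#' @param grid wavelength vector
#' @param n_per_class spectra per class per storage time (>= 1)
#' @param storage_h vector of storage hours
#' @param classes class labels to include
#' @param seed integer seed
#' @return a [spectral_dataset] with `label` = class and `storage_h` column
#' @export
simulate_dataset <- function(model = spectral_class_model(),
                             grid = make_wavelength_grid(380, 1010, 440),
                             n_per_class = 135,
                             storage_h = 0,
                             classes = phantom_classes,
                             seed = 0L) {
  stopifnot(n_per_class >= 1)
  rng <- local_rng(seed)
  nb <- length(grid)
  rows <- list(); labels <- character(); hours <- numeric()
  for (cl in classes) for (h in storage_h) {
    proto <- class_prototype(model, cl, h, grid)
    block <- matrix(proto, n_per_class, nb, byrow = TRUE)
    if (model$scatter_sd > 0)
      block <- block * (1 + rng$norm(n_per_class, sd = model$scatter_sd))
    if (model$noise_sd > 0)
      block <- block + matrix(rng$norm(n_per_class * nb, sd = model$noise_sd),
                              n_per_class, nb)
    rows[[length(rows) + 1L]] <- pmin(pmax(block, 0), 1)
    labels <- c(labels, rep(cl, n_per_class))
    hours <- c(hours, rep(h, n_per_class))
  }
  spectral_dataset(do.call(rbind, rows), labels, grid, storage_h = hours)
}
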
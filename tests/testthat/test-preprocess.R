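test_that("ROI mean spectra average exactly the ROI pixels", {
  wl <- c(500, 600, 700)
  d <- array(0.2, c(2, 2, 3))
  cube <- hsi_cube(d, wl, calibrated = TRUE)
  roi <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(mean_roi_spectrum(cube, roi), rep(0.2, 3))

  d2 <- d; d2[1, 1, ] <- 0.2; d2[2, 1, ] <- 0.4
  expect_equal(mean_roi_spectrum(hsi_cube(d2, wl, calibrated = TRUE), roi),
               rep(0.3, 3))
  expect_error(mean_roi_spectrum(cube, matrix(FALSE, 2, 2)), "empty")

  # phantom: ROI mean of an intact fruit is the intact prototype
  grid <- test_grid_small()
  m <- noise_free_model()
  sim <- simulate_cube(phantom_scene(bruise_axes = NULL,
                                     target_bruise_ratio = NULL, seed = 1),
                       m, grid)
  expect_equal(mean_roi_spectrum(sim$cube, sim$masks),
               simulate_spectrum(m, "Intact", 0, grid), tolerance = 1e-12)
})

test_that("moving average smooths with truncated edges", {
  expect_equal(moving_average(rep(3, 10)), rep(3, 10))
  imp <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(moving_average(imp), c(0, 0, 0.2, 0.2, 0.2, 0.2, 0.2, 0, 0))
  ramp <- as.numeric(1:11)
  expect_equal(moving_average(ramp)[3:9], ramp[3:9])  # linear interior fixed
  expect_error(moving_average(1:10, window = 4), "odd")
  expect_error(moving_average(1:3, window = 5), "length")
  # never widens the value range
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(50)
    s <- moving_average(v)
    expect_gte(min(s), min(v)); expect_lte(max(s), max(v))
  }
  # matrix rows smoothed independently
  m <- rbind(imp, rep(1, 9))
  expect_equal(moving_average(m)[1, ], moving_average(imp))
})

test_that("first derivative uses central differences and kills offsets", {
  wl <- as.numeric(1:10)
  expect_equal(first_derivative(rep(5, 10), wl), rep(0, 10))
  expect_equal(first_derivative(2 * wl, wl), rep(2, 10))
  d <- first_derivative(c(1, 4, 9), c(1, 2, 3))
  expect_equal(d[2], 4)          # (9 - 1) / (3 - 1)
  expect_equal(d[1], 3); expect_equal(d[3], 5)
  # additive-offset invariance
  set.seed(2)
  s <- rnorm(30); wl30 <- sort(runif(30, 400, 900))
  expect_equal(first_derivative(s + 7.3, wl30), first_derivative(s, wl30))
  expect_error(first_derivative(1:5, c(1, 3, 2, 4, 5)), "monotone")
})

test_that("the preprocessing pipeline is the composition of its steps", {
  wl <- make_wavelength_grid(380, 1010, 60)
  set.seed(3)
  x <- matrix(runif(5 * 60), 5, 60)
  out <- preprocess_pipeline(x, wl, keep_range_nm = c(400, 1000))
  manual <- trim_bands(x, c(400, 1000), wl)
  wl_kept <- attr(manual, "wavelengths")
  attr(manual, "wavelengths") <- NULL
  manual <- first_derivative(moving_average(manual), wl_kept)
  expect_equal(out$spectra, manual)
  expect_equal(out$wavelengths, wl_kept)
  expect_equal(out$steps[1], "trim[400,1000]")

  expect_equal(preprocess_pipeline(rep(0.4, 60), wl)$spectra, rep(0, 60))

  # class prototypes stay nearest-prototype separable after the pipeline
  grid <- test_grid_small()
  m <- noise_free_model()
  ds <- simulate_dataset(m, grid, n_per_class = 5, seed = 4)
  pp <- preprocess_dataset(ds, keep_range_nm = c(380, 1010))
  protos <- pp$spectra[!duplicated(pp$labels), ]
  rownames(protos) <- pp$labels[!duplicated(pp$labels)]
  hits <- vapply(seq_len(nrow(pp$spectra)), function(i)
    nearest_prototype(pp$spectra[i, ], protos) == pp$labels[i], logical(1))
  expect_true(all(hits))
})

test_that("Kennard-Stone selection matches hand execution and brute force", {
  # 1D: the extreme pair is selected
  x <- matrix(c(0, 1, 10), 3)
  sp <- kennard_stone_split(x, 2 / 3)
  expect_equal(sp$cal, c(1, 3)); expect_equal(sp$val, 2)

  # all-identical points: lowest indices under the tie rule
  xi <- matrix(1, 6, 2)
  expect_equal(kennard_stone_split(xi, 2 / 3)$cal, c(1, 2, 3, 4))

  # unit square corners, cal 2: lowest-index main-diagonal pair
  xc <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(kennard_stone_split(xc, 0.5)$cal, c(1, 4))

  expect_error(kennard_stone_split(matrix(1, 1, 1), 0.5), "at least 2")
  expect_error(kennard_stone_split(xc, 1.2), "cal_fraction")

  # oracle equivalence on every splittable size n <= 8
  set.seed(5)
  for (n in 3:8) for (rep in 1:5) {
    x <- matrix(rnorm(n * 3), n, 3)
    n_cal <- min(n - 1, max(2, round(n * 2 / 3)))
    expect_equal(kennard_stone_split(x, n_cal / n)$cal, ks_bruteforce(x, n_cal))
  }
})

test_that("Kennard-Stone is permutation-covariant up to its tie rule", {
  set.seed(6)
  x <- matrix(rnorm(12 * 4), 12, 4)  # continuous data: ties have measure zero
  base <- kennard_stone_split(x, 2 / 3)$cal
  for (i in 1:5) {
    perm <- sample(12)
    permuted <- kennard_stone_split(x[perm, , drop = FALSE], 2 / 3)$cal
    expect_setequal(perm[permuted], base)
  }
})

test_that("per-class splitting keeps every class balanced 2:1", {
  set.seed(7)
  x <- rbind(matrix(rnorm(30, 0), 15), matrix(rnorm(30, 5), 15))
  labels <- rep(c("A", "B"), each = 15)
  sp <- kennard_stone_split(x, 2 / 3, labels = labels)
  expect_equal(sum(sp$cal <= 15), 10L)   # round(15 * 2/3)
  expect_equal(sum(sp$cal > 15), 10)
  expect_setequal(c(sp$cal, sp$val), 1:30)

  ds <- spectral_dataset(x, labels, seq_len(ncol(x)))
  ds <- split_dataset(ds)
  expect_equal(as.integer(sort(table(ds$labels[ds$split$cal]))), c(10L, 10L))
})

test_that("spectra tables round-trip through CSV", {
  grid <- test_grid_small(20L)
  ds <- simulate_dataset(spectral_class_model(), grid, n_per_class = 4,
                         storage_h = c(0, 12), seed = 8)
  path <- file.path(withr::local_tempdir(), "spectra.csv")
  write_spectra_csv(ds, path)
  back <- read_spectra_csv(path)
  expect_equal(back$spectra, ds$spectra, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$storage_h, ds$storage_h)
  expect_equal(back$wavelengths, round(ds$wavelengths, 2), tolerance = 0.01)
})
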
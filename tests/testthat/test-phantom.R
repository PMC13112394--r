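test_that("wavelength grids span the acquisition ranges evenly", {
  wl <- make_wavelength_grid(380, 1010, 440)
  expect_length(wl, 440)
  expect_equal(wl[1], 380)
  expect_equal(wl[440], 1010)
  # spacing matches the ~1.43 nm camera resolution
  expect_equal(diff(wl)[1], (1010 - 380) / 439, tolerance = 1e-12)
  expect_equal(round(diff(wl)[1], 2), 1.44)
  expect_true(all(diff(wl) > 0))

  expect_equal(make_wavelength_grid(0, 1, 2), c(0, 1))
  swir <- make_wavelength_grid(1000, 2000, 146)
  expect_length(swir, 146)
  expect_equal(range(swir), c(1000, 2000))

  expect_error(make_wavelength_grid(500, 400, 10), "exceed")
  expect_error(make_wavelength_grid(0, 1, 1), "n_bands")
})

test_that("noise-free spectra follow the generative formula exactly", {
  grid <- test_grid_small()
  # no absorption, no depression: the baseline itself
  m0 <- spectral_class_model(
    absorption_bands = data.frame(center_nm = numeric(), sigma_nm = numeric(),
                                  depth = numeric(), bruise_gain = numeric()),
    class_depression = c(Intact = 1, BruisedI = 1, BruisedII = 1),
    noise_sd = 0, scatter_sd = 0)
  base <- simulate_spectrum(m0, "Intact", 0, grid)
  expect_true(all(base >= 0 & base <= 1))

  # pure multiplicative depression: BruisedII = 0.8 x Intact
  m1 <- spectral_class_model(
    absorption_bands = data.frame(center_nm = numeric(), sigma_nm = numeric(),
                                  depth = numeric(), bruise_gain = numeric()),
    class_depression = c(Intact = 1, BruisedI = 0.9, BruisedII = 0.8),
    noise_sd = 0, scatter_sd = 0)
  expect_equal(simulate_spectrum(m1, "BruisedII", 0, grid),
               0.8 * simulate_spectrum(m1, "Intact", 0, grid),
               tolerance = 1e-12)

  # a single absorption band pulls the minimum to its center
  # (flat baseline so the band is the only structure)
  m2 <- spectral_class_model(
    baseline_knots = cbind(c(380, 700, 1010), c(0.6, 0.6, 0.6)),
    absorption_bands = data.frame(center_nm = 970, sigma_nm = 10,
                                  depth = 0.3, bruise_gain = 0),
    noise_sd = 0, scatter_sd = 0)
  s <- simulate_spectrum(m2, "Intact", 0, grid)
  expect_lt(abs(grid[which.min(s)] - 970), diff(grid)[1] + 1e-9)

  expect_error(simulate_spectrum(m2, "Squashed", 0, grid), "unknown class")
})

test_that("expected reflectance is ordered BruisedII <= BruisedI <= Intact", {
  grid <- make_wavelength_grid(380, 2000, 300)
  m <- noise_free_model()
  for (h in c(0, 12, 24, 48)) {
    si <- simulate_spectrum(m, "Intact", h, grid)
    s1 <- simulate_spectrum(m, "BruisedI", h, grid)
    s2 <- simulate_spectrum(m, "BruisedII", h, grid)
    expect_true(all(s2 <= s1 + 1e-12))
    expect_true(all(s1 <= si + 1e-12))
    expect_true(all(si <= 1 & s2 >= 0))
  }
})

test_that("simulated cubes carry consistent ground truth", {
  grid <- test_grid_small()
  m <- noise_free_model()

  # intact scene: no bruised pixels at all
  sc0 <- phantom_scene(bruise_axes = NULL, target_bruise_ratio = NULL, seed = 2)
  sim0 <- simulate_cube(sc0, m, grid)
  expect_equal(sim0$true_ratio, 0)

  # concentric ellipses: ratio of areas (pi a b), within rasterization slack
  sc <- phantom_scene(image_shape = c(90, 70), fruit_axes = c(40, 30),
                      bruise_center = c(45.5, 35.5), bruise_axes = c(10, 7.5),
                      n_achenes = 0, seed = 3)
  sim <- simulate_cube(sc, m, grid)
  expect_lt(abs(sim$true_ratio - 6.25), 1)

  # determinism: identical seed, bit-identical cube and masks
  sim_a <- simulate_cube(phantom_scene(target_bruise_ratio = 12, seed = 9),
                         spectral_class_model(), grid)
  sim_b <- simulate_cube(phantom_scene(target_bruise_ratio = 12, seed = 9),
                         spectral_class_model(), grid)
  expect_identical(sim_a$cube$data, sim_b$cube$data)
  expect_identical(sim_a$masks$roi, sim_b$masks$roi)

  # all reflectances in [0,1]; mask algebra holds
  expect_true(all(sim_a$cube$data >= 0 & sim_a$cube$data <= 1))
  expect_true(all(sim_a$masks$achene <= sim_a$masks$fruit))     # achene in fruit
  expect_false(any(sim_a$masks$leaf & sim_a$masks$fruit))        # leaf disjoint
  expect_identical(sim_a$masks$roi,
                   sim_a$masks$fruit & !sim_a$masks$achene & !sim_a$masks$leaf)

  # a bruise that escapes the fruit is rejected
  expect_error(
    phantom_scene(fruit_axes = c(20, 15), bruise_center = c(10, 10),
                  bruise_axes = c(12, 12)),
    "escapes")
})

test_that("rasterized bruise ratio converges to the ellipse-area ratio", {
  grid <- make_wavelength_grid(380, 1010, 5)
  m <- noise_free_model()
  target <- 100 * (0.25 * 0.25)  # bruise axes = fruit axes / 4
  err <- sapply(c(1, 2, 4), function(scale) {
    sc <- phantom_scene(image_shape = c(36, 30) * scale + 1,
                        fruit_axes = c(16, 12) * scale,
                        target_bruise_ratio = target,
                        n_achenes = 0, seed = 1)
    abs(simulate_cube(sc, m, grid)$true_ratio - target)
  })
  expect_lt(err[3], 1)
  expect_true(err[3] <= err[1] + 0.1)  # finer raster, smaller error
})

test_that("simulated datasets are balanced, stable and prototype-exact", {
  grid <- test_grid_small()
  m <- noise_free_model()
  ds <- simulate_dataset(m, grid, n_per_class = 135, seed = 0)
  expect_equal(nrow(ds$spectra), 405)  # the per-timepoint design: 135 x 3
  expect_equal(as.vector(table(ds$labels)), rep(135L, 3))

  # n_per_class = 1, noise 0: exactly the three class prototypes
  ds1 <- simulate_dataset(m, grid, n_per_class = 1, seed = 0)
  protos <- ds1$spectra
  rownames(protos) <- ds1$labels
  expect_equal(unname(protos["Intact", ]),
               simulate_spectrum(m, "Intact", 0, grid))
  expect_equal(unname(protos["BruisedII", ]),
               simulate_spectrum(m, "BruisedII", 0, grid))

  # same seed, identical matrices (with noise enabled)
  mn <- spectral_class_model()
  expect_identical(simulate_dataset(mn, grid, 10, seed = 4)$spectra,
                   simulate_dataset(mn, grid, 10, seed = 4)$spectra)

  # noise-free separability: nearest prototype classifies perfectly
  ds2 <- simulate_dataset(m, grid, n_per_class = 20, seed = 5)
  hits <- vapply(seq_len(nrow(ds2$spectra)), function(i)
    nearest_prototype(ds2$spectra[i, ], protos) == ds2$labels[i], logical(1))
  expect_true(all(hits))
})

test_that("phantom leaves are NDVI-bright and achenes dark by construction", {
  grid <- test_grid_small(200L)
  m <- noise_free_model()
  sc <- phantom_scene(target_bruise_ratio = 10, leaf_rect = c(2, 2, 12, 12),
                      seed = 6)
  sim <- simulate_cube(sc, m, grid)
  nir <- sim$cube$data[, , which.min(abs(grid - 800))]
  red <- sim$cube$data[, , which.min(abs(grid - 670))]
  ndvi <- ifelse(nir + red == 0, 0, (nir - red) / (nir + red))
  expect_true(all(ndvi[sim$masks$leaf] > 0.6))
  expect_true(all(ndvi[sim$masks$roi] < 0.4))
  g647 <- sim$cube$data[, , which.min(abs(grid - 647))]
  expect_true(mean(g647[sim$masks$achene]) < 0.5 * mean(g647[sim$masks$roi]))
})
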
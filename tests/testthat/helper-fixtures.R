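# Shared fixtures: small grids, noise-free class models, and a memoized
# compact trained model so several test files can reuse one training run.

test_grid_small <- function(n = 80L) make_wavelength_grid(380, 1010, n)

noise_free_model <- function() spectral_class_model(noise_sd = 0, scatter_sd = 0)

# nearest-prototype classifier used as the independent separability oracle
nearest_prototype <- function(x, protos) {
  d <- apply(protos, 1, function(p) sum((x - p)^2))
  rownames(protos)[which.min(d)]
}

# one compact model trained on a small separable phantom dataset (80 bands),
# built on first use and cached for the session
trained_compact_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    grid <- test_grid_small()
    ds <- simulate_dataset(noise_free_model(), grid, n_per_class = 30, seed = 11)
    ds <- preprocess_dataset(ds, keep_range_nm = c(380, 1010))
    ds <- split_dataset(ds)
    cfg <- e1d_compact_config(ncol(ds$spectra), 3L)
    fit <- train_model(ds, cfg, train_hyper(learning_rate = 5e-4,
                                            epochs = 25L, n_repeats = 1L))
    cache <<- list(fit = fit, grid = grid, dataset = ds)
    cache
  }
})
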
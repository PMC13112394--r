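test_that("silu matches its closed form and asymptotes", {
  expect_equal(silu(0), 0)
  expect_equal(silu(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_lt(abs(silu(20) - 20), 1e-6)
  expect_equal(silu(c(-1, 0, 2)), c(-1, 0, 2) * plogis(c(-1, 0, 2)))
})

test_that("squeeze-excitation attention follows its formula", {
  H2 <- matrix(rnorm(4 * 6), 4, 6)
  # zero weights: sigmoid(0) = 0.5 on every channel
  a0 <- se_attention(H2, matrix(0, 2, 4), matrix(0, 4, 2))
  expect_equal(as.numeric(a0), rep(0.5, 4))
  # constant channels: GAP recovers the constants through W1 = I
  Hc <- matrix(rep(c(1, 2, 3), each = 5), 3, 5, byrow = TRUE)
  W1 <- diag(3); W2 <- diag(3)
  a <- se_attention(Hc, W1, W2)
  expect_equal(as.numeric(a), plogis(pmax(c(1, 2, 3), 0)), tolerance = 1e-12)
  # strictly inside (0, 1) for any weights
  set.seed(1)
  a2 <- se_attention(matrix(rnorm(40), 8, 5), matrix(rnorm(16), 2, 8),
                     matrix(rnorm(16), 8, 2))
  expect_true(all(a2 > 0 & a2 < 1))
  expect_error(se_attention(H2, matrix(0, 2, 3), matrix(0, 4, 2)), "channel")
})

test_that("mbconv forward matches a straight-line hand computation", {
  toy <- mbconv_toy()
  spec <- toy$spec; U <- toy$U; w <- toy$w
  out <- mbconv_forward(U, spec, w, batch_norm = FALSE)
  expect_true(spec$residual)
  expect_equal(out, mbconv_by_hand(U, spec, w), tolerance = 1e-12)

  # stride-2 variant: shorter output, no residual
  spec2 <- mbconv_spec(2L, 2L, expansion = 2L, kernel = 3L, stride = 2L)
  expect_false(spec2$residual)
  out2 <- mbconv_forward(U, spec2, w, batch_norm = FALSE)
  expect_equal(ncol(out2), (6 + 2 * 1 - 3) %/% 2 + 1)
  expect_equal(out2, mbconv_by_hand(U, spec2, w), tolerance = 1e-12)
})

test_that("the residual rule activates exactly for stride 1 and equal widths", {
  expect_true(mbconv_spec(8, 8, stride = 1)$residual)
  expect_false(mbconv_spec(8, 8, stride = 2)$residual)
  expect_false(mbconv_spec(8, 16, stride = 1)$residual)

  # zero-weight probe: output == input iff the skip is active
  U <- matrix(rnorm(4 * 10), 4, 10)
  zero_w <- function(spec) list(
    pw1_W = matrix(0, spec$expanded, spec$in_channels),
    dw_W = matrix(0, spec$expanded, spec$kernel),
    se_W1 = matrix(0, spec$se_dim, spec$expanded), se_b1 = rep(0, spec$se_dim),
    se_W2 = matrix(0, spec$expanded, spec$se_dim), se_b2 = rep(0, spec$expanded),
    pw2_W = matrix(0, spec$out_channels, spec$expanded))
  s1 <- mbconv_spec(4L, 4L, expansion = 1L, kernel = 3L, stride = 1L)
  expect_equal(mbconv_forward(U, s1, zero_w(s1), batch_norm = FALSE), U)
  expect_equal(s1$expanded, 4L)  # expansion 1 preserves the channel count
  s2 <- mbconv_spec(4L, 4L, expansion = 1L, kernel = 3L, stride = 2L)
  expect_true(all(mbconv_forward(U, s2, zero_w(s2), batch_norm = FALSE) == 0))
})

test_that("model probabilities are softmax-normalized and batch-equivariant", {
  cfg <- e1d_compact_config(40L, 3L)
  st <- init_e1d_weights(cfg, 1L)
  set.seed(2)
  X <- matrix(rnorm(7 * 40), 7, 40)
  p <- model_forward(X, cfg, st$weights, st$buffers)
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  perm <- c(3, 1, 7, 2, 6, 5, 4)
  expect_equal(model_forward(X[perm, ], cfg, st$weights, st$buffers), p[perm, ])
  expect_error(model_forward(matrix(0, 2, 39), cfg, st$weights, st$buffers),
               "length")
  # degenerate single-class head
  cfg1 <- e1d_config(40L, 1L, stem = cfg$stem, blocks = cfg$blocks)
  st1 <- init_e1d_weights(cfg1, 1L)
  expect_equal(as.numeric(model_forward(X, cfg1, st1$weights, st1$buffers)),
               rep(1, 7))
})

test_that("analytic parameter counts equal the framework totals", {
  # frozen reference budget for 440 bands / 3 classes
  ref <- e1d_reference_config(440L, 3L)
  expect_identical(count_parameters(ref), 405098L)
  st <- init_e1d_weights(ref, 0L)
  expect_identical(strawbruise:::n_trainable_scalars(st$weights), 405098L)

  # stem-only hand count: one 1x1 kernel + one classifier weight
  bare <- e1d_config(16L, 1L,
                     stem = list(out_channels = 1L, kernel = 1L, stride = 1L,
                                 padding = 0L),
                     blocks = list(), batch_norm = FALSE,
                     classifier_bias = FALSE)
  expect_identical(count_parameters(bare), 2L)

  # property: analytic count == initialized scalar total on random configs
  set.seed(3)
  for (i in 1:8) {
    c0 <- sample(4:12, 1)
    ch <- c(c0, sample(6:20, 3, replace = TRUE))
    blocks <- lapply(1:3, function(j)
      mbconv_spec(ch[j], ch[j + 1], expansion = sample(c(1, 2, 4, 6), 1),
                  kernel = sample(c(3, 5), 1), stride = sample(1:2, 1)))
    cfg <- e1d_config(64L, sample(2:5, 1),
                      stem = list(out_channels = c0, kernel = 3L, stride = 2L,
                                  padding = 1L),
                      blocks = blocks,
                      classifier_bias = sample(c(TRUE, FALSE), 1))
    st <- init_e1d_weights(cfg, i)
    expect_identical(count_parameters(cfg),
                     strawbruise:::n_trainable_scalars(st$weights))
  }

  # widening strictly increases capacity
  wide <- e1d_config(440L, 3L,
                     stem = list(out_channels = 32L, kernel = 3L, stride = 2L,
                                 padding = 1L),
                     blocks = list(mbconv_spec(32L, 48L)))
  wider <- e1d_config(440L, 3L,
                      stem = list(out_channels = 64L, kernel = 3L, stride = 2L,
                                  padding = 1L),
                      blocks = list(mbconv_spec(64L, 96L)))
  expect_gt(count_parameters(wider), count_parameters(wide))

  # inconsistent channel chains are rejected
  expect_error(e1d_config(64L, 3L,
                          stem = list(out_channels = 8L, kernel = 3L,
                                      stride = 2L, padding = 1L),
                          blocks = list(mbconv_spec(16L, 24L))),
               "chain")
})

test_that("compound scaling obeys the alpha-beta-gamma constraint", {
  expect_equal(unname(compound_scale(phi = 0)), c(1, 1, 1))
  expect_equal(unname(compound_scale(1.2, 1.1, 1.15, phi = 1)),
               c(1.2, 1.1, 1.15))
  expect_equal(unname(compound_scale(1.2, 1.1, 1.15, phi = 2)),
               c(1.44, 1.21, 1.3225), tolerance = 1e-12)
  expect_error(compound_scale(1.8, 1.3, 1.3, phi = 1), "deviates")
  expect_warning(compound_scale(1.8, 1.3, 1.3, phi = 1, strict = FALSE),
                 "deviates")
  expect_error(compound_scale(0.9, 1, 1, phi = 1), ">= 1")
})

test_that("backpropagated gradients match numerical differentiation", {
  ns <- asNamespace("strawbruise")
  cfg <- e1d_config(12L, 3L,
                    stem = list(out_channels = 4L, kernel = 3L, stride = 2L,
                                padding = 1L),
                    blocks = list(mbconv_spec(4L, 4L, expansion = 2L),
                                  mbconv_spec(4L, 6L, expansion = 2L,
                                              stride = 2L)))
  st <- init_e1d_weights(cfg, 7L)
  W <- st$weights; B <- st$buffers
  set.seed(4)
  X <- array(rnorm(1 * 12 * 5), c(1L, 12L, 5L))
  y <- c(1L, 2L, 3L, 1L, 2L)
  loss_at <- function(W)
    ns$softmax_ce(ns$e1d_forward(X, cfg, W, B, "train")$logits, y)$loss
  fw <- ns$e1d_forward(X, cfg, W, B, "train")
  G <- ns$e1d_backward(ns$softmax_ce(fw$logits, y)$dlogits, cfg, W, fw$cache)
  flat_paths <- function(x, pre = character()) {
    if (!is.list(x)) return(list(pre))
    out <- list()
    for (nm in names(x)) if (!is.null(x[[nm]]))
      out <- c(out, flat_paths(x[[nm]], c(pre, nm)))
    out
  }
  eps <- 1e-5
  for (path in flat_paths(W)) {
    arr <- W[[path]]; grad <- G[[path]]
    for (i in sample(length(arr), min(2, length(arr)))) {
      Wp <- W; Wp[[path]][i] <- Wp[[path]][i] + eps
      Wm <- W; Wm[[path]][i] <- Wm[[path]][i] - eps
      num <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)
      expect_equal(grad[i], num, tolerance = 1e-4,
                   label = paste(c(path, i), collapse = "/"))
    }
  }
})

test_that("training separates the phantom classes and is reproducible", {
  tm <- trained_compact_model()
  h <- tm$fit$history
  expect_equal(tail(h$val_acc, 1), 1)
  expect_equal(tail(h$train_acc, 1), 1)

  # prototypes classify as themselves
  protos <- tm$dataset$spectra[!duplicated(tm$dataset$labels), ]
  pred <- predict(tm$fit, protos)
  expect_equal(pred$labels, tm$dataset$labels[!duplicated(tm$dataset$labels)])
  expect_equal(rowSums(pred$probs), rep(1, 3), tolerance = 1e-6)
  # batch-of-one equals the batched row
  one <- predict(tm$fit, protos[2, ])
  expect_equal(one$probs[1, ], pred$probs[2, ], tolerance = 1e-12)

  # determinism: a short re-run with fixed seeds is bit-identical
  ds <- tm$dataset
  cfg <- e1d_compact_config(ncol(ds$spectra), 3L)
  hy <- train_hyper(learning_rate = 5e-4, epochs = 3L, n_repeats = 2L)
  f1 <- train_model(ds, cfg, hy)
  f2 <- train_model(ds, cfg, hy)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  expect_equal(nrow(f1$history), 2 * 3)  # n_repeats x epochs rows
  expect_true(f1$selected_repeat %in% 1:2)

  unsplit <- spectral_dataset(ds$spectra, ds$labels, ds$wavelengths)
  expect_error(train_model(unsplit, cfg), "split")
  single <- spectral_dataset(ds$spectra, rep("A", nrow(ds$spectra)),
                             ds$wavelengths, split = ds$split)
  expect_error(train_model(single, cfg), "2 classes")
})

test_that("repeat bookkeeping follows the protocol", {
  # tiny problem: verify the requested number of repeats and epoch counts
  grid <- make_wavelength_grid(380, 1010, 24)
  ds <- simulate_dataset(noise_free_model(), grid, n_per_class = 6, seed = 2)
  ds <- split_dataset(ds)
  cfg <- e1d_config(24L, 3L,
                    stem = list(out_channels = 4L, kernel = 3L, stride = 2L,
                                padding = 1L),
                    blocks = list(mbconv_spec(4L, 6L, expansion = 2L)))
  hy <- train_hyper(epochs = 4L, n_repeats = 5L)
  fit <- train_model(ds, cfg, hy)
  expect_equal(unname(table(fit$history$repeat_id)), rep(4L, 5),
               ignore_attr = TRUE)
  expect_equal(nrow(fit$history), 20)
  finals <- sapply(1:5, function(r)
    tail(fit$history$val_acc[fit$history$repeat_id == r], 1))
  expect_equal(fit$selected_repeat, which.max(finals))
})
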
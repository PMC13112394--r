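#' Fit a PLS-DA classifier
#'
#' Partial least squares discriminant analysis: class labels are coded as
#' one-hot indicator columns and latent components maximizing the X/Y
#' covariance of the centered data are extracted sequentially (NIPALS).
#' Prediction is the argmax of the predicted class indicators. Centering
#' makes predictions invariant to adding a constant to all X columns.
#'
#' @param spectra n x p matrix
#' @param labels length-n class labels (>= 2 classes)
#' @param n_components number of latent variables (reduced with a warning if
#'   it exceeds the data rank)
#' @return an object of class `plsda_model`
#' @export
plsda_fit <- function(spectra, labels, n_components = 10L) {
  X <- as.matrix(spectra)
  labels <- as.character(labels)
  classes <- encode_classes(labels)
  if (length(classes) < 2) stop("plsda_fit: need at least 2 classes")
  if (n_components < 1) stop("plsda_fit: n_components must be >= 1")
  Y <- outer(labels, classes, "==") * 1
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  max_rank <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_rank) {
    warning(sprintf("plsda_fit: n_components reduced from %d to rank %d",
                    n_components, max_rank))
    n_components <- max_rank
  }
  p <- ncol(X); K <- length(classes)
  Wmat <- matrix(0, p, n_components)   # X weights
  Pmat <- matrix(0, p, n_components)   # X loadings
  Qmat <- matrix(0, K, n_components)   # Y loadings
  Tmat <- matrix(0, nrow(X), n_components)
  ncomp_used <- 0L
  for (a in seq_len(n_components)) {
    S <- crossprod(Xc, Yc)              # p x K covariance
    if (sqrt(sum(S^2)) < 1e-12) break   # nothing left to explain
    # dominant covariance direction via SVD of S
    sv <- svd(S, nu = 1, nv = 0)
    w <- sv$u[, 1]
    t_scr <- Xc %*% w
    tt <- sum(t_scr^2)
    if (tt < 1e-12) break
    p_load <- crossprod(Xc, t_scr) / tt
    q_load <- crossprod(Yc, t_scr) / tt
    Xc <- Xc - t_scr %*% t(p_load)
    Yc <- Yc - t_scr %*% t(q_load)
    Wmat[, a] <- w; Pmat[, a] <- p_load; Qmat[, a] <- q_load
    Tmat[, a] <- t_scr
    ncomp_used <- a
  }
  if (ncomp_used == 0L) stop("plsda_fit: no usable covariance structure")
  Wmat <- Wmat[, seq_len(ncomp_used), drop = FALSE]
  Pmat <- Pmat[, seq_len(ncomp_used), drop = FALSE]
  Qmat <- Qmat[, seq_len(ncomp_used), drop = FALSE]
  # regression coefficients B = W (P'W)^-1 Q'
  Bcoef <- Wmat %*% solve(crossprod(Pmat, Wmat), t(Qmat))
  structure(
    list(classes = classes, x_mean = x_mean, y_mean = y_mean,
         coef = Bcoef, weights = Wmat, loadings = Pmat, y_loadings = Qmat,
         scores = Tmat, n_components = ncomp_used),
    class = "plsda_model")
}

#' Predict with a PLS-DA model
#'
#' @param object a [plsda_fit] result
#' @param spectra n x p matrix (or length-p vector)
#' @param ... unused
#' @return list with `labels`, `scores` (predicted class indicators)
#' @export
predict.plsda_model <- function(object, spectra, ...) {
  X <- if (is.null(dim(spectra))) matrix(spectra, 1) else as.matrix(spectra)
  if (ncol(X) != length(object$x_mean)) stop("predict.plsda_model: wrong band count")
  scores <- sweep(X, 2, object$x_mean) %*% object$coef
  scores <- sweep(scores, 2, object$y_mean, "+")
  colnames(scores) <- object$classes
  list(labels = object$classes[max.col(scores, ties.method = "first")],
       scores = scores)
}

# ---- compact reference baselines -------------------------------------------

#' Reference 1D-CNN baseline configuration
#'
#' A conventional plain 1D CNN (conv/BN/SiLU x3 with stride-2 downsampling,
#' GAP, wide dense softmax head) behind the same [e1d_config] machinery but
#' without MBConv structure. The default width is deliberately generous:
#' plain CNNs of this era carry roughly twice the parameters of the MBConv
#' network at similar depth.
#'
#' @param input_length spectrum length
#' @param n_classes classes
#' @param width base channel width
#' @return a list of class `cnn1d_config`
#' @export
cnn1d_reference_config <- function(input_length = 440L, n_classes = 3L,
                                   width = 96L) {
  structure(list(input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes),
                 channels = as.integer(c(width, 2L * width, 4L * width)),
                 kernel = 7L, hidden = 256L),
            class = "cnn1d_config")
}

cnn1d_count_parameters <- function(config) {
  ch <- c(1L, config$channels)
  tot <- 0L
  for (i in seq_along(config$channels))
    tot <- tot + ch[i] * config$kernel * ch[i + 1L] + 2L * ch[i + 1L]
  tot <- tot + ch[length(ch)] * config$hidden + config$hidden +
    config$hidden * config$n_classes + config$n_classes
  as.integer(tot)
}

cnn1d_init <- function(config, rng) {
  ch <- c(1L, config$channels)
  k <- config$kernel
  weights <- list()
  buffers <- list()
  for (i in seq_along(config$channels)) {
    nm <- sprintf("conv%d", i)
    weights[[nm]] <- list(
      W = matrix(rng$norm(ch[i + 1L] * ch[i] * k, sd = sqrt(2 / (ch[i] * k))),
                 ch[i + 1L], ch[i] * k),
      bn = list(gamma = rep(1, ch[i + 1L]), beta = rep(0, ch[i + 1L])))
    buffers[[nm]] <- list(bn = list(mean = rep(0, ch[i + 1L]),
                                    var = rep(1, ch[i + 1L])))
  }
  Cl <- ch[length(ch)]
  weights$fc1 <- list(W = matrix(rng$norm(config$hidden * Cl, sd = sqrt(2 / Cl)),
                                 config$hidden, Cl),
                      b = rep(0, config$hidden))
  weights$head <- list(W = matrix(rng$norm(config$n_classes * config$hidden,
                                           sd = sqrt(2 / config$hidden)),
                                  config$n_classes, config$hidden),
                       b = rep(0, config$n_classes))
  list(weights = weights, buffers = buffers)
}

cnn1d_forward <- function(X, config, weights, buffers, mode) {
  cache <- list()
  Y <- X
  new_buf <- buffers
  k <- config$kernel
  for (i in seq_along(config$channels)) {
    nm <- sprintf("conv%d", i)
    r <- conv1d_forward(Y, weights[[nm]]$W, k, 2L, (k - 1L) %/% 2L)
    cache[[paste0(nm, "_conv")]] <- r$cache
    b <- bn_forward(r$Y, weights[[nm]]$bn$gamma, weights[[nm]]$bn$beta,
                    buffers[[nm]]$bn$mean, buffers[[nm]]$bn$var, mode)
    cache[[paste0(nm, "_bn")]] <- b$cache
    if (mode == "train") new_buf[[nm]]$bn <- list(mean = b$run_mean, var = b$run_var)
    a <- silu_forward(b$Y)
    cache[[paste0(nm, "_act")]] <- a$cache
    Y <- a$Y
  }
  g <- gap_forward(Y); cache$gap <- g$cache
  f1 <- dense_forward(g$Y, weights$fc1$W, weights$fc1$b); cache$fc1 <- f1$cache
  a1 <- silu_forward(f1$Y); cache$fc1_act <- a1$cache
  hd <- dense_forward(a1$Y, weights$head$W, weights$head$b); cache$head <- hd$cache
  list(logits = hd$Y, cache = cache, buffers = new_buf)
}

cnn1d_backward <- function(dlogits, config, weights, cache) {
  grads <- list()
  r <- dense_backward(dlogits, weights$head$W, weights$head$b, cache$head)
  grads$head <- list(W = r$dW, b = r$db)
  dh <- silu_backward(r$dg, cache$fc1_act)
  r <- dense_backward(dh, weights$fc1$W, weights$fc1$b, cache$fc1)
  grads$fc1 <- list(W = r$dW, b = r$db)
  dY <- gap_backward(r$dg, cache$gap)
  for (i in rev(seq_along(config$channels))) {
    nm <- sprintf("conv%d", i)
    dY <- silu_backward(dY, cache[[paste0(nm, "_act")]])
    b <- bn_backward(dY, weights[[nm]]$bn$gamma, cache[[paste0(nm, "_bn")]])
    r <- conv1d_backward(b$dX, weights[[nm]]$W, cache[[paste0(nm, "_conv")]])
    grads[[nm]] <- list(W = r$dW, bn = list(gamma = b$dgamma, beta = b$dbeta))
    dY <- r$dX
  }
  out <- list()
  for (i in seq_along(config$channels)) {
    nm <- sprintf("conv%d", i)
    out[[nm]] <- grads[[nm]]
  }
  out$fc1 <- grads$fc1
  out$head <- grads$head
  out
}

#' Reference LSTM baseline configuration
#'
#' A compact recurrent baseline: the spectrum is reshaped into
#' `timesteps` windows of `input_length / timesteps` contiguous bands,
#' passed through a single LSTM layer, and the mean hidden state feeds a
#' dense softmax head. Truncating the sequence to ~20 steps keeps
#' backpropagation-through-time shallow while preserving the coarse
#' spectral ordering.
#'
#' @param input_length spectrum length; padded up to a multiple of
#'   `timesteps` with zeros if needed
#' @param n_classes classes
#' @param hidden hidden state size
#' @param timesteps sequence length after reshaping
#' @return a list of class `lstm_config`
#' @export
lstm_reference_config <- function(input_length = 440L, n_classes = 3L,
                                  hidden = 64L, timesteps = 20L) {
  feat <- as.integer(ceiling(input_length / timesteps))
  structure(list(input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden),
                 timesteps = as.integer(timesteps), features = feat),
            class = "lstm_config")
}

lstm_count_parameters <- function(config) {
  H <- config$hidden; Fe <- config$features
  as.integer(4L * H * (Fe + H) + 4L * H +
               H * config$n_classes + config$n_classes)
}

lstm_init <- function(config, rng) {
  H <- config$hidden; Fe <- config$features
  sd_x <- sqrt(1 / Fe); sd_h <- sqrt(1 / H)
  weights <- list(
    Wx = matrix(rng$norm(4L * H * Fe, sd = sd_x), 4L * H, Fe),
    Wh = matrix(rng$norm(4L * H * H, sd = sd_h), 4L * H, H),
    b = rep(0, 4L * H),
    head = list(W = matrix(rng$norm(config$n_classes * H, sd = sd_h),
                           config$n_classes, H),
                b = rep(0, config$n_classes)))
  # forget-gate bias 1 for stable early training
  weights$b[(H + 1L):(2L * H)] <- 1
  weights
}

# X: (features, timesteps, batch) ; gates order: input, forget, cell, output
lstm_forward <- function(X, config, weights) {
  H <- config$hidden
  d <- dim(X); Tt <- d[2]; B <- d[3]
  h <- matrix(0, H, B); c_st <- matrix(0, H, B)
  cache <- vector("list", Tt)
  hsum <- matrix(0, H, B)
  for (t in seq_len(Tt)) {
    xt <- matrix(X[, t, ], d[1], B)
    z <- weights$Wx %*% xt + weights$Wh %*% h + weights$b
    i_g <- stats::plogis(z[1:H, , drop = FALSE])
    f_g <- stats::plogis(z[(H + 1):(2 * H), , drop = FALSE])
    g_g <- tanh(z[(2 * H + 1):(3 * H), , drop = FALSE])
    o_g <- stats::plogis(z[(3 * H + 1):(4 * H), , drop = FALSE])
    c_new <- f_g * c_st + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    cache[[t]] <- list(xt = xt, h_prev = h, c_prev = c_st, i = i_g, f = f_g,
                       g = g_g, o = o_g, c = c_new, tc = tc)
    h <- h_new; c_st <- c_new
    hsum <- hsum + h
  }
  hbar <- hsum / Tt
  logits <- weights$head$W %*% hbar + weights$head$b
  list(logits = logits, cache = cache, hbar = hbar, Tt = Tt, B = B)
}

lstm_backward <- function(dlogits, config, weights, fw) {
  H <- config$hidden; Tt <- fw$Tt; B <- fw$B
  dW_head <- dlogits %*% t(fw$hbar)
  db_head <- rowSums(dlogits)
  dhbar <- t(weights$head$W) %*% dlogits
  dh_mean <- dhbar / Tt                      # flows into every timestep's h
  dWx <- matrix(0, 4L * H, nrow(fw$cache[[1]]$xt))
  dWh <- matrix(0, 4L * H, H)
  db <- rep(0, 4L * H)
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  for (t in rev(seq_len(Tt))) {
    cc <- fw$cache[[t]]
    dh <- dh_next + dh_mean
    do_g <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; df <- dc * cc$c_prev; dg <- dc * cc$i
    dz <- rbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_g * cc$o * (1 - cc$o))
    dWx <- dWx + dz %*% t(cc$xt)
    dWh <- dWh + dz %*% t(cc$h_prev)
    db <- db + rowSums(dz)
    dh_next <- t(weights$Wh) %*% dz
    dc_next <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db, head = list(W = dW_head, b = db_head))
}

# ---- common baseline interface ----------------------------------------------

#' Train a comparison classifier
#'
#' Trains one of the reference baselines behind a single interface:
#' `"svm"` (radial-kernel support vector machine, delegated to
#' \pkg{e1071}), `"plsda"` ([plsda_fit]), `"cnn1d"` and `"lstm"` (compact
#' gradient-trained reference networks sharing the Adam/cross-entropy
#' protocol), or `"efficient1dnet"` ([train_model]). All baselines consume a
#' split [spectral_dataset] and return predictions through [predict_baseline].
#'
#' @param kind one of `"svm"`, `"plsda"`, `"cnn1d"`, `"lstm"`,
#'   `"efficient1dnet"`
#' @param dataset a [spectral_dataset] with a split
#' @param hyper a [train_hyper] (used by the gradient-trained kinds; the
#'   networks use `learning_rate` as given, so pass a larger rate than the
#'   MBConv default if desired)
#' @param config optional model configuration override
#' @param n_components PLS-DA latent variables
#' @param svm_cost,svm_gamma RBF-SVM hyperparameters (`NULL` gamma = 1/p)
#' @return an object of class `baseline_model`
#' @export
baseline_train <- function(kind, dataset, hyper = train_hyper(),
                           config = NULL, n_components = 10L,
                           svm_cost = 1, svm_gamma = NULL) {
  kind <- match.arg(kind, c("svm", "plsda", "cnn1d", "lstm", "efficient1dnet"))
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (is.null(dataset$split))
    stop("baseline_train: dataset needs a calibration/validation split")
  Xcal <- dataset$spectra[dataset$split$cal, , drop = FALSE]
  ycal <- dataset$labels[dataset$split$cal]
  classes <- encode_classes(dataset$labels)
  fit <- switch(kind,
    svm = {
      if (is.null(svm_gamma)) svm_gamma <- 1 / ncol(Xcal)
      e1071::svm(Xcal, factor(ycal, levels = classes), kernel = "radial",
                 cost = svm_cost, gamma = svm_gamma, probability = FALSE)
    },
    plsda = plsda_fit(Xcal, ycal, n_components),
    cnn1d = train_seq_net("cnn1d", dataset, classes, hyper, config),
    lstm = train_seq_net("lstm", dataset, classes, hyper, config),
    efficient1dnet = train_model(dataset, config, hyper))
  structure(list(kind = kind, fit = fit, classes = classes,
                 n_parameters = switch(kind,
                   cnn1d = cnn1d_count_parameters(fit$config),
                   lstm = lstm_count_parameters(fit$config),
                   efficient1dnet = count_parameters(fit$config),
                   NA_integer_)),
            class = "baseline_model")
}

# shared Adam/cross-entropy training loop for the cnn1d and lstm baselines
train_seq_net <- function(kind, dataset, classes, hyper, config) {
  Xcal <- dataset$spectra[dataset$split$cal, , drop = FALSE]
  Xval <- dataset$spectra[dataset$split$val, , drop = FALSE]
  ycal <- match(dataset$labels[dataset$split$cal], classes)
  yval <- match(dataset$labels[dataset$split$val], classes)
  scaler <- fit_autoscaler(Xcal)
  Xcal <- apply_autoscaler(scaler, Xcal)
  Xval <- apply_autoscaler(scaler, Xval)
  L <- ncol(Xcal)
  if (is.null(config))
    config <- if (kind == "cnn1d") cnn1d_reference_config(L, length(classes))
              else lstm_reference_config(L, length(classes))
  shape_batch <- function(X, idx) {
    if (kind == "cnn1d") {
      array(t(X[idx, , drop = FALSE]), c(1L, L, length(idx)))
    } else {
      n_pad <- config$features * config$timesteps
      M <- cbind(X[idx, , drop = FALSE],
                 matrix(0, length(idx), n_pad - L))
      array(t(M), c(config$features, config$timesteps, length(idx)))
    }
  }
  fwd <- function(Xb, weights, buffers, mode) {
    if (kind == "cnn1d") cnn1d_forward(Xb, config, weights, buffers, mode)
    else c(lstm_forward(Xb, config, weights), list(buffers = buffers))
  }
  history <- list(); runs <- list()
  for (r in seq_len(hyper$n_repeats)) {
    rng <- local_rng(hyper$seeds[r])
    if (kind == "cnn1d") {
      st <- cnn1d_init(config, rng); weights <- st$weights; buffers <- st$buffers
    } else {
      weights <- lstm_init(config, rng); buffers <- NULL
    }
    adam <- adam_init(weights)
    for (ep in seq_len(hyper$epochs)) {
      perm <- rng$sample(nrow(Xcal))
      for (s0 in seq(1L, length(perm), by = hyper$batch_size)) {
        idx <- perm[s0:min(s0 + hyper$batch_size - 1L, length(perm))]
        Xb <- shape_batch(Xcal, idx)
        fw <- fwd(Xb, weights, buffers, "train")
        if (kind == "cnn1d") buffers <- fw$buffers
        ce <- softmax_ce(fw$logits, ycal[idx])
        grads <- if (kind == "cnn1d")
          cnn1d_backward(ce$dlogits, config, weights, fw$cache)
        else lstm_backward(ce$dlogits, config, weights, fw)
        upd <- adam_step(weights, grads, adam, lr = hyper$learning_rate)
        weights <- upd$weights; adam <- upd$state
      }
      acc_of <- function(X, y) {
        ok <- 0L
        for (s0 in seq(1L, nrow(X), by = 256L)) {
          idx <- s0:min(s0 + 255L, nrow(X))
          pr <- fwd(shape_batch(X, idx), weights, buffers, "eval")
          ok <- ok + sum(apply(pr$logits, 2, which.max) == y[idx])
        }
        ok / nrow(X)
      }
      history[[length(history) + 1L]] <- data.frame(
        repeat_id = r, epoch = ep,
        train_acc = acc_of(Xcal, ycal), val_acc = acc_of(Xval, yval))
    }
    runs[[r]] <- list(weights = weights, buffers = buffers)
  }
  history <- do.call(rbind, history)
  crit <- vapply(seq_len(hyper$n_repeats), function(r) {
    h <- history[history$repeat_id == r, ]
    h$val_acc[nrow(h)]
  }, numeric(1))
  selected <- which.max(crit)
  list(kind = kind, config = config, weights = runs[[selected]]$weights,
       buffers = runs[[selected]]$buffers, history = history,
       selected_repeat = selected, classes = classes, scaler = scaler,
       shape_batch = shape_batch, fwd = fwd)
}

#' Predict with any baseline
#'
#' @param model a [baseline_train] result
#' @param spectra n x p matrix
#' @return list with `labels` (character vector)
#' @export
predict_baseline <- function(model, spectra) {
  stopifnot(inherits(model, "baseline_model"))
  X <- if (is.null(dim(spectra))) matrix(spectra, 1) else as.matrix(spectra)
  labels <- switch(model$kind,
    svm = as.character(stats::predict(model$fit, X)),
    plsda = predict(model$fit, X)$labels,
    efficient1dnet = predict(model$fit, X)$labels,
    {
      fit <- model$fit
      X <- apply_autoscaler(fit$scaler, X)
      out <- character(nrow(X))
      for (s0 in seq(1L, nrow(X), by = 256L)) {
        idx <- s0:min(s0 + 255L, nrow(X))
        pr <- fit$fwd(fit$shape_batch(X, idx), fit$weights, fit$buffers, "eval")
        out[idx] <- fit$classes[apply(pr$logits, 2, which.max)]
      }
      out
    })
  list(labels = labels)
}
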
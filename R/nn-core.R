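# Minimal 1D neural-network engine: forward/backward passes for the layer
# types the spectral classifiers need (pointwise/depthwise/general 1D
# convolution, batch normalization, SiLU/ReLU/sigmoid, squeeze-excitation,
# global average pooling, dense softmax head) plus an Adam optimizer.
# Tensors are numeric arrays with dim (channels, length, batch).

as_clb <- function(x) {
  # accept (C, L) matrices and promote to batch of one
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# ---- general conv1d (im2col) ------------------------------------------------

conv1d_forward <- function(X, W, k, s, p) {
  d <- dim(X); Cin <- d[1]; L <- d[2]; B <- d[3]
  Lp <- L + 2L * p
  Xpad <- array(0, c(Cin, Lp, B))
  Xpad[, (p + 1L):(p + L), ] <- X
  Lout <- (Lp - k) %/% s + 1L
  Xcol <- array(0, c(Cin * k, Lout, B))
  base <- (seq_len(Lout) - 1L) * s
  for (j in seq_len(k))
    Xcol[((j - 1L) * Cin + 1L):(j * Cin), , ] <- Xpad[, base + j, , drop = FALSE]
  Y <- W %*% matrix(Xcol, Cin * k, Lout * B)
  list(Y = array(Y, c(nrow(W), Lout, B)),
       cache = list(Xcol = Xcol, dims = d, k = k, s = s, p = p, Lout = Lout))
}

conv1d_backward <- function(dY, W, cache) {
  d <- cache$dims; Cin <- d[1]; L <- d[2]; B <- d[3]
  k <- cache$k; s <- cache$s; p <- cache$p; Lout <- cache$Lout
  dY_mat <- matrix(dY, nrow(W), Lout * B)
  dW <- dY_mat %*% t(matrix(cache$Xcol, Cin * k, Lout * B))
  dXcol <- array(t(W) %*% dY_mat, c(Cin * k, Lout, B))
  dXpad <- array(0, c(Cin, L + 2L * p, B))
  base <- (seq_len(Lout) - 1L) * s
  for (j in seq_len(k)) {
    idx <- base + j
    dXpad[, idx, ] <- dXpad[, idx, , drop = FALSE] +
      dXcol[((j - 1L) * Cin + 1L):(j * Cin), , , drop = FALSE]
  }
  list(dX = dXpad[, (p + 1L):(p + L), , drop = FALSE], dW = dW)
}

# ---- pointwise conv (kernel 1, stride 1) ------------------------------------

pw_forward <- function(X, W) {
  d <- dim(X)
  Y <- W %*% matrix(X, d[1], d[2] * d[3])
  list(Y = array(Y, c(nrow(W), d[2], d[3])), cache = list(X = X))
}

pw_backward <- function(dY, W, cache) {
  d <- dim(cache$X); dd <- dim(dY)
  dY_mat <- matrix(dY, dd[1], dd[2] * dd[3])
  X_mat <- matrix(cache$X, d[1], d[2] * d[3])
  list(dX = array(t(W) %*% dY_mat, d), dW = dY_mat %*% t(X_mat))
}

# ---- depthwise conv ---------------------------------------------------------

dw_forward <- function(X, W, s, p) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  k <- ncol(W)
  Lp <- L + 2L * p
  Xpad <- array(0, c(C, Lp, B))
  Xpad[, (p + 1L):(p + L), ] <- X
  Lout <- (Lp - k) %/% s + 1L
  Y <- array(0, c(C, Lout, B))
  base <- (seq_len(Lout) - 1L) * s
  for (j in seq_len(k))
    Y <- Y + as.vector(W[, j]) * Xpad[, base + j, , drop = FALSE]
  list(Y = Y, cache = list(Xpad = Xpad, dims = d, k = k, s = s, p = p,
                           Lout = Lout))
}

dw_backward <- function(dY, W, cache) {
  d <- cache$dims; C <- d[1]; L <- d[2]; B <- d[3]
  k <- cache$k; s <- cache$s; p <- cache$p; Lout <- cache$Lout
  base <- (seq_len(Lout) - 1L) * s
  dW <- matrix(0, C, k)
  dXpad <- array(0, c(C, L + 2L * p, B))
  for (j in seq_len(k)) {
    idx <- base + j
    dW[, j] <- rowSums(matrix(dY * cache$Xpad[, idx, , drop = FALSE], C,
                              Lout * B))
    dXpad[, idx, ] <- dXpad[, idx, , drop = FALSE] + as.vector(W[, j]) * dY
  }
  list(dX = dXpad[, (p + 1L):(p + L), , drop = FALSE], dW = dW)
}

# ---- batch normalization ----------------------------------------------------

bn_forward <- function(X, gamma, beta, run_mean, run_var, mode,
                       eps = 1e-5, momentum = 0.1) {
  d <- dim(X); C <- d[1]; N <- d[2] * d[3]
  Xm <- matrix(X, C, N)
  if (mode == "train") {
    mu <- rowMeans(Xm)
    vr <- rowMeans((Xm - mu)^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * vr
  } else {
    mu <- run_mean; vr <- run_var
  }
  invstd <- 1 / sqrt(vr + eps)
  xhat <- (Xm - mu) * invstd
  Y <- array(gamma * xhat + beta, d)
  list(Y = Y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, invstd = invstd, dims = d, mode = mode))
}

bn_backward <- function(dY, gamma, cache) {
  d <- cache$dims; C <- d[1]; N <- d[2] * d[3]
  dYm <- matrix(dY, C, N)
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  if (cache$mode == "train") {
    dX <- (gamma * cache$invstd) *
      (dYm - dbeta / N - cache$xhat * (dgamma / N))
  } else {
    dX <- (gamma * cache$invstd) * dYm
  }
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ------------------------------------------------------------

#' SiLU activation
#'
#' The sigmoid-weighted linear unit \eqn{SiLU(z) = z \sigma(z)}, the
#' activation used throughout the MBConv stack.
#'
#' @param z numeric vector/array
#' @return same shape as `z`
#' @export
silu <- function(z) z * stats::plogis(z)

silu_forward <- function(X) {
  s <- stats::plogis(X)
  list(Y = X * s, cache = list(X = X, s = s))
}

silu_backward <- function(dY, cache) {
  dY * (cache$s * (1 + cache$X * (1 - cache$s)))
}

# ---- squeeze-and-excitation -------------------------------------------------

#' Squeeze-and-excitation channel attention
#'
#' Computes the attention vector
#' \eqn{a = \sigma(W_2\, \mathrm{ReLU}(W_1\, \mathrm{GAP}(H_2) + b_1) + b_2)}
#' from globally pooled channel statistics; every component lies strictly in
#' (0, 1). The caller multiplies the feature map channel-wise by `a`.
#'
#' @param H2 feature map: (C, L) matrix or (C, L, B) array
#' @param W1 squeeze weights, `m x C`
#' @param W2 excitation weights, `C x m`
#' @param b1,b2 biases (default zero)
#' @return attention matrix `C x B`
#' @export
se_attention <- function(H2, W1, W2, b1 = 0, b2 = 0) {
  X <- as_clb(H2)
  C <- dim(X)[1]
  if (ncol(W1) != C || nrow(W2) != C)
    stop("se_attention: weight shapes do not match channel count")
  if (ncol(W2) != nrow(W1))
    stop("se_attention: W1/W2 bottleneck widths disagree")
  se_forward(X, W1, b1, W2, b2)$a
}

se_forward <- function(X, W1, b1, W2, b2) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  g <- matrix(colMeans(matrix(aperm(X, c(2, 1, 3)), L, C * B)), C, B)
  z1 <- W1 %*% g + b1
  h <- pmax(z1, 0)
  z2 <- W2 %*% h + b2
  a <- stats::plogis(z2)
  aexp <- array(a[, rep(seq_len(B), each = L), drop = FALSE], c(C, L, B))
  list(Y = X * aexp, a = a,
       cache = list(X = X, g = g, z1 = z1, h = h, a = a, aexp = aexp))
}

se_backward <- function(dY, W1, W2, cache) {
  d <- dim(cache$X); C <- d[1]; L <- d[2]; B <- d[3]
  a <- cache$a
  dX_direct <- dY * cache$aexp
  da <- matrix(colSums(matrix(aperm(dY * cache$X, c(2, 1, 3)), L, C * B)),
               C, B)
  dz2 <- da * a * (1 - a)
  dW2 <- dz2 %*% t(cache$h)
  db2 <- rowSums(dz2)
  dh <- t(W2) %*% dz2
  dz1 <- dh * (cache$z1 > 0)
  dW1 <- dz1 %*% t(cache$g)
  db1 <- rowSums(dz1)
  dg <- t(W1) %*% dz1
  dgexp <- array(dg[, rep(seq_len(B), each = L), drop = FALSE] / L, c(C, L, B))
  list(dX = dX_direct + dgexp, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- pooling and head -------------------------------------------------------

gap_forward <- function(X) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  g <- matrix(colMeans(matrix(aperm(X, c(2, 1, 3)), L, C * B)), C, B)
  list(Y = g, cache = list(dims = d))
}

gap_backward <- function(dg, cache) {
  d <- cache$dims; C <- d[1]; L <- d[2]; B <- d[3]
  array(dg[, rep(seq_len(B), each = L), drop = FALSE] / L, d)
}

dense_forward <- function(g, W, b) {
  Y <- W %*% g
  if (!is.null(b)) Y <- Y + b
  list(Y = Y, cache = list(g = g))
}

dense_backward <- function(dY, W, b, cache) {
  list(dg = t(W) %*% dY, dW = dY %*% t(cache$g),
       db = if (is.null(b)) NULL else rowSums(dY))
}

softmax_rows_to_probs <- function(logits) {
  # logits: K x B; column-wise softmax, numerically stable
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

softmax_ce <- function(logits, y_int) {
  # y_int in 1..K, length B; returns mean loss and dlogits
  B <- ncol(logits)
  probs <- softmax_rows_to_probs(logits)
  picked <- probs[cbind(y_int, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- probs
  dlogits[cbind(y_int, seq_len(B))] <-
    dlogits[cbind(y_int, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B, probs = probs)
}

# ---- Adam over nested weight lists ------------------------------------------

adam_init <- function(weights) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else if (is.null(x)) NULL
    else if (is.null(dim(x))) numeric(length(x))
    else array(0, dim = dim(x))
  }
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr = 5e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(w, g, m, v) {
    if (is.list(w)) {
      out_w <- w; out_m <- m; out_v <- v
      for (nm in names(w)) {
        r <- upd(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_w[[nm]] <- r$w; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(w = out_w, m = out_m, v = out_v))
    }
    if (is.null(w) || is.null(g)) return(list(w = w, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(weights, grads, state$m, state$v)
  list(weights = r$w, state = list(m = r$m, v = r$v, t = tt))
}
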
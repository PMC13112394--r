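# Independent oracles used by both the module tests and the acceptance
# suite. Each one is a deliberately naive re-derivation (explicit loops,
# closed forms) kept free of the package's own code paths.

# exhaustive between-class-variance search over the same 256-bin histogram
otsu_bruteforce <- function(v, n_bins = 256L) {
  lo <- min(v); hi <- max(v)
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  best_t <- NA; best_s <- -Inf
  for (t in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * centers[1:t]) / n0
    mu1 <- sum(counts[(t + 1):n_bins] * centers[(t + 1):n_bins]) / n1
    s <- n0 * n1 * (mu0 - mu1)^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  lo + best_t / n_bins * (hi - lo)
}

# brute-force greedy max-min Kennard-Stone with explicit loops
ks_bruteforce <- function(x, n_cal) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  best <- c(NA, NA); bestd <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    pick <- NA; pickd <- -1
    for (i in cand) {
      mind <- min(d[i, sel])
      if (mind > pickd) { pickd <- mind; pick <- i }
    }
    sel <- c(sel, pick)
  }
  sort(sel)
}

# straight-line scalar-loop evaluation of one MBConv block (no BN)
mbconv_by_hand <- function(U, spec, w) {
  C <- nrow(U); L <- ncol(U); Ch <- spec$expanded
  silu_s <- function(z) z / (1 + exp(-z))
  H1 <- matrix(0, Ch, L)
  for (i in 1:Ch) for (l in 1:L) {
    acc <- 0
    for (c in 1:C) acc <- acc + w$pw1_W[i, c] * U[c, l]
    H1[i, l] <- silu_s(acc)
  }
  k <- spec$kernel; s <- spec$stride; p <- spec$padding
  Lout <- (L + 2 * p - k) %/% s + 1
  H2 <- matrix(0, Ch, Lout)
  for (i in 1:Ch) for (t in 1:Lout) {
    acc <- 0
    for (j in 1:k) {
      pos <- (t - 1) * s + j - p
      if (pos >= 1 && pos <= L) acc <- acc + w$dw_W[i, j] * H1[i, pos]
    }
    H2[i, t] <- silu_s(acc)
  }
  g <- rowMeans(H2)
  z1 <- as.numeric(w$se_W1 %*% g + w$se_b1)
  h <- pmax(z1, 0)
  a <- 1 / (1 + exp(-(as.numeric(w$se_W2 %*% h + w$se_b2))))
  V <- matrix(0, spec$out_channels, Lout)
  for (o in 1:spec$out_channels) for (t in 1:Lout) {
    acc <- 0
    for (i in 1:Ch) acc <- acc + w$pw2_W[o, i] * H2[i, t] * a[i]
    V[o, t] <- acc
  }
  if (spec$residual) U + V else V
}

# hand-set small-integer MBConv toy shared by the oracle checks
mbconv_toy <- function() {
  list(
    spec = mbconv_spec(2L, 2L, expansion = 2L, kernel = 3L, stride = 1L),
    U = matrix(c(1, -1, 2, 0, 1, 1, -2, 3, 0, 1, 2, -1), 2, 6),
    w = list(
      pw1_W = matrix(c(1, 0, -1, 2, 1, 1, 0, -1), 4, 2),
      dw_W = matrix(c(1, 0, -1, 2, 1, 0, 0, 1, 1, -1, 2, 1), 4, 3),
      se_W1 = matrix(c(1, 0, -1, 1), 1, 4), se_b1 = 0.5,
      se_W2 = matrix(c(1, -1, 2, 0), 4, 1), se_b2 = c(0, 0.5, -0.5, 1),
      pw2_W = matrix(c(1, -1, 0, 2, 1, 0, -1, 1), 2, 4)))
}
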
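# Independent straight-line oracles used across the suite.  These are
# deliberately naive (nested loops, direct formulas) and share no code with
# the implementation paths they check.

# dense 2D true convolution (kernel flipped), mirror (reflect) border
# padding, same size
reflect_ix <- function(i, n) {
  while (i < 1 || i > n) { if (i < 1) i <- 2 - i; if (i > n) i <- 2 * n - i }
  i
}
oracle_conv2d <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  ph <- kh %/% 2; pw <- kw %/% 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      ii <- reflect_ix(i - (a - 1 - ph), H)  # kernel index runs backwards
      jj <- reflect_ix(j - (b - 1 - pw), W)
      acc <- acc + x[ii, jj] * k[a, b]
    }
    out[i, j] <- acc
  }
  out
}

# agreement statistics computed by direct formula loops on a contingency table
oracle_agreement <- function(cm) {
  K <- nrow(cm); n <- sum(cm)
  po <- 0
  for (i in seq_len(K)) po <- po + cm[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(K)) pe <- pe + sum(cm[i, ]) * sum(cm[, i])
  pe <- pe / n^2
  num_b <- 0; den_b <- 0
  for (i in seq_len(K)) {
    num_b <- num_b + cm[i, i]^2
    den_b <- den_b + sum(cm[i, ]) * sum(cm[, i])
  }
  list(accuracy = po,
       hamming = 1 - po,
       kappa = (po - pe) / (1 - pe),
       bennett_s = (po - 1 / K) / (1 - 1 / K),
       bangdiwala_b = num_b / den_b,
       ari = oracle_ari_pairs(cm),
       df = (K - 1)^2)
}

# ARI by brute-force enumeration of all pixel pairs reconstructed from the table
oracle_ari_pairs <- function(cm) {
  K <- nrow(cm)
  truth <- integer(0); pred <- integer(0)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    truth <- c(truth, rep(i, cm[i, j]))
    pred <- c(pred, rep(j, cm[i, j]))
  }
  n <- length(truth)
  a <- b <- c_ <- d <- 0
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    st <- truth[p] == truth[q]
    sp <- pred[p] == pred[q]
    if (st && sp) a <- a + 1
    else if (!st && sp) b <- b + 1
    else if (st && !sp) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  exp_a <- (a + c_) * (a + b) / tot
  max_a <- ((a + c_) + (a + b)) / 2
  if (max_a == exp_a) 1 else (a - exp_a) / (max_a - exp_a)
}

# boundary band of one class by definition: class pixels touching another
# class (4-neighbourhood), dilated to Chebyshev radius r
oracle_band <- function(mask, cls, r) {
  H <- nrow(mask); W <- ncol(mask)
  core <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != cls) next
    for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + dd[1]; jj <- j + dd[2]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && mask[ii, jj] != cls)
        core[i, j] <- TRUE
    }
  }
  band <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    for (ii in max(1, i - r):min(H, i + r))
      for (jj in max(1, j - r):min(W, j + r))
        if (core[ii, jj]) band[i, j] <- TRUE
  }
  band
}

# small helpers ---------------------------------------------------------------

tiny_synth <- function(n = 4, h = 32, w = 16, seed = 7, ...) {
  cfg <- synth_config(height = h, width = w, seed = seed, ...)
  generate_dataset(cfg, n)$pairs
}

random_confusion <- function(K, max_count = 12) {
  matrix(sample.int(max_count + 1, K * K, replace = TRUE) - 1L, K, K)
}
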
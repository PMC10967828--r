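# Internal layer primitives.  All activations are (H, W, C, N) arrays.
# Each *_fwd returns list(out, cache, ...); each *_bwd consumes the cache and
# the upstream gradient and returns gradients for inputs and parameters.

# keep_ws retains the im2col workspace so the backward pass can reuse it
conv_fwd <- function(x, p, keep_ws = FALSE) {
  r <- cpp_conv2d_fwd(x, p$w, p$b, keep_ws)
  if (keep_ws) r else r$y
}
conv_bwd <- function(ws, p, dy) cpp_conv2d_bwd(ws, p$w, dy)

convT_fwd <- function(x, p) cpp_convT2d_fwd(x, p$w, p$b)
convT_bwd <- function(x, p, dy) cpp_convT2d_bwd(x, p$w, dy)

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, mask = m)
}
relu_bwd <- function(cache, dy) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# per-channel sums/means over (H, W, N) and channel broadcasting, written
# against flat vector views for speed
channel_sums <- function(x) {
  d <- dim(x)
  s <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(matrix(s, d[3], d[4]), d[3], d[4])
}
channel_means <- function(x) {
  d <- dim(x)
  channel_sums(x) / (d[1] * d[2] * d[4])
}
bc_channel <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

# batch normalisation over (H, W, N) per channel
bn_fwd <- function(x, p, state, train) {
  d <- dim(x)
  if (train) {
    mu <- channel_means(x)
    xc <- x - bc_channel(mu, d)
    v <- channel_means(xc * xc)
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- x - bc_channel(mu, d)
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * bc_channel(istd, d)
  out <- xhat * bc_channel(p$gamma, d) + bc_channel(p$beta, d)
  list(out = out, cache = list(xhat = xhat, istd = istd), state = state)
}

bn_bwd <- function(p, cache, dy) {
  d <- dim(dy)
  xhat <- cache$xhat
  dgamma <- channel_sums(dy * xhat)
  dbeta <- channel_sums(dy)
  dxhat <- dy * bc_channel(p$gamma, d)
  t1 <- dxhat - bc_channel(channel_means(dxhat), d)
  t2 <- xhat * bc_channel(channel_means(dxhat * xhat), d)
  dx <- (t1 - t2) * bc_channel(cache$istd, d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# conv -> BN -> ReLU unit
cbr_fwd <- function(x, p, state, train) {
  cv <- conv_fwd(x, p$conv, keep_ws = train)
  y1 <- if (train) cv$y else cv
  bn <- bn_fwd(y1, p$bn, state, train)
  r <- relu_fwd(bn$out)
  list(out = r$out,
       cache = if (train) list(ws = cv$ws, bn = bn$cache, relu = r),
       state = bn$state)
}

cbr_bwd <- function(p, cache, dy) {
  dy <- relu_bwd(cache$relu, dy)
  b <- bn_bwd(p$bn, cache$bn, dy)
  cv <- conv_bwd(cache$ws, p$conv, b$dx)
  list(dx = cv$dx,
       grads = list(conv = list(w = cv$dw, b = cv$db),
                    bn = list(gamma = b$dgamma, beta = b$dbeta)))
}

# nearest-neighbour 2x upsampling (used for the edge-attention gate)
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}
upsample2_bwd <- function(dy) {
  d <- dim(dy)
  H <- d[1] / 2L; W <- d[2] / 2L
  o <- dy[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    dy[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    dy[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
    dy[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
  array(o, c(H, W, d[3], d[4]))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , (c1 + 1):d[3], , drop = FALSE])
}

# channel-wise max and mean with argmax bookkeeping (spatial attention)
channel_pool <- function(x) {
  d <- dim(x); C <- d[3]
  mx <- x[, , 1, , drop = FALSE]
  am <- array(1L, dim(mx))
  if (C > 1) for (c in 2:C) {
    xc <- x[, , c, , drop = FALSE]
    upd <- xc > mx
    mx[upd] <- xc[upd]
    am[upd] <- c
  }
  av <- array(0, dim(mx))
  for (c in seq_len(C)) av <- av + x[, , c, , drop = FALSE]
  list(max = mx, avg = av / C, argmax = am)
}

# He-style initialisers -------------------------------------------------------

init_conv <- function(kh, kw, cin, cout) {
  w <- array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))
init_bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

softmax_channels <- function(logits) {
  d <- dim(logits)
  mx <- logits[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) mx <- pmax(mx, logits[, , c, , drop = FALSE])
  e <- exp(sweep_channel_sub(logits, mx))
  s <- e[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) s <- s + e[, , c, , drop = FALSE]
  sweep_channel_div(e, s)
}

# broadcast helpers: op(x[,,c,], m[,,1,]) over every channel c; operating on
# the flat vector keeps x's dim attribute without an extra array() copy
sweep_channel_sub <- function(x, m) x - m[rep_channel_index(dim(x))]
sweep_channel_div <- function(x, m) x / m[rep_channel_index(dim(x))]
sweep_channel_mul <- function(x, m) x * m[rep_channel_index(dim(x))]
rep_channel_index <- function(d) {
  # linear indices into an (H, W, 1, N) array replicated across C channels
  hw <- d[1] * d[2]
  base <- rep(seq_len(hw), times = d[3])            # per (c)
  off <- rep((seq_len(d[4]) - 1) * hw, each = hw * d[3])
  base + off
}

# sum over channels -> (H, W, 1, N)
sum_channels <- function(x) {
  d <- dim(x)
  s <- x[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) s <- s + x[, , c, , drop = FALSE]
  s
}
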
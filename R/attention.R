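#' Sobel gradient kernel pair used by the edge-attention block
#'
#' The transverse (horizontal-edge) and longitudinal (vertical-edge) 3x3
#' derivative operators used inside the Canny detector.  Both kernels sum to
#' zero, so a constant feature map produces a zero edge response.  The full
#' Canny pipeline (non-maximum suppression, hysteresis) is not used: the edge
#' response must stay differentiable, and it is a pure convolution-and-sum.
#'
#' By default the kernels are normalised to unit gain (divided by 4, as in
#' the scikit-image convention) so that the edge response lives on the same
#' scale as the features it is fused with; the raw integer Sobel pair is
#' available with `normalize = FALSE`.
#'
#' @param normalize divide the classic integer kernels by 4.
#' @return list with `transverse` and `longitudinal` 3x3 matrices.
#' @export
edge_kernels <- function(normalize = TRUE) {
  kt <- matrix(c(-1, -2, -1,
                  0,  0,  0,
                  1,  2,  1), 3, 3, byrow = TRUE)
  if (normalize) kt <- kt / 4
  list(transverse = kt, longitudinal = t(kt))
}

rot180 <- function(k) k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]

# effective correlation kernel implementing conv(x, Kt) + conv(x, Kl)
edge_corr_kernel <- function(kernels) rot180(kernels$transverse) +
  rot180(kernels$longitudinal)

#' Edge response of a feature map
#'
#' Per channel, the pointwise sum of the feature map convolved (true
#' convolution: the kernel is flipped) with the transverse and longitudinal
#' gradient operators, at the input's size with mirror (reflect) border
#' padding, so a constant map yields an exactly zero response everywhere.
#'
#' @param x numeric matrix, H x W x C array, or H x W x C x N array.
#' @param kernels kernel pair as returned by [edge_kernels()]; each kernel
#'   must sum to zero and be no larger than the feature map.
#' @return array of the same shape as `x`.
#' @export
canny_edge_response <- function(x, kernels = edge_kernels()) {
  x4 <- as_tensor4(x)
  if (any(!is.finite(x4))) stop("feature map contains non-finite values", call. = FALSE)
  d <- dim(x4)
  for (nm in c("transverse", "longitudinal")) {
    k <- kernels[[nm]]
    if (nrow(k) > d[1] || ncol(k) > d[2])
      stop(sprintf("kernel '%s' is larger than the feature map", nm), call. = FALSE)
    if (abs(sum(k)) > 1e-12)
      stop(sprintf("kernel '%s' does not sum to zero", nm), call. = FALSE)
  }
  restore_dim(cpp_depthwise_corr(x4, edge_corr_kernel(kernels)), dim(x))
}

# internal: edge response fwd/bwd on 4D tensors with a fixed kernel
edge_fwd <- function(x, keff) cpp_depthwise_corr(x, keff, TRUE)
edge_bwd <- function(dy, keff) cpp_depthwise_corr_adj(dy, keff)

#' Initialise edge-attention gate parameters
#'
#' The gate is the additive attention construction of the attention U-Net
#' lineage: 1x1 convolutions map the edge-enhanced skip and the (upsampled)
#' decoder gate into an intermediate space, their sum passes through ReLU and
#' a final 1x1 convolution, and a sigmoid yields per-pixel coefficients in
#' `[0, 1]`.
#'
#' The gate is initialised open (`gate_bias` on the final 1x1 convolution,
#' so the initial coefficients sit near `sigmoid(gate_bias)`): the block
#' starts close to an identity on the enhanced features and learns what to
#' suppress, rather than starting half-closed and having to learn what to
#' pass.
#'
#' @param c_skip,c_gate channel counts of skip and gate features.
#' @param c_int intermediate channels (default `max(c_skip %/% 2, 1)`).
#' @param gate_bias initial bias of the sigmoid gate (default 3, giving
#'   initial coefficients around 0.95).
#' @export
ea_params <- function(c_skip, c_gate, c_int = max(c_skip %/% 2L, 1L),
                      gate_bias = 3) {
  psi <- init_conv(1L, 1L, c_int, 1L)
  psi$b[] <- gate_bias
  list(ws = init_conv(1L, 1L, c_skip, c_int),
       wg = init_conv(1L, 1L, c_gate, c_int),
       psi = psi)
}

# forward pass with cache; gate at half resolution is upsampled internally
ea_fwd <- function(skip, gate, p, keff, train = FALSE) {
  ds <- dim(skip); dg <- dim(gate)
  upsampled <- FALSE
  if (dg[1] == ds[1] / 2 && dg[2] == ds[2] / 2) {
    gate_u <- upsample2_fwd(gate)
    upsampled <- TRUE
  } else if (all(dg[1:2] == ds[1:2])) {
    gate_u <- gate
  } else stop("gate is not spatially compatible with the skip", call. = FALSE)
  if (dim(p$ws$w)[3] != ds[3] || dim(p$wg$w)[3] != dg[3])
    stop("incompatible channel counts for the edge-attention block", call. = FALSE)
  edge <- edge_fwd(skip, keff)
  enhanced <- skip + edge
  c_s <- conv_fwd(enhanced, p$ws, keep_ws = train)
  c_g <- conv_fwd(gate_u, p$wg, keep_ws = train)
  q <- relu_fwd((if (train) c_s$y else c_s) + (if (train) c_g$y else c_g))
  c_z <- conv_fwd(q$out, p$psi, keep_ws = train)
  alpha <- sigmoid(if (train) c_z$y else c_z)
  out <- sweep_channel_mul(enhanced, alpha)
  list(out = out, alpha = alpha,
       cache = if (train) list(enhanced = enhanced, ws_s = c_s$ws,
                               ws_g = c_g$ws, ws_z = c_z$ws, q = q,
                               alpha = alpha, upsampled = upsampled,
                               keff = keff))
}

ea_bwd <- function(p, cache, dy) {
  alpha <- cache$alpha
  denh <- sweep_channel_mul(dy, alpha)
  dalpha <- sum_channels(dy * cache$enhanced)
  dz <- dalpha * alpha * (1 - alpha)
  g_psi <- conv_bwd(cache$ws_z, p$psi, dz)
  dq <- relu_bwd(cache$q, g_psi$dx)
  g_ws <- conv_bwd(cache$ws_s, p$ws, dq)
  g_wg <- conv_bwd(cache$ws_g, p$wg, dq)
  denh <- denh + g_ws$dx
  dskip <- denh + edge_bwd(denh, cache$keff)
  dgate <- if (cache$upsampled) upsample2_bwd(g_wg$dx) else g_wg$dx
  list(dskip = dskip, dgate = dgate,
       grads = list(ws = list(w = g_ws$dw, b = g_ws$db),
                    wg = list(w = g_wg$dw, b = g_wg$db),
                    psi = list(w = g_psi$dw, b = g_psi$db)))
}

#' Edge-attention block
#'
#' Enhances a skip-connection feature map with its gradient (edge) response,
#' fuses enhancement and original features by addition, computes additive
#' attention coefficients against a decoder gate, and returns the enhanced
#' features scaled by those coefficients.
#'
#' @param skip H x W x C (or 4D) skip feature map.
#' @param gate gating feature map at the same or half spatial resolution.
#' @param params gate parameters from [ea_params()]; generated (seeded from
#'   0) when omitted.
#' @param kernels gradient kernel pair, see [edge_kernels()].
#' @return gated feature map, same shape as `skip`, with the coefficient map
#'   attached as attribute `"alpha"` (all values in `[0, 1]`).
#' @export
edge_attention_block <- function(skip, gate, params = NULL,
                                 kernels = edge_kernels()) {
  s4 <- as_tensor4(skip); g4 <- as_tensor4(gate)
  if (is.null(params))
    params <- with_seed(0L, ea_params(dim(s4)[3], dim(g4)[3]))
  f <- ea_fwd(s4, g4, params, edge_corr_kernel(kernels))
  out <- restore_dim(f$out, dim(skip))
  attr(out, "alpha") <- drop(f$alpha)
  out
}

# spatial attention ----------------------------------------------------------

sa_fwd <- function(x) {
  cp <- channel_pool(x)
  smx <- sigmoid(cp$max)
  sav <- sigmoid(cp$avg)
  att <- (smx + sav) / 2
  out <- sweep_channel_mul(x, att)
  list(out = out, att = att,
       cache = list(x = x, smx = smx, sav = sav, att = att,
                    argmax = cp$argmax))
}

sa_bwd <- function(cache, dy) {
  x <- cache$x
  d <- dim(x); C <- d[3]
  dx <- sweep_channel_mul(dy, cache$att)
  datt <- sum_channels(dy * x)
  dmx <- datt * cache$smx * (1 - cache$smx) / 2
  dav <- datt * cache$sav * (1 - cache$sav) / 2 / C
  for (c in seq_len(C)) {
    sel <- cache$argmax == c
    slc <- dx[, , c, , drop = FALSE]
    slc[sel] <- slc[sel] + dmx[sel]
    dx[, , c, ] <- slc + dav
  }
  dx
}

#' Spatial-attention block
#'
#' Pools the input feature map across channels with max and average pooling,
#' stacks the two pooled maps, applies a sigmoid to each, and rescales the
#' input by the per-pixel mean of the two sigmoid maps.  All attention values
#' are strictly inside `(0, 1)`.
#'
#' @param x numeric matrix, H x W x C array, or 4D array.
#' @return rescaled feature map with the attention map as attribute
#'   `"alpha"`.
#' @export
spatial_attention_block <- function(x) {
  x4 <- as_tensor4(x)
  if (any(!is.finite(x4))) stop("feature map contains non-finite values", call. = FALSE)
  f <- sa_fwd(x4)
  out <- restore_dim(f$out, dim(x))
  attr(out, "alpha") <- drop(f$att)
  out
}

#' Residual skip pooling
#'
#' Max-pooling where the skip connection keeps the complement of what goes
#' down the encoder: `pooled` holds the maximum of every `pool_size` x
#' `pool_size` window, and `residual` is the input with exactly that argmax
#' pixel zeroed in each window (ties broken by first occurrence in row-major
#' window order).  Scattering `pooled` back into the zeroed positions
#' reconstructs the input exactly.
#'
#' @param x numeric matrix, H x W x C array, or 4D array with spatial
#'   dimensions divisible by `pool_size`.
#' @param pool_size pooling window side (default 2).
#' @return list with `pooled` and `residual`; the argmax index array is
#'   attached to `residual` as attribute `"argmax"`.
#' @export
residual_skip <- function(x, pool_size = 2L) {
  x4 <- as_tensor4(x)
  d <- dim(x4)
  if (d[1] %% pool_size != 0 || d[2] %% pool_size != 0)
    stop("spatial dimensions are not divisible by 'pool_size'", call. = FALSE)
  r <- cpp_maxpool_res(x4, as.integer(pool_size))
  pooled_dim <- if (is.null(dim(x)) || length(dim(x)) == 2L)
    c(d[1] / pool_size, d[2] / pool_size)
  else c(d[1] / pool_size, d[2] / pool_size, dim(x)[-(1:2)])
  pooled <- array(r$pooled, pooled_dim)
  if (length(pooled_dim) == 2L) pooled <- matrix(pooled, pooled_dim[1], pooled_dim[2])
  residual <- restore_dim(r$residual, dim(x))
  attr(residual, "argmax") <- r$argmax
  list(pooled = pooled, residual = residual)
}
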
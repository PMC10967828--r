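#' Architecture configuration for the hybrid attention U-Net
#'
#' The default geometry is the proposed network: five encoder stages, one
#' base stage and five decoder stages, channels doubling per stage from
#' `base_channels`, edge attention (EA) on the two shallowest skip
#' connections and spatial attention (SA) on the three deepest.  Every
#' encoder stage is two 3x3 conv + batch-norm + ReLU layers followed by
#' residual-skip max pooling; every decoder stage is a 2x2 transposed
#' convolution, an attention-gated skip concatenation and two conv layers;
#' the head is a 1x1 projection to `n_classes` with a per-pixel softmax.
#'
#' @param depth number of encoder (= decoder) stages.
#' @param base_channels channels at the first stage; doubles each stage.
#' @param n_classes output classes.
#' @param input_shape `(rows, cols)`, each divisible by `2^depth`.
#' @param attention_layout character vector of length `depth` with entries
#'   `"EA"`, `"SA"` or `"none"` giving the attention type on each skip
#'   (stage 1 = shallowest).  Default: EA on stages 1-2, SA on the rest.
#' @param variant `"proposed"`, ablation codes `"A"`-`"D"`, or `"none"`
#'   (no attention anywhere, the plain-U-Net baseline of equal capacity).
#' @return object of class `model_config`.
#' @export
model_config <- function(depth = 5L, base_channels = 16L, n_classes = 5L,
                         input_shape = c(512L, 256L),
                         attention_layout = NULL,
                         variant = c("proposed", "A", "B", "C", "D", "none")) {
  variant <- match.arg(variant)
  depth <- as.integer(depth)
  if (depth < 1L) stop_config("depth", "must be >= 1")
  if (n_classes < 2L) stop_config("n_classes", "must be >= 2")
  if (length(input_shape) != 2L || any(input_shape %% 2L^depth != 0))
    stop_config("input_shape",
                sprintf("rows and cols must be divisible by 2^depth = %d", 2L^depth))
  if (is.null(attention_layout))
    attention_layout <- ifelse(seq_len(depth) <= 2L, "EA", "SA")
  if (length(attention_layout) != depth ||
      !all(attention_layout %in% c("EA", "SA", "none")))
    stop_config("attention_layout", "must be 'EA'/'SA'/'none' per stage")
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 attention_layout = attention_layout,
                 variant = variant),
            class = "model_config")
}

# effective placement of attention blocks for a variant
attention_plan <- function(cfg) {
  D <- cfg$depth
  none <- rep("none", D)
  switch(cfg$variant,
         proposed = list(skip = cfg$attention_layout, enc = none, dec = none),
         A = list(skip = none, enc = cfg$attention_layout, dec = none),
         B = list(skip = none, enc = none, dec = cfg$attention_layout),
         C = list(skip = rep("EA", D), enc = none, dec = none),
         D = list(skip = rep("SA", D), enc = none, dec = none),
         none = list(skip = none, enc = none, dec = none))
}

stage_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

#' Build a hybrid attention U-Net
#'
#' Initialises all weights from scratch (He-scaled Gaussian convolutions,
#' unit-gain batch norm) under the given seed.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `octseg_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  if (!inherits(config, "model_config")) config <- do.call(model_config, config)
  plan <- attention_plan(config)
  D <- config$depth
  ch <- stage_channels(config)
  base_ch <- config$base_channels * 2L^D
  with_seed(derive_seed(seed, 0L, 17L), {
    params <- list(enc = vector("list", D), dec = vector("list", D),
                   att_skip = vector("list", D), att_enc = vector("list", D),
                   att_dec = vector("list", D))
    bn_state <- list(enc = vector("list", D), dec = vector("list", D))
    cin <- 1L
    for (k in seq_len(D)) {
      params$enc[[k]] <- list(
        u1 = list(conv = init_conv(3L, 3L, cin, ch[k]), bn = init_bn(ch[k])),
        u2 = list(conv = init_conv(3L, 3L, ch[k], ch[k]), bn = init_bn(ch[k])))
      bn_state$enc[[k]] <- list(u1 = init_bn_state(ch[k]),
                                u2 = init_bn_state(ch[k]))
      if (plan$enc[k] == "EA")
        params$att_enc[[k]] <- ea_params(ch[k], ch[k])
      cin <- ch[k]
    }
    params$base <- list(
      u1 = list(conv = init_conv(3L, 3L, ch[D], base_ch), bn = init_bn(base_ch)),
      u2 = list(conv = init_conv(3L, 3L, base_ch, base_ch), bn = init_bn(base_ch)))
    bn_state$base <- list(u1 = init_bn_state(base_ch), u2 = init_bn_state(base_ch))
    for (k in seq_len(D)) {
      cin_dec <- if (k == D) base_ch else ch[k + 1L]
      params$dec[[k]] <- list(
        up = init_conv(2L, 2L, cin_dec, ch[k]),
        u1 = list(conv = init_conv(3L, 3L, 2L * ch[k], ch[k]), bn = init_bn(ch[k])),
        u2 = list(conv = init_conv(3L, 3L, ch[k], ch[k]), bn = init_bn(ch[k])))
      bn_state$dec[[k]] <- list(u1 = init_bn_state(ch[k]),
                                u2 = init_bn_state(ch[k]))
      if (plan$skip[k] == "EA")
        params$att_skip[[k]] <- ea_params(ch[k], cin_dec)
      if (plan$dec[k] == "EA")
        params$att_dec[[k]] <- ea_params(ch[k], ch[k])
    }
    params$head <- init_conv(1L, 1L, ch[1L], config$n_classes)
    structure(list(config = config, plan = plan, params = params,
                   bn_state = bn_state, keff = edge_corr_kernel(edge_kernels()),
                   fitted = FALSE, seed = as.integer(seed)),
              class = "octseg_model")
  })
}

#' Build an ablation variant of the network
#'
#' `"A"` places attention only inside the encoder stages, `"B"` only inside
#' the decoder stages (skips are plain in both); `"C"` puts edge attention
#' on all skips, `"D"` spatial attention on all skips.
#'
#' @param code one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param config a [model_config()]; its variant field is overridden.
#' @param seed passed to [build_model()].
#' @export
build_ablation_variant <- function(code, config = model_config(), seed = 1L) {
  if (!is.character(code) || length(code) != 1L || !code %in% c("A", "B", "C", "D"))
    stop("unknown ablation code; expected one of 'A','B','C','D'", call. = FALSE)
  config$variant <- code
  build_model(config, seed)
}

# attention dispatch used inside the network
att_block_fwd <- function(type, x, gate, p, keff, train = FALSE) {
  switch(type,
         EA = ea_fwd(x, gate, p, keff, train),
         SA = sa_fwd(x),
         none = list(out = x, cache = NULL))
}

att_block_bwd <- function(type, p, cache, dy) {
  switch(type,
         EA = ea_bwd(p, cache, dy),
         SA = list(dskip = sa_bwd(cache, dy), dgate = NULL, grads = NULL),
         none = list(dskip = dy, dgate = NULL, grads = NULL))
}

# full forward pass; x is (H, W, 1, N)
net_forward <- function(model, x, train = FALSE) {
  cfg <- model$config; plan <- model$plan; P <- model$params
  S <- model$bn_state; D <- cfg$depth; keff <- model$keff
  cache <- list(enc = vector("list", D), dec = vector("list", D))
  cur <- x
  for (k in seq_len(D)) {
    c1 <- cbr_fwd(cur, P$enc[[k]]$u1, S$enc[[k]]$u1, train)
    S$enc[[k]]$u1 <- c1$state
    c2 <- cbr_fwd(c1$out, P$enc[[k]]$u2, S$enc[[k]]$u2, train)
    S$enc[[k]]$u2 <- c2$state
    f <- c2$out
    ea <- att_block_fwd(plan$enc[k], f, f, P$att_enc[[k]], keff, train)
    pool <- cpp_maxpool_res(ea$out, 2L)
    cache$enc[[k]] <- list(c1 = c1$cache, c2 = c2$cache, att = ea$cache,
                           argmax = pool$argmax, in_dim = dim(ea$out))
    cache$skip[[k]] <- pool$residual
    cur <- pool$pooled
  }
  b1 <- cbr_fwd(cur, P$base$u1, S$base$u1, train); S$base$u1 <- b1$state
  b2 <- cbr_fwd(b1$out, P$base$u2, S$base$u2, train); S$base$u2 <- b2$state
  cache$base <- list(c1 = b1$cache, c2 = b2$cache)
  cur <- b2$out
  for (k in rev(seq_len(D))) {
    up <- convT_fwd(cur, P$dec[[k]]$up)
    att <- att_block_fwd(plan$skip[k], cache$skip[[k]], cur, P$att_skip[[k]], keff, train)
    cat_ <- concat_channels(up, att$out)
    c1 <- cbr_fwd(cat_, P$dec[[k]]$u1, S$dec[[k]]$u1, train)
    S$dec[[k]]$u1 <- c1$state
    c2 <- cbr_fwd(c1$out, P$dec[[k]]$u2, S$dec[[k]]$u2, train)
    S$dec[[k]]$u2 <- c2$state
    da <- att_block_fwd(plan$dec[k], c2$out, c2$out, P$att_dec[[k]], keff, train)
    cache$dec[[k]] <- list(dec_in = cur, up_out_ch = dim(up)[3],
                           att = att$cache, c1 = c1$cache, c2 = c2$cache,
                           datt = da$cache)
    cur <- da$out
  }
  ch_ <- conv_fwd(cur, P$head, keep_ws = train)
  logits <- if (train) ch_$y else ch_
  probs <- softmax_channels(logits)
  if (train) cache$head_ws <- ch_$ws
  cache$probs <- probs
  list(probs = probs, logits = logits, cache = cache, bn_state = S)
}

# full backward pass from dlogits; returns gradients mirroring model$params
net_backward <- function(model, cache, dlogits) {
  cfg <- model$config; plan <- model$plan; P <- model$params
  D <- cfg$depth
  G <- list(enc = vector("list", D), dec = vector("list", D),
            att_skip = vector("list", D), att_enc = vector("list", D),
            att_dec = vector("list", D))
  gh <- conv_bwd(cache$head_ws, P$head, dlogits)
  G$head <- list(w = gh$dw, b = gh$db)
  dcur <- gh$dx
  dskip <- vector("list", D)
  for (k in seq_len(D)) {   # decoder ran D..1, so reverse is 1..D
    ck <- cache$dec[[k]]
    ab <- att_block_bwd(plan$dec[k], P$att_dec[[k]], ck$datt, dcur)
    if (!is.null(ab$grads)) G$att_dec[[k]] <- ab$grads
    dy <- ab$dskip
    if (plan$dec[k] == "EA" && !is.null(ab$dgate)) dy <- dy + ab$dgate
    g2 <- cbr_bwd(P$dec[[k]]$u2, ck$c2, dy)
    G$dec[[k]]$u2 <- g2$grads
    g1 <- cbr_bwd(P$dec[[k]]$u1, ck$c1, g2$dx)
    G$dec[[k]]$u1 <- g1$grads
    sp <- split_channels(g1$dx, ck$up_out_ch)
    gu <- convT_bwd(ck$dec_in, P$dec[[k]]$up, sp$a)
    G$dec[[k]]$up <- list(w = gu$dw, b = gu$db)
    sb <- att_block_bwd(plan$skip[k], P$att_skip[[k]], ck$att, sp$b)
    if (!is.null(sb$grads)) G$att_skip[[k]] <- sb$grads
    dskip[[k]] <- sb$dskip
    dcur <- gu$dx
    if (plan$skip[k] == "EA" && !is.null(sb$dgate)) dcur <- dcur + sb$dgate
  }
  gb2 <- cbr_bwd(P$base$u2, cache$base$c2, dcur)
  gb1 <- cbr_bwd(P$base$u1, cache$base$c1, gb2$dx)
  G$base <- list(u1 = gb1$grads, u2 = gb2$grads)
  dcur <- gb1$dx
  for (k in rev(seq_len(D))) {
    ck <- cache$enc[[k]]
    H <- ck$in_dim[1]; W <- ck$in_dim[2]
    # residual branch: identity except the zeroed argmax positions
    df <- dskip[[k]]
    Hp <- dim(dcur)[1]; Wp <- dim(dcur)[2]
    plane <- (seq_along(ck$argmax) - 1) %/% (Hp * Wp)
    pos <- plane * (H * W) + ck$argmax
    df[pos] <- dcur          # pooled branch gradient replaces the zeroed slot
    ab <- att_block_bwd(plan$enc[k], P$att_enc[[k]], ck$att, df)
    if (!is.null(ab$grads)) G$att_enc[[k]] <- ab$grads
    df <- ab$dskip
    if (plan$enc[k] == "EA" && !is.null(ab$dgate)) df <- df + ab$dgate
    g2 <- cbr_bwd(P$enc[[k]]$u2, ck$c2, df)
    g1 <- cbr_bwd(P$enc[[k]]$u1, ck$c1, g2$dx)
    G$enc[[k]] <- list(u1 = g1$grads, u2 = g2$grads)
    dcur <- g1$dx
  }
  G
}

#' Count attention blocks in a model
#'
#' @param model an `octseg_model`.
#' @return named integer vector with `ea` and `sa` counts.
#' @export
attention_block_counts <- function(model) {
  plan <- model$plan
  all_types <- c(plan$skip, plan$enc, plan$dec)
  c(ea = sum(all_types == "EA"), sa = sum(all_types == "SA"))
}

count_params <- function(p) {
  if (is.numeric(p)) return(length(p))
  if (is.list(p)) return(sum(vapply(p, count_params, numeric(1))))
  0
}

#' Architecture summary
#'
#' Stage list, attention placement, and parameter counts; serialisable to
#' JSON with [jsonlite::toJSON()].
#'
#' @param model an `octseg_model`.
#' @export
architecture_summary <- function(model) {
  cfg <- model$config
  cnt <- attention_block_counts(model)
  list(variant = cfg$variant,
       n_encoder_stages = cfg$depth,
       n_decoder_stages = cfg$depth,
       n_base_stages = 1L,
       channels = stage_channels(cfg),
       input_shape = cfg$input_shape,
       n_classes = cfg$n_classes,
       n_edge_attention = unname(cnt["ea"]),
       n_spatial_attention = unname(cnt["sa"]),
       skip_attention = model$plan$skip,
       n_parameters = count_params(model$params))
}
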
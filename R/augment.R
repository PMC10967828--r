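#' The nine-transform augmentation set
#'
#' Each training image is expanded into nine variants: vertical flip,
#' horizontal flip, random snow, CLAHE, blur, invert, coarse dropout,
#' downscale and equalise.  Only the two geometric flips touch the label
#' mask; the seven photometric transforms corrupt intensities and leave
#' labels byte-identical.  Stochastic parameters (snow threshold, blur
#' radius, dropout hole placement, CLAHE clip) are drawn from a seeded
#' stream, so an augmentation run is reproducible.
#'
#' Parameter ranges follow the conventional defaults of the augmentation
#' library whose transform vocabulary these names come from; all are
#' overridable through `params`.
#'
#' @param seed integer seed for the stochastic transforms.
#' @param params named list overriding per-transform parameters; see
#'   Details in the package vignette.
#' @return object of class `augmentation_set`.
#' @export
augmentation_set <- function(seed = 0L, params = list()) {
  defaults <- list(
    random_snow = list(snow_point = c(0.1, 0.3), brightness_coeff = 2.5),
    clahe = list(clip_limit = c(1, 4), tile_grid = c(8L, 8L)),
    blur = list(blur_limit = c(3L, 7L)),
    coarse_dropout = list(max_holes = 8L, max_height = 8L, max_width = 8L),
    downscale = list(scale = c(0.25, 0.25))
  )
  p <- modifyList(defaults, params)
  structure(list(transforms = augment_transform_names(),
                 params = p, seed = as.integer(seed)),
            class = "augmentation_set")
}

#' @rdname augmentation_set
#' @export
augment_transform_names <- function() {
  c("vertical_flip", "horizontal_flip", "random_snow", "clahe", "blur",
    "invert", "coarse_dropout", "downscale", "equalize")
}

geometric_transforms <- function() c("vertical_flip", "horizontal_flip")

#' Apply one named augmentation transform to an image/mask pair
#'
#' @param name one of [augment_transform_names()].
#' @param image numeric matrix in `[0,1]`.
#' @param mask integer label matrix (same shape); flipped for the two
#'   geometric transforms, returned unchanged otherwise.
#' @param seed integer seed making stochastic transforms deterministic.
#' @param params parameter list as in [augmentation_set()].
#' @return list with transformed `image` and `mask`.
#' @export
apply_transform <- function(name, image, mask, seed = 0L,
                            params = augmentation_set()$params) {
  if (!name %in% augment_transform_names())
    stop(sprintf("unknown transform '%s'", name), call. = FALSE)
  if (!all(dim(image) == dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  with_seed(derive_seed(seed, match(name, augment_transform_names())), {
    img <- switch(
      name,
      vertical_flip   = image[rev(seq_len(nrow(image))), , drop = FALSE],
      horizontal_flip = image[, rev(seq_len(ncol(image))), drop = FALSE],
      random_snow     = aug_random_snow(image, params$random_snow),
      clahe           = aug_clahe(image, params$clahe),
      blur            = aug_blur(image, params$blur),
      invert          = 1 - image,
      coarse_dropout  = aug_coarse_dropout(image, params$coarse_dropout),
      downscale       = aug_downscale(image, params$downscale),
      equalize        = hist_equalize(image)
    )
    msk <- switch(name,
                  vertical_flip = mask[rev(seq_len(nrow(mask))), , drop = FALSE],
                  horizontal_flip = mask[, rev(seq_len(ncol(mask))), drop = FALSE],
                  mask)
    list(image = img, mask = msk)
  })
}

aug_random_snow <- function(image, p) {
  sp <- runif(1, p$snow_point[1], p$snow_point[2])
  out <- image
  sel <- image < sp
  out[sel] <- image[sel] * p$brightness_coeff
  clamp01(out)
}

aug_clahe <- function(image, p) {
  clip <- runif(1, p$clip_limit[1], p$clip_limit[2])
  tg <- pmin(p$tile_grid, dim(image))
  clahe_enhance(image, clip_limit = clip, tile_grid = tg)
}

aug_blur <- function(image, p) {
  ks <- sample(seq(p$blur_limit[1], p$blur_limit[2], by = 2L), 1L)
  k <- matrix(1 / (ks * ks), ks, ks)
  cpp_filter2_reflect(image, k)
}

aug_coarse_dropout <- function(image, p) {
  out <- image
  H <- nrow(image); W <- ncol(image)
  for (i in seq_len(p$max_holes)) {
    hh <- min(p$max_height, H); ww <- min(p$max_width, W)
    r0 <- sample.int(H - hh + 1L, 1L); c0 <- sample.int(W - ww + 1L, 1L)
    out[r0:(r0 + hh - 1L), c0:(c0 + ww - 1L)] <- 0
  }
  out
}

aug_downscale <- function(image, p) {
  sc <- runif(1, p$scale[1], p$scale[2])
  d <- dim(image)
  small <- pmax(c(1L, 1L), as.integer(round(d * sc)))
  resize_mask(resize_mask(image, small), d)  # nearest-neighbour down then up
}

# global histogram equalisation over 256 bins
hist_equalize <- function(image, bins = 256L) {
  v <- pmin(as.integer(floor(image * bins)), bins - 1L)
  h <- tabulate(v + 1L, nbins = bins)
  cdf <- cumsum(h)
  cdf_min <- cdf[which(h > 0)[1]]
  n <- length(v)
  if (n == cdf_min) return(image)  # constant image
  lut <- (cdf - cdf_min) / (n - cdf_min)
  matrix(lut[v + 1L], nrow(image), ncol(image))
}

#' Expand a dataset tenfold with the nine augmentation transforms
#'
#' Every original pair is retained and accompanied by its nine transformed
#' versions, so `n` pairs become exactly `10 n`.  Each output item records
#' its provenance (`source` index and `transform` name).
#'
#' @param pairs non-empty list of `list(image, mask)` pairs.
#' @param augset an [augmentation_set()].
#' @return list of `10 * length(pairs)` items.
#' @export
expand_dataset <- function(pairs, augset = augmentation_set()) {
  if (length(pairs) == 0L) stop("input list is empty", call. = FALSE)
  out <- vector("list", 10L * length(pairs))
  j <- 0L
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (!all(dim(p$image) == dim(p$mask)))
      stop(sprintf("pair %d: image and mask shapes differ", i), call. = FALSE)
    j <- j + 1L
    out[[j]] <- list(image = p$image, mask = p$mask, source = i,
                     transform = "original")
    for (tname in augset$transforms) {
      j <- j + 1L
      tp <- apply_transform(tname, p$image, p$mask,
                            seed = derive_seed(augset$seed, i,
                                               match(tname, augset$transforms)),
                            params = augset$params)
      out[[j]] <- list(image = tp$image, mask = tp$mask, source = i,
                       transform = tname)
    }
  }
  out
}
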
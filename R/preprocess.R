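#' Pre-processing configuration
#'
#' Parameters of the image-conditioning chain applied before training:
#' crop away black background margins, resize to a fixed geometry, Gaussian
#' smoothing against speckle, and CLAHE contrast enhancement.  The target
#' geometry follows the convention rows x cols = depth x lateral, so the
#' default `c(512, 256)` means 512 depth rows by 256 lateral columns.
#'
#' @param target_shape integer `(rows, cols)` of the output image.
#' @param gaussian_sigma Gaussian smoothing standard deviation in pixels;
#'   0 disables smoothing.
#' @param clahe_clip_limit CLAHE contrast clip limit (unitless, > 0).
#' @param clahe_tile_grid integer `(rows, cols)` number of CLAHE tiles.
#' @param border_mode convolution edge handling, `"reflect"` or `"zero"`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_shape = c(512L, 256L),
                              gaussian_sigma = 1.0,
                              clahe_clip_limit = 2.0,
                              clahe_tile_grid = c(8L, 8L),
                              border_mode = c("reflect", "zero")) {
  border_mode <- match.arg(border_mode)
  if (length(target_shape) != 2L || any(target_shape <= 0))
    stop_config("target_shape", "must be two positive integers")
  if (gaussian_sigma < 0) stop_config("gaussian_sigma", "must be >= 0")
  if (clahe_clip_limit <= 0) stop_config("clahe_clip_limit", "must be > 0")
  if (length(clahe_tile_grid) != 2L || any(clahe_tile_grid < 1))
    stop_config("clahe_tile_grid", "must be two positive integers")
  structure(list(target_shape = as.integer(target_shape),
                 gaussian_sigma = gaussian_sigma,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 border_mode = border_mode),
            class = "preprocess_config")
}

# indices of rows/cols that carry any signal above the black threshold
crop_margins <- function(image, threshold = 1 / 255) {
  keep_r <- which(apply(image, 1, max) >= threshold)
  keep_c <- which(apply(image, 2, max) >= threshold)
  if (length(keep_r) == 0L || length(keep_c) == 0L)
    stop("image is entirely black: nothing to crop to", call. = FALSE)
  list(rows = min(keep_r):max(keep_r), cols = min(keep_c):max(keep_c))
}

#' Crop black margins and resize to the target geometry
#'
#' Rows and columns whose every pixel is below 1/255 at the image border are
#' treated as background and removed before a bilinear resize to
#' `config$target_shape`.
#'
#' @param image numeric matrix in `[0,1]`.
#' @param config a [preprocess_config()].
#' @export
crop_resize <- function(image, config = preprocess_config()) {
  if (length(dim(image)) != 2L) stop("'image' must be a 2D matrix", call. = FALSE)
  m <- crop_margins(image)
  cropped <- image[m$rows, m$cols, drop = FALSE]
  resize_bilinear(cropped, config$target_shape)
}

resize_bilinear <- function(image, target_shape) {
  if (all(dim(image) == target_shape)) return(image)
  out <- EBImage::resize(image, w = target_shape[1], h = target_shape[2],
                         filter = "bilinear")
  clamp01(matrix(out, target_shape[1], target_shape[2]))
}

#' Nearest-neighbour resize for label masks
#'
#' Masks are never interpolated: each output pixel copies the label of its
#' nearest source pixel, so the class set is preserved exactly.
#'
#' @param mask integer matrix of class labels.
#' @param target_shape integer `(rows, cols)`.
#' @export
resize_mask <- function(mask, target_shape) {
  d <- dim(mask)
  ri <- pmin(d[1], floor((seq_len(target_shape[1]) - 0.5) * d[1] / target_shape[1]) + 1L)
  ci <- pmin(d[2], floor((seq_len(target_shape[2]) - 0.5) * d[2] / target_shape[2]) + 1L)
  mask[ri, ci, drop = FALSE]
}

#' Gaussian smoothing
#'
#' Convolution with a normalised discrete Gaussian kernel truncated at three
#' standard deviations.  `sigma = 0` returns the input unchanged.
#'
#' @param image numeric matrix.
#' @param sigma kernel standard deviation in pixels.
#' @param border_mode `"reflect"` (mirror) or `"zero"` padding.
#' @export
gaussian_smooth <- function(image, sigma = 1.0,
                            border_mode = c("reflect", "zero")) {
  border_mode <- match.arg(border_mode)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(image)
  k <- gaussian_kernel(sigma)
  if (border_mode == "reflect") {
    cpp_filter2_reflect(image, k)
  } else {
    x4 <- as_tensor4(image)
    restore_dim(cpp_depthwise_corr(x4, k, FALSE), dim(image))
  }
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Standard CLAHE: the image is divided into a grid of tiles, each tile's
#' 256-bin histogram is clipped at `clip_limit` times the uniform bin count
#' (the excess redistributed uniformly) and equalised, and each pixel's
#' mapping is bilinearly interpolated between the four neighbouring tile
#' mappings.  With a single tile and a clip limit high enough not to bite,
#' this reduces to plain global histogram equalisation.
#'
#' @param image numeric matrix in `[0,1]`.
#' @param clip_limit contrast clip limit (> 0), in multiples of the uniform
#'   histogram height.
#' @param tile_grid integer `(rows, cols)` tile counts.
#' @param bins histogram bins.
#' @export
clahe_enhance <- function(image, clip_limit = 2.0, tile_grid = c(8L, 8L),
                          bins = 256L) {
  if (clip_limit <= 0) stop("'clip_limit' must be > 0", call. = FALSE)
  if (any(tile_grid < 1)) stop("'tile_grid' must be positive", call. = FALSE)
  if (tile_grid[1] > nrow(image) || tile_grid[2] > ncol(image))
    stop("'tile_grid' is larger than the image", call. = FALSE)
  if (diff(range(image)) == 0) return(image)  # no contrast to spread
  H <- nrow(image); W <- ncol(image)
  tr <- tile_grid[1]; tc <- tile_grid[2]
  v <- matrix(pmin(as.integer(floor(image * bins)), bins - 1L), H, W)
  row_tile <- tile_index(H, tr)
  col_tile <- tile_index(W, tc)
  # per-tile clipped, equalised lookup tables
  lut <- array(0, c(bins, tr, tc))
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    sel <- v[row_tile$id == i, col_tile$id == j]
    h <- tabulate(sel + 1L, nbins = bins)
    npix <- length(sel)
    clip <- max(1, clip_limit * npix / bins)
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip) + excess / bins
    cdf <- cumsum(h)
    cdfmin <- cdf[which(h > 0)[1]]
    lut[, i, j] <- if (npix > cdfmin) (cdf - cdfmin) / (npix - cdfmin)
    else rep(0, bins)
  }
  # bilinear interpolation between the four surrounding tile mappings
  ri <- row_tile$interp; ci <- col_tile$interp
  vv <- as.vector(v) + 1L
  i0 <- rep(ri$lo, times = W); i1 <- rep(ri$hi, times = W)
  wy <- rep(ri$w, times = W)
  j0 <- rep(ci$lo, each = H); j1 <- rep(ci$hi, each = H)
  wx <- rep(ci$w, each = H)
  at <- function(i, j) lut[vv + (i - 1L) * bins + (j - 1L) * bins * tr]
  out <- (1 - wy) * (1 - wx) * at(i0, j0) + (1 - wy) * wx * at(i0, j1) +
    wy * (1 - wx) * at(i1, j0) + wy * wx * at(i1, j1)
  clamp01(matrix(out, H, W))
}

# tile membership and interpolation weights along one axis
tile_index <- function(n, k) {
  bounds <- floor(seq(0, n, length.out = k + 1L))
  id <- findInterval(seq_len(n) - 0.5, bounds, rightmost.closed = TRUE)
  centers <- (head(bounds, -1L) + bounds[-1L] + 1) / 2
  pos <- seq_len(n)
  lo <- pmin(pmax(findInterval(pos, centers), 1L), k)
  hi <- pmin(lo + 1L, k)
  lo_adj <- ifelse(pos < centers[1], 1L, lo)
  w <- ifelse(hi == lo_adj, 0,
              (pos - centers[lo_adj]) / (centers[hi] - centers[lo_adj]))
  w <- pmin(pmax(w, 0), 1)
  list(id = id, interp = list(lo = lo_adj, hi = hi, w = w))
}

#' Full pre-processing pipeline
#'
#' Grayscale extraction (channel mean for multi-channel input), black-margin
#' crop and bilinear resize, Gaussian smoothing, then CLAHE.
#'
#' @param image numeric matrix or H x W x C array in `[0,1]`.
#' @param config a [preprocess_config()].
#' @return numeric matrix of size `config$target_shape`, values in `[0,1]`.
#' @export
preprocess_pipeline <- function(image, config = preprocess_config()) {
  if (length(dim(image)) == 3L) {
    image <- apply(image, c(1, 2), mean)  # luminance average
  }
  x <- crop_resize(image, config)
  x <- gaussian_smooth(x, config$gaussian_sigma, config$border_mode)
  clamp01(clahe_enhance(x, config$clahe_clip_limit, config$clahe_tile_grid))
}

#' Pre-process an image/mask pair consistently
#'
#' The crop window is decided from the image; the mask is cropped with the
#' same window and resized nearest-neighbour so labels stay integral.
#'
#' @param image numeric matrix (or H x W x C array).
#' @param mask integer label matrix of the same spatial size.
#' @param config a [preprocess_config()].
#' @export
preprocess_pair <- function(image, mask, config = preprocess_config()) {
  if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  if (!all(dim(image) == dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  m <- crop_margins(image)
  img <- resize_bilinear(image[m$rows, m$cols, drop = FALSE], config$target_shape)
  img <- gaussian_smooth(img, config$gaussian_sigma, config$border_mode)
  img <- clamp01(clahe_enhance(img, config$clahe_clip_limit, config$clahe_tile_grid))
  msk <- resize_mask(mask[m$rows, m$cols, drop = FALSE], config$target_shape)
  list(image = img, mask = msk)
}
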
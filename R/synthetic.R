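#' Configuration for the synthetic layered B-scan generator
#'
#' The generator emulates the structure the segmenter assumes in real OCT
#' B-scans: a stack of ordered, non-crossing tissue bands running laterally
#' across the image, each with a characteristic mean reflectivity, corrupted
#' by multiplicative speckle.  Rows are depth, columns lateral position.
#'
#' Default reflectivities follow the qualitative appearance of a macular
#' B-scan: dark vitreous above the ILM, a bright inner-retina band (NFL/IPL),
#' a mid-grey outer retina, a bright RPE complex, and a darker choroid/sclera
#' region under Bruch's membrane.
#'
#' @param height,width image size in pixels (rows = depth, cols = lateral).
#' @param n_classes number of ordered bands (classes `0:(n_classes-1)`).
#' @param boundary_smoothness standard deviation, in pixels, of the
#'   low-frequency wobble added to each band boundary; 0 gives flat bands.
#' @param band_intensities mean reflectivity of each band, in `[0,1]`.
#' @param speckle_sigma standard deviation of the multiplicative Gaussian
#'   speckle term `(1 + N(0, sigma))`.
#' @param fluid_probability probability that a scan receives one dark
#'   elliptical fluid-like pocket.  Pockets darken intensities but never
#'   change labels: the five segmented classes are regions, not fluids.
#' @param seed integer RNG seed; together with the item index it makes every
#'   generated pair reproducible.
#' @return an object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(height = 64, width = 32, speckle_sigma = 0)
#' pair <- generate_bscan(cfg, 1)
#' table(pair$mask)
synth_config <- function(height = 512L, width = 256L, n_classes = 5L,
                         boundary_smoothness = 4,
                         band_intensities = NULL,
                         speckle_sigma = 0.1,
                         fluid_probability = 0.1,
                         seed = 1L) {
  if (is.null(band_intensities)) {
    band_intensities <- if (n_classes == 5L) c(0.05, 0.65, 0.35, 0.85, 0.15)
    else seq(0.1, 0.9, length.out = n_classes)
  }
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_classes = as.integer(n_classes),
              boundary_smoothness = boundary_smoothness,
              band_intensities = band_intensities,
              speckle_sigma = speckle_sigma,
              fluid_probability = fluid_probability,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_classes < 2L) stop_config("n_classes", "must be >= 2")
  if (cfg$height < 16L) stop_config("height", "must be >= 16")
  if (cfg$width < 16L) stop_config("width", "must be >= 16")
  if (length(cfg$band_intensities) != cfg$n_classes)
    stop_config("band_intensities",
                sprintf("must have exactly %d entries", cfg$n_classes))
  if (any(cfg$band_intensities < 0 | cfg$band_intensities > 1))
    stop_config("band_intensities", "entries must lie in [0,1]")
  if (cfg$boundary_smoothness < 0)
    stop_config("boundary_smoothness", "must be >= 0")
  if (cfg$speckle_sigma < 0) stop_config("speckle_sigma", "must be >= 0")
  if (cfg$fluid_probability < 0 || cfg$fluid_probability > 1)
    stop_config("fluid_probability", "must lie in [0,1]")
  invisible(cfg)
}

# smooth non-crossing boundary curves, one row index per column per boundary.
# Construction: evenly spaced base depths plus low-pass-filtered Gaussian
# wobble, then a cumulative-max pass that enforces strict ordering.
synth_boundaries <- function(cfg) {
  H <- cfg$height; W <- cfg$width; K <- cfg$n_classes
  base <- H * seq_len(K - 1) / K
  B <- matrix(0, K - 1, W)
  for (k in seq_len(K - 1)) {
    if (cfg$boundary_smoothness > 0) {
      z <- rnorm(W)
      sig <- max(2, W / 16)
      r <- ceiling(3 * sig)
      g <- exp(-((-r:r)^2) / (2 * sig^2)); g <- g / sum(g)
      zp <- c(rev(z[seq_len(min(r, W))]), z, rev(z[max(1, W - r + 1):W]))
      if (length(zp) < W + 2 * r) zp <- c(zp, rep(zp[length(zp)], W + 2 * r - length(zp)))
      sm <- stats::filter(zp, g, sides = 2)[(r + 1):(r + W)]
      sm <- sm - mean(sm)
      s <- stats::sd(sm)
      if (s > 0) sm <- sm / s * cfg$boundary_smoothness
      B[k, ] <- base[k] + sm
    } else {
      B[k, ] <- base[k]
    }
  }
  # clamp and enforce strictly increasing depth at every column
  B <- pmin(pmax(B, 1), H - 1)
  if (K > 2) for (k in 2:(K - 1)) B[k, ] <- pmax(B[k, ], B[k - 1, ] + 1)
  B <- pmin(B, H - 1)
  if (K > 2) for (k in (K - 2):1) B[k, ] <- pmin(B[k, ], B[k + 1, ] - 1)
  B
}

#' Generate one synthetic B-scan and its label mask
#'
#' Deterministic given `(config$seed, index)`: the same pair of arguments
#' always returns bit-identical image and mask.
#'
#' @param config a [synth_config()].
#' @param index positive integer identifying the item within the dataset.
#' @return a list with `image` (numeric matrix in `[0,1]`), `mask` (integer
#'   matrix, values `0:(n_classes-1)`), and `seed` (the derived item seed).
#' @export
generate_bscan <- function(config, index = 1L) {
  validate_synth_config(config)
  if (!is.numeric(index) || length(index) != 1L || index < 1)
    stop("'index' must be a positive integer", call. = FALSE)
  item_seed <- derive_seed(config$seed, index)
  with_seed(item_seed, {
    H <- config$height; W <- config$width; K <- config$n_classes
    B <- synth_boundaries(config)
    rows <- matrix(seq_len(H), H, W)
    mask <- matrix(0L, H, W)
    for (k in seq_len(K - 1))
      mask <- mask + (rows > matrix(B[k, ], H, W, byrow = TRUE))
    img <- matrix(config$band_intensities[mask + 1L], H, W)
    if (runif(1) < config$fluid_probability && K >= 3) {
      # one dark elliptical pocket inside a random interior band; labels keep
      # the enclosing band's class
      band <- sample(seq_len(K - 2), 1L) # interior bands 1..K-2
      ctr_c <- runif(1, 0.2 * W, 0.8 * W)
      top <- B[band, round(ctr_c)]
      bot <- B[band + 1L, round(ctr_c)]
      ctr_r <- (top + bot) / 2
      a <- max(2, (bot - top) * runif(1, 0.2, 0.45))
      b <- max(3, W * runif(1, 0.05, 0.15))
      cols <- matrix(seq_len(W), H, W, byrow = TRUE)
      inside <- ((rows - ctr_r) / a)^2 + ((cols - ctr_c) / b)^2 <= 1
      img[inside & mask == band] <- img[inside & mask == band] * 0.3
    }
    if (config$speckle_sigma > 0)
      img <- img * (1 + matrix(rnorm(H * W, 0, config$speckle_sigma), H, W))
    img <- clamp01(img)
    list(image = img, mask = mask, seed = item_seed)
  })
}

#' Generate a synthetic dataset of B-scan/mask pairs
#'
#' @param config a [synth_config()].
#' @param n number of pairs.
#' @return list with `pairs` (list of `generate_bscan()` results) and
#'   `manifest` (the config plus per-item seeds; regenerating from the
#'   manifest reproduces the dataset exactly).
#' @export
generate_dataset <- function(config, n) {
  validate_synth_config(config)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  pairs <- lapply(seq_len(n), function(i) generate_bscan(config, i))
  manifest <- list(
    config = unclass(config),
    n = n,
    item_seeds = vapply(pairs, `[[`, integer(1), "seed")
  )
  list(pairs = pairs, manifest = manifest)
}
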
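# Dataset readers and writers.
#
# Images are 8-bit grayscale PNG (or TIFF on input); label masks are 8-bit
# grayscale PNG whose raw byte values are the literal class ids 0..K-1, so
# reading and writing are exactly inverse operations.

#' Write / read a B-scan image
#'
#' @param image numeric matrix in `[0,1]`.
#' @param path PNG file path.
#' @export
write_bscan <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  clamp01(img)
}

#' Write / read a label mask
#'
#' @param mask integer matrix with values in `0:(n_classes-1)`.
#' @param path PNG file path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Save a dataset of pairs to an image/mask folder layout
#'
#' Writes `images/<stem>.png`, `masks/<stem>.png` and `manifest.json`.
#'
#' @param pairs list of `list(image, mask)` pairs.
#' @param dir output directory (created if needed).
#' @param manifest optional manifest list to record alongside.
#' @export
save_dataset <- function(pairs, dir, manifest = NULL) {
  img_dir <- file.path(dir, "images"); msk_dir <- file.path(dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pairs)) {
    stem <- sprintf("item_%04d", i)
    write_bscan(pairs[[i]]$image, file.path(img_dir, paste0(stem, ".png")))
    write_mask(pairs[[i]]$mask, file.path(msk_dir, paste0(stem, ".png")))
  }
  if (!is.null(manifest))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a dataset from an image/mask folder layout
#'
#' Every image must have exactly one mask with the same file stem and the
#' same pixel dimensions; pairs are returned in lexicographic stem order.
#'
#' @param dir dataset directory containing `images/` and `masks/`, or a list
#'   with `images_dir` and `masks_dir`.
#' @param n_classes labels must be `< n_classes`.
#' @return list of `list(image, mask)` pairs.
#' @export
load_dataset <- function(dir, n_classes = 5L) {
  if (is.list(dir)) {
    img_dir <- dir$images_dir; msk_dir <- dir$masks_dir
  } else {
    img_dir <- file.path(dir, "images"); msk_dir <- file.path(dir, "masks")
  }
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("dataset directories do not exist", call. = FALSE)
  imgs <- sort(list.files(img_dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
  msks <- sort(list.files(msk_dir, pattern = "\\.png$", ignore.case = TRUE))
  istem <- tools::file_path_sans_ext(imgs)
  mstem <- tools::file_path_sans_ext(msks)
  orphan <- setdiff(istem, mstem)
  if (length(orphan) > 0)
    stop(sprintf("image without mask: %s", orphan[1]), call. = FALSE)
  orphan <- setdiff(mstem, istem)
  if (length(orphan) > 0)
    stop(sprintf("mask without image: %s", orphan[1]), call. = FALSE)
  lapply(seq_along(imgs), function(i) {
    img <- read_bscan(file.path(img_dir, imgs[i]))
    msk <- read_mask(file.path(msk_dir, paste0(istem[i], ".png")))
    if (!all(dim(img) == dim(msk)))
      stop(sprintf("dimension mismatch between image and mask for '%s'",
                   istem[i]), call. = FALSE)
    if (any(msk < 0 | msk >= n_classes))
      stop(sprintf("mask '%s' contains a label outside 0..%d",
                   paste0(istem[i], ".png"), n_classes - 1L), call. = FALSE)
    list(image = img, mask = msk, stem = istem[i])
  })
}
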
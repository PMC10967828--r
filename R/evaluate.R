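#' Pixel confusion matrix
#'
#' @param pred,truth integer label matrices/arrays of identical shape with
#'   values in `0:(K-1)`.
#' @param K number of classes.
#' @return K x K matrix of pixel counts; rows are truth, columns prediction.
#' @export
confusion_matrix <- function(pred, truth, K) {
  if (!all(dim(pred) == dim(truth)) || length(pred) != length(truth))
    stop("prediction and truth shapes differ", call. = FALSE)
  p <- as.integer(pred); t <- as.integer(truth)
  if (any(p < 0L | p >= K) || any(t < 0L | t >= K))
    stop("label out of range for K classes", call. = FALSE)
  matrix(tabulate(t * K + p + 1L, nbins = K * K), K, K, byrow = TRUE)
}

#' Per-class overlap metrics from a confusion matrix
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 and Dice
#' `2TP/(2TP+FN+FP)`.  When a denominator is zero the metric is reported as
#' 0 and the class is flagged degenerate.
#'
#' @param cm K x K confusion matrix (rows truth, columns prediction).
#' @return data frame with one row per class.
#' @export
per_class_metrics <- function(cm) {
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  dice <- safe(2 * tp, 2 * tp + fn + fp)
  data.frame(class = seq_len(K) - 1L, tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall, f1 = f1, dice = dice,
             degenerate = (tp + fp + fn) == 0)
}

#' Boundary intersection-over-union
#'
#' For each class, the boundary band is the set of pixels within `band_px`
#' (Chebyshev distance) of a pixel of that class that touches a different
#' class; BIoU is the IoU of the predicted and true bands.  The mean is
#' taken over classes present in the truth.  A class whose bands are both
#' empty (it has no boundary in either mask) scores 1; a class with exactly
#' one empty band scores 0.
#'
#' @param pred,truth integer label matrices.
#' @param band_px band half-width in pixels.
#' @param K number of classes (default: maximum label + 1).
#' @return list with `per_class` (NA for classes absent from truth) and
#'   `mean`.
#' @export
boundary_iou <- function(pred, truth, band_px = 2L, K = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth shapes differ", call. = FALSE)
  if (is.null(K)) K <- max(pred, truth) + 1L
  per <- rep(NA_real_, K)
  for (k in seq_len(K) - 1L) {
    if (!any(truth == k)) next
    bt <- class_boundary_band(truth, k, band_px)
    bp <- class_boundary_band(pred, k, band_px)
    nt <- sum(bt); np <- sum(bp)
    per[k + 1L] <- if (nt == 0 && np == 0) 1
    else if (nt == 0 || np == 0) 0
    else sum(bt & bp) / sum(bt | bp)
  }
  list(per_class = per, mean = mean(per, na.rm = TRUE))
}

class_boundary_band <- function(mask, k, band_px) {
  d <- dim(mask)
  is_k <- mask == k
  b <- matrix(FALSE, d[1], d[2])
  if (d[1] > 1) {
    df <- is_k[-1, , drop = FALSE] != is_k[-d[1], , drop = FALSE]
    b[-1, ] <- b[-1, ] | (df & is_k[-1, , drop = FALSE])
    b[-d[1], ] <- b[-d[1], ] | (df & is_k[-d[1], , drop = FALSE])
  }
  if (d[2] > 1) {
    df <- is_k[, -1, drop = FALSE] != is_k[, -d[2], drop = FALSE]
    b[, -1] <- b[, -1] | (df & is_k[, -1, drop = FALSE])
    b[, -d[2]] <- b[, -d[2]] | (df & is_k[, -d[2], drop = FALSE])
  }
  dilate_chebyshev(b, band_px)
}

#' Chance-corrected agreement statistics from a confusion matrix
#'
#' Computes overall accuracy, Hamming loss (`1 - accuracy`), Cohen's kappa
#' (expected agreement from the marginals), Bennett's S (expected agreement
#' `1/K`), Bangdiwala's B in its marginal-product form
#' `sum(n_ii^2) / sum(r_i * c_i)`, the adjusted Rand index by pair counting
#' on the K x K contingency table, and the chi-squared degrees of freedom
#' `(K-1)^2`.
#'
#' @param cm K x K confusion matrix with positive total.
#' @return named list of statistics, each carrying a strength-of-agreement
#'   label where a conventional banding exists (Landis-Koch for kappa and S,
#'   Bangdiwala's own bands for B, Fleiss-style bands for ARI).
#' @export
agreement_stats <- function(cm) {
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix is empty", call. = FALSE)
  K <- nrow(cm)
  po <- sum(diag(cm)) / n
  r <- rowSums(cm); cl <- colSums(cm)
  pe <- sum(r * cl) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  bennett_s <- (po - 1 / K) / (1 - 1 / K)
  bangdiwala_b <- sum(diag(cm)^2) / sum(r * cl)
  # ARI by pair counting
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(cm))
  sum_a <- sum(ch2(r)); sum_b <- sum(ch2(cl))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == expected) 1 else (sum_ij - expected) / (max_idx - expected)
  list(accuracy = po,
       hamming_loss = 1 - po,
       kappa = structure(kappa, soa = soa_landis_koch(kappa)),
       bennett_s = structure(bennett_s, soa = soa_landis_koch(bennett_s)),
       bangdiwala_b = structure(bangdiwala_b, soa = soa_bangdiwala(bangdiwala_b)),
       ari = structure(ari, soa = soa_fleiss(ari)),
       chi_squared_df = (K - 1)^2)
}

# Landis & Koch (1977) bands
soa_landis_koch <- function(v) {
  if (v < 0) "Poor" else if (v <= 0.2) "Slight" else if (v <= 0.4) "Fair"
  else if (v <= 0.6) "Moderate" else if (v <= 0.8) "Substantial"
  else "Almost Perfect"
}
# Munoz & Bangdiwala (1997) bands for B
soa_bangdiwala <- function(v) {
  if (v < 0.16) "Poor" else if (v < 0.36) "Weak" else if (v < 0.61) "Moderate"
  else if (v < 0.81) "Good" else if (v < 0.93) "Very Good" else "Excellent"
}
# Fleiss-style banding applied to ARI
soa_fleiss <- function(v) {
  if (v < 0.4) "Poor" else if (v < 0.75) "Intermediate to Good" else "Excellent"
}

#' Evaluate a model on a dataset
#'
#' Runs inference on every pair, pools one global confusion matrix over all
#' pixels (micro aggregation) for the headline statistics, and also reports
#' the per-image macro mean Dice.
#'
#' @param model an `octseg_model` or `octseg_fit`.
#' @param dataset non-empty list of `list(image, mask)` pairs.
#' @param band_px boundary-band half-width for BIoU.
#' @return object of class `octseg_report`: `per_class` data frame,
#'   `aggregate` list and the pooled confusion matrix.
#' @export
evaluate_model <- function(model, dataset, band_px = 2L) {
  if (inherits(model, "octseg_fit")) model <- model$model
  if (length(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  K <- model$config$n_classes
  cm <- matrix(0, K, K)
  per_image_dice <- numeric(length(dataset))
  biou_per <- matrix(NA_real_, length(dataset), K)
  for (i in seq_along(dataset)) {
    p <- dataset[[i]]
    pred <- predict(model, p$image)
    cmi <- confusion_matrix(pred, p$mask, K)
    cm <- cm + cmi
    per_image_dice[i] <- mean(per_class_metrics(cmi)$dice)
    biou_per[i, ] <- boundary_iou(pred, p$mask, band_px, K)$per_class
  }
  pcm <- per_class_metrics(cm)
  ag <- agreement_stats(cm)
  biou_class <- colMeans(biou_per, na.rm = TRUE)
  pcm$biou <- ifelse(is.nan(biou_class), NA_real_, biou_class)
  aggregate <- c(list(mean_dice = mean(pcm$dice),
                      mean_biou = mean(pcm$biou, na.rm = TRUE),
                      macro_image_dice = mean(per_image_dice)),
                 ag)
  structure(list(per_class = pcm, aggregate = aggregate, confusion = cm,
                 n_images = length(dataset), band_px = band_px),
            class = "octseg_report")
}

#' Serialise an evaluation report
#'
#' Writes the report as JSON (everything) and optionally CSV (per-class
#' table).
#'
#' @param report an `octseg_report`.
#' @param json_path,csv_path output paths; NULL skips that format.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    agg <- lapply(report$aggregate, function(x) {
      if (!is.null(attr(x, "soa")))
        list(value = as.numeric(x), soa = attr(x, "soa"))
      else as.numeric(x)
    })
    jsonlite::write_json(
      list(per_class = report$per_class, aggregate = agg,
           confusion = report$confusion, n_images = report$n_images),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) write.csv(report$per_class, csv_path, row.names = FALSE)
  invisible(report)
}
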
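#' Predict segmentation masks
#'
#' @param object an `octseg_model`.
#' @param images a single image matrix, an H x W x N array, or a list of
#'   matrices (all sized to the model's input shape).
#' @param type `"class"` for integer label masks, `"prob"` for per-pixel
#'   class probabilities.
#' @param batch_size images per forward pass.
#' @param ... unused.
#' @return for a single image, a label matrix (or H x W x K probability
#'   array); otherwise a list of them.
#' @export
predict.octseg_model <- function(object, images, type = c("class", "prob"),
                                 batch_size = 4L, ...) {
  type <- match.arg(type)
  single <- FALSE
  if (is.matrix(images)) {
    images <- list(images)
    single <- TRUE
  } else if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  }
  out <- vector("list", length(images))
  idx <- seq_along(images)
  for (s in split(idx, ceiling(idx / batch_size))) {
    d <- dim(images[[s[1]]])
    x <- array(0, c(d[1], d[2], 1L, length(s)))
    for (i in seq_along(s)) x[, , 1, i] <- images[[s[i]]]
    fw <- net_forward(object, x, train = FALSE)
    for (i in seq_along(s)) {
      out[[s[i]]] <- if (type == "class")
        hard_labels(fw$probs[, , , i, drop = FALSE])[, , 1]
      else array(fw$probs[, , , i], dim(fw$probs)[1:3])
    }
  }
  if (single) out[[1]] else out
}

#' @export
predict.octseg_fit <- function(object, images, ...) {
  predict(object$model, images, ...)
}

#' @export
print.octseg_model <- function(x, ...) {
  s <- architecture_summary(x)
  cat(sprintf("Hybrid attention U-Net (variant '%s'%s)\n", s$variant,
              if (x$fitted) ", fitted" else ""))
  cat(sprintf("  stages: %d encoder + 1 base + %d decoder, channels %s\n",
              s$n_encoder_stages, s$n_decoder_stages,
              paste(s$channels, collapse = "-")))
  cat(sprintf("  attention: %d edge + %d spatial (skips: %s)\n",
              s$n_edge_attention, s$n_spatial_attention,
              paste(s$skip_attention, collapse = " ")))
  cat(sprintf("  input %dx%d, %d classes, %s parameters\n",
              s$input_shape[1], s$input_shape[2], s$n_classes,
              format(s$n_parameters, big.mark = ",")))
  invisible(x)
}

#' @export
summary.octseg_model <- function(object, ...) architecture_summary(object)

#' @export
print.octseg_fit <- function(x, ...) {
  print(x$model)
  h <- x$history
  cat(sprintf("Trained %d epochs; best epoch %d (val Dice %.4f, val loss %.4f)\n",
              nrow(h), x$best_epoch, h$val_dice[x$best_epoch],
              h$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.octseg_fit <- function(object, ...) {
  list(architecture = architecture_summary(object$model),
       epochs = nrow(object$history),
       best_epoch = object$best_epoch,
       final = as.list(tail(object$history, 1)),
       events = object$events)
}

#' Plot the training history
#'
#' Validation and training loss (left axis) and validation mean Dice (right
#' axis) against epoch.
#'
#' @param x an `octseg_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.octseg_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$val_loss, type = "l", col = "firebrick",
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(h$val_loss, h$train_loss)), ...)
  graphics::lines(h$epoch, h$train_loss, col = "grey40", lty = 2)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$val_dice, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("val mean Dice", side = 4, line = 2.5)
  graphics::legend("right", legend = c("val loss", "train loss", "val Dice"),
                   col = c("firebrick", "grey40", "steelblue"),
                   lty = c(1, 2, 1), bty = "n")
  invisible(x)
}

#' @export
print.octseg_report <- function(x, ...) {
  cat(sprintf("Segmentation report over %d image(s)\n", x$n_images))
  print(x$per_class[, c("class", "precision", "recall", "f1", "dice", "biou")],
        row.names = FALSE, digits = 4)
  a <- x$aggregate
  cat(sprintf("mean Dice %.4f | mean BIoU %.4f | accuracy %.4f\n",
              a$mean_dice, a$mean_biou, a$accuracy))
  cat(sprintf("kappa %.4f (%s) | Bennett S %.4f (%s) | Bangdiwala B %.4f (%s)\n",
              a$kappa, attr(a$kappa, "soa"), a$bennett_s,
              attr(a$bennett_s, "soa"), a$bangdiwala_b,
              attr(a$bangdiwala_b, "soa")))
  cat(sprintf("ARI %.4f (%s) | Hamming loss %.4f | chi-squared DF %d\n",
              a$ari, attr(a$ari, "soa"), a$hamming_loss,
              as.integer(a$chi_squared_df)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Weights, batch-norm state and configuration are serialised with
#' [saveRDS()].
#'
#' @param model an `octseg_model` or `octseg_fit`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, c("octseg_model", "octseg_fit")))
    stop(sprintf("'%s' is not an octseg checkpoint", path), call. = FALSE)
  m
}
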
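#' Training protocol configuration
#'
#' Defaults encode the training protocol: a composite loss with weights
#' `(1, 0, 1)` on cross-entropy, Dice loss and boundary cross-entropy;
#' AdaBound with initial learning rate 0.001 (final rate 0.1, bound speed
#' 1e-3); the learning rate multiplied by 0.1 when the validation loss has
#' not decreased for five consecutive epochs; early stopping after ten
#' stagnant epochs; checkpoint restoration every 100 epochs; a ceiling of
#' 300 epochs; batches of four images; 6-fold cross-validation.
#'
#' @param loss_weights numeric `(alpha, beta, gamma)` weighting plain
#'   cross-entropy, Dice loss and boundary-band cross-entropy.
#' @param initial_lr,final_lr,adabound_gamma AdaBound parameters.
#' @param batch_size images per gradient step.
#' @param lr_factor,lr_patience plateau reduction factor and patience.
#' @param early_stop_patience epochs of stagnation before stopping.
#' @param checkpoint_interval epochs between weight-restoration checkpoints.
#' @param max_epochs training ceiling.
#' @param k_folds folds for cross-validation.
#' @param boundary_band half-width in pixels of the label-boundary band used
#'   by the third loss term.
#' @param seed master RNG seed for shuffling and initialisation.
#' @return object of class `train_config`.
#' @export
train_config <- function(loss_weights = c(1, 0, 1),
                         initial_lr = 0.001, final_lr = 0.1,
                         adabound_gamma = 1e-3,
                         batch_size = 4L,
                         lr_factor = 0.1, lr_patience = 5L,
                         early_stop_patience = 10L,
                         checkpoint_interval = 100L,
                         max_epochs = 300L,
                         k_folds = 6L,
                         boundary_band = 2L,
                         seed = 1L) {
  if (any(loss_weights < 0)) stop_config("loss_weights", "must be >= 0")
  if (lr_factor <= 0 || lr_factor >= 1)
    stop_config("lr_factor", "must lie strictly between 0 and 1")
  for (f in c("lr_patience", "early_stop_patience", "checkpoint_interval",
              "max_epochs", "batch_size"))
    if (get(f) <= 0) stop_config(f, "must be > 0")
  structure(list(loss_weights = loss_weights, initial_lr = initial_lr,
                 final_lr = final_lr, adabound_gamma = adabound_gamma,
                 batch_size = as.integer(batch_size),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 max_epochs = as.integer(max_epochs),
                 k_folds = as.integer(k_folds),
                 boundary_band = as.integer(boundary_band),
                 seed = as.integer(seed)),
            class = "train_config")
}

IMPROVE_TOL <- 1e-6  # strict-decrease tolerance shared by scheduler and stopper

#' Pixels within a band of a label boundary
#'
#' A boundary pixel is one whose 4-neighbourhood contains a different label;
#' the band is its Chebyshev dilation by `band` pixels.
#'
#' @param mask integer label matrix.
#' @param band half-width in pixels.
#' @return logical matrix.
#' @export
boundary_band_mask <- function(mask, band = 2L) {
  d <- dim(mask)
  b <- matrix(FALSE, d[1], d[2])
  if (d[1] > 1) {
    df <- mask[-1, , drop = FALSE] != mask[-d[1], , drop = FALSE]
    b[-1, ] <- b[-1, ] | df
    b[-d[1], ] <- b[-d[1], ] | df
  }
  if (d[2] > 1) {
    df <- mask[, -1, drop = FALSE] != mask[, -d[2], drop = FALSE]
    b[, -1] <- b[, -1] | df
    b[, -d[2]] <- b[, -d[2]] | df
  }
  dilate_chebyshev(b, band)
}

dilate_chebyshev <- function(b, r) {
  if (r <= 0) return(b)
  d <- dim(b)
  out <- matrix(FALSE, d[1], d[2])
  for (di in -r:r) for (dj in -r:r) {
    r0 <- max(1, 1 - di); r1 <- min(d[1], d[1] - di)
    c0 <- max(1, 1 - dj); c1 <- min(d[2], d[2] - dj)
    if (r1 < r0 || c1 < c0) next        # shift exceeds the mask extent
    sr <- r0:r1; sc <- c0:c1
    out[sr + di, sc + dj] <- out[sr + di, sc + dj] | b[sr, sc]
  }
  out
}

# probabilities (H,W,K,N), masks (H,W,N) 0-based; returns loss + dlogits
composite_loss_grad <- function(probs, masks, weights, boundary_band = 2L,
                                need_grad = TRUE) {
  d <- dim(probs); K <- d[3]; N <- d[4]
  npix <- d[1] * d[2] * N
  m3 <- array(masks, c(d[1], d[2], N))
  if (any(m3 < 0 | m3 >= K)) stop("mask contains an invalid class id", call. = FALSE)
  # one-hot as linear indices into probs
  hw <- d[1] * d[2]
  pix <- seq_len(hw)
  idx_true <- unlist(lapply(seq_len(N), function(n) {
    (n - 1) * hw * K + as.vector(m3[, , n]) * hw + pix
  }), use.names = FALSE)
  p_true <- pmax(probs[idx_true], 1e-12)
  ce <- -mean(log(p_true))

  bmask <- vapply(seq_len(N),
                  function(n) boundary_band_mask(matrix(m3[, , n], d[1], d[2]),
                                                 boundary_band),
                  logical(hw))
  nb <- sum(bmask)
  edge_ce <- if (nb > 0) -sum(log(p_true)[as.vector(bmask)]) / nb else 0

  eps <- 1e-6
  onehot_sums <- numeric(K); inter <- numeric(K); psums <- numeric(K)
  for (k in seq_len(K)) {
    tk <- m3 == (k - 1)
    pk <- probs[, , k, , drop = FALSE]
    inter[k] <- sum(pk[tk])
    psums[k] <- sum(pk)
    onehot_sums[k] <- sum(tk)
  }
  dice_k <- (2 * inter + eps) / (psums + onehot_sums + eps)
  dice_loss <- 1 - mean(dice_k)

  loss <- weights[1] * ce + weights[2] * dice_loss + weights[3] * edge_ce
  components <- c(ce = ce, dice_loss = dice_loss, edge_ce = edge_ce)
  if (!need_grad)
    return(list(loss = loss, components = components))

  # gradient w.r.t. logits (pre-softmax)
  onehot <- array(0, d)
  onehot[idx_true] <- 1
  dlogits <- array(0, d)
  if (weights[1] > 0)
    dlogits <- dlogits + weights[1] * (probs - onehot) / npix
  if (weights[3] > 0 && nb > 0) {
    bm4 <- array(rep(as.double(bmask), times = 1)[rep_channel_index(d)], d)
    dlogits <- dlogits + weights[3] * bm4 * (probs - onehot) / nb
  }
  if (weights[2] > 0) {
    dprob <- array(0, d)
    for (k in seq_len(K)) {
      tk <- (m3 == (k - 1))
      B <- psums[k] + onehot_sums[k] + eps
      # d dice_k / d p_k(x) = (2*t(x)*B - (2*inter+eps)) / B^2
      dd <- (2 * as.double(tk) * B - (2 * inter[k] + eps)) / (B * B)
      dprob[, , k, ] <- -dd / K
    }
    rowsum_term <- sum_channels(dprob * probs)
    dlogits <- dlogits + weights[2] * probs * sweep_channel_sub(dprob, rowsum_term)
  }
  list(loss = loss, components = components, dlogits = dlogits)
}

#' Composite segmentation loss
#'
#' `alpha * CE + beta * DiceLoss + gamma * EdgeCE`, where CE is mean
#' per-pixel sparse categorical cross-entropy, DiceLoss is one minus the mean
#' soft Dice over classes, and EdgeCE is cross-entropy restricted to pixels
#' within `boundary_band` pixels of a ground-truth label boundary.
#'
#' @param probs per-pixel class probabilities: H x W x K (or 4D with a batch
#'   axis).
#' @param mask integer label matrix (or H x W x N array), values in `0:(K-1)`.
#' @param weights numeric `(alpha, beta, gamma)`.
#' @param boundary_band boundary band half-width in pixels.
#' @return scalar loss with the three components as attribute `"components"`.
#' @export
composite_loss <- function(probs, mask, weights = c(1, 0, 1),
                           boundary_band = 2L) {
  p4 <- if (length(dim(probs)) == 3L) array(probs, c(dim(probs), 1L)) else probs
  d <- dim(p4)
  m3 <- array(as.integer(mask), c(d[1], d[2], d[4]))
  if (!all(dim(m3)[1:2] == d[1:2]) ||
      length(mask) != d[1] * d[2] * d[4])
    stop("probability and mask shapes differ", call. = FALSE)
  r <- composite_loss_grad(p4, m3, weights, boundary_band, need_grad = FALSE)
  structure(r$loss, components = r$components)
}

# number of trailing epochs with no strict improvement over best-so-far;
# `reset_at` marks epochs where a reduction consumed the counter
stagnation_trace <- function(val_losses, patience) {
  best <- Inf
  count <- 0L
  reductions <- integer(0)
  counts <- integer(length(val_losses))
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best - IMPROVE_TOL) {
      best <- val_losses[i]
      count <- 0L
    } else {
      count <- count + 1L
    }
    if (count >= patience) {
      reductions <- c(reductions, i)
      count <- 0L
    }
    counts[i] <- count
  }
  list(reductions = reductions, counts = counts)
}

#' Plateau learning-rate schedule
#'
#' Replays the validation-loss history: the rate is multiplied by
#' `lr_factor` each time `lr_patience` consecutive epochs fail to improve
#' (strictly decrease, tolerance 1e-6) on the best loss so far; the
#' stagnation counter resets on improvement and after each reduction.
#'
#' @param history data frame (or list) with a `val_loss` column, one row per
#'   completed epoch.
#' @param config a [train_config()].
#' @return the learning rate in force after the recorded epochs.
#' @export
lr_scheduler_step <- function(history, config = train_config()) {
  vl <- history_losses(history)
  if (length(vl) == 0L) stop("history is empty", call. = FALSE)
  tr <- stagnation_trace(vl, config$lr_patience)
  config$initial_lr * config$lr_factor^length(tr$reductions)
}

#' Early-stopping decision
#'
#' TRUE exactly when the last `early_stop_patience` epochs contain no strict
#' improvement over the best validation loss seen before them.
#'
#' @inheritParams lr_scheduler_step
#' @export
early_stopping_check <- function(history, config = train_config()) {
  vl <- history_losses(history)
  if (length(vl) == 0L) stop("history is empty", call. = FALSE)
  best <- Inf
  count <- 0L
  for (v in vl) {
    if (v < best - IMPROVE_TOL) {
      best <- v
      count <- 0L
    } else count <- count + 1L
  }
  count >= config$early_stop_patience
}

history_losses <- function(history) {
  if (is.data.frame(history)) history$val_loss
  else if (is.list(history) && !is.null(history$val_loss)) history$val_loss
  else as.numeric(history)
}

#' Checkpoint policy
#'
#' At every multiple of `checkpoint_interval` epochs the weights of the best
#' epoch so far are restored before training continues: best by highest
#' validation Dice, ties broken by lowest validation loss.  Training never
#' exceeds `max_epochs`.
#'
#' @param history data frame with `val_loss` and `val_dice` columns.
#' @param config a [train_config()].
#' @return list with `action` (`"restore"` or `"none"`), `restore_epoch`
#'   (NA unless restoring) and `stop` (TRUE once `max_epochs` is reached).
#' @export
checkpoint_policy <- function(history, config = train_config()) {
  epoch <- nrow(as.data.frame(history))
  stop_now <- epoch >= config$max_epochs
  if (epoch %% config$checkpoint_interval != 0L)
    return(list(action = "none", restore_epoch = NA_integer_, stop = stop_now))
  h <- as.data.frame(history)
  best <- order(-h$val_dice, h$val_loss)[1]
  list(action = "restore", restore_epoch = as.integer(best), stop = stop_now)
}

#' Seeded k-fold split
#'
#' @param n_items number of items.
#' @param k folds (`2 <= k <= n_items`).
#' @param seed RNG seed.
#' @return list of `k` lists with disjoint `train` and `val` index vectors;
#'   validation folds partition `1:n_items` with sizes differing by at most
#'   one.
#' @export
kfold_split <- function(n_items, k = 6L, seed = 1L) {
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  if (n_items < k) stop("'n_items' must be >= k", call. = FALSE)
  perm <- with_seed(derive_seed(seed, 0L, 23L), sample.int(n_items))
  sizes <- rep(n_items %/% k, k)
  extra <- n_items %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    val <- sort(perm[starts[i]:ends[i]])
    list(train = sort(setdiff(seq_len(n_items), val)), val = val)
  })
}

# stack a list of pairs into network tensors
batch_tensors <- function(pairs, idx) {
  d <- dim(pairs[[idx[1]]]$image)
  N <- length(idx)
  x <- array(0, c(d[1], d[2], 1L, N))
  y <- array(0L, c(d[1], d[2], N))
  for (i in seq_along(idx)) {
    x[, , 1, i] <- pairs[[idx[i]]]$image
    y[, , i] <- pairs[[idx[i]]]$mask
  }
  list(x = x, y = y)
}

validate_pass <- function(model, pairs, idx, config) {
  tot_loss <- 0; npx <- 0
  K <- model$config$n_classes
  cm <- matrix(0, K, K)
  bs <- max(config$batch_size, 1L)
  for (s in split(idx, ceiling(seq_along(idx) / bs))) {
    b <- batch_tensors(pairs, s)
    fw <- net_forward(model, b$x, train = FALSE)
    lo <- composite_loss_grad(fw$probs, b$y, config$loss_weights,
                              config$boundary_band, need_grad = FALSE)
    tot_loss <- tot_loss + lo$loss * length(s)
    pred <- hard_labels(fw$probs)
    cm <- cm + confusion_matrix(pred, b$y, K)
  }
  pcm <- per_class_metrics(cm)
  list(loss = tot_loss / length(idx), dice = mean(pcm$dice), cm = cm)
}

hard_labels <- function(probs) {
  d <- dim(probs)
  lab <- array(0L, c(d[1], d[2], d[4]))
  best <- probs[, , 1, , drop = FALSE]
  for (k in 2:d[3]) {
    pk <- probs[, , k, , drop = FALSE]
    upd <- pk > best
    best[upd] <- pk[upd]
    lab[array(upd, dim(lab))] <- k - 1L
  }
  lab
}

#' Train a model on image/mask pairs
#'
#' Runs the full protocol: seeded shuffling into batches, AdaBound updates,
#' per-epoch validation loss and mean Dice, plateau learning-rate reduction,
#' early stopping, checkpoint restoration at 100-epoch marks, and weight
#' initialisation from scratch.  At the end the weights of the best
#' validation-Dice epoch are restored.
#'
#' @param model an `octseg_model` from [build_model()].
#' @param dataset list of `list(image, mask)` pairs (preprocessed, image
#'   dimensions equal to `model$config$input_shape`).
#' @param config a [train_config()].
#' @param val either a fraction in (0,1) (seeded random holdout, default
#'   0.2) or an integer vector of validation indices into `dataset`.
#' @param verbose print one line per epoch.
#' @return object of class `octseg_fit`: the trained model, the epoch
#'   history data frame, and bookkeeping of checkpoint events.
#' @export
train_model <- function(model, dataset, config = train_config(), val = 0.2,
                        verbose = FALSE) {
  if (length(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  n <- length(dataset)
  if (length(val) == 1L && val > 0 && val < 1) {
    val_idx <- with_seed(derive_seed(config$seed, 1L, 29L),
                         sort(sample.int(n, max(1L, round(val * n)))))
  } else val_idx <- sort(as.integer(val))
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0L) stop("no training items left", call. = FALSE)

  opt <- adabound_init(model$params, lr = config$initial_lr,
                       final_lr = config$final_lr,
                       gamma = config$adabound_gamma)
  lr <- config$initial_lr
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_dice = numeric(0),
                        lr = numeric(0))
  best_dice <- -Inf; best_loss <- Inf
  best_dice_snap <- NULL; best_epoch <- NA_integer_
  events <- list()

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, epoch, 31L),
                     sample(train_idx))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bidx in batches) {
      b <- batch_tensors(dataset, bidx)
      fw <- net_forward(model, b$x, train = TRUE)
      model$bn_state <- fw$bn_state
      lo <- composite_loss_grad(fw$probs, b$y, config$loss_weights,
                                config$boundary_band)
      if (!is.finite(lo$loss))
        stop(sprintf("training aborted: non-finite loss at epoch %d", epoch),
             call. = FALSE)
      grads <- net_backward(model, fw$cache, lo$dlogits)
      st <- adabound_step(model$params, grads, opt, lr)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + lo$loss * length(bidx)
    }
    ep_loss <- ep_loss / length(ord)
    vp <- validate_pass(model, dataset, val_idx, config)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = vp$loss, val_dice = vp$dice,
                                lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f  lr %.2g",
                      epoch, ep_loss, vp$loss, vp$dice, lr))
    if (vp$dice > best_dice ||
        (vp$dice == best_dice && vp$loss < best_loss)) {
      best_dice <- max(vp$dice, best_dice)
      best_dice_snap <- list(params = model$params, bn = model$bn_state,
                             epoch = epoch)
      best_epoch <- epoch
    }
    best_loss <- min(best_loss, vp$loss)

    cp <- checkpoint_policy(history, config)
    if (cp$action == "restore" && !is.null(best_dice_snap)) {
      model$params <- best_dice_snap$params
      model$bn_state <- best_dice_snap$bn
      events <- c(events, list(list(epoch = epoch, action = "restore",
                                    restored = best_dice_snap$epoch)))
    }
    if (early_stopping_check(history, config)) {
      events <- c(events, list(list(epoch = epoch, action = "early_stop")))
      break
    }
    lr <- lr_scheduler_step(history, config)
    if (cp$stop) break
  }
  if (!is.null(best_dice_snap)) {
    model$params <- best_dice_snap$params
    model$bn_state <- best_dice_snap$bn
  }
  model$fitted <- TRUE
  structure(list(model = model, history = history, events = events,
                 best_epoch = best_epoch, config = config,
                 val_idx = val_idx),
            class = "octseg_fit")
}

#' k-fold cross-validation
#'
#' Trains one model per fold (fresh weights each time) and evaluates it on
#' the held-out fold.
#'
#' @param dataset list of `list(image, mask)` pairs.
#' @param model_cfg a [model_config()].
#' @param config a [train_config()]; `config$k_folds` folds are used.
#' @param verbose passed to [train_model()].
#' @return list with per-fold fits and a data frame of held-out mean Dice.
#' @export
cross_validate <- function(dataset, model_cfg = model_config(),
                           config = train_config(), verbose = FALSE) {
  folds <- kfold_split(length(dataset), config$k_folds, config$seed)
  res <- lapply(seq_along(folds), function(i) {
    model <- build_model(model_cfg, seed = derive_seed(config$seed, i, 37L))
    fit <- train_model(model, dataset, config, val = folds[[i]]$val,
                       verbose = verbose)
    rep <- evaluate_model(fit$model, dataset[folds[[i]]$val])
    list(fit = fit, report = rep)
  })
  summary <- data.frame(
    fold = seq_along(folds),
    mean_dice = vapply(res, function(r) r$report$aggregate$mean_dice, numeric(1)),
    mean_biou = vapply(res, function(r) r$report$aggregate$mean_biou, numeric(1)))
  list(folds = res, summary = summary)
}
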
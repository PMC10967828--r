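test_that("composite loss has the stated closed-form limits", {
  # perfect one-hot prediction: every term vanishes
  mask <- matrix(c(0L, 1L, 2L, 3L, 4L, 0L, 1L, 2L), 4, 2)
  K <- 5
  probs <- array(1e-15, c(4, 2, K))
  for (i in 1:4) for (j in 1:2) probs[i, j, mask[i, j] + 1] <- 1
  expect_lt(composite_loss(probs, mask, c(1, 0, 1)), 1e-10)
  # uniform prediction, CE only: loss = ln K
  uni <- array(1 / K, c(4, 2, K))
  expect_equal(as.numeric(composite_loss(uni, mask, c(1, 0, 0))), log(5),
               tolerance = 1e-12)
  expect_error(composite_loss(uni, mask + 10L, c(1, 0, 0)), "invalid class")
})

test_that("cross-entropy matches an independent per-pixel -log p sum", {
  set.seed(6)
  K <- 5
  mask <- matrix(sample(0:4, 48, TRUE), 8, 6)
  raw <- array(runif(8 * 6 * K), c(8, 6, K))
  probs <- raw / array(rep(apply(raw, c(1, 2), sum), K), dim(raw))
  got <- as.numeric(composite_loss(probs, mask, c(1, 0, 0)))
  want <- 0
  for (i in 1:8) for (j in 1:6)
    want <- want - log(probs[i, j, mask[i, j] + 1])
  expect_equal(got, want / 48, tolerance = 1e-12)
  # boundary term equals CE restricted to the band
  band <- boundary_band_mask(mask, 2L)
  want_edge <- 0
  for (i in 1:8) for (j in 1:6)
    if (band[i, j]) want_edge <- want_edge - log(probs[i, j, mask[i, j] + 1])
  got_full <- composite_loss(probs, mask, c(0, 0, 1))
  expect_equal(as.numeric(got_full), want_edge / sum(band), tolerance = 1e-12)
})

test_that("plateau schedule reduces by x0.1 after exactly five stagnant epochs", {
  cfg <- train_config()
  h <- data.frame(val_loss = c(2, 1.5, 1.2, 1.1, 1.05))
  expect_equal(lr_scheduler_step(h, cfg), 0.001)
  h <- data.frame(val_loss = c(1.0, 1.2, 1.1, 1.3, 1.0, 1.4))
  expect_equal(lr_scheduler_step(h, cfg), 0.001 * 0.1)
  # four stagnant epochs then an improvement: no reduction
  h <- data.frame(val_loss = c(1.0, 1.2, 1.1, 1.3, 1.2, 0.9))
  expect_equal(lr_scheduler_step(h, cfg), 0.001)
  # two full stagnation cycles compound the factor
  h <- data.frame(val_loss = c(1, rep(1.5, 10)))
  expect_equal(lr_scheduler_step(h, cfg), 0.001 * 0.01)
  expect_error(lr_scheduler_step(data.frame(val_loss = numeric(0)), cfg),
               "empty")
})

test_that("early stopping triggers after exactly ten stagnant epochs", {
  cfg <- train_config()
  expect_true(early_stopping_check(data.frame(val_loss = c(1, rep(1.2, 10))), cfg))
  expect_false(early_stopping_check(data.frame(val_loss = c(1, rep(1.2, 9))), cfg))
  expect_false(early_stopping_check(
    data.frame(val_loss = seq(2, 1, length.out = 20)), cfg))
})

test_that("checkpoints restore the best-Dice epoch at 100-epoch marks only", {
  cfg <- train_config()
  h <- data.frame(val_loss = runif(100, 1, 2), val_dice = runif(100, 0, 0.8))
  h$val_dice[73] <- 0.95
  cp <- checkpoint_policy(h, cfg)
  expect_equal(cp$action, "restore")
  expect_equal(cp$restore_epoch, 73L)
  expect_false(cp$stop)
  h150 <- rbind(h, h[1:50, ])
  expect_equal(checkpoint_policy(h150, cfg)$action, "none")
  h300 <- rbind(h, h, h)
  expect_true(checkpoint_policy(h300, cfg)$stop)
  # Dice tie: lowest loss wins
  h2 <- data.frame(val_loss = c(rep(1, 99), 2), val_dice = rep(0.5, 100))
  h2$val_loss[40] <- 0.2
  expect_equal(checkpoint_policy(h2, cfg)$restore_epoch, 40L)
})

test_that("k-fold splits partition the items with near-equal sizes", {
  f <- kfold_split(12, 6, seed = 3)
  expect_length(f, 6)
  vals <- lapply(f, `[[`, "val")
  expect_true(all(lengths(vals) == 2))
  expect_equal(sort(unlist(vals)), 1:12)
  for (i in 1:6) expect_length(intersect(f[[i]]$train, f[[i]]$val), 0)
  f13 <- kfold_split(13, 6, seed = 3)
  expect_equal(sort(lengths(lapply(f13, `[[`, "val")), decreasing = TRUE),
               c(3, 2, 2, 2, 2, 2))
  expect_identical(kfold_split(20, 6, seed = 9), kfold_split(20, 6, seed = 9))
  expect_error(kfold_split(4, 6), "n_items")
})

test_that("a short training run logs history and is seed-reproducible", {
  pairs <- tiny_synth(8, 32, 16, seed = 13)
  mc <- model_config(depth = 3, base_channels = 4, n_classes = 5,
                     input_shape = c(32L, 16L))
  tc <- train_config(max_epochs = 2, seed = 5)
  fit1 <- train_model(build_model(mc, seed = 5), pairs, tc)
  expect_s3_class(fit1, "octseg_fit")
  expect_equal(nrow(fit1$history), 2)
  expect_true(all(fit1$history$lr == 0.001))
  expect_true(all(is.finite(fit1$history$val_loss)))
  fit2 <- train_model(build_model(mc, seed = 5), pairs, tc)
  expect_equal(fit1$history, fit2$history)
  expect_error(train_model(build_model(mc), list(), tc), "empty")
})

test_that("adabound steps never exceed the moving bounds", {
  ns <- asNamespace("octseg")
  p <- list(w = matrix(0.5, 2, 2))
  st <- ns$adabound_init(p, lr = 0.001)
  g <- list(w = matrix(1e-8, 2, 2))       # tiny gradient: raw step explodes
  r <- ns$adabound_step(p, g, st, lr = 0.001)
  ub1 <- 0.1 * (1 + 1 / 1e-3)             # upper bound at t = 1
  expect_true(all(abs(r$params$w - p$w) <= ub1 * abs(r$state$m$w) + 1e-15))
  # learning rate never increases across a stagnating schedule replay
  cfg <- train_config()
  losses <- c(1, rep(1.1, 12))
  lrs <- vapply(seq_along(losses), function(i)
    lr_scheduler_step(data.frame(val_loss = losses[1:i]), cfg), numeric(1))
  expect_true(all(diff(lrs) <= 1e-15))
})
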
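test_that("confusion matrix counts match a nested-loop oracle", {
  pred <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 2L, 1L, 0L), 3, 3)
  truth <- matrix(c(0L, 1L, 1L, 1L, 0L, 2L, 2L, 2L, 0L), 3, 3)
  got <- confusion_matrix(pred, truth, 3)
  want <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    want[truth[i, j] + 1, pred[i, j] + 1] <- want[truth[i, j] + 1, pred[i, j] + 1] + 1
  expect_equal(got, want)
  expect_equal(sum(got), 9)
  same <- confusion_matrix(truth, truth, 3)
  expect_true(all(same[upper.tri(same) | lower.tri(same)] == 0))
  expect_error(confusion_matrix(pred, truth[1:2, ], 3), "differ")
  expect_error(confusion_matrix(pred + 5L, truth, 3), "out of range")
})

test_that("per-class metrics give the textbook values", {
  cm <- matrix(c(2, 1, 1, 6), 2, 2, byrow = TRUE)  # class 0: TP=2, FN=1, FP=1
  m <- per_class_metrics(cm)
  expect_equal(m$precision[1], 2 / 3)
  expect_equal(m$recall[1], 2 / 3)
  expect_equal(m$f1[1], 2 / 3)
  expect_equal(m$dice[1], 2 / 3)
  perfect <- per_class_metrics(diag(c(5, 3)))
  expect_true(all(perfect$dice == 1))
  # absent class: all-zero row/column -> flagged degenerate, metrics 0
  cm3 <- diag(c(4, 2, 0))
  m3 <- per_class_metrics(cm3)
  expect_true(m3$degenerate[3])
  expect_equal(m3$dice[3], 0)
  # F1 == Dice identically
  set.seed(8)
  for (i in 1:20) {
    m <- per_class_metrics(random_confusion(4))
    expect_equal(m$f1, m$dice, tolerance = 1e-12)
  }
})

test_that("agreement statistics hit their analytic anchors", {
  perfect <- diag(c(10, 20, 30, 5, 35))
  a <- agreement_stats(perfect)
  expect_equal(as.numeric(a$kappa), 1)
  expect_equal(as.numeric(a$bennett_s), 1)
  expect_equal(as.numeric(a$bangdiwala_b), 1)
  expect_equal(as.numeric(a$ari), 1)
  expect_equal(a$hamming_loss, 0)
  expect_equal(a$chi_squared_df, 16)
  expect_equal(attr(a$kappa, "soa"), "Almost Perfect")
  flat <- matrix(25, 2, 2)
  b <- agreement_stats(flat)
  expect_equal(as.numeric(b$kappa), 0)
  expect_equal(as.numeric(b$bennett_s), 0)
  expect_equal(as.numeric(b$ari), oracle_ari_pairs(flat), tolerance = 1e-10)
  expect_lt(abs(as.numeric(b$ari) - (-0.0102)), 5e-4)
  expect_error(agreement_stats(matrix(0, 2, 2)), "empty")
})

test_that("all agreement statistics match the brute-force oracle", {
  set.seed(23)
  for (i in 1:40) {
    K <- sample(2:5, 1)
    cm <- random_confusion(K, 8)
    if (sum(diag(cm)) == 0 || sum(cm) < 2) cm <- cm + diag(K)
    got <- agreement_stats(cm)
    want <- oracle_agreement(cm)
    expect_lt(abs(as.numeric(got$accuracy) - want$accuracy), 1e-10)
    expect_lt(abs(as.numeric(got$kappa) - want$kappa), 1e-10)
    expect_lt(abs(as.numeric(got$bennett_s) - want$bennett_s), 1e-10)
    expect_lt(abs(as.numeric(got$bangdiwala_b) - want$bangdiwala_b), 1e-10)
    expect_lt(abs(as.numeric(got$ari) - want$ari), 1e-10)
    expect_equal(got$chi_squared_df, want$df)
  }
})

test_that("statistics degrade as mass moves off the diagonal", {
  base <- diag(c(30, 30, 30))
  seq_k <- numeric(4); seq_ari <- numeric(4)
  for (s in 0:3) {
    cm <- base
    cm[1, 2] <- s * 8
    cm[1, 1] <- 30 - s * 8
    a <- agreement_stats(cm)
    seq_k[s + 1] <- as.numeric(a$kappa)
    seq_ari[s + 1] <- as.numeric(a$ari)
    expect_lte(as.numeric(a$kappa), a$accuracy + 1e-12)
  }
  expect_true(all(diff(seq_k) < 0))
  expect_true(all(diff(seq_ari) < 0))
})

test_that("boundary IoU agrees with a set-arithmetic oracle", {
  truth <- matrix(0L, 16, 16)
  truth[5:10, 5:10] <- 1L
  pred <- matrix(0L, 16, 16)
  pred[6:11, 6:11] <- 1L                       # same square shifted by 1 px
  got <- boundary_iou(pred, truth, band_px = 2L)
  for (k in 0:1) {
    bt <- oracle_band(truth, k, 2)
    bp <- oracle_band(pred, k, 2)
    expect_equal(got$per_class[k + 1], sum(bt & bp) / sum(bt | bp))
  }
  expect_equal(got$mean, mean(got$per_class))
  same <- boundary_iou(truth, truth, 2L)
  expect_true(all(same$per_class == 1))
  # disjoint bands score zero
  far_t <- matrix(0L, 20, 20); far_t[2:4, 2:4] <- 1L
  far_p <- matrix(0L, 20, 20); far_p[15:17, 15:17] <- 1L
  expect_equal(boundary_iou(far_p, far_t, 1L)$per_class[2], 0)
})

test_that("evaluate_model reports five classes and consistent aggregates", {
  pairs <- tiny_synth(3, 32, 16, seed = 19)
  m <- build_model(model_config(depth = 3, base_channels = 4,
                                input_shape = c(32L, 16L)), seed = 2)
  rep <- evaluate_model(m, pairs)
  expect_equal(nrow(rep$per_class), 5)
  expect_equal(rep$aggregate$mean_dice, mean(rep$per_class$dice))
  expect_equal(rep$aggregate$accuracy + rep$aggregate$hamming_loss, 1)
  expect_equal(sum(rep$confusion), 3 * 32 * 16)
  # JSON round trip preserves the numbers
  tf <- tempfile(fileext = ".json")
  write_report(rep, json_path = tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$aggregate$mean_dice, rep$aggregate$mean_dice)
  expect_equal(back$aggregate$kappa$value, as.numeric(rep$aggregate$kappa))
  expect_error(evaluate_model(m, list()), "empty")
})
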
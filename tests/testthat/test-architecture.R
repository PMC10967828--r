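test_that("edge response kills constants and matches dense convolution", {
  kers <- edge_kernels()
  expect_equal(sum(kers$transverse), 0)
  expect_equal(sum(kers$longitudinal), 0)
  const <- array(5, c(8, 8, 1))
  expect_equal(canny_edge_response(const), array(0, c(8, 8, 1)),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:25) {
    x <- matrix(rnorm(64), 8, 8)
    got <- canny_edge_response(x)
    want <- oracle_conv2d(x, kers$transverse) + oracle_conv2d(x, kers$longitudinal)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("edge response of a unit impulse is the flipped kernel sum", {
  x <- matrix(0, 9, 9); x[5, 5] <- 1
  got <- canny_edge_response(x)
  kers <- edge_kernels()
  ksum <- kers$transverse + kers$longitudinal
  # under true convolution the impulse response reproduces the kernel sum
  # (the internal correlation works on the pre-flipped kernels); the dense
  # oracle pins the same convention
  expect_equal(got[4:6, 4:6], ksum, tolerance = 1e-12)
  expect_equal(got[4:6, 4:6],
               oracle_conv2d(x, kers$transverse)[4:6, 4:6] +
                 oracle_conv2d(x, kers$longitudinal)[4:6, 4:6],
               tolerance = 1e-12)
  got[4:6, 4:6] <- 0
  expect_true(all(got == 0))
})

test_that("edge response of a vertical step lives on the step columns", {
  x <- matrix(0, 8, 8); x[, 5:8] <- 1
  got <- canny_edge_response(x)
  expect_true(all(abs(got[, c(1:3, 6:8)]) < 1e-12))
  expect_true(any(abs(got[, 4:5]) > 0))
})

test_that("edge response is equivariant under horizontal flip", {
  set.seed(5)
  x <- matrix(rnorm(96), 12, 8)
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  a <- flip(canny_edge_response(x))
  # the longitudinal kernel is antisymmetric in the column direction, the
  # transverse one symmetric: flipping negates the longitudinal response
  kers <- edge_kernels()
  b <- canny_edge_response(flip(x), kernels = list(
    transverse = kers$transverse, longitudinal = -kers$longitudinal))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("edge attention reduces to identity/zero at saturated gates", {
  set.seed(8)
  skip <- array(rnorm(4 * 8 * 8), c(8, 8, 4))
  gate <- array(rnorm(4 * 8 * 8), c(8, 8, 4))
  p <- ea_params(4, 4)
  enhanced <- skip + canny_edge_response(skip)
  p_ones <- p
  p_ones$psi$w[] <- 0; p_ones$psi$b[] <- 50     # sigmoid saturates at 1
  out <- edge_attention_block(skip, gate, p_ones)
  expect_equal(as.vector(out), as.vector(enhanced), tolerance = 1e-10)
  p_zero <- p
  p_zero$psi$w[] <- 0; p_zero$psi$b[] <- -50    # sigmoid saturates at 0
  out0 <- edge_attention_block(skip, gate, p_zero)
  expect_lt(max(abs(out0)), 1e-10)
})

test_that("edge attention matches a straight-line composition oracle", {
  set.seed(21)
  skip <- array(rnorm(4 * 8 * 8), c(8, 8, 4))
  gate <- array(rnorm(4 * 8 * 8), c(8, 8, 4))
  p <- ea_params(4, 4)
  got <- edge_attention_block(skip, gate, p)
  kers <- edge_kernels()
  enhanced <- array(0, dim(skip))
  for (c in 1:4)
    enhanced[, , c] <- skip[, , c] +
      oracle_conv2d(skip[, , c], kers$transverse) +
      oracle_conv2d(skip[, , c], kers$longitudinal)
  conv1 <- function(x, w, b) {
    cout <- dim(w)[4]
    out <- array(0, c(dim(x)[1], dim(x)[2], cout))
    for (i in seq_len(cout)) {
      acc <- matrix(b[i], dim(x)[1], dim(x)[2])
      for (c in seq_len(dim(x)[3])) acc <- acc + x[, , c] * w[1, 1, c, i]
      out[, , i] <- acc
    }
    out
  }
  q <- pmax(conv1(enhanced, p$ws$w, p$ws$b) + conv1(gate, p$wg$w, p$wg$b), 0)
  alpha <- 1 / (1 + exp(-conv1(q, p$psi$w, p$psi$b)[, , 1]))
  want <- enhanced * array(rep(alpha, 4), dim(skip))
  expect_lt(max(abs(got - want)), 1e-10)
  a <- attr(got, "alpha")
  expect_true(all(a >= 0 & a <= 1))
})

test_that("spatial attention follows the max/avg sigmoid construction", {
  z <- array(0, c(4, 4, 3))
  out <- spatial_attention_block(z)
  expect_equal(attr(out, "alpha"), matrix(0.5, 4, 4))  # sigmoid(0)
  expect_true(all(out == 0))
  x <- matrix(c(1, 3, 2, 4), 2, 2)            # single channel: max = avg = x
  out <- spatial_attention_block(x)
  sig <- 1 / (1 + exp(-x))
  expect_equal(attr(out, "alpha"), sig, tolerance = 1e-12)
  expect_equal(as.vector(out), as.vector(x * sig), tolerance = 1e-12)
  set.seed(3)
  r <- array(rnorm(5 * 6 * 7), c(6, 7, 5))
  a <- attr(spatial_attention_block(r), "alpha")
  expect_true(all(a > 0 & a < 1))
  # multi-channel oracle
  mx <- apply(r, c(1, 2), max); av <- apply(r, c(1, 2), mean)
  want <- (1 / (1 + exp(-mx)) + 1 / (1 + exp(-av))) / 2
  expect_equal(a, want, tolerance = 1e-12)
})

test_that("residual skip pooling zeroes exactly the argmax per window", {
  r <- residual_skip(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(as.vector(r$pooled), 4)
  expect_equal(matrix(r$residual, 2, 2), matrix(c(1, 3, 2, 0), 2, 2))
  # all-equal window: first occurrence in row-major order wins
  r <- residual_skip(matrix(7, 2, 2))
  expect_equal(matrix(r$residual, 2, 2), matrix(c(0, 7, 7, 7), 2, 2))
  expect_error(residual_skip(matrix(0, 3, 3)), "divisible")
})

test_that("scattering pooled maxima back reconstructs the input exactly", {
  set.seed(17)
  for (i in 1:200) {
    x <- array(rnorm(64), c(8, 8, 1))
    r <- residual_skip(x)
    rec <- r$residual
    am <- attr(r$residual, "argmax")
    rec[as.vector(am)] <- as.vector(r$pooled)
    expect_identical(as.vector(rec), as.vector(x))
  }
})

test_that("the default model has the published stage and attention layout", {
  m <- build_model(model_config())
  s <- architecture_summary(m)
  expect_equal(s$n_encoder_stages, 5L)
  expect_equal(s$n_decoder_stages, 5L)
  expect_equal(s$n_base_stages, 1L)
  expect_equal(s$n_edge_attention, 2L)
  expect_equal(s$n_spatial_attention, 3L)
  expect_equal(m$plan$skip, c("EA", "EA", "SA", "SA", "SA"))
  expect_equal(s$channels, c(16L, 32L, 64L, 128L, 256L))
})

test_that("ablation variants place attention as described", {
  cfg <- model_config(input_shape = c(64L, 32L), base_channels = 4L)
  cC <- attention_block_counts(build_ablation_variant("C", cfg))
  expect_equal(unname(cC), c(5L, 0L))
  cD <- attention_block_counts(build_ablation_variant("D", cfg))
  expect_equal(unname(cD), c(0L, 5L))
  cA <- build_ablation_variant("A", cfg)
  expect_true(all(cA$plan$skip == "none"))
  expect_equal(cA$plan$enc, c("EA", "EA", "SA", "SA", "SA"))
  cB <- build_ablation_variant("B", cfg)
  expect_true(all(cB$plan$skip == "none"))
  expect_equal(cB$plan$dec, c("EA", "EA", "SA", "SA", "SA"))
  expect_error(build_ablation_variant("X", cfg), "unknown ablation code")
  expect_error(model_config(input_shape = c(100L, 64L)), "divisible")
})

test_that("forward pass emits a per-pixel probability simplex, deterministically", {
  cfg <- model_config(input_shape = c(32L, 32L), base_channels = 4L)
  m <- build_model(cfg, seed = 3)
  img <- tiny_synth(1, 32, 32)[[1]]$image
  p1 <- predict(m, img, type = "prob")
  expect_equal(dim(p1), c(32, 32, 5))
  sums <- apply(p1, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  p2 <- predict(m, img, type = "prob")
  expect_identical(p1, p2)
  cls <- predict(m, img)
  expect_true(all(cls %in% 0:4))
})

test_that("analytic gradients agree with finite differences end to end", {
  ns <- asNamespace("octseg")
  cfg <- model_config(depth = 2, base_channels = 3, n_classes = 3,
                      input_shape = c(8L, 8L),
                      attention_layout = c("EA", "SA"))
  m <- build_model(cfg, seed = 7)
  set.seed(42)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(sample(0:2, 8 * 8 * 2, TRUE), c(8, 8, 2))
  w <- c(1, 0.5, 1)
  loss_of <- function(model) {
    fw <- ns$net_forward(model, x, train = TRUE)
    ns$composite_loss_grad(fw$probs, y, w, 2L, need_grad = FALSE)$loss
  }
  fw <- ns$net_forward(m, x, train = TRUE)
  lo <- ns$composite_loss_grad(fw$probs, y, w, 2L)
  G <- ns$net_backward(m, fw$cache, lo$dlogits)
  paths <- list(list("enc", 1, "u1", "conv", "w"),
                list("dec", 1, "u1", "bn", "beta"),
                list("att_skip", 1, "psi", "b"),
                list("dec", 2, "up", "w"),
                list("head", "w"))
  getp <- function(tree, path) { for (p in path) tree <- tree[[p]]; tree }
  setp <- function(tree, path, val) {
    if (length(path) == 1) { tree[[path[[1]]]] <- val; return(tree) }
    tree[[path[[1]]]] <- setp(tree[[path[[1]]]], path[-1], val)
    tree
  }
  eps <- 1e-5
  for (pth in paths) {
    pv <- getp(m$params, pth); gv <- getp(G, pth)
    i <- sample(length(pv), 1)
    m2 <- m
    v <- pv; v[i] <- v[i] + eps
    m2$params <- setp(m$params, pth, v); lp <- loss_of(m2)
    v <- pv; v[i] <- v[i] - eps
    m2$params <- setp(m$params, pth, v); lm_ <- loss_of(m2)
    fd <- (lp - lm_) / (2 * eps)
    expect_lt(abs(gv[i] - fd) / max(1e-6, abs(fd)), 1e-3,
              label = paste(unlist(pth), collapse = "/"))
  }
})
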
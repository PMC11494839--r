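# Architecture contracts: shapes, gate ranges, hand-set-weight oracles,
# gradient flow, determinism.

test_that("conv_bn_relu preserves space, sets channels, and is nonnegative", {
  set.seed(1)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  y <- conv_bn_relu(x, filters = 128)
  expect_equal(dim(y), c(64L, 64L, 128L, 1L))
  expect_true(all(y >= 0))
  expect_error(conv_bn_relu(x, filters = 0), "filters")
})

test_that("squeeze-excitation gates lie in (0,1) and honor forced weights", {
  set.seed(2)
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  r <- se_block(x, reduction = 4, return_gates = TRUE)
  expect_equal(dim(r$y), dim(x))
  expect_true(all(r$gates > 0 & r$gates < 1))
  # expansion layer forced to zero -> sigmoid(0) = 0.5 gates exactly
  p <- duralseg:::se_init(8, 4)
  p$fc2$W[] <- 0
  p$fc2$b[] <- 0
  r0 <- se_block(x, params = p, return_gates = TRUE)
  expect_true(all(r0$gates == 0.5))
  expect_equal(r0$y, 0.5 * x)
})

test_that("residual unit keeps shape and reduces to the shortcut", {
  set.seed(3)
  x <- array(rnorm(32 * 32 * 4 * 2), c(32, 32, 4, 2))
  y <- residual_unit(x)
  expect_equal(dim(y), dim(x))
  # zeroed residual branch, matching channels: output = identity shortcut
  p <- duralseg:::res_init(4)
  p$c2$W[] <- 0
  p$c2$b[] <- 0
  expect_equal(residual_unit(x, params = p), x)
  # gradient flows through the identity path even with a dead branch:
  # perturbing the input moves the output one-for-one
  dx <- array(0, dim(x))
  dx[5, 5, 2, 1] <- 1e-3
  y2 <- residual_unit(x + dx, params = p)
  expect_equal(y2 - x, dx)
})

test_that("CSR block applies the additive skip around conv + SE", {
  set.seed(4)
  x <- array(rnorm(32 * 32 * 4), c(32, 32, 4, 1))
  y <- csr_block(x, filters = 8, reduction = 2)
  expect_equal(dim(y), c(32L, 32L, 8L, 1L))
  # conv weights zero and SE gates forced open: output = projected input
  p <- duralseg:::csr_init(4, 8, 2)
  p$cbr$conv$W[] <- 0
  p$cbr$conv$b[] <- 0
  p$se$fc2$W[] <- 0
  p$se$fc2$b[] <- 100           # sigmoid(100) ~ 1: gates fully open
  y0 <- csr_block(x, filters = 8, params = p)
  pc <- duralseg:::conv_fwd(x, p$proj$W, p$proj$b)
  expect_equal(y0, pc$y)
  # matching channels: identity skip, zeroed branch returns x exactly
  pid <- duralseg:::csr_init(4, 4, 2)
  pid$cbr$conv$W[] <- 0
  pid$cbr$conv$b[] <- 0
  expect_equal(csr_block(x, filters = 4, params = pid), x)
  # evaluation determinism
  expect_identical(csr_block(x, filters = 4, params = pid, training = FALSE),
                   csr_block(x, filters = 4, params = pid, training = FALSE))
})

test_that("spatial attention maps stay in (0,1) with the CBAM structure", {
  set.seed(5)
  g <- array(rnorm(16 * 16 * 6 * 2), c(16, 16, 6, 2))
  r <- spatial_attention(g, return_map = TRUE)
  expect_equal(dim(r$y), dim(g))
  expect_true(all(r$attention > 0 & r$attention < 1))
  # zeroed conv: attention = sigmoid(0) = 0.5 everywhere, output = 0.5 g
  p <- duralseg:::sa_init(7)
  p$W[] <- 0
  p$b[] <- 0
  r0 <- spatial_attention(g, params = p, return_map = TRUE)
  expect_true(all(r0$attention == 0.5))
  expect_equal(r0$y, 0.5 * g)
  # spatially constant input -> constant attention map away from the
  # zero-padded border (the 7x7 kernel sees padding in the outer 3 pixels)
  gc <- array(rep(rnorm(6), each = 16 * 16), c(16, 16, 6, 1))
  rc <- spatial_attention(gc, return_map = TRUE)
  expect_lt(diff(range(rc$attention[4:13, 4:13, 1, 1])), 1e-12)
  expect_error(spatial_attention(g, kernel = 4), "odd")
})

test_that("softmax is shift-invariant and numerically stable", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(1000, 1000)), c(0.5, 0.5))
  set.seed(6)
  z <- matrix(rnorm(10), 2, 5)
  expect_equal(rowSums(softmax(z)), c(1, 1), tolerance = 1e-9)
  expect_equal(softmax(z + 17), softmax(z))
  expect_false(any(is.nan(softmax(c(1e4, 0, -1e4)))))
})

test_that("leaky ReLU follows its two-branch definition", {
  expect_equal(leaky_relu(5, 0.001), 5)
  expect_equal(leaky_relu(-1, 0.001), -0.001)
  expect_equal(leaky_relu(0, 0.7), 0)
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(leaky_relu(x, 0.1), c(-0.2, -0.05, 0, 0.5, 2))
})

test_that("the full model honors the end-to-end shape contract", {
  cfg <- model_config(base_filters = 2, se_reduction = 2,
                      cls_channels = c(3, 2))
  model <- build_model(cfg, seed = 9)
  for (sz in c(32, 64)) {
    x <- array(runif(sz * sz), c(sz, sz, 1, 1))
    out <- predict(model, x)
    expect_equal(dim(out$seg_probs), c(sz, sz, 1L, 1L))
    expect_equal(dim(out$class_probs), c(1L, 2L))
    expect_equal(rowSums(out$class_probs), 1, tolerance = 1e-6)
    expect_true(all(out$seg_probs > 0 & out$seg_probs < 1))
  }
  # batch input
  xb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  ob <- predict(model, xb)
  expect_equal(dim(ob$seg_probs), c(32L, 32L, 1L, 3L))
  expect_equal(rowSums(ob$class_probs), rep(1, 3), tolerance = 1e-6)
  # non-/16-divisible input is rejected
  expect_error(predict(model, matrix(runif(40 * 40), 40, 40)), "16")
  # encoder channel doubling as configured
  expect_equal(cfg$encoder_filters, c(2L, 4L, 8L, 16L))
  expect_equal(cfg$bottleneck_filters, 32L)
  expect_error(model_config(attention_kernel = 6), "odd")
})

test_that("evaluation-mode forward passes are bit-identical", {
  model <- tiny_model(seed = 12)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  a <- predict(model, x)
  b <- predict(model, x)
  expect_identical(a, b)
})

test_that("analytic gradients match numerical differentiation end-to-end", {
  # one representative parameter per region of the network, on a tiny model
  cfg <- model_config(base_filters = 2, se_reduction = 2,
                      cls_channels = c(3, 2))
  model <- build_model(cfg, seed = 21)
  set.seed(22)
  n <- 2
  X <- array(runif(16 * 16 * n), c(16, 16, 1, n))
  M <- array(rbinom(16 * 16 * n, 1, 0.3), c(16, 16, 1, n))
  y <- c(1L, 2L)
  lc <- loss_config()
  loss_of <- function(m) {
    out <- duralseg:::model_forward(m, X, training = TRUE)
    duralseg:::batch_losses(out, M, y, lc)$total
  }
  out <- duralseg:::model_forward(model, X, training = TRUE)
  dp <- array(0, dim(out$seg_probs))
  for (i in seq_len(n)) {
    dp[, , , i] <- duralseg:::dice_loss_grad(out$seg_probs[, , , i],
                                             M[, , , i], lc$smooth) / n
  }
  dz_seg <- dp * out$seg_probs * (1 - out$seg_probs)
  dz_cls <- duralseg:::focal_grad_logits(out$class_probs, y, lc$focal_gamma,
                                         lc$focal_alpha)
  bw <- duralseg:::model_backward(model, out$caches, dz_seg, dz_cls)
  paths <- list(list("enc", 1, "c1", "conv", "W"),
                list("csr", 2, "se", "fc2", "W"),
                list("res", "bn1", "g"),
                list("dec", 3, "att", "W"),
                list("dec", 1, "c1", "conv", "W"),
                list("seg", "W"),
                list("cls", "fc", "W"))
  get_in <- function(l, path) {
    for (p in path) l <- l[[p]]
    l
  }
  set_in <- function(l, path, val) {
    if (length(path) == 1) {
      l[[path[[1]]]] <- val
      return(l)
    }
    l[[path[[1]]]] <- set_in(l[[path[[1]]]], path[-1], val)
    l
  }
  eps <- 1e-6
  for (pth in paths) {
    arr <- get_in(model$params, pth)
    k <- sample(length(arr), 1)
    ap <- arr; ap[k] <- ap[k] + eps
    am <- arr; am[k] <- am[k] - eps
    mp <- model; mp$params <- set_in(mp$params, pth, ap)
    mm <- model; mm$params <- set_in(mm$params, pth, am)
    num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
    ana <- get_in(bw$grads, pth)[k]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste(unlist(pth), collapse = "/"))
  }
})
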
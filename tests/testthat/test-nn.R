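# Engine-level checks: compiled convolutions against a naive dense oracle,
# loss values against closed forms, and backpropagation against finite
# differences.

test_that("compiled convolutions match a naive dense-convolution oracle", {
  set.seed(20)
  # 3D, 2 in / 3 out channels
  sp <- c(6, 5, 4)
  x <- array(rnorm(prod(sp) * 2), c(sp, 2))
  W <- matrix(rnorm(27 * 2 * 3), 27 * 2, 3)
  b <- rnorm(3)
  got <- tomopict:::conv_fw(matrix(x, ncol = 2), sp, W, b)$out
  want <- naive_conv(x, W, b)
  expect_equal(array(got, c(sp, 3)), want, tolerance = 1e-12)
  # 2D
  sp2 <- c(7, 5)
  x2 <- array(rnorm(prod(sp2) * 2), c(sp2, 2))
  W2 <- matrix(rnorm(9 * 2 * 2), 18, 2)
  b2 <- rnorm(2)
  got2 <- tomopict:::conv_fw(matrix(x2, ncol = 2), sp2, W2, b2)$out
  expect_equal(array(got2, c(sp2, 2)), naive_conv(x2, W2, b2),
               tolerance = 1e-12)
})

test_that("dice loss matches its closed form", {
  g <- c(rep(1, 10), rep(0, 10))
  expect_lt(dice_loss(g, g), 1e-6)
  expect_gt(dice_loss(c(rep(1, 10), rep(0, 10)),
                      c(rep(0, 10), rep(1, 10))), 0.999)
  # pred = 0.5 everywhere, target covers half the voxels -> 0.5
  n <- 100
  expect_equal(dice_loss(rep(0.5, n), rep(c(1, 0), each = n / 2)), 0.5,
               tolerance = 1e-4)
  expect_error(dice_loss(1:3, 1:4), "mismatch")
  # symmetry for binary inputs and boundedness
  set.seed(21)
  a <- rbinom(50, 1, 0.4); b <- rbinom(50, 1, 0.4)
  expect_equal(dice_loss(a, b), dice_loss(b, a))
  expect_gte(dice_loss(a, b), 0)
  expect_lte(dice_loss(a, b), 1)
})

test_that("generalized dice reduces to dice for one class and guards empties", {
  set.seed(22)
  p <- matrix(runif(80), ncol = 1)
  g <- matrix(rbinom(80, 1, 0.3), ncol = 1)
  expect_equal(generalized_dice_loss(p, g), dice_loss(p, g),
               tolerance = 1e-6)
  expect_lt(generalized_dice_loss(g, g), 1e-6)
  # an empty class stays finite
  p2 <- cbind(p, runif(80))
  g2 <- cbind(g, rep(0, 80))
  expect_true(is.finite(generalized_dice_loss(p2, g2)))
})

fd_check <- function(cfg, loss, seed = 30, n_checks = 4, tol = 1e-5) {
  ns <- asNamespace("tomopict")
  params <- ns$unet_init(cfg, seed = seed)
  sp <- rep(8, cfg$nd)
  N <- prod(sp)
  set.seed(seed + 1)
  x <- matrix(rnorm(N * cfg$in_channels), ncol = cfg$in_channels)
  y <- matrix(as.numeric(runif(N * cfg$n_classes) < 0.3),
              ncol = cfg$n_classes)
  lossfun <- function(p) {
    fw <- ns$unet_fw(p, x, sp, train = TRUE)
    ns$loss_and_dlogits(fw, y, loss)$loss
  }
  fw <- ns$unet_fw(params, x, sp, train = TRUE)
  ld <- ns$loss_and_dlogits(fw, y, loss)
  g <- ns$unet_bw(params, fw, ld$dlogits)
  leaves <- list(
    list(get = function(p) p$enc[[1]]$conv1$W[3, 1],
         set = function(p, v) { p$enc[[1]]$conv1$W[3, 1] <- v; p },
         grad = g$enc[[1]]$conv1$W[3, 1]),
    list(get = function(p) p$enc[[2]]$conv2$W[11, 2],
         set = function(p, v) { p$enc[[2]]$conv2$W[11, 2] <- v; p },
         grad = g$enc[[2]]$conv2$W[11, 2]),
    list(get = function(p) p$dec[[1]]$conv1$W[20, 1],
         set = function(p, v) { p$dec[[1]]$conv1$W[20, 1] <- v; p },
         grad = g$dec[[1]]$conv1$W[20, 1]),
    list(get = function(p) p$final$b[1],
         set = function(p, v) { p$final$b[1] <- v; p },
         grad = g$final$b[1]))
  if (cfg$BN)
    leaves <- c(leaves, list(
      list(get = function(p) p$enc[[1]]$conv2$gamma[1],
           set = function(p, v) { p$enc[[1]]$conv2$gamma[1] <- v; p },
           grad = g$enc[[1]]$conv2$gamma[1])))
  eps <- 1e-6
  for (lf in leaves[seq_len(min(n_checks + cfg$BN, length(leaves)))]) {
    v0 <- lf$get(params)
    num <- (lossfun(lf$set(params, v0 + eps)) -
              lossfun(lf$set(params, v0 - eps))) / (2 * eps)
    expect_equal(lf$grad, num, tolerance = tol)
  }
}

test_that("backpropagation matches finite differences (3D, norm on)", {
  fd_check(list(nd = 3, depth = 2, IF = 2, n_classes = 1, BN = TRUE,
                ED = 0, DD = 0, in_channels = 1), "dice")
})

test_that("backpropagation matches finite differences (2D, norm off, GDL, 2 classes)", {
  fd_check(list(nd = 2, depth = 3, IF = 2, n_classes = 2, BN = FALSE,
                ED = 0, DD = 0, in_channels = 1), "generalized_dice")
})

test_that("forward passes are deterministic and probabilities bounded", {
  ns <- asNamespace("tomopict")
  cfg <- list(nd = 3, depth = 2, IF = 2, n_classes = 2, BN = TRUE,
              ED = 0.2, DD = 0.2, in_channels = 1)
  params <- ns$unet_init(cfg, seed = 3)
  x <- matrix(rnorm(8^3), ncol = 1)
  f1 <- ns$unet_fw(params, x, c(8, 8, 8), train = FALSE)
  f2 <- ns$unet_fw(params, x, c(8, 8, 8), train = FALSE)
  expect_identical(f1$prob, f2$prob)
  expect_true(all(f1$prob >= 0 & f1$prob <= 1))
})
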
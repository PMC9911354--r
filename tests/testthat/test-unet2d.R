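test_that("tile geometry follows the 288 = 256 + 2x16 layout and validates", {
  cfg <- unet2d_config()
  expect_equal(cfg$tile_size, cfg$core_size + 2 * cfg$pad)
  expect_error(unet2d_config(tile_size = 288, core_size = 250, pad = 16),
               "core_size")
  expect_error(unet2d_config(crop = 160), "crop")
})

test_that("a 256x256 slice yields 4 tiles whose cropped outputs tessellate", {
  set.seed(40)
  sl <- matrix(rnorm(256 * 256), 256)
  tl <- extract_tiles(sl, unet2d_config())
  expect_length(tl$tiles, 4)
  # identity round trip: assembling the input tiles reproduces the slice
  expect_equal(assemble_tiles(tl$tiles, tl), sl, tolerance = 0)
  # each output pixel is covered exactly once after cropping
  ones <- lapply(tl$tiles, function(t) t * 0 + 1)
  cover <- assemble_tiles(ones, tl)
  expect_true(all(cover == 1))
  # constant slices give constant tiles
  tlc <- extract_tiles(matrix(3, 100, 80), unet2d_config())
  expect_true(all(vapply(tlc$tiles, function(t) all(t == 3), logical(1))))
})

test_that("tiling round-trips non-multiple slice shapes exactly", {
  set.seed(41)
  for (dims in list(c(100, 130), c(64, 64), c(300, 200))) {
    sl <- matrix(rnorm(prod(dims)), dims[1])
    tl <- extract_tiles(sl, unet2d_config())
    expect_equal(assemble_tiles(tl$tiles, tl), sl, tolerance = 0)
  }
})

test_that("stitching averages overlaps like a brute-force paste oracle", {
  # hand-made tile outputs (not derived from a slice) on a 128^2 slice
  cfg <- unet2d_config(depth = 3, initial_features = 4, tile_size = 96,
                       core_size = 80, pad = 8, crop = 24)
  sl <- matrix(0, 128, 128)
  tl <- extract_tiles(sl, cfg)
  set.seed(42)
  outs <- lapply(tl$tiles, function(t) matrix(rnorm(length(t)), nrow(t)))
  got <- assemble_tiles(outs, tl)
  # oracle: paste cropped blocks into accumulators pixel by pixel
  acc <- matrix(0, 128, 128); cnt <- matrix(0, 128, 128)
  core <- (cfg$crop + 1):(cfg$tile_size - cfg$crop)
  for (i in seq_len(nrow(tl$placements))) {
    for (a in seq_along(core)) for (b in seq_along(core)) {
      r <- tl$placements$row0[i] + a
      cc <- tl$placements$col0[i] + b
      if (r <= 128 && cc <= 128) {
        acc[r, cc] <- acc[r, cc] + outs[[i]][core[a], core[b]]
        cnt[r, cc] <- cnt[r, cc] + 1
      }
    }
  }
  expect_equal(got, acc / pmax(cnt, 1), tolerance = 1e-12)
})

test_that("augmentation is seeded, dihedral, and mass-preserving", {
  set.seed(43)
  tile <- matrix(rnorm(64 * 64), 64)
  lab <- matrix(rbinom(64 * 64, 1, 0.2), 64)
  a1 <- augment_tile(tile, lab, seed = 5)
  a2 <- augment_tile(tile, lab, seed = 5)
  expect_identical(a1, a2)
  expect_equal(sum(a1$label), sum(lab))
  # the 8 dihedral transforms form a group containing the identity
  seen_identity <- FALSE
  for (s in 1:50) {
    a <- augment_tile(tile, lab, seed = s)
    if (identical(a$tile, tile)) seen_identity <- TRUE
  }
  expect_true(seen_identity)
})

test_that("2D training learns a separable toy task deterministically", {
  # bright disc vs background, one volume of a few slices
  set.seed(44)
  arr <- array(rnorm(8 * 64 * 64, sd = 0.3), c(8, 64, 64))
  msk <- array(0L, c(8, 64, 64))
  for (z in 1:8) {
    cx <- 32; cy <- 32
    d <- outer((1:64 - cy)^2, (1:64 - cx)^2, `+`)
    disc <- d <= 15^2
    arr[z, , ][disc] <- arr[z, , ][disc] + 2
    msk[z, , ][disc] <- 1L
  }
  cfg <- unet2d_config(depth = 2, initial_features = 4, tile_size = 64,
                       core_size = 48, pad = 8, crop = 8)
  sp <- train_spec(max_epochs = 10, batch_size = 4, seed = 3)
  m <- train_unet2d(tomogram(arr), label_mask(msk), cfg, sp)
  expect_lt(m$log$train_loss[nrow(m$log)], m$log$train_loss[1])
  m2 <- train_unet2d(tomogram(arr), label_mask(msk), cfg, sp)
  expect_identical(m$log$train_loss[1], m2$log$train_loss[1])
  # mismatched shapes error out
  expect_error(train_unet2d(tomogram(arr), label_mask(msk[, 1:32, ]),
                            cfg, sp), "shape")
  # prediction on the training volume recovers the disc
  pm <- predict(m, tomogram(arr))
  expect_true(all(pm$data >= 0 & pm$data <= 1))
  expect_gt(voxel_f1((pm$data >= 0.5) + 0L, msk), 0.8)
})

test_that("a constant-output model reassembles to a constant volume", {
  cfg <- unet2d_config(depth = 2, initial_features = 2, tile_size = 64,
                       core_size = 48, pad = 8, crop = 8)
  ns <- asNamespace("tomopict")
  params <- ns$unet_init(list(nd = 2, depth = 2, IF = 2, n_classes = 1,
                              BN = FALSE, ED = 0, DD = 0, in_channels = 1),
                         seed = 1)
  model <- structure(list(params = params, config = cfg,
                          log = data.frame(epoch = 1, train_loss = 1,
                                           val_loss = 1), best_epoch = 1),
                     class = "unet2d")
  model <- constant_model(model, 0.3)
  pm <- predict(model, tomogram(array(rnorm(10 * 100 * 70), c(10, 100, 70))))
  expect_equal(range(pm$data), c(0.3, 0.3), tolerance = 1e-9)
})

test_that("z-smoothing preserves mass, matches a dense 1D oracle, and thresholds", {
  # sigma = 0 on a binary map is the identity
  set.seed(45)
  gt <- array(rbinom(6 * 5 * 4, 1, 0.3), c(6, 5, 4))
  out <- zsmooth_threshold(gt + 0, sigma = 0, threshold = 0.75)
  expect_identical(out$data, gt + 0L)
  # single-slice spike: per-column mass preserved before threshold
  spike <- array(0, c(9, 4, 4))
  spike[5, , ] <- 1
  sm <- smooth_z(spike, sigma = 1)
  expect_equal(apply(sm, c(2, 3), sum), matrix(1, 4, 4), tolerance = 1e-6)
  # values match a dense 1D convolution oracle along z
  arr <- array(rnorm(16 * 3 * 3), c(16, 3, 3))
  sm2 <- smooth_z(arr, sigma = 1.5)
  r <- ceiling(3 * 1.5)
  k <- dnorm(-r:r, sd = 1.5); k <- k / sum(k)
  for (y in 1:3) for (x in 1:3) {
    col <- arr[, y, x]
    padded <- col[tomopict:::reflect_index(seq(1 - r, 16 + r), 16)]
    want <- vapply(1:16, function(z) sum(padded[z:(z + 2 * r)] * k),
                   numeric(1))
    expect_equal(sm2[, y, x], want, tolerance = 1e-12)
  }
})

test_that("a small 2D network segments the cytosol of held-out phantoms", {
  # scaled-down analogue of the compartment task: bright cytosol ellipsoid
  mk <- function(seed) generate_phantom(phantom_spec(
    shape = c(32, 64, 64), n_dense = 0, n_hollow = 0, n_membranes = 0,
    region_contrast = -1, snr = 5, tilt_range_deg = 90, seed = seed))
  train_ph <- mk(50)
  test_ph <- mk(51)
  cfg <- unet2d_config(depth = 3, initial_features = 8, tile_size = 64,
                       core_size = 48, pad = 8, crop = 8)
  m <- train_unet2d(standardize(train_ph$tomogram), train_ph$masks$cytosol,
                    cfg, train_spec(max_epochs = 15, batch_size = 8,
                                    seed = 6),
                    slices = seq(1, 32, by = 2))
  pm <- predict(m, standardize(test_ph$tomogram))
  pred <- zsmooth_threshold(pm, sigma = 1, threshold = 0.75)
  expect_gte(voxel_f1(pred, test_ph$masks$cytosol), 0.9)
})
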
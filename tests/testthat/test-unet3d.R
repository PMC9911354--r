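test_that("patch extraction follows the 64/12 stride arithmetic", {
  v <- array(0, c(64, 64, 64))
  expect_length(extract_patches(v)$patches, 1)
  v128 <- array(rnorm(128^3), c(128, 128, 128))
  ep <- extract_patches(v128)
  # ceil((128 - 64) / 52) + 1 = 3 starts per axis -> 27 patches
  expect_length(ep$patches, 27)
  expect_equal(sort(unique(ep$placements$z0)), c(0, 52, 64))
  # every voxel is covered by at least one patch
  cover <- array(0, c(128, 128, 128))
  for (i in seq_len(nrow(ep$placements))) {
    s <- as.numeric(ep$placements[i, ])
    cover[s[1] + 1:64, s[2] + 1:64, s[3] + 1:64] <-
      cover[s[1] + 1:64, s[2] + 1:64, s[3] + 1:64] + 1
  }
  expect_true(all(cover >= 1))
  # identity round trip through trim-and-average reassembly
  expect_equal(assemble_patches(ep$patches, ep), v128, tolerance = 1e-12)
})

test_that("config invariants are enforced", {
  expect_error(unet3d_config(D = 3, patch_size = 50), "divisible")
  expect_error(unet3d_config(overlap = 13), "overlap")
  expect_error(unet3d_config(D = 1), "D")
  expect_silent(unet3d_config(D = 2, IF = 4, patch_size = 48))
})

test_that("patch reassembly equals the brute-force paste-and-average oracle", {
  set.seed(60)
  v <- array(0, c(96, 80, 96))
  ep <- extract_patches(v, patch_size = 64, overlap = 12)
  outs <- lapply(ep$patches, function(p) array(rnorm(length(p)), dim(p)))
  got <- assemble_patches(outs, ep)
  want <- naive_assemble_patches(outs, ep)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("a constant-output 3D model reassembles to a constant map in [0,1]", {
  ns <- asNamespace("tomopict")
  cfg <- unet3d_config(D = 2, IF = 2, patch_size = 32, overlap = 8)
  params <- ns$unet_init(list(nd = 3, depth = 2, IF = 2, n_classes = 1,
                              BN = FALSE, ED = 0, DD = 0, in_channels = 1),
                         seed = 1)
  model <- structure(list(params = params, config = cfg,
                          log = data.frame(epoch = 1, train_loss = 1,
                                           val_loss = 1), best_epoch = 1),
                     class = "unet3d")
  model <- constant_model(model, 0.7)
  pm <- predict(model, array(rnorm(48 * 80 * 56), c(48, 80, 56)))
  expect_equal(range(pm$data), c(0.7, 0.7), tolerance = 1e-9)
  expect_true(all(pm$data >= 0 & pm$data <= 1))
})

test_that("3D training runs, learns, and supports BN on/off and multi-label", {
  ph <- small_phantom(seed = 61, shape = c(48, 48, 48), n_dense = 3,
                      snr = 3, tilt = 90)
  vol <- standardize(ph$tomogram)
  cfg <- unet3d_config(D = 2, IF = 2, patch_size = 32, overlap = 8)
  sp <- train_spec(learning_rate = 1e-3, batch_size = 4, max_epochs = 4,
                   seed = 9)
  m <- suppressWarnings(train_unet3d(vol, ph$masks$dense, cfg, sp,
                                     patches_per_epoch = 8,
                                     n_val_patches = 4))
  expect_lt(min(m$log$val_loss), m$log$val_loss[1] + 1e-12)
  expect_s3_class(m, "unet3d")
  # BN off runs to completion too
  cfg_nobn <- unet3d_config(D = 2, IF = 2, BN = FALSE, patch_size = 32,
                            overlap = 8)
  m2 <- suppressWarnings(train_unet3d(vol, ph$masks$dense, cfg_nobn, sp,
                                      patches_per_epoch = 4,
                                      n_val_patches = 2))
  expect_false(isTRUE(all.equal(m$params$cfg$BN, m2$params$cfg$BN)))
  # multi-label training gives a two-channel output volume
  cfg_ml <- unet3d_config(D = 2, IF = 2, n_classes = 2, patch_size = 32,
                          overlap = 8)
  m3 <- suppressWarnings(train_unet3d(
    list(vol), list(list(ph$masks$dense, ph$masks$cytosol)), cfg_ml,
    train_spec(learning_rate = 1e-3, max_epochs = 2, seed = 9),
    patches_per_epoch = 4, n_val_patches = 2))
  pm <- predict(m3, vol)
  expect_equal(dim(pm$data), c(48, 48, 48, 2))
  # degenerate training data errors out
  empty <- label_mask(array(0L, c(48, 48, 48)))
  expect_error(suppressWarnings(train_unet3d(vol, empty, cfg, sp)),
               "degenerate")
  # instance-count warning below the recommended minimum
  expect_warning(train_unet3d(vol, ph$masks$dense, cfg,
                              train_spec(learning_rate = 1e-3,
                                         max_epochs = 1, seed = 9),
                              patches_per_epoch = 2, n_val_patches = 2),
                 "300")
})

test_that("seeded 3D training is reproducible", {
  ph <- small_phantom(seed = 62, shape = c(48, 48, 48), n_dense = 3,
                      snr = 3, tilt = 90)
  vol <- standardize(ph$tomogram)
  cfg <- unet3d_config(D = 2, IF = 2, patch_size = 32, overlap = 8)
  sp <- train_spec(learning_rate = 1e-3, max_epochs = 2, seed = 17)
  m1 <- suppressWarnings(train_unet3d(vol, ph$masks$dense, cfg, sp,
                                      patches_per_epoch = 4, n_val_patches = 2))
  m2 <- suppressWarnings(train_unet3d(vol, ph$masks$dense, cfg, sp,
                                      patches_per_epoch = 4, n_val_patches = 2))
  expect_identical(m1$log$train_loss[1], m2$log$train_loss[1])
  expect_identical(m1$log$val_loss, m2$log$val_loss)
})

test_that("model containers round-trip through save/load", {
  ns <- asNamespace("tomopict")
  params <- ns$unet_init(list(nd = 3, depth = 2, IF = 2, n_classes = 1,
                              BN = TRUE, ED = 0, DD = 0, in_channels = 1),
                         seed = 2)
  m <- structure(list(params = params,
                      config = unet3d_config(D = 2, IF = 2),
                      log = data.frame(epoch = 1, train_loss = 0.5,
                                       val_loss = 0.6), best_epoch = 1),
                 class = "unet3d")
  path <- tempfile(fileext = ".rds")
  save_unet(m, path)
  expect_identical(load_unet(path)$params$enc[[1]]$conv1$W,
                   m$params$enc[[1]]$conv1$W)
})

test_that("the coordinate-wise sweep recovers a separable optimum with sum-sized cost", {
  # separable mock score with a unique optimum per coordinate
  best <- list(D = 3, IF = 8, BN = TRUE, ED = 0.1, DD = 0.2)
  evaluator <- function(cfg) {
    -( (cfg$D - best$D)^2 + (log2(cfg$IF) - log2(best$IF))^2 +
         (cfg$BN != best$BN) + 10 * (cfg$ED - best$ED)^2 +
         10 * (cfg$DD - best$DD)^2 )
  }
  grid <- list(D = c(2, 3, 4), IF = c(4, 8, 16), BN = c(TRUE, FALSE),
               ED = c(0, 0.1, 0.3), DD = c(0, 0.2))
  res <- hyperparameter_sweep(evaluator, grid,
                              unet3d_config(D = 2, IF = 4, patch_size = 64))
  expect_equal(res$n_evaluations, sum(lengths(grid)))
  expect_equal(res$config$D, 3)
  expect_equal(res$config$IF, 8)
  expect_true(res$config$BN)
  expect_equal(res$config$ED, 0.1)
  expect_equal(res$config$DD, 0.2)
  # exhaustive-grid oracle agrees on the optimum
  full <- expand.grid(grid, stringsAsFactors = FALSE)
  scores <- apply(full, 1, function(r)
    evaluator(list(D = r[["D"]], IF = r[["IF"]], BN = r[["BN"]],
                   ED = r[["ED"]], DD = r[["DD"]])))
  top <- full[which.max(scores), ]
  expect_equal(res$config$D, top$D)
  expect_equal(res$config$IF, top$IF)
  # single-candidate grids return the candidate after exactly 5 evaluations
  one <- lapply(grid, `[`, 1)
  res1 <- hyperparameter_sweep(evaluator, one)
  expect_equal(res1$n_evaluations, 5)
  expect_equal(res1$config$D, 2)
  # evaluator failures abort with the partial trace attached
  err <- tryCatch(
    hyperparameter_sweep(function(cfg) stop("boom"), list(D = 2:3)),
    tomopict_sweep_error = function(e) e)
  expect_s3_class(err, "tomopict_sweep_error")
  expect_true(is.data.frame(err$trace))
})
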
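# Slice-wise 2D U-Net for compartment segmentation: fixed-architecture
# encoder-decoder applied per z-slice on mirror-padded tiles, with crop-and-
# stitch reassembly into 3D probability maps.

#' Configuration of the 2D compartment-segmentation network
#'
#' The network has a fixed U-Net architecture (default depth 5, 16 initial
#' features).  Slices are processed as tiles of `tile_size` pixels
#' (`core_size` plus `pad` on each side, 288 = 256 + 2 x 16 by default);
#' predictions are cropped by `crop` pixels per side before reassembly, so
#' tiles advance with stride `tile_size - 2 * crop` and the cropped outputs
#' tessellate exactly.
#'
#' @param depth number of resolution levels (default 5, i.e. 4 max-pools).
#' @param initial_features channels at the first level (default 16).
#' @param tile_size,core_size,pad tile geometry; `tile_size` must equal
#'   `core_size + 2 * pad`.
#' @param crop pixels cropped from each tile side at reassembly.
#' @param n_classes output channels (per-class sigmoid).
#' @return An object of class `"unet2d_config"`.
#' @export
unet2d_config <- function(depth = 5, initial_features = 16, tile_size = 288,
                          core_size = 256, pad = 16, crop = 48,
                          n_classes = 1) {
  stopifnot(depth >= 2, initial_features >= 1, n_classes >= 1)
  if (tile_size != core_size + 2 * pad)
    stopf("tile_size must equal core_size + 2*pad (%d != %d + 2*%d)",
          tile_size, core_size, pad)
  if (crop >= tile_size / 2) stopf("crop must be < tile_size / 2")
  if (tile_size %% 2^(depth - 1) != 0)
    stopf("tile_size must be divisible by 2^(depth-1)")
  structure(list(depth = depth, initial_features = initial_features,
                 tile_size = tile_size, core_size = core_size, pad = pad,
                 crop = crop, n_classes = n_classes),
            class = "unet2d_config")
}

# Reflect an out-of-range 1-based index back into [1, n] (symmetric
# boundary with edge duplication, period 2n).
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

mirror_pad_2d <- function(m, before, after) {
  ri <- reflect_index(seq(1 - before[1], nrow(m) + after[1]), nrow(m))
  ci <- reflect_index(seq(1 - before[2], ncol(m) + after[2]), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Split a 2D slice into overlapping mirror-padded tiles
#'
#' Tiles advance with stride `tile_size - 2 * crop`; the slice is
#' mirror-padded by `crop` on each side (plus whatever is needed so the last
#' tile fits), which makes the crop-trimmed tile outputs tessellate the
#' slice exactly.  The returned placements invert the mapping.
#'
#' @param slice 2D numeric matrix.
#' @param config a [unet2d_config()].
#' @return A list with `tiles` (list of `tile_size` x `tile_size` matrices),
#'   `placements` (data frame of 0-based padded-grid starts), and the
#'   padding bookkeeping used by [assemble_tiles()].
#' @export
extract_tiles <- function(slice, config = unet2d_config()) {
  stopifnot(is.matrix(slice))
  ts <- config$tile_size
  crop <- config$crop
  stride <- ts - 2 * crop
  dims <- dim(slice)
  k <- pmax(ceiling(dims / stride), 1)
  padded_dims <- k * stride + 2 * crop
  padded <- mirror_pad_2d(slice, before = c(crop, crop),
                          after = padded_dims - dims - crop)
  starts_r <- (seq_len(k[1]) - 1) * stride
  starts_c <- (seq_len(k[2]) - 1) * stride
  pl <- expand.grid(row0 = starts_r, col0 = starts_c)
  tiles <- lapply(seq_len(nrow(pl)), function(i)
    padded[pl$row0[i] + seq_len(ts), pl$col0[i] + seq_len(ts), drop = FALSE])
  list(tiles = tiles, placements = pl, orig_dim = dims,
       padded_dim = padded_dims, config = config)
}

#' Reassemble cropped tile outputs into a full slice
#'
#' Each tile output is trimmed by `crop` pixels per side and pasted at its
#' slice position; any overlapping contributions are averaged.
#'
#' @param outputs list of `tile_size` x `tile_size` matrices, in the order
#'   produced by [extract_tiles()].
#' @param tiling the list returned by [extract_tiles()].
#' @return A matrix with the original slice dimensions.
#' @export
assemble_tiles <- function(outputs, tiling) {
  cfg <- tiling$config
  ts <- cfg$tile_size
  crop <- cfg$crop
  dims <- tiling$orig_dim
  acc <- matrix(0, dims[1], dims[2])
  cnt <- matrix(0, dims[1], dims[2])
  core <- (crop + 1):(ts - crop)
  for (i in seq_len(nrow(tiling$placements))) {
    out <- outputs[[i]][core, core, drop = FALSE]
    # padded coords of the cropped block, shifted into original coords
    r <- tiling$placements$row0[i] + seq_len(ts - 2 * crop)
    cc <- tiling$placements$col0[i] + seq_len(ts - 2 * crop)
    keep_r <- r <= dims[1]
    keep_c <- cc <= dims[2]
    acc[r[keep_r], cc[keep_c]] <- acc[r[keep_r], cc[keep_c]] +
      out[keep_r, keep_c, drop = FALSE]
    cnt[r[keep_r], cc[keep_c]] <- cnt[r[keep_r], cc[keep_c]] + 1
  }
  acc / pmax(cnt, 1)
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Randomly flip/rotate a tile and its label together
#'
#' Draws a transform from the dihedral group (horizontal flip x rotations in
#' 90-degree increments) and applies it identically to image and label.
#'
#' @param tile,label matrices of equal shape.
#' @param seed optional seed for a reproducible draw.
#' @return A list with transformed `tile` and `label`.
#' @export
augment_tile <- function(tile, label, seed = NULL) {
  draw <- function() list(flip = runif(1) < 0.5,
                          rot = sample(0:3, 1))
  tr <- if (is.null(seed)) draw() else with_seed(seed, draw())
  apply_dihedral <- function(m) {
    if (tr$flip) m <- m[nrow(m):1, , drop = FALSE]
    if (tr$rot > 0) for (i in seq_len(tr$rot)) m <- rot90cw(m)
    m
  }
  list(tile = apply_dihedral(tile), label = apply_dihedral(label))
}

mask_to_channels <- function(mask_slice, n_classes) {
  if (n_classes == 1) matrix(as.numeric(mask_slice > 0), ncol = 1)
  else vapply(seq_len(n_classes),
              function(c) as.numeric(mask_slice == c),
              numeric(length(mask_slice)))
}

#' Train the 2D compartment-segmentation network
#'
#' Fits the fixed-architecture 2D U-Net on slice tiles extracted from
#' annotated tomograms, with random flip/rotate augmentation, Dice (or
#' generalized Dice) loss, Adam, and early stopping on a held-out tile
#' validation set.  The best-validation-loss weights are returned.
#'
#' @param tomograms a [tomogram()] or list of tomograms (pre-processed as
#'   they will be at prediction time).
#' @param masks matching [label_mask()] (or list); values `> 0` are
#'   foreground for single-class training, values `1..n_classes` are class
#'   channels otherwise.
#' @param config a [unet2d_config()].
#' @param spec a [train_spec()].
#' @param slices optional vector of z indices to train on (default: all).
#' @return An object of class `"unet2d"` with elements `params`, `config`,
#'   `spec`, `log` (per-epoch train/validation loss) and `best_epoch`.
#' @export
train_unet2d <- function(tomograms, masks, config = unet2d_config(),
                         spec = train_spec(), slices = NULL) {
  if (inherits(tomograms, "tomogram")) tomograms <- list(tomograms)
  if (inherits(masks, "label_mask")) masks <- list(masks)
  stopifnot(length(tomograms) >= 1, length(tomograms) == length(masks))
  for (i in seq_along(tomograms))
    if (!identical(dim(tomograms[[i]]$data), dim(masks[[i]]$data)))
      stopf("shape error: tomogram %d and its mask differ in shape", i)
  if (all(vapply(masks, function(m) all(m$data == 0), logical(1))))
    stopf("degenerate training data: no foreground voxels in any mask")

  pairs <- list()
  for (i in seq_along(tomograms)) {
    nz <- dim(tomograms[[i]]$data)[1]
    zi <- if (is.null(slices)) seq_len(nz) else intersect(slices, seq_len(nz))
    for (z in zi) {
      tl <- extract_tiles(tomograms[[i]]$data[z, , ], config)
      ml <- extract_tiles(masks[[i]]$data[z, , ] + 0, config)
      for (j in seq_along(tl$tiles))
        pairs[[length(pairs) + 1]] <- list(x = tl$tiles[[j]],
                                           y = ml$tiles[[j]])
    }
  }

  ccfg <- list(nd = 2, depth = config$depth, IF = config$initial_features,
               n_classes = config$n_classes, BN = TRUE, ED = 0, DD = 0,
               in_channels = 1)
  sp <- c(config$tile_size, config$tile_size)
  fit <- with_seed(spec$seed, {
    n <- length(pairs)
    n_val <- max(1, round(spec$validation_fraction * n))
    if (n_val >= n) stopf("too few tiles (%d) for validation split", n)
    val_idx <- sample(n, n_val)
    to_sample <- function(p, augment) {
      if (augment) {
        a <- augment_tile(p$x, p$y)
        p <- list(x = a$tile, y = a$label)
      }
      list(x = matrix(as.numeric(p$x), ncol = 1),
           y = mask_to_channels(p$y, config$n_classes), sp = sp)
    }
    val_samples <- lapply(pairs[val_idx], to_sample, augment = FALSE)
    train_pairs <- pairs[-val_idx]
    params <- unet_init(ccfg, seed = sample.int(2^30, 1))
    sampler <- function(epoch)
      lapply(train_pairs[sample(length(train_pairs))], to_sample,
             augment = TRUE)
    train_loop(params, sampler, val_samples, spec)
  })
  structure(list(params = fit$params, config = config, spec = spec,
                 log = fit$log, best_epoch = fit$best_epoch),
            class = "unet2d")
}

#' @export
print.unet2d <- function(x, ...) {
  cat(sprintf(paste0("<unet2d> depth %d, %d initial features, %d class(es); ",
                     "trained %d epoch(s), best val loss %.4f (epoch %d)\n"),
              x$config$depth, x$config$initial_features, x$config$n_classes,
              nrow(x$log), min(x$log$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
plot.unet2d <- function(x, ...) plot_training_log(x$log, "2D U-Net", ...)

plot_training_log <- function(log, label, ...) {
  graphics::matplot(log$epoch, cbind(log$train_loss, log$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", main = label, ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
}

#' Predict per-voxel class probabilities with a trained 2D network
#'
#' Each z-slice is tiled, passed through the network, cropped by the
#' configured margin to suppress border artifacts, and the cropped outputs
#' are stitched back (overlaps averaged) into a 3D probability map.
#'
#' @param object a trained [train_unet2d()] model.
#' @param tomogram a [tomogram()] (pre-processed like the training data).
#' @param ... unused.
#' @return A `"prob_map"`: values in `[0, 1]`, same shape as the input
#'   (class as a 4th dimension when `n_classes > 1`).
#' @export
predict.unet2d <- function(object, tomogram, ...) {
  arr <- if (inherits(tomogram, "tomogram")) tomogram$data else tomogram
  d <- dim(arr)
  nc <- object$config$n_classes
  out <- if (nc == 1) array(0, d) else array(0, c(d, nc))
  sp <- c(object$config$tile_size, object$config$tile_size)
  for (z in seq_len(d[1])) {
    tiling <- extract_tiles(arr[z, , ], object$config)
    probs <- lapply(tiling$tiles, function(tl) {
      fw <- unet_fw(object$params, matrix(as.numeric(tl), ncol = 1), sp,
                    train = FALSE)
      fw$prob
    })
    for (c in seq_len(nc)) {
      mats <- lapply(probs, function(p) matrix(p[, c], sp[1], sp[2]))
      sl <- assemble_tiles(mats, tiling)
      if (nc == 1) out[z, , ] <- sl else out[z, , , c] <- sl
    }
  }
  prob_map(out, n_classes = nc)
}

#' Per-voxel probability map
#'
#' @param data array of probabilities in `[0, 1]` (`(z, y, x)` or
#'   `(z, y, x, class)`).
#' @param n_classes number of class channels.
#' @param class_names optional class names.
#' @return An object of class `"prob_map"`.
#' @export
prob_map <- function(data, n_classes = 1, class_names = NULL) {
  stopifnot(min(data) >= -1e-9, max(data) <= 1 + 1e-9)
  structure(list(data = data, n_classes = n_classes,
                 class_names = class_names), class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map> %s, %d class(es), range [%.3f, %.3f]\n",
              paste(dim(x$data), collapse = "x"), x$n_classes,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Smooth a probability map along z with a 1D Gaussian
#'
#' Reduces single-slice false positives in reassembled 2D-network output.
#' The kernel is normalized, so per-column probability mass along z is
#' preserved (up to boundary reflection); `sigma = 0` is the identity.
#'
#' @param arr 3D array or `"prob_map"`.
#' @param sigma Gaussian standard deviation in slices.
#' @return Object of the same type, smoothed along the z axis.
#' @export
smooth_z <- function(arr, sigma = 1) {
  x <- if (inherits(arr, "prob_map")) arr$data else arr
  stopifnot(sigma >= 0, length(dim(x)) == 3)
  if (sigma > 0) {
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    nz <- dim(x)[1]
    out <- array(0, dim(x))
    for (i in seq_along(k)) {
      zi <- reflect_index(seq_len(nz) + (i - r - 1L), nz)
      out <- out + k[i] * x[zi, , , drop = FALSE]
    }
    x <- out
  }
  if (inherits(arr, "prob_map")) {
    arr$data <- x
    arr
  } else x
}

#' Threshold a z-smoothed probability map into a binary mask
#'
#' The standard 2D-network post-processing: 1D Gaussian smoothing along z
#' ([smooth_z()]) followed by binarization at a user-definable threshold
#' (default 0.75).
#'
#' @param probmap a `"prob_map"` or 3D array.
#' @param sigma smoothing standard deviation in slices (0 = none).
#' @param threshold binarization threshold in (0, 1).
#' @return A binary [label_mask()].
#' @export
zsmooth_threshold <- function(probmap, sigma = 1, threshold = 0.75) {
  x <- smooth_z(if (inherits(probmap, "prob_map")) probmap$data else probmap,
                sigma)
  label_mask((x >= threshold) + 0L)
}
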
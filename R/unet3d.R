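# Configurable 3D U-Net for particle/structure segmentation: multi-label
# per-class sigmoid outputs, Dice / generalized Dice losses, 64^3 patch
# handling with overlap-aware reassembly, optional augmentation, and a
# coordinate-wise hyperparameter sweep.

#' Configuration of the 3D segmentation network
#'
#' Architectural knobs exposed to the user: depth `D`, initial filters `IF`,
#' batch-normalization switch `BN`, and dropout rates in the encoder (`ED`)
#' and decoder (`DD`).  Volumes are processed in cubic patches (default
#' 64^3 voxels with 12 voxels overlap per dimension).
#'
#' @param D depth (resolution levels), >= 2.
#' @param IF initial filters, >= 1.
#' @param BN logical: include normalization layers.
#' @param ED,DD dropout rates in encoder / decoder blocks, in `[0, 1)`.
#' @param n_classes output channels (multi-label per-class sigmoid).
#' @param patch_size cubic patch edge in voxels; divisible by `2^(D-1)`.
#' @param overlap patch overlap per dimension (even, `< patch_size / 2`).
#' @return An object of class `"unet3d_config"`.
#' @export
unet3d_config <- function(D = 3, IF = 8, BN = TRUE, ED = 0, DD = 0,
                          n_classes = 1, patch_size = 64, overlap = 12) {
  stopifnot(D >= 2, IF >= 1, ED >= 0, ED < 1, DD >= 0, DD < 1,
            n_classes >= 1)
  if (patch_size %% 2^(D - 1) != 0)
    stopf("patch_size (%d) must be divisible by 2^(D-1) = %d", patch_size,
          2^(D - 1))
  if (overlap %% 2 != 0 || overlap >= patch_size / 2)
    stopf("overlap must be even and < patch_size / 2")
  structure(list(D = D, IF = IF, BN = BN, ED = ED, DD = DD,
                 n_classes = n_classes, patch_size = patch_size,
                 overlap = overlap), class = "unet3d_config")
}

#' @export
print.unet3d_config <- function(x, ...) {
  cat(sprintf("<unet3d_config> D=%d IF=%d BN=%s ED=%.2f DD=%.2f, %d class(es), patch %d^3 overlap %d\n",
              x$D, x$IF, x$BN, x$ED, x$DD, x$n_classes, x$patch_size,
              x$overlap))
  invisible(x)
}

mirror_pad_3d <- function(arr, after) {
  d <- dim(arr)
  zi <- reflect_index(seq_len(d[1] + after[1]), d[1])
  yi <- reflect_index(seq_len(d[2] + after[2]), d[2])
  xi <- reflect_index(seq_len(d[3] + after[3]), d[3])
  arr[zi, yi, xi, drop = FALSE]
}

patch_starts <- function(n, patch, stride) {
  if (n <= patch) return(0L)
  k <- ceiling((n - patch) / stride) + 1
  s <- (seq_len(k) - 1L) * stride
  unique(pmin(s, n - patch))
}

#' Split a volume into overlapping cubic patches
#'
#' Patches advance with stride `patch_size - overlap` (52 for the 64/12
#' defaults) and the final patch per axis is shifted back so the volume is
#' fully covered; volumes smaller than a patch are mirror-padded up.
#'
#' @param volume a [tomogram()] or 3D array.
#' @param patch_size cubic patch edge.
#' @param overlap overlap per dimension in voxels.
#' @return A list with `patches` (list of 3D arrays), `placements`
#'   (data frame of 0-based starts `z0, y0, x0`), `orig_dim` and
#'   bookkeeping for [assemble_patches()].
#' @export
extract_patches <- function(volume, patch_size = 64, overlap = 12) {
  arr <- if (inherits(volume, "tomogram")) volume$data else volume
  stopifnot(length(dim(arr)) == 3)
  stride <- patch_size - overlap
  d <- dim(arr)
  pad_after <- pmax(patch_size - d, 0)
  if (any(pad_after > 0)) arr <- mirror_pad_3d(arr, pad_after)
  sz <- patch_starts(d[1], patch_size, stride)
  sy <- patch_starts(d[2], patch_size, stride)
  sx <- patch_starts(d[3], patch_size, stride)
  pl <- expand.grid(z0 = sz, y0 = sy, x0 = sx)
  patches <- lapply(seq_len(nrow(pl)), function(i)
    arr[pl$z0[i] + seq_len(patch_size), pl$y0[i] + seq_len(patch_size),
        pl$x0[i] + seq_len(patch_size), drop = FALSE])
  list(patches = patches, placements = pl, orig_dim = d,
       patch_size = patch_size, overlap = overlap)
}

#' Reassemble per-patch outputs into a volume
#'
#' Patch outputs are trimmed by `overlap / 2` voxels on faces interior to
#' the volume; any residual overlapping contributions are averaged.
#'
#' @param outputs list of `patch_size`^3 arrays in [extract_patches()] order.
#' @param patching the list returned by [extract_patches()].
#' @return A 3D array with the original volume shape.
#' @export
assemble_patches <- function(outputs, patching) {
  ps <- patching$patch_size
  trim <- patching$overlap / 2
  d <- patching$orig_dim
  acc <- array(0, d)
  cnt <- array(0, d)
  pl <- patching$placements
  for (i in seq_len(nrow(pl))) {
    s <- c(pl$z0[i], pl$y0[i], pl$x0[i])
    lo <- ifelse(s > 0, trim, 0)
    hi <- ifelse(s + ps < d, trim, 0)
    idx <- lapply(1:3, function(a) (lo[a] + 1):(ps - hi[a]))
    tgt <- lapply(1:3, function(a) {
      v <- s[a] + idx[[a]]
      v[v <= d[a]]
    })
    idx <- lapply(1:3, function(a) idx[[a]][seq_along(tgt[[a]])])
    blk <- outputs[[i]][idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    acc[tgt[[1]], tgt[[2]], tgt[[3]]] <-
      acc[tgt[[1]], tgt[[2]], tgt[[3]]] + blk
    cnt[tgt[[1]], tgt[[2]], tgt[[3]]] <-
      cnt[tgt[[1]], tgt[[2]], tgt[[3]]] + 1
  }
  acc / pmax(cnt, 1)
}

#' Augmentation settings for 3D training patches
#'
#' Optional random transforms applied to training patches: axis flips,
#' in-plane (x-y) rotations in 90-degree increments, multiplicative
#' intensity jitter and additive Gaussian noise (intensity transforms touch
#' the image only, geometry is applied to image and labels alike).
#'
#' @param flip_prob per-axis flip probability.
#' @param rotate_prob probability of a random in-plane 90-degree rotation.
#' @param intensity_jitter maximal relative intensity scale change.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @return An object of class `"augment_spec"`.
#' @export
augment_spec <- function(flip_prob = 0.5, rotate_prob = 0.5,
                         intensity_jitter = 0, noise_sd = 0) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, rotate_prob >= 0,
            rotate_prob <= 1, intensity_jitter >= 0, noise_sd >= 0)
  structure(list(flip_prob = flip_prob, rotate_prob = rotate_prob,
                 intensity_jitter = intensity_jitter, noise_sd = noise_sd),
            class = "augment_spec")
}

flip_axis <- function(arr, axis) {
  d <- dim(arr)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- d[axis]:1
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

rot90_inplane <- function(arr) {
  # 90-degree rotation in the (y, x) plane, slice-wise over z
  aperm(flip_axis(arr, 2), c(1, 3, 2))
}

augment_patch <- function(x, ys, aspec) {
  ops <- list()
  for (axis in 1:3)
    if (runif(1) < aspec$flip_prob)
      ops <- c(ops, list(local({
        ax <- axis
        function(a) flip_axis(a, ax)
      })))
  if (runif(1) < aspec$rotate_prob) {
    k <- sample(1:3, 1)
    ops <- c(ops, list(function(a) { for (i in seq_len(k)) a <- rot90_inplane(a); a }))
  }
  for (f in ops) {
    x <- f(x)
    ys <- lapply(ys, f)
  }
  if (aspec$intensity_jitter > 0)
    x <- x * (1 + runif(1, -aspec$intensity_jitter, aspec$intensity_jitter))
  if (aspec$noise_sd > 0)
    x <- x + array(rnorm(length(x), sd = aspec$noise_sd), dim(x))
  list(x = x, ys = ys)
}

normalize_mask_list <- function(masks, n_classes) {
  # one element per tomogram; each either a label_mask (single class) or a
  # list of n_classes label_masks (multi-label channels)
  lapply(masks, function(m) {
    if (inherits(m, "label_mask")) {
      if (n_classes != 1)
        stopf("multi-label training needs one mask per class per tomogram")
      list(m)
    } else {
      if (length(m) != n_classes)
        stopf("expected %d class masks, got %d", n_classes, length(m))
      m
    }
  })
}

#' Train the 3D particle/structure segmentation network
#'
#' Fits a configurable 3D U-Net on foreground-aware random patches: at least
#' half of the training patches per epoch contain foreground, which keeps
#' sparse classes (e.g. shell-like particles) represented.  Training uses
#' Dice or generalized Dice loss, Adam, optional augmentation, and early
#' stopping on a fixed validation patch set; the best-validation weights are
#' returned.  A warning is issued when fewer than 300 annotated instances
#' (connected foreground components) are available.
#'
#' @param tomograms a [tomogram()] or list of tomograms.
#' @param masks per-tomogram ground truth: a [label_mask()] (single class)
#'   or a list of `n_classes` masks (multi-label).
#' @param config a [unet3d_config()].
#' @param spec a [train_spec()]; 3D default learning rate 1e-4, batch 4.
#' @param augment an [augment_spec()], or `NULL` to disable.
#' @param patches_per_epoch training patches sampled per epoch.
#' @param n_val_patches fixed validation patches.
#' @param init_model optional trained `"unet3d"` used as a warm start; its
#'   architecture must match `config`.
#' @return An object of class `"unet3d"` with `params`, `config`, `spec`,
#'   `log`, and `best_epoch`.
#' @export
train_unet3d <- function(tomograms, masks, config = unet3d_config(),
                         spec = train_spec(learning_rate = 1e-4,
                                           batch_size = 4),
                         augment = augment_spec(),
                         patches_per_epoch = 32, n_val_patches = 8,
                         init_model = NULL) {
  if (inherits(tomograms, "tomogram")) tomograms <- list(tomograms)
  if (inherits(masks, "label_mask") || (is.list(masks) &&
      length(masks) && inherits(masks[[1]], "label_mask") &&
      length(masks) == config$n_classes && length(tomograms) == 1 &&
      config$n_classes > 1))
    masks <- list(masks)
  stopifnot(length(tomograms) == length(masks))
  masks <- normalize_mask_list(masks, config$n_classes)
  for (i in seq_along(tomograms))
    for (m in masks[[i]])
      if (!identical(dim(tomograms[[i]]$data), dim(m$data)))
        stopf("shape error: tomogram %d and mask differ in shape", i)

  fg_any <- lapply(seq_along(tomograms), function(i) {
    f <- Reduce(`|`, lapply(masks[[i]], function(m) m$data > 0))
    which(f)
  })
  if (all(vapply(fg_any, length, integer(1)) == 0))
    stopf("degenerate training data: no foreground voxels in any mask")

  n_inst <- sum(vapply(seq_along(masks), function(i)
    sum(vapply(masks[[i]], function(m)
      max(label_components(as.integer(m$data > 0), dim(m$data), 26L)),
      numeric(1))), numeric(1)))
  if (n_inst < 300)
    warnf(paste0("only %d annotated instances available; at least 300 are ",
                 "recommended for particle learning"), n_inst)

  ps <- config$patch_size
  grab <- function(arr, s) arr[s[1] + seq_len(ps), s[2] + seq_len(ps),
                               s[3] + seq_len(ps), drop = FALSE]
  sample_start <- function(vol_dim, fg_idx, want_fg) {
    lo <- c(0, 0, 0)
    hi <- pmax(vol_dim - ps, 0)
    if (want_fg && length(fg_idx)) {
      v <- fg_idx[sample.int(length(fg_idx), 1)] - 1L
      ctr <- c(v %% vol_dim[1], (v %/% vol_dim[1]) %% vol_dim[2],
               v %/% (vol_dim[1] * vol_dim[2]))
      jit <- round(runif(3, -ps / 4, ps / 4))
      pmin(pmax(ctr - ps %/% 2 + jit, lo), hi)
    } else round(runif(3, lo, hi))
  }
  make_sample <- function(want_fg, aug) {
    i <- sample.int(length(tomograms), 1)
    s <- sample_start(dim(tomograms[[i]]$data), fg_any[[i]], want_fg)
    x <- grab(tomograms[[i]]$data, s)
    ys <- lapply(masks[[i]], function(m) grab(m$data + 0, s))
    if (aug && !is.null(augment)) {
      a <- augment_patch(x, ys, augment)
      x <- a$x
      ys <- a$ys
    }
    list(x = matrix(as.numeric(x), ncol = 1),
         y = do.call(cbind, lapply(ys, function(yy) as.numeric(yy > 0))),
         sp = rep(ps, 3))
  }

  ccfg <- list(nd = 3, depth = config$D, IF = config$IF,
               n_classes = config$n_classes, BN = config$BN,
               ED = config$ED, DD = config$DD, in_channels = 1)
  fit <- with_seed(spec$seed, {
    n_fg_quota <- ceiling(patches_per_epoch / 2)
    sampler <- function(epoch) {
      lapply(seq_len(patches_per_epoch), function(k)
        make_sample(want_fg = k <= n_fg_quota || runif(1) < 0.5,
                    aug = TRUE))
    }
    val_samples <- lapply(seq_len(n_val_patches), function(k)
      make_sample(want_fg = k %% 2 == 0, aug = FALSE))
    params <- if (is.null(init_model)) {
      unet_init(ccfg, seed = sample.int(2^30, 1))
    } else {
      stopifnot(inherits(init_model, "unet3d"))
      if (!identical(init_model$params$cfg[c("nd", "depth", "IF",
                                             "n_classes")],
                     ccfg[c("nd", "depth", "IF", "n_classes")]))
        stopf("init_model architecture does not match config")
      init_model$params
    }
    train_loop(params, sampler, val_samples, spec)
  })
  structure(list(params = fit$params, config = config, spec = spec,
                 log = fit$log, best_epoch = fit$best_epoch),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  cat(sprintf(paste0("<unet3d> D=%d IF=%d BN=%s ED=%.2f DD=%.2f, %d ",
                     "class(es); trained %d epoch(s), best val loss %.4f ",
                     "(epoch %d)\n"),
              x$config$D, x$config$IF, x$config$BN, x$config$ED,
              x$config$DD, x$config$n_classes, nrow(x$log),
              min(x$log$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
plot.unet3d <- function(x, ...) plot_training_log(x$log, "3D U-Net", ...)

#' Predict per-voxel class probabilities with a trained 3D network
#'
#' The volume is split into overlapping cubic patches, each patch is passed
#' through the network, patch outputs are trimmed by half the overlap on
#' interior faces and residual overlaps are averaged.
#'
#' @param object a trained [train_unet3d()] model.
#' @param tomogram a [tomogram()] or 3D array.
#' @param ... unused.
#' @return A `"prob_map"` with the input shape (class as 4th dimension when
#'   `n_classes > 1`).
#' @export
predict.unet3d <- function(object, tomogram, ...) {
  arr <- if (inherits(tomogram, "tomogram")) tomogram$data else tomogram
  cfg <- object$config
  patching <- extract_patches(arr, cfg$patch_size, cfg$overlap)
  sp <- rep(cfg$patch_size, 3)
  probs <- lapply(patching$patches, function(p) {
    unet_fw(object$params, matrix(as.numeric(p), ncol = 1), sp,
            train = FALSE)$prob
  })
  nc <- cfg$n_classes
  d <- patching$orig_dim
  out <- if (nc == 1) array(0, d) else array(0, c(d, nc))
  for (c in seq_len(nc)) {
    arrs <- lapply(probs, function(p) array(p[, c], sp))
    vol <- assemble_patches(arrs, patching)
    if (nc == 1) out <- vol else out[, , , c] <- vol
  }
  prob_map(out, n_classes = nc)
}

#' Save / load a trained network as a single-file container
#'
#' The container holds the configuration, weights, training settings and
#' the training log.
#'
#' @param model a `"unet2d"` or `"unet3d"` object.
#' @param path file path (conventionally `.rds`).
#' @return `save_unet` returns `path` invisibly; `load_unet` the model.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, c("unet2d", "unet3d")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, c("unet2d", "unet3d")))
    stopf("%s does not contain a trained network", path)
  m
}

#' Coordinate-wise hyperparameter sweep
#'
#' Searches the architectural hyperparameters one at a time in the fixed
#' order D, IF, BN, ED, DD: every candidate value of the current parameter
#' is evaluated with the other parameters held at their current best, the
#' best value is fixed, and the search moves to the next parameter.  The
#' number of evaluations is the sum (not the product) of the grid sizes.
#'
#' @param evaluator function mapping a [unet3d_config()] to a numeric score
#'   (higher is better).
#' @param grid named list of candidate vectors for any of `D`, `IF`, `BN`,
#'   `ED`, `DD`.
#' @param base_config starting [unet3d_config()].
#' @return A list with `config` (best), `trace` (data frame of every
#'   evaluation) and `n_evaluations`.  An evaluator failure aborts with a
#'   condition of class `"tomopict_sweep_error"` carrying the partial trace.
#' @export
hyperparameter_sweep <- function(evaluator, grid,
                                 base_config = unet3d_config()) {
  order_all <- c("D", "IF", "BN", "ED", "DD")
  bad <- setdiff(names(grid), order_all)
  if (length(bad)) stopf("unknown sweep parameter(s): %s",
                         paste(bad, collapse = ", "))
  if (!length(grid) || any(!lengths(grid)))
    stopf("sweep grid must have at least one candidate per parameter")
  cur <- base_config
  trace <- data.frame(param = character(), value = numeric(),
                      score = numeric())
  for (p in intersect(order_all, names(grid))) {
    scores <- numeric(0)
    for (v in grid[[p]]) {
      cand <- unclass(cur)
      cand[[p]] <- v
      cand_cfg <- do.call(unet3d_config, cand)
      sc <- tryCatch(evaluator(cand_cfg), error = function(e) {
        stop(errorCondition(
          sprintf("sweep aborted while evaluating %s = %s: %s", p,
                  format(v), conditionMessage(e)),
          trace = trace, class = c("tomopict_sweep_error", "error")))
      })
      scores <- c(scores, sc)
      trace <- rbind(trace, data.frame(param = p, value = as.numeric(v),
                                       score = sc))
    }
    best_v <- grid[[p]][which.max(scores)]
    cur <- do.call(unet3d_config, {
      tmp <- unclass(cur)
      tmp[[p]] <- best_v
      tmp
    })
  }
  list(config = cur, trace = trace, n_evaluations = nrow(trace))
}
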
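# U-Net engine shared by the 2D and 3D networks.
#
# Activations are stored as N x C matrices (N = prod(spatial dims) in R
# array order, C channels).  Convolutions are 3^nd kernels with zero
# padding, evaluated by the compiled direct-convolution kernels in src/;
# backpropagation is explicit.  Normalization (the BN switch) standardizes
# each channel over the spatial dimensions of the sample with learned
# scale/shift and running statistics for inference.  Dropout is inverted dropout applied once per
# convolution block (rate ED in the encoder, DD in the decoder).

conv_fw <- function(x, sp, W, b) {
  out <- if (length(sp) == 3) conv3_fw(x, as.integer(sp), W, b)
  else conv2_fw(x, as.integer(sp), W, b)
  list(out = out, x = x, sp = sp, W = W)
}

conv_bw <- function(cache, dy) {
  sp <- as.integer(cache$sp)
  C <- ncol(cache$x)
  if (length(sp) == 3) {
    list(dx = conv3_bw_x(dy, sp, cache$W, C),
         dW = conv3_bw_w(cache$x, dy, sp), db = colSums(dy))
  } else {
    list(dx = conv2_bw_x(dy, sp, cache$W, C),
         dW = conv2_bw_w(cache$x, dy, sp), db = colSums(dy))
  }
}

norm_fw <- function(x, gamma, beta, running, train, momentum = 0.1,
                    eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  n <- nrow(x)
  xhat <- (x - rep(mu, each = n)) * rep(invstd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = y, xhat = xhat, invstd = invstd, gamma = gamma,
       running = running, train = train)
}

norm_bw <- function(cache, dy) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(cache$gamma, each = n)
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dx <- (dxhat - rep(m1, each = n) -
             cache$xhat * rep(m2, each = n)) * rep(cache$invstd, each = n)
  } else {
    dx <- dxhat * rep(cache$invstd, each = n)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) list(out = pmax(x, 0), pos = x > 0)
relu_bw <- function(cache, dy) dy * cache$pos

dropout_fw <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix((runif(length(x)) >= rate) / (1 - rate),
                 nrow(x), ncol(x))
  list(out = x * mask, mask = mask)
}
dropout_bw <- function(cache, dy)
  if (is.null(cache$mask)) dy else dy * cache$mask

# Pool-cell index matrix for spatial dims sp (all even): one row per coarse
# cell, columns = flat 1-based fine indices of its 2^nd members.
pool_index <- function(sp) {
  nd <- length(sp)
  sc <- sp %/% 2
  coarse <- as.matrix(expand.grid(lapply(sc, function(n) seq_len(n) - 1L)))
  offs <- as.matrix(expand.grid(rep(list(0:1), nd)))
  strides <- cumprod(c(1, sp[-nd]))
  idx <- matrix(0L, nrow(coarse), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    fine <- sweep(2L * coarse, 2, offs[j, ], `+`)
    idx[, j] <- as.integer(fine %*% strides) + 1L
  }
  idx
}

maxpool_fw <- function(x, sp) {
  P <- pool_index(sp)
  M <- nrow(P)
  C <- ncol(x)
  N <- nrow(x)
  y <- matrix(0, M, C)
  arg <- matrix(0L, M, C)
  for (c in seq_len(C)) {
    xc <- x[, c]
    g <- matrix(xc[P], M)
    a <- max.col(g, ties.method = "first")
    arg[, c] <- P[cbind(seq_len(M), a)]
    y[, c] <- g[cbind(seq_len(M), a)]
  }
  list(out = y, arg = arg, N = N, sp_out = sp %/% 2L)
}

maxpool_bw <- function(cache, dy) {
  C <- ncol(dy)
  dx <- matrix(0, cache$N, C)
  for (c in seq_len(C))
    dx[cbind(cache$arg[, c], c)] <- dy[, c]
  dx
}

upsample_fw <- function(x, sp_coarse) {
  sp_fine <- sp_coarse * 2L
  P <- pool_index(sp_fine)
  C <- ncol(x)
  N <- prod(sp_fine)
  y <- matrix(0, N, C)
  for (c in seq_len(C)) y[as.vector(P), c] <- rep(x[, c], ncol(P))
  list(out = y, P = P, sp_out = sp_fine)
}

upsample_bw <- function(cache, dy) {
  P <- cache$P
  M <- nrow(P)
  C <- ncol(dy)
  dx <- matrix(0, M, C)
  for (c in seq_len(C)) dx[, c] <- rowSums(matrix(dy[, c][P], M))
  dx
}

he_init <- function(fan_in, n_out) {
  matrix(rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

new_conv_params <- function(K, c_in, c_out, bn) {
  p <- list(W = he_init(K * c_in, c_out), b = numeric(c_out))
  if (bn) {
    p$gamma <- rep(1, c_out)
    p$beta <- numeric(c_out)
  }
  p
}

# Initialize U-Net parameters.  cfg: list(nd, depth, IF, n_classes, BN,
# ED, DD, in_channels).  Running norm statistics live alongside the params
# (they are state, not trained weights, and are skipped by the optimizer).
unet_init <- function(cfg, seed = 1) {
  with_seed(seed, {
    K <- 3^cfg$nd
    f <- cfg$IF * 2^(seq_len(cfg$depth) - 1)
    enc <- vector("list", cfg$depth)
    for (l in seq_len(cfg$depth)) {
      cin <- if (l == 1) cfg$in_channels else f[l - 1]
      enc[[l]] <- list(conv1 = new_conv_params(K, cin, f[l], cfg$BN),
                       conv2 = new_conv_params(K, f[l], f[l], cfg$BN))
    }
    dec <- vector("list", max(cfg$depth - 1, 0))
    for (l in seq_len(cfg$depth - 1)) {
      cin <- f[l] + f[l + 1]                # skip + upsampled channels
      dec[[l]] <- list(conv1 = new_conv_params(K, cin, f[l], cfg$BN),
                       conv2 = new_conv_params(K, f[l], f[l], cfg$BN))
    }
    final <- list(W = he_init(f[1], cfg$n_classes),
                  b = numeric(cfg$n_classes))
    norm_state <- if (cfg$BN) {
      st <- list()
      for (l in seq_len(cfg$depth))
        st[[paste0("enc", l)]] <- list(
          conv1 = list(mean = numeric(f[l]), var = rep(1, f[l])),
          conv2 = list(mean = numeric(f[l]), var = rep(1, f[l])))
      for (l in seq_len(cfg$depth - 1))
        st[[paste0("dec", l)]] <- list(
          conv1 = list(mean = numeric(f[l]), var = rep(1, f[l])),
          conv2 = list(mean = numeric(f[l]), var = rep(1, f[l])))
      st
    } else NULL
    list(enc = enc, dec = dec, final = final, norm_state = norm_state,
         cfg = cfg)
  })
}

# One conv -> (norm) -> relu unit.
unit_fw <- function(x, sp, p, st, train) {
  cv <- conv_fw(x, sp, p$W, p$b)
  h <- cv$out
  nc <- NULL
  if (!is.null(p$gamma)) {
    nc <- norm_fw(h, p$gamma, p$beta, st, train)
    h <- nc$out
  }
  rl <- relu_fw(h)
  list(out = rl$out, conv = cv, norm = nc, relu = rl,
       running = if (is.null(nc)) st else nc$running)
}

unit_bw <- function(cache, dy) {
  dy <- relu_bw(cache$relu, dy)
  g <- list()
  if (!is.null(cache$norm)) {
    nb <- norm_bw(cache$norm, dy)
    dy <- nb$dx
    g$gamma <- nb$dgamma
    g$beta <- nb$dbeta
  }
  cb <- conv_bw(cache$conv, dy)
  g$W <- cb$dW
  g$b <- cb$db
  list(dx = cb$dx, grads = g)
}

block_fw <- function(x, sp, blk, st, drop_rate, train) {
  u1 <- unit_fw(x, sp, blk$conv1, st$conv1, train)
  u2 <- unit_fw(u1$out, sp, blk$conv2, st$conv2, train)
  dp <- dropout_fw(u2$out, drop_rate, train)
  list(out = dp$out, u1 = u1, u2 = u2, dp = dp,
       running = list(conv1 = u1$running, conv2 = u2$running))
}

block_bw <- function(cache, dy) {
  dy <- dropout_bw(cache$dp, dy)
  b2 <- unit_bw(cache$u2, dy)
  b1 <- unit_bw(cache$u1, b2$dx)
  list(dx = b1$dx, grads = list(conv1 = b1$grads, conv2 = b2$grads))
}

# Full forward pass.  x: N x in_channels matrix; sp: spatial dims.
# Returns probabilities (per-class sigmoid), logits and caches.
unet_fw <- function(params, x, sp, train = FALSE) {
  cfg <- params$cfg
  D <- cfg$depth
  st <- params$norm_state
  empty_st <- list(conv1 = NULL, conv2 = NULL)
  enc_cache <- vector("list", D)
  pools <- vector("list", D - 1)
  sps <- vector("list", D)
  h <- x
  cur_sp <- sp
  for (l in seq_len(D)) {
    sps[[l]] <- cur_sp
    blk <- block_fw(h, cur_sp, params$enc[[l]],
                    if (cfg$BN) st[[paste0("enc", l)]] else empty_st,
                    cfg$ED, train)
    if (cfg$BN) st[[paste0("enc", l)]] <- blk$running
    enc_cache[[l]] <- blk
    if (l < D) {
      mp <- maxpool_fw(blk$out, cur_sp)
      pools[[l]] <- mp
      h <- mp$out
      cur_sp <- mp$sp_out
    } else h <- blk$out
  }
  dec_cache <- vector("list", max(D - 1, 0))
  ups <- vector("list", max(D - 1, 0))
  for (l in rev(seq_len(D - 1))) {
    up <- upsample_fw(h, cur_sp)
    ups[[l]] <- up
    cur_sp <- up$sp_out
    h <- cbind(enc_cache[[l]]$out, up$out)
    blk <- block_fw(h, cur_sp, params$dec[[l]],
                    if (cfg$BN) st[[paste0("dec", l)]] else empty_st,
                    cfg$DD, train)
    if (cfg$BN) st[[paste0("dec", l)]] <- blk$running
    dec_cache[[l]] <- blk
    h <- blk$out
  }
  logits <- h %*% params$final$W +
    rep(params$final$b, each = nrow(h))
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits,
       cache = list(enc = enc_cache, pools = pools, dec = dec_cache,
                    ups = ups, head_in = h, sps = sps),
       norm_state = st)
}

# Backward pass from d(loss)/d(logits).  Returns gradients shaped like the
# trainable parameters.
unet_bw <- function(params, fw, dlogits) {
  cfg <- params$cfg
  D <- cfg$depth
  g <- list(enc = vector("list", D), dec = vector("list", max(D - 1, 0)),
            final = list(W = crossprod(fw$cache$head_in, dlogits),
                         b = colSums(dlogits)))
  dy <- tcrossprod(dlogits, params$final$W)
  skip_grads <- vector("list", D)
  for (l in seq_len(D - 1)) {
    bb <- block_bw(fw$cache$dec[[l]], dy)
    g$dec[[l]] <- bb$grads
    f_l <- ncol(fw$cache$enc[[l]]$out)
    skip_grads[[l]] <- bb$dx[, seq_len(f_l), drop = FALSE]
    dy <- upsample_bw(fw$cache$ups[[l]],
                      bb$dx[, -seq_len(f_l), drop = FALSE])
    # dy now flows into the output of the block below (level l+1)
  }
  for (l in rev(seq_len(D))) {
    dblk <- if (l == D) dy else {
      maxpool_bw(fw$cache$pools[[l]], dy) + skip_grads[[l]]
    }
    bb <- block_bw(fw$cache$enc[[l]], dblk)
    g$enc[[l]] <- bb$grads
    dy <- bb$dx
  }
  g
}

# ---- losses ------------------------------------------------------------

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)`: 0 for a perfect
#' binary match, approaching 1 for disjoint prediction and target.  Inputs
#' may be arrays or vectors of equal shape; predictions in `[0, 1]`.
#'
#' @param pred predicted probabilities.
#' @param target binary target.
#' @param eps smoothing constant guarding empty inputs.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (length(pred) != length(target)) stopf("shape mismatch in dice_loss")
  p <- as.numeric(pred); g <- as.numeric(target)
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

dice_loss_grad <- function(pred, target, eps = 1e-6) {
  S <- sum(pred) + sum(target) + eps
  num <- 2 * sum(pred * target) + eps
  list(loss = 1 - num / S, grad = -2 * target / S + num / S^2)
}

#' Generalized Dice loss over classes
#'
#' Multi-class Dice with per-class weights `w_c = 1 / (sum(g_c) + eps)^2`,
#' which rebalances rare classes:
#' `1 - 2 * sum_c w_c sum(p_c g_c) / sum_c w_c sum(p_c + g_c)`.
#' With a single class present it reduces to [dice_loss()].
#'
#' @param pred N x C matrix (or array with class as last dimension) of
#'   predicted probabilities.
#' @param target binary targets of the same shape.
#' @param eps smoothing constant (also guards empty classes).
#' @return Scalar loss.
#' @export
generalized_dice_loss <- function(pred, target, eps = 1e-6) {
  gd <- gdice_loss_grad(as_class_matrix(pred), as_class_matrix(target), eps)
  gd$loss
}

as_class_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (is.null(d)) return(matrix(as.numeric(x), ncol = 1))
  if (length(d) <= 3) return(matrix(as.numeric(x), ncol = 1))
  matrix(as.numeric(x), ncol = d[length(d)])
}

gdice_loss_grad <- function(pred, target, eps = 1e-6) {
  w <- 1 / (colSums(target) + eps)^2
  inter <- colSums(pred * target)
  tot <- colSums(pred) + colSums(target)
  num <- sum(w * inter)
  den <- sum(w * tot)
  epsw <- eps * mean(w)     # smoothing on the scale of the weighted sums
  loss <- 1 - (2 * num + epsw) / (den + epsw)
  grad <- -2 * sweep(target, 2, w, `*`) / (den + epsw) +
    (2 * num + epsw) / (den + epsw)^2 *
      matrix(w, nrow(pred), ncol(pred), byrow = TRUE)
  list(loss = loss, grad = grad)
}

# Loss + gradient wrt logits for a forward pass.
loss_and_dlogits <- function(fw, target, loss = c("dice", "generalized_dice")) {
  loss <- match.arg(loss)
  p <- fw$prob
  lg <- if (loss == "dice") {
    if (ncol(p) == 1) dice_loss_grad(p, target) else {
      # mean of per-class Dice
      tot <- 0; grad <- p * 0
      for (c in seq_len(ncol(p))) {
        d <- dice_loss_grad(p[, c], target[, c])
        tot <- tot + d$loss
        grad[, c] <- d$grad
      }
      list(loss = tot / ncol(p), grad = grad / ncol(p))
    }
  } else gdice_loss_grad(p, target)
  dlogits <- lg$grad * p * (1 - p)
  # flush vanishing gradients from saturated sigmoids to exact zero:
  # sub-1e-12 contributions are irrelevant to the update but their
  # denormal descendants stall the conv kernels by orders of magnitude
  dlogits[abs(dlogits) < 1e-12] <- 0
  list(loss = lg$loss, dlogits = dlogits)
}

# ---- optimizer ---------------------------------------------------------

walk_leaves <- function(x, f) {
  if (is.list(x)) {
    for (i in seq_along(x)) x[[i]] <- walk_leaves(x[[i]], f)
    x
  } else f(x)
}

# Pairs nested lists leaf-by-leaf, matching by name where both sides are
# named (gradient lists may order their fields differently from the
# parameter lists) and by position otherwise.
map2_leaves <- function(a, b, f) {
  if (is.list(a)) {
    nms <- names(a)
    by_name <- !is.null(nms) && !is.null(names(b)) && all(nzchar(nms))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[nms[i]]] else b[[i]]
      a[[i]] <- map2_leaves(a[[i]], bi, f)
    }
    a
  } else f(a, b)
}

trainable <- function(params) params[c("enc", "dec", "final")]

adam_init <- function(params) {
  z <- walk_leaves(trainable(params), function(x) x * 0)
  list(m = z, v = z, t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- map2_leaves(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_leaves(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_leaves(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  new_tr <- map2_leaves(trainable(params), upd, `-`)
  params[c("enc", "dec", "final")] <- new_tr
  list(params = params, state = state)
}

sum_grads <- function(a, b) if (is.null(a)) b else map2_leaves(a, b, `+`)
scale_grads <- function(g, s) walk_leaves(g, function(x) x * s)

# ---- generic training loop --------------------------------------------

#' Training settings shared by the 2D and 3D networks
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size samples per optimizer update (gradients accumulated).
#' @param max_epochs training epoch limit.
#' @param loss `"dice"` or `"generalized_dice"`.
#' @param validation_fraction fraction of samples held out for validation.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed RNG seed controlling initialization, sampling, augmentation
#'   and dropout.
#' @return An object of class `"train_spec"`.
#' @export
train_spec <- function(learning_rate = 1e-3, batch_size = 8, max_epochs = 60,
                       loss = c("dice", "generalized_dice"),
                       validation_fraction = 0.2, patience = 10, seed = 1) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            validation_fraction > 0, validation_fraction < 1, patience >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, loss = loss,
                 validation_fraction = validation_fraction,
                 patience = patience, seed = seed), class = "train_spec")
}

# Generic epoch loop.  sampler(epoch) must return a list of samples, each a
# list(x = N x Cin matrix, y = N x n_classes matrix, sp = spatial dims);
# val_samples is a fixed list of the same shape.  Runs under the caller's
# RNG (caller seeds once), so dropout/sampling/augmentation are reproducible.
train_loop <- function(params, sampler, val_samples, spec) {
  state <- adam_init(params)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- list(params = params, val = Inf, epoch = 0)
  stall <- 0
  for (epoch in seq_len(spec$max_epochs)) {
    samples <- sampler(epoch)
    ep_loss <- 0
    i <- 1
    while (i <= length(samples)) {
      j <- min(i + spec$batch_size - 1, length(samples))
      acc <- NULL
      for (k in i:j) {
        s <- samples[[k]]
        fw <- unet_fw(params, s$x, s$sp, train = TRUE)
        params$norm_state <- fw$norm_state
        ld <- loss_and_dlogits(fw, s$y, spec$loss)
        ep_loss <- ep_loss + ld$loss
        acc <- sum_grads(acc, unet_bw(params, fw, ld$dlogits))
      }
      acc <- scale_grads(acc, 1 / (j - i + 1))
      st <- adam_step(params, acc, state, spec$learning_rate)
      params <- st$params
      state <- st$state
      i <- j + 1
    }
    ep_loss <- ep_loss / length(samples)
    val_loss <- mean(vapply(val_samples, function(s) {
      fw <- unet_fw(params, s$x, s$sp, train = FALSE)
      loss_and_dlogits(fw, s$y, spec$loss)$loss
    }, numeric(1)))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss,
                                 val_loss = val_loss))
    if (isTRUE(getOption("tomopict.verbose")))
      message(sprintf("epoch %d: train %.4f, val %.4f", epoch, ep_loss,
                      val_loss))
    if (val_loss < best$val - 1e-9) {
      best <- list(params = params, val = val_loss, epoch = epoch)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= spec$patience) break
    }
  }
  list(params = best$params, log = log, best_epoch = best$epoch,
       best_val = best$val)
}
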
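# Shared fixtures and independent oracles used across the test files.

# A small, quickly generated phantom with dense particles only.
small_phantom <- function(seed = 1, shape = c(64, 64, 64), n_dense = 5,
                          snr = 2, tilt = 60, ...) {
  generate_phantom(phantom_spec(shape = shape, n_dense = n_dense,
                                n_hollow = 0, n_membranes = 0, snr = snr,
                                tilt_range_deg = tilt, seed = seed, ...))
}

# Naive dense 2D/3D convolution (kernel 3, zero padding), independent of
# the compiled kernels: direct translation of the definition.
naive_conv <- function(x_arr, W, b) {
  d <- dim(x_arr)
  nd <- length(d) - 1
  Cin <- d[length(d)]
  K <- 3^nd
  Cout <- ncol(W)
  sp <- d[seq_len(nd)]
  out <- array(0, c(sp, Cout))
  offsets <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  for (f in seq_len(Cout)) {
    acc <- array(b[f], sp)
    for (c in seq_len(Cin)) for (k in seq_len(K)) {
      w <- W[(c - 1) * K + k, f]
      dvec <- offsets[k, ]
      idx_src <- lapply(seq_len(nd), function(a) {
        i <- seq_len(sp[a]) + dvec[a]
        i
      })
      ok <- lapply(seq_len(nd), function(a)
        idx_src[[a]] >= 1 & idx_src[[a]] <= sp[a])
      sel_dst <- lapply(seq_len(nd), function(a) which(ok[[a]]))
      sel_src <- lapply(seq_len(nd), function(a) idx_src[[a]][ok[[a]]])
      if (nd == 2) {
        acc[sel_dst[[1]], sel_dst[[2]]] <-
          acc[sel_dst[[1]], sel_dst[[2]]] +
          w * x_arr[sel_src[[1]], sel_src[[2]], c]
      } else {
        acc[sel_dst[[1]], sel_dst[[2]], sel_dst[[3]]] <-
          acc[sel_dst[[1]], sel_dst[[2]], sel_dst[[3]]] +
          w * x_arr[sel_src[[1]], sel_src[[2]], sel_src[[3]], c]
      }
    }
    if (nd == 2) out[, , f] <- acc else out[, , , f] <- acc
  }
  out
}

# Build a trained-model shell whose output is a constant probability,
# by zeroing all weights and setting the final bias to logit(const).
constant_model <- function(model, const) {
  tr <- tomopict:::walk_leaves(tomopict:::trainable(model$params),
                               function(x) x * 0)
  model$params[c("enc", "dec", "final")] <- tr
  model$params$final$b[] <- log(const / (1 - const))
  model
}

# Brute-force paste-and-average reassembly oracle for 3D patches.
naive_assemble_patches <- function(outputs, patching) {
  ps <- patching$patch_size
  trim <- patching$overlap / 2
  d <- patching$orig_dim
  acc <- array(0, d)
  cnt <- array(0, d)
  for (i in seq_len(nrow(patching$placements))) {
    s <- c(patching$placements$z0[i], patching$placements$y0[i],
           patching$placements$x0[i])
    for (a1 in seq_len(ps)) for (a2 in seq_len(ps)) for (a3 in seq_len(ps)) {
      pos <- s + c(a1, a2, a3)
      if (any(pos > d)) next
      local <- c(a1, a2, a3)
      trimmed <- FALSE
      for (ax in 1:3) {
        if (s[ax] > 0 && local[ax] <= trim) trimmed <- TRUE
        if (s[ax] + ps < d[ax] && local[ax] > ps - trim) trimmed <- TRUE
      }
      if (trimmed) next
      acc[pos[1], pos[2], pos[3]] <- acc[pos[1], pos[2], pos[3]] +
        outputs[[i]][a1, a2, a3]
      cnt[pos[1], pos[2], pos[3]] <- cnt[pos[1], pos[2], pos[3]] + 1
    }
  }
  acc / pmax(cnt, 1)
}

# Maximum-cardinality bipartite matching count within tolerance, as an
# independent assignment oracle (igraph).
oracle_matching_tp <- function(pred, gt, tol) {
  np <- nrow(pred)
  ng <- nrow(gt)
  if (np == 0 || ng == 0) return(0L)
  dd <- sqrt(outer(pred$x, gt$x, `-`)^2 + outer(pred$y, gt$y, `-`)^2 +
               outer(pred$z, gt$z, `-`)^2)
  edges <- which(dd <= tol, arr.ind = TRUE)
  if (!nrow(edges)) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, ng)),
    edges = as.vector(t(cbind(edges[, 1], np + edges[, 2]))))
  igraph::max_bipartite_match(g)$matching_size
}
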
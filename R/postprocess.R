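# Post-processing of probability maps: thresholding and connected-component
# clustering, size and context filtering against a region mask, centroid
# export, and centerline sampling for filamentous structures.

flat_to_coords <- function(v, d) {
  # 1-based flat index -> 0-based (z, y, x)
  v0 <- v - 1L
  cbind(z = v0 %% d[1], y = (v0 %/% d[1]) %% d[2],
        x = v0 %/% (d[1] * d[2]))
}

#' Threshold a probability map and cluster it into connected components
#'
#' Voxels with probability `>= threshold` (default 0.5) are grouped into
#' connected components (26-connectivity by default) and filtered for size.
#'
#' @param probmap a `"prob_map"` or 3D array of per-voxel scores.
#' @param threshold probability threshold in (0, 1).
#' @param min_size,max_size cluster size bounds in voxels.
#' @param connectivity 26 (default) or 6.
#' @return An object of class `"cluster_set"`: a list of clusters (voxel
#'   indices, size, centroid in 0-based voxel coordinates, mean score) plus
#'   the source shape.
#' @export
threshold_cluster <- function(probmap, threshold = 0.5, min_size = 1,
                              max_size = Inf, connectivity = 26) {
  arr <- if (inherits(probmap, "prob_map")) probmap$data else probmap
  stopifnot(length(dim(arr)) == 3, threshold > 0, threshold < 1,
            min_size >= 1, connectivity %in% c(6, 26))
  d <- dim(arr)
  bin <- as.integer(arr >= threshold)
  labs <- label_components(bin, d, as.integer(connectivity))
  idx <- which(labs > 0)
  clusters <- list()
  if (length(idx)) {
    groups <- split(idx, labs[idx])
    for (g in groups) {
      n <- length(g)
      if (n < min_size || n > max_size) next
      co <- flat_to_coords(g, d)
      clusters[[length(clusters) + 1]] <- list(
        voxels = g, size = n,
        centroid = c(x = mean(co[, "x"]), y = mean(co[, "y"]),
                     z = mean(co[, "z"])),
        scores = arr[g], score = mean(arr[g]))
    }
  }
  structure(list(clusters = clusters, shape = d,
                 connectivity = connectivity, threshold = threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sz <- vapply(x$clusters, `[[`, numeric(1), "size")
  cat(sprintf("<cluster_set> %d cluster(s) in %s volume", length(sz),
              paste(x$shape, collapse = "x")))
  if (length(sz)) cat(sprintf(", sizes %d..%d", min(sz), max(sz)))
  cat("\n")
  invisible(x)
}

#' Export cluster centroids as a particle list
#'
#' One particle per cluster: the unweighted mean of the member voxel
#' coordinates, scored by the mean probability, ordered by decreasing
#' cluster size.
#'
#' @param clusters a [threshold_cluster()] result.
#' @param class_label class assigned to the exported particles.
#' @return A [particle_set()].
#' @export
centroids <- function(clusters, class_label = "particle") {
  stopifnot(inherits(clusters, "cluster_set"))
  cl <- clusters$clusters
  if (!length(cl)) return(particle_set(class_label = class_label))
  ord <- order(-vapply(cl, `[[`, numeric(1), "size"))
  cl <- cl[ord]
  particle_set(x = vapply(cl, function(c) c$centroid[["x"]], numeric(1)),
               y = vapply(cl, function(c) c$centroid[["y"]], numeric(1)),
               z = vapply(cl, function(c) c$centroid[["z"]], numeric(1)),
               class_label = class_label,
               score = vapply(cl, `[[`, numeric(1), "score"))
}

#' Context-integration mode for region filtering
#'
#' @param mode `"intersection"` (clip clusters to the region),
#'   `"contact"` (keep whole clusters touching the region dilated by
#'   `dilation_voxels`), or `"colocalization"` (keep whole clusters whose
#'   in-region voxel fraction reaches `overlap_fraction`).
#' @param dilation_voxels dilation radius for contact mode (>= 0).
#' @param overlap_fraction required in-region fraction for colocalization.
#' @return An object of class `"region_mode"`.
#' @export
region_mode <- function(mode = c("intersection", "contact",
                                 "colocalization"),
                        dilation_voxels = 1, overlap_fraction = 0.5) {
  mode <- match.arg(mode)
  stopifnot(dilation_voxels >= 0, overlap_fraction > 0,
            overlap_fraction <= 1)
  structure(list(mode = mode, dilation_voxels = dilation_voxels,
                 overlap_fraction = overlap_fraction),
            class = "region_mode")
}

# Binary dilation with the full 26-neighborhood, `iterations` times.
dilate_mask <- function(bin, iterations = 1) {
  d <- dim(bin)
  out <- bin
  for (it in seq_len(iterations)) {
    cur <- out
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      sz <- max(1, 1 + dz):min(d[1], d[1] + dz)
      sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
      sx <- max(1, 1 + dx):min(d[3], d[3] + dx)
      tz <- sz - dz; ty <- sy - dy; tx <- sx - dx
      out[sz, sy, sx] <- out[sz, sy, sx] | cur[tz, ty, tx]
    }
  }
  out
}

#' Filter clusters by cellular context against a region mask
#'
#' Integrates structure predictions with a compartment segmentation (for
#' example the cytosol output of the 2D network) to remove out-of-context
#' false positives.  In `intersection` mode cluster voxels outside the
#' region are removed and centroids recomputed (emptied clusters are
#' dropped); `contact` keeps whole clusters that touch the dilated region;
#' `colocalization` keeps whole clusters with a sufficient in-region voxel
#' fraction.
#'
#' @param clusters a [threshold_cluster()] result.
#' @param region a binary [label_mask()] (or 3D array) of matching shape.
#' @param mode a [region_mode()].
#' @return The filtered `"cluster_set"`.
#' @export
apply_region_mask <- function(clusters, region,
                              mode = region_mode("intersection")) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(mode, "region_mode"))
  reg <- if (inherits(region, "label_mask")) region$data else region
  if (!identical(dim(reg), clusters$shape))
    stopf("region mask shape %s does not match cluster volume %s",
          paste(dim(reg), collapse = "x"),
          paste(clusters$shape, collapse = "x"))
  inside <- reg > 0
  d <- clusters$shape
  kept <- list()
  if (mode$mode == "contact" && mode$dilation_voxels > 0)
    inside <- dilate_mask(inside, mode$dilation_voxels)
  for (cl in clusters$clusters) {
    inreg <- inside[cl$voxels]
    if (mode$mode == "intersection") {
      if (!any(inreg)) next
      v <- cl$voxels[inreg]
      co <- flat_to_coords(v, d)
      kept[[length(kept) + 1]] <- list(
        voxels = v, size = length(v),
        centroid = c(x = mean(co[, "x"]), y = mean(co[, "y"]),
                     z = mean(co[, "z"])),
        scores = cl$scores[inreg], score = mean(cl$scores[inreg]))
    } else if (mode$mode == "contact") {
      if (any(inreg)) kept[[length(kept) + 1]] <- cl
    } else {
      if (mean(inreg) >= mode$overlap_fraction)
        kept[[length(kept) + 1]] <- cl
    }
  }
  structure(list(clusters = kept, shape = d,
                 connectivity = clusters$connectivity,
                 threshold = clusters$threshold),
            class = "cluster_set")
}

# Vectorized BFS over the voxel graph restricted to `member` (logical over
# the flat volume), 26-connectivity.  Returns hop distances and parents.
mask_bfs <- function(seeds, member, d) {
  N <- length(member)
  dist <- rep(NA_integer_, N)
  parent <- rep(NA_integer_, N)
  dist[seeds] <- 0L
  frontier <- seeds
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  step <- 0L
  while (length(frontier)) {
    step <- step + 1L
    nxt <- integer(0)
    f0 <- frontier - 1L
    fz <- f0 %% d[1]
    fy <- (f0 %/% d[1]) %% d[2]
    fx <- f0 %/% (d[1] * d[2])
    for (k in seq_len(nrow(offs))) {
      nz <- fz + offs$dz[k]; ny <- fy + offs$dy[k]; nx <- fx + offs$dx[k]
      ok <- nz >= 0 & nz < d[1] & ny >= 0 & ny < d[2] & nx >= 0 & nx < d[3]
      if (!any(ok)) next
      cand <- (nz[ok] + ny[ok] * d[1] + nx[ok] * d[1] * d[2]) + 1L
      src <- frontier[ok]
      new <- member[cand] & is.na(dist[cand])
      if (!any(new)) next
      cand <- cand[new]
      src <- src[new]
      dup <- !duplicated(cand)
      cand <- cand[dup]
      src <- src[dup]
      dist[cand] <- step
      parent[cand] <- src
      nxt <- c(nxt, cand)
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, parent = parent)
}

backtrack <- function(v, parent) {
  path <- v
  while (!is.na(parent[v])) {
    v <- parent[v]
    path <- c(path, v)
  }
  rev(path)
}

# Sample points along an ordered voxel path at arc-length steps of
# `spacing` (Euclidean step lengths); start and end are always included.
sample_path <- function(path, d, spacing) {
  co <- flat_to_coords(path, d)
  if (nrow(co) == 1) return(co)
  steps <- sqrt(rowSums(diff(co)^2))
  cum <- c(0, cumsum(steps))
  take <- 1L
  last <- 0
  for (i in seq_along(cum)[-1]) {
    if (cum[i] - last >= spacing) {
      take <- c(take, i)
      last <- cum[i]
    }
  }
  # sample the far endpoint too, unless it falls within half a step of the
  # previous sample (a component shorter than the spacing gives one point)
  if (take[length(take)] != nrow(co) &&
      cum[nrow(co)] - last >= spacing / 2)
    take <- c(take, nrow(co))
  co[take, , drop = FALSE]
}

#' Sample coordinates along structure centerlines
#'
#' For filamentous segmentations (e.g. microtubules), coordinates are
#' sampled along each component's centerline at a chosen arc-length spacing
#' (6 voxels is typical at 4x binning).  The centerline of each 26-connected
#' component is extracted as the geodesic path between the two most distant
#' voxels of the component (double breadth-first search); side branches
#' further than the branch threshold from the centerline are traced and
#' sampled recursively.  Path endpoints are sampled whenever they lie at
#' least half a spacing beyond the previous sample, so components shorter
#' than the spacing yield a single point.  All sampled points are mask
#' voxels.
#'
#' @param mask a binary [label_mask()] or 3D array.
#' @param spacing_voxels arc-length spacing between samples (>= 1).
#' @param class_label class for the exported particles.
#' @return A [particle_set()] of centerline samples.
#' @export
sample_centerline <- function(mask, spacing_voxels = 6,
                              class_label = "filament") {
  arr <- if (inherits(mask, "label_mask")) mask$data else mask
  stopifnot(spacing_voxels >= 1, length(dim(arr)) == 3)
  d <- dim(arr)
  labs <- label_components(as.integer(arr > 0), d, 26L)
  member_all <- labs > 0
  pts <- matrix(numeric(0), ncol = 3,
                dimnames = list(NULL, c("z", "y", "x")))
  for (lab in seq_len(max(labs, 0))) {
    member <- labs == lab
    vox <- which(member)
    b1 <- mask_bfs(vox[1], member, d)
    e1 <- which.max(b1$dist)
    b2 <- mask_bfs(e1, member, d)
    e2 <- which.max(b2$dist)
    path <- backtrack(e2, b2$parent)
    pts <- rbind(pts, sample_path(path, d, spacing_voxels))
    # side branches: voxels far from the centerline (beyond the tube
    # radius) get their own geodesic paths back to it
    size <- length(vox)
    r_est <- sqrt(size / (pi * max(length(path), 1)))
    branch_thr <- max(spacing_voxels, 2 * r_est)
    path_set <- path
    for (iter in 1:50) {
      bp <- mask_bfs(path_set, member, d)
      far <- which.max(bp$dist)
      if (is.na(bp$dist[far]) || bp$dist[far] <= branch_thr) break
      branch <- backtrack(far, bp$parent)
      pts <- rbind(pts, sample_path(branch, d, spacing_voxels))
      path_set <- c(path_set, branch)
    }
  }
  if (!nrow(pts)) return(particle_set(class_label = class_label))
  particle_set(x = pts[, "x"], y = pts[, "y"], z = pts[, "z"],
               class_label = class_label)
}
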
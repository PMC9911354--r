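#' Particle coordinate lists
#'
#' A particle set is an ordered table of point annotations with 0-based
#' (possibly fractional) voxel coordinates `x`, `y`, `z`, a class label, and
#' an optional score.  Coordinates refer to the binned tomogram the particles
#' were picked in: the voxel at array position `(z+1, y+1, x+1)` (1-based R
#' indexing of the `(z, y, x)` array) has its center at coordinate
#' `(x, y, z)`.
#'
#' @param x,y,z numeric coordinate vectors (0-based voxel units).
#' @param class_label character class per particle (recycled).
#' @param score optional numeric score per particle.
#' @return A data frame of class `"particle_set"` with columns
#'   `x, y, z, class, score`.
#' @export
particle_set <- function(x = numeric(), y = numeric(), z = numeric(),
                         class_label = "particle", score = NA_real_) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  cl <- rep_len(as.character(class_label), n)
  if (n > 0 && any(!nzchar(cl))) stopf("class labels must be non-empty")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   class = cl, score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("particle_set", "data.frame")
  df
}

as_particle_set <- function(df) {
  particle_set(df$x, df$y, df$z,
               class_label = if (is.null(df$class)) "particle" else df$class,
               score = if (is.null(df$score)) NA_real_ else df$score)
}

#' Read a particle CSV (columns `x,y,z[,class][,score]`)
#'
#' @param path CSV file path; `x`, `y`, `z` columns are mandatory, 0-based
#'   voxel units.
#' @return A [particle_set()].
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stopf("particle file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("x", "y", "z"), names(df))
  if (length(need))
    stopf("particle CSV %s lacks mandatory column(s): %s", path,
          paste(need, collapse = ", "))
  as_particle_set(df)
}

#' Write a particle set as CSV
#'
#' @param particles a [particle_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(particles, path) {
  df <- as.data.frame(particles)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particle(s), class(es): %s\n", nrow(x),
              paste(unique(x$class), collapse = ", ")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Voxelize particles by pasting spherical masks
#'
#' Ground-truth particle lists are turned into voxel masks by pasting a
#' sphere of fixed physical radius at every coordinate (e.g. 10.78 nm for
#' ribosomes and 13.48 nm for FAS at 13.48 Angstrom voxel spacing).  A voxel
#' belongs to the mask when the physical distance from its center to some
#' particle center is at most `radius_nm`; spheres are clipped at the volume
#' border and overlaps merge into a single binary mask.
#'
#' @param particles a [particle_set()].
#' @param radius_nm sphere radius in nanometres.
#' @param shape integer vector `(nz, ny, nx)` of the target volume.
#' @param voxel_size_A voxel spacing in Angstrom (length 1 or 3, `(z, y, x)`).
#' @return A binary [label_mask()].
#' @export
paste_spheres <- function(particles, radius_nm, shape, voxel_size_A = 1) {
  stopifnot(radius_nm > 0, length(shape) == 3)
  vox <- rep(voxel_size_A, length.out = 3)     # (z, y, x) in Angstrom
  r_A <- radius_nm * 10
  out <- array(0L, shape)
  if (nrow(particles) == 0) return(label_mask(out))
  nzv <- shape[1]; nyv <- shape[2]; nxv <- shape[3]
  for (i in seq_len(nrow(particles))) {
    cz <- particles$z[i]; cy <- particles$y[i]; cx <- particles$x[i]
    if (cx < 0 || cx > nxv - 1 || cy < 0 || cy > nyv - 1 ||
        cz < 0 || cz > nzv - 1) {
      warnf("particle %d at (%.1f, %.1f, %.1f) outside volume; skipped",
            i, cx, cy, cz)
      next
    }
    # bounding box in 1-based array indices, clipped at borders
    iz <- max(1, floor(cz + 1 - r_A / vox[1])):min(nzv, ceiling(cz + 1 + r_A / vox[1]))
    iy <- max(1, floor(cy + 1 - r_A / vox[2])):min(nyv, ceiling(cy + 1 + r_A / vox[2]))
    ix <- max(1, floor(cx + 1 - r_A / vox[3])):min(nxv, ceiling(cx + 1 + r_A / vox[3]))
    dz2 <- ((iz - 1 - cz) * vox[1])^2
    dy2 <- ((iy - 1 - cy) * vox[2])^2
    dx2 <- ((ix - 1 - cx) * vox[3])^2
    d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    sub <- out[iz, iy, ix, drop = FALSE]
    sub[d2 <= r_A^2] <- 1L
    out[iz, iy, ix] <- sub
  }
  label_mask(out)
}

#' Remove duplicate picks by elliptic distance constraints
#'
#' Particle lists assembled from several picking rounds are cleaned for
#' duplicates: a pair of particles conflicts when
#' `(dx/r_x)^2 + (dy/r_y)^2 + (dz/r_z)^2 < 1`.  Particles are visited in
#' order of decreasing score (ties and missing scores fall back to list
#' order); a particle is kept only if it conflicts with no previously kept
#' particle.  The default z radius is inflated relative to x/y to compensate
#' for missing-wedge elongation along the beam axis.
#'
#' @param particles a [particle_set()].
#' @param radii_voxels exclusion radii `(r_x, r_y, r_z)` in voxels; a scalar
#'   `r` expands to `(r, r, 1.5 r)`.
#' @return The cleaned [particle_set()] in original list order.
#' @export
remove_duplicates <- function(particles, radii_voxels) {
  stopifnot(all(radii_voxels > 0))
  if (length(radii_voxels) == 1)
    radii_voxels <- c(radii_voxels, radii_voxels, 1.5 * radii_voxels)
  stopifnot(length(radii_voxels) == 3)
  n <- nrow(particles)
  if (n <= 1) return(particles)
  sc <- particles$score
  sc[is.na(sc)] <- -Inf
  ord <- order(-sc, seq_len(n))
  keep <- logical(n)
  kx <- ky <- kz <- numeric(0)
  for (i in ord) {
    if (length(kx)) {
      q <- ((particles$x[i] - kx) / radii_voxels[1])^2 +
           ((particles$y[i] - ky) / radii_voxels[2])^2 +
           ((particles$z[i] - kz) / radii_voxels[3])^2
      if (any(q < 1)) next
    }
    keep[i] <- TRUE
    kx <- c(kx, particles$x[i]); ky <- c(ky, particles$y[i])
    kz <- c(kz, particles$z[i])
  }
  out <- particles[keep, , drop = FALSE]
  class(out) <- c("particle_set", "data.frame")
  rownames(out) <- NULL
  out
}
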
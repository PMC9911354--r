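# Synthetic tomographic phantoms: seeded volumes with dense (ribosome-like)
# particles, hollow shell (FAS-like) particles, membrane vesicles, a cytosol
# ellipsoid, missing-wedge corruption and additive Gaussian noise, together
# with exact ground truth.  Densities follow cryo-ET convention: dense
# objects are darker (negative contrast).

#' Specification of a synthetic tomographic phantom
#'
#' Defaults emulate 4x-binned cryo-electron tomograms of yeast cytoplasm:
#' 13.48 Angstrom voxel spacing, abundant dense particles of ribosome size
#' (10.78 nm radius), sparse hollow shell particles of FAS size (13.48 nm
#' outer radius), membrane vesicles, a +/-60 degree tilt-range missing wedge,
#' and additive white Gaussian noise.  `snr` is the ratio of the noise-free
#' (post-wedge) signal variance over the whole volume to the noise variance.
#'
#' @param shape volume dimensions `(nz, ny, nx)`.
#' @param voxel_size_A voxel spacing in Angstrom.
#' @param n_dense,dense_radius_nm,dense_contrast dense particle count,
#'   radius (nm) and contrast (negative = dark).
#' @param n_hollow,hollow_outer_radius_nm,shell_thickness_nm,hollow_contrast
#'   hollow shell particle parameters.
#' @param n_membranes,membrane_thickness_nm,membrane_contrast vesicle
#'   (closed membrane shell) parameters.
#' @param region_fraction cytosol ellipsoid semi-axes as fractions of the
#'   half-extent per axis.
#' @param region_contrast contrast of the cytosol interior.
#' @param snr signal-variance / noise-variance ratio (> 0).
#' @param tilt_range_deg tilt range in degrees (90 = no missing wedge).
#' @param seed RNG seed for placement and noise.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128), voxel_size_A = 13.48,
                         n_dense = 40, dense_radius_nm = 10.78,
                         dense_contrast = -1,
                         n_hollow = 5, hollow_outer_radius_nm = 13.48,
                         shell_thickness_nm = 4, hollow_contrast = -0.8,
                         n_membranes = 2, membrane_thickness_nm = 5,
                         membrane_contrast = -0.7,
                         region_fraction = c(0.9, 0.9, 0.9),
                         region_contrast = -0.2,
                         snr = 1.0, tilt_range_deg = 60, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 8),
            n_dense >= 0, n_hollow >= 0, n_membranes >= 0,
            dense_radius_nm > 0, hollow_outer_radius_nm > 0,
            shell_thickness_nm > 0, membrane_thickness_nm > 0,
            snr > 0, tilt_range_deg > 0, tilt_range_deg <= 90)
  structure(as.list(environment()), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %s voxels @ %.2f A, %d dense + %d ",
                     "hollow particles, %d vesicles, SNR %.2g, tilt +/-%g ",
                     "deg, seed %d\n"),
              paste(x$shape, collapse = "x"), x$voxel_size_A, x$n_dense,
              x$n_hollow, x$n_membranes, x$snr, x$tilt_range_deg, x$seed))
  invisible(x)
}

# Ellipsoid membership value: <= 1 inside.  coords are 0-based voxel coords.
ellipsoid_value <- function(shape, semi_axes) {
  ctr <- (shape - 1) / 2
  z2 <- ((0:(shape[1] - 1) - ctr[1]) / semi_axes[1])^2
  y2 <- ((0:(shape[2] - 1) - ctr[2]) / semi_axes[2])^2
  x2 <- ((0:(shape[3] - 1) - ctr[3]) / semi_axes[3])^2
  outer(outer(z2, y2, `+`), x2, `+`)
}

# Rejection-sample n centers (0-based, fractional) of radius own_r inside
# the cytosol ellipsoid (with clearance own_r), keeping a minimum center
# separation of own_r + r_other plus a two-voxel clearance to everything
# already placed -- the clearance guarantees that rendered masks of
# distinct objects can never touch, even diagonally, so ground truth
# round-trips through 26-connected clustering.
sample_centers <- function(n, shape, semi_axes, own_r, placed,
                           max_tries = 5000) {
  ctr <- (shape - 1) / 2
  out <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- runif(3, -1, 1)
      cand <- ctr + u * (semi_axes - own_r)
      ev <- sum(((cand - ctr) / pmax(semi_axes - own_r, 1e-9))^2)
      if (ev > 1) next
      if (nrow(placed)) {
        d <- sqrt(rowSums(sweep(placed[, 1:3, drop = FALSE], 2, cand)^2))
        if (any(d < own_r + placed[, 4] + 2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stopf(paste0("capacity error: could not place particle %d of %d in a ",
                   "%s volume; reduce counts or radii"), i, n,
            paste(shape, collapse = "x"))
    placed <- rbind(placed, c(cand, own_r))
    out <- rbind(out, cand)
  }
  list(centers = out, placed = placed)
}

# Paint a spherical shell band |dist - radius| <= thickness/2 around a center.
paint_shell <- function(mask, center, radius_vox, thickness_vox) {
  shp <- dim(mask)
  rmax <- radius_vox + thickness_vox / 2
  iz <- max(1, floor(center[1] + 1 - rmax)):min(shp[1], ceiling(center[1] + 1 + rmax))
  iy <- max(1, floor(center[2] + 1 - rmax)):min(shp[2], ceiling(center[2] + 1 + rmax))
  ix <- max(1, floor(center[3] + 1 - rmax)):min(shp[3], ceiling(center[3] + 1 + rmax))
  d <- sqrt(outer(outer((iz - 1 - center[1])^2, (iy - 1 - center[2])^2, `+`),
                  (ix - 1 - center[3])^2, `+`))
  sub <- mask[iz, iy, ix, drop = FALSE]
  sub[abs(d - radius_vox) <= thickness_vox / 2] <- 1L
  mask[iz, iy, ix] <- sub
  mask
}

#' Generate a synthetic tomographic phantom with ground truth
#'
#' Places membrane vesicles and particles by rejection sampling inside the
#' cytosol ellipsoid (minimum center separation = sum of radii plus a
#' two-voxel clearance, so rendered masks of distinct objects never touch),
#' renders the noise-free density, applies the missing wedge, and adds white
#' Gaussian noise scaled to the requested SNR.  The dense-class ground-truth mask is
#' produced by [paste_spheres()] from the returned particle list, so mask and
#' coordinates are consistent by construction.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `"phantom_bundle"`: a list with `tomogram`
#'   (noisy volume), `clean` (noise-free, post-wedge volume), `masks` (named
#'   list of binary [label_mask()]: `dense`, `hollow`, `membrane`,
#'   `cytosol`), `particles` (named list of [particle_set()]: `dense`,
#'   `hollow`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shp <- spec$shape
    vox_nm <- spec$voxel_size_A / 10
    semi <- spec$region_fraction * shp / 2
    r_dense <- spec$dense_radius_nm / vox_nm
    r_hollow <- spec$hollow_outer_radius_nm / vox_nm
    t_hollow <- spec$shell_thickness_nm / vox_nm
    t_memb <- spec$membrane_thickness_nm / vox_nm

    cyt <- (ellipsoid_value(shp, semi) <= 1) + 0L

    # placed: rows of (z, y, x, radius); vesicles first, then particles
    placed <- matrix(numeric(0), ncol = 4)
    ves_r <- numeric(0)
    ves_centers <- matrix(0, 0, 3)
    if (spec$n_membranes > 0) {
      ves_r <- runif(spec$n_membranes, 0.07, 0.11) * min(shp)
      for (i in seq_len(spec$n_membranes)) {
        res <- sample_centers(1, shp, semi, ves_r[i] + t_memb, placed)
        placed <- res$placed
        ves_centers <- rbind(ves_centers, res$centers)
      }
    }

    # large sparse objects first, abundant small ones last
    res_h <- sample_centers(spec$n_hollow, shp, semi, r_hollow, placed)
    placed <- res_h$placed
    hollow_centers <- res_h$centers

    res_d <- sample_centers(spec$n_dense, shp, semi, r_dense, placed)
    dense_centers <- res_d$centers

    mk_ps <- function(centers, label) {
      if (nrow(centers) == 0) return(particle_set(class_label = label))
      particle_set(x = centers[, 3], y = centers[, 2], z = centers[, 1],
                   class_label = label)
    }
    dense_ps <- mk_ps(dense_centers, "dense")
    hollow_ps <- mk_ps(hollow_centers, "hollow")

    dense_mask <- paste_spheres(dense_ps, spec$dense_radius_nm, shp,
                                spec$voxel_size_A)$data
    hollow_mask <- array(0L, shp)
    for (i in seq_len(nrow(hollow_centers)))
      hollow_mask <- paint_shell(hollow_mask, hollow_centers[i, ],
                                 r_hollow - t_hollow / 2, t_hollow)
    memb_mask <- array(0L, shp)
    for (i in seq_len(nrow(ves_centers)))
      memb_mask <- paint_shell(memb_mask, ves_centers[i, ], ves_r[i], t_memb)

    sig <- array(0, shp)
    sig[cyt == 1L] <- spec$region_contrast
    sig[memb_mask == 1L] <- spec$membrane_contrast
    sig[hollow_mask == 1L] <- spec$hollow_contrast
    sig[dense_mask == 1L] <- spec$dense_contrast

    if (spec$tilt_range_deg < 90)
      sig <- apply_missing_wedge(sig, spec$tilt_range_deg)

    sigma <- sd(as.vector(sig)) / sqrt(spec$snr)
    noisy <- sig + array(rnorm(prod(shp), sd = sigma), shp)

    structure(list(
      tomogram = tomogram(noisy, spec$voxel_size_A, name = "phantom"),
      clean = tomogram(sig, spec$voxel_size_A, name = "phantom_clean"),
      masks = list(dense = label_mask(dense_mask),
                   hollow = label_mask(hollow_mask),
                   membrane = label_mask(memb_mask),
                   cytosol = label_mask(cyt)),
      particles = list(dense = dense_ps, hollow = hollow_ps),
      spec = spec), class = "phantom_bundle")
  })
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> %s, %d dense / %d hollow particles\n",
              paste(dim(x$tomogram$data), collapse = "x"),
              nrow(x$particles$dense), nrow(x$particles$hollow)))
  invisible(x)
}

#' Apply a missing-wedge filter to a volume
#'
#' Cryo-ET tilt series sample only +/- `tilt_range_deg` degrees about the
#' tilt (y) axis, leaving a wedge of Fourier space unmeasured and causing the
#' familiar elongation of features along z.  Fourier coefficients whose angle
#' in the (z, x) plane from the x axis exceeds the tilt range are zeroed;
#' a tilt range of 90 degrees is the identity.
#'
#' @param tomo a [tomogram()] or 3D array.
#' @param tilt_range_deg tilt range in degrees, in (0, 90].
#' @return The wedge-filtered volume (same class as the input).
#' @export
apply_missing_wedge <- function(tomo, tilt_range_deg) {
  stopifnot(tilt_range_deg > 0, tilt_range_deg <= 90)
  arr <- if (inherits(tomo, "tomogram")) tomo$data else tomo
  if (tilt_range_deg >= 90) return(tomo)
  shp <- dim(arr)
  fz <- abs(fft_freqs(shp[1]))
  fx <- abs(fft_freqs(shp[3]))
  ang <- atan2(outer(fz, fx, function(a, b) a),
               outer(fz, fx, function(a, b) b)) * 180 / pi
  keep_zx <- ang <= tilt_range_deg            # (z, x) plane mask
  keep <- aperm(array(rep(keep_zx, shp[2]), c(shp[1], shp[3], shp[2])),
                c(1, 3, 2))
  ftv <- fft(arr)
  ftv[!keep] <- 0
  out <- Re(fft(ftv, inverse = TRUE)) / length(arr)
  if (inherits(tomo, "tomogram")) {
    tomo$data <- out
    tomo
  } else out
}
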
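#' Tomogram: a 3D density volume with physical voxel spacing
#'
#' The universal container for reconstructed cryo-ET volumes.  Data are held
#' as a numeric 3D array indexed `(z, y, x)` (first index fastest, matching R
#' array order); `voxel_size_A` is the physical spacing in Angstrom per voxel,
#' either a scalar or a length-3 vector `(z, y, x)`.
#'
#' @param data numeric 3D array, indexed `(z, y, x)`.
#' @param voxel_size_A positive voxel spacing in Angstrom (length 1 or 3).
#' @param name identifier string.
#' @return An object of class `"tomogram"`.
#' @examples
#' tomo <- tomogram(array(rnorm(8^3), c(8, 8, 8)), voxel_size_A = 13.48)
#' dim(tomo$data)
#' @export
tomogram <- function(data, voxel_size_A = 1, name = "tomogram") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("tomogram data must be a 3D array, got %d dimension(s)",
          length(dim(data)))
  if (any(dim(data) < 1L)) stopf("all tomogram dimensions must be >= 1")
  if (!all(is.finite(data))) stopf("tomogram data contains non-finite values")
  if (!length(voxel_size_A) %in% c(1L, 3L) || any(voxel_size_A <= 0))
    stopf("voxel_size_A must be positive (length 1 or 3)")
  structure(list(data = data, voxel_size_A = as.numeric(voxel_size_A),
                 name = as.character(name)[1]),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomogram> '%s'  %d x %d x %d (z,y,x), voxel %s A\n",
              x$name, d[1], d[2], d[3],
              paste(format(x$voxel_size_A, digits = 4), collapse = " x ")))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g, sd %.4g\n",
              min(x$data), max(x$data), mean(x$data), sd(as.vector(x$data))))
  invisible(x)
}

as_tomogram <- function(x, template = NULL, name = NULL) {
  if (inherits(x, "tomogram")) return(x)
  tomogram(x,
           voxel_size_A = if (is.null(template)) 1 else template$voxel_size_A,
           name = name %||% "tomogram")
}

#' Integer-labelled segmentation mask aligned to a tomogram
#'
#' Voxel value 0 is background; positive integers identify compartments or
#' structures.  `label_names` optionally maps label values to names.
#'
#' @param data integer-valued 3D array (same shape as the paired tomogram).
#' @param label_names optional named character vector, names = label values.
#' @return An object of class `"label_mask"`.
#' @export
label_mask <- function(data, label_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("label mask must be a 3D array")
  if (any(data < 0)) stopf("label values must be >= 0")
  if (any(data != round(data))) stopf("label values must be integers")
  structure(list(data = data, label_names = label_names),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  labs <- sort(unique(as.vector(x$data)))
  cat(sprintf("<label_mask> %d x %d x %d, labels: %s\n", d[1], d[2], d[3],
              paste(labs, collapse = ", ")))
  invisible(x)
}

#' Standardize a volume to zero mean and unit variance
#'
#' Tomograms are normalized to a uniform mean of 0 and variance of 1 before
#' filtering and network training, so intensities are comparable across
#' acquisitions.
#'
#' @param x a [tomogram()] or 3D array.
#' @return The standardized object (same class as the input).
#' @export
standardize <- function(x) {
  arr <- if (inherits(x, "tomogram")) x$data else x
  s <- sd(as.vector(arr))
  if (!is.finite(s) || s < 1e-12)
    stopf("degenerate input: volume has (near-)zero variance")
  out <- (arr - mean(arr)) / s
  if (inherits(x, "tomogram")) {
    x$data <- out
    x
  } else out
}

#' Select a subset of labels as a binary mask
#'
#' Each compartment carries a unique numerical label so that subsets of
#' compartments can be selected; this returns a binary mask that is 1 exactly
#' where the input label lies in `labels`.
#'
#' @param mask a [label_mask()].
#' @param labels integer vector of label values to select.
#' @return A binary [label_mask()].
#' @export
select_labels <- function(mask, labels) {
  stopifnot(inherits(mask, "label_mask"))
  present <- unique(as.vector(mask$data))
  missing <- setdiff(labels, present)
  if (length(missing))
    warnf("label(s) %s absent from mask; selection may be empty",
          paste(missing, collapse = ", "))
  out <- array(0L, dim(mask$data))
  out[mask$data %in% labels] <- 1L
  label_mask(out)
}
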
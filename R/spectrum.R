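# Amplitude-spectrum equalization: match a tomogram's radial amplitude
# spectrum to that of a high-contrast target to improve image contrast
# before training/prediction.

# Per-axis normalized FFT sample frequencies (cycles/voxel, in [-0.5, 0.5)).
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

n_shells_for <- function(shape) floor(min(shape) / 2) + 1

# Continuous radial shell coordinate for every 3D frequency sample: the
# Euclidean norm of the per-axis normalized frequencies rescaled so that the
# Nyquist frequency (0.5 cycles/voxel) maps to the last shell index.
radial_shell_grid <- function(shape) {
  ns <- n_shells_for(shape)
  fz2 <- fft_freqs(shape[1])^2
  fy2 <- fft_freqs(shape[2])^2
  fx2 <- fft_freqs(shape[3])^2
  r <- sqrt(outer(outer(fz2, fy2, `+`), fx2, `+`))
  r / 0.5 * (ns - 1)
}

#' Radially averaged Fourier amplitude spectrum
#'
#' Computes the 3D FFT of a volume and averages the Fourier amplitudes over
#' integer radial-frequency shells (shell 0 = DC, last shell = Nyquist).
#' Frequency samples beyond Nyquist (grid corners) are ignored.
#'
#' @param tomo a [tomogram()] or 3D array.
#' @return An object of class `"radial_spectrum"`: a list with `amplitudes`
#'   (one mean amplitude per shell) and `source_shape`.
#' @export
radial_amplitude_spectrum <- function(tomo) {
  arr <- if (inherits(tomo, "tomogram")) tomo$data else tomo
  stopifnot(length(dim(arr)) == 3)
  ns <- n_shells_for(dim(arr))
  shell <- as.vector(round(radial_shell_grid(dim(arr))))
  amp <- as.vector(Mod(fft(arr)))
  sel <- shell <= ns - 1
  g <- shell[sel] + 1L
  sums <- rowsum(amp[sel], g)
  cnts <- tabulate(g, nbins = ns)
  amps <- numeric(ns)
  amps[as.integer(rownames(sums))] <- sums[, 1]
  amps <- amps / pmax(cnts, 1)
  radial_spectrum(amps, source_shape = dim(arr))
}

#' Construct a radial spectrum object
#'
#' @param amplitudes non-negative amplitudes per integer shell (DC first).
#' @param source_shape shape of the originating volume, if known.
#' @return An object of class `"radial_spectrum"`.
#' @export
radial_spectrum <- function(amplitudes, source_shape = NULL) {
  if (length(amplitudes) < 2 || any(amplitudes < 0))
    stopf("a radial spectrum needs >= 2 non-negative amplitudes")
  structure(list(amplitudes = as.numeric(amplitudes),
                 source_shape = source_shape),
            class = "radial_spectrum")
}

#' @export
print.radial_spectrum <- function(x, ...) {
  cat(sprintf("<radial_spectrum> %d shells (DC %.4g ... Nyquist %.4g)\n",
              length(x$amplitudes), x$amplitudes[1],
              x$amplitudes[length(x$amplitudes)]))
  invisible(x)
}

#' Read / write a radial spectrum as CSV (`shell,amplitude`)
#'
#' @param path CSV file path.
#' @return `read_spectrum` returns a [radial_spectrum()]; `write_spectrum`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  df <- read.csv(path)
  if (!all(c("shell", "amplitude") %in% names(df)))
    stopf("spectrum CSV must have columns shell,amplitude")
  radial_spectrum(df$amplitude[order(df$shell)])
}

#' @rdname read_spectrum
#' @param spec a [radial_spectrum()].
#' @export
write_spectrum <- function(spec, path) {
  write.csv(data.frame(shell = seq_along(spec$amplitudes) - 1L,
                       amplitude = spec$amplitudes),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sigmoidal low-pass filter specification
#'
#' `S(s) = 1 / (1 + exp((s - c) / k))` over shell index `s`, with
#' `c = cutoff_fraction * N_shells` and `k = steepness * N_shells`: a smooth
#' roll-off that suppresses high-frequency noise above the cutoff.
#'
#' @param cutoff_fraction cutoff as a fraction of Nyquist, in (0, 1].
#' @param steepness transition width as a fraction of the shell count.
#' @return An object of class `"lowpass_spec"`.
#' @export
lowpass_spec <- function(cutoff_fraction = 0.5, steepness = 0.03) {
  stopifnot(cutoff_fraction > 0, cutoff_fraction <= 1, steepness > 0)
  structure(list(cutoff_fraction = cutoff_fraction, steepness = steepness),
            class = "lowpass_spec")
}

lowpass_gain <- function(lowpass, shell_coord, n_shells) {
  cc <- lowpass$cutoff_fraction * n_shells
  kk <- lowpass$steepness * n_shells
  1 / (1 + exp((shell_coord - cc) / kk))
}

#' Per-shell equalization gains (target over input spectrum)
#'
#' `gain[s] = target[s] / max(input[s], eps)`.  When the target spectrum is
#' shorter than the input spectrum it is padded with zeros, so trailing gains
#' are exactly zero.
#'
#' @param input_spec,target_spec [radial_spectrum()] objects (or amplitude
#'   vectors).
#' @param eps_fraction division guard as a fraction of the input maximum.
#' @return Numeric gain vector with the input spectrum's length.
#' @export
equalization_vector <- function(input_spec, target_spec,
                                eps_fraction = 1e-8) {
  a_in <- if (inherits(input_spec, "radial_spectrum"))
    input_spec$amplitudes else as.numeric(input_spec)
  a_tg <- if (inherits(target_spec, "radial_spectrum"))
    target_spec$amplitudes else as.numeric(target_spec)
  n <- length(a_in)
  if (length(a_tg) < n) a_tg <- c(a_tg, rep(0, n - length(a_tg)))
  a_tg <- a_tg[seq_len(n)]
  eps <- eps_fraction * max(a_in)
  a_tg / pmax(a_in, eps)
}

#' Match a tomogram's amplitude spectrum to a target spectrum
#'
#' The per-shell equalization gains (target / input) are expanded into a
#' rotational kernel over the 3D frequency grid and multiplied with the
#' tomogram's Fourier transform, optionally combined with a sigmoidal
#' low-pass; the filtered volume is returned after inverse transform.  Every
#' frequency sample receives the gain of the integer shell it is averaged
#' into, so the filtered volume's radial spectrum reproduces the target
#' exactly on the shells (set `interpolation = "linear"` for linear radial
#' interpolation of the gains instead).
#'
#' @param tomo a [tomogram()] or 3D array.
#' @param target_spec target [radial_spectrum()].
#' @param lowpass optional [lowpass_spec()]; `NULL` disables low-pass.
#' @param interpolation `"shell"` (piecewise-constant per shell; default) or
#'   `"linear"` (linear between shell centers).
#' @return The filtered volume (same class and shape as the input).
#' @export
match_spectrum <- function(tomo, target_spec, lowpass = NULL,
                           interpolation = c("shell", "linear")) {
  interpolation <- match.arg(interpolation)
  arr <- if (inherits(tomo, "tomogram")) tomo$data else tomo
  stopifnot(length(dim(arr)) == 3)
  input_spec <- radial_amplitude_spectrum(arr)
  ns <- length(input_spec$amplitudes)
  cutoff_shell <- if (is.null(lowpass)) ns else
    lowpass$cutoff_fraction * ns
  dead <- which(input_spec$amplitudes == 0)
  dead <- dead[dead - 1 < cutoff_shell & target_amp(target_spec, dead) > 0]
  if (length(dead))
    stopf("degenerate input: empty spectrum shell(s) %s below cutoff",
          paste(dead - 1, collapse = ", "))
  gain <- equalization_vector(input_spec, target_spec)
  rg <- radial_shell_grid(dim(arr))
  g3 <- if (interpolation == "shell") {
    gain[pmin(round(rg), ns - 1) + 1L]
  } else {
    approx(0:(ns - 1), gain, xout = pmin(rg, ns - 1), rule = 2)$y
  }
  dim(g3) <- dim(arr)
  if (!is.null(lowpass)) g3 <- g3 * lowpass_gain(lowpass, rg, ns)
  out <- Re(fft(fft(arr) * g3, inverse = TRUE)) / length(arr)
  if (inherits(tomo, "tomogram")) {
    tomo$data <- out
    tomo
  } else out
}

target_amp <- function(target_spec, idx) {
  a <- if (inherits(target_spec, "radial_spectrum"))
    target_spec$amplitudes else as.numeric(target_spec)
  out <- rep(0, length(idx))
  ok <- idx <= length(a)
  out[ok] <- a[idx[ok]]
  out
}

# Session cache for the packaged default target spectrum.
.spectrum_cache <- new.env(parent = emptyenv())

#' Default high-contrast target spectrum
#'
#' The packaged equalization target is the radial spectrum of a
#' deterministic, high-contrast synthetic phantom (dense particles and
#' membranes at SNR 10, no missing wedge), standing in for a manually
#' selected high-contrast acquisition.  It is synthetic and generated at run
#' time; see the methods vignette.
#'
#' @param shape volume shape the spectrum should be computed for.
#' @return A [radial_spectrum()].
#' @export
default_target_spectrum <- function(shape = c(64, 64, 64)) {
  key <- paste(shape, collapse = "x")
  if (!is.null(.spectrum_cache[[key]])) return(.spectrum_cache[[key]])
  # particle size and count scale with the volume so any shape stays
  # comfortably below the packing limit
  r_nm <- 0.07 * min(shape) * 1.348
  spec <- phantom_spec(shape = shape, n_dense = 16, dense_radius_nm = r_nm,
                       n_hollow = 0, n_membranes = 1, snr = 10,
                       tilt_range_deg = 90, seed = 971)
  ph <- generate_phantom(spec)
  out <- radial_amplitude_spectrum(standardize(ph$tomogram))
  .spectrum_cache[[key]] <- out
  out
}
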
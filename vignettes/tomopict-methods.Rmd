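---
title: "Segmenting and localizing macromolecules in cryo-electron tomograms with tomopict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and localizing macromolecules in cryo-electron tomograms with tomopict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomopict)
```

## The problem

Cellular cryo-electron tomography images vitrified cells in three dimensions
at molecular resolution, but the resulting tomograms are noisy, low-contrast,
and distorted by the missing wedge — the un-sampled region of Fourier space
left by the limited tilt range of the stage, which elongates every feature
along the beam (z) axis. Finding the molecules of interest in such volumes —
abundant dense particles such as ribosomes, sparse low-density shell-like
complexes such as fatty acid synthase (FAS), membranes, filaments — and
knowing which cellular compartment they sit in, is the rate-limiting step
between data collection and structural analysis.

tomopict implements a complete workflow for this task: a spectrum-equalization
pre-filter that standardizes tomogram contrast, a fixed-architecture 2D U-Net
that segments cellular compartments slice by slice, a configurable 3D U-Net
that segments particles and continuous structures, contextual post-processing
that turns probability maps into coordinate lists filtered by compartment,
and the evaluation metrics used to score such predictions. A seeded synthetic
phantom generator stands in for real tomograms, so the entire pipeline is
exercised end-to-end by the test suite without external data.

## Pre-processing: amplitude spectrum equalization

Tomograms acquired under different optical conditions (Volta phase plate
versus conventional defocus) differ strongly in contrast. The equalization
filter matches the radial amplitude spectrum of an input tomogram to that of
a high-contrast target: volumes are standardized to mean 0 and variance 1,
the 3D FFT amplitudes are radially averaged into integer frequency shells
(`radial_amplitude_spectrum()`), per-shell gains `target / input` are
expanded into a rotational kernel, multiplied with the input's Fourier
transform together with a sigmoidal low-pass
`S(s) = 1 / (1 + exp((s - c)/k))`, and the volume is transformed back
(`match_spectrum()`). A target spectrum shorter than the input spectrum is
zero-padded, so gains beyond the target's Nyquist are zero.

Numerical choices:

* **Shell indexing.** Per-axis frequencies are normalized to cycles/voxel, the
  radial coordinate is rescaled so the Nyquist frequency maps to the last
  shell, and each frequency sample contributes to the shell it rounds to.
  Samples beyond Nyquist (grid corners) are excluded from the averages and
  clamped to the last shell when the kernel is applied.
* **Gain application.** By default each Fourier sample receives the gain of
  the shell it rounds to — the same binning used for measurement — so the
  re-measured spectrum of the filtered volume reproduces the target exactly
  on the shells below the cutoff. This is the filter's defining contract and
  the form the acceptance checks verify. Linear radial interpolation of the
  gains is available (`interpolation = "linear"`) for users who prefer a
  smooth kernel; it trades shell-exactness (a few percent at the lowest
  shells, where gains change fastest) for the absence of shell-boundary
  discontinuities.
* **Low-pass defaults.** The sigmoid midpoint sits at `cutoff_fraction`
  (default 0.5) of the shell count and the transition width at 3% of the
  shell count; the division guard is `1e-8` of the input spectrum maximum.
* **Degenerate inputs.** An exactly empty input shell below the cutoff with a
  non-zero target is refused rather than amplified from nothing.
* **Normalization domain.** "Mean 0 and variance 1" is implemented as
  spatial-domain standardization before filtering. By Parseval's theorem this
  fixes the total Fourier power as well; interpreting the normalization as a
  per-coefficient frequency-domain operation would instead whiten the
  spectrum and destroy the very structure the filter transfers, so the
  spatial reading is used.
* **Packaged target.** The default target spectrum is generated at run time
  from a deterministic, high-contrast synthetic phantom (SNR 10, no wedge).
  It is a synthetic stand-in for a manually selected high-contrast
  acquisition, and any measured spectrum can be supplied as a CSV instead.

## Synthetic phantoms

`generate_phantom()` renders the classes of structures the networks are meant
to learn, with exact ground truth:

* **Dense particles** (ribosome-like): filled spheres of 10.78 nm radius at
  13.48 Å voxel spacing (the standard 4x-binned geometry), dark on the
  cryo-ET density convention (contrast −1 relative to the background).
* **Hollow particles** (FAS-like): spherical shells with 13.48 nm outer
  radius and 4 nm wall, at reduced contrast (−0.8) — the "low-density print"
  that makes such complexes hard to detect.
* **Membranes**: closed vesicle shells of 5 nm thickness.
* **Cytosol**: an ellipsoid (semi-axes 90% of the half-extent) that contains
  everything; its interior carries a mild contrast offset (−0.2) so
  compartment segmentation is learnable from intensity.

Placement is rejection sampling inside the cytosol with a minimum center
separation equal to the sum of the radii of the two objects involved plus a
two-voxel clearance; the clearance guarantees that rendered masks of
distinct objects can never touch (even diagonally), so ground-truth masks
round-trip exactly through 26-connected clustering. Large sparse objects
(vesicles, hollow shells) are placed before the abundant small ones, and an
over-packed request raises a capacity error rather than degrading silently.
The noise-free volume is corrupted by the missing wedge
(`apply_missing_wedge()`, Fourier coefficients outside ±`tilt_range_deg` of
the x axis in the (z, x) plane zeroed; ±60° by default) and then by additive
white Gaussian noise. The signal-to-noise ratio is defined as the variance of
the noise-free, wedge-filtered volume (over all voxels) divided by the noise
variance; defining it over foreground voxels only would be degenerate here,
because the rendered particles are near-constant inside (their
foreground-restricted variance is dominated by wedge ringing rather than by
the contrast that actually separates them from background). The default SNR
of 1.0 emulates a low-contrast acquisition.

What the phantoms deliberately do not model: the contrast transfer function,
dose-dependent damage, crowding by unannotated macromolecules, reconstruction
artifacts other than the wedge, and non-Gaussian detector noise. Passing
tests on phantoms therefore demonstrates that the machinery — filtering,
training, stitching, post-processing, scoring — is correct and learns under
realistic geometry, wedge and noise; it does not certify performance numbers
on real tomograms.

## The 2D compartment network

The 2D U-Net has a fixed architecture: depth 5 (four max-pools) and 16
initial features, doubling per level, with two 3x3 convolutions
(normalization + ReLU) per level, nearest-neighbour upsampling, skip
concatenation, and a per-class sigmoid head. Slices are processed as
288 x 288 tiles (a 256-pixel core plus 16 pixels of padding per side), and
predictions are cropped by 48 pixels per side before reassembly to suppress
border artifacts.

Because the crop (48) exceeds the tile padding (16), the tile geometry does
not determine a unique stitching scheme: seamless tessellation of the
crop-trimmed outputs forces a stride of `tile - 2 * crop` = 192, which is
what `extract_tiles()` uses (the slice is mirror-padded by the crop width,
plus whatever the last tile needs). The reassembly accumulator averages any
overlapping contributions, so it is also correct for denser tilings.
Reassembled maps are smoothed along z with a normalized 1D Gaussian (default
sigma: 1 slice) to remove single-slice false positives and thresholded at
0.75 by default.

Training uses Dice (or generalized Dice) loss, Adam (default learning rate
1e-3, batch 8), random dihedral augmentation (flips and 90° rotations applied
identically to tile and label), an 80/20 tile-level train/validation split,
early stopping with patience 10, and returns the best-validation weights.

## The 3D structure network

The 3D U-Net exposes the architectural knobs that matter for particles of
different size, abundance and contrast: depth `D`, initial filters `IF`, a
normalization switch `BN`, and dropout rates `ED` (encoder) and `DD`
(decoder), with multi-label support through per-class sigmoid outputs.
Volumes are processed in 64^3-voxel patches with 12 voxels of overlap;
at prediction time patch outputs are trimmed by half the overlap on interior
faces and residual overlaps averaged.

Design choices worth recording:

* **Normalization at batch size 1.** Gradients are accumulated over the
  batch sample by sample, so the `BN` layers normalize each channel over the
  spatial dimensions of the individual sample (with running statistics for
  inference). At batch size 1 this is exactly what batch normalization
  computes; it is sometimes called instance normalization.
* **Decoder shape.** Upsampled features are concatenated directly with the
  skip connection and reduced by the block's first convolution, rather than
  through a separate transposed convolution — one of the standard U-Net
  variants, chosen to keep the full-resolution compute down.
* **Dropout placement.** One inverted-dropout layer after each two-convolution
  block: rate `ED` in the encoder, `DD` in the decoder.
* **Foreground-aware sampling.** At least half of each epoch's training
  patches are centred (with jitter) on a foreground voxel. Sparse classes
  such as shell particles would otherwise almost never appear in uniformly
  sampled patches.
* **Generalized Dice weights** are `1 / (sum(target_c) + eps)^2`, the
  standard inverse-squared-volume weighting that rebalances rare classes.
* **Training data volume.** A warning is issued when fewer than 300 annotated
  instances (connected foreground components) are available, the practical
  minimum for particle learning.
* **Hyperparameter search** (`hyperparameter_sweep()`) is coordinate-wise in
  the fixed order D, IF, BN, ED, DD: each parameter's candidates are
  evaluated with the others held at their current best, then frozen. The
  cost is the sum, not the product, of the grid sizes.

The engine underneath both networks stores activations as voxels x channels
matrices and runs the 3^nd convolutions through compiled forward/backward
kernels with explicit backpropagation and Adam; gradient correctness is
pinned by finite-difference tests, and the compiled convolutions are checked
against a naive dense oracle.

## Post-processing and context integration

Probability maps are thresholded (default 0.5) and clustered into connected
components. 26-connectivity is the default — diagonal contacts are common in
anisotropic, wedge-elongated reconstructions — with 6-connectivity available.
Clusters can be filtered by size, then integrated with a region mask (for
example the 2D network's cytosol segmentation) in one of three modes:

* **intersection** — clip cluster voxels to the region and recompute
  centroids, dropping emptied clusters;
* **contact** — keep whole clusters that touch the region dilated by
  `dilation_voxels` (default 1);
* **colocalization** — keep whole clusters whose in-region voxel fraction
  reaches `overlap_fraction` (default 0.5).

The exact semantics of the three modes are this package's explicit
definitions of the three integration concepts; the defaults are conservative
and user-overridable. Particle coordinates are exported as cluster centroids
(unweighted voxel mean, scored by mean probability, largest cluster first).

For filaments, `sample_centerline()` exports coordinates at a fixed
arc-length spacing (6 voxels is the conventional step at 4x binning). The
centerline is extracted per 26-connected component as the geodesic path
between the component's two most distant voxels (double breadth-first
search); voxels further from the path than the estimated tube radius seed
additional branch paths, which are sampled the same way. This path-based
centerline was chosen over full topological thinning because it is simple,
robust on tubes, guarantees on-mask samples, and samples path endpoints
whenever they are at least half a spacing from the previous sample (so a
component shorter than the spacing yields a single point); it will
under-sample dense junction networks, which is acceptable for the sparse
filaments it is meant for.

## Evaluation

* `match_particles()` scores localization: a prediction is a true positive if
  it lies within a tolerance radius (default 10 voxels, 135 Å at 13.48 Å
  spacing) of an unmatched ground-truth particle. Matching is one-to-one and
  greedy by ascending distance, with ties broken by prediction order; the
  tests verify that this greedy rule attains the optimal assignment cardinality
  on instances with unique nearest neighbours.
* `voxel_f1()` scores segmentation: the Sorensen-Dice coefficient
  `2|A ∩ B| / (|A| + |B|)`, defined as 1 when both masks are empty (logged
  convention).
* `auprc()` scores probability maps on 5,000 randomly sampled voxels,
  sweeping every threshold attained by the sampled scores and integrating
  precision over recall by the trapezoidal rule — the curve is exact on the
  sample.
* `make_folds()` plans cross-validation with fixed-size held-out test sets;
  10 tomograms with 3 folds of 2 test tomograms reproduce the 8-train/2-test
  threefold layout used for particle tasks.

## Problem sizes used by the test suite and acceptance script

The repository's own experiments run at desk scale, chosen so a full
training-and-evaluation cycle completes on a single CPU while leaving the
task genuinely learnable rather than trivial:

* The 3D particle benchmark trains a D = 2 / IF = 4 network on four 128^3
  phantoms at SNR 1.0 with ~40 dense particles each (wedge ±60°), in 32^3
  patches (32 per epoch, batch 2, Adam 3e-3, 28 epochs, no augmentation —
  with four statistically identical training volumes the dihedral transforms
  add little and slow early convergence), and evaluates particle F1 on a
  fifth, held-out phantom after cytosol-intersection post-processing. The
  run is repeated with a second seed to check stability.
* The 2D compartment benchmark trains a depth-3 / IF-8 network on 64-pixel
  tiles of a cytosol-ellipsoid phantom at SNR 5 and evaluates voxel-F1 on a
  held-out phantom.

These are scaled-down analogues of the full-size tasks (which use GPU-scale
training on real tomograms); the pass criteria (particle F1 at least 0.8,
voxel-F1 at least 0.9) are sanity floors for the machinery, not performance
claims about real data.

## Conventions and limitations

* Arrays are indexed `(z, y, x)` with z fastest; particle CSVs store
  `x, y, z` in 0-based voxel units of the binned tomogram. MRC I/O permutes
  axes to the on-disk x-fastest order and writes mode-2 (float32) MRC2014.
* Duplicate removal keeps the higher-scoring member of a conflicting pair
  (elliptic constraint), falling back to list order; default exclusion radii
  are the particle radius in x/y and 1.5x that in z, compensating
  missing-wedge elongation.
* Training is deterministic for a fixed seed and thread count; all package
  randomness is drawn from seeded, restored RNG state.
* The networks here are CPU-scale re-implementations: they reproduce the
  architecture family and the processing contracts (tiling, stitching,
  losses, post-processing), not any released set of trained weights.
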
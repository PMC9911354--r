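# MRC2014 volume I/O.  The format stores a 1024-byte header followed by the
# voxel data with the x (column) axis fastest; tomogram arrays in this package
# are indexed (z, y, x) with z fastest, so axes are permuted on the way in
# and out.  Only single-volume files are supported; mode 2 (float32) is
# written, modes 0/1/2/6 are read.

#' Read an MRC2014 volume
#'
#' @param path path to an MRC file.
#' @param name identifier for the returned tomogram (defaults to the file name).
#' @return A [tomogram()] with `voxel_size_A` taken from the header cell
#'   dimensions.
#' @export
read_mrc <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("MRC file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 56, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 56, size = 4, endian = "little")
  seek(con, 208)
  map_tag <- rawToChar(readBin(con, "raw", n = 4))
  if (!identical(substr(map_tag, 1, 3), "MAP"))
    stopf("malformed MRC header (missing MAP tag): %s", path)
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (any(c(nx, ny, nz) < 1))
    stopf("malformed MRC header: non-positive dimensions")
  if (nz < 2)
    stopf("volume is not 3D (nz = %d); 2D MRC images are not supported", nz)
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_num[11:13]
  vox <- c(
    if (mz > 0 && cella[3] > 0) cella[3] / mz else 1,
    if (my > 0 && cella[2] > 0) cella[2] / my else 1,
    if (mx > 0 && cella[1] > 0) cella[1] / mx else 1)
  nsymbt <- hdr_int[24]
  seek(con, 1024 + max(0, nsymbt))
  n <- as.numeric(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little")),
    stopf("unsupported MRC mode %d", mode))
  if (length(vals) != n) stopf("truncated MRC data section: %s", path)
  arr <- aperm(array(vals, c(nx, ny, nz)), c(3, 2, 1))
  if (length(unique(round(vox, 6))) == 1L) vox <- vox[1]
  tomogram(arr, voxel_size_A = vox,
           name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a tomogram as an MRC2014 volume (mode 2, float32)
#'
#' Round-tripping through [read_mrc()] preserves the data to float32
#' precision and the voxel size to header precision.
#'
#' @param tomo a [tomogram()] or [label_mask()] (masks are written as float).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(tomo, path) {
  if (inherits(tomo, "label_mask"))
    tomo <- tomogram(tomo$data + 0, voxel_size_A = 1, name = "mask")
  stopifnot(inherits(tomo, "tomogram"))
  d <- dim(tomo$data)                      # (nz, ny, nx)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  vox <- rep(tomo$voxel_size_A, length.out = 3)  # (z, y, x)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  vals <- as.vector(aperm(tomo$data, c(3, 2, 1)))
  wi(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz))
  wf(c(nx * vox[3], ny * vox[2], nz * vox[1], 90, 90, 90))
  wi(c(1L, 2L, 3L))
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(1L, 0L))                            # ispg, nsymbt
  wi(rep(0L, 2))                           # extra words 25-26
  wi(c(0L, 20140L))                        # exttyp, nversion
  wi(rep(0L, 21))                          # remaining extra
  wf(c(0, 0, 0))                           # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(sd(vals))
  wi(0L)                                   # nlabl
  writeBin(raw(800), con)
  wf(vals)
  invisible(path)
}
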
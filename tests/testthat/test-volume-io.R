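test_that("MRC volumes round-trip bit-exactly with header voxel size", {
  set.seed(1)
  arr <- array(rnorm(32^3), c(32, 32, 32))
  # float32 storage: quantize first so the round trip is bit-exact
  arr <- readBin(writeBin(as.vector(arr), raw(), size = 4), "numeric",
                 n = length(arr), size = 4)
  dim(arr) <- c(32, 32, 32)
  tomo <- tomogram(arr, voxel_size_A = 13.48, name = "toy")
  path <- tempfile(fileext = ".mrc")
  write_mrc(tomo, path)
  back <- read_mrc(path)
  expect_identical(back$data, arr)
  expect_equal(back$voxel_size_A, 13.48, tolerance = 1e-6)
})

test_that("2D MRC images are rejected with a dimensionality error", {
  # hand-build a minimal header with nz = 1
  path <- tempfile(fileext = ".mrc")
  con <- file(path, "wb")
  writeBin(as.integer(c(4, 4, 1, 2, 0, 0, 0, 4, 4, 1)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(4, 4, 1, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")
  writeBin(as.integer(rep(0, 30)), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(0, con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(numeric(16), con, size = 4, endian = "little")
  close(con)
  expect_error(read_mrc(path), "not 3D")
})

test_that("malformed headers are rejected", {
  path <- tempfile(fileext = ".mrc")
  writeBin(raw(2048), path)
  expect_error(read_mrc(path), "malformed|MAP")
})

test_that("standardize yields zero mean, unit variance, and is idempotent", {
  set.seed(2)
  v <- tomogram(array(rnorm(16^3, mean = 5, sd = 2), c(16, 16, 16)))
  s <- standardize(v)
  expect_lt(abs(mean(s$data)), 1e-6)
  expect_lt(abs(sd(as.vector(s$data)) - 1), 1e-6)
  s2 <- standardize(s)
  expect_equal(s2$data, s$data, tolerance = 1e-6)
  expect_error(standardize(array(0, c(4, 4, 4))), "degenerate")
})

test_that("select_labels picks exactly the requested labels", {
  m <- label_mask(array(rep(0:2, length.out = 4^3), c(4, 4, 4)))
  b2 <- select_labels(m, 2)
  expect_identical(b2$data == 1L, m$data == 2)
  b12 <- select_labels(m, c(1, 2))
  expect_identical(as.vector(b12$data == 1L), m$data %in% c(1, 2))
  expect_warning(b9 <- select_labels(m, 9), "absent")
  expect_true(all(b9$data == 0))
})

test_that("paste_spheres matches the physical-distance definition", {
  # ribosome radius at the standard 4x-binned spacing: 10.78 nm / 1.348 nm
  # per voxel ~ 8 voxels
  ps <- particle_set(x = 16, y = 16, z = 16)
  m <- paste_spheres(ps, 10.78, c(33, 33, 33), voxel_size_A = 13.48)
  r_vox <- 10.78 * 10 / 13.48
  expect_equal(r_vox, 7.9970, tolerance = 1e-4)
  co <- which(m$data == 1, arr.ind = TRUE)
  dmax <- max(sqrt(rowSums((co - 17)^2)))
  expect_lte(dmax, r_vox)
  # radius of exactly one voxel spacing: center + 6 face neighbours
  m1 <- paste_spheres(particle_set(4, 4, 4), 1, c(9, 9, 9),
                      voxel_size_A = 10)
  expect_equal(sum(m1$data), 7)
  # coincident particles merge
  m2 <- paste_spheres(particle_set(c(4, 4), c(4, 4), c(4, 4)), 1,
                      c(9, 9, 9), voxel_size_A = 10)
  expect_equal(sum(m2$data), 7)
})

test_that("paste_spheres equals the brute-force union-of-balls oracle", {
  set.seed(3)
  for (rep in 1:3) {
    n <- sample(1:10, 1)
    ps <- particle_set(runif(n, 5, 58), runif(n, 5, 58), runif(n, 5, 58))
    r_nm <- runif(1, 2, 8)
    vox <- 10
    m <- paste_spheres(ps, r_nm, c(64, 64, 64), voxel_size_A = vox)
    co <- as.matrix(expand.grid(z = 0:63, y = 0:63, x = 0:63))
    inside <- rep(FALSE, nrow(co))
    for (i in seq_len(n)) {
      d2 <- (co[, "x"] - ps$x[i])^2 + (co[, "y"] - ps$y[i])^2 +
        (co[, "z"] - ps$z[i])^2
      inside <- inside | (sqrt(d2) * vox <= r_nm * 10)
    }
    expect_equal(sum(m$data), sum(inside))
  }
})

test_that("out-of-volume particles are skipped with a warning", {
  ps <- particle_set(c(4, 100), c(4, 4), c(4, 4))
  expect_warning(m <- paste_spheres(ps, 1, c(9, 9, 9), voxel_size_A = 10),
                 "outside")
  expect_equal(sum(m$data), 7)
})

test_that("remove_duplicates honors elliptic constraints, scores, and is idempotent", {
  # identical coordinates collapse to one particle
  p <- particle_set(c(5, 5), c(5, 5), c(5, 5))
  expect_equal(nrow(remove_duplicates(p, c(2, 2, 3))), 1)
  # boundary: separation just past r_x keeps both
  p2 <- particle_set(c(0, 2.001), c(0, 0), c(0, 0))
  expect_equal(nrow(remove_duplicates(p2, c(2, 2, 3))), 2)
  # the higher-score member of a conflicting pair wins
  p3 <- particle_set(c(0, 0.5), c(0, 0), c(0, 0), score = c(0.2, 0.9))
  kept <- remove_duplicates(p3, c(2, 2, 3))
  expect_equal(kept$score, 0.9)
  # idempotence on a random cloud
  set.seed(4)
  p4 <- particle_set(runif(50, 0, 30), runif(50, 0, 30), runif(50, 0, 30),
                     score = runif(50))
  once <- remove_duplicates(p4, c(3, 3, 4.5))
  twice <- remove_duplicates(once, c(3, 3, 4.5))
  expect_identical(once, twice)
})

test_that("remove_duplicates equals a brute-force elimination oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 50
    p <- particle_set(runif(n, 0, 25), runif(n, 0, 25), runif(n, 0, 25),
                      score = runif(n))
    r <- c(3, 3, 4.5)
    got <- remove_duplicates(p, r)
    # independent oracle: visit in score order, eliminate conflicters
    ord <- order(-p$score, seq_len(n))
    kept <- integer(0)
    for (i in ord) {
      conflict <- FALSE
      for (j in kept) {
        q <- ((p$x[i] - p$x[j]) / r[1])^2 + ((p$y[i] - p$y[j]) / r[2])^2 +
          ((p$z[i] - p$z[j]) / r[3])^2
        if (q < 1) { conflict <- TRUE; break }
      }
      if (!conflict) kept <- c(kept, i)
    }
    expect_setequal(got$score, p$score[kept])
  }
})

test_that("particle CSVs round-trip and validate mandatory columns", {
  p <- particle_set(c(1.25, 2, 3), c(4, 5, 6), c(7, 8, 9.5),
                    class_label = "ribosome", score = c(0.1, NA, 0.9))
  path <- tempfile(fileext = ".csv")
  write_particles(p, path)
  back <- read_particles(path)
  expect_equal(back$x, p$x, tolerance = 1e-6)
  expect_equal(back$z, p$z, tolerance = 1e-6)
  expect_equal(back$class, p$class)
  expect_equal(nrow(read_particles(path)), 3)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2"), bad)
  expect_error(read_particles(bad), "mandatory")
})
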
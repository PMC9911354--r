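ball_map <- function(shape, centers, r, value = 0.9) {
  arr <- array(0, shape)
  for (i in seq_len(nrow(centers))) {
    m <- paste_spheres(particle_set(centers[i, 1], centers[i, 2],
                                    centers[i, 3]),
                       r, shape, voxel_size_A = 10)
    arr[m$data == 1] <- value
  }
  arr
}

test_that("threshold_cluster separates components and filters by size", {
  pm <- ball_map(c(40, 40, 40), rbind(c(10, 10, 10), c(30, 30, 30)), 2.8)
  cl <- threshold_cluster(pm, 0.5, min_size = 50)
  expect_length(cl$clusters, 2)
  expect_length(threshold_cluster(pm, 0.5, min_size = 150)$clusters, 0)
  # conservation: total cluster voxels equal the supra-threshold count
  cl_all <- threshold_cluster(pm, 0.5, min_size = 1)
  expect_equal(sum(vapply(cl_all$clusters, `[[`, numeric(1), "size")),
               sum(pm >= 0.5))
})

test_that("corner-touching blobs merge under 26- but not 6-connectivity", {
  arr <- array(0, c(8, 8, 8))
  arr[2:3, 2:3, 2:3] <- 1
  arr[4:5, 4:5, 4:5] <- 1          # touches only at the corner voxel pair
  expect_length(threshold_cluster(arr, 0.5, connectivity = 26)$clusters, 1)
  expect_length(threshold_cluster(arr, 0.5, connectivity = 6)$clusters, 2)
})

test_that("centroids equal the mean-of-indices oracle and order by size", {
  set.seed(70)
  arr <- array(0, c(30, 30, 30))
  arr[3:6, 4:5, 2:8] <- 0.8         # 4*2*7 = 56 voxels
  arr[20:21, 20:21, 20:21] <- 0.9   # 8 voxels
  cl <- threshold_cluster(arr, 0.5)
  ps <- centroids(cl)
  expect_equal(nrow(ps), 2)
  # largest first
  expect_equal(ps$z[1], mean(3:6) - 1)
  expect_equal(ps$y[1], mean(4:5) - 1)
  expect_equal(ps$x[1], mean(2:8) - 1)
  expect_equal(ps$score[1], 0.8)
  expect_equal(ps$z[2], mean(20:21) - 1)
  # symmetric ball: centroid within half a voxel of its center
  pm <- ball_map(c(21, 21, 21), rbind(c(10, 10, 10)), 3)
  cb <- centroids(threshold_cluster(pm, 0.5))
  expect_lt(max(abs(c(cb$x, cb$y, cb$z) - 10)), 0.5)
  # empty cluster set gives an empty particle set
  expect_equal(nrow(centroids(threshold_cluster(array(0, c(5, 5, 5)) + 0.01,
                                                0.5))), 0)
})

test_that("region filtering implements intersection, contact, colocalization", {
  arr <- array(0, c(20, 20, 20))
  arr[5:8, 5:8, 5:8] <- 0.9            # cluster A: 64 voxels
  arr[14:16, 14:16, 14:16] <- 0.9      # cluster B: fully outside region
  cl <- threshold_cluster(arr, 0.5)
  region <- array(0L, c(20, 20, 20))
  region[1:10, 1:10, 1:6] <- 1L        # covers part of A only
  # fully-outside clusters are removed in every mode
  for (mode in c("intersection", "contact", "colocalization")) {
    out <- apply_region_mask(cl, label_mask(region), region_mode(mode))
    expect_length(out$clusters, 1)
  }
  # intersection clips voxels and recomputes the centroid
  out_i <- apply_region_mask(cl, label_mask(region),
                             region_mode("intersection"))
  expect_equal(out_i$clusters[[1]]$size, 4 * 4 * 2)
  expect_equal(out_i$clusters[[1]]$centroid[["x"]], mean(5:6) - 1)
  # contact keeps whole clusters across a 1-voxel gap
  gap_region <- array(0L, c(20, 20, 20))
  gap_region[5:8, 5:8, 9] <- 1L        # adjacent plane, no overlap
  out_c <- apply_region_mask(cl, label_mask(gap_region),
                             region_mode("contact", dilation_voxels = 1))
  expect_length(out_c$clusters, 1)
  expect_equal(out_c$clusters[[1]]$size, 64)   # intact, not clipped
  out_c0 <- apply_region_mask(cl, label_mask(gap_region),
                              region_mode("contact", dilation_voxels = 0))
  expect_length(out_c0$clusters, 0)
  # colocalization: cluster 50% inside passes at 0.5, fails above
  half_region <- array(0L, c(20, 20, 20))
  half_region[5:8, 5:8, 5:6] <- 1L     # covers half of A
  out_h <- apply_region_mask(cl, label_mask(half_region),
                             region_mode("colocalization",
                                         overlap_fraction = 0.5))
  expect_length(out_h$clusters, 1)
  out_h2 <- apply_region_mask(cl, label_mask(half_region),
                              region_mode("colocalization",
                                          overlap_fraction = 0.6))
  expect_length(out_h2$clusters, 0)
  expect_error(region_mode("nearby"), "arg")
})

test_that("centerline sampling spaces points along a straight cylinder", {
  arr <- array(0L, c(20, 20, 70))
  for (x in 6:65)                       # 60-voxel cylinder along x
    arr[8:12, 8:12, x] <- 1L
  ps <- sample_centerline(arr, spacing_voxels = 6)
  expect_gte(nrow(ps), 9)
  expect_lte(nrow(ps), 12)
  # consecutive samples along the path are spaced about one step apart
  gaps <- sqrt(diff(ps$x)^2 + diff(ps$y)^2 + diff(ps$z)^2)
  expect_true(all(gaps >= 4))
  expect_true(all(gaps <= 8))
  # all samples lie inside the mask
  expect_true(all(arr[cbind(ps$z + 1, ps$y + 1, ps$x + 1)] == 1))
})

test_that("short components give one point and curved tubes stay in-mask", {
  arr <- array(0L, c(10, 10, 10))
  arr[5, 5, 4:6] <- 1L
  expect_equal(nrow(sample_centerline(arr, spacing_voxels = 10)), 1)
  # quarter-circle tube
  big <- array(0L, c(12, 60, 60))
  for (t in seq(0, pi / 2, length.out = 200)) {
    cy <- round(8 + 40 * sin(t)); cx <- round(8 + 40 * cos(t))
    big[5:7, cy + (-1:1), cx + (-1:1)] <- 1L
  }
  ps <- sample_centerline(big, spacing_voxels = 6)
  expect_gt(nrow(ps), 5)
  expect_true(all(big[cbind(ps$z + 1, ps$y + 1, ps$x + 1)] == 1))
})
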
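# Volumetric data model, NIfTI round-trips, mm geometry, peaks and clusters.

test_that("NIfTI round-trip preserves values and geometry", {
  g <- volume_grid(c(4, 4, 4), voxel_size = 2, origin = c(-10, -20, -30))
  vals <- array(rnorm(64), c(4, 4, 4))
  m <- volume_map(vals, g)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  back <- read_volume(f)
  expect_identical(as.vector(back$values), as.vector(vals))
  expect_equal(back$grid$voxel_size, c(2, 2, 2), tolerance = 1e-6)
  expect_equal(back$grid$origin, c(-10, -20, -30), tolerance = 1e-6)

  zero <- volume_map(array(0, c(4, 4, 4)), volume_grid(c(4, 4, 4)))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(zero, f2)
  expect_identical(as.vector(read_volume(f2)$values), rep(0, 64))
})

test_that("4D runs round-trip and bad inputs are rejected", {
  g <- volume_grid(c(3, 3, 2))
  br <- bold_run(array(rnorm(3 * 3 * 2 * 5), c(3, 3, 2, 5)), g, tr_s = 3.2)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(br, f)
  back <- read_volume(f)
  expect_s3_class(back, "bold_run")
  expect_identical(as.vector(back$data), as.vector(br$data))
  expect_equal(back$tr_s, 3.2, tolerance = 1e-6)

  # 5D image is rejected
  img5 <- RNifti::asNifti(array(0, c(2, 2, 2, 2, 2)))
  f5 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img5, f5)
  expect_error(read_volume(f5), "3D or 4D")

  # sheared affine is rejected
  a <- array(rnorm(8), c(2, 2, 2))
  img <- RNifti::asNifti(a)
  aff <- diag(c(2, 2, 2, 1)); aff[1, 2] <- 0.5
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  fs <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, fs)
  expect_error(read_volume(fs), "shear")
})

test_that("mm/index mapping round-trips on voxel centers", {
  g <- volume_grid(c(5, 6, 7), voxel_size = c(2, 2.5, 3), origin = c(1, -2, 3))
  idx <- as.matrix(expand.grid(0:4, 0:5, 0:6))
  expect_identical(mm_to_index(g, index_to_mm(g, idx)), matrix(as.integer(idx), ncol = 3))
})

test_that("sphere_voxels matches brute-force enumeration and known counts", {
  g <- volume_grid(c(9, 9, 9))
  ctr <- index_to_mm(g, matrix(c(4L, 4L, 4L), 1))
  expect_equal(nrow(sphere_voxels(g, ctr, 4)), 33)
  g17 <- volume_grid(c(17, 17, 17))
  ctr17 <- index_to_mm(g17, matrix(c(8L, 8L, 8L), 1))
  expect_equal(nrow(sphere_voxels(g17, ctr17, 8)), 257)

  # radius 0 returns exactly the center voxel
  s0 <- sphere_voxels(g, ctr, 0)
  expect_equal(nrow(s0), 1)
  expect_equal(as.integer(s0), c(4L, 4L, 4L))

  # equality with brute force, monotone growth in radius, mask respected
  set.seed(42)
  mask <- array(runif(9^3) > 0.3, c(9, 9, 9))
  prev <- -1
  for (r in c(0, 1.5, 2, 3.7, 4, 6)) {
    sv <- sphere_voxels(g, ctr, r, mask)
    bf <- brute_sphere(g, ctr, r, mask)
    expect_equal(nrow(sv), nrow(bf))
    expect_setequal(paste(sv[, 1], sv[, 2], sv[, 3]),
                    paste(bf[, 1], bf[, 2], bf[, 3]))
    expect_gte(nrow(sv), prev)
    prev <- nrow(sv)
  }
  expect_error(sphere_voxels(g, c(100, 0, 0), 4), "outside")
})

test_that("greedy peak selection honours the 16-mm rule and tie-breaks", {
  # three peaks on a line at x = 0, 10, 20 mm with T = 10, 9, 8
  g <- volume_grid(c(15, 5, 5))
  vals <- array(0, c(15, 5, 5))
  vals[1, 3, 3] <- 10; vals[6, 3, 3] <- 9; vals[11, 3, 3] <- 8
  pk <- select_peaks(volume_map(vals, g), voxel_threshold = 5, min_distance_mm = 16)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$x_mm, c(0, 20))
  expect_equal(pk$stat, c(10, 8))

  # min_distance 0 returns all local maxima
  pk0 <- select_peaks(volume_map(vals, g), 5, 0)
  expect_equal(nrow(pk0), 3)

  # single suprathreshold voxel -> one-row table
  v1 <- array(0, c(5, 5, 5)); v1[2, 2, 2] <- 7
  expect_equal(nrow(select_peaks(volume_map(v1, volume_grid(c(5, 5, 5))), 5, 16)), 1)

  # equal-valued peaks 10 mm apart: smaller linear index wins
  v2 <- array(0, c(9, 5, 5))
  v2[2, 3, 3] <- 5; v2[7, 3, 3] <- 5
  pk2 <- select_peaks(volume_map(v2, volume_grid(c(9, 5, 5))), 1, 16)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$x_mm, 2)

  # selected peaks are pairwise >= min_distance apart (property)
  set.seed(7)
  vr <- array(rnorm(9^3), c(9, 9, 9))
  pkr <- select_peaks(volume_map(vr, volume_grid(c(9, 9, 9))), 0.5, 6)
  if (nrow(pkr) > 1) {
    dm <- as.matrix(dist(pkr[, c("x_mm", "y_mm", "z_mm")]))
    expect_true(all(dm[upper.tri(dm)] >= 6))
  }
})

test_that("threshold_clusters partitions suprathreshold voxels correctly", {
  g <- volume_grid(c(6, 6, 6))
  v <- array(0, c(6, 6, 6))
  v[2, 2, 2] <- 1; v[3, 2, 2] <- 1          # face-sharing pair
  cl <- threshold_clusters(volume_map(v, g), 0.5, connectivity = 6)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 2)

  v2 <- array(0, c(6, 6, 6))
  v2[2, 2, 2] <- 1; v2[3, 3, 3] <- 1        # corner-diagonal pair
  expect_length(threshold_clusters(volume_map(v2, g), 0.5, connectivity = 6), 2)
  expect_length(threshold_clusters(volume_map(v2, g), 0.5, connectivity = 26), 1)

  # 3x3x3 block is one 27-voxel cluster at any connectivity
  v3 <- array(0, c(6, 6, 6))
  v3[2:4, 2:4, 2:4] <- 1
  for (conn in c(6, 18, 26)) {
    cl3 <- threshold_clusters(volume_map(v3, g), 0.5, connectivity = conn)
    expect_length(cl3, 1)
    expect_equal(cl3[[1]]$size, 27)
  }

  # partition property on random maps: disjoint and exhaustive
  set.seed(11)
  vr <- array(rnorm(6^3), c(6, 6, 6))
  clr <- threshold_clusters(volume_map(vr, g), 1, connectivity = 18)
  all_vox <- do.call(rbind, lapply(clr, `[[`, "voxels"))
  keys <- paste(all_vox[, 1], all_vox[, 2], all_vox[, 3])
  expect_false(anyDuplicated(keys) > 0)
  expect_equal(length(keys), sum(vr > 1))
})
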
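test_that("sphere masks match the brute-force lattice count", {
  aff <- diag(c(3, 3, 3, 1))
  # brute force: 3 mm lattice points within 8 mm of a lattice point
  cnt <- 0L
  for (i in -3:3) for (j in -3:3) for (k in -3:3)
    if (9 * (i^2 + j^2 + k^2) <= 64) cnt <- cnt + 1L
  m <- makeSphereMask(list(name = "v", x = 21, y = 21, z = 21, radius = 8),
                      c(15, 15, 15), aff)
  expect_equal(nrow(m), cnt)
  expect_equal(cnt, 81L)
  # translation by a lattice vector preserves the count
  m2 <- makeSphereMask(list(name = "v", x = 24, y = 18, z = 27, radius = 8),
                       c(17, 17, 17), aff)
  expect_equal(nrow(m2), 81L)
  # sub-voxel radius centered on a voxel center: exactly 1 voxel
  m3 <- makeSphereMask(list(name = "v", x = 21, y = 21, z = 21, radius = 1),
                       c(15, 15, 15), aff)
  expect_equal(nrow(m3), 1L)
  expect_equal(unname(m3[1, ]), c(8L, 8L, 8L))
  expect_error(
    makeSphereMask(list(name = "far", x = 500, y = 0, z = 0, radius = 8),
                   c(15, 15, 15), aff),
    "far")
})

test_that("mean extraction is the voxel average", {
  dim3 <- c(6, 6, 4); nT <- 20
  set.seed(31)
  arr <- array(rnorm(prod(dim3) * nT), c(dim3, nT))
  aff <- diag(c(3, 3, 3, 1))
  mask <- makeSphereMask(list(name = "m", x = 6, y = 6, z = 3, radius = 4),
                         dim3, aff)
  got <- extractMean(arr, mask)
  # brute-force summation oracle
  oracle <- numeric(nT)
  for (t in seq_len(nT)) {
    s <- 0
    for (v in seq_len(nrow(mask)))
      s <- s + arr[mask[v, 1], mask[v, 2], mask[v, 3], t]
    oracle[t] <- s / nrow(mask)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # identical voxels: unchanged; s and -s: zero
  series <- sin(seq_len(nT))
  arr2 <- array(0, c(2, 1, 1, nT))
  arr2[1, 1, 1, ] <- series; arr2[2, 1, 1, ] <- series
  maskAll <- structure(cbind(c(1L, 2L), 1L, 1L), linear = 1:2)
  expect_equal(extractMean(arr2, maskAll), series)
  arr2[2, 1, 1, ] <- -series
  expect_equal(extractMean(arr2, maskAll), rep(0, nT))
})

test_that("first eigenvariate recovers rank-1 structure with the sign rule", {
  nT <- 50
  set.seed(37)
  series <- rnorm(nT)
  arr <- array(0, c(3, 1, 1, nT))
  for (v in 1:3) arr[v, 1, 1, ] <- series * c(1, 2, 0.5)[v]
  mask <- structure(cbind(1:3, 1L, 1L), linear = 1:3)
  eig <- extractFirstEigenvariate(arr, mask)
  expect_gt(cor(eig, series), 1 - 1e-10)
  # s and -s voxels: mean is degenerate; tie-break on the first voxel
  arr2 <- array(0, c(2, 1, 1, nT))
  arr2[1, 1, 1, ] <- series; arr2[2, 1, 1, ] <- -series
  mask2 <- structure(cbind(1:2, 1L, 1L), linear = 1:2)
  eig2 <- extractFirstEigenvariate(arr2, mask2)
  expect_gt(cor(eig2, series), 1 - 1e-10)
  # matches an independent full decomposition up to sign
  dim3 <- c(5, 2, 1); nVox <- 10
  arr3 <- array(rnorm(prod(dim3) * nT), c(dim3, nT))
  mask3 <- structure(as.matrix(expand.grid(1:5, 1:2, 1)),
                     linear = 1:10)
  eig3 <- extractFirstEigenvariate(arr3, mask3)
  V <- t(matrix(arr3, nVox, nT))
  V <- V - rep(1, nT) %*% t(colMeans(V))
  full <- eigen(V %*% t(V))$vectors[, 1]
  expect_equal(cor(eig3, full)^2, 1, tolerance = 1e-10)
})

test_that("extraction is invariant to voxel ordering within the mask", {
  dim3 <- c(6, 6, 4); nT <- 15
  set.seed(41)
  arr <- array(rnorm(prod(dim3) * nT), c(dim3, nT))
  mask <- makeSphereMask(list(name = "m", x = 6, y = 6, z = 3, radius = 4),
                         dim3, diag(c(3, 3, 3, 1)))
  perm <- sample(nrow(mask))
  maskP <- structure(mask[perm, ], linear = attr(mask, "linear")[perm])
  expect_equal(extractMean(arr, mask), extractMean(arr, maskP))
  e1 <- extractFirstEigenvariate(arr, mask)
  e2 <- extractFirstEigenvariate(arr, maskP)
  expect_equal(abs(cor(e1, e2)), 1, tolerance = 1e-10)
})

test_that("embedded synthetic volumes round-trip through extraction", {
  cfg <- syntheticConfig(nSubjects = 1L, seed = 2L,
                         roiNames = c("A", "B"), activatedRois = "A",
                         trajectories = list(), design = shortDesign())
  ds <- simulateCohort(cfg)
  rois <- data.frame(name = c("A", "B"), x = c(12, 36), y = c(12, 36),
                     z = c(15, 15), radius = c(8, 8))
  # noiseless: mean extraction is exact
  out0 <- embedInVolumes(ds, rois, dim = c(20, 20, 12), voxelNoiseSd = 0,
                         dir = tempfile("vol0"))
  img0 <- RNifti::readNifti(out0$imagePaths[1])
  rt0 <- extractRoiSeries(img0, readRoiTable(out0$roiTablePath),
                          method = "mean", t0 = ds@subjects[[1]]@t0)
  expect_equal(roiValues(rt0), roiValues(cohortSubjects(ds)[[1]]),
               tolerance = 1e-6)
  expect_equal(repetitionTime(cfg@design), rt0@tr, tolerance = 1e-6)
  # default voxel noise: correlation above 0.99, both methods
  out1 <- embedInVolumes(ds, rois, dim = c(20, 20, 12),
                         voxelNoiseSd = 0.1, dir = tempfile("vol1"))
  img1 <- RNifti::readNifti(out1$imagePaths[1])
  for (method in c("mean", "eigenvariate")) {
    rt1 <- extractRoiSeries(img1, readRoiTable(out1$roiTablePath),
                            method = method, t0 = ds@subjects[[1]]@t0)
    for (roi in c("A", "B"))
      expect_gt(cor(roiValues(rt1)[, roi],
                    roiValues(cohortSubjects(ds)[[1]])[, roi]), 0.99)
  }
  # overlapping spheres are a geometry error
  bad <- data.frame(name = c("A", "B"), x = c(12, 16), y = c(12, 12),
                    z = c(15, 15), radius = c(8, 8))
  expect_error(embedInVolumes(ds, bad, dim = c(20, 20, 12)), "overlap")
})
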
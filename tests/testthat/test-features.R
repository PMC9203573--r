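# compact extraction config used in the slower end-to-end feature tests
fastConfig <- extractionConfig(filtersEnabled = "original",
                               binCounts = c(8L, 32L),
                               textureFamilies = c("glcm", "glrlm"))

test_that("isotropic preprocessing short-circuits and rescales correctly", {
  msk <- mkSphereMask(6)
  img <- mkNoiseImage(dim(voxels(msk)))
  out <- preprocessImage(img, msk)
  expect_identical(voxels(out$image), voxels(img))

  msk2 <- mkSphereMask(8, spacing = c(2, 2, 2))
  img2 <- mkNoiseImage(dim(voxels(msk2)), spacing = c(2, 2, 2))
  out2 <- preprocessImage(img2, msk2)
  expect_equal(spacing(out2$image), c(1, 1, 1))
  expect_true(all(abs(dim(voxels(out2$image)) -
                      2 * dim(voxels(img2))) <= 1))
  # B-spline interpolation reproduces constants (partition of unity)
  flat <- imageVolume(array(55, dim(voxels(msk2))), spacing = c(2, 2, 2))
  outF <- preprocessImage(flat, msk2)
  expect_lt(max(abs(voxels(outF$image) - 55)), 1e-8)
})

test_that("resegmentation windows the mask by intensity", {
  dims <- c(10L, 10L, 10L)
  vox <- array(0, dims)
  msk <- array(0, dims); msk[3:8, 3:8, 3:8] <- 1
  vox[3:8, 3:8, 3:5] <- 500   # half the mask out of window
  img <- imageVolume(vox); m <- roiMask(msk)
  expect_identical(sum(voxels(resegmentMask(img, m, c(-150, 180)))),
                   sum(msk) / 2)
  inWin <- imageVolume(array(50, dims))
  expect_identical(voxels(resegmentMask(inWin, m, c(-150, 180))),
                   voxels(m))
  air <- imageVolume(array(-1000, dims))
  expect_error(resegmentMask(air, m, c(-150, 180)), "emptied")
})

test_that("fixed-bin-count discretization follows the bin-edge arithmetic", {
  dims <- c(8L, 1L, 1L)
  m <- roiMask(array(1, dims))
  img <- imageVolume(array(0:7, dims))
  expect_identical(as.integer(discretizeIntensities(img, m, 8L)), 1:8)
  const <- imageVolume(array(3.7, dims))
  expect_true(all(discretizeIntensities(const, m, 8L) == 1L))
  dims2 <- c(4L, 1L, 1L)
  vals <- imageVolume(array(c(0, 3.9, 4.0, 8.0), dims2))
  expect_identical(as.integer(discretizeIntensities(vals, roiMask(array(1, dims2)), 2L)),
                   c(1L, 1L, 2L, 2L))
})

test_that("the filter bank yields 12 images with the expected responses", {
  img <- mkNoiseImage(c(20L, 20L, 20L))
  bank <- filterBank(img)
  expect_length(bank, 12L)
  expect_identical(names(bank)[1:4],
                   c("original", "log-sigma-1-0-mm-3D",
                     "log-sigma-3-0-mm-3D", "log-sigma-6-0-mm-3D"))
  const <- imageVolume(array(77, c(20L, 20L, 20L)))
  bankC <- filterBank(const)
  expect_lt(max(abs(voxels(bankC[["log-sigma-3-0-mm-3D"]]))), 1e-10)
  expect_lt(max(abs(voxels(bankC[["wavelet-LLL"]]) - 77)), 1e-10)
  expect_lt(max(abs(voxels(bankC[["wavelet-HHH"]]))), 1e-10)
})

test_that("first-order features match closed forms on a lattice fixture", {
  dims <- c(3L, 3L, 3L)
  img <- imageVolume(array(1:27, dims))
  msk <- roiMask(array(1, dims))
  cfg <- extractionConfig(filtersEnabled = "original",
                          familiesEnabled = "firstorder",
                          resegmentationWindowHu = c(-1000, 1000))
  fv <- extractFeatures(img, msk, cfg)
  f <- function(n) fv[[paste0("original_firstorder_", n)]]
  expect_equal(f("Mean"), 14)
  expect_equal(f("Median"), 14)
  expect_equal(f("Minimum"), 1)
  expect_equal(f("Maximum"), 27)
  expect_equal(f("Range"), 26)
  expect_equal(f("Energy"), sum((1:27)^2))
  expect_equal(f("Variance"), mean((1:27 - 14)^2), tolerance = 1e-12)
  expect_equal(f("RootMeanSquared"), sqrt(mean((1:27)^2)), tolerance = 1e-12)
  expect_equal(f("MeanAbsoluteDeviation"), mean(abs(1:27 - 14)),
               tolerance = 1e-12)
  expect_equal(f("Skewness"), 0, tolerance = 1e-12)
  expect_equal(f("TotalEnergy"), sum((1:27)^2))  # 1 mm isotropic voxels
})

test_that("GLCM and GLRLM match hand-enumerated matrices on a 4x4 slice", {
  # gray-level pattern; first index is x, so x-lines are the rows below
  #   1 2 2 3
  #   1 1 3 3
  #   2 2 2 1
  #   3 1 2 1
  M <- matrix(c(1, 2, 2, 3,
                1, 1, 3, 3,
                2, 2, 2, 1,
                3, 1, 2, 1), nrow = 4, byrow = TRUE)
  # transpose so x-lines (first array index) equal the printed rows
  disc <- array(as.integer(t(M)), c(4L, 4L, 1L))
  glcm <- ipbm:::cpp_glcm(disc, c(4L, 4L, 1L), 3L)
  # direction (1,0,0): hand-tallied symmetric co-occurrences
  expected <- matrix(c(2, 4, 2,
                       4, 6, 1,
                       2, 1, 2), 3, 3, byrow = TRUE)
  expect_identical(glcm[, , 1], expected)

  glrlm <- ipbm:::cpp_glrlm(disc, c(4L, 4L, 1L), 3L)
  # direction (1,0,0): runs per level x length, hand-tallied
  expectedRl <- matrix(c(4, 1, 0, 0,
                         1, 1, 1, 0,
                         2, 1, 0, 0), 3, 4, byrow = TRUE)
  expect_identical(glrlm[, , 1], expectedRl)
  # out-of-plane direction (0,0,1): every voxel is a length-1 run
  expect_identical(glrlm[, 1, 3], as.numeric(table(factor(M, 1:3))))

  # single-voxel ROI: one run with probability 1 -> RunEntropy 0
  one <- array(0L, c(3L, 3L, 3L)); one[2, 2, 2] <- 1L
  rl1 <- ipbm:::cpp_glrlm(one, c(3L, 3L, 3L), 1L)
  fv <- ipbm:::glrlmFeatures(rl1, 1)
  expect_equal(fv[["RunEntropy"]], 0)
  expect_equal(fv[["RunPercentage"]], 1)  # one run covering the one voxel
})

test_that("whole-voxel translation leaves features exactly unchanged", {
  msk <- mkSphereMask(6, marginMm = 7)
  img <- mkNoiseImage(dim(voxels(msk)), seed = 3)
  fv1 <- extractFeatures(img, msk, fastConfig)
  shift <- function(a) {
    d <- dim(a); out <- array(0, d)
    out[2:d[1], , ] <- a[1:(d[1] - 1), , ]
    out
  }
  img2 <- imageVolume(shift(voxels(img)))
  msk2 <- roiMask(shift(voxels(msk)))
  fv2 <- extractFeatures(img2, msk2, fastConfig)
  expect_equal(fv1, fv2, tolerance = 1e-12)
})

test_that("aggregated texture features are stable under lattice rotation", {
  msk <- mkSphereMask(7, marginMm = 6)
  img <- mkNoiseImage(dim(voxels(msk)), seed = 9)
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , ]  # 90 deg about z
  fv1 <- extractFeatures(img, msk, fastConfig)
  fv2 <- extractFeatures(imageVolume(rot(voxels(img))),
                         roiMask(rot(voxels(msk))), fastConfig)
  tex <- grep("_glcm_|_glrlm_", names(fv1), value = TRUE)
  rel <- abs(fv2[tex] - fv1[tex]) / pmax(abs(fv1[tex]), 1e-8)
  expect_lt(max(rel), 0.05)
})

test_that("the inventory reproduces the published catalogue arithmetic", {
  inv <- enumerateInventory()
  expect_length(inv, 5486L)
  info <- parseFeatureName(inv)
  expect_identical(sum(info$family == "shape"), 14L)
  expect_identical(sum(info$family == "firstorder"), 216L)
  expect_identical(sum(!info$family %in% c("shape", "firstorder")), 5256L)
  expect_false(anyDuplicated(inv) > 0)
  # counts decompose as 14 + 12*18 + 12*73*|binCounts| for any bin set
  cfg2 <- extractionConfig(binCounts = c(8L, 32L))
  expect_length(enumerateInventory(cfg2), 14 + 12 * 18 + 12 * 73 * 2)
  shapeOnly <- extractionConfig(familiesEnabled = "shape")
  expect_length(enumerateInventory(shapeOnly), 14L)
  # extraction emits exactly the enumerated names, in order
  msk <- mkSphereMask(5, marginMm = 5)
  img <- mkNoiseImage(dim(voxels(msk)), seed = 2)
  fv <- extractFeatures(img, msk, fastConfig)
  expect_identical(names(fv), enumerateInventory(fastConfig))
})

test_that("shape features reflect the geometry of known solids", {
  msk <- mkSphereMask(10)
  fv <- extractFeatures(mkNoiseImage(dim(voxels(msk))), msk,
                        extractionConfig(familiesEnabled = "shape"))
  vol <- fv[["original_shape_VoxelVolume"]]
  expect_lt(abs(vol - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.05)
  expect_lt(abs(fv[["original_shape_Maximum3DDiameter"]] - 20) / 20, 0.1)
  # voxel-union surface of a sphere exceeds the smooth-sphere surface,
  # so Sphericity < 1; elongation of a sphere is ~1
  expect_lt(fv[["original_shape_Sphericity"]], 1)
  expect_gt(fv[["original_shape_Elongation"]], 0.95)
  ell <- mkEllipsoidMask(c(14, 7, 7))
  fe <- extractFeatures(mkNoiseImage(dim(voxels(ell))), ell,
                        extractionConfig(familiesEnabled = "shape"))
  expect_lt(abs(fe[["original_shape_Elongation"]] - 0.5), 0.06)
  expect_gt(fe[["original_shape_MajorAxisLength"]],
            fe[["original_shape_LeastAxisLength"]])
})

test_that("a plug-in extractor can replace the built-in engine", {
  msk <- mkSphereMask(5, marginMm = 5)
  img <- mkNoiseImage(dim(voxels(msk)))
  engine <- function(image, mask, config) c(custom_feature = 1.5)
  expect_identical(extractFeatures(img, msk, fastConfig, engine = engine),
                   c(custom_feature = 1.5))
})
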
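test_that("zero rigid transform short-circuits to the identity", {
  msk <- mkSphereMask(8)
  img <- mkNoiseImage(dim(voxels(msk)))
  out <- rigidPerturb(img, msk, c(0, 0, 0), c(0, 0, 0))
  expect_identical(voxels(out$image), voxels(img))
  expect_identical(voxels(out$mask), voxels(msk))
  expect_error(rigidPerturb(img, msk, c(NA, 0, 0), c(0, 0, 0)), "finite")
})

test_that("whole-voxel translation preserves the mask voxel count", {
  msk <- mkSphereMask(8)
  img <- mkNoiseImage(dim(voxels(msk)))
  out <- rigidPerturb(img, msk, c(0, 0, 0), c(1, 0, 0))
  expect_identical(sum(voxels(out$mask)), sum(voxels(msk)))
})

test_that("90-degree z-rotation of a box matches the analytic rotation", {
  dims <- c(40L, 40L, 40L)
  box <- array(0, dims)
  box[13:28, 17:24, 18:22] <- 1   # axis-aligned box, centred-ish
  msk <- roiMask(box)
  img <- mkNoiseImage(dims)
  out <- rigidPerturb(img, msk, c(0, 0, 90), c(0, 0, 0))
  got <- sum(voxels(out$mask))
  expect_lt(abs(got - sum(box)) / sum(box), 0.01)
  # the rotated box's bounding extents swap x and y
  idx <- which(voxels(out$mask) != 0, arr.ind = TRUE)
  expect_gt(diff(range(idx[, 2])), diff(range(idx[, 1])))
})

test_that("Gaussian noise field matches its nominal level and seed", {
  img <- imageVolume(array(100, c(64L, 64L, 64L)))
  expect_identical(voxels(addNoiseField(img, 0, seed = 1)), voxels(img))
  noisy <- addNoiseField(img, 20, seed = 7)
  expect_lt(abs(sd(voxels(noisy)) - 20) / 20, 0.02)
  expect_lt(abs(mean(voxels(noisy)) - 100), 0.5)
  expect_identical(voxels(noisy), voxels(addNoiseField(img, 20, seed = 7)))
  expect_false(identical(voxels(noisy),
                         voxels(addNoiseField(img, 20, seed = 8))))
  expect_error(addNoiseField(img, -1), ">= 0")
})

test_that("contour randomization behaves at its limits and is seeded", {
  msk <- mkSphereMask(20)
  expect_identical(voxels(randomizeContour(msk, 0, 8, 1)), voxels(msk))
  # small amplitude on a 20 mm sphere barely moves the boundary shell
  small <- randomizeContour(msk, 0.5, 8, seed = 2)
  expect_gt(diceCoefficient(msk, small), 0.9)
  a <- randomizeContour(msk, 3, 8, seed = 5)
  expect_identical(voxels(a), voxels(randomizeContour(msk, 3, 8, seed = 5)))
  expect_false(identical(voxels(a),
                         voxels(randomizeContour(msk, 3, 8, seed = 6))))
  # a huge field sweeps a tiny mask out of the grid entirely
  tiny <- array(0, c(10L, 10L, 10L)); tiny[5, 5, 5] <- 1
  expect_error(randomizeContour(roiMask(tiny), 400, 8, seed = 1),
               "amplitude")
})

test_that("Dice matches hand-counted overlaps and validates input", {
  msk <- mkSphereMask(8)
  expect_equal(diceCoefficient(msk, msk), 1.0)
  dims <- c(12L, 12L, 6L)
  a <- array(0, dims); a[2:3, 2:3, 2:3] <- 1          # 8 voxels
  b <- array(0, dims); b[2:3, 2:3, 3:4] <- 1          # overlap = 4
  expect_equal(diceCoefficient(roiMask(a), roiMask(b)), 0.5)
  disjoint <- array(0, dims); disjoint[9:10, 9:10, 4:5] <- 1
  expect_equal(diceCoefficient(roiMask(a), roiMask(disjoint)), 0.0)
  empty <- roiMask(array(0, dims))
  expect_error(diceCoefficient(empty, empty), "empty")
  expect_equal(diceCoefficient(roiMask(a), roiMask(b)),
               diceCoefficient(roiMask(b), roiMask(a)))
})

test_that("Hausdorff distance agrees with the brute-force boundary oracle", {
  dims <- c(16L, 16L, 16L)
  a <- array(0, dims); a[3, 3, 3] <- 1
  b <- array(0, dims); b[8, 3, 3] <- 1
  expect_equal(hausdorffDistance(roiMask(a), roiMask(b)), 5.0)
  expect_equal(hausdorffDistance(roiMask(a), roiMask(a)), 0.0)

  # nested boxes: outer 10^3, inner centred 6^3, computed by the O(n^2)
  # pairwise oracle
  outer <- array(0, dims); outer[4:13, 4:13, 4:13] <- 1
  inner <- array(0, dims); inner[6:11, 6:11, 6:11] <- 1
  expect_equal(hausdorffDistance(roiMask(outer), roiMask(inner)),
               oracleHausdorff(roiMask(outer), roiMask(inner)))

  # random small masks, anisotropic spacing, symmetry
  set.seed(42)
  for (rep in 1:10) {
    d <- c(9L, 9L, 9L)
    va <- array(0, d); vb <- array(0, d)
    va[sample(prod(d), 15)] <- 1
    vb[sample(prod(d), 15)] <- 1
    sp <- c(1, 1.5, 2)
    ma <- roiMask(va, sp); mb <- roiMask(vb, sp)
    expect_equal(hausdorffDistance(ma, mb), oracleHausdorff(ma, mb),
                 tolerance = 1e-12)
    expect_equal(hausdorffDistance(ma, mb), hausdorffDistance(mb, ma))
  }
  expect_error(hausdorffDistance(roiMask(array(0, dims)), roiMask(a)),
               "nonempty")
})

test_that("mean Dice decreases monotonically with DVF amplitude", {
  masks <- list(mkSphereMask(15), mkSphereMask(20))
  meanDice <- function(amp) {
    mean(unlist(lapply(masks, function(m)
      vapply(1:5, function(s)
        diceCoefficient(m, randomizeContour(m, amp, 8, seed = s)), 0))))
  }
  d <- vapply(c(1, 2, 4, 8), meanDice, 0)
  expect_true(all(diff(d) < 0))
})

test_that("the amplitude tuner reaches its Dice target on spheres", {
  masks <- lapply(c(15, 18, 22), mkSphereMask)
  spec <- perturbationSpec(targetDice = 0.85, seed = 3L)
  tuned <- tuneContourAmplitude(masks, spec, calibBatch = 2L)
  expect_true(tuned$converged)
  expect_lt(abs(tuned$achievedDice - 0.85), 0.011)
  # doubling the tuned amplitude strictly lowers the mean Dice
  diceAt <- function(amp) mean(unlist(lapply(masks, function(m)
    vapply(1:3, function(s)
      diceCoefficient(m, randomizeContour(m, amp, 8, seed = 50 + s)), 0))))
  expect_lt(diceAt(2 * tuned$amplitudeMm), diceAt(tuned$amplitudeMm))
})

test_that("perturbation sets honour the spec and a zero spec is identity", {
  cohort <- generatePhantomCohort(
    phantomConfig(nPatients = 2L, gridShape = c(26L, 26L, 26L),
                  lesionRadiusRangeMm = c(6, 8), seed = 6L))
  null <- perturbationSpec(nPerturbations = 3L, rotationDegRange = 0,
                           translationMmRange = 0, noiseSigmaHu = 0,
                           dvfAmplitudeMm = 0, seed = 1L)
  pset <- simulatePerturbationSet(cohort, null)
  expect_length(pset, 2L)
  expect_length(pset[[1]], 3L)
  for (s in pset[[1]]) {
    expect_identical(voxels(s$image), voxels(cohort[[1]]$image))
    expect_identical(voxels(s$mask), voxels(cohort[[1]]$mask))
  }
  spec <- perturbationSpec(nPerturbations = 2L, rotationDegRange = 5,
                           translationMmRange = 2, noiseSigmaHu = 5,
                           dvfAmplitudeMm = 1.5, seed = 9L)
  p1 <- simulatePerturbationSet(cohort, spec)
  p2 <- simulatePerturbationSet(cohort, spec)
  expect_identical(p1[[1]][[1]]$params, p2[[1]][[1]]$params)
  expect_identical(voxels(p1[[2]][[2]]$image), voxels(p2[[2]][[2]]$image))
  # independent draws per patient by default; shared draws when requested
  expect_false(identical(p1[[1]][[1]]$params$angles,
                         p1[[2]][[1]]$params$angles))
  shared <- perturbationSpec(nPerturbations = 2L, rotationDegRange = 5,
                             translationMmRange = 2, noiseSigmaHu = 5,
                             dvfAmplitudeMm = 1.5, sharedDraws = TRUE,
                             seed = 9L)
  ps <- simulatePerturbationSet(cohort, shared)
  expect_identical(ps[[1]][[1]]$params$angles, ps[[2]][[1]]$params$angles)
})
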
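test_that("ICC(1,1) matches the sum-of-squares oracle and clamps", {
  # 4x3 hand-built matrix against the spreadsheet-style oracle
  m <- matrix(c(9, 10, 8,
                6, 5, 7,
                8, 8, 9,
                2, 3, 2), 4, 3, byrow = TRUE)
  r <- icc11(m)
  expect_equal(r@estimate, oracleIcc11(m), tolerance = 1e-10)
  expect_true(r@ciLow <= r@estimate && r@estimate <= r@ciHigh)

  set.seed(1)
  for (rep in 1:40) {
    n <- sample(4:12, 1); k <- sample(2:6, 1)
    mm <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)) +
                 rep(rnorm(n, sd = runif(1, 0, 3)), k), n, k)
    expect_equal(icc11(mm)@estimate, min(1, max(0, oracleIcc11(mm))),
                 tolerance = 1e-10)
  }

  # raters agree exactly, subjects differ -> ICC 1
  perfect <- matrix(rep(c(1, 5, 9, 13), 3), 4, 3)
  expect_equal(icc11(perfect)@estimate, 1)
  expect_equal(icc11(perfect)@ciHigh, 1)
  # no subject variance, raters pure noise -> clamped to 0
  set.seed(2)
  flat <- matrix(rnorm(40), 4, 10)
  flat <- flat - rowMeans(flat) + 5
  expect_equal(icc11(flat)@estimate, 0)
  expect_error(icc11(matrix(3, 4, 3)), "zero total variance")
  expect_error(icc11(matrix(1:3, 1, 3)), ">= 2 subjects")
})

test_that("reliability labels follow the conventional bands", {
  expect_identical(classifyIcc(0.565), "moderate")
  expect_identical(classifyIcc(0), "poor")
  expect_identical(classifyIcc(0.499), "poor")
  expect_identical(classifyIcc(0.75), "good")
  expect_identical(classifyIcc(0.9), "excellent")  # left-closed boundary
  expect_identical(classifyIcc(1), "excellent")
  expect_error(classifyIcc(1.2), "in \\[0,1\\]")
  expect_error(classifyIcc(-0.1), "in \\[0,1\\]")
})

test_that("feature robustness recovers known variance structure", {
  n <- 50; k <- 20
  set.seed(31)
  subj <- rnorm(n, sd = 3)
  tabs <- lapply(seq_len(k), function(j) {
    tab <- cbind(
      invariant = seq_len(n),                    # identical across raters
      planted = subj + rnorm(n, sd = 1),         # true ICC 0.9
      noise = rnorm(n),                          # true ICC 0
      degenerate = rep(1, n))                    # no variance anywhere
    rownames(tab) <- sprintf("P%03d", seq_len(n))
    tab
  })
  rob <- featureRobustness(tabs)
  expect_equal(rob$icc[rob$feature == "invariant"], 1)
  expect_lt(abs(rob$icc[rob$feature == "planted"] - 0.9), 0.06)
  expect_lt(rob$icc[rob$feature == "noise"], 0.15)
  expect_true(rob$degenerate[rob$feature == "degenerate"])
  expect_equal(rob$icc[rob$feature == "degenerate"], 0)

  expect_identical(screenFeatures(rob, 0.75),
                   c("invariant", "planted"))
  # strict inequality at the threshold
  fake <- data.frame(feature = c("at", "above"), icc = c(0.75, 0.751))
  expect_identical(screenFeatures(fake, 0.75), "above")

  bad <- tabs
  rownames(bad[[2]]) <- rev(rownames(bad[[2]]))
  expect_error(featureRobustness(bad), "identical patient")
})

test_that("ICC confidence intervals cover the true value near 95%", {
  # reduced-replicate coverage check (the 500-replicate version runs in the
  # acceptance suite)
  hits <- vapply(1:150, function(s) {
    r <- icc11(generateIccTable(varianceComponentSpec(30, 10, 1, 1,
                                                      seed = 1000 + s)))
    r@ciLow <= 0.5 && 0.5 <= r@ciHigh
  }, TRUE)
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("model reliability is exactly 1 under identical perturbations", {
  d <- mkSurvivalData(30, beta = 1, seed = 12)
  raw <- cbind(f = d$x, g = rnorm(30))
  rownames(raw) <- sprintf("P%03d", 1:30)
  zs <- zscoreFit(raw)
  model <- fitCox(zscoreApply(raw, zs), d$time, d$event, 0.01,
                  center = zs$center, scale = zs$scale)
  tabs <- lapply(1:5, function(j) raw)
  rel <- modelReliability(model, tabs, d$time, d$event)
  origC <- cIndex(predictRisk(model, raw), d$time, d$event)
  expect_true(all(rel$cindex$cindex == origC))
  expect_identical(nrow(rel$cindex), 5L)
  expect_equal(rel$icc@estimate, 1)
  expect_identical(rel$icc@label, "excellent")
})

test_that("robustness screening improves model reliability (paired)", {
  # compact version of the validation experiment: 6 seeds here, 20 in the
  # acceptance suite
  delta <- vapply(1:6, function(s) {
    sim <- mkScreeningCohort(n = 60, k = 10, seed = 200 + s)
    split <- stratifiedSplit(sim$outcomes, 0.3, seed = s)
    cfg <- selectionConfig(nBootstrap = 40L, topFraction = 0.35, seed = s)
    un <- runModelingPipeline(sim$original, sim$perturbed, sim$outcomes,
                              split$train, split$test, cfg, NULL,
                              rfeRepeats = 3L, seed = s)
    sc <- runModelingPipeline(sim$original, sim$perturbed, sim$outcomes,
                              split$train, split$test, cfg, 0.75,
                              rfeRepeats = 3L, seed = s)
    if (!isTRUE(un$fitted) || !isTRUE(sc$fitted)) return(NA_real_)
    sc$reliabilityTest$icc@estimate - un$reliabilityTest$icc@estimate
  }, 0)
  delta <- delta[!is.na(delta)]
  expect_gte(length(delta), 4)
  expect_gt(mean(delta > 0), 0.5)
})

test_that("monotone degradation: stronger perturbation lowers feature ICC", {
  n <- 40
  set.seed(51)
  subj <- rnorm(n, sd = 2)
  meanIcc <- function(sdWithin) {
    tabs <- lapply(1:8, function(j) {
      tab <- cbind(f1 = subj + rnorm(n, sd = sdWithin),
                   f2 = 2 * subj + rnorm(n, sd = 2 * sdWithin))
      rownames(tab) <- sprintf("P%03d", seq_len(n)); tab
    })
    mean(featureRobustness(tabs)$icc)
  }
  levels <- vapply(c(0.5, 1.5, 4), meanIcc, 0)
  expect_true(all(diff(levels) < 0))
})
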
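test_that("z-score standardization uses training parameters only", {
  tab <- cbind(a = c(1, 2, 3), b = c(4, 4, 4), c = c(0, 10, 20))
  expect_warning(fit <- zscoreFit(tab), "constant")
  expect_identical(fit$features, c("a", "c"))
  z <- zscoreApply(tab, fit)
  expect_equal(z[, "a"], c(-1, 0, 1))  # sample SD convention
  # leakage guard: a test table transformed with train parameters differs
  # from a self-fitted transform
  test <- cbind(a = c(10, 11, 12), c = c(5, 6, 7))
  zTrain <- zscoreApply(test, fit)
  zSelf <- zscoreApply(test, zscoreFit(test))
  expect_false(isTRUE(all.equal(zTrain, zSelf)))
  allConst <- cbind(a = c(1, 1), b = c(2, 2))
  expect_error(zscoreFit(allConst), "zero variance")
})

test_that("log-rank p-values match the hand-computed O-E oracle", {
  # two groups with identical event-time patterns: statistic exactly 0
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- rep(1L, 8)
  feat <- c(0, 0, 0, 0, 1, 1, 1, 1)  # median split separates the halves
  p <- logrankP(feat, tt, ev)
  expect_equal(attr(p, "statistic"), 0, tolerance = 1e-12)
  expect_equal(as.numeric(p), 1)

  # textbook fixture with censoring: wrapper matches the O-E table oracle
  tt2 <- c(3, 5, 7, 9, 11, 2, 4, 6, 8, 10)
  ev2 <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  feat2 <- c(rep(0, 5), rep(1, 5))
  p2 <- logrankP(feat2, tt2, ev2)
  expect_equal(attr(p2, "statistic"),
               oracleLogrank(tt2, ev2, feat2 > median(feat2)),
               tolerance = 1e-6)
  # constant feature -> degenerate group with p = 1
  pc <- logrankP(rep(1, 10), tt2, ev2)
  expect_equal(as.numeric(pc), 1)
  expect_true(attr(pc, "degenerate"))
})

test_that("relevance filter returns the exact top fraction with tie rules", {
  set.seed(21)
  n <- 40
  tab <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, sprintf("f%02d", 1:20)))
  tt <- rexp(n); ev <- rbinom(n, 1, 0.5)
  cfg <- selectionConfig(nBootstrap = 20L, topFraction = 0.1, seed = 4L)
  rep1 <- relevanceFilter(tab, tt, ev, cfg)
  expect_length(rep1$selected, 2L)  # ceiling(0.1 * 20)
  expect_true(all(rep1$frequency >= 0 & rep1$frequency <= 20))
  expect_identical(rep1$selected,
                   relevanceFilter(tab, tt, ev, cfg)$selected)
})

test_that("relevance filter has power for a planted predictor and is
          calibrated under the null", {
  set.seed(8)
  n <- 60
  x <- rnorm(n)
  tt <- rexp(n, exp(1.5 * x))
  ev <- rbinom(n, 1, 0.75)
  tab <- cbind(signal = x, matrix(rnorm(n * 9), n, 9,
                                  dimnames = list(NULL, paste0("n", 1:9))))
  cfg <- selectionConfig(nBootstrap = 40L, seed = 2L)
  rep1 <- relevanceFilter(tab, tt, ev, cfg)
  expect_gt(rep1$frequency["signal"], 0.8 * 40)
  expect_true("signal" %in% rep1$selected)
  # pure-noise features fire at roughly the alpha rate
  expect_lt(median(rep1$frequency[-1]), 0.35 * 40)
})

test_that("redundancy filter removes the higher-mean-correlation member", {
  set.seed(5)
  n <- 200
  base <- rnorm(n)
  a <- base + rnorm(n, sd = 0.1)   # a,b nearly duplicate
  b <- base + rnorm(n, sd = 0.1)
  c3 <- rnorm(n) + 0.25 * base     # weakly tied to the pair
  tab <- cbind(a = a, b = b, c = c3)
  kept <- redundancyFilter(tab, corrThreshold = 0.6)
  expect_length(kept, 2L)
  expect_true("c" %in% kept)
  # the survivor of {a,b} is the one with lower mean |r|
  r <- abs(cor(tab)); diag(r) <- 0
  expect_identical(setdiff(kept, "c"),
                   names(which.min(rowMeans(r)[c("a", "b")])))
  # no remaining pair exceeds the threshold (postcondition)
  rk <- abs(cor(tab[, kept])); diag(rk) <- 0
  expect_lt(max(rk), 0.6)

  # uncorrelated input passes through unchanged
  ind <- matrix(rnorm(150 * 4), 150, 4,
                dimnames = list(NULL, paste0("u", 1:4)))
  expect_identical(redundancyFilter(ind, corrThreshold = 0.95),
                   colnames(ind))
  # exact duplicates: exactly one copy survives
  dup <- cbind(x1 = base, x2 = base, y = rnorm(n))
  keptDup <- redundancyFilter(dup, corrThreshold = 0.6)
  expect_length(intersect(c("x1", "x2"), keptDup), 1L)
})

test_that("full selection is invariant to feature column order", {
  set.seed(13)
  n <- 50
  x <- rnorm(n)
  tt <- rexp(n, exp(x)); ev <- rbinom(n, 1, 0.7)
  tab <- cbind(s1 = x + rnorm(n, sd = 0.3), s2 = x + rnorm(n, sd = 0.3),
               matrix(rnorm(n * 8), n, 8,
                      dimnames = list(NULL, paste0("z", 1:8))))
  cfg <- selectionConfig(nBootstrap = 25L, topFraction = 0.3, seed = 6L)
  sel1 <- selectFeatures(tab, tt, ev, cfg)
  perm <- sample(ncol(tab))
  sel2 <- selectFeatures(tab[, perm], tt, ev, cfg)
  expect_setequal(sel1$selected, sel2$selected)
})
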
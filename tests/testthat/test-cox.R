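test_that("ridge Cox matches coxph at zero penalty and the PL oracle", {
  d <- mkSurvivalData(50, beta = 0.8, seed = 2)
  x <- cbind(f = d$x)
  fit <- fitCox(x, d$time, d$event, penalty = 0)
  ref <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)

  # 5-subject toy data, no ties: the fitted beta is a stationary point of
  # the directly-evaluated partial likelihood
  x5 <- cbind(a = c(-1.2, 0.4, 1.1, -0.3, 0.8))
  t5 <- c(2, 5, 1, 8, 3); e5 <- c(1, 1, 1, 0, 1)
  f5 <- fitCox(x5, t5, e5, penalty = 0)
  nll <- function(b) oracleCoxNegLogLik(b, x5, t5, e5)
  expect_equal(nll(f5@coefficients),
               ipbm:::coxObjective(f5@coefficients, x5, t5, e5, 0)$value,
               tolerance = 1e-10)
  grad <- (nll(f5@coefficients + 1e-6) - nll(f5@coefficients - 1e-6)) / 2e-6
  expect_lt(abs(grad), 1e-5)
})

test_that("Cox coefficients respect sign and shrinkage limits", {
  # strong binary separation: the short-survival group gets a positive sign
  x <- cbind(g = rep(c(1, 0), each = 10))
  tt <- c(rexp(10, 5), rexp(10, 0.2))
  ev <- rep(1L, 20)
  fit <- fitCox(x, tt, ev, penalty = 1e-8)
  expect_gt(coef(fit)[["g"]], 0)
  # penalty -> infinity shrinks all coefficients to zero
  big <- fitCox(x, tt, ev, penalty = 1e8)
  expect_lt(max(abs(big@coefficients)), 1e-5)
  expect_error(fitCox(x, tt, rep(0L, 20), penalty = 0), "events")
})

test_that("partial likelihood is invariant to case duplication (Breslow)", {
  d <- mkSurvivalData(30, beta = 0.6, seed = 5)
  x <- cbind(f = d$x)
  fit1 <- fitCox(x, d$time, d$event, penalty = 0)
  fit2 <- fitCox(rbind(x, x), rep(d$time, 2), rep(d$event, 2), penalty = 0)
  expect_equal(fit1@coefficients, fit2@coefficients, tolerance = 1e-6)
})

test_that("concordance matches the pairwise oracle on random instances", {
  expect_equal(cIndex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(cIndex(rep(1, 5), 1:5, rep(1, 5)), 0.5)
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    sc <- sample(rnorm(n), n, replace = TRUE)  # occasional score ties
    tt <- sample(rexp(n), n, replace = TRUE)   # occasional time ties
    ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0 || max(tt[ev == 1]) >= max(tt)) ev[which.max(tt)] <- 0
    expect_equal(cIndex(sc, tt, ev), oracleCIndex(sc, tt, ev))
  }
  expect_error(cIndex(1, 5, 1), "comparable")
})

test_that("RFE recovers planted features and satisfies its argmax property", {
  recovered <- 0L
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 90
    z1 <- rnorm(n); z2 <- rnorm(n)
    tt <- rexp(n, exp(0.9 * z1 + 0.9 * z2))
    ev <- rbinom(n, 1, 0.8)
    x <- cbind(s1 = z1, s2 = z2,
               matrix(rnorm(n * 6), n, 6,
                      dimnames = list(NULL, paste0("n", 1:6))))
    x <- scale(x)
    rfe <- rfeCox(x, tt, ev, folds = 3L, repeats = 3L, seed = s)
    expect_identical(nrow(rfe$trace), ncol(x))
    expect_true(all(diff(rfe$trace$nFeatures) == -1))
    best <- rfe$trace$meanValC[rfe$optimalStep]
    expect_true(all(rfe$trace$meanValC <= best + 1e-12))
    if (all(c("s1", "s2") %in% rfe$optimalFeatures))
      recovered <- recovered + 1L
  }
  expect_gte(recovered, 3L)
})

test_that("single-feature RFE yields a one-step trace", {
  d <- mkSurvivalData(40, beta = 1, seed = 7)
  x <- scale(cbind(only = d$x))
  rfe <- rfeCox(x, d$time, d$event, folds = 3L, repeats = 2L, seed = 1L)
  expect_identical(nrow(rfe$trace), 1L)
  expect_identical(rfe$optimalFeatures, "only")
})

test_that("penalty tuning shrinks under the null and keeps signal intact", {
  set.seed(77)
  n <- 80
  noise <- scale(matrix(rnorm(n * 5), n, 5,
                        dimnames = list(NULL, paste0("n", 1:5))))
  tt <- rexp(n); ev <- rbinom(n, 1, 0.7)
  tunedNull <- tunePenalty(noise, tt, ev, seed = 3L)
  expect_gte(tunedNull$penalty, 1)  # at or near the grid maximum
  # strong signal: the tuned model's CV C-index tracks the true predictor's
  z <- rnorm(n)
  ttS <- rexp(n, exp(1.2 * z))
  xs <- scale(cbind(s = z, noise))
  tunedSig <- tunePenalty(xs, ttS, rep(1L, n),
                          features = c("s", "n1", "n2"), seed = 3L)
  trueC <- cIndex(z, ttS, rep(1L, n))
  expect_gt(max(tunedSig$cv$meanValC), trueC - 0.05)
  expect_identical(tunedSig$penalty,
                   tunePenalty(xs, ttS, rep(1L, n),
                               features = c("s", "n1", "n2"),
                               seed = 3L)$penalty)
})

test_that("risk prediction is the standardized linear predictor", {
  d <- mkSurvivalData(40, beta = 1, seed = 9)
  raw <- cbind(f = d$x, g = rnorm(40))
  fit0 <- zscoreFit(raw)
  z <- zscoreApply(raw, fit0)
  model <- fitCox(z, d$time, d$event, penalty = 0.05,
                  center = fit0$center, scale = fit0$scale)
  # a subject at the training means scores 0
  at0 <- rbind(fit0$center)
  expect_equal(unname(predictRisk(model, at0)), 0, tolerance = 1e-12)
  # +1 SD in one feature moves the score by that coefficient
  up <- at0; up[, "f"] <- up[, "f"] + fit0$scale["f"]
  expect_equal(unname(predictRisk(model, up)),
               unname(coef(model)["f"]), tolerance = 1e-12)
  # a raw shift c with fixed parameters moves the score by beta * c / sigma
  shift <- at0; shift[, "f"] <- shift[, "f"] + 3
  expect_equal(unname(predictRisk(model, shift)),
               unname(coef(model)["f"] * 3 / fit0$scale["f"]),
               tolerance = 1e-12)
  expect_error(predictRisk(model, at0[, "f", drop = FALSE]), "lacks")
})
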
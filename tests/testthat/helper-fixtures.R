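# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written as naive, brute-force computations that
# share no code path with the package implementation.

mkSphereMask <- function(radiusMm, spacing = c(1, 1, 1), marginMm = 9) {
  # even grid sizes keep the FFT-based field smoothing fast
  dims <- as.integer(2 * ceiling((radiusMm + marginMm) / spacing))
  ctr <- (dims - 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) - ctr[a]) * spacing[a])
  r2 <- outer(outer((ax[[1]] / radiusMm)^2, (ax[[2]] / radiusMm)^2, "+"),
              (ax[[3]] / radiusMm)^2, "+")
  roiMask(array(as.numeric(r2 <= 1), dims), spacing = spacing)
}

mkEllipsoidMask <- function(radiiMm, spacing = c(1, 1, 1), marginMm = 9) {
  dims <- as.integer(2 * ceiling((max(radiiMm) + marginMm) / spacing))
  ctr <- (dims - 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) - ctr[a]) * spacing[a])
  r2 <- outer(outer((ax[[1]] / radiiMm[1])^2, (ax[[2]] / radiiMm[2])^2, "+"),
              (ax[[3]] / radiiMm[3])^2, "+")
  roiMask(array(as.numeric(r2 <= 1), dims), spacing = spacing)
}

mkNoiseImage <- function(dims, mean = 50, sd = 20, seed = 1,
                         spacing = c(1, 1, 1)) {
  set.seed(seed)
  imageVolume(array(rnorm(prod(dims), mean, sd), dims), spacing = spacing)
}

# ICC(1,1) from explicit sums of squares (spreadsheet-style)
oracleIcc11 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(m[i, ]) - grand)^2
  ssw <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ssw <- ssw + (m[i, j] - mean(m[i, ]))^2
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Harrell's C by explicit pair enumeration
oracleCIndex <- function(scores, time, event) {
  conc <- 0; comp <- 0
  n <- length(scores)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      comp <- comp + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# two-group log-rank chi-square from the observed-minus-expected table
oracleLogrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  oMinusE <- 0; varSum <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    oMinusE <- oMinusE + d1 - d * n1 / n
    if (n > 1)
      varSum <- varSum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oMinusE^2 / varSum
}

# brute-force symmetric Hausdorff distance over 6-connectivity boundary
# voxel sets, O(n^2) pairwise
oracleHausdorff <- function(a, b) {
  boundary <- function(m) {
    v <- voxels(m); d <- dim(v)
    out <- NULL
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (v[x, y, z] == 0) next
      nb <- c(
        if (x > 1) v[x - 1, y, z] else 0, if (x < d[1]) v[x + 1, y, z] else 0,
        if (y > 1) v[x, y - 1, z] else 0, if (y < d[2]) v[x, y + 1, z] else 0,
        if (z > 1) v[x, y, z - 1] else 0, if (z < d[3]) v[x, y, z + 1] else 0)
      edge <- x == 1 || x == d[1] || y == 1 || y == d[2] || z == 1 ||
        z == d[3]
      if (edge || any(nb == 0)) out <- rbind(out, c(x, y, z) - 1)
    }
    sweep(out, 2, spacing(m), "*")
  }
  pa <- boundary(a); pb <- boundary(b)
  directed <- function(p, q) {
    mx <- 0
    for (i in seq_len(nrow(p))) {
      mn <- Inf
      for (j in seq_len(nrow(q)))
        mn <- min(mn, sum((p[i, ] - q[j, ])^2))
      mx <- max(mx, mn)
    }
    mx
  }
  sqrt(max(directed(pa, pb), directed(pb, pa)))
}

# negative Breslow log partial likelihood by direct risk-set summation
oracleCoxNegLogLik <- function(beta, x, time, event) {
  eta <- drop(as.matrix(x) %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  -ll
}

# small survival cohort fixture with controlled signal
mkSurvivalData <- function(n, beta = 0, seed = 1, censorRate = 0.3) {
  set.seed(seed)
  x <- rnorm(n)
  tt <- rexp(n, rate = exp(beta * x))
  cc <- rexp(n, rate = censorRate / (1 - censorRate))
  list(x = x, time = pmin(tt, cc), event = as.integer(tt <= cc))
}

# feature-table simulator with two latent hazard drivers measured by
# high-robustness (eta1) and low-robustness (eta2) feature groups, plus
# uninformative features of mixed robustness; returns the original table,
# per-perturbation tables and outcomes (the study design behind the
# screening-improves-reliability validation)
mkScreeningCohort <- function(n = 60, k = 12, seed = 1, censorTarget = 0.4,
                              nNoise = 44) {
  set.seed(seed)
  eta1 <- rnorm(n); eta2 <- rnorm(n)
  sdRobust <- 0.2; sdNoisy <- 1.2
  # informative features measure one of two latent hazard drivers; noise
  # features have their own independent subject effect; half of each kind
  # is robust (small within-subject SD) and half fragile (large)
  feats <- c(
    lapply(1:4, function(j) list(base = eta1, sd = sdRobust,
                                 name = paste0("robustSignal", j))),
    lapply(1:4, function(j) list(base = eta2, sd = sdNoisy,
                                 name = paste0("fragileSignal", j))),
    lapply(seq_len(nNoise), function(j)
      list(base = rnorm(n), sd = if (j %% 2) sdRobust else sdNoisy,
           name = paste0("noise", j))))
  draw <- function() {
    tab <- vapply(feats, function(f) f$base + rnorm(n, sd = f$sd),
                  numeric(n))
    colnames(tab) <- vapply(feats, `[[`, "", "name")
    rownames(tab) <- sprintf("P%03d", seq_len(n))
    tab
  }
  original <- draw()
  perturbed <- lapply(seq_len(k), function(j) draw())
  hazard <- exp(0.8 * eta1 + 0.8 * eta2)
  tt <- 40 * (-log(runif(n)) / hazard)^(1 / 1.2)
  cc <- -log(runif(n)) * quantile(tt, 1 - censorTarget)
  outcomes <- data.frame(patient_id = rownames(original),
                         time_months = pmin(tt, cc),
                         event = as.integer(tt <= cc))
  list(original = original, perturbed = perturbed, outcomes = outcomes,
       trueRobust = paste0("robustSignal", 1:4),
       trueFragile = paste0("fragileSignal", 1:4))
}
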
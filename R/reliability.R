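#' One-way random-effects intraclass correlation ICC(1,1)
#'
#' Single-rater, absolute-agreement ICC from the one-way ANOVA decomposition
#' of a subjects x raters matrix (here: patients x perturbations):
#' `MSB = k * sum_i (m_i - m)^2 / (n-1)`,
#' `MSW = sum_ij (x_ij - m_i)^2 / (n(k-1))`,
#' `ICC = (MSB - MSW) / (MSB + (k-1) MSW)`. The 95% CI comes from
#' `F = MSB/MSW` with `(n-1, n(k-1))` degrees of freedom; estimate and bounds
#' are clamped to [0, 1].
#'
#' @param m Numeric matrix, subjects in rows, raters in columns; no missing
#'   cells.
#' @return An [ICCResult-class] object.
#' @export
icc11 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC(1,1) needs >= 2 subjects and >= 2 raters")
  if (anyNA(m)) stop("missing cells are not supported")
  rowM <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((rowM - grand)^2) / (n - 1)
  msw <- sum((m - rowM)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0)
    stop("ICC undefined: zero total variance")
  clamp <- function(v) min(1, max(0, v))
  if (msw == 0) {
    est <- low <- high <- 1
  } else {
    est <- (msb - msw) / (msb + (k - 1) * msw)
    f <- msb / msw
    fl <- f / qf(0.975, n - 1, n * (k - 1))
    fu <- f * qf(0.975, n * (k - 1), n - 1)
    low <- (fl - 1) / (fl + k - 1)
    high <- (fu - 1) / (fu + k - 1)
    est <- clamp(est); low <- clamp(low); high <- clamp(high)
  }
  new("ICCResult", estimate = est, ciLow = low, ciHigh = high,
      nSubjects = as.integer(n), nRaters = as.integer(k),
      label = classifyIcc(est))
}

#' Reliability label of an ICC value
#'
#' Conventional bands: below 0.5 poor, 0.5 to 0.75 moderate, 0.75 to 0.9
#' good, 0.9 and above excellent (bands are left-closed: 0.9 is excellent).
#'
#' @param value ICC in [0, 1].
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
classifyIcc <- function(value) {
  if (!is.finite(value) || value < 0 || value > 1)
    stop("ICC value must be in [0,1]")
  if (value < 0.5) "poor"
  else if (value < 0.75) "moderate"
  else if (value < 0.9) "good"
  else "excellent"
}

#' Per-feature robustness ICC across perturbations
#'
#' For each feature, assembles the patients x perturbations matrix of raw
#' (unstandardized) values and computes [icc11()]. Features with degenerate
#' (zero) total variance are flagged and assigned ICC 0.
#'
#' @param perturbedTables list of feature matrices, one per perturbation,
#'   identical row (patient) and column (feature) sets.
#' @return data.frame with columns `feature`, `icc`, `ciLow`, `ciHigh`,
#'   `label`, `degenerate`.
#' @export
featureRobustness <- function(perturbedTables) {
  pids <- rownames(perturbedTables[[1]])
  feats <- colnames(perturbedTables[[1]])
  for (tab in perturbedTables)
    if (!identical(rownames(tab), pids) || !identical(colnames(tab), feats))
      stop("perturbation tables must share identical patient and feature sets")
  rows <- lapply(feats, function(f) {
    m <- vapply(perturbedTables, function(tab) tab[, f], numeric(length(pids)))
    if (all(m == m[1])) {
      data.frame(feature = f, icc = 0, ciLow = 0, ciHigh = 0,
                 label = "poor", degenerate = TRUE)
    } else {
      r <- icc11(m)
      data.frame(feature = f, icc = r@estimate, ciLow = r@ciLow,
                 ciHigh = r@ciHigh, label = r@label, degenerate = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Screen features by robustness
#'
#' Retains features with ICC strictly above `minIcc` (an ICC exactly at the
#' threshold is dropped).
#'
#' @param robustness Output of [featureRobustness()].
#' @param minIcc Screening threshold (default 0.75).
#' @return Character vector of retained feature names.
#' @export
screenFeatures <- function(robustness, minIcc = 0.75) {
  as.character(robustness$feature[robustness$icc > minIcc])
}

#' Model reliability under perturbation
#'
#' For each perturbation the trained model predicts risk scores for all
#' patients and the C-index is computed against the (unchanged) outcomes; the
#' patients x perturbations risk-score matrix then yields the model
#' reliability ICC(1,1). When every perturbation reproduces the original risk
#' vector exactly the ICC is exactly 1.
#'
#' @param model A [CoxModel-class].
#' @param perturbedTables list of raw feature matrices, one per perturbation.
#' @param time,event Outcomes aligned with the table rows.
#' @return list of class `ReliabilityReport`: `icc` ([ICCResult-class]),
#'   `cindex` (per-perturbation data.frame), `summary` (mean/sd/min/max) and
#'   the risk-score matrix.
#' @export
modelReliability <- function(model, perturbedTables, time, event) {
  if (length(perturbedTables) < 2) stop("need >= 2 perturbations")
  risks <- vapply(perturbedTables, function(tab) predictRisk(model, tab),
                  numeric(nrow(perturbedTables[[1]])))
  cidx <- apply(risks, 2, cIndex, time = time, event = event)
  structure(list(
    icc = icc11(risks),
    cindex = data.frame(perturbation = seq_along(cidx), cindex = cidx),
    summary = c(mean = mean(cidx), sd = sd(cidx), min = min(cidx),
                max = max(cidx)),
    riskMatrix = risks), class = "ReliabilityReport")
}

# --- end-to-end modelling helper -------------------------------------------

#' Run the radiomic modelling pipeline on a fixed train/test split
#'
#' Feature selection (optionally restricted to robustness-screened columns),
#' backward RFE, penalty tuning, final ridge Cox fit, evaluation on the
#' original cohorts, and reliability assessment on the perturbed cohorts.
#'
#' @param table Raw feature matrix for all patients.
#' @param perturbedTables list of raw per-perturbation feature matrices
#'   (same rows as `table`).
#' @param outcomes data.frame with `patient_id`, `time_months`, `event`.
#' @param trainIds,testIds Patient id vectors defining the split.
#' @param selConfig A [selectionConfig()].
#' @param screenMinIcc NULL for no screening, or the ICC threshold; screening
#'   uses the perturbed-train tables only.
#' @param rfeFolds,rfeRepeats,seed Cross-validation layout for RFE.
#' @return list with the fitted `model`, `selection`, `rfe`, `penalty`,
#'   `trainC`, `testC`, `reliabilityTrain`, `reliabilityTest` and
#'   `screenedFeatures` (NULL when unscreened); or a list with
#'   `fitted = FALSE` and a `reason` when no features survive.
#' @export
runModelingPipeline <- function(table, perturbedTables, outcomes, trainIds,
                                testIds, selConfig = selectionConfig(),
                                screenMinIcc = NULL, rfeFolds = 3L,
                                rfeRepeats = 10L, seed = 1L) {
  ids <- as.character(outcomes$patient_id)
  stopifnot(identical(sort(rownames(table)), sort(ids)))
  trIdx <- match(trainIds, rownames(table))
  teIdx <- match(testIds, rownames(table))
  oc <- outcomes[match(rownames(table), ids), ]
  time <- oc$time_months; event <- oc$event

  candidates <- colnames(table)
  screened <- NULL
  if (!is.null(screenMinIcc)) {
    ptTrain <- lapply(perturbedTables, function(tab)
      tab[trainIds, , drop = FALSE])
    rob <- featureRobustness(ptTrain)
    screened <- screenFeatures(rob, screenMinIcc)
    if (!length(screened))
      return(list(fitted = FALSE, reason = "no features above ICC threshold"))
    candidates <- screened
  }

  sel <- tryCatch(
    selectFeatures(table[trIdx, candidates, drop = FALSE], time[trIdx],
                   event[trIdx], selConfig),
    error = function(e) NULL)
  if (is.null(sel) || !length(sel$selected))
    return(list(fitted = FALSE, reason = "no features selected"))

  ztrain <- zscoreApply(table[trIdx, , drop = FALSE], sel$zscore)
  rfe <- rfeCox(ztrain[, sel$selected, drop = FALSE], time[trIdx],
                event[trIdx], folds = rfeFolds, repeats = rfeRepeats,
                seed = seed)
  tuned <- tunePenalty(ztrain, time[trIdx], event[trIdx],
                       rfe$optimalFeatures, seed = seed)
  model <- fitCox(ztrain[, rfe$optimalFeatures, drop = FALSE], time[trIdx],
                  event[trIdx], tuned$penalty,
                  center = sel$zscore$center, scale = sel$zscore$scale)

  trainC <- cIndex(predictRisk(model, table[trIdx, , drop = FALSE]),
                   time[trIdx], event[trIdx])
  testC <- if (length(teIdx))
    cIndex(predictRisk(model, table[teIdx, , drop = FALSE]), time[teIdx],
           event[teIdx]) else NA_real_

  relOf <- function(idx) {
    if (!length(idx)) return(NULL)
    tabs <- lapply(perturbedTables, function(tab) tab[idx, , drop = FALSE])
    modelReliability(model, tabs, time[idx], event[idx])
  }
  list(fitted = TRUE, model = model, selection = sel, rfe = rfe,
       penalty = tuned$penalty, trainC = trainC, testC = testC,
       reliabilityTrain = relOf(trIdx), reliabilityTest = relOf(teIdx),
       screenedFeatures = screened)
}

#' Subgroup analysis per filtered-image family
#'
#' Re-runs the full pipeline (selection, RFE, model, reliability) restricted
#' to each filter family's feature columns (`original`, `log-sigma`,
#' `wavelet`; shape features are excluded from all three groups), with and
#' without ICC screening.
#'
#' @inheritParams runModelingPipeline
#' @param screenMinIcc Screening threshold used for the screened arm.
#' @return list per family with `unscreened` and `screened` pipeline results
#'   plus a `summary` data.frame (train/test C-index and model ICC for both
#'   arms; NA where a family could not be fitted).
#' @export
subgroupAnalysis <- function(table, perturbedTables, outcomes, trainIds,
                             testIds, selConfig = selectionConfig(),
                             screenMinIcc = 0.75, rfeFolds = 3L,
                             rfeRepeats = 10L, seed = 1L) {
  info <- parseFeatureName(colnames(table))
  nonShape <- info$family != "shape"
  groups <- split(colnames(table)[nonShape], info$filterFamily[nonShape])
  out <- list()
  rows <- list()
  for (g in names(groups)) {
    cols <- groups[[g]]
    sub <- table[, cols, drop = FALSE]
    psub <- lapply(perturbedTables, function(tab) tab[, cols, drop = FALSE])
    un <- runModelingPipeline(sub, psub, outcomes, trainIds, testIds,
                              selConfig, NULL, rfeFolds, rfeRepeats, seed)
    sc <- runModelingPipeline(sub, psub, outcomes, trainIds, testIds,
                              selConfig, screenMinIcc, rfeFolds, rfeRepeats,
                              seed)
    cell <- function(res, what) {
      if (!isTRUE(res$fitted)) return(NA_real_)
      switch(what, trainC = res$trainC, testC = res$testC,
             icc = if (!is.null(res$reliabilityTest))
               res$reliabilityTest$icc@estimate else NA_real_)
    }
    rows[[g]] <- data.frame(
      family = g,
      trainC = cell(un, "trainC"), testC = cell(un, "testC"),
      modelIcc = cell(un, "icc"),
      trainCScreened = cell(sc, "trainC"), testCScreened = cell(sc, "testC"),
      modelIccScreened = cell(sc, "icc"))
    out[[g]] <- list(unscreened = un, screened = sc)
  }
  out$summary <- do.call(rbind, rows)
  rownames(out$summary) <- NULL
  out
}

#' Repeated stratified cross-validation of the reliability assessment
#'
#' Splits patients into stratified `folds`-fold train/test pairs, `repeats`
#' times (default 3 x 20 = 60 splits); on each split the complete pipeline
#' runs with and without robustness screening. Reports mean/SD of train and
#' test C-index and model ICC per arm, and a Wilcoxon signed-rank test of the
#' screened vs unscreened test-cohort ICC across splits.
#'
#' @inheritParams runModelingPipeline
#' @param folds,repeats Cross-validation layout.
#' @param screenMinIcc Robustness screening threshold for the screened arm.
#' @return list with `splits` (per-split data.frame), `summary` (mean/SD per
#'   arm) and `screeningImprovementP`.
#' @export
crossValidationAnalysis <- function(table, perturbedTables, outcomes,
                                    folds = 3L, repeats = 20L, seed = 1L,
                                    selConfig = selectionConfig(),
                                    screenMinIcc = 0.75, rfeFolds = 3L,
                                    rfeRepeats = 10L) {
  ids <- as.character(outcomes$patient_id)
  ev <- outcomes$event
  seeds <- deriveSeeds(seed, repeats)
  rows <- list()
  s <- 0L
  for (r in seq_len(repeats)) {
    fold <- stratifiedFolds(ev, folds, seeds[r])
    for (f in seq_len(folds)) {
      s <- s + 1L
      trainIds <- ids[fold != f]
      testIds <- ids[fold == f]
      un <- runModelingPipeline(table, perturbedTables, outcomes, trainIds,
                                testIds, selConfig, NULL, rfeFolds,
                                rfeRepeats, seeds[r] + f)
      sc <- runModelingPipeline(table, perturbedTables, outcomes, trainIds,
                                testIds, selConfig, screenMinIcc, rfeFolds,
                                rfeRepeats, seeds[r] + f)
      val <- function(res, what) {
        if (!isTRUE(res$fitted)) return(NA_real_)
        switch(what, trainC = res$trainC, testC = res$testC,
               icc = if (!is.null(res$reliabilityTest))
                 res$reliabilityTest$icc@estimate else NA_real_)
      }
      rows[[s]] <- data.frame(
        repetition = r, fold = f,
        trainC = val(un, "trainC"), testC = val(un, "testC"),
        icc = val(un, "icc"),
        trainCScreened = val(sc, "trainC"),
        testCScreened = val(sc, "testC"),
        iccScreened = val(sc, "icc"))
    }
  }
  splits <- do.call(rbind, rows)
  summarize <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = sd(v, na.rm = TRUE))
  summary <- rbind(
    trainC = summarize(splits$trainC), testC = summarize(splits$testC),
    icc = summarize(splits$icc),
    trainCScreened = summarize(splits$trainCScreened),
    testCScreened = summarize(splits$testCScreened),
    iccScreened = summarize(splits$iccScreened))
  ok <- stats::complete.cases(splits[, c("icc", "iccScreened")])
  pval <- if (sum(ok) >= 3)
    suppressWarnings(wilcox.test(splits$iccScreened[ok], splits$icc[ok],
                                 paired = TRUE,
                                 alternative = "greater")$p.value)
  else NA_real_
  list(splits = splits, summary = summary, screeningImprovementP = pval)
}
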
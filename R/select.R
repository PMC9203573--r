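#' Fit z-score standardization on a training table
#'
#' Column means and sample SDs are estimated on the training cohort only and
#' applied unchanged to test or perturbed tables, so all cohorts share the
#' training scale. Zero-SD (constant) columns are dropped with a warning.
#'
#' @param train Numeric matrix (patients x features).
#' @return list with `center`, `scale` (named) and `features` kept.
#' @export
zscoreFit <- function(train) {
  if (nrow(train) < 2) stop("need >= 2 rows to standardize")
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  keep <- scl > 0
  if (!any(keep)) stop("all columns have zero variance")
  if (any(!keep))
    warnf("dropped %d constant column(s)", sum(!keep))
  list(center = ctr[keep], scale = scl[keep],
       features = colnames(train)[keep])
}

#' Apply a fitted z-score transform
#' @param table Numeric matrix containing the fitted features.
#' @param fit Output of [zscoreFit()].
#' @return Standardized matrix restricted to the fitted features.
#' @export
zscoreApply <- function(table, fit) {
  missing <- setdiff(fit$features, colnames(table))
  if (length(missing))
    stopf("table lacks %d fitted feature(s), e.g. %s", length(missing),
          missing[1])
  x <- table[, fit$features, drop = FALSE]
  scale(x, center = fit$center, scale = fit$scale)[, , drop = FALSE]
}

#' Log-rank p-value for a continuous feature
#'
#' Dichotomizes the feature at its within-sample median (above vs not-above)
#' and runs the two-group log-rank test (chi-square, 1 df). A constant feature
#' leaves a group empty and returns p = 1 with a `degenerate` attribute.
#'
#' @param featureValues Numeric vector.
#' @param time,event Survival outcome vectors.
#' @return p-value, with attribute `statistic` (the chi-square statistic).
#' @export
logrankP <- function(featureValues, time, event) {
  grp <- featureValues > median(featureValues)
  if (length(unique(grp)) < 2L)
    return(structure(1, statistic = 0, degenerate = TRUE))
  sd <- suppressWarnings(survival::survdiff(survival::Surv(time, event) ~ grp))
  if (!is.finite(sd$chisq))  # e.g. no events in the sample
    return(structure(1, statistic = 0, degenerate = TRUE))
  structure(pchisq(sd$chisq, df = 1, lower.tail = FALSE),
            statistic = sd$chisq)
}

#' Bootstrap log-rank relevance filter
#'
#' Per iteration, draws a class-balanced subsample without replacement (all
#' subjects of the minority outcome class plus an equal-size draw from the
#' majority class), computes the median-dichotomized log-rank p-value of
#' every feature, and counts features with p below `logrankAlpha`. After
#' `nBootstrap` iterations the `ceiling(topFraction * n_features)` features
#' with the highest selection frequencies survive; ties at the cutoff break
#' by smaller mean p, then lexicographic name.
#'
#' @param table Standardized numeric matrix (patients x features).
#' @param time,event Survival outcomes aligned with the rows.
#' @param config A [selectionConfig()].
#' @return list of class `SelectionReport`: `frequency` and `meanP` (named
#'   per feature), `selected` (surviving names) and the config.
#' @export
relevanceFilter <- function(table, time, event, config = selectionConfig()) {
  stopifnot(is(config, "SelectionConfig"))
  classes <- split(seq_len(nrow(table)), event)
  if (length(classes) < 2L) stop("both outcome classes must be present")
  nMin <- min(lengths(classes))
  if (nMin < 2L) stop("minority outcome class has < 2 subjects")
  if (nMin < 5L) warnf("minority outcome class has only %d subjects", nMin)
  ord <- order(lengths(classes))  # ties: the two classes stay distinct
  minority <- classes[[ord[1]]]
  majority <- classes[[ord[2]]]
  p <- ncol(table)
  seeds <- deriveSeeds(config@seed, config@nBootstrap)
  freq <- numeric(p)
  pSum <- numeric(p)
  for (it in seq_len(config@nBootstrap)) {
    idx <- c(minority, withSeed(seeds[it], sample(majority, nMin)))
    pv <- vapply(seq_len(p), function(k)
      as.numeric(logrankP(table[idx, k], time[idx], event[idx])), 0)
    freq <- freq + (pv < config@logrankAlpha)
    pSum <- pSum + pv
  }
  meanP <- pSum / config@nBootstrap
  names(freq) <- names(meanP) <- colnames(table)
  nSel <- ceiling(config@topFraction * p)
  ord <- order(-freq, meanP, colnames(table))
  selected <- colnames(table)[ord[seq_len(min(nSel, p))]]
  structure(list(frequency = freq, meanP = meanP, selected = selected,
                 config = config), class = "SelectionReport")
}

#' Pairwise-correlation redundancy filter
#'
#' Iteratively removes features until no pair has absolute Pearson
#' correlation above the threshold: at each step, among features involved in
#' an offending pair, the one with the highest mean absolute correlation to
#' all remaining features is removed (ties break lexicographically).
#'
#' @param table Numeric matrix whose columns include `features`.
#' @param features Candidate feature names (default all columns).
#' @param corrThreshold Redundancy threshold on |r|.
#' @return Character vector of surviving feature names.
#' @export
redundancyFilter <- function(table, features = colnames(table),
                             corrThreshold = 0.6) {
  keep <- sort(features)
  if (length(keep) < 2L) return(features[features %in% keep])
  repeat {
    r <- abs(cor(table[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r, na.rm = TRUE) <= corrThreshold) break
    inPair <- rowSums(r > corrThreshold) > 0
    meanAbs <- rowMeans(r)  # mean |r| to all remaining features
    cand <- keep[inPair]
    # remove the highest mean |r|; ties break lexicographically
    cand <- cand[order(-meanAbs[cand], cand)]
    keep <- setdiff(keep, cand[1])
    if (length(keep) < 2L) break
  }
  features[features %in% keep]
}

#' Two-stage feature selection
#'
#' Standardizes the training table, applies the bootstrap log-rank relevance
#' filter and then the correlation redundancy filter (Pearson correlations on
#' the z-scored training table only).
#'
#' @param train Raw training feature matrix.
#' @param time,event Training outcomes.
#' @param config A [selectionConfig()].
#' @return list of class `SelectionReport` with the relevance report plus
#'   `zscore` (the fitted standardization), `afterRelevance`,
#'   `afterRedundancy` and `selected` (final names).
#' @export
selectFeatures <- function(train, time, event, config = selectionConfig()) {
  zs <- zscoreFit(train)
  ztab <- zscoreApply(train, zs)
  rel <- relevanceFilter(ztab, time, event, config)
  red <- redundancyFilter(ztab, rel$selected, config@corrThreshold)
  structure(list(frequency = rel$frequency, meanP = rel$meanP,
                 zscore = zs, afterRelevance = rel$selected,
                 afterRedundancy = red, selected = red, config = config),
            class = "SelectionReport")
}
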
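#' Generate a synthetic CT-like phantom cohort
#'
#' Each patient is a soft-tissue background volume carrying one ellipsoidal
#' lesion filled with a smoothed Gaussian random-field texture. The latent
#' texture parameters (amplitude in HU and correlation length in mm, drawn
#' per patient) set the linear log-hazard of a Weibull proportional-hazards
#' survival model; censoring is independent exponential, calibrated by
#' bisection to the requested censoring rate. All randomness derives from the
#' config seed via per-patient sub-streams, so cohorts are bit-reproducible.
#'
#' @param config A [phantomConfig()] object.
#' @return An object of class `PhantomCohort`: a list of per-patient entries
#'   (`patientId`, `image`, `mask`, `outcome` with `timeMonths`/`event`, and
#'   the realized `latent` predictors on standardized scale), with the config
#'   stored as an attribute.
#' @export
generatePhantomCohort <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  n <- config@nPatients
  seeds <- deriveSeeds(config@seed, n + 1L)
  dims <- config@gridShape
  sp <- config@spacingMm
  ctr <- (dims - 1) / 2          # lesion centre, voxel coordinates

  # latent predictors: uniform multipliers around the configured texture
  # parameters; standardized versions feed the log-hazard
  lat <- withSeed(seeds[n + 1L], {
    list(uAmp = runif(n, -1, 1), uCor = runif(n, -1, 1),
         uSurv = runif(n), uCens = runif(n))
  })
  zAmp <- lat$uAmp * sqrt(3)     # U(-1,1) has SD 1/sqrt(3)
  zCor <- lat$uCor * sqrt(3)

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    ampHu <- config@textureAmplitudeHu * (1 + 0.5 * lat$uAmp[i])
    corMm <- config@textureCorrelationLengthMm * (1 + 0.3 * lat$uCor[i])
    patients[[i]] <- withSeed(seeds[i], {
      radii <- runif(3, config@lesionRadiusRangeMm[1],
                     config@lesionRadiusRangeMm[2])
      ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) - ctr[a]) * sp[a])
      r2 <- outer(outer((ax[[1]] / radii[1])^2, (ax[[2]] / radii[2])^2, "+"),
                  (ax[[3]] / radii[3])^2, "+")
      lesion <- r2 <= 1
      field <- array(rnorm(prod(dims)), dim = dims)
      field <- smoothGaussian3d(field, sp, rep(corMm, 3))
      fin <- field[lesion]
      field <- (field - mean(fin)) / sd(fin) * ampHu
      vox <- array(config@backgroundHu + rnorm(prod(dims), sd = 3),
                   dim = dims)
      vox[lesion] <- config@lesionMeanHu + field[lesion]
      list(image = imageVolume(vox, spacing = sp),
           mask = roiMask(array(as.numeric(lesion), dim = dims),
                          spacing = sp))
    })
  }

  # Weibull PH survival: T = scale * (-log U / exp(eta))^(1/shape)
  eta <- config@hazardCoefficients["amplitude"] %0% 0 * zAmp +
         config@hazardCoefficients["corlength"] %0% 0 * zCor
  tEvent <- config@weibullScaleMonths *
    (-log(lat$uSurv) / exp(eta))^(1 / config@weibullShape)

  if (config@censoringRate > 0) {
    cens <- calibrateCensoring(tEvent, lat$uCens, config@censoringRate)
  } else {
    cens <- rep(Inf, n)
  }
  time <- pmin(tEvent, cens)
  event <- as.integer(tEvent <= cens)

  for (i in seq_len(n)) {
    patients[[i]]$patientId <- sprintf("P%03d", i)
    patients[[i]]$outcome <- list(timeMonths = time[i], event = event[i])
    patients[[i]]$latent <- c(amplitude = zAmp[i], corlength = zCor[i])
  }
  structure(patients, class = "PhantomCohort", config = config)
}

# named-element lookup that treats a missing name as `default`
`%0%` <- function(x, default) if (length(x) == 1 && !is.na(x)) x else default

# Bisection on the exponential censoring rate so that the realized censored
# fraction (with fixed uniform draws) is within 5% of the target.
calibrateCensoring <- function(tEvent, uCens, target) {
  frac <- function(rate) mean(-log(uCens) / rate < tEvent)
  lo <- 1e-6; hi <- 1
  while (frac(hi) < target && hi < 1e6) hi <- hi * 2
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < target) lo <- mid else hi <- mid
    if (abs(frac(mid) - target) <= 0.01) break
  }
  rate <- sqrt(lo * hi)
  if (abs(frac(rate) - target) > 0.05)
    warnf("censoring calibration reached %.2f (target %.2f)",
          frac(rate), target)
  -log(uCens) / rate
}

#' Extract the survival outcomes of a cohort as a data frame
#' @param cohort A `PhantomCohort` or list of entries with `$outcome`.
#' @return data.frame with `patient_id`, `time_months`, `event`.
#' @export
cohortOutcomes <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort, `[[`, "", "patientId"),
    time_months = vapply(cohort, function(p) p$outcome$timeMonths, 0),
    event = vapply(cohort, function(p) p$outcome$event, 0L))
}

#' Simulate a subjects-by-raters table with known ICC
#'
#' Draws `x_ij = mu + b_i + e_ij` with `b_i ~ N(0, sigmaBetween^2)` and
#' `e_ij ~ N(0, sigmaWithin^2)`: the model underlying the one-way
#' random-effects ICC(1,1), with patients as subjects and perturbations as
#' raters. Used as a ground-truth fixture for the ICC estimator.
#'
#' @param spec A [varianceComponentSpec()] object.
#' @return Numeric matrix (`nSubjects` x `nRaters`).
#' @export
generateIccTable <- function(spec) {
  stopifnot(is(spec, "VarianceComponentSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    b <- rnorm(spec@nSubjects, sd = spec@sigmaBetween)
    e <- matrix(rnorm(spec@nSubjects * spec@nRaters, sd = spec@sigmaWithin),
                spec@nSubjects, spec@nRaters)
    m <- spec@mu + b + e
    dimnames(m) <- list(sprintf("S%03d", seq_len(spec@nSubjects)),
                        sprintf("R%03d", seq_len(spec@nRaters)))
    m
  })
}
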
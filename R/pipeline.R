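#' Read a run configuration from YAML
#'
#' The YAML mirrors the parameter objects: top-level keys `seed`,
#' `output_dir`, `manifest` (optional: use a real cohort instead of the
#' phantom), and sections `phantom`, `perturbation`, `extraction`,
#' `selection`, `model` (`rfe_folds`, `rfe_repeats`), `reliability`
#' (`screen_min_icc`), `split` (`test_fraction`). Missing entries take the
#' package defaults; the global seed derives all stage seeds.
#'
#' @param path Path to a YAML file.
#' @return A nested list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg %||% list(), class = "RunConfig")
}

applyArgs <- function(constructor, args) {
  if (is.null(args)) args <- list()
  do.call(constructor, args[names(args) %in% names(formals(constructor))])
}

#' Run the full image-perturbation reliability experiment
#'
#' Orchestrates the complete workflow: cohort generation (phantom) or loading
#' (manifest), stratified 70/30 split, perturbation simulation, feature
#' extraction on original and perturbed data, feature selection, RFE + ridge
#' Cox model building, and reliability quantification with and without
#' robustness screening. All stage outputs are written under
#' `config$output_dir` together with a run manifest recording the seeds, so a
#' rerun with the same config is reproducible.
#'
#' @param config A list (or `RunConfig` from [readRunConfig()]).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runFullPipeline <- function(config = list()) {
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$output_dir %||% "ipbm_run"
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- deriveSeeds(seed, 5L)

  # --- cohort --------------------------------------------------------------
  if (!is.null(config$manifest)) {
    cohort <- loadCohort(config$manifest)
  } else {
    phArgs <- config$phantom %||% list()
    phArgs$seed <- seeds[1]
    cohort <- generatePhantomCohort(applyArgs(phantomConfig, phArgs))
  }
  outcomes <- cohortOutcomes(cohort)

  split <- stratifiedSplit(outcomes,
                           (config$split %||% list())$test_fraction %||% 0.30,
                           seeds[2])
  write.csv(data.frame(patient_id = outcomes$patient_id,
                       split = ifelse(outcomes$patient_id %in% split$test,
                                      "test", "train")),
            file.path(outDir, "split.csv"), row.names = FALSE)

  # --- perturbation --------------------------------------------------------
  peArgs <- config$perturbation %||% list()
  peArgs$seed <- seeds[3]
  spec <- applyArgs(perturbationSpec, peArgs)
  pset <- simulatePerturbationSet(cohort, spec)

  # --- extraction ----------------------------------------------------------
  exCfg <- applyArgs(extractionConfig, config$extraction %||% list())
  table <- extractFeatureTable(cohort, exCfg)
  perturbed <- extractPerturbedFeatureTables(pset, exCfg)
  write.csv(table, file.path(outDir, "features_original.csv"))

  # --- modelling + reliability --------------------------------------------
  selArgs <- config$selection %||% list()
  selArgs$seed <- seeds[4]
  selCfg <- applyArgs(selectionConfig, selArgs)
  mod <- config$model %||% list()
  rel <- config$reliability %||% list()
  un <- runModelingPipeline(table, perturbed, outcomes, split$train,
                            split$test, selCfg, NULL,
                            mod$rfe_folds %||% 3L, mod$rfe_repeats %||% 10L,
                            seeds[5])
  sc <- runModelingPipeline(table, perturbed, outcomes, split$train,
                            split$test, selCfg,
                            rel$screen_min_icc %||% 0.75,
                            mod$rfe_folds %||% 3L, mod$rfe_repeats %||% 10L,
                            seeds[5])

  saveJson <- function(x, f) jsonlite::write_json(
    x, file.path(outDir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(un$fitted)) {
    write.csv(un$rfe$trace[, setdiff(names(un$rfe$trace), "dropped")],
              file.path(outDir, "rfe_trace.csv"), row.names = FALSE)
    saveJson(list(features = un$model@features,
                  coefficients = un$model@coefficients,
                  penalty = un$model@penalty,
                  center = un$model@center, scale = un$model@scale),
             "model.json")
    write.csv(data.frame(feature = names(un$selection$frequency),
                         frequency = un$selection$frequency,
                         mean_p = un$selection$meanP,
                         selected = names(un$selection$frequency) %in%
                           un$selection$selected),
              file.path(outDir, "selection_report.csv"), row.names = FALSE)
  }
  relSummary <- function(res) {
    if (!isTRUE(res$fitted)) return(list(fitted = FALSE, reason = res$reason))
    f <- function(r) if (is.null(r)) NULL else list(
      icc = r$icc@estimate, ci = c(r$icc@ciLow, r$icc@ciHigh),
      label = r$icc@label, cindex = as.list(r$summary))
    list(fitted = TRUE, trainC = res$trainC, testC = res$testC,
         perturbedTrain = f(res$reliabilityTrain),
         perturbedTest = f(res$reliabilityTest))
  }
  saveJson(list(unscreened = relSummary(un), screened = relSummary(sc)),
           "reliability.json")
  saveJson(list(seed = seed, stageSeeds = seeds,
                amplitudeMm = attr(pset, "amplitudeMm"),
                nPerturbations = spec@nPerturbations,
                package = as.character(utils::packageVersion("ipbm")),
                config = unclass(config)),
           "run_manifest.json")
  invisible(list(cohort = cohort, split = split, perturbationSet = pset,
                 table = table, perturbed = perturbed, unscreened = un,
                 screened = sc, outputDir = outDir))
}
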
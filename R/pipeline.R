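#' @include evaluate.R
NULL

#' Pipeline configuration
#'
#' A single validated configuration object driving the whole pipeline:
#' simulation, filtering, windowing, classification and comparison. It
#' round-trips losslessly through YAML ([writePipelineConfig()] /
#' [readPipelineConfig()]), and the master seed fans out deterministically to
#' the stage seeds.
#'
#' @param nTrials Number of simulated trials.
#' @param protocol,effects,noise Simulation specs.
#' @param effectScale,noiseScale,jitterSd Simulation condition multipliers.
#' @param filterCutoff Low-pass cutoff, Hz.
#' @param splitNum Windowing subdivision factor.
#' @param testFraction Held-out fraction.
#' @param arch Architecture of the neural models.
#' @param train Training configuration.
#' @param classifiers Classifier names to compare.
#' @param nRuns Repeated runs for the comparison.
#' @param seed Master seed.
#' @param outDir Output directory for [runPipeline()].
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(nTrials = 69L, protocol = simProtocol(),
                           effects = effectSpec(), noise = noiseSpec(),
                           effectScale = 1, noiseScale = 1, jitterSd = 0.2,
                           filterCutoff = 0.09, splitNum = 8L,
                           testFraction = 0.2, arch = architectureConfig(),
                           train = trainConfig(), classifiers = c("decision_tree", "xgboost", "cnn_transformer"),
                           nRuns = 3L, seed = 1L, outDir = "fnirs-out") {
  cfg <- list(nTrials = as.integer(nTrials), protocol = protocol,
              effects = effects, noise = noise, effectScale = effectScale,
              noiseScale = noiseScale, jitterSd = jitterSd,
              filterCutoff = filterCutoff, splitNum = as.integer(splitNum),
              testFraction = testFraction, arch = arch, train = train,
              classifiers = classifiers, nRuns = as.integer(nRuns),
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Delegates to the component validity methods and checks cross-component
#' constraints (e.g. that `splitNum` divides the emotion-segment length and
#' that the architecture input matches the window length).
#'
#' @param cfg A `PipelineConfig`.
#' @return `cfg`, invisibly; stops with an informative message otherwise.
#' @export
validatePipelineConfig <- function(cfg) {
  for (s in c("protocol", "effects", "noise", "arch", "train"))
    methods::validObject(cfg[[s]])
  segSamples <- as.integer(round(cfg$protocol@clipS * cfg$protocol@sampleRate))
  if (segSamples %% cfg$splitNum != 0L)
    stop(sprintf("split_num = %d does not divide the emotion-segment length of %d samples",
                 cfg$splitNum, segSamples))
  wlen <- segSamples %/% cfg$splitNum
  if (cfg$arch@inputLen != wlen)
    stop(sprintf("architecture inputLen (%d) must equal the window length (%d = %d samples / split_num %d)",
                 cfg$arch@inputLen, wlen, segSamples, cfg$splitNum))
  if (cfg$testFraction <= 0 || cfg$testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  nyq <- cfg$protocol@sampleRate / 2
  if (cfg$filterCutoff <= 0 || cfg$filterCutoff >= nyq)
    stop(sprintf("filterCutoff must lie strictly between 0 and the Nyquist frequency (%g Hz)", nyq))
  bad <- setdiff(cfg$classifiers, classifierNames())
  if (length(bad))
    stop("unknown classifier(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

.s4ToList <- function(x) {
  out <- lapply(methods::slotNames(class(x)), function(nm) {
    v <- methods::slot(x, nm)
    if (is.matrix(v))
      list(.matrix = TRUE, nrow = nrow(v), data = as.vector(v),
           rownames = rownames(v), colnames = colnames(v))
    else v
  })
  names(out) <- methods::slotNames(class(x))
  out
}

.listToS4 <- function(cls, lst) {
  slots <- lapply(lst, function(v) {
    if (is.list(v) && isTRUE(v$.matrix))
      matrix(v$data, nrow = v$nrow,
             dimnames = if (!is.null(v$rownames) || !is.null(v$colnames))
               list(v$rownames, v$colnames))
    else v
  })
  types <- methods::getSlots(cls)
  for (nm in names(slots))
    if (types[[nm]] == "integer") slots[[nm]] <- as.integer(slots[[nm]])
  do.call(methods::new, c(list(cls), slots))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A `PipelineConfig`.
#' @param path YAML file path.
#' @return `readPipelineConfig` returns the reconstructed, re-validated
#'   `PipelineConfig`; the writer returns `path` invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  ser <- cfg
  for (s in c("protocol", "effects", "noise", "arch", "train"))
    ser[[s]] <- .s4ToList(cfg[[s]])
  ser <- unclass(ser)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- c(protocol = "SimProtocol", effects = "EffectSpec",
           noise = "NoiseSpec", arch = "ArchitectureConfig",
           train = "TrainConfig")
  for (s in names(cls)) lst[[s]] <- .listToS4(cls[[s]], lst[[s]])
  do.call(pipelineConfig, lst)
}

#' Run the full pipeline
#'
#' Chains simulate -> filter -> window -> repeated-run comparison, and
#' writes all artifacts under `cfg$outDir`: `metrics.json` (per-classifier
#' accuracy, confusion and the Friedman comparison), `accuracy.csv` (the
#' run x classifier table), `boxplot.png`, and `manifest.json` (config file
#' hash, seed, package version, outputs). Identical config + seed reproduce
#' identical metrics.
#'
#' @param cfg A `PipelineConfig`.
#' @param writeTrials Also write each simulated trial's matrix CSV under
#'   `outDir/trials/`.
#' @return Invisibly, the `compareAll()` result.
#' @export
runPipeline <- function(cfg, writeTrials = FALSE) {
  validatePipelineConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stageSeeds <- sample.int(.Machine$integer.max - 1L, 2L)
  trials <- simulateDataset(cfg$nTrials, cfg$protocol, cfg$effects, cfg$noise,
                            seed = stageSeeds[1], effectScale = cfg$effectScale,
                            noiseScale = cfg$noiseScale, jitterSd = cfg$jitterSd)
  mats <- lapply(trials, function(tr) {
    rec <- trialRecord(lowpassFilter(tr@hemoglobin, cutoff = cfg$filterCutoff),
                       tr@protocol, tr@trialId)
    assembleTrialMatrix(rec)
  })
  if (writeTrials) {
    dir.create(file.path(cfg$outDir, "trials"), showWarnings = FALSE)
    for (m in mats)
      writeTrialMatrix(m, file.path(cfg$outDir, "trials",
                                    paste0(m@trialId, ".csv")))
  }
  ds <- segmentWindows(mats, splitNum = cfg$splitNum)
  control <- list(arch = cfg$arch, epochs = cfg$train@epochs,
                  learningRate = cfg$train@learningRate,
                  batchSize = cfg$train@batchSize)
  res <- compareAll(ds, cfg$classifiers, nRuns = cfg$nRuns,
                    seed = stageSeeds[2], testFraction = cfg$testFraction,
                    control = control)
  metrics <- list(
    classifiers = lapply(res$reports, function(r)
      list(name = r@classifier, accuracy = r@accuracy,
           run_accuracies = r@runAccuracies,
           confusion = list(.matrix = TRUE, nrow = 3L,
                            data = as.vector(r@confusion)))),
    friedman = if (!is.null(res$friedman)) list(
      statistic = res$friedman@statistic, p_value = res$friedman@pValue,
      kendalls_w = res$friedman@kendallsW, cohens_f = res$friedman@cohensF,
      n_runs = res$friedman@nRuns, k_classifiers = res$friedman@kClassifiers,
      medians = as.list(res$friedman@medians)))
  jsonlite::write_json(metrics, file.path(cfg$outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$accuracy, file.path(cfg$outDir, "accuracy.csv"),
                   row.names = FALSE)
  accuracyBoxplot(res$accuracy, file = file.path(cfg$outDir, "boxplot.png"))
  cfgPath <- file.path(cfg$outDir, "config.yaml")
  writePipelineConfig(cfg, cfgPath)
  manifest <- list(
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfgPath)),
    master_seed = cfg$seed,
    package_version = as.character(utils::packageVersion("fnirsEmotion")),
    n_windows = nWindows(ds),
    outputs = c("metrics.json", "accuracy.csv", "boxplot.png", "config.yaml"))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
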
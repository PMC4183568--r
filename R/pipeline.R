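#' Assemble a run configuration
#'
#' Bundles every tunable of the end-to-end workflow; all defaults are the
#' protocol's stated values. Returned as a plain list of class
#' `"RunConfig"` so it can be serialised alongside results for provenance.
#'
#' @param fasta Optional FASTA path of genotype amplicons; when `NULL`,
#'   genotypes come from [generateGenotypeSequences()] under `seed`.
#' @param outDir Output directory for file-writing commands.
#' @param enzymes Enzyme list (see [restrictionEnzyme()]).
#' @param channelRule Enzyme -> analysed dye.
#' @param convention TRF length convention.
#' @param minHeight,minSize,binWidth,noiseThreshold,driftWindow Peak
#'   processing parameters.
#' @param bias A [BiasConfig-class] for simulation.
#' @param nReplicates,nTechReps,pipettingCv,totalArea Study-design
#'   parameters.
#' @param nPerm,nComponents,simpsonVariant Statistical options.
#' @param pairDeltas Deltas of the two-genotype templates.
#' @param seed Root seed for every stochastic step.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(fasta = NULL, outDir = tempdir(),
                      enzymes = defaultEnzymes(),
                      channelRule = defaultChannelRule(),
                      convention = "labelled_strand", minHeight = 100,
                      minSize = 100, binWidth = 2, noiseThreshold = 0.05,
                      driftWindow = c(-14, 2), bias = biasConfig(),
                      nReplicates = 3, nTechReps = 3, pipettingCv = 0.02,
                      totalArea = 5e4, nPerm = 10000, nComponents = 2,
                      simpsonVariant = "gini",
                      pairDeltas = c(0, 0.025, 0.05), seed = 1L) {
  cfg <- list(fasta = fasta, outDir = outDir, enzymes = enzymes,
              channelRule = channelRule, convention = convention,
              minHeight = minHeight, minSize = minSize,
              binWidth = binWidth, noiseThreshold = noiseThreshold,
              driftWindow = driftWindow, bias = bias,
              nReplicates = nReplicates, nTechReps = nTechReps,
              pipettingCv = pipettingCv, totalArea = totalArea,
              nPerm = nPerm, nComponents = nComponents,
              simpsonVariant = simpsonVariant, pairDeltas = pairDeltas,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' @noRd
.configGenotypes <- function(config) {
  if (!is.null(config$fasta)) readGenotypeFasta(config$fasta)
  else generateGenotypeSequences(6, enzymes = config$enzymes,
                                 seed = config$seed,
                                 channelRule = config$channelRule)
}

#' Digest command: predict and write the TRF table
#'
#' @param config A [runConfig()] list.
#' @param records Optional genotype list overriding `config$fasta`.
#' @return The TRF prediction table (invisibly written to
#'   `outDir/trf_table.tsv`).
#' @export
runDigest <- function(config = runConfig(), records = NULL) {
  if (is.null(records)) records <- .configGenotypes(config)
  trfTable <- predictTRFTable(records, config$enzymes,
                              config$channelRule, config$convention)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  writeTRFTable(trfTable, file.path(config$outDir, "trf_table.tsv"))
  trfTable
}

#' Simulate command: write the full synthetic study dataset
#'
#' @inheritParams runDigest
#' @return The dataset list from [generateStudyDataset()]; the manifest,
#'   per-enzyme peak-table CSVs, templates and FASTA are written to
#'   `config$outDir`.
#' @export
runSimulate <- function(config = runConfig(), records = NULL) {
  if (is.null(records)) records <- .configGenotypes(config)
  trfTable <- predictTRFTable(records, config$enzymes,
                              config$channelRule, config$convention)
  templates <- studyTemplates(vapply(records, genotypeId, character(1)),
                              config$pairDeltas)
  dataset <- generateStudyDataset(
    templates, trfTable,
    enzymes = vapply(config$enzymes, enzymeName, character(1)),
    bias = config$bias, nReplicates = config$nReplicates,
    nTechReps = config$nTechReps, pipettingCv = config$pipettingCv,
    totalArea = config$totalArea, seed = config$seed,
    channelRule = config$channelRule)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypeFasta(records, file.path(config$outDir, "genotypes.fasta"))
  writeTemplates(templates, file.path(config$outDir, "templates.tsv"))
  utils::write.table(dataset$manifest,
                     file.path(config$outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (enz in names(dataset$peaks))
    writePeakTable(dataset$peaks[[enz]],
                   file.path(config$outDir, paste0("peaks_", enz, ".csv")))
  dataset$templates <- templates
  dataset$trfTable <- trfTable
  dataset
}

#' Analyse command: process observed peaks and compare with predictions
#'
#' Processes each enzyme channel through the filtering/binning/noise/pooling
#' pipeline, averages technical replicates to the template-replicate level,
#' and runs the full agreement analysis per enzyme.
#'
#' @param dataset Dataset list from [runSimulate()] /
#'   [generateStudyDataset()] (must carry `trfTable`; `runSimulate` output
#'   does).
#' @param config A [runConfig()] list.
#' @return Named list (per enzyme) of [TRFLPComparison-class] objects; a
#'   JSON report per enzyme is written to `config$outDir`.
#' @export
runAnalyse <- function(dataset, config = runConfig()) {
  trfTable <- dataset$trfTable
  if (is.null(trfTable)) stop("dataset carries no TRF table")
  out <- list()
  for (enz in names(dataset$peaks)) {
    observed <- processPeakTable(
      dataset$peaks[[enz]], enz, trfTable = trfTable,
      channelRule = config$channelRule, minHeight = config$minHeight,
      minSize = config$minSize, binWidth = config$binWidth,
      noiseThreshold = config$noiseThreshold,
      driftWindow = config$driftWindow)
    obsAvg <- averageTechReps(observed, dataset$manifest)
    predAvg <- averageTechReps(dataset$predicted[[enz]], dataset$manifest)
    cmp <- comparePredictedObserved(
      predAvg, obsAvg, nPerm = config$nPerm, seed = config$seed,
      nComponents = config$nComponents,
      simpsonVariant = config$simpsonVariant,
      predictedTotalArea = config$totalArea)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeComparisonJSON(cmp, file.path(config$outDir,
                                       paste0("comparison_", enz, ".json")))
    out[[enz]] <- cmp
  }
  out
}
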
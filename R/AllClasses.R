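#' RestrictionEnzyme: a type II restriction enzyme for terminal-fragment
#' arithmetic
#'
#' Holds an IUPAC recognition pattern of length `r` and a cut offset `c`
#' (`0 <= c <= r`): scanning a strand 5'->3', the enzyme cuts after `c` bases
#' of the recognition site. Both enzymes used in the fingerprinting protocol
#' (AluI, HinfI) have reverse-complement-palindromic recognition patterns, so
#' single-strand scanning finds every duplex site; [restrictionEnzyme()]
#' asserts this at construction.
#'
#' @slot name Enzyme name, e.g. `"AluI"`.
#' @slot recognition IUPAC recognition pattern (e.g. `"AGCT"`, `"GANTC"`).
#' @slot cutOffset Integer cut position within the site on the scanned strand.
#'
#' @seealso [restrictionEnzyme()], [defaultEnzymes()]
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@recognition) != 1L ||
      !grepl("^[ACGTRYSWKMBDHVN]+$", object@recognition))
    msg <- c(msg, "'recognition' must be a non-empty IUPAC pattern")
  if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
      object@cutOffset < 0L || object@cutOffset > nchar(object@recognition))
    msg <- c(msg, "'cutOffset' must lie within the recognition site")
  if (length(msg)) msg else TRUE
})

#' GenotypeRecord: one end-labelled amplicon sequence
#'
#' An amplicon genotype with its stored-strand sequence and the mapping of
#' fluorescent dyes to sequence ends. In the SSU rDNA protocol the amplicon is
#' delimited by the NS31 and AM1 primers; FAM labels the NS31 end and HEX the
#' AM1 end, and the analysed channel couples HEX to AluI digests and FAM to
#' HinfI digests.
#'
#' @slot id Accession-like identifier.
#' @slot sequence Nucleotide sequence of the stored strand. IUPAC ambiguity
#'   codes are tolerated on read but rejected by digestion.
#' @slot dyeEnds Named character vector mapping dye name to `"left"`
#'   (position 1 of the stored strand) or `"right"` (last position).
#'
#' @seealso [genotypeRecord()], [readGenotypeFasta()]
#' @exportClass GenotypeRecord
setClass("GenotypeRecord",
  representation(id = "character", sequence = "character",
                 dyeEnds = "character"))

setValidity("GenotypeRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    msg <- c(msg, "'sequence' must be a non-empty string")
  else if (!grepl("^[ACGTRYSWKMBDHVN]+$", object@sequence))
    msg <- c(msg, "'sequence' must contain only IUPAC nucleotide codes")
  de <- object@dyeEnds
  if (length(de) == 0L || is.null(names(de)) || any(!nzchar(names(de))))
    msg <- c(msg, "'dyeEnds' must be a named vector (dye -> end)")
  else {
    if (!all(de %in% c("left", "right")))
      msg <- c(msg, "'dyeEnds' values must be \"left\" or \"right\"")
    if (anyDuplicated(names(de)))
      msg <- c(msg, "each dye must be assigned to exactly one end")
    if (length(de) == 2L && de[[1L]] == de[[2L]])
      msg <- c(msg, "two dyes must sit on opposite ends")
    if (length(de) > 2L)
      msg <- c(msg, "at most two dyes (one per end) are supported")
  }
  if (length(msg)) msg else TRUE
})

#' CommunityTemplate: an artificial community of known composition
#'
#' A named genotype -> proportion map describing one artificial community
#' template. Proportions are strictly positive and sum to one; templates hold
#' between two and six genotypes, the richness range typical of AM fungal
#' field samples that the experimental design spans.
#'
#' @slot name Template name.
#' @slot composition Named numeric vector of genotype proportions.
#'
#' @seealso [communityTemplate()], [equalProportions()],
#'   [brokenStickProportions()], [nearEqualPair()]
#' @exportClass CommunityTemplate
setClass("CommunityTemplate",
  representation(name = "character", composition = "numeric"))

setValidity("CommunityTemplate", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  comp <- object@composition
  if (is.null(names(comp)) || any(!nzchar(names(comp))))
    msg <- c(msg, "'composition' must be named by genotype id")
  else if (anyDuplicated(names(comp)))
    msg <- c(msg, "duplicate genotype ids in composition")
  if (length(comp) < 2L || length(comp) > 6L)
    msg <- c(msg, "templates hold 2-6 genotypes")
  if (any(comp <= 0))
    msg <- c(msg, "proportions must be strictly positive")
  if (abs(sum(comp) - 1) > 1e-9)
    msg <- c(msg, "proportions must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})

#' TRFProfile: a relative-abundance profile over TRF lengths
#'
#' One sample's fingerprint: a map from TRF length (bp) to relative abundance.
#' Predicted profiles are induced by a [CommunityTemplate-class] and a TRF
#' prediction table; observed (processed) profiles come out of the
#' peak-processing pipeline. Abundances sum to one.
#'
#' @slot sampleId Sample identifier.
#' @slot enzyme Enzyme whose digest the profile describes.
#' @slot dye Analysed dye channel.
#' @slot abundance Named numeric vector; names are TRF lengths in bp.
#' @slot kind `"predicted"` or `"observed"`.
#'
#' @seealso [trfProfile()], [buildPredictedProfile()], [processPeakTable()]
#' @exportClass TRFProfile
setClass("TRFProfile",
  representation(sampleId = "character", enzyme = "character",
                 dye = "character", abundance = "numeric",
                 kind = "character"))

setValidity("TRFProfile", function(object) {
  msg <- character(0)
  ab <- object@abundance
  if (length(ab)) {
    keys <- suppressWarnings(as.numeric(names(ab)))
    if (any(is.na(keys)) || any(keys <= 0))
      msg <- c(msg, "abundance names must be positive TRF lengths (bp)")
    if (any(ab < 0)) msg <- c(msg, "abundances must be non-negative")
    if (abs(sum(ab) - 1) > 1e-9)
      msg <- c(msg, "abundances must sum to 1 (tolerance 1e-9)")
  }
  if (!object@kind %in% c("predicted", "observed"))
    msg <- c(msg, "'kind' must be \"predicted\" or \"observed\"")
  if (length(msg)) msg else TRUE
})

#' BiasConfig: measurement-bias parameters for the peak-table simulator
#'
#' Phenomenological model of the biases documented for the fingerprinting
#' protocol. Observed size = predicted + driftIntercept +
#' driftSlope * predicted + N(0, sizeSd) (TRF drift: fluorophore-dependent
#' migration makes fragments run fast, so sizes are underestimated by about
#' 1-14 bp). With probability `splitProb` a TRF's area is split over 2-3
#' nearby peaks within +/- `splitSpread` bp. A fraction `pseudoRate` of each
#' genotype's area is diverted to its pseudo-TRF lengths (under-digestion),
#' scaled up with template richness. Areas are multiplied by lognormal noise
#' with coefficient of variation `areaNoiseCv`; peaks whose height
#' (area / `peakWidth`) falls below `detectionFloor` fluorescence units are
#' dropped.
#'
#' @slot driftIntercept,driftSlope,sizeSd Linear drift model (bp, bp/bp, bp).
#' @slot splitProb,splitSpread Peak-splitting probability and spread (bp).
#' @slot pseudoRate Fraction of area diverted to pseudo-TRFs, in `[0, 1)`.
#' @slot areaNoiseCv Lognormal area-noise coefficient of variation.
#' @slot detectionFloor Detection threshold in fluorescence units.
#' @slot peakWidth Divisor converting peak area to peak height.
#'
#' @seealso [biasConfig()], [calibrateDrift()], [simulateObservedPeakTable()]
#' @exportClass BiasConfig
setClass("BiasConfig",
  representation(driftIntercept = "numeric", driftSlope = "numeric",
                 sizeSd = "numeric", splitProb = "numeric",
                 splitSpread = "numeric", pseudoRate = "numeric",
                 areaNoiseCv = "numeric", detectionFloor = "numeric",
                 peakWidth = "numeric"))

setValidity("BiasConfig", function(object) {
  msg <- character(0)
  one <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("driftIntercept", "driftSlope", "sizeSd", "splitProb",
              "splitSpread", "pseudoRate", "areaNoiseCv", "detectionFloor",
              "peakWidth"))
    if (!one(slot(object, s))) msg <- c(msg, paste0("'", s, "' must be a single finite number"))
  if (length(msg)) return(msg)
  if (object@splitProb < 0 || object@splitProb > 1)
    msg <- c(msg, "'splitProb' must be in [0, 1]")
  if (object@pseudoRate < 0 || object@pseudoRate >= 1)
    msg <- c(msg, "'pseudoRate' must be in [0, 1)")
  if (object@sizeSd < 0 || object@splitSpread < 0 || object@areaNoiseCv < 0)
    msg <- c(msg, "spreads and noise levels must be >= 0")
  if (object@peakWidth <= 0) msg <- c(msg, "'peakWidth' must be positive")
  if (length(msg)) msg else TRUE
})

#' TRFLPComparison: predicted-versus-observed agreement report
#'
#' Result container for [comparePredictedObserved()]: Mantel statistics on
#' Euclidean PC-score distances and on Bray-Curtis dissimilarities, per-sample
#' Margalef and Simpson diversity indices, and ordinary least-squares
#' regressions of observed on predicted indices.
#'
#' @slot mantelEuclidean,mantelBray Lists with elements `r`, `p`, `nPerm`.
#' @slot pcaPredicted,pcaObserved Covariance-PCA summaries (see
#'   [covariancePCA()]).
#' @slot diversity Per-sample data frame of predicted and observed indices.
#' @slot regressions Named list of regression summaries (`margalef`,
#'   `simpson`), each with slope, intercept, r_squared, f_statistic, df, p.
#' @slot nComponents Number of PC axes used for Euclidean distances.
#'
#' @seealso [comparePredictedObserved()]
#' @exportClass TRFLPComparison
setClass("TRFLPComparison",
  representation(mantelEuclidean = "list", mantelBray = "list",
                 pcaPredicted = "list", pcaObserved = "list",
                 diversity = "data.frame", regressions = "list",
                 nComponents = "integer"))
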
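#' Read / write electropherogram peak tables
#'
#' CSV dialect of typical fragment-analysis exports: one row per peak with
#' columns `sample_id`, `dye`, `size_bp`, `height`, `area`.
#'
#' @param path CSV path.
#' @param peaks Peak data frame.
#' @return Data frame of peaks (reader) or `path` (writer).
#' @export
readPeakTable <- function(path) {
  peaks <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "dye", "size_bp", "height", "area")
  missing <- setdiff(required, names(peaks))
  if (length(missing))
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  peaks
}

#' @rdname readPeakTable
#' @export
writePeakTable <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter raw peaks by height, size and dye channel
#'
#' Retains peaks strictly higher than `minHeight` fluorescence units and
#' strictly longer than `minSize` bp (the protocol analyses peaks *greater
#' than* 100 units representing TRFs *longer than* 100 bp), in the analysed
#' dye channel of the enzyme (HEX for AluI, FAM for HinfI by default).
#'
#' @param peaks Peak data frame (see [readPeakTable()]).
#' @param enzyme Enzyme name of the digest being analysed.
#' @param minHeight Height threshold (FU), strict.
#' @param minSize Size threshold (bp), strict.
#' @param channelRule Named vector enzyme -> analysed dye.
#' @return Filtered peak data frame.
#' @export
filterPeaks <- function(peaks, enzyme, minHeight = 100, minSize = 100,
                        channelRule = defaultChannelRule()) {
  knownDyes <- unique(unname(channelRule))
  bad <- setdiff(unique(peaks$dye), knownDyes)
  if (length(bad))
    stop("unknown dye value(s) in peak table: ", paste(bad, collapse = ", "))
  if (!enzyme %in% names(channelRule))
    stop("channel rule has no dye for enzyme ", enzyme)
  keep <- peaks$dye == channelRule[[enzyme]] &
    peaks$height > minHeight & peaks$size_bp > minSize
  peaks[keep, , drop = FALSE]
}

#' Bin peak areas on a fixed 2-bp grid
#'
#' Half-open bins anchored at 100.0 bp (`[100,102)`, `[102,104)`, ...),
#' labelled by lower edge; peak areas are summed within a bin. A fixed grid
#' keeps binning deterministic (clustering-based binning would depend on the
#' sample set).
#'
#' @param peaks Filtered peak data frame (all sizes > `anchor`).
#' @param binWidth Bin width in bp.
#' @param anchor Grid origin in bp.
#' @return Named numeric vector of per-bin summed areas (names = lower bin
#'   edges), sorted by bin.
#' @examples
#' binPeaks(data.frame(sample_id = "s", dye = "HEX",
#'                     size_bp = c(157.7, 157.9), height = c(500, 400),
#'                     area = c(10, 5)))  # bin 156 -> 15
#' @export
binPeaks <- function(peaks, binWidth = 2, anchor = 100) {
  if (nrow(peaks) == 0L) return(stats::setNames(numeric(0), character(0)))
  bin <- anchor + floor((peaks$size_bp - anchor) / binWidth) * binWidth
  areas <- tapply(peaks$area, bin, sum)
  out <- stats::setNames(as.numeric(areas), names(areas))
  out[order(as.numeric(names(out)))]
}

#' Exclude low-abundance TRF bins across a profile set
#'
#' A TRF bin is noise when, averaged over the profiles *in which it is
#' present* (area > 0), it represents `threshold` (default 5%) or less of
#' the profile total; such bins are removed from every profile and the
#' remainder re-normalized. The rule is inclusive ("5% or less") and
#' idempotent: surviving bins can only gain relative abundance on
#' re-normalization.
#'
#' @param profiles Named list of named numeric vectors (per-sample relative
#'   abundances; absolute areas are accepted and normalized first).
#' @param threshold Mean relative abundance at or below which a bin is
#'   dropped.
#' @return List of filtered, re-normalized abundance vectors; attribute
#'   `"emptied"` names samples whose profile lost every bin (their entry is
#'   an empty vector).
#' @export
noiseFilter <- function(profiles, threshold = 0.05) {
  if (length(profiles) == 0L) stop("at least one profile required")
  rel <- lapply(profiles, function(p) if (sum(p) > 0) p / sum(p) else p)
  bins <- unique(unlist(lapply(rel, names)))
  meanWhenPresent <- vapply(bins, function(b) {
    v <- vapply(rel, function(p) if (b %in% names(p)) p[[b]] else 0,
                numeric(1))
    mean(v[v > 0])
  }, numeric(1))
  drop <- bins[meanWhenPresent <= threshold]
  out <- lapply(rel, function(p) {
    p <- p[setdiff(names(p), drop)]
    if (length(p) && sum(p) > 0) p / sum(p) else p[p > 0]
  })
  emptied <- names(out)[vapply(out, length, integer(1)) == 0L]
  if (length(emptied))
    warning("noise filter emptied profile(s): ",
            paste(emptied, collapse = ", "))
  attr(out, "emptied") <- emptied
  out
}

#' Match observed TRF bins to predicted TRFs under drift
#'
#' Capillary electrophoresis underestimates labelled-fragment sizes ("TRF
#' drift"), so an observed bin is matched to the predicted complete-digest
#' TRF whose deviation `observed - predicted` falls inside `driftWindow`
#' (default (-14, +2) bp, the documented deviation range plus margin);
#' nearest absolute deviation wins, ties go to the smaller predicted size.
#' Bins matching only pseudo-TRF predictions are flagged `"pseudo"`; the
#' rest are `"unmatched"`.
#'
#' @param observedBins Numeric vector of observed bin edges / sizes (bp).
#' @param trfTable Prediction table from [predictTRFTable()].
#' @param enzyme Enzyme name selecting rows of `trfTable`.
#' @param driftWindow Length-2 numeric `(lower, upper)`, `lower < upper`.
#' @return Data frame with columns `bin`, `status`
#'   (`matched`/`pseudo`/`unmatched`), `predicted_bp` (NA when unmatched)
#'   and `genotype_id`.
#' @export
matchTRFs <- function(observedBins, trfTable, enzyme,
                      driftWindow = c(-14, 2)) {
  if (length(driftWindow) != 2L || driftWindow[1] >= driftWindow[2])
    stop("driftWindow must be (lower, upper) with lower < upper")
  sub <- trfTable[trfTable$enzyme == enzyme, , drop = FALSE]
  complete <- sub$complete_trf_bp
  pseudoLens <- unlist(sub$pseudo_trfs_bp)
  pseudoIds <- rep(sub$genotype_id,
                   vapply(sub$pseudo_trfs_bp, length, integer(1)))
  pick <- function(obs, lens) {
    dev <- obs - lens
    ok <- which(dev >= driftWindow[1] & dev <= driftWindow[2])
    if (!length(ok)) return(NA_integer_)
    ok[order(abs(dev[ok]), lens[ok])][1L]
  }
  rows <- lapply(observedBins, function(b) {
    i <- pick(b, complete)
    if (!is.na(i)) {
      return(data.frame(bin = b, status = "matched",
                        predicted_bp = complete[i],
                        genotype_id = sub$genotype_id[i]))
    }
    j <- pick(b, pseudoLens)
    if (!is.na(j)) {
      return(data.frame(bin = b, status = "pseudo",
                        predicted_bp = pseudoLens[j],
                        genotype_id = pseudoIds[j]))
    }
    data.frame(bin = b, status = "unmatched", predicted_bp = NA_real_,
               genotype_id = NA_character_)
  })
  do.call(rbind, rows)
}

#' Pool split peaks onto canonical TRFs
#'
#' Empirical digests often spread one genotype's TRF over 2-3 nearby peaks;
#' pooling sums the areas of all bins assigned to the same canonical
#' predicted TRF (as established by digesting genotypes individually).
#' Unmapped bins pass through unchanged; total area is conserved.
#'
#' @param profile Named numeric vector (bin -> area or relative abundance).
#' @param poolingMap Named numeric/character vector mapping observed bin
#'   (name) to canonical TRF label (value); each bin at most once.
#' @return Named numeric vector keyed by canonical label or original bin.
#' @export
poolSplitPeaks <- function(profile, poolingMap) {
  if (anyDuplicated(names(poolingMap)))
    stop("pooling map assigns a bin more than once")
  if (length(profile) == 0L) return(profile)
  key <- ifelse(names(profile) %in% names(poolingMap),
                as.character(poolingMap[names(profile)]), names(profile))
  pooled <- tapply(profile, key, sum)
  out <- stats::setNames(as.numeric(pooled), names(pooled))
  out[order(as.numeric(names(out)))]
}

#' Build a pooling map from predictions
#'
#' Convenience wrapper around [matchTRFs()]: every observed bin matched to a
#' predicted complete TRF is pooled under that predicted length; pseudo and
#' unmatched bins are left unmapped (they remain distinct TRFs, which is how
#' under-digestion inflates observed richness).
#'
#' @inheritParams matchTRFs
#' @return Named numeric vector (bin -> canonical predicted length).
#' @export
poolingMapFromPredictions <- function(observedBins, trfTable, enzyme,
                                      driftWindow = c(-14, 2)) {
  m <- matchTRFs(observedBins, trfTable, enzyme, driftWindow)
  m <- m[m$status == "matched", , drop = FALSE]
  stats::setNames(m$predicted_bp, as.character(m$bin))
}

#' Process raw peak tables into TRF profiles
#'
#' Full pipeline in the order: channel/height/size filter -> 2-bp binning ->
#' relative abundance -> cross-sample noise exclusion -> pooling of split
#' peaks onto predicted TRFs (when a prediction table is supplied) ->
#' re-normalization.
#'
#' @param peaks Peak data frame covering one or more samples.
#' @param enzyme Enzyme name of the digest.
#' @param trfTable Optional prediction table enabling pooling.
#' @param channelRule,minHeight,minSize,binWidth,noiseThreshold,driftWindow
#'   Pipeline parameters, see the individual stage functions.
#' @return Named list of [TRFProfile-class] objects (kind `"observed"`),
#'   one per sample; samples emptied by filtering are dropped with a
#'   warning. Each profile carries the sample's total retained area in
#'   attribute `"total_area"`.
#' @export
processPeakTable <- function(peaks, enzyme, trfTable = NULL,
                             channelRule = defaultChannelRule(),
                             minHeight = 100, minSize = 100, binWidth = 2,
                             noiseThreshold = 0.05,
                             driftWindow = c(-14, 2)) {
  filtered <- filterPeaks(peaks, enzyme, minHeight, minSize, channelRule)
  samples <- unique(peaks$sample_id)
  binned <- lapply(samples, function(s)
    binPeaks(filtered[filtered$sample_id == s, , drop = FALSE], binWidth))
  names(binned) <- samples
  totals <- vapply(binned, sum, numeric(1))
  nonEmpty <- totals > 0
  if (any(!nonEmpty))
    warning("no retained peaks for sample(s): ",
            paste(samples[!nonEmpty], collapse = ", "))
  binned <- binned[nonEmpty]
  if (length(binned) == 0L) return(list())
  filteredProfiles <- noiseFilter(binned, noiseThreshold)
  emptied <- attr(filteredProfiles, "emptied")
  filteredProfiles <- filteredProfiles[
    setdiff(names(filteredProfiles), emptied)]
  if (!is.null(trfTable)) {
    allBins <- unique(as.numeric(unlist(lapply(filteredProfiles, names))))
    pmap <- poolingMapFromPredictions(allBins, trfTable, enzyme, driftWindow)
    filteredProfiles <- lapply(filteredProfiles, poolSplitPeaks,
                               poolingMap = pmap)
  }
  dye <- defaultChannelRule()[[enzyme]]
  if (enzyme %in% names(channelRule)) dye <- channelRule[[enzyme]]
  out <- lapply(names(filteredProfiles), function(s) {
    p <- trfProfile(s, enzyme, dye, filteredProfiles[[s]], kind = "observed")
    attr(p, "total_area") <- unname(totals[s])
    p
  })
  names(out) <- names(filteredProfiles)
  out
}

#' Write processed profiles as a wide TSV (samples x TRF bins)
#'
#' @param profiles List of [TRFProfile-class] objects.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeProfileMatrix <- function(profiles, path) {
  m <- profilesToMatrix(profiles)
  utils::write.table(data.frame(sample_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
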
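#' Published reference TRF measurements
#'
#' The printed predicted and observed TRF sizes for the six genotypes of the
#' original artificial-community experiment (HEX/AluI and FAM/HinfI
#' channels), used as calibration input for the bias simulator. Rows with
#' `role = "complete"` pair a predicted complete-digest TRF with one
#' observed peak (split peaks give several rows per genotype); rows with
#' `role = "pseudo_observation"` are observed peaks attributed to
#' under-digestion, with no complete-digest counterpart.
#'
#' @return Data frame with columns `enzyme`, `genotype`, `accession`,
#'   `predicted_bp`, `observed_bp`, `deviation_bp`, `role`.
#' @export
referenceTRFTable <- function() {
  complete <- function(enzyme, genotype, accession, predicted, observed) {
    data.frame(enzyme = enzyme, genotype = genotype, accession = accession,
               predicted_bp = predicted, observed_bp = observed,
               deviation_bp = observed - predicted, role = "complete")
  }
  pseudo <- function(enzyme, observed) {
    data.frame(enzyme = enzyme, genotype = NA_character_,
               accession = NA_character_, predicted_bp = NA_real_,
               observed_bp = observed, deviation_bp = NA_real_,
               role = "pseudo_observation")
  }
  rbind(
    complete("AluI", "Genotype 1", "KJ749695", 162.0, 157.7),
    complete("AluI", "Genotype 6", "KJ749700", 309.0,
             c(302.0, 303.8, 305.1)),
    pseudo("AluI", c(309.6, 310.6)),
    complete("AluI", "Genotype 4", "KJ749698", 416.0, c(406.7, 411.7)),
    complete("AluI", "Genotype 5", "KJ749699", 449.0,
             c(436.0, 442.3, 443.5)),
    complete("AluI", "Genotype 3", "KJ749697", 469.0,
             c(455.6, 459.5, 463.7)),
    complete("AluI", "Genotype 2", "KJ749696", 504.0,
             c(497.0, 498.3, 499.2)),
    complete("HinfI", "Genotype 1", "KJ749695", 141.5, 137.6),
    complete("HinfI", "Genotype 5", "KJ749699", 160.5, 154.4),
    complete("HinfI", "Genotype 4", "KJ749698", 190.5, 188.2),
    complete("HinfI", "Genotype 2", "KJ749696", 299.5, 297.4),
    pseudo("HinfI", c(503.4, 518.9, 522.6)),
    complete("HinfI", "Genotype 6", "KJ749700", 524.5, 523.6),
    complete("HinfI", "Genotype 3", "KJ749697", 547.0, 548.1)
  )
}

#' Calibrate the linear TRF-drift model
#'
#' Least-squares fit of `deviation ~ predicted` over the reference
#' predicted/observed pairs (both enzymes pooled): observed sizes are
#' consistently underestimated by about 1-14 bp, more so for larger
#' fragments, which a linear-in-size model captures.
#'
#' @param reference Reference measurements, default [referenceTRFTable()];
#'   only `role == "complete"` rows are used.
#' @return List with `intercept` (bp), `slope` (bp/bp) and `sigma` (bp,
#'   residual standard deviation).
#' @export
calibrateDrift <- function(reference = referenceTRFTable()) {
  ref <- reference[reference$role == "complete", , drop = FALSE]
  fit <- stats::lm(deviation_bp ~ predicted_bp, data = ref)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       sigma = stats::sd(stats::residuals(fit)))
}

#' Construct a bias configuration
#'
#' Defaults are calibrated to the published single-genotype digests: the
#' drift line and its residual scatter are fitted to the reference
#' predicted/observed pairs ([calibrateDrift()]); splitting reflects that 5
#' of 6 genotypes produced 2-3 peaks under AluI spanning 2-8 bp; the
#' under-digestion rate sits mid-way in the 1-5% band bounded below by
#' single-genotype purities above 99%.
#'
#' @param driftIntercept,driftSlope,sizeSd Drift model; defaults fitted at
#'   call time.
#' @param splitProb,splitSpread Peak splitting (probability; +/- bp).
#' @param pseudoRate Base fraction of area diverted to pseudo-TRFs.
#' @param areaNoiseCv Lognormal area-noise CV.
#' @param detectionFloor Height threshold (FU) below which peaks are lost.
#' @param peakWidth Area-to-height divisor.
#' @return A [BiasConfig-class].
#' @examples
#' biasConfig()
#' zeroBiasConfig()
#' @export
biasConfig <- function(driftIntercept = NULL, driftSlope = NULL,
                       sizeSd = NULL, splitProb = 0.8, splitSpread = 4,
                       pseudoRate = 0.02, areaNoiseCv = 0.1,
                       detectionFloor = 100, peakWidth = 5) {
  if (is.null(driftIntercept) || is.null(driftSlope) || is.null(sizeSd)) {
    drift <- calibrateDrift()
    if (is.null(driftIntercept)) driftIntercept <- drift$intercept
    if (is.null(driftSlope)) driftSlope <- drift$slope
    if (is.null(sizeSd)) sizeSd <- drift$sigma
  }
  new("BiasConfig", driftIntercept = driftIntercept,
      driftSlope = driftSlope, sizeSd = sizeSd, splitProb = splitProb,
      splitSpread = splitSpread, pseudoRate = pseudoRate,
      areaNoiseCv = areaNoiseCv, detectionFloor = detectionFloor,
      peakWidth = peakWidth)
}

#' @rdname biasConfig
#' @export
zeroBiasConfig <- function() {
  new("BiasConfig", driftIntercept = 0, driftSlope = 0, sizeSd = 0,
      splitProb = 0, splitSpread = 0, pseudoRate = 0, areaNoiseCv = 0,
      detectionFloor = 0, peakWidth = 5)
}

setMethod("show", "BiasConfig", function(object) {
  cat(sprintf(paste0(
    "BiasConfig: drift %.2f %+.4f*size bp (sd %.2f); split p=%.2f ",
    "+/-%.1f bp;\n  pseudo rate %.3f; area CV %.2f; floor %.0f FU\n"),
    object@driftIntercept, object@driftSlope, object@sizeSd,
    object@splitProb, object@splitSpread, object@pseudoRate,
    object@areaNoiseCv, object@detectionFloor))
})

#' Simulate an observed peak table for one sample
#'
#' Generates electropherogram peaks for one digested community sample. For
#' each genotype: a richness-scaled fraction of its area
#' (`pseudoRate * (richness - 1) / (maxRichness - 1)`; mixed templates
#' under-digest more than single-genotype ones) is diverted equally to its
#' pseudo-TRF lengths; the remaining area is, with probability `splitProb`,
#' split over 2-3 peaks within +/- `splitSpread` bp; every size receives
#' linear drift plus Gaussian jitter; areas are multiplied by lognormal
#' noise; peaks whose height (`area / peakWidth`) drops below the detection
#' floor are lost.
#'
#' @param template A [CommunityTemplate-class] (or named proportion vector).
#' @param trfTable Prediction table from [predictTRFTable()].
#' @param enzyme Enzyme name.
#' @param bias A [BiasConfig-class].
#' @param totalArea Total fluorescence area of the sample.
#' @param sampleId Sample identifier for the peak rows.
#' @param seed Integer seed (deterministic output for a given seed).
#' @param channelRule Enzyme -> dye map.
#' @param maxRichness Richness at which the full `pseudoRate` applies.
#' @return Peak data frame (`sample_id`, `dye`, `size_bp`, `height`,
#'   `area`).
#' @export
simulateObservedPeakTable <- function(template, trfTable, enzyme, bias,
                                      totalArea = 5e4,
                                      sampleId = "sample1", seed = 1L,
                                      channelRule = defaultChannelRule(),
                                      maxRichness = 6) {
  comp <- if (is(template, "CommunityTemplate")) composition(template)
          else template
  .checkProportions(comp)
  if (totalArea <= 0) stop("totalArea must be positive")
  sub <- trfTable[trfTable$enzyme == enzyme, , drop = FALSE]
  missing <- setdiff(names(comp), sub$genotype_id)
  if (length(missing))
    stop("no TRF prediction for genotype(s): ",
         paste(missing, collapse = ", "))
  dye <- channelRule[[enzyme]]
  richness <- length(comp)
  pseudoEff <- if (maxRichness > 1)
    bias@pseudoRate * (richness - 1) / (maxRichness - 1) else 0

  set.seed(.subSeed(seed, c(sampleId, enzyme)))
  drift <- function(size) size + bias@driftIntercept +
    bias@driftSlope * size +
    if (bias@sizeSd > 0) stats::rnorm(length(size), 0, bias@sizeSd) else 0

  sizes <- numeric(0); areas <- numeric(0)
  for (g in names(comp)) {
    row <- sub[sub$genotype_id == g, , drop = FALSE][1, ]
    gArea <- totalArea * comp[[g]]
    pseudoLens <- row$pseudo_trfs_bp[[1]]
    pseudoArea <- if (length(pseudoLens)) gArea * pseudoEff else 0
    if (pseudoArea > 0) {
      each <- pseudoArea / length(pseudoLens)
      sizes <- c(sizes, drift(pseudoLens))
      areas <- c(areas, rep(each, length(pseudoLens)))
    }
    mainArea <- gArea - pseudoArea
    if (bias@splitProb > 0 && stats::runif(1) < bias@splitProb) {
      nSplit <- sample(2:3, 1)
      w <- stats::runif(nSplit, 0.2, 1)
      w <- w / sum(w)
      offsets <- stats::runif(nSplit, -bias@splitSpread, bias@splitSpread)
      sizes <- c(sizes, drift(rep(row$complete_trf_bp, nSplit)) + offsets)
      areas <- c(areas, mainArea * w)
    } else {
      sizes <- c(sizes, drift(row$complete_trf_bp))
      areas <- c(areas, mainArea)
    }
  }
  if (bias@areaNoiseCv > 0) {
    sdlog <- sqrt(log(1 + bias@areaNoiseCv^2))
    areas <- areas * stats::rlnorm(length(areas), -sdlog^2 / 2, sdlog)
  }
  heights <- areas / bias@peakWidth
  keep <- heights >= bias@detectionFloor | bias@detectionFloor == 0
  peaks <- data.frame(sample_id = sampleId, dye = dye,
                      size_bp = sizes[keep], height = heights[keep],
                      area = areas[keep])
  peaks[order(peaks$size_bp), , drop = FALSE]
}

#' Generate a full study dataset
#'
#' Emulates the complete experimental design: each template is mixed in
#' `nReplicates` replicate mixes (proportions perturbed by a lognormal
#' pipetting error of CV `pipettingCv`, then renormalized), and each mix is
#' measured `nTechReps` times per enzyme, giving 9 x 3 x 3 = 81 observed
#' peak-table samples per enzyme channel under the default design. The
#' predicted (theoretical) profile of a sample is built from the *nominal*
#' template composition, as in the original analysis.
#'
#' @param templates Named list of [CommunityTemplate-class] objects
#'   (default design requires nine, see [studyTemplates()]).
#' @param trfTable Prediction table from [predictTRFTable()].
#' @param enzymes Character vector of enzyme names to simulate.
#' @param bias A [BiasConfig-class].
#' @param nReplicates,nTechReps Replicate mixes per template and technical
#'   measurements per mix.
#' @param pipettingCv Lognormal CV of the replicate-mix pipetting error.
#' @param totalArea Total fluorescence area per sample.
#' @param seed Root seed; per-sample sub-seeds are derived by stable
#'   hashing of (template, replicate, tech rep, enzyme).
#' @param channelRule Enzyme -> dye map.
#' @return List with `manifest` (data frame: `sample_id`, `template`,
#'   `replicate`, `tech_rep`), `peaks` (per-enzyme combined peak data
#'   frame) and `predicted` (per-enzyme named list of predicted
#'   [TRFProfile-class], one per sample).
#' @export
generateStudyDataset <- function(templates, trfTable,
                                 enzymes = c("AluI", "HinfI"),
                                 bias = biasConfig(), nReplicates = 3,
                                 nTechReps = 3, pipettingCv = 0.02,
                                 totalArea = 5e4, seed = 1L,
                                 channelRule = defaultChannelRule()) {
  manifest <- list(); peaks <- list(); predicted <- list()
  for (enz in enzymes) {
    peaks[[enz]] <- list()
    predicted[[enz]] <- list()
  }
  for (tname in names(templates)) {
    tpl <- templates[[tname]]
    for (r in seq_len(nReplicates)) {
      comp <- composition(tpl)
      if (pipettingCv > 0) {
        set.seed(.subSeed(seed, c(tname, "mix", r)))
        sdlog <- sqrt(log(1 + pipettingCv^2))
        comp <- comp * stats::rlnorm(length(comp), -sdlog^2 / 2, sdlog)
        comp <- comp / sum(comp)
      }
      for (k in seq_len(nTechReps)) {
        sid <- sprintf("%s_r%d_t%d", tname, r, k)
        manifest[[length(manifest) + 1L]] <- data.frame(
          sample_id = sid, template = tname, replicate = r, tech_rep = k)
        for (enz in enzymes) {
          peaks[[enz]][[sid]] <- simulateObservedPeakTable(
            comp, trfTable, enz, bias, totalArea = totalArea,
            sampleId = sid, seed = .subSeed(seed, c(sid, enz)),
            channelRule = channelRule)
          predicted[[enz]][[sid]] <- buildPredictedProfile(
            tpl, trfTable, enz, sampleId = sid)
        }
      }
    }
  }
  list(manifest = do.call(rbind, manifest),
       peaks = lapply(peaks, function(p) do.call(rbind, c(p, list(make.row.names = FALSE)))),
       predicted = predicted)
}

#' Average technical replicates of observed profiles
#'
#' Mean relative abundance per TRF bin over the technical replicates of
#' each template-replicate mix (the level at which distances between
#' samples are compared); total retained areas are averaged too.
#'
#' @param profiles Named list of [TRFProfile-class] objects.
#' @param manifest Manifest data frame from [generateStudyDataset()].
#' @return Named list of averaged profiles, sample ids `template_rX`.
#' @export
averageTechReps <- function(profiles, manifest) {
  manifest <- manifest[manifest$sample_id %in% names(profiles), ,
                       drop = FALSE]
  groups <- split(manifest$sample_id,
                  paste0(manifest$template, "_r", manifest$replicate))
  out <- lapply(names(groups), function(gname) {
    members <- profiles[groups[[gname]]]
    bins <- sort(unique(as.numeric(unlist(
      lapply(members, function(p) names(profileAbundance(p)))))))
    m <- vapply(members, function(p) {
      ab <- profileAbundance(p)
      v <- stats::setNames(numeric(length(bins)), as.character(bins))
      v[names(ab)] <- ab
      v
    }, numeric(length(bins)))
    mean_ab <- if (is.matrix(m)) rowMeans(m) else m
    first <- members[[1]]
    prof <- trfProfile(gname, first@enzyme, first@dye, mean_ab,
                       kind = first@kind)
    tareas <- vapply(members, function(p) {
      ta <- attr(p, "total_area")
      if (is.null(ta)) NA_real_ else ta
    }, numeric(1))
    if (!all(is.na(tareas)))
      attr(prof, "total_area") <- mean(tareas, na.rm = TRUE)
    prof
  })
  names(out) <- names(groups)
  out
}

#' Generate random genotype amplicon sequences under the design criteria
#'
#' Rejection-samples sequences so that each genotype (i) lies in the target
#' length and GC ranges, (ii) yields a complete-digest TRF in the analysed
#' channel that is unique per enzyme (separated from all others by at least
#' `minTrfSeparation` bp) and longer than `minTrf` bp (so it survives the
#' size filter), and (iii) shares at most `maxSimilarity` global-alignment
#' identity with every other genotype. Deterministic for a given seed.
#'
#' @param n Number of genotypes (2-12).
#' @param lengthRange,gcRange Amplicon length (bp) and GC fraction ranges;
#'   defaults match the characterized study amplicons (527-548 bp, GC
#'   0.397-0.417).
#' @param enzymes Enzyme list (default both protocol enzymes).
#' @param maxSimilarity Maximum pairwise identity (default 0.97, the OTU
#'   delimitation cut-off).
#' @param minTrfSeparation Minimum TRF spacing per enzyme (bp).
#' @param minTrf Minimum TRF length (bp).
#' @param seed Integer seed.
#' @param maxAttempts Per-genotype rejection budget.
#' @param channelRule Enzyme -> dye map.
#' @return Named list of [GenotypeRecord-class] objects (`SIM001`, ...).
#' @export
generateGenotypeSequences <- function(n = 6, lengthRange = c(527, 548),
                                      gcRange = c(0.397, 0.417),
                                      enzymes = defaultEnzymes(),
                                      maxSimilarity = 0.97,
                                      minTrfSeparation = 4, minTrf = 101,
                                      seed = 1L, maxAttempts = 500,
                                      channelRule = defaultChannelRule()) {
  if (n < 2 || n > 12) stop("n must be in 2..12")
  set.seed(.subSeed(seed, "genotypes"))
  accepted <- list()
  acceptedTrfs <- lapply(enzymes, function(e) numeric(0))
  names(acceptedTrfs) <- vapply(enzymes, enzymeName, character(1))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(maxAttempts)) {
      len <- sample(lengthRange[1]:lengthRange[2], 1)
      gcTarget <- stats::runif(1, gcRange[1], gcRange[2])
      nGC <- round(len * gcTarget)
      if (nGC / len < gcRange[1] || nGC / len > gcRange[2]) next
      bases <- sample(c(rep(c("G", "C"), c(ceiling(nGC / 2), floor(nGC / 2))),
                        sample(c("A", "T"), len - nGC, replace = TRUE)))
      rec <- genotypeRecord(sprintf("SIM%03d", i),
                            paste(bases, collapse = ""))
      trfs <- vapply(enzymes, function(e)
        terminalFragmentLength(rec, e, channelRule[[enzymeName(e)]]),
        numeric(1))
      if (any(trfs <= minTrf)) next
      sep <- vapply(names(acceptedTrfs), function(en) {
        prev <- acceptedTrfs[[en]]
        !length(prev) || min(abs(prev - trfs[[en]])) >= minTrfSeparation
      }, logical(1))
      if (!all(sep)) next
      tooSimilar <- any(vapply(accepted, function(a) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(genotypeSequence(a)),
          Biostrings::DNAString(genotypeSequence(rec)), type = "global")
        Biostrings::pid(aln) / 100 > maxSimilarity
      }, logical(1)))
      if (tooSimilar) next
      accepted[[genotypeId(rec)]] <- rec
      for (en in names(acceptedTrfs))
        acceptedTrfs[[en]] <- c(acceptedTrfs[[en]], trfs[[en]])
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not satisfy generator constraints for genotype ", i,
           " after ", maxAttempts, " attempts (accepted so far: ",
           length(accepted), "; TRFs: ",
           paste(vapply(acceptedTrfs, function(v)
             paste(round(v), collapse = ","), character(1)),
             collapse = " | "), ")")
    }
  }
  accepted
}

#' Synthetic stand-ins for the six deposited reference genotypes
#'
#' The deposited amplicon sequences are not redistributable offline, so this
#' constructs six *synthetic* sequences engineered to satisfy every printed
#' property of the originals: exact predicted complete-digest TRF sizes in
#' both channels (AluI via HEX on the right/AM1 end: 162, 504, 469, 416,
#' 449, 309 bp; HinfI via FAM on the left/NS31 end under the duplex-mean
#' convention: 141.5, 299.5, uncut 547, 190.5, 160.5, 524.5 bp), lengths
#' within 527-548 bp, GC within 39.7-41.7%, a genotype-1 AluI pseudo-TRF at
#' 310 bp and a genotype-2 HinfI pseudo-TRF near 520 bp. The backgrounds
#' contain no G outside the planted recognition sites, which provably
#' excludes accidental AluI/HinfI sites. Ids carry a `_syn` suffix; these
#' are stand-ins, not the deposited sequences.
#'
#' @param seed Integer seed for the random backgrounds.
#' @return Named list of six [GenotypeRecord-class] objects.
#' @export
syntheticReferenceGenotypes <- function(seed = 1L) {
  # length, AluI TRF (right end), HinfI duplex-mean TRF (left end; NA = no
  # site), extra planted sites for documented pseudo-TRFs
  design <- list(
    KJ749695_syn = list(len = 527, alu = 162, hinf = 141.5, aluPseudo = 310),
    KJ749696_syn = list(len = 548, alu = 504, hinf = 299.5, hinfPseudo = 519.5),
    KJ749697_syn = list(len = 547, alu = 469, hinf = NA),
    KJ749698_syn = list(len = 533, alu = 416, hinf = 190.5),
    KJ749699_syn = list(len = 538, alu = 449, hinf = 160.5),
    KJ749700_syn = list(len = 530, alu = 309, hinf = 524.5)
  )
  set.seed(.subSeed(seed, "synthetic_reference"))
  out <- list()
  for (id in names(design)) {
    d <- design[[id]]
    plants <- list()  # 0-based start -> pattern
    # AluI sites are planted relative to the right (HEX) end: a fragment of
    # x bp needs the site to start at stored position len - (x - 2) - 4.
    aluSites <- c(d$alu, d$aluPseudo)
    for (x in aluSites[!is.na(aluSites)])
      plants[[length(plants) + 1L]] <- list(pos = d$len - (x - 2) - 4,
                                            pat = "AGCT")
    # HinfI sites relative to the left (FAM) end: duplex-mean fragment of
    # x bp puts the site start at x - 2.5 (r/2 = 2.5); GACTC instantiates
    # the GANTC pattern.
    hinfSites <- c(d$hinf, d$hinfPseudo)
    for (x in hinfSites[!is.na(hinfSites)])
      plants[[length(plants) + 1L]] <- list(pos = x - 2.5, pat = "GACTC")
    plantedGC <- sum(vapply(plants, function(p)
      sum(strsplit(p$pat, "")[[1]] %in% c("G", "C")), numeric(1)))
    plantedLen <- sum(vapply(plants, function(p) nchar(p$pat), numeric(1)))
    # G-free background: GC content comes from C alone, so no AGCT/GANTC
    # can occur outside the planted windows.
    gcTarget <- stats::runif(1, 0.40, 0.414)
    nC <- round(d$len * gcTarget) - plantedGC
    bg <- sample(c(rep("C", nC),
                   sample(c("A", "T"), d$len - plantedLen - nC,
                          replace = TRUE)))
    seqChars <- character(d$len)
    occupied <- logical(d$len)
    for (p in plants) {
      idx <- (p$pos + 1):(p$pos + nchar(p$pat))
      if (any(occupied[idx])) stop("internal: planted sites overlap")
      seqChars[idx] <- strsplit(p$pat, "")[[1]]
      occupied[idx] <- TRUE
    }
    seqChars[!occupied] <- bg
    out[[id]] <- genotypeRecord(id, paste(seqChars, collapse = ""),
                                c(FAM = "left", HEX = "right"))
  }
  out
}
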
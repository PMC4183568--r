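test_that("drift calibration recovers the reference deviations", {
  drift <- calibrateDrift()
  ref <- referenceTRFTable()
  ref <- ref[ref$role == "complete", ]
  fitted <- drift$intercept + drift$slope * ref$predicted_bp
  # every reference deviation lies within the documented drift range and
  # the fitted line stays inside it too
  expect_true(all(ref$deviation_bp >= -13.4 - 1e-9 &
                    ref$deviation_bp <= 1.1 + 1e-9))
  expect_true(all(fitted > -14 & fitted < 2))
  expect_gt(drift$sigma, 0)
  # negative mean drift: sizes are underestimated on average
  expect_lt(mean(fitted), 0)
})

test_that("synthetic reference genotypes reproduce the design constraints", {
  recs <- syntheticReferenceGenotypes(1)
  expect_length(recs, 6L)
  chars <- characterizeSequences(recs)
  expect_true(all(chars$length >= 527 & chars$length <= 548))
  expect_true(all(chars$gc_percent >= 39.7 & chars$gc_percent <= 41.7))
  # deterministic given seed
  again <- syntheticReferenceGenotypes(1)
  expect_equal(vapply(recs, genotypeSequence, character(1)),
               vapply(again, genotypeSequence, character(1)))
  # pairwise global-alignment identity below the OTU cut-off
  seqs <- vapply(recs, genotypeSequence, character(1))
  for (i in 1:5) for (j in (i + 1):6) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seqs[i]),
                                         Biostrings::DNAString(seqs[j]),
                                         type = "global")
    expect_lt(Biostrings::pid(aln), 97)
  }
})

test_that("random genotype generation honours every constraint", {
  enz <- defaultEnzymes()
  recs <- generateGenotypeSequences(4, seed = 5)
  chars <- characterizeSequences(recs)
  expect_true(all(chars$length >= 527 & chars$length <= 548))
  expect_true(all(chars$gc_percent >= 39.6 & chars$gc_percent <= 41.8))
  tt <- predictTRFTable(recs)
  for (e in c("AluI", "HinfI")) {
    trfs <- tt$complete_trf_bp[tt$enzyme == e]
    expect_true(all(trfs > 100))
    expect_true(min(dist(trfs)) >= 4)
  }
  # determinism
  recs2 <- generateGenotypeSequences(4, seed = 5)
  expect_equal(vapply(recs, genotypeSequence, character(1)),
               vapply(recs2, genotypeSequence, character(1)))
  # GC forcing
  gcForced <- generateGenotypeSequences(2, gcRange = c(0.5, 0.5), seed = 2)
  expect_equal(characterizeSequences(gcForced)$gc_percent, c(50, 50))
  expect_error(generateGenotypeSequences(1), "2..12")
})

test_that("simulated peaks implement each bias term in isolation", {
  recs <- syntheticReferenceGenotypes(1)
  tt <- predictTRFTable(recs)
  tpl <- equalProportions(names(recs)[1:4])
  pred <- buildPredictedProfile(tpl, tt, "AluI")
  # all-zero bias: peaks sit exactly at predicted sizes, areas by proportion
  p0 <- simulateObservedPeakTable(tpl, tt, "AluI", zeroBiasConfig(),
                                  seed = 3)
  expect_equal(sort(p0$size_bp),
               sort(as.numeric(names(profileAbundance(pred)))))
  expect_equal(sum(p0$area), 5e4)
  # pure intercept drift shifts every size by exactly -5
  shift <- zeroBiasConfig()
  shift@driftIntercept <- -5
  p5 <- simulateObservedPeakTable(tpl, tt, "AluI", shift, seed = 3)
  expect_equal(sort(p5$size_bp), sort(p0$size_bp) - 5)
  # pseudo diversion bookkeeping at known rate
  pr <- zeroBiasConfig()
  pr@pseudoRate <- 0.1
  pair <- nearEqualPair(names(recs)[c(1, 3)], 0)  # genotype 1 has pseudo set
  pp <- simulateObservedPeakTable(pair, tt, "AluI", pr, seed = 3,
                                  maxRichness = 2)
  g1area <- 5e4 * 0.5
  pseudoPeaks <- pp[pp$size_bp %in% c(310, 527), ]
  expect_equal(sum(pseudoPeaks$area), 0.1 * g1area)
  expect_equal(sum(pp$area), 5e4)
})

test_that("richness scales the effective under-digestion rate", {
  recs <- syntheticReferenceGenotypes(1)
  tt <- predictTRFTable(recs)
  pr <- zeroBiasConfig()
  pr@pseudoRate <- 0.05
  area610 <- function(tpl) {
    p <- simulateObservedPeakTable(tpl, tt, "AluI", pr, seed = 9)
    sum(p$area[p$size_bp %in% c(310, 527)]) /
      (5e4 * unname(composition(tpl)[1]))
  }
  # same genotype-1 proportion, increasing richness -> more diversion
  eq2 <- nearEqualPair(names(recs)[1:2], 0)
  eq6 <- equalProportions(names(recs))
  expect_equal(area610(eq2), 0.05 * 1 / 5)
  expect_equal(area610(eq6), 0.05)
})

test_that("area noise preserves expected totals and splitting conserves
           area", {
  recs <- syntheticReferenceGenotypes(1)
  tt <- predictTRFTable(recs)
  tpl <- equalProportions(names(recs)[1:4])
  splitOnly <- zeroBiasConfig()
  splitOnly@splitProb <- 1
  splitOnly@splitSpread <- 4
  ps <- simulateObservedPeakTable(tpl, tt, "AluI", splitOnly, seed = 2)
  expect_equal(sum(ps$area), 5e4)
  expect_gt(nrow(ps), 4)          # every TRF split into 2-3 peaks
  expect_true(all(table(round(ps$size_bp / 10)) <= 3))
  # lognormal noise has mean 1: across many seeds the total stays near 5e4
  noisy <- zeroBiasConfig()
  noisy@areaNoiseCv <- 0.2
  totals <- vapply(1:50, function(s)
    sum(simulateObservedPeakTable(tpl, tt, "AluI", noisy, seed = s)$area),
    numeric(1))
  expect_equal(mean(totals), 5e4, tolerance = 0.05)
})

test_that("the study dataset has the full 9 x 3 x 3 design", {
  recs <- syntheticReferenceGenotypes(1)
  tt <- predictTRFTable(recs)
  tpls <- studyTemplates(names(recs))
  ds <- generateStudyDataset(tpls, tt, enzymes = "AluI",
                             bias = zeroBiasConfig(), pipettingCv = 0,
                             seed = 4)
  expect_equal(nrow(ds$manifest), 81L)
  expect_equal(length(unique(ds$peaks$AluI$sample_id)), 81L)
  expect_length(ds$predicted$AluI, 81L)
  # zero pipetting error and zero bias: replicate mixes are identical
  p1 <- ds$peaks$AluI[ds$peaks$AluI$sample_id == "equal4_r1_t1",
                      c("size_bp", "area")]
  p2 <- ds$peaks$AluI[ds$peaks$AluI$sample_id == "equal4_r2_t1",
                      c("size_bp", "area")]
  expect_equal(p1$size_bp, p2$size_bp)
  expect_equal(p1$area, p2$area)
  # fixed seed: byte-identical rerun
  ds2 <- generateStudyDataset(tpls, tt, enzymes = "AluI",
                              bias = zeroBiasConfig(), pipettingCv = 0,
                              seed = 4)
  expect_identical(ds$peaks, ds2$peaks)
})

test_that("technical-replicate averaging preserves normalization", {
  recs <- syntheticReferenceGenotypes(1)
  out <- runSmallStudy(biasConfig(), seed = 31, records = recs)
  expect_length(out$observed, 27L)
  sums <- vapply(out$observed, function(p) sum(profileAbundance(p)),
                 numeric(1))
  expect_equal(unname(sums), rep(1, 27))
  expect_true(all(vapply(out$predicted, function(p) p@kind, character(1))
                  == "predicted"))
})
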
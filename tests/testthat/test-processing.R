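peakRow <- function(size, height = 500, area = 100, dye = "HEX",
                    sample = "s1") {
  data.frame(sample_id = sample, dye = dye, size_bp = size,
             height = height, area = area)
}

test_that("peak filter applies strict height, size and channel rules", {
  peaks <- rbind(peakRow(150, height = 99), peakRow(150, height = 101),
                 peakRow(150, height = 100), peakRow(100.0, height = 500),
                 peakRow(150, dye = "FAM"))
  kept <- filterPeaks(peaks, "AluI")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$height, 101)
  expect_error(filterPeaks(peakRow(150, dye = "NED"), "AluI"),
               "unknown dye")
})

test_that("binning sums areas on the half-open 2-bp grid anchored at 100", {
  b <- binPeaks(rbind(peakRow(157.7, area = 10), peakRow(157.9, area = 5)))
  expect_equal(b, c("156" = 15))
  expect_equal(names(binPeaks(peakRow(102.0))), "102")
  expect_equal(length(binPeaks(peakRow(150)[0, ])), 0L)
  # area conservation
  set.seed(1)
  peaks <- peakRow(runif(50, 101, 500), area = runif(50, 1, 10))
  expect_equal(sum(binPeaks(peaks)), sum(peaks$area))
})

test_that("noise filter drops bins at or below 5% mean-when-present and
           re-normalizes", {
  profiles <- list(
    s1 = c("150" = 0.96, "200" = 0.04),
    s2 = c("150" = 0.96, "200" = 0.04))
  out <- noiseFilter(profiles)
  expect_equal(out$s1, c("150" = 1))
  # exactly 5% is excluded ("5% or less")
  boundary <- list(s1 = c("150" = 0.95, "200" = 0.05))
  expect_equal(names(noiseFilter(boundary)$s1), "150")
  # 6% mean is retained
  kept <- list(s1 = c("150" = 0.94, "200" = 0.06))
  expect_equal(sort(names(noiseFilter(kept)$s1)), c("150", "200"))
  expect_equal(sum(noiseFilter(kept)$s1), 1)
  # mean over profiles where present only
  sparse <- list(s1 = c("150" = 0.9, "200" = 0.1),
                 s2 = c("150" = 1))
  expect_true("200" %in% names(noiseFilter(sparse)$s1))
})

test_that("noise filter is idempotent and flags emptied profiles", {
  set.seed(5)
  profiles <- lapply(1:6, function(i) {
    v <- runif(8)
    names(v) <- seq(102, 116, 2)
    v / sum(v)
  })
  names(profiles) <- paste0("s", 1:6)
  once <- noiseFilter(profiles)
  twice <- noiseFilter(once)
  attr(once, "emptied") <- NULL
  attr(twice, "emptied") <- NULL
  expect_equal(once, twice)
  # a profile spread thinly over many bins loses every bin
  thin <- setNames(rep(1 / 25, 25), seq(102, 150, 2))
  expect_warning(out <- noiseFilter(list(s1 = thin)), "emptied")
  expect_equal(attr(out, "emptied"), "s1")
})

test_that("pooling sums split peaks and conserves area", {
  prof <- c("302" = 10, "304" = 5, "416" = 20, "500" = 2)
  pmap <- c("302" = "309", "304" = "309")
  pooled <- poolSplitPeaks(prof, pmap)
  expect_equal(pooled, c("309" = 15, "416" = 20, "500" = 2))
  expect_equal(sum(pooled), sum(prof))
  expect_equal(poolSplitPeaks(prof, character(0)), prof[order(as.numeric(names(prof)))])
  expect_error(poolSplitPeaks(prof, c("302" = "309", "302" = "310")),
               "more than once")
})

test_that("observed bins match predictions inside the drift window", {
  tt <- data.frame(genotype_id = paste0("g", 1:6), enzyme = "AluI",
                   dye = "HEX",
                   complete_trf_bp = c(162, 309, 416, 449, 469, 504))
  tt$pseudo_trfs_bp <- c(list(c(310, 527)), rep(list(numeric(0)), 5))
  m <- matchTRFs(c(157.7, 200, 312), tt, "AluI")
  expect_equal(m$status, c("matched", "unmatched", "pseudo"))
  expect_equal(m$predicted_bp[1], 162)
  # 312 is outside the window of every complete TRF but within the pseudo
  # window of genotype 1's 310 bp fragment
  expect_equal(m$predicted_bp[3], 310)
  # 310.5 sits within the window of both complete 309 and pseudo 310;
  # complete matches take precedence
  m2 <- matchTRFs(310.5, tt, "AluI")
  expect_equal(m2$status, "matched")
  expect_equal(m2$predicted_bp, 309)
  # nearest-by-absolute-deviation, tie to lower predicted size
  tie <- data.frame(genotype_id = c("a", "b"), enzyme = "AluI",
                    dye = "HEX", complete_trf_bp = c(300, 304))
  tie$pseudo_trfs_bp <- rep(list(numeric(0)), 2)
  expect_equal(matchTRFs(302, tie, "AluI")$predicted_bp, 300)
  expect_error(matchTRFs(150, tt, "AluI", driftWindow = c(2, -14)), "lower")
})

test_that("match precedence prefers complete TRFs over pseudo-TRFs", {
  tt <- data.frame(genotype_id = "g1", enzyme = "AluI", dye = "HEX",
                   complete_trf_bp = 162)
  tt$pseudo_trfs_bp <- list(310)
  m <- matchTRFs(309, tt, "AluI")
  expect_equal(m$status, "pseudo")
  expect_equal(m$genotype_id, "g1")
})

test_that("processing an ideal peak table reproduces the predicted profile", {
  recs <- syntheticReferenceGenotypes(1)
  tt <- predictTRFTable(recs)
  tpl <- equalProportions(names(recs)[1:4])
  pred <- buildPredictedProfile(tpl, tt, "AluI", sampleId = "s1")
  peaks <- simulateObservedPeakTable(tpl, tt, "AluI", zeroBiasConfig(),
                                     sampleId = "s1", seed = 1)
  prof <- processPeakTable(peaks, "AluI", trfTable = tt)[["s1"]]
  expect_equal(profileAbundance(prof), profileAbundance(pred))
  expect_equal(attr(prof, "total_area"), 5e4)
})

test_that("profile matrices stack samples over the union of bins", {
  p1 <- trfProfile("s1", "AluI", "HEX", c("150" = 0.5, "200" = 0.5))
  p2 <- trfProfile("s2", "AluI", "HEX", c("150" = 1))
  m <- profilesToMatrix(list(p1, p2))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["s2", "200"], 0)
  expect_equal(rowSums(m), c(s1 = 1, s2 = 1))
})

test_that("peak tables round-trip through CSV", {
  peaks <- rbind(peakRow(150.5), peakRow(203.2, dye = "FAM"))
  path <- withr::local_tempfile(fileext = ".csv")
  writePeakTable(peaks, path)
  expect_equal(readPeakTable(path), peaks)
  expect_error(readPeakTable(withr::local_tempfile(lines = "a,b\n1,2")),
               "lacks column")
})
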
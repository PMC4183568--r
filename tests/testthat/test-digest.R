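test_that("recognition-site search matches hand-derived cases", {
  enz <- defaultEnzymes()
  expect_equal(findRecognitionSites("CCCCAGCTCCCC", enz$AluI), 4L)
  expect_equal(findRecognitionSites("AAAAAAAA", enz$AluI), integer(0))
  expect_equal(findRecognitionSites("AAGATTCAA", enz$HinfI), 2L)
  # pattern longer than sequence
  expect_equal(findRecognitionSites("AGC", enz$AluI), integer(0))
  expect_error(findRecognitionSites("ACGNACGT", enz$AluI), "ambiguity")
})

test_that("enzyme registration rejects non-palindromic patterns", {
  expect_s4_class(restrictionEnzyme("AluI", "AGCT", 2), "RestrictionEnzyme")
  expect_error(restrictionEnzyme("FakeI", "GACGC", 1), "palindromic")
  expect_error(restrictionEnzyme("BadOffset", "AGCT", 5), "cutOffset")
})

test_that("site search equals brute-force IUPAC scan on random sequences", {
  enz <- defaultEnzymes()
  set.seed(42)
  for (i in 1:300) {
    s <- randomSequence(sample(10:80, 1))
    for (e in enz) {
      expect_identical(findRecognitionSites(s, e),
                       as.integer(bruteForceSites(s, recognitionSite(e))))
    }
  }
})

test_that("terminal fragment lengths follow the cut arithmetic", {
  enz <- defaultEnzymes()
  rec <- genotypeRecord("g", "CCCCAGCTCCCC", c(HEX = "left"))
  expect_equal(terminalFragmentLength(rec, enz$AluI, "HEX"), 6)
  # no site: full length
  siteFree <- genotypeRecord("g2", strrep("AT", 20), c(FAM = "left"))
  expect_equal(terminalFragmentLength(siteFree, enz$HinfI, "FAM"), 40)
  # right-end dye measures from the other side
  rec2 <- genotypeRecord("g3", "CCCCAGCTCC", c(FAM = "left", HEX = "right"))
  expect_equal(terminalFragmentLength(rec2, enz$AluI, "FAM"), 6)
  expect_equal(terminalFragmentLength(rec2, enz$AluI, "HEX"), 10 - 6)
  expect_error(terminalFragmentLength(rec, enz$AluI, "TAMRA"), "unknown dye")
})

test_that("duplex-mean convention adds half the overhang ambiguity", {
  enz <- defaultEnzymes()
  rec <- genotypeRecord("g", "CCGACTCCCC", c(FAM = "left"))
  # HinfI: site at 2, labelled-strand cut at 3, duplex mean at 2 + 5/2
  expect_equal(terminalFragmentLength(rec, enz$HinfI, "FAM"), 3)
  expect_equal(
    terminalFragmentLength(rec, enz$HinfI, "FAM", "duplex_mean"), 4.5)
  # blunt AluI: both conventions coincide
  recA <- genotypeRecord("g", "CCCCAGCTCC", c(FAM = "left"))
  expect_equal(
    terminalFragmentLength(recA, enz$AluI, "FAM", "duplex_mean"),
    terminalFragmentLength(recA, enz$AluI, "FAM"))
})

test_that("terminal fragment length is invariant under distal extension and
           strand reversal", {
  enz <- defaultEnzymes()
  set.seed(7)
  for (i in 1:50) {
    s <- randomSequence(60)
    rec <- genotypeRecord("g", s, c(FAM = "left"))
    trf <- terminalFragmentLength(rec, enz$AluI, "FAM")
    ext <- genotypeRecord("g", paste0(s, randomSequence(20)),
                          c(FAM = "left"))
    if (length(findRecognitionSites(s, enz$AluI))) {
      expect_equal(terminalFragmentLength(ext, enz$AluI, "FAM"), trf)
    } else {
      expect_equal(terminalFragmentLength(rec, enz$AluI, "FAM"), nchar(s))
    }
    # palindromic pattern: digesting the reverse complement with the dye on
    # the opposite end gives identical lengths
    rcrec <- genotypeRecord("g", TRFLPbias:::.reverseComplement(s),
                            c(FAM = "right"))
    expect_equal(terminalFragmentLength(rcrec, enz$AluI, "FAM"), trf)
  }
})

test_that("pseudo-TRF enumeration matches hand-built cases", {
  enz <- defaultEnzymes()
  # cut coordinates 6 and 10 in a 20-bp sequence -> pseudo {10, 20}
  rec <- genotypeRecord("g", "CCCCAGCTAGCTCCCCCCCC", c(HEX = "left"))
  expect_equal(enumeratePseudoTRFs(rec, enz$AluI, "HEX"), c(10, 20))
  one <- genotypeRecord("g", "CCCCAGCTCCCCCCCCCCCC", c(HEX = "left"))
  expect_equal(enumeratePseudoTRFs(one, enz$AluI, "HEX"), 20)
  none <- genotypeRecord("g", strrep("C", 20), c(HEX = "left"))
  expect_equal(enumeratePseudoTRFs(none, enz$AluI, "HEX"), numeric(0))
})

test_that("pseudo-TRF enumeration equals exhaustive subset enumeration", {
  enz <- defaultEnzymes()$AluI
  set.seed(11)
  for (i in 1:100) {
    s <- randomSequence(sample(30:120, 1), gc = 0.5)
    rec <- genotypeRecord("g", s, c(FAM = "left"))
    sites <- findRecognitionSites(s, enz)
    if (length(sites) > 10) next
    cuts <- sites + cutOffset(enz)
    expect_equal(enumeratePseudoTRFs(rec, enz, "FAM"),
                 bruteForcePseudo(cuts, nchar(s)))
  }
})

test_that("prediction table covers every genotype x enzyme and flags TRF
           collisions", {
  recs <- list(genotypeRecord("a", "CCCCAGCTCCGACTCCCC"),
               genotypeRecord("b", "TTTTAGCTTTGACTCTTT"))
  # both have AluI TRF (right end, RC): identical by construction
  expect_warning(tab <- predictTRFTable(recs), "uniqueness")
  expect_equal(nrow(tab), 4L)
  expect_true(nrow(attr(tab, "collisions")) > 0)
  single <- predictTRFTable(list(genotypeRecord("a", "CCCCAGCTCCGACTCCCC")))
  expect_equal(nrow(single), 2L)
})

test_that("TRF tables round-trip through TSV", {
  recs <- syntheticReferenceGenotypes(3)
  tab <- predictTRFTable(recs)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTRFTable(tab, path)
  back <- readTRFTable(path)
  expect_equal(back$complete_trf_bp, tab$complete_trf_bp)
  expect_equal(back$pseudo_trfs_bp, tab$pseudo_trfs_bp)
})

test_that("sequence characterization reports length and GC", {
  chars <- characterizeSequences(list(genotypeRecord("a", "ATGC")))
  expect_equal(chars$length, 4)
  expect_equal(chars$gc_percent, 50.0)
  two <- characterizeSequences(list(genotypeRecord("g", "GGGG"),
                                    genotypeRecord("a", "AAAA")))
  s <- attr(two, "summary")
  expect_equal(s$gc_max, 100)
  expect_equal(s$gc_min, 0)
  expect_error(characterizeSequences(list()), "at least one")
})

test_that("FASTA IO round-trips and dye ends are auto-detectable", {
  recs <- syntheticReferenceGenotypes(2)
  path <- withr::local_tempfile(fileext = ".fasta")
  writeGenotypeFasta(recs, path)
  back <- readGenotypeFasta(path)
  expect_equal(vapply(back, genotypeSequence, character(1)),
               vapply(recs, genotypeSequence, character(1)))
  # amplicon flanked by the two primers in forward orientation
  s <- paste0(TRFLPbias:::NS31_PRIMER, randomSequence(100),
              TRFLPbias:::.reverseComplement(TRFLPbias:::AM1_PRIMER))
  expect_equal(detectDyeEnds(s), c(FAM = "left", HEX = "right"))
  expect_equal(detectDyeEnds(TRFLPbias:::.reverseComplement(s)),
               c(FAM = "right", HEX = "left"))
})
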
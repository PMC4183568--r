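# TRFLPbias

Terminal restriction fragment length polymorphism (TRFLP) fingerprints a
microbial community by PCR-amplifying a marker gene with fluorescently
end-labelled primers, digesting the amplicons with restriction enzymes, and
sizing the labelled terminal fragments (TRFs) on a capillary sequencer. For
arbuscular mycorrhizal (AM) fungi — profiled via the ~550 bp NS31/AM1 SSU
rDNA amplicon, HEX on the AM1 end read against AluI digests and FAM on the
NS31 end against HinfI digests — the open question is whether such
fingerprints can be read *quantitatively*: do peak areas recover relative
genotype abundances, community distances and diversity, or do PCR bias,
under-digestion and electrophoretic size drift destroy that signal?

`TRFLPbias` is an in-silico test bench for that question, aimed at
microbial ecologists who use (or simulate) fingerprinting protocols. It:

- predicts complete-digest TRFs and partial-digest **pseudo-TRFs** from
  amplicon sequences by IUPAC-aware in silico digestion
  (`predictTRFTable()`); for a labelled end with ordered cut coordinates
  `c1 < c2 < … < ck` in a sequence of length `L`, the complete TRF is `c1`
  and the pseudo-TRF set is `{c2, …, ck, L}`;
- builds artificial community templates of known composition
  (`studyTemplates()`): equal-abundance, MacArthur broken-stick
  (`p_i = (1/n) Σ_{k=i..n} 1/k`), and near-equal two-genotype designs;
- simulates observed peak tables with empirically calibrated measurement
  biases (`simulateObservedPeakTable()`): linear TRF drift fitted to
  published single-genotype digests, 2–3-way peak splitting, richness-scaled
  area diversion to pseudo-TRFs, lognormal area noise and a detection floor;
- processes peak tables with the standard rules (`processPeakTable()`):
  height > 100 FU, size > 100 bp, one dye channel per enzyme, 2-bp binning,
  exclusion of TRFs averaging ≤ 5% where present, pooling of split peaks
  onto predicted TRFs within a (−14, +2) bp drift window;
- quantifies predicted-versus-observed agreement
  (`comparePredictedObserved()`): covariance PCA, Euclidean PC-score and
  Bray–Curtis (`1 − 2Σmin(a,b)/(Σa+Σb)`) distances compared by Mantel
  permutation tests, plus per-sample Margalef (`(S−1)/ln N`) and
  Gini–Simpson (`1 − Σp²`) indices with observed-on-predicted regressions.

## Worked example

```r
library(TRFLPbias)

records  <- syntheticReferenceGenotypes(1)       # six engineered amplicons
trfTable <- predictTRFTable(records)             # TRFs + pseudo-TRFs
tpls     <- studyTemplates(names(records))       # the nine-template design

ds  <- generateStudyDataset(tpls, trfTable, enzymes = "AluI",
                            bias = biasConfig(), seed = 7)
obs <- processPeakTable(ds$peaks$AluI, "AluI", trfTable = trfTable)
cmp <- comparePredictedObserved(averageTechReps(ds$predicted$AluI, ds$manifest),
                                averageTechReps(obs, ds$manifest),
                                nPerm = 999, seed = 3)
cmp
#> TRFLPComparison over 27 samples
#>   Mantel (Euclidean PC 2 distances): r = 0.978, p = 0.001 (999 permutations)
#>   Mantel (Bray-Curtis): r = 0.982, p = 0.001 (999 permutations)
#>   PCA variance on PC1+PC2: predicted 92% / observed 89%
#>   Margalef regression: slope = 1.093, R^2 = 0.822, F(1,25) = 115.7, p = 7.24e-11
#>   Simpson regression:  slope = 0.881, R^2 = 0.920, F(1,25) = 287.1, p = 3.24e-15
```

Read: even with drift, splitting, under-digestion and area noise at their
calibrated levels, community distances correlate at r ≈ 0.98 between theory
and simulated observation (the protocol is quantitative for composition),
while Margalef slopes above 1 show how pseudo-TRFs inflate observed
richness. Setting `bias = zeroBiasConfig()` turns the whole pipeline into
an exact identity (r = 1, R² = 1), which is the package's key correctness
check.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole workflow from scratch against the installed package —
TRF prediction for the six reference genotypes, the 9 × 3 × 3 study
simulation under calibrated biases for both enzyme channels, peak
processing, and the Mantel/PCA/diversity comparison — printing the per-
channel reports and writing the JSON report to `--out`.
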
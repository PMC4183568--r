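---
title: "Testing TRFLP fingerprints for quantitative bias: models and design choices"
author: "TRFLPbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing TRFLP fingerprints for quantitative bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TRFLPbias)
```

## The question and the approach

TRFLP community fingerprinting digests fluorescently end-labelled PCR
amplicons and sizes the labelled terminal fragments. If the protocol is
unbiased, the relative peak *areas* of a sample are the relative abundances
of the genotypes behind them, and community-level statistics computed from
fingerprints (ordination distances, diversity indices) should recover the
true values. `TRFLPbias` implements the experiment that tests this for AM
fungal SSU rDNA amplicons entirely in silico: communities of *known*
composition are paired with (a) the theoretical fingerprint derived from
sequence alone and (b) a simulated "observed" fingerprint carrying the
measurement biases documented for the wet protocol. Agreement between the
two, measured exactly as a practitioner would measure it, quantifies how
much signal the biases destroy.

## The digest engine

An enzyme is a recognition pattern (IUPAC) plus a cut offset; both protocol
enzymes (AluI `AG^CT`, HinfI `G^ANTC`) are reverse-complement palindromes,
so scanning the stored strand finds every duplex site. This is *asserted*
at enzyme registration rather than assumed — a non-palindromic enzyme would
silently miss sites under single-strand scanning, so registration refuses
it. Site search runs through `Biostrings::matchPattern(fixed = FALSE)` and
is cross-checked in the tests against a position-by-position brute-force
IUPAC scan. Sequences containing ambiguity codes are readable but not
digestible: an `N` inside a potential site makes cut certainty undecidable,
and we prefer a hard error to a guess.

Coordinates are 0-based half-open internally; reported lengths are
distances from the labelled end. Two length conventions are offered:

* `labelled_strand` (default): distance to the cut on the labelled strand,
  `site + cutOffset` — always an integer.
* `duplex_mean`: the mean of the two strands' cut coordinates, which for a
  palindromic site of length `r` is `site + r/2`. For HinfI (`r = 5`, 3-nt
  5' overhang) this yields half-integer lengths, exactly the `.5` endings
  of the published HinfI predictions; for blunt-cutting AluI the two
  conventions coincide. We read the half-integers as evidence for an
  overhang-averaging convention in the original in silico digests, but we
  keep `labelled_strand` as the default because it is the physically
  unambiguous single-strand length; comparisons downstream tolerate ±2 bp
  regardless.

Pseudo-TRFs — fragments from incomplete digestion — are enumerated from the
ordered cut coordinates `c1 < … < ck`: omitting any subset of sites leaves
the labelled fragment ending at the nearest *retained* cut, so the
achievable set is `{c2, …, ck, L}` minus the complete length `c1`. The
tests verify this closed form against exhaustive enumeration over all `2^k`
subsets.

## Community templates

The nine-template design spans richness 4–6 in equal-abundance and
broken-stick shapes, plus three two-genotype mixtures at proportions
`0.5 ± δ`. The exact proportions of the original design are figure-only, so
the defaults are the MacArthur broken-stick *expectation*
(`p_i = (1/n) Σ_{k=i..n} 1/k`; stochastic stick-breaking is deliberately
not offered) and `δ ∈ {0, 0.025, 0.05}`, chosen to bracket the resolution
question (identical mixtures through a 10% relative difference). Users who
digitize the original figure can supply their own templates; everything
downstream is agnostic.

## The bias model (what the simulator emulates)

`biasConfig()` encodes five phenomena, each traceable to the published
single-genotype digests; defaults are calibrated once and are not tuned:

* **TRF drift.** Fluorophores change electrophoretic mobility, so observed
  sizes are *underestimated*, by ~1–14 bp and more for larger fragments.
  Modelled as `observed = predicted + a + b·predicted + N(0, σ)` with
  `a`, `b`, `σ` fitted at run time by least squares to the published
  predicted/observed pairs (`calibrateDrift()`; a ≈ −4.0 bp,
  b ≈ −0.0043, σ ≈ 3.5 bp).
* **Peak splitting.** Five of six genotypes produced 2–3 nearby peaks per
  TRF under AluI, spanning 2–8 bp. Default `splitProb = 0.8` (5/6) and
  `splitSpread = 4` bp; split areas get random weights.
* **Under-digestion.** A fraction `pseudoRate` of a genotype's area is
  diverted equally over its pseudo-TRF lengths. Single-genotype digests
  were >99% pure while mixed templates showed pseudo-TRFs throughout, so
  the rate scales with template richness,
  `pseudoRate · (richness − 1)/(maxRichness − 1)`, and the default base
  rate is 0.02 — the middle of the 1–5% band consistent with those purity
  figures. This is phenomenology, not chemistry: chimera formation,
  single-stranded DNA and heteroduplexes (the candidate mechanisms) are
  out of scope.
* **Area noise.** Mean-one lognormal with CV 0.10 per peak — the scale of
  replicate pipetting plus detector variation consistent with the very
  small technical-replicate scatter reported.
* **Detection floor.** Peaks below 100 FU in height vanish; height is
  `area / peakWidth` with `peakWidth = 5`, and the default per-sample total
  area of 5 × 10⁴ FU puts a 2% genotype at height 200 — visible, but close
  enough to the floor that noise can delete it, as in real traces.

Replicate mixes additionally perturb template proportions with a CV-0.02
lognormal pipetting error. One root seed drives everything; per-sample
streams are derived by stable hashing of (template, replicate, technical
replicate, enzyme), so any subset of the design is reproducible in
isolation.

What a green test does **not** establish: the generator never emulates PCR
(primer mismatch, template GC effects, cycle kinetics), raw
electropherogram baselines, or size-standard calibration error. Agreement
under this simulator therefore says "the *processing and analysis* chain
recovers what the bias model leaves intact", not that any particular wet
protocol is bias-free.

## Peak processing

The pipeline order is: dye-channel/height/size filter → 2-bp binning →
relative abundance → cross-sample noise exclusion → pooling of split peaks
→ re-normalization. The thresholds follow the protocol wording exactly:
strictly greater than 100 FU and 100 bp; "5% or less" is inclusive; the
noise mean is taken over profiles *where the TRF is present*, on relative
area. The bin grid is fixed and anchored at 100.0 bp with half-open bins —
the original software's binning is anchor-unspecified, and a fixed grid is
the deterministic choice. The order itself is a design decision (the
original text does not state one); each rule is applied to the quantity it
names, and the identity test below is the guard that the composition of all
six stages is lossless when biases are off.

Observed bins are matched to predicted TRFs inside a (−14, +2) bp drift
window — the published deviation range (−13.4 to +1.1 bp) plus ~1 bp margin
— nearest absolute deviation first, ties to the smaller predicted size.
Bins explainable only as pseudo-TRFs stay *unpooled*: that is precisely how
under-digestion inflates observed richness, and folding them into their
parent genotype would hide the effect the framework exists to measure.

## Agreement statistics

PCA is covariance PCA (mean-centred, unscaled) with a deterministic sign
convention (largest-magnitude loading positive). Euclidean distances
default to the first two PC axes — the axes the original analysis plotted
and tested — and are configurable up to the full isometric embedding (the
tests pin `dist(scores) == dist(centered rows)` to machine precision).
Bray–Curtis and the Mantel test are written out in the package (the Mantel
permutes the second matrix's labels jointly, with the add-one p-value
`(#{r* ≥ r} + 1)/(nPerm + 1)`); `vegan` serves as the independent oracle in
the tests rather than the implementation, because the zero-distance-pair
and seeding contracts here are stricter than `vegdist`'s.

Simpson's index defaults to the Gini–Simpson form `1 − Σp²` (the original
treats larger as more even; the inverse form is available). Margalef's
`(S − 1)/ln N` needs an integer `N`, which fluorescence data do not supply;
the convention here is total retained peak area rounded — defensible, but
it makes the index depend on overall fluorescence yield, so compare only
samples run at similar yield. Technical replicates are averaged to the
template-replicate level (27 samples) before distances are computed, the
level at which the original distance analysis operated.

## Numerical and degenerate-input choices

Profile abundances must sum to 1 within 1e-9; constant matrices yield
all-zero PCA gracefully; a pair of all-zero rows gets Bray–Curtis 0 with a
warning instead of NaN; a zero-variance distance triangle makes the Mantel
r an error, not an NA; the noise filter warns and flags samples it empties.
Half-open binning puts a peak at exactly 102.0 bp into bin 102. All
acceptance-style comparisons of TRF sizes tolerate ±2 bp (one bin).

## The synthetic reference genotypes

The six deposited amplicons behind the published table are not bundled
(offline builds cannot download them), so `syntheticReferenceGenotypes()`
engineers stand-ins that satisfy every *printed* property: the exact
complete-digest TRF sizes in both channels (including the uncut 547 bp
HinfI case), amplicon lengths spanning 527–548 bp, GC within 39.7–41.7%,
pairwise identity below the 97% OTU cut-off, and the documented genotype-1
pseudo-TRF at 310 bp. Their backgrounds contain no `G` outside the planted
recognition sites, which provably excludes accidental AluI/HinfI sites, so
the digestion arithmetic against the printed sizes is exact by
construction. They are labelled synthetic everywhere; conclusions about
the real accessions require the real sequences.

## Known limitations

* Pseudo-TRF formation is modelled as a single area-diversion rate; real
  under-digestion likely varies by site and genotype.
* Margalef's N convention (peak area) is a stated convention, not a fact
  about the data.
* The drift fit pools both enzymes (15 + 6 published pairs); per-enzyme
  fits are possible but under-determined for HinfI alone.
* ANOVA/Tukey comparisons of PC scores between templates are deliberately
  omitted as routine; the Mantel and regression analyses carry the
  quantitative claim.
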
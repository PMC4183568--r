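# Independent brute-force oracles used to cross-check the digest engine and
# the permutation statistics.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Position-by-position IUPAC scan; returns 0-based site starts.
bruteForceSites <- function(sequence, pattern) {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s); r <- length(p)
  if (r > n) return(integer(0))
  hits <- integer(0)
  for (start in 0:(n - r)) {
    ok <- TRUE
    for (k in seq_len(r)) {
      if (!s[start + k] %in% IUPAC_ORACLE[[p[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

# Exhaustive pseudo-TRF enumeration over all 2^k subsets of cut coordinates:
# the terminal fragment ends at the nearest retained cut, or the full length
# for the empty subset. Returns achievable lengths excluding the
# complete-digest one.
bruteForcePseudo <- function(cutCoords, fullLength) {
  k <- length(cutCoords)
  if (k == 0) return(numeric(0))
  lens <- c()
  for (mask in 0:(2^k - 1)) {
    retained <- cutCoords[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    lens <- c(lens, if (length(retained)) min(retained) else fullLength)
  }
  complete <- min(cutCoords)
  sort(unique(lens[lens > complete]))
}

randomSequence <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exhaustive Mantel p-value over all n! joint label permutations of d2.
exhaustiveMantelP <- function(d1, d2) {
  n <- nrow(d1)
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  r_obs <- cor(v1, d2[lower])
  perms <- .allPermutations(n)
  rs <- vapply(perms, function(p) cor(v1, d2[p, p][lower]), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

.allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in .allPermutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# Small complete pipeline run used by several suites: simulate the full
# study design for one enzyme and return template-replicate-level predicted
# and observed profiles.
runSmallStudy <- function(bias, seed, enzyme = "AluI", pipettingCv = 0.02,
                          records = syntheticReferenceGenotypes(1)) {
  tt <- predictTRFTable(records)
  tpls <- studyTemplates(names(records))
  ds <- generateStudyDataset(tpls, tt, enzymes = enzyme, bias = bias,
                             pipettingCv = pipettingCv, seed = seed)
  obs <- processPeakTable(ds$peaks[[enzyme]], enzyme, trfTable = tt)
  list(predicted = averageTechReps(ds$predicted[[enzyme]], ds$manifest),
       observed = averageTechReps(obs, ds$manifest),
       dataset = ds, trfTable = tt)
}
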
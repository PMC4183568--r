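# Internal helpers shared across modules.

# IUPAC nucleotide code -> set of unambiguous bases it matches.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' @keywords internal
#' @noRd
.isUnambiguous <- function(sequence) {
  grepl("^[ACGT]+$", sequence)
}

#' @keywords internal
#' @noRd
.assertUnambiguous <- function(sequence, what = "sequence") {
  if (!.isUnambiguous(sequence)) {
    bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "T"))
    stop(what, " contains IUPAC ambiguity codes (",
         paste(bad, collapse = ", "),
         "): digestion requires unambiguous bases", call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
#' @noRd
.reverseComplement <- function(sequence) {
  chars <- rev(strsplit(sequence, "")[[1]])
  paste(unname(IUPAC_COMPLEMENT[chars]), collapse = "")
}

# Stable 32-bit sub-seed from a root seed and a character key, so that every
# simulated sample draws from its own reproducible stream.
#' @keywords internal
#' @noRd
.subSeed <- function(seed, key) {
  codes <- utf8ToInt(paste(key, collapse = "|"))
  h <- as.numeric(seed %% 2147483647L)
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

#' @keywords internal
#' @noRd
.checkProportions <- function(p, tol = 1e-9) {
  if (any(p <= 0)) stop("proportions must be strictly positive", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop("proportions must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}
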
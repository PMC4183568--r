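#' Register a restriction enzyme
#'
#' Creates a [RestrictionEnzyme-class]. Registration asserts that the
#' recognition pattern equals its own reverse complement (under IUPAC
#' complementation): the digest engine scans only the stored strand, which
#' finds every duplex site exactly when the pattern is
#' reverse-complement-palindromic. Both enzymes of the protocol satisfy this
#' (AluI `AG^CT`, HinfI `G^ANTC`, standard REBASE definitions).
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition pattern.
#' @param cutOffset Cut position on the scanned strand, `0 <= cutOffset <=
#'   nchar(recognition)` (AluI: 2, blunt; HinfI: 1, 3-nt 5' overhang).
#' @return A `RestrictionEnzyme` object.
#' @examples
#' restrictionEnzyme("AluI", "AGCT", 2)
#' @export
restrictionEnzyme <- function(name, recognition, cutOffset) {
  recognition <- toupper(recognition)
  obj <- new("RestrictionEnzyme", name = as.character(name),
             recognition = recognition, cutOffset = as.integer(cutOffset))
  if (.reverseComplement(recognition) != recognition) {
    stop("recognition pattern '", recognition, "' of ", name,
         " is not reverse-complement palindromic; single-strand scanning ",
         "would miss sites on the other strand", call. = FALSE)
  }
  obj
}

#' Default enzyme registry for the fingerprinting protocol
#'
#' AluI (`AG^CT`, blunt cutter) and HinfI (`G^ANTC`, 3-nt 5' overhang), the
#' two enzymes of the TRFLP protocol under test.
#'
#' @return Named list of [RestrictionEnzyme-class] objects.
#' @examples
#' defaultEnzymes()
#' @export
defaultEnzymes <- function() {
  list(
    AluI  = restrictionEnzyme("AluI", "AGCT", 2L),
    HinfI = restrictionEnzyme("HinfI", "GANTC", 1L)
  )
}

#' Default dye-channel rule
#'
#' The analysed channel couples each enzyme to one dye: HEX-labelled TRFs
#' (AM1 primer end) for AluI digests and FAM-labelled TRFs (NS31 primer end)
#' for HinfI digests. TRFs in the other channel are short and identical
#' across genotypes, hence uninformative.
#'
#' @return Named character vector mapping enzyme name to dye name.
#' @examples
#' defaultChannelRule()
#' @export
defaultChannelRule <- function() {
  c(AluI = "HEX", HinfI = "FAM")
}

#' @rdname RestrictionEnzyme-class
#' @export
setMethod("enzymeName", "RestrictionEnzyme", function(x) x@name)

#' @rdname RestrictionEnzyme-class
#' @export
setMethod("recognitionSite", "RestrictionEnzyme", function(x) x@recognition)

#' @rdname RestrictionEnzyme-class
#' @export
setMethod("cutOffset", "RestrictionEnzyme", function(x) x@cutOffset)

setMethod("show", "RestrictionEnzyme", function(object) {
  r <- object@recognition
  c <- object@cutOffset
  cat("RestrictionEnzyme ", object@name, ": ",
      substr(r, 1, c), "^", substr(r, c + 1, nchar(r)), "\n", sep = "")
})
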
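#' Create a genotype record
#'
#' @param id Accession-like identifier.
#' @param sequence Nucleotide sequence (stored strand, 5'->3'). IUPAC
#'   ambiguity codes are accepted here but rejected later by digestion.
#' @param dyeEnds Named character vector mapping dye to `"left"` or
#'   `"right"`; default places FAM on the left (NS31) end and HEX on the
#'   right (AM1) end, the convention for amplicons stored NS31->AM1.
#' @return A [GenotypeRecord-class] object.
#' @examples
#' genotypeRecord("G1", "ACGTACGT")
#' @export
genotypeRecord <- function(id, sequence,
                           dyeEnds = c(FAM = "left", HEX = "right")) {
  new("GenotypeRecord", id = as.character(id),
      sequence = toupper(as.character(sequence)), dyeEnds = dyeEnds)
}

#' @rdname GenotypeRecord-class
#' @export
setMethod("genotypeId", "GenotypeRecord", function(x) x@id)

#' @rdname GenotypeRecord-class
#' @export
setMethod("genotypeSequence", "GenotypeRecord", function(x) x@sequence)

#' @rdname GenotypeRecord-class
#' @export
setMethod("dyeEnds", "GenotypeRecord", function(x) x@dyeEnds)

setMethod("show", "GenotypeRecord", function(object) {
  cat("GenotypeRecord", object@id, "—", nchar(object@sequence), "bp;",
      paste(names(object@dyeEnds), object@dyeEnds, sep = "@",
            collapse = ", "), "\n")
})

# Published primer sequences delimiting the partial SSU rDNA amplicon.
NS31_PRIMER <- "TTGGAGGGCAAGTCTGGTGCC"
AM1_PRIMER  <- "GTTTCCCGTAAGGCGCCGAA"

#' Detect which dye sits on which end of an amplicon
#'
#' The FAM dye is carried by the NS31 primer and HEX by the AM1 primer.
#' For a stored strand of unknown orientation, each primer is scored against
#' the left end (primer as-is) and the right end (reverse complement of the
#' primer) by fractional prefix/suffix identity; the orientation with the
#' better total score wins. Supply `dyeEnds` to [genotypeRecord()] directly
#' to override.
#'
#' @param sequence Nucleotide sequence of the stored strand.
#' @param famPrimer,hexPrimer Primer sequences carrying FAM and HEX
#'   (defaults: NS31 and AM1).
#' @return Named character vector, e.g. `c(FAM = "left", HEX = "right")`.
#' @examples
#' seq <- paste0("TTGGAGGGCAAGTCTGGTGCC", strrep("AT", 50),
#'               "TTCGGCGCCTTACGGGAAAC")
#' detectDyeEnds(seq)
#' @export
detectDyeEnds <- function(sequence, famPrimer = NS31_PRIMER,
                          hexPrimer = AM1_PRIMER) {
  sequence <- toupper(sequence)
  idFrac <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    mean(strsplit(substr(a, 1, n), "")[[1]] == strsplit(substr(b, 1, n), "")[[1]])
  }
  left <- function(p) idFrac(sequence, p)
  right <- function(p) {
    rc <- .reverseComplement(p)
    idFrac(substr(sequence, nchar(sequence) - nchar(rc) + 1, nchar(sequence)),
           rc)
  }
  forwardScore <- left(famPrimer) + right(hexPrimer)   # FAM left, HEX right
  reverseScore <- left(hexPrimer) + right(famPrimer)
  if (forwardScore >= reverseScore) c(FAM = "left", HEX = "right")
  else c(FAM = "right", HEX = "left")
}

#' Read genotype amplicons from a FASTA file
#'
#' Multi-record, wrapped-line FASTA via [Biostrings::readDNAStringSet()].
#' Ambiguity codes are tolerated at this stage.
#'
#' @param path FASTA file path.
#' @param dyeEnds Dye-to-end assignment applied to every record, or `NULL`
#'   to auto-detect per record with [detectDyeEnds()].
#' @return A list of [GenotypeRecord-class] objects, named by record id.
#' @export
readGenotypeFasta <- function(path, dyeEnds = c(FAM = "left", HEX = "right")) {
  stringset <- Biostrings::readDNAStringSet(path)
  if (length(stringset) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(stringset), "\\s+"), `[[`, character(1), 1L)
  seqs <- as.character(stringset)
  records <- lapply(seq_along(seqs), function(i) {
    de <- if (is.null(dyeEnds)) detectDyeEnds(seqs[[i]]) else dyeEnds
    genotypeRecord(ids[[i]], seqs[[i]], de)
  })
  names(records) <- ids
  records
}

#' Write genotype records to FASTA
#'
#' @param records List of [GenotypeRecord-class] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeGenotypeFasta <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(records, genotypeSequence, character(1)))
  names(seqs) <- vapply(records, genotypeId, character(1))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Characterize amplicon sequences
#'
#' Per-record length and GC content, plus exact min/max summaries. The study
#' design expects little length variation (~527-548 bp) and low GC
#' (~39.7-41.7%), typical of AM fungal SSU amplicons; large departures are a
#' hint that the wrong region was amplified.
#'
#' @param records List of [GenotypeRecord-class] objects (at least one).
#' @return A data frame with columns `id`, `length`, `gc_percent` (one
#'   decimal place), with a `summary` attribute holding exact min/max of
#'   length and GC percentage.
#' @examples
#' characterizeSequences(list(genotypeRecord("a", "ATGC")))
#' @export
characterizeSequences <- function(records) {
  if (length(records) == 0L) stop("at least one record required")
  ids <- vapply(records, genotypeId, character(1))
  lens <- vapply(records, function(r) nchar(genotypeSequence(r)), numeric(1))
  gc <- vapply(records, function(r) {
    s <- strsplit(genotypeSequence(r), "")[[1]]
    100 * sum(s %in% c("G", "C", "S")) / length(s)
  }, numeric(1))
  out <- data.frame(id = ids, length = lens, gc_percent = round(gc, 1),
                    row.names = NULL)
  attr(out, "summary") <- list(
    length_min = min(lens), length_max = max(lens),
    gc_min = min(gc), gc_max = max(gc))
  out
}
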
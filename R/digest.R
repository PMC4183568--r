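#' Find restriction recognition sites on the stored strand
#'
#' Scans the stored strand only; this finds every duplex site because
#' [restrictionEnzyme()] guarantees the pattern is reverse-complement
#' palindromic. Matching is IUPAC-aware in the pattern (e.g. the `N` of
#' HinfI's `GANTC`); ambiguity codes in the *sequence* are rejected because
#' cut certainty cannot be resolved.
#'
#' @param sequence Nucleotide string over `{A,C,G,T}`.
#' @param enzyme A [RestrictionEnzyme-class].
#' @return Sorted integer vector of 0-based site start positions.
#' @examples
#' findRecognitionSites("CCCCAGCTCCCC", defaultEnzymes()$AluI)  # 4
#' @export
findRecognitionSites <- function(sequence, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  .assertUnambiguous(sequence)
  pat <- enzyme@recognition
  if (nchar(pat) > nchar(sequence)) return(integer(0))
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(sequence),
                                fixed = FALSE)
  sort(Biostrings::start(m) - 1L)
}

# Orient a record so the labelled end of `dye` is at position 0; returns the
# scan strand (reverse complement for right-end dyes).
#' @noRd
.labelledStrand <- function(record, dye) {
  de <- dyeEnds(record)
  if (!dye %in% names(de)) {
    stop("unknown dye '", dye, "'; available: ",
         paste(names(de), collapse = ", "), call. = FALSE)
  }
  s <- genotypeSequence(record)
  if (de[[dye]] == "left") s else .reverseComplement(s)
}

# Cut coordinate (bp from the labelled end) for a 0-based site start under a
# length convention. labelled_strand: distance to the cut on the labelled
# strand itself (site + cutOffset). duplex_mean: mean of the two strands' cut
# coordinates; for a palindromic site of length r the opposite-strand cut
# falls at site + (r - cutOffset), so the mean is site + r/2 — this is what
# turns HinfI (r = 5) predictions into half-integers.
#' @noRd
.cutCoordinate <- function(sites, enzyme, convention) {
  switch(convention,
    labelled_strand = sites + enzyme@cutOffset,
    duplex_mean = sites + nchar(enzyme@recognition) / 2,
    stop("unknown length convention: ", convention))
}

#' Complete-digest terminal restriction fragment length
#'
#' Length of the fluorescently labelled fragment between the labelled end and
#' the nearest restriction cut, under complete digestion. With no site the
#' amplicon stays uncut and the TRF is the full sequence length.
#'
#' @param record A [GenotypeRecord-class].
#' @param enzyme A [RestrictionEnzyme-class].
#' @param dye Dye name; must be present in `dyeEnds(record)`.
#' @param convention `"labelled_strand"` (default; integer distance to the
#'   cut on the labelled strand) or `"duplex_mean"` (mean of the two
#'   strands' cut coordinates, giving half-integer lengths for enzymes with
#'   overhangs, e.g. HinfI).
#' @return TRF length in bp.
#' @examples
#' rec <- genotypeRecord("g", "CCCCAGCTCCCC", c(HEX = "left"))
#' terminalFragmentLength(rec, defaultEnzymes()$AluI, "HEX")  # 6
#' @export
terminalFragmentLength <- function(record, enzyme, dye,
                                   convention = c("labelled_strand",
                                                  "duplex_mean")) {
  convention <- match.arg(convention)
  strand <- .labelledStrand(record, dye)
  sites <- findRecognitionSites(strand, enzyme)
  if (length(sites) == 0L) return(nchar(strand))
  .cutCoordinate(min(sites), enzyme, convention)
}

#' Enumerate pseudo-TRF lengths from partial digestion
#'
#' A pseudo-TRF is the labelled fragment left when one or more cut sites go
#' uncut. Omitting any subset of the k sites leaves the labelled fragment
#' ending at the nearest *retained* site (or the full length when all are
#' skipped), so the achievable set is the distance to every site beyond the
#' first, plus the full length, minus the complete-digest length.
#'
#' @inheritParams terminalFragmentLength
#' @return Numeric vector of pseudo-TRF lengths (bp), sorted ascending;
#'   empty when the sequence has no site.
#' @examples
#' rec <- genotypeRecord("g", "CCCCCCAGCTCCCCCCCCCC", c(HEX = "left"))
#' enumeratePseudoTRFs(rec, defaultEnzymes()$AluI, "HEX")  # 20
#' @export
enumeratePseudoTRFs <- function(record, enzyme, dye,
                                convention = c("labelled_strand",
                                               "duplex_mean")) {
  convention <- match.arg(convention)
  strand <- .labelledStrand(record, dye)
  sites <- findRecognitionSites(strand, enzyme)
  if (length(sites) == 0L) return(numeric(0))
  lens <- c(.cutCoordinate(sites, enzyme, convention), nchar(strand))
  complete <- lens[[1L]]
  sort(unique(lens[lens > complete]))
}

#' Predict the TRF table for a set of genotypes
#'
#' One prediction per genotype x enzyme in the analysed dye channel:
#' complete-digest TRF plus the pseudo-TRF set. Pairs of genotypes sharing a
#' complete TRF length under the same enzyme violate the design criterion
#' that every genotype yields a uniquely sized TRF; such collisions are
#' flagged (attribute `"collisions"`) and raised as a warning.
#'
#' @param records List of [GenotypeRecord-class] objects.
#' @param enzymes List of [RestrictionEnzyme-class] objects (default both
#'   protocol enzymes).
#' @param channelRule Named character vector enzyme -> analysed dye
#'   (default [defaultChannelRule()]).
#' @param convention Length convention, see [terminalFragmentLength()].
#' @return Data frame with columns `genotype_id`, `enzyme`, `dye`,
#'   `complete_trf_bp` and list column `pseudo_trfs_bp`; attribute
#'   `"collisions"` is a data frame of flagged genotype pairs.
#' @export
predictTRFTable <- function(records, enzymes = defaultEnzymes(),
                            channelRule = defaultChannelRule(),
                            convention = c("labelled_strand",
                                           "duplex_mean")) {
  convention <- match.arg(convention)
  rows <- list()
  for (enz in enzymes) {
    if (!enz@name %in% names(channelRule))
      stop("channel rule has no dye for enzyme ", enz@name)
    dye <- channelRule[[enz@name]]
    for (rec in records) {
      rows[[length(rows) + 1L]] <- data.frame(
        genotype_id = genotypeId(rec), enzyme = enz@name, dye = dye,
        complete_trf_bp = terminalFragmentLength(rec, enz, dye, convention),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$pseudo_trfs_bp <-
        list(enumeratePseudoTRFs(rec, enz, dye, convention))
    }
  }
  out <- do.call(rbind, rows)
  collisions <- do.call(rbind, lapply(split(out, out$enzyme), function(d) {
    dup <- d$complete_trf_bp[duplicated(d$complete_trf_bp)]
    d[d$complete_trf_bp %in% dup, c("genotype_id", "enzyme",
                                    "complete_trf_bp")]
  }))
  rownames(collisions) <- NULL
  if (nrow(collisions)) {
    warning("genotypes share a complete TRF length (uniqueness criterion ",
            "violated): ",
            paste(unique(collisions$genotype_id), collapse = ", "))
  }
  attr(out, "collisions") <- collisions
  out
}

#' Write / read a TRF prediction table as TSV
#'
#' Pseudo-TRF sets are semicolon-joined in the file.
#'
#' @param trfTable Data frame from [predictTRFTable()].
#' @param path TSV path.
#' @return `path` (writer) or the table (reader).
#' @export
writeTRFTable <- function(trfTable, path) {
  flat <- trfTable
  flat$pseudo_trfs_bp <- vapply(trfTable$pseudo_trfs_bp,
                                function(v) paste(v, collapse = ";"),
                                character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTRFTable
#' @export
readTRFTable <- function(path) {
  flat <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(pseudo_trfs_bp = "character"))
  flat$pseudo_trfs_bp <- lapply(strsplit(flat$pseudo_trfs_bp, ";"),
                                function(v) as.numeric(v[nzchar(v)]))
  flat
}
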
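#' Create a community template
#'
#' @param name Template name.
#' @param composition Named numeric vector of strictly positive genotype
#'   proportions summing to 1 (2-6 genotypes).
#' @return A [CommunityTemplate-class].
#' @examples
#' communityTemplate("eq2", c(g1 = 0.5, g2 = 0.5))
#' @export
communityTemplate <- function(name, composition) {
  new("CommunityTemplate", name = as.character(name),
      composition = composition)
}

#' @rdname CommunityTemplate-class
#' @export
setMethod("templateName", "CommunityTemplate", function(x) x@name)

#' @rdname CommunityTemplate-class
#' @export
setMethod("composition", "CommunityTemplate", function(x) x@composition)

setMethod("show", "CommunityTemplate", function(object) {
  cat("CommunityTemplate", object@name, "—", length(object@composition),
      "genotypes\n")
  print(round(object@composition, 4))
})

#' Equal-abundance template
#'
#' All genotypes in equal proportion, the design used to test whether any
#' genotype is preferentially detected.
#'
#' @param genotypeIds Character vector of 2-6 unique genotype ids.
#' @param name Template name.
#' @return A [CommunityTemplate-class].
#' @examples
#' composition(equalProportions(c("a", "b", "c", "d")))
#' @export
equalProportions <- function(genotypeIds, name = paste0("equal", length(genotypeIds))) {
  if (anyDuplicated(genotypeIds)) stop("duplicate genotype ids")
  n <- length(genotypeIds)
  communityTemplate(name, stats::setNames(rep(1 / n, n), genotypeIds))
}

#' Broken-stick expected proportions
#'
#' MacArthur's broken-stick expectation for `n` taxa, ranked descending:
#' `p_i = (1/n) * sum_{k=i..n} 1/k`. Used to shape templates that mimic the
#' rank-abundance structure of field communities.
#'
#' @param n Number of taxa, `n >= 2`.
#' @return Numeric vector of proportions, strictly decreasing, summing to 1.
#' @examples
#' brokenStickProportions(2)  # 0.75 0.25
#' @export
brokenStickProportions <- function(n) {
  if (n < 2) stop("broken-stick templates need n >= 2")
  rev(cumsum(rev(1 / seq_len(n)))) / n
}

#' Broken-stick template
#'
#' @inheritParams equalProportions
#' @return A [CommunityTemplate-class] with broken-stick proportions
#'   assigned in the order of `genotypeIds` (most abundant first).
#' @export
brokenStickTemplate <- function(genotypeIds,
                                name = paste0("brokenstick", length(genotypeIds))) {
  if (anyDuplicated(genotypeIds)) stop("duplicate genotype ids")
  p <- brokenStickProportions(length(genotypeIds))
  communityTemplate(name, stats::setNames(p, genotypeIds))
}

#' Near-equal two-genotype template
#'
#' Two genotypes at proportions `0.5 + delta` and `0.5 - delta`, the design
#' probing the resolution of the protocol for almost-equal mixtures.
#'
#' @param genotypeIds Exactly two genotype ids.
#' @param delta Proportion offset, `0 <= delta < 0.5`.
#' @param name Template name.
#' @return A [CommunityTemplate-class].
#' @examples
#' composition(nearEqualPair(c("a", "b"), 0.05))  # 0.55 0.45
#' @export
nearEqualPair <- function(genotypeIds, delta,
                          name = sprintf("pair_delta%.3f", delta)) {
  if (length(genotypeIds) != 2L || anyDuplicated(genotypeIds))
    stop("exactly two distinct genotype ids required")
  if (delta < 0 || delta >= 0.5)
    stop("delta must satisfy 0 <= delta < 0.5")
  communityTemplate(name, stats::setNames(c(0.5 + delta, 0.5 - delta),
                                          genotypeIds))
}

#' The nine-template study design
#'
#' Equal-abundance and broken-stick templates at richness 4, 5 and 6 plus
#' three near-equal two-genotype templates. The exact proportions of the
#' original design are figure-only, so broken-stick templates use the
#' MacArthur expectation and the pair deltas default to 0, 0.025 and 0.05;
#' both are overridable.
#'
#' @param genotypeIds At least six genotype ids; richness-n templates use
#'   the first n, pairs use the first two.
#' @param pairDeltas Numeric vector of deltas for the two-genotype
#'   templates.
#' @return Named list of nine [CommunityTemplate-class] objects.
#' @export
studyTemplates <- function(genotypeIds, pairDeltas = c(0, 0.025, 0.05)) {
  if (length(genotypeIds) < 6L) stop("need at least six genotype ids")
  templates <- list()
  for (n in 4:6) {
    eq <- equalProportions(genotypeIds[seq_len(n)])
    bs <- brokenStickTemplate(genotypeIds[seq_len(n)])
    templates[[templateName(eq)]] <- eq
    templates[[templateName(bs)]] <- bs
  }
  for (d in pairDeltas) {
    tpl <- nearEqualPair(genotypeIds[1:2], d)
    templates[[templateName(tpl)]] <- tpl
  }
  if (length(templates) != 9L)
    stop("study design requires exactly nine distinct templates")
  templates
}

#' Predicted TRFLP profile of a template
#'
#' The theoretical fingerprint under unbiased amplification and complete
#' digestion: each genotype contributes its whole proportion at its
#' complete-digest TRF length. Genotypes sharing a TRF length collapse into
#' one entry by summation; pseudo-TRFs carry zero abundance in the ideal
#' prediction and are therefore absent.
#'
#' @param template A [CommunityTemplate-class].
#' @param trfTable Prediction table from [predictTRFTable()].
#' @param enzyme Enzyme name selecting rows of `trfTable`.
#' @param sampleId Sample id for the resulting profile (defaults to the
#'   template name).
#' @return A [TRFProfile-class] of kind `"predicted"`.
#' @export
buildPredictedProfile <- function(template, trfTable, enzyme,
                                  sampleId = templateName(template)) {
  comp <- composition(template)
  sub <- trfTable[trfTable$enzyme == enzyme, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no predictions for enzyme ", enzyme)
  missing <- setdiff(names(comp), sub$genotype_id)
  if (length(missing))
    stop("no TRF prediction for genotype(s): ",
         paste(missing, collapse = ", "))
  trf <- sub$complete_trf_bp[match(names(comp), sub$genotype_id)]
  ab <- tapply(comp, trf, sum)
  ab <- stats::setNames(as.numeric(ab), names(ab))
  trfProfile(sampleId, enzyme, unique(sub$dye)[1], ab, kind = "predicted")
}

#' Create a TRF profile
#'
#' @param sampleId,enzyme,dye Identifiers.
#' @param abundance Named numeric vector (names = TRF lengths in bp); it is
#'   normalized to sum to 1.
#' @param kind `"predicted"` or `"observed"`.
#' @return A [TRFProfile-class].
#' @export
trfProfile <- function(sampleId, enzyme, dye, abundance, kind = "observed") {
  total <- sum(abundance)
  if (length(abundance) && total > 0) abundance <- abundance / total
  o <- order(as.numeric(names(abundance)))
  new("TRFProfile", sampleId = as.character(sampleId),
      enzyme = as.character(enzyme), dye = as.character(dye),
      abundance = abundance[o], kind = kind)
}

#' @rdname TRFProfile-class
#' @export
setMethod("sampleId", "TRFProfile", function(x) x@sampleId)

#' @rdname TRFProfile-class
#' @export
setMethod("profileAbundance", "TRFProfile", function(x) x@abundance)

setMethod("show", "TRFProfile", function(object) {
  cat("TRFProfile [", object@kind, "] ", object@sampleId, " (",
      object@enzyme, "/", object@dye, "): ", length(object@abundance),
      " TRFs\n", sep = "")
  print(round(object@abundance, 4))
})

#' Stack profiles into a samples x TRF-bins abundance matrix
#'
#' Bins absent from a profile are filled with zero; columns are ordered by
#' TRF length.
#'
#' @param profiles List of [TRFProfile-class] objects.
#' @return Numeric matrix, rows named by sample id, columns by TRF length.
#' @export
profilesToMatrix <- function(profiles) {
  bins <- sort(unique(as.numeric(unlist(lapply(profiles, function(p)
    names(profileAbundance(p)))))))
  m <- matrix(0, nrow = length(profiles), ncol = length(bins),
              dimnames = list(vapply(profiles, sampleId, character(1)),
                              as.character(bins)))
  for (i in seq_along(profiles)) {
    ab <- profileAbundance(profiles[[i]])
    m[i, names(ab)] <- ab
  }
  m
}

#' Write / read community templates as TSV
#'
#' Long format: `template_name`, `genotype_id`, `proportion`.
#'
#' @param templates List of [CommunityTemplate-class] objects.
#' @param path TSV path.
#' @return `path` (writer) or a named list of templates (reader).
#' @export
writeTemplates <- function(templates, path) {
  rows <- do.call(rbind, lapply(templates, function(t) {
    data.frame(template_name = templateName(t),
               genotype_id = names(composition(t)),
               proportion = unname(composition(t)))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTemplates
#' @export
readTemplates <- function(path) {
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  out <- lapply(split(rows, rows$template_name), function(d) {
    communityTemplate(d$template_name[1],
                      stats::setNames(d$proportion, d$genotype_id))
  })
  out[unique(rows$template_name)]
}
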
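#' @rdname RestrictionEnzyme-class
#' @param object,x An object.
#' @export
setGeneric("enzymeName", function(x) standardGeneric("enzymeName"))

#' @rdname RestrictionEnzyme-class
#' @export
setGeneric("recognitionSite", function(x) standardGeneric("recognitionSite"))

#' @rdname RestrictionEnzyme-class
#' @export
setGeneric("cutOffset", function(x) standardGeneric("cutOffset"))

#' @rdname GenotypeRecord-class
#' @export
setGeneric("genotypeId", function(x) standardGeneric("genotypeId"))

#' @rdname GenotypeRecord-class
#' @export
setGeneric("genotypeSequence", function(x) standardGeneric("genotypeSequence"))

#' @rdname GenotypeRecord-class
#' @export
setGeneric("dyeEnds", function(x) standardGeneric("dyeEnds"))

#' @rdname CommunityTemplate-class
#' @export
setGeneric("templateName", function(x) standardGeneric("templateName"))

#' @rdname CommunityTemplate-class
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))

#' @rdname TRFProfile-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname TRFProfile-class
#' @export
setGeneric("profileAbundance", function(x) standardGeneric("profileAbundance"))
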
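## Generics for the S4 interface.

#' @rdname templateLength
#' @export
setGeneric("templateLength", function(x) standardGeneric("templateLength"))

#' @rdname positionCounts
#' @export
setGeneric("positionCounts", function(x) standardGeneric("positionCounts"))

#' @rdname theoreticalDiversity
#' @export
setGeneric("theoreticalDiversity",
           function(x, mode = c("declared", "codon_derived"))
             standardGeneric("theoreticalDiversity"))

#' @rdname degenerateGene
#' @export
setGeneric("degenerateGene", function(x) standardGeneric("degenerateGene"))

#' @rdname templatePositions
#' @export
setGeneric("templatePositions", function(x) standardGeneric("templatePositions"))

#' @rdname SynthLibrary-accessors
#' @export
setGeneric("dnaSeqs", function(x) standardGeneric("dnaSeqs"))

#' @rdname SynthLibrary-accessors
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))

#' @rdname SynthLibrary-accessors
#' @export
setGeneric("errorEvents", function(x) standardGeneric("errorEvents"))

#' @rdname ConformityReport-accessors
#' @export
setGeneric("conformityScore", function(x) standardGeneric("conformityScore"))

#' @rdname ConformityReport-accessors
#' @export
setGeneric("indels", function(x) standardGeneric("indels"))

#' @rdname ConformityReport-accessors
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))

#' @rdname ConformityReport-accessors
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))
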
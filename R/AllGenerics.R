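#' @rdname TranscriptSet-class
#' @param x a \linkS4class{TranscriptSet}.
#' @export
setGeneric("taxon", function(x) standardGeneric("taxon"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname KsPeakMatrix-class
#' @param x a \linkS4class{KsPeakMatrix}.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname KsPeakMatrix-class
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @rdname CladeTree-class
#' @param x a \linkS4class{CladeTree}.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' @rdname CladeTree-class
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
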
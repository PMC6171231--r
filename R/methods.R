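# Accessors and show methods.

#' @rdname TranscriptSet-class
#' @aliases taxon,TranscriptSet-method
setMethod("taxon", "TranscriptSet", function(x) x@taxon)

#' @rdname TranscriptSet-class
#' @aliases sequences,TranscriptSet-method
setMethod("sequences", "TranscriptSet", function(x) x@sequences)

#' @rdname TranscriptSet-class
#' @aliases length,TranscriptSet-method
setMethod("length", "TranscriptSet", function(x) length(x@sequences))

#' @rdname KsPeakMatrix-class
#' @aliases peaks,KsPeakMatrix-method
setMethod("peaks", "KsPeakMatrix", function(x) {
  m <- x@peaks
  dimnames(m) <- list(x@taxa, x@taxa)
  m
})

#' @rdname KsPeakMatrix-class
#' @aliases pairCounts,KsPeakMatrix-method
setMethod("pairCounts", "KsPeakMatrix", function(x) {
  m <- x@nPairs
  dimnames(m) <- list(x@taxa, x@taxa)
  m
})

#' @rdname CladeTree-class
#' @aliases asPhylo,CladeTree-method
setMethod("asPhylo", "CladeTree", function(x) x@tree)

#' @rdname CladeTree-class
#' @aliases nodeTable,CladeTree-method
setMethod("nodeTable", "CladeTree", function(x) x@nodes)

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet for taxon '", object@taxon, "': ",
      length(object@sequences), " transcripts\n", sep = "")
  if (length(object@sequences)) {
    w <- Biostrings::width(object@sequences)
    cat("  length range: ", min(w), "-", max(w), " nt\n", sep = "")
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed=", object@seed,
      " nCodons=", object@nCodons, " omega=", object@omega,
      " ksTarget=", object@ksTarget, " nGenes=", object@nGenes,
      " nDecoys=", object@nDecoys,
      if (is.null(object@tree)) " (no tree)" else
        paste0(" tree with ", length(object@tree$tip.label), " taxa"),
      "\n", sep = "")
})

setMethod("show", "RateEstimate", function(object) {
  cat("RateEstimate: S=", round(object@S, 2), " N=", round(object@N, 2),
      " Sd=", round(object@Sd, 2), " Nd=", round(object@Nd, 2), "\n",
      "  Ka=", signif(object@Ka, 4), " Ks=", signif(object@Ks, 4),
      " Ka/Ks=",
      if (object@flag == "> 1") "> 1" else signif(object@omega, 4),
      " [", object@flag, "]\n", sep = "")
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment ", object@idA, " vs ", object@idB, ": ",
      length(object@codonsA), " columns (",
      sum(object@excluded), " excluded)\n", sep = "")
})

setMethod("show", "KsPeakMatrix", function(object) {
  cat("KsPeakMatrix over", length(object@taxa), "taxa\n")
  print(peaks(object))
})

setMethod("show", "CladeTree", function(object) {
  cat("CladeTree rooted on '", object@outgroup, "' (",
      length(object@tree$tip.label), " taxa), clock rate ",
      format(object@rate, scientific = TRUE), " subs/site/yr\n", sep = "")
  if (nrow(object@nodes)) {
    cat("  dated splits:\n")
    print(object@nodes[, c("ks", "ageMya")])
  }
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: ", length(object@fastaFiles), " taxa; thresholds ",
      "redundancy>", object@redundancyThreshold,
      ", orthology>=", object@orthologyThreshold,
      "; bin=", object@binWidth, ", cap=", object@ksCap,
      "; clock=", format(object@clockRate, scientific = TRUE),
      "; outgroup=", object@outgroup, "\n", sep = "")
})
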
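#' Accessors for condseg classes
#'
#' `gridBins()` returns the bin `GRanges` of a [GenomeGrid] (or of the
#' grid underlying a [BinnedTrackMatrix]); `binSize()` the bin width in
#' bp; `chromSizes()` the named chromosome-length vector; `nBins()` the
#' number of bins. `normTag()` reports which normalization a
#' [BinnedTrackMatrix] carries, and `genomeGrid()` rebuilds its
#' [GenomeGrid]. `pc1()`, `varianceExplained()` and `pcLoadings()`
#' extract the reduced signal, the percent variance on component 1 and
#' the per-track component-1 weights from a [PCAResult].
#'
#' @param x a GenomeGrid, BinnedTrackMatrix or PCAResult.
#' @return see above; scalar, vector or `GRanges` as appropriate.
#' @name condseg-accessors
NULL

#' @rdname condseg-accessors
#' @export
setGeneric("gridBins", function(x) standardGeneric("gridBins"))
#' @rdname condseg-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname condseg-accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @rdname condseg-accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname condseg-accessors
#' @export
setGeneric("normTag", function(x) standardGeneric("normTag"))
#' @rdname condseg-accessors
#' @export
setGeneric("genomeGrid", function(x) standardGeneric("genomeGrid"))
#' @rdname condseg-accessors
#' @export
setGeneric("pc1", function(x) standardGeneric("pc1"))
#' @rdname condseg-accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @rdname condseg-accessors
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname condseg-accessors
#' @export
setMethod("gridBins", "GenomeGrid", function(x) x@bins)
#' @rdname condseg-accessors
#' @export
setMethod("binSize", "GenomeGrid", function(x) x@binSize)
#' @rdname condseg-accessors
#' @export
setMethod("chromSizes", "GenomeGrid", function(x) {
  sl <- seqlengths(x@bins)
  setNames(as.integer(sl), names(sl))
})
#' @rdname condseg-accessors
#' @export
setMethod("nBins", "GenomeGrid", function(x) length(x@bins))

#' @rdname condseg-accessors
#' @export
setMethod("gridBins", "BinnedTrackMatrix", function(x) rowRanges(x))
#' @rdname condseg-accessors
#' @export
setMethod("binSize", "BinnedTrackMatrix", function(x) x@binSize)
#' @rdname condseg-accessors
#' @export
setMethod("normTag", "BinnedTrackMatrix", function(x) x@normTag)
#' @rdname condseg-accessors
#' @export
setMethod("genomeGrid", "BinnedTrackMatrix", function(x)
  new("GenomeGrid", bins = granges(rowRanges(x)), binSize = x@binSize))

#' @rdname condseg-accessors
#' @export
setMethod("pc1", "PCAResult", function(x) x@pc1)
#' @rdname condseg-accessors
#' @export
setMethod("varianceExplained", "PCAResult", function(x)
  x@varianceExplainedPct)
#' @rdname condseg-accessors
#' @export
setMethod("pcLoadings", "PCAResult", function(x) x@loadings)
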
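#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom IRanges IRanges CharacterList overlapsAny
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   strand<- findOverlaps pintersect granges distance
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   rowRanges colData assayNames
#' @importFrom stats median sd prcomp optim rnorm rbinom runif rgamma rpois
#'   dnorm pnorm dnbinom pnbinom quantile setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' GenomeGrid: a fixed-resolution binning of a genome
#'
#' Tiles each chromosome into consecutive bins of `binSize` base pairs
#' (0-based half-open, BED convention); the last bin of a chromosome is
#' truncated at the chromosome end. The grid is the coordinate substrate
#' for the binned track matrix, the segmentation and the enhancer-bin
#' calls, so every downstream object refers back to it.
#'
#' @slot bins a [GenomicRanges::GRanges] tiling every chromosome, in
#'   chromosome order then start order, with `seqlengths` set.
#' @slot binSize bin width in bp.
#'
#' @seealso [makeGenomeGrid()]
#' @export
setClass("GenomeGrid",
  representation(bins = "GRanges", binSize = "integer"))

setValidity("GenomeGrid", function(object) {
  b <- object@bins
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize < 1L)
    return("binSize must be a single positive integer")
  sl <- seqlengths(b)
  if (any(is.na(sl))) return("seqlengths must be set for all chromosomes")
  # per-chromosome tiling: gap-free, non-overlapping, truncated last bin
  for (chr in seqlevels(b)) {
    bb <- b[seqnames(b) == chr]
    if (length(bb) == 0L) return(sprintf("chromosome %s has no bins", chr))
    s <- start(bb); e <- end(bb)
    if (s[1L] != 1L) return(sprintf("%s does not start at position 1", chr))
    if (length(bb) > 1L && any(s[-1L] != e[-length(e)] + 1L))
      return(sprintf("bins on %s are not contiguous", chr))
    if (e[length(e)] != sl[[chr]])
      return(sprintf("bins on %s do not reach the chromosome end", chr))
    if (length(bb) > 1L && any(width(bb)[-length(bb)] != object@binSize))
      return(sprintf("non-terminal bin on %s has width != binSize", chr))
  }
  TRUE
})

#' BinnedTrackMatrix: bins-by-experiments signal matrix on a GenomeGrid
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are the
#' bins of a [GenomeGrid] and whose columns are coverage tracks
#' (experiments). The single assay `"signal"` holds non-negative,
#' possibly depth-normalized signal; absent coverage is 0, never NA.
#'
#' @slot normTag which per-track normalization the assay carries:
#'   `"raw"`, `"cpm"` or `"rpkm"`.
#' @slot binSize the grid bin width in bp.
#'
#' @seealso [buildTrackMatrix()], [normalizeTracks()], [logZScore()]
#' @export
setClass("BinnedTrackMatrix",
  contains = "RangedSummarizedExperiment",
  representation(normTag = "character", binSize = "integer"))

setValidity("BinnedTrackMatrix", function(object) {
  if (!object@normTag %in% c("raw", "cpm", "rpkm"))
    return("normTag must be one of raw, cpm, rpkm")
  m <- assay(object, "signal")
  if (anyNA(m)) return("signal matrix must not contain NA")
  if (any(m < 0)) return("signal matrix must be non-negative")
  if (anyDuplicated(colnames(object)))
    return("track names must be unique")
  TRUE
})

#' PCAResult: one-dimensional reduction of a track matrix
#'
#' Holds the first principal component of the standardized
#' bins-by-experiments matrix -- the 1D signal that is segmented --
#' together with its loadings and the variance captured.
#'
#' @slot pc1 numeric vector, one value per bin.
#' @slot varianceExplainedPct percent of total variance on component 1.
#' @slot allVariancePct percent of variance per component (sums to 100).
#' @slot loadings per-experiment weight on component 1.
#' @slot signFlipped whether the sign convention flipped the raw
#'   eigenvector (PC1 is oriented to correlate non-negatively with the
#'   per-bin mean signal).
#'
#' @seealso [computePC1()]
#' @export
setClass("PCAResult",
  representation(pc1 = "numeric", varianceExplainedPct = "numeric",
                 allVariancePct = "numeric", loadings = "numeric",
                 signFlipped = "logical"))

setValidity("PCAResult", function(object) {
  v <- object@varianceExplainedPct
  if (length(v) != 1L || v < 0 || v > 100 + 1e-8)
    return("varianceExplainedPct must be a single value in [0, 100]")
  TRUE
})

setMethod("show", "GenomeGrid", function(object) {
  sl <- seqlengths(object@bins)
  cat(sprintf("GenomeGrid: %d bins of %d bp on %d chromosome(s)\n",
              length(object@bins), object@binSize, length(sl)))
  cat("  ", paste(sprintf("%s:%d", names(sl), sl), collapse = " "), "\n")
})

setMethod("show", "BinnedTrackMatrix", function(object) {
  cat(sprintf(
    "BinnedTrackMatrix: %d bins (%d bp) x %d track(s), normalization: %s\n",
    nrow(object), object@binSize, ncol(object), object@normTag))
  cat("  tracks:", paste(colnames(object), collapse = ", "), "\n")
})

setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d bins, PC1 captures %.2f%% of variance%s\n",
              length(object@pc1), object@varianceExplainedPct,
              if (object@signFlipped) " (sign flipped)" else ""))
  cat("  loadings:", paste(sprintf("%s=%.3f", names(object@loadings),
                                   object@loadings), collapse = " "), "\n")
})
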
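#' Run the full segmentation -> annotation -> PTC pipeline
#'
#' Convenience driver tying the modules together for one condition:
#' log10 + Z-score transform, PC1 reduction, sliding-window
#' segmentation, joint-mark enhancer-bin calling, shuffled-genome ZINB
#' annotation, contact-score pooling, cutoff estimation (unless a
#' cutoff on the contact scores' own scale is supplied) and PTC
#' calling.
#'
#' @param btm a [BinnedTrackMatrix].
#' @param contacts contact score set.
#' @param marks joint enhancer-mark track names (default first two
#'   tracks).
#' @param cfg a [segmentationConfig()].
#' @param zThreshold enhancer-bin Z cutoff (default 1).
#' @param nShuffles background placements per segment (default 1000).
#' @param alpha annotation significance level (default 0.05).
#' @param cutoff PTC score cutoff; `NULL` (default) estimates it by
#'   permutation. A fixed cutoff only makes sense on an externally
#'   normalized score scale.
#' @param nPerm permutations for cutoff estimation (default 100).
#' @param dMaxBp inter-segment distance cap (default 2e6).
#' @param seed integer seed for the shuffles and permutations.
#' @param condition condition label for the PTCs.
#' @return list with `grid`, `pcares`, `segments`, `enhancerBins`,
#'   `annotation`, `table`, `cutoff`, `cutoffScan`, `ptcs`.
#' @export
runCondensatePipeline <- function(btm, contacts, marks = NULL,
                                  cfg = segmentationConfig(),
                                  zThreshold = 1, nShuffles = 1000L,
                                  alpha = 0.05, cutoff = NULL,
                                  nPerm = 100L, dMaxBp = 2e6,
                                  seed = 1L,
                                  condition = NA_character_) {
  stopifnot(is(btm, "BinnedTrackMatrix"))
  if (is.null(marks)) marks <- colnames(btm)[1:2]
  grid <- genomeGrid(btm)
  zmat <- logZScore(btm)
  pcares <- computePC1(zmat)
  segments <- segmentGenome(pc1(pcares), grid, cfg)
  enh <- callEnhancerBins(zmat, marks, zThreshold)
  set.seed(seed)
  annot <- annotateSegments(segments, enh, grid, nShuffles = nShuffles,
                            alpha = alpha)
  tab <- scoreSegmentPairs(contacts, segments, dMaxBp)
  scan <- NULL
  if (is.null(cutoff)) {
    set.seed(seed + 1L)
    scan <- estimateCutoff(contacts, segments, grid, nPerm = nPerm,
                           dMaxBp = dMaxBp)
    cutoff <- scan$cutoff
  }
  ptcs <- callPTCs(tab, annot, segments, cutoff, dMaxBp,
                   condition = condition)
  list(grid = grid, pcares = pcares, segments = segments,
       enhancerBins = enh, annotation = annot, table = tab,
       cutoff = cutoff, cutoffScan = scan, ptcs = ptcs)
}
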
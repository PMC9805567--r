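#' Classify segments into the four downstream categories
#'
#' `Condensate`: enhancer-enriched and a member of some PTC.
#' `Enhancer`: enhancer-enriched but in no PTC. The enhancer-depleted
#' segments split by the sign of their mean PC1 -- PC1 is oriented to
#' correlate positively with the activity tracks, so depleted segments
#' with mean PC1 above `activeThreshold` (default 0) are `Active` and
#' the rest `Repressed`. Every segment receives exactly one category.
#'
#' @param annot annotation `DataFrame` from [annotateSegments()].
#' @param ptcs PTC `GRanges` from [callPTCs()].
#' @param segments segment `GRanges` (for mean_pc1).
#' @param activeThreshold mean-PC1 split point for depleted segments.
#' @return data.frame with columns segment_id, category.
#' @export
classifySegmentsFourWay <- function(annot, ptcs, segments,
                                    activeThreshold = 0) {
  ids <- mcols(segments)$segment_id
  if (!all(ids %in% annot$segment_id))
    stop("segment(s) missing from annotation: ",
         paste(head(setdiff(ids, annot$segment_id)), collapse = ", "))
  ann <- annot[match(ids, annot$segment_id), ]
  inptc <- ids %in% unlist(mcols(ptcs)$members)
  enriched <- ann$label == "enhancer_enriched"
  category <- ifelse(enriched & inptc, "Condensate",
              ifelse(enriched, "Enhancer",
              ifelse(mcols(segments)$mean_pc1 > activeThreshold,
                     "Active", "Repressed")))
  data.frame(segment_id = ids, category = category)
}

#' Read a gene annotation table
#'
#' Accepts BED6 (chrom, start, end, gene_id, score, strand) or a
#' 4-column TSV (gene_id, chrom, start, end); coordinates 0-based
#' half-open. The TSS is the strand-aware 5' end when strand is
#' present, else the span start.
#'
#' @param path TSV/BED path (no header, or header starting with
#'   "gene_id"/"chrom").
#' @return `GRanges` with mcols `gene_id` and `tss` (1-based bp).
#' @export
readGenesBed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (is.character(df[[2L]]) || df[1L, 1L] %in% c("gene_id", "chrom")) {
    if (df[1L, 1L] %in% c("gene_id", "chrom"))
      df <- df[-1L, , drop = FALSE]
    gr <- GRanges(df[[2L]], IRanges(as.integer(df[[3L]]) + 1L,
                                    as.integer(df[[4L]])))
    mcols(gr)$gene_id <- df[[1L]]
    strand(gr) <- if (ncol(df) >= 5L) df[[5L]] else "*"
  } else {
    gr <- GRanges(df[[1L]], IRanges(as.integer(df[[2L]]) + 1L,
                                    as.integer(df[[3L]])))
    mcols(gr)$gene_id <- df[[4L]]
    strand(gr) <- if (ncol(df) >= 6L) df[[6L]] else "*"
  }
  mcols(gr)$tss <- ifelse(as.character(strand(gr)) == "-",
                          end(gr), start(gr))
  gr
}

#' Read a long-format expression table
#'
#' @param path TSV with header gene_id, condition, tpm.
#' @return data.frame gene_id, condition, tpm.
#' @export
readTpmTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric"))
}

#' Genes falling exclusively within segments of one category
#'
#' A gene qualifies when its span overlaps at least one segment of the
#' requested category and no segment of any other category; genes
#' straddling a category boundary are excluded, so the four per-
#' category gene lists are pairwise disjoint.
#'
#' @param genes gene `GRanges` (see [readGenesBed()]).
#' @param segments segment `GRanges`.
#' @param classes data.frame from [classifySegmentsFourWay()].
#' @param category one of Condensate, Enhancer, Active, Repressed.
#' @return character vector of gene ids.
#' @export
genesInCategory <- function(genes, segments, classes, category) {
  stopifnot(category %in% c("Condensate", "Enhancer", "Active",
                            "Repressed"))
  cats <- classes$category[match(mcols(segments)$segment_id,
                                 classes$segment_id)]
  hits <- findOverlaps(genes, segments, ignore.strand = TRUE)
  bygene <- split(cats[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
  qual <- vapply(bygene, function(cs)
    all(cs == category), logical(1))
  idx <- as.integer(names(bygene)[qual])
  mcols(genes)$gene_id[idx]
}

#' Select condition-specific candidate genes within PTCs
#'
#' Per condition, a gene passes when (i) its span overlaps a PTC span,
#' (ii) its TPM in that condition is > 0, and (iii) its promoter window
#' (TSS +/- `promoterHalfwidth`) overlaps at least one enhancer bin --
#' the joint accessibility + H3K27ac bin call standing in for an
#' "accessible and acetylated" promoter. The candidate flag singles out
#' genes that pass in EVERY condition after the first but NOT in the
#' first of the declared condition order: with conditions ordered along
#' a time course this is the "acquired later, absent at the start"
#' pattern.
#'
#' @param genes gene `GRanges` with `gene_id` and `tss` mcols.
#' @param tpm data.frame gene_id, condition, tpm.
#' @param ptcsByCondition named list of PTC `GRanges`, in condition
#'   order (first = baseline).
#' @param enhancerBinsByCondition named list of 0/1 bin vectors,
#'   matching names.
#' @param grid the [GenomeGrid].
#' @param promoterHalfwidth promoter window half-width in bp
#'   (default 5000).
#' @return data.frame with gene_id, one pass_<condition> column per
#'   condition, and candidate_flag.
#' @export
selectCandidates <- function(genes, tpm, ptcsByCondition,
                             enhancerBinsByCondition, grid,
                             promoterHalfwidth = 5000) {
  conds <- names(ptcsByCondition)
  stopifnot(length(conds) >= 2L,
            identical(conds, names(enhancerBinsByCondition)))
  bins <- gridBins(grid)
  known <- as.character(seqnames(genes)) %in% seqlevels(bins)
  if (!all(known)) {
    warning(sum(!known), " gene(s) on unknown chromosomes skipped")
    genes <- genes[known]
  }
  sl <- seqlengths(bins)
  prom <- GRanges(seqnames(genes),
                  IRanges(pmax(1L, mcols(genes)$tss - promoterHalfwidth),
                          pmin(sl[as.character(seqnames(genes))],
                               mcols(genes)$tss + promoterHalfwidth)))
  pass <- sapply(conds, function(cd) {
    in_ptc <- overlapsAny(genes, ptcsByCondition[[cd]],
                          ignore.strand = TRUE)
    tt <- tpm[tpm$condition == cd, ]
    gtpm <- tt$tpm[match(mcols(genes)$gene_id, tt$gene_id)]
    gtpm[is.na(gtpm)] <- 0
    ebins <- bins[enhancerBinsByCondition[[cd]] == 1L]
    marked <- overlapsAny(prom, ebins, ignore.strand = TRUE)
    in_ptc & gtpm > 0 & marked
  })
  pass <- matrix(pass, nrow = length(genes),
                 dimnames = list(NULL, conds))
  later <- conds[-1L]
  flag <- rowSums(pass[, later, drop = FALSE]) == length(later) &
    !pass[, conds[1L]]
  out <- data.frame(gene_id = mcols(genes)$gene_id)
  for (cd in conds) out[[paste0("pass_", cd)]] <- pass[, cd]
  out$candidate_flag <- flag
  out
}
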
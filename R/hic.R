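#' Load a normalized per-contact score track
#'
#' Reads a 5-column tab-delimited point list (chrom1, pos1, chrom2,
#' pos2, score; header optional) of normalized chromatin-contact
#' scores, e.g. the output of a per-contact Hi-C normalizer.
#' Same-chromosome records are canonicalized to `pos1 <= pos2`;
#' inter-chromosomal records are kept but flagged, since only
#' intra-chromosomal contacts are scored downstream.
#'
#' @param path TSV path.
#' @param sourceTag provenance of the score scale:
#'   `"external_normalized"` (a cutoff on this scale may be supplied
#'   directly) or `"fallback"` (cutoff must be re-estimated).
#' @return data.frame with columns chrom1, pos1, chrom2, pos2, score
#'   and attributes `sourceTag` and `nInterChrom`.
#' @export
loadContactScores <- function(path, sourceTag = "external_normalized") {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty contact file: ", path)
    return(.contact_set(data.frame(chrom1 = character(),
                                   pos1 = integer(),
                                   chrom2 = character(),
                                   pos2 = integer(), score = numeric()),
                        sourceTag))
  }
  hdr <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][2L])))
  df <- tryCatch(
    read.table(path, sep = "\t", header = hdr,
               col.names = c("chrom1", "pos1", "chrom2", "pos2", "score"),
               colClasses = c("character", "numeric", "character",
                              "numeric", "numeric")),
    error = function(e) stop("malformed contact file ", path, ": ",
                             conditionMessage(e)))
  if (anyNA(df$score) || anyNA(df$pos1) || anyNA(df$pos2)) {
    bad <- which(!complete.cases(df))[1L] + hdr
    stop("malformed contact record at line ", bad, " of ", path)
  }
  .contact_set(df, sourceTag)
}

.contact_set <- function(df, sourceTag) {
  same <- df$chrom1 == df$chrom2
  swap <- same & df$pos1 > df$pos2
  if (any(swap)) {
    tmp <- df$pos1[swap]
    df$pos1[swap] <- df$pos2[swap]
    df$pos2[swap] <- tmp
  }
  attr(df, "sourceTag") <- sourceTag
  attr(df, "nInterChrom") <- sum(!same)
  df
}

#' Distance-decay normalized scores from raw contact pairs
#'
#' A built-in stand-in normalizer for when no externally normalized
#' score track is available: raw intra-chromosomal contact pairs are
#' binned on the grid, and each observed bin pair at bin distance d is
#' scored as `log2((observed + 1) / (expected_d + 1))`, where
#' `expected_d` is the genome-wide mean contact count over all possible
#' bin pairs at distance d (the distance-decay expectation). The
#' resulting scores are NOT on any external normalizer's scale, so the
#' PTC cutoff must be re-estimated with [estimateCutoff()] rather than
#' taken from elsewhere.
#'
#' @param rawPairs data.frame of intra-chromosomal contacts: chrom,
#'   pos1, pos2 (bp).
#' @param grid the [GenomeGrid].
#' @param maxDistBp ignore pairs farther apart than this (default 4 Mb,
#'   comfortably beyond the 2 Mb scoring cap).
#' @return contact score set as from [loadContactScores()], one record
#'   per observed bin pair, positions at bin midpoints,
#'   `sourceTag = "fallback"`.
#' @export
fallbackScoreContacts <- function(rawPairs, grid, maxDistBp = 4e6) {
  if (nrow(rawPairs) == 0L)
    return(.contact_set(data.frame(chrom1 = character(), pos1 = integer(),
                                   chrom2 = character(), pos2 = integer(),
                                   score = numeric()), "fallback"))
  chrom <- as.character(rawPairs[[1L]])
  if (any(!chrom %in% seqlevels(gridBins(grid))))
    stop("unknown chromosome in raw pairs")
  bs <- binSize(grid)
  rngs <- .chrom_bin_ranges(grid)
  nb_per_chrom <- rngs[, 2L] - rngs[, 1L] + 1L
  b1 <- pmin((as.numeric(rawPairs[[2L]]) - 1) %/% bs,
             nb_per_chrom[chrom] - 1L)
  b2 <- pmin((as.numeric(rawPairs[[3L]]) - 1) %/% bs,
             nb_per_chrom[chrom] - 1L)
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  d <- hi - lo
  keep <- d * bs <= maxDistBp
  dt <- data.table::data.table(chrom = chrom[keep], b1 = lo[keep],
                               b2 = hi[keep], d = d[keep])
  obs <- dt[, list(observed = .N), by = c("chrom", "b1", "b2", "d")]
  # possible bin pairs at distance d, summed over chromosomes
  npairs_d <- vapply(sort(unique(obs$d)), function(dd)
    sum(pmax(0L, nb_per_chrom - dd)), numeric(1))
  names(npairs_d) <- sort(unique(obs$d))
  tot_d <- obs[, list(total = sum(observed)), by = "d"]
  expd <- setNames(tot_d$total / npairs_d[as.character(tot_d$d)],
                   tot_d$d)
  score <- log2((obs$observed + 1) / (expd[as.character(obs$d)] + 1))
  mid <- function(b) as.integer(b * bs + bs %/% 2L)
  .contact_set(data.frame(chrom1 = obs$chrom, pos1 = mid(obs$b1),
                          chrom2 = obs$chrom, pos2 = mid(obs$b2),
                          score = as.numeric(score)), "fallback")
}

#' Pool contact scores into segment-pair interaction medians
#'
#' Every intra-chromosomal contact whose two positions both fall into
#' segments contributes its score to that (possibly identical) segment
#' pair; the pooled statistic per pair is the median score. Intra-
#' segment entries (both ends in the same segment) are always kept;
#' inter-segment pairs are kept only when the segments are within
#' `dMaxBp` of each other, because normalized contact density decays
#' with distance and distant pairs carry too few contacts to pool.
#'
#' @param contacts contact score set ([loadContactScores()] /
#'   [fallbackScoreContacts()]).
#' @param segments segment `GRanges` (non-overlapping per chromosome).
#' @param dMaxBp inter-segment distance cap in bp (default 2e6). The
#'   distance is the gap between the closer ends (0 when adjacent);
#'   set `anchor = "midpoint"` for midpoint-to-midpoint distance.
#' @param anchor `"gap"` (default) or `"midpoint"`.
#' @return data.frame of class `InteractionTable` with columns seg_a,
#'   seg_b (seg_a == seg_b for intra entries; unordered pairs stored
#'   once with seg_a <= seg_b by segment order), median_score,
#'   n_contacts, distance_bp; attribute `nOutside` counts contacts that
#'   fell outside any segment.
#' @export
scoreSegmentPairs <- function(contacts, segments, dMaxBp = 2e6,
                              anchor = c("gap", "midpoint")) {
  anchor <- match.arg(anchor)
  same <- contacts$chrom1 == contacts$chrom2
  cc <- contacts[same, , drop = FALSE]
  ids <- mcols(segments)$segment_id
  empty <- data.frame(seg_a = character(), seg_b = character(),
                      median_score = numeric(), n_contacts = integer(),
                      distance_bp = numeric())
  class(empty) <- c("InteractionTable", "data.frame")
  if (nrow(cc) == 0L) {
    attr(empty, "nOutside") <- 0L
    return(empty)
  }
  p1 <- GRanges(cc$chrom1, IRanges(cc$pos1 + 1L, cc$pos1 + 1L))
  p2 <- GRanges(cc$chrom2, IRanges(cc$pos2 + 1L, cc$pos2 + 1L))
  h1 <- findOverlaps(p1, segments, select = "all")
  h2 <- findOverlaps(p2, segments, select = "all")
  dt1 <- data.table::data.table(ci = S4Vectors::queryHits(h1),
                                sa = S4Vectors::subjectHits(h1))
  dt2 <- data.table::data.table(ci = S4Vectors::queryHits(h2),
                                sb = S4Vectors::subjectHits(h2))
  dd <- merge(dt1, dt2, by = "ci", allow.cartesian = TRUE)
  nOutside <- nrow(cc) - length(unique(dd$ci))
  if (nrow(dd) == 0L) {
    attr(empty, "nOutside") <- nOutside
    return(empty)
  }
  dd[, `:=`(a = pmin(sa, sb), b = pmax(sa, sb))]
  dd[, score := cc$score[ci]]
  pooled <- dd[, list(median_score = median(score),
                      n_contacts = .N), by = c("a", "b")]

  segdist <- function(a, b) {
    if (anchor == "midpoint") {
      m <- (start(segments) + end(segments)) / 2
      abs(m[a] - m[b])
    } else {
      d <- GenomicRanges::distance(segments[a], segments[b])
      d[is.na(d)] <- 0  # overlap -> 0
      d
    }
  }
  dist_bp <- ifelse(pooled$a == pooled$b, 0,
                    segdist(pooled$a, pooled$b))
  keep <- pooled$a == pooled$b | dist_bp <= dMaxBp
  out <- data.frame(seg_a = ids[pooled$a[keep]],
                    seg_b = ids[pooled$b[keep]],
                    median_score = pooled$median_score[keep],
                    n_contacts = pooled$n_contacts[keep],
                    distance_bp = as.numeric(dist_bp[keep]))
  out <- out[order(match(out$seg_a, ids), match(out$seg_b, ids)), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("InteractionTable", "data.frame")
  attr(out, "nOutside") <- nOutside
  out
}

#' Look up the pooled score of a segment pair
#'
#' The table stores each unordered pair once; this accessor is
#' symmetric in its arguments.
#'
#' @param table an `InteractionTable`.
#' @param a,b segment ids.
#' @return median score, or NA if the pair is absent.
#' @export
pairScore <- function(table, a, b) {
  i <- (table$seg_a == a & table$seg_b == b) |
    (table$seg_a == b & table$seg_b == a)
  if (!any(i)) NA_real_ else table$median_score[which(i)[1L]]
}

# random re-placement of segments (same bin lengths, chromosome chosen
# proportional to valid start bins), as a GRanges; overlaps allowed
.shuffle_segments <- function(segments, grid) {
  bins <- gridBins(grid)
  rngs <- .chrom_bin_ranges(grid)
  bs <- binSize(grid)
  lens <- mcols(segments)$n_bins
  chroms <- rownames(rngs)
  nb <- rngs[, 2L] - rngs[, 1L] + 1L
  placed <- lapply(seq_along(segments), function(i) {
    nvalid <- pmax(0L, nb - lens[i] + 1L)
    if (sum(nvalid) == 0L) stop("segment too long to place")
    pick <- sample.int(sum(nvalid), 1L)
    offs <- c(0L, cumsum(nvalid))
    ci <- findInterval(pick - 1L, offs[-length(offs)])
    ci <- min(ci, length(chroms))
    sbin <- (pick - offs[ci] - 1L)  # 0-based within chromosome
    st <- sbin * bs + 1L
    en <- min(st + lens[i] * bs - 1L, seqlengths(bins)[[chroms[ci]]])
    GRanges(chroms[ci], IRanges(st, en))
  })
  out <- suppressWarnings(do.call(c, placed))
  seqlevels(out) <- seqlevels(bins)
  seqlengths(out) <- seqlengths(bins)
  mcols(out)$segment_id <- mcols(segments)$segment_id
  mcols(out)$n_bins <- lens
  out
}

#' Estimate the PTC score cutoff by permutation
#'
#' For each candidate cutoff c the objective is the number of true
#' segment-pair entries with median score >= c minus the mean, over
#' permutations, of the same count computed after randomly re-placing
#' the segments (same lengths, uniform over the genome). The returned
#' cutoff maximizes this signal-minus-background count; ties break
#' toward the smallest cutoff. With several conditions (e.g.
#' timepoints), `combine = "mean_over_conditions"` averages the
#' per-condition objectives before the argmax.
#'
#' @param contacts one contact score set, or a list of them (one per
#'   condition) when combining.
#' @param segments segment `GRanges`, or a list parallel to `contacts`.
#' @param grid the [GenomeGrid] the segments live on (one, shared by
#'   all conditions), used to re-place segments.
#' @param nPerm number of permutations (default 100).
#' @param cutoffGrid candidate cutoffs; default integer grid spanning
#'   the observed score range.
#' @param dMaxBp distance cap passed to [scoreSegmentPairs()].
#' @param combine `"single"` or `"mean_over_conditions"`.
#' @return list with `cutoff` (the argmax), `grid`, `objective`.
#'   Seed via `set.seed()` before calling for reproducibility.
#' @export
estimateCutoff <- function(contacts, segments, grid, nPerm = 100L,
                           cutoffGrid = NULL, dMaxBp = 2e6,
                           combine = c("single", "mean_over_conditions")) {
  combine <- match.arg(combine)
  stopifnot(is(grid, "GenomeGrid"))
  if (combine == "single") {
    contacts <- list(contacts); segments <- list(segments)
  }
  stopifnot(length(contacts) == length(segments), nPerm >= 1L)
  if (is.null(cutoffGrid)) {
    allsc <- unlist(lapply(contacts, function(cc) cc$score))
    if (length(allsc) == 0L) stop("no contacts to estimate a cutoff from")
    cutoffGrid <- seq(floor(min(allsc)), ceiling(max(allsc)), by = 1)
  }
  objs <- matrix(0, nrow = length(contacts), ncol = length(cutoffGrid))
  for (ci in seq_along(contacts)) {
    segs <- segments[[ci]]
    true_tab <- scoreSegmentPairs(contacts[[ci]], segs, dMaxBp)
    if (nrow(true_tab) == 0L) stop("empty interaction table")
    ntrue <- vapply(cutoffGrid, function(c0)
      sum(true_tab$median_score >= c0), numeric(1))
    nrand <- matrix(0, nrow = nPerm, ncol = length(cutoffGrid))
    for (p in seq_len(nPerm)) {
      rsegs <- .shuffle_segments(segs, grid)
      rtab <- scoreSegmentPairs(contacts[[ci]], rsegs, dMaxBp)
      if (nrow(rtab) > 0L)
        nrand[p, ] <- vapply(cutoffGrid, function(c0)
          sum(rtab$median_score >= c0), numeric(1))
    }
    objs[ci, ] <- ntrue - colMeans(nrand)
  }
  obj <- colMeans(objs)
  list(cutoff = cutoffGrid[which.max(obj)], grid = cutoffGrid,
       objective = obj)
}

#' Call putative transcriptional condensates (PTCs)
#'
#' Builds a graph whose nodes are enhancer-enriched segments: an edge
#' joins two distinct enriched segments when their pooled median score
#' is at or above the cutoff (and they are within `dMaxBp`); a segment
#' with no qualifying edge still enters alone when its intra-segment
#' median passes the cutoff (condensate hubs of a single segment are
#' real). PTCs are the connected components of this graph.
#'
#' @param table an `InteractionTable` from [scoreSegmentPairs()].
#' @param annot annotation `DataFrame` from [annotateSegments()].
#' @param segments segment `GRanges` (for spans).
#' @param cutoff inclusive score threshold (finite).
#' @param dMaxBp inter-segment distance cap (default 2e6).
#' @param condition optional condition label stored on each PTC.
#' @return `GRanges` of PTC spans (per component: min start to max end
#'   on its chromosome) with mcols `ptc_id`, `n_segments`, `members`
#'   (CharacterList), `condition`; and attribute `edges`, the
#'   qualifying edge list.
#' @export
callPTCs <- function(table, annot, segments, cutoff, dMaxBp = 2e6,
                     condition = NA_character_) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  enriched <- annot$segment_id[annot$label == "enhancer_enriched"]
  inter <- table[table$seg_a != table$seg_b &
                   table$median_score >= cutoff &
                   table$distance_bp <= dMaxBp &
                   table$seg_a %in% enriched &
                   table$seg_b %in% enriched, , drop = FALSE]
  intra <- table[table$seg_a == table$seg_b &
                   table$median_score >= cutoff &
                   table$seg_a %in% enriched, , drop = FALSE]
  nodes <- union(union(inter$seg_a, inter$seg_b), intra$seg_a)
  edges <- inter[, c("seg_a", "seg_b", "median_score")]
  empty <- GRanges()
  mcols(empty)$ptc_id <- character(0)
  mcols(empty)$n_segments <- integer(0)
  mcols(empty)$members <- IRanges::CharacterList()
  mcols(empty)$condition <- character(0)
  if (length(nodes) == 0L) {
    attr(empty, "edges") <- edges
    return(empty)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("seg_a", "seg_b")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  # deterministic order: by first member's segment order
  ids <- mcols(segments)$segment_id
  ord <- order(vapply(members, function(m) min(match(m, ids)), numeric(1)))
  members <- members[ord]
  spans <- lapply(members, function(m) {
    s <- segments[match(m, ids)]
    GRanges(as.character(seqnames(s))[1L],
            IRanges(min(start(s)), max(end(s))))
  })
  out <- suppressWarnings(do.call(c, unname(spans)))
  seqlevels(out) <- seqlevels(segments)
  seqlengths(out) <- seqlengths(segments)
  mcols(out)$ptc_id <- sprintf("PTC%03d", seq_along(out))
  mcols(out)$n_segments <- lengths(members)
  mcols(out)$members <- IRanges::CharacterList(unname(members))
  mcols(out)$condition <- condition
  attr(out, "edges") <- edges
  out
}

#' Count PTCs of one condition overlapping any PTC of another
#'
#' Asymmetric: how many PTCs in `ptcsA` overlap (>= 1 bp of genomic
#' span) at least one PTC in `ptcsB`; a PTC overlapping several
#' counterparts counts once.
#'
#' @param ptcsA,ptcsB PTC `GRanges` from [callPTCs()].
#' @return integer count.
#' @export
overlapPTCs <- function(ptcsA, ptcsB) {
  if (length(ptcsA) == 0L || length(ptcsB) == 0L) return(0L)
  length(unique(S4Vectors::queryHits(suppressWarnings(
    findOverlaps(ptcsA, ptcsB, ignore.strand = TRUE)))))
}

#' Write a PTC table as TSV
#'
#' One row per PTC: ptc_id, condition, comma-separated member segment
#' ids, chrom, span_start (0-based), span_end.
#'
#' @param ptcs PTC `GRanges` from [callPTCs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePtcTable <- function(ptcs, path) {
  df <- data.frame(
    ptc_id = mcols(ptcs)$ptc_id,
    condition = mcols(ptcs)$condition,
    members = vapply(mcols(ptcs)$members, paste, character(1),
                     collapse = ","),
    chrom = as.character(seqnames(ptcs)),
    span_start = start(ptcs) - 1L,
    span_end = end(ptcs))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
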